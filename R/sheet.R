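#' The canonical 40-vertex Fuchsine unit template
#'
#' Degree-based indices of the sheet depend on the unit only through its edge
#' partition, which for one Fuchsine unit is 24 edges between degree-3
#' vertices and 18 pendant edges (degree pair (1,3)).  The canonical template
#' realises exactly that partition with a minimal, easily verified
#' construction: a 22-cycle `c0..c21` (22 edges), two chords `c0--c11` and
#' `c5--c16` (2 edges), and one pendant `p_i` on every cycle vertex except
#' the four chord endpoints (18 pendant edges).  Every core vertex then has
#' degree 3.  Four pendants are designated as attachment ports for sheet
#' assembly: W = p2, E = p13, N = p8, S = p19.
#'
#' @return a `fuchsine_unit`: list with `graph` (igraph, 40 vertices and 42
#'   edges) and `ports` (named character vector W/E/N/S of pendant names).
#' @examples
#' u <- canonical_unit()
#' edge_partition(u)
#' @export
canonical_unit <- function() {
  core <- paste0("c", 0:21)
  cyc <- cbind(core, core[c(2:22, 1)])
  chords <- rbind(c("c0", "c11"), c("c5", "c16"))
  pend_idx <- setdiff(0:21, c(0, 5, 11, 16))
  pend <- rbind(paste0("c", pend_idx), paste0("p", pend_idx))
  edges <- rbind(cyc, chords, t(pend))
  g <- igraph::graph_from_edgelist(edges, directed = FALSE)
  t <- structure(list(graph = g,
                      ports = c(W = "p2", E = "p13", N = "p8", S = "p19")),
                 class = "fuchsine_unit")
  t
}

#' Validate a unit template
#'
#' Checks the contract every usable unit template must satisfy: 40 vertices,
#' 42 edges, edge partition {(3,3): 24, (1,3): 18}, simple and connected,
#' and four distinct ports, each a pendant whose unique neighbour has
#' degree 3.
#'
#' @param t a `fuchsine_unit`.
#' @return character vector of violations; empty if valid.
#' @export
validate_unit_template <- function(t) {
  out <- character(0)
  g <- t$graph
  out <- c(out, validate_graph(g))
  nv <- igraph::vcount(g)
  ne <- igraph::ecount(g)
  if (nv != 40L) out <- c(out, sprintf("unit must have 40 vertices, found %d", nv))
  if (ne != 42L) out <- c(out, sprintf("unit must have 42 edges, found %d", ne))
  p <- edge_partition(g)
  if (!(nrow(p) == 2L && partition_count(p, 3, 3) == 24L &&
        partition_count(p, 1, 3) == 18L))
    out <- c(out, "unit edge partition must be {(3,3): 24, (1,3): 18}")
  ports <- t$ports
  if (!identical(sort(names(ports)), c("E", "N", "S", "W")))
    out <- c(out, "ports must be named W, E, N, S")
  if (anyDuplicated(ports))
    out <- c(out, "ports must be four distinct vertices")
  deg <- degree_map(g)
  for (side in names(ports)) {
    v <- ports[[side]]
    if (!v %in% names(deg)) {
      out <- c(out, sprintf("port %s vertex '%s' not in graph", side, v))
      next
    }
    if (deg[[v]] != 1L)
      out <- c(out, sprintf("port %s vertex '%s' must be a pendant (degree 1), found degree %d",
                            side, v, deg[[v]]))
    else {
      nb <- igraph::neighbors(g, v)$name
      if (deg[[nb]] != 3L)
        out <- c(out, sprintf("port %s neighbour '%s' must have degree 3", side, nb))
    }
  }
  out
}

#' @export
print.fuchsine_unit <- function(x, ...) {
  cat("Fuchsine unit template:", igraph::vcount(x$graph), "vertices,",
      igraph::ecount(x$graph), "edges\n")
  cat("ports:", paste(names(x$ports), x$ports, sep = "=", collapse = " "), "\n")
  invisible(x)
}

#' Fuse two pendant vertices into one degree-2 connector
#'
#' Identifies pendants `u` and `v` into a single vertex named `u+v`.  The
#' vertex count drops by exactly one and the edge count is unchanged, which
#' is what the sheet's printed counts (38mn+m+n vertices, 42mn edges) force:
#' units are joined on a common vertex, not by inserting a bridge edge.
#'
#' @param g an undirected igraph graph.
#' @param u,v names of two distinct pendant vertices with distinct neighbours.
#' @return the fused igraph graph.
#' @export
fuse_pendants <- function(g, u, v) {
  g <- get_graph(g)
  if (identical(u, v)) stop("cannot fuse a pendant with itself")
  deg <- igraph::degree(g)
  for (w in c(u, v)) {
    if (!w %in% names(deg)) stop(sprintf("vertex '%s' not in graph", w))
    if (deg[[w]] != 1L)
      stop(sprintf("vertex '%s' is not a pendant (degree %d)", w, deg[[w]]))
  }
  nu <- igraph::neighbors(g, u)$name
  nv <- igraph::neighbors(g, v)$name
  if (identical(nu, nv))
    stop(sprintf("pendants '%s' and '%s' hang off the same vertex '%s'", u, v, nu))
  fused <- paste(u, v, sep = "+")
  ends <- igraph::as_edgelist(g, names = TRUE)
  ends[ends == u | ends == v] <- fused
  igraph::graph_from_edgelist(ends, directed = FALSE)
}

#' Build the supramolecular Fuchsine sheet F[m, n]
#'
#' Lays out an m-by-n grid of unit copies (columns i = 1..m, rows j = 1..n)
#' and joins neighbours by pendant fusion: the E port of unit (i, j) with the
#' W port of unit (i+1, j) within each row, and the S port of unit (i, j)
#' with the N port of unit (i, j+1) across rows.  The result has
#' 38mn + m + n vertices, 42mn edges, and edge partition
#' {(3,3): 24mn, (1,3): 14mn + 2(m+n), (2,3): 4mn - 2m - 2n}.
#'
#' @param m,n positive integers: units per row, and number of rows.
#' @param template unit template; defaults to [canonical_unit()].
#' @return a `fuchsine_sheet`: list with `graph` (igraph), `m`, `n`.
#' @examples
#' s <- build_sheet(2, 2)
#' s
#' @export
build_sheet <- function(m, n, template = canonical_unit()) {
  if (!(length(m) == 1L && length(n) == 1L && m == round(m) && n == round(n) &&
        m >= 1 && n >= 1))
    stop("m and n must be integers >= 1")
  bad <- validate_unit_template(template)
  if (length(bad))
    stop("invalid unit template:\n  ", paste(bad, collapse = "\n  "))
  ends0 <- igraph::as_edgelist(template$graph, names = TRUE)
  ports <- template$ports
  all_ends <- vector("list", m * n)
  k <- 0L
  for (j in seq_len(n)) for (i in seq_len(m)) {
    k <- k + 1L
    pre <- sprintf("u%d.%d_", i, j)
    all_ends[[k]] <- matrix(paste0(pre, ends0), ncol = 2L)
  }
  g <- igraph::graph_from_edgelist(do.call(rbind, all_ends), directed = FALSE)
  at <- function(i, j, side) sprintf("u%d.%d_%s", i, j, ports[[side]])
  for (j in seq_len(n)) for (i in seq_len(m)) {
    if (i < m) g <- fuse_pendants(g, at(i, j, "E"), at(i + 1L, j, "W"))
    if (j < n) g <- fuse_pendants(g, at(i, j, "S"), at(i, j + 1L, "N"))
  }
  # canonical deterministic vertex order (lexicographic on the u<i>.<j>_<local> names)
  g <- igraph::permute(g, rank(igraph::V(g)$name))
  structure(list(graph = g, m = m, n = n), class = "fuchsine_sheet")
}

#' @export
print.fuchsine_sheet <- function(x, ...) {
  cat(sprintf("Fuchsine sheet F[%d, %d]: %d vertices, %d edges\n",
              x$m, x$n, igraph::vcount(x$graph), igraph::ecount(x$graph)))
  invisible(x)
}

#' @export
summary.fuchsine_sheet <- function(object, ...) {
  p <- edge_partition(object)
  deg <- degree_map(object)
  cat(sprintf("Fuchsine sheet F[%d, %d]\n", object$m, object$n))
  cat(sprintf("  vertices: %d   edges: %d   connector (degree-2) vertices: %d\n",
              igraph::vcount(object$graph), igraph::ecount(object$graph),
              sum(deg == 2L)))
  print(p)
  invisible(p)
}

#' @export
plot.fuchsine_sheet <- function(x, ...) {
  deg <- degree_map(x)
  cols <- c("grey70", "steelblue", "black")[pmin(deg, 3L)]
  plot(x$graph, vertex.size = 3, vertex.label = NA, vertex.color = cols,
       main = sprintf("F[%d, %d]", x$m, x$n), ...)
  invisible(x)
}

#' Write / read a unit template file
#'
#' Plain-text format: lines `edge u v` and `port W|E|N|S v`; blank lines and
#' `#` comments ignored; vertex names are arbitrary tokens.  On read, the
#' full unit-template contract is enforced and every violation is reported.
#'
#' @param t a `fuchsine_unit`.
#' @param path file path.
#' @export
write_template <- function(t, path) {
  ends <- igraph::as_edgelist(t$graph, names = TRUE)
  lines <- c("# Fuchsine unit template",
             sprintf("edge %s %s", ends[, 1L], ends[, 2L]),
             sprintf("port %s %s", names(t$ports), t$ports))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_template
#' @export
read_template <- function(path) {
  lines <- readLines(path)
  edges <- NULL
  ports <- character(0)
  for (i in seq_along(lines)) {
    ln <- trimws(lines[i])
    if (!nzchar(ln) || startsWith(ln, "#")) next
    tok <- strsplit(ln, "[[:space:]]+")[[1L]]
    if (tok[1L] == "edge" && length(tok) == 3L) {
      edges <- rbind(edges, tok[2:3])
    } else if (tok[1L] == "port" && length(tok) == 3L) {
      if (!tok[2L] %in% c("W", "E", "N", "S"))
        stop(sprintf("line %d: unknown port side '%s'", i, tok[2L]))
      if (tok[2L] %in% names(ports))
        stop(sprintf("line %d: duplicate port %s", i, tok[2L]))
      ports[tok[2L]] <- tok[3L]
    } else {
      stop(sprintf("line %d: malformed line '%s'", i, lines[i]))
    }
  }
  if (is.null(edges)) stop("template file lists no edges")
  missing_ports <- setdiff(c("W", "E", "N", "S"), names(ports))
  if (length(missing_ports))
    stop("template file missing port line(s): ", paste(missing_ports, collapse = ", "))
  g <- igraph::graph_from_edgelist(edges, directed = FALSE)
  t <- structure(list(graph = g, ports = ports[c("W", "E", "N", "S")]),
                 class = "fuchsine_unit")
  bad <- validate_unit_template(t)
  if (length(bad))
    stop("invalid unit template:\n  ", paste(bad, collapse = "\n  "))
  t
}
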