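#' Degree map of a graph
#'
#' @param g an undirected [igraph::igraph] graph, a [fuchsine_unit], or a
#'   [fuchsine_sheet].
#' @return a named integer vector mapping each vertex name to its degree.
#' @export
degree_map <- function(g) {
  g <- get_graph(g)
  igraph::degree(g)
}

get_graph <- function(g) {
  if (inherits(g, "fuchsine_sheet") || inherits(g, "fuchsine_unit")) return(g$graph)
  if (igraph::is_igraph(g)) {
    if (igraph::is_directed(g)) stop("graph must be undirected")
    return(g)
  }
  stop("not a graph: expected an igraph, fuchsine_unit or fuchsine_sheet")
}

#' Edge partition by endpoint degrees
#'
#' Tallies the edges of a graph by the unordered pair of endpoint degrees,
#' stored canonically as (lo, hi) with lo <= hi.  The partition is a
#' sufficient statistic for every degree-based topological index.
#'
#' @inheritParams degree_map
#' @return an `edge_partition`: a data frame with columns `lo`, `hi`,
#'   `count`, sorted by (lo, hi); counts sum to the edge count.
#' @examples
#' edge_partition(build_sheet(1, 1))   # 24 edges (3,3), 18 edges (1,3)
#' @export
edge_partition <- function(g) {
  g <- get_graph(g)
  deg <- igraph::degree(g)
  ends <- igraph::as_edgelist(g, names = TRUE)
  if (nrow(ends) == 0L) {
    out <- data.frame(lo = integer(0), hi = integer(0), count = integer(0))
    class(out) <- c("edge_partition", "data.frame")
    return(out)
  }
  d1 <- deg[ends[, 1L]]
  d2 <- deg[ends[, 2L]]
  lo <- pmin(d1, d2)
  hi <- pmax(d1, d2)
  tab <- table(paste(lo, hi, sep = ","))
  key <- do.call(rbind, strsplit(names(tab), ",", fixed = TRUE))
  out <- data.frame(lo = as.integer(key[, 1L]), hi = as.integer(key[, 2L]),
                    count = as.integer(tab))
  out <- out[order(out$lo, out$hi), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("edge_partition", "data.frame")
  out
}

#' Look up one count in an edge partition (0 if the pair is absent)
#' @param p an `edge_partition`.
#' @param lo,hi the canonical degree pair.
#' @export
partition_count <- function(p, lo, hi) {
  stopifnot(inherits(p, "edge_partition"), lo <= hi)
  i <- which(p$lo == lo & p$hi == hi)
  if (length(i)) p$count[i] else 0L
}

#' @export
print.edge_partition <- function(x, ...) {
  cat("Edge partition (", sum(x$count), " edges):\n", sep = "")
  for (i in seq_len(nrow(x)))
    cat(sprintf("  (%d, %d): %d\n", x$lo[i], x$hi[i], x$count[i]))
  invisible(x)
}

#' Validate that a graph is simple and connected
#'
#' Violations are returned as data, not raised as errors: an empty character
#' vector means the graph is a valid simple connected graph.  The empty graph
#' is accepted (sheet-level constructors impose their own requirements).
#'
#' @inheritParams degree_map
#' @return character vector of human-readable violation descriptions.
#' @export
validate_graph <- function(g) {
  g <- get_graph(g)
  out <- character(0)
  loops <- which(igraph::which_loop(g))
  for (e in loops) {
    v <- igraph::as_edgelist(g, names = TRUE)[e, 1L]
    out <- c(out, sprintf("self-loop at vertex '%s'", v))
  }
  multi <- which(igraph::which_multiple(g))
  for (e in multi) {
    ends <- igraph::as_edgelist(g, names = TRUE)[e, ]
    out <- c(out, sprintf("duplicate edge '%s'--'%s'", ends[1L], ends[2L]))
  }
  if (igraph::vcount(g) > 0L && !igraph::is_connected(g)) {
    comp <- igraph::components(g)
    small <- which(comp$membership != which.max(comp$csize)[1L])
    out <- c(out, sprintf(
      "graph is disconnected (%d components; e.g. vertex '%s' is separated)",
      comp$no, names(small)[1L]))
  }
  out
}

#' Write / read a graph as a plain-text edge list
#'
#' Format: a header line `# vertices=<N> edges=<M>` followed by one
#' `u<TAB>v` line per edge.  Isolated vertices cannot be represented and are
#' rejected on write; on read the header counts are checked against the body.
#'
#' @inheritParams degree_map
#' @param path file path.
#' @export
write_edgelist <- function(g, path) {
  g <- get_graph(g)
  if (any(igraph::degree(g) == 0L))
    stop("edge-list format cannot represent isolated vertices")
  ends <- igraph::as_edgelist(g, names = TRUE)
  lines <- c(sprintf("# vertices=%d edges=%d", igraph::vcount(g), igraph::ecount(g)),
             sprintf("%s\t%s", ends[, 1L], ends[, 2L]))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_edgelist
#' @return `read_edgelist` returns an undirected igraph graph.
#' @export
read_edgelist <- function(path) {
  lines <- readLines(path)
  if (!length(lines) || !grepl("^# vertices=\\d+ edges=\\d+$", lines[1L]))
    stop("missing or malformed header line '# vertices=<N> edges=<M>'")
  nv <- as.integer(sub("^# vertices=(\\d+) edges=\\d+$", "\\1", lines[1L]))
  ne <- as.integer(sub("^# vertices=\\d+ edges=(\\d+)$", "\\1", lines[1L]))
  body <- lines[-1L]
  body <- body[nzchar(body)]
  if (length(body) != ne)
    stop(sprintf("header declares %d edges but file lists %d", ne, length(body)))
  parts <- strsplit(body, "\t", fixed = TRUE)
  bad <- which(lengths(parts) != 2L)
  if (length(bad))
    stop(sprintf("line %d: expected 'u<TAB>v'", bad[1L] + 1L))
  ends <- do.call(rbind, parts)
  g <- igraph::graph_from_edgelist(ends, directed = FALSE)
  if (igraph::vcount(g) != nv)
    stop(sprintf("header declares %d vertices but edges mention %d",
                 nv, igraph::vcount(g)))
  g
}

#' Write a graph in GraphML for interoperability with graph tooling
#' @inheritParams write_edgelist
#' @export
write_graphml <- function(g, path) {
  g <- get_graph(g)
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}

# round to nearest integer, halves away from zero (the convention every
# reproducible published table cell is consistent with)
round_half_away <- function(x) sign(x) * floor(abs(x) + 0.5)
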