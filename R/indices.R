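#' Degree-based topological index specifications
#'
#' A degree-based index has the form \eqn{\sum_{uv \in E} f(d_u, d_v)} for a
#' symmetric edge function \eqn{f}.  Supported indices:
#' \describe{
#'   \item{M1}{first Zagreb, \eqn{d_u + d_v}}
#'   \item{M2}{second Zagreb, \eqn{d_u d_v}}
#'   \item{HM}{hyper-Zagreb, \eqn{(d_u + d_v)^2}}
#'   \item{H}{harmonic, \eqn{2/(d_u + d_v)}}
#'   \item{F}{forgotten, \eqn{d_u^2 + d_v^2}}
#'   \item{ABC}{atom-bond connectivity, \eqn{\sqrt{(d_u + d_v - 2)/(d_u d_v)}}}
#'   \item{GA}{geometric-arithmetic, \eqn{2\sqrt{d_u d_v}/(d_u + d_v)}}
#'   \item{R}{general Randic, \eqn{(d_u d_v)^\lambda}; `lambda = -1/2` is the
#'     classical Randic branching index}
#' }
#'
#' @param name one of "M1", "M2", "HM", "H", "F", "ABC", "GA", "R".
#' @param lambda exponent for the general Randic index (required iff
#'   `name == "R"`).
#' @return an `index_spec`.
#' @export
index_spec <- function(name, lambda = NULL) {
  name <- match.arg(name, c("M1", "M2", "HM", "H", "F", "ABC", "GA", "R"))
  if (name == "R") {
    if (is.null(lambda) || !is.finite(lambda))
      stop("the general Randic index needs a finite exponent lambda")
  } else if (!is.null(lambda)) {
    stop("lambda is only meaningful for the general Randic index")
  }
  label <- if (name == "R") paste0("R", format_lambda(lambda)) else name
  structure(list(name = name, lambda = lambda, label = label),
            class = "index_spec")
}

format_lambda <- function(lambda) {
  for (den in 1:4) if (abs(lambda * den - round(lambda * den)) < 1e-12) {
    num <- round(lambda * den)
    return(if (den == 1L) format(num) else paste0(num, "/", den))
  }
  format(lambda)
}

#' @export
print.index_spec <- function(x, ...) {
  cat("<index_spec>", x$label, "\n")
  invisible(x)
}

#' The index set used throughout the sheet analysis
#'
#' M1, M2, HM, H, F, ABC, GA and the general Randic index at the four
#' exponents with closed forms on this family (1, -1, 1/2, -1/2).
#'
#' @return named list of `index_spec` objects, keyed by label.
#' @export
all_index_specs <- function() {
  specs <- c(lapply(c("M1", "M2", "HM", "H", "F", "ABC", "GA"), index_spec),
             lapply(c(1, -1, 1 / 2, -1 / 2), function(l) index_spec("R", l)))
  names(specs) <- vapply(specs, `[[`, "", "label")
  specs
}

#' Per-edge value of an index at a degree pair
#'
#' The numeric path is defined for all positive integer degrees.  The exact
#' path returns a [surd] whenever the value lies in the ring
#' Q + Q*sqrt(2) + Q*sqrt(3) + Q*sqrt(6) — which covers all sheet degree
#' pairs (1,3), (2,3), (3,3) for every supported index — and otherwise
#' falls back to the numeric value with a warning.
#'
#' @param spec an [index_spec].
#' @param d_u,d_v positive integer endpoint degrees.
#' @param exact return a `surd` (TRUE) or a double (FALSE).
#' @export
edge_value <- function(spec, d_u, d_v, exact = FALSE) {
  stopifnot(inherits(spec, "index_spec"))
  if (d_u < 1 || d_v < 1 || d_u != round(d_u) || d_v != round(d_v))
    stop("degrees must be positive integers")
  if (!exact) return(edge_value_num(spec, d_u, d_v))
  v <- edge_value_exact(spec, d_u, d_v)
  if (is.null(v)) {
    warning(sprintf(
      "%s at degree pair (%d, %d) has no exact surd representation; using float",
      spec$label, d_u, d_v))
    return(edge_value_num(spec, d_u, d_v))
  }
  v
}

edge_value_num <- function(spec, d_u, d_v) {
  s <- d_u + d_v
  p <- d_u * d_v
  switch(spec$name,
    M1 = s,
    M2 = p,
    HM = s^2,
    H = 2 / s,
    F = d_u^2 + d_v^2,
    ABC = sqrt((s - 2) / p),
    GA = 2 * sqrt(p) / s,
    R = p^spec$lambda)
}

# exact per-edge value, or NULL when it leaves the surd ring
edge_value_exact <- function(spec, d_u, d_v) {
  s <- d_u + d_v
  p <- d_u * d_v
  switch(spec$name,
    M1 = surd(s),
    M2 = surd(p),
    HM = surd(s^2),
    H = surd(c(2, s)),
    F = surd(d_u^2 + d_v^2),
    ABC = surd_sqrt(s - 2, p),
    GA = {
      r <- surd_sqrt(p)
      if (is.null(r)) NULL else r * surd(c(2, s))
    },
    R = {
      l <- spec$lambda
      if (abs(l - round(l)) < 1e-12) {
        l <- round(l)
        if (l >= 0) surd(p^l) else surd(c(1, p^(-l)))
      } else if (abs(abs(l) - 0.5) < 1e-12) {
        r <- surd_sqrt(p)
        if (is.null(r)) NULL
        else if (l > 0) r else r * surd(c(1, p))  # 1/sqrt(p) = sqrt(p)/p
      } else NULL
    })
}

#' Compute a topological index by direct edge summation
#'
#' Walks every edge of the graph, evaluates the index's edge function at the
#' endpoint degrees, and sums.  This is the definitional route; it is the
#' oracle the partition-based and closed-form routes are checked against.
#'
#' @inheritParams degree_map
#' @param spec an [index_spec].
#' @param exact sum exactly in the surd ring (TRUE) or in doubles (FALSE).
#' @return a double, or a [surd] when `exact = TRUE`.
#' @examples
#' compute_index(build_sheet(1, 1), index_spec("M1"))          # 216
#' compute_index(build_sheet(1, 1), index_spec("H"), exact = TRUE)  # 17
#' @export
compute_index <- function(g, spec, exact = FALSE) {
  g <- get_graph(g)
  deg <- igraph::degree(g)
  ends <- igraph::as_edgelist(g, names = TRUE)
  d1 <- deg[ends[, 1L]]
  d2 <- deg[ends[, 2L]]
  if (!exact) {
    if (!nrow(ends)) return(0)
    return(sum(mapply(function(a, b) edge_value_num(spec, a, b), d1, d2)))
  }
  acc <- surd(0)
  cache <- new.env(parent = emptyenv())   # per-edge values recur; cache by pair
  for (i in seq_len(nrow(ends))) {
    key <- paste0(min(d1[[i]], d2[[i]]), ",", max(d1[[i]], d2[[i]]))
    v <- get0(key, envir = cache)
    if (is.null(v)) {
      v <- edge_value(spec, d1[[i]], d2[[i]], exact = TRUE)
      assign(key, v, envir = cache)
    }
    acc <- acc + v
  }
  acc
}

#' Compute a topological index from an edge partition
#'
#' \eqn{\sum_{(a,b)} count(a,b) \cdot f(a,b)}: since the partition is a
#' sufficient statistic for any degree-based index, this must agree exactly
#' with [compute_index()] on the source graph.
#'
#' @param p an [edge_partition].
#' @inheritParams compute_index
#' @export
compute_from_partition <- function(p, spec, exact = FALSE) {
  stopifnot(inherits(p, "edge_partition"))
  if (!exact) {
    if (!nrow(p)) return(0)
    return(sum(mapply(function(a, b, k) k * edge_value_num(spec, a, b),
                      p$lo, p$hi, p$count)))
  }
  acc <- surd(0)
  for (i in seq_len(nrow(p)))
    acc <- acc + surd(p$count[i]) * edge_value(spec, p$lo[i], p$hi[i], exact = TRUE)
  acc
}

#' General Randic index by direct float summation
#'
#' @inheritParams degree_map
#' @param lambda finite real exponent; `lambda = 0` gives the edge count,
#'   `lambda = 1` coincides with the second Zagreb index.
#' @export
general_randic <- function(g, lambda) {
  compute_index(g, index_spec("R", lambda))
}
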