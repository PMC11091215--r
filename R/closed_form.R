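#' Bilinear closed forms c_mn*mn + c_m*m + c_n*n + c_1
#'
#' Every degree-based index of the sheet family F[m, n] is a bilinear
#' function of the dimensions, because the edge partition itself is: each
#' degree-pair count is of the form a*mn + b*m + c*n + d.  Coefficients are
#' exact [surd] values.
#'
#' @param c_mn,c_m,c_n,c_1 coefficients; surds, whole numbers or `c(num, den)`
#'   fractions.
#' @return a `bilinear_poly`.
#' @export
bilinear_poly <- function(c_mn = 0, c_m = 0, c_n = 0, c_1 = 0) {
  coef <- lapply(list(c_mn = c_mn, c_m = c_m, c_n = c_n, c_1 = c_1),
                 function(x) if (is_surd(x)) x else do.call(surd, list(x)))
  structure(coef, class = "bilinear_poly")
}

#' Evaluate a bilinear form at integer (m, n), exactly
#' @param p a [bilinear_poly].
#' @param m,n positive integers.
#' @param exact return a [surd] (TRUE, default) or a double.
#' @export
eval_bilinear <- function(p, m, n, exact = TRUE) {
  stopifnot(inherits(p, "bilinear_poly"), m == round(m), n == round(n))
  v <- p$c_mn * surd(m * n) + p$c_m * surd(m) + p$c_n * surd(n) + p$c_1
  if (exact) v else as.numeric(v)
}

#' @export
format.bilinear_poly <- function(x, ...) {
  term <- function(s, basis) {
    if (s == surd(0)) return(NULL)
    f <- format(s)
    if (grepl("[+-]", substr(f, 2, nchar(f)))) f <- paste0("(", f, ")")
    if (!nzchar(basis)) f else paste0(f, "*", basis)
  }
  parts <- unlist(c(term(x$c_mn, "mn"), term(x$c_m, "m"), term(x$c_n, "n"),
                    term(x$c_1, "")))
  if (is.null(parts)) return("0")
  out <- parts[1L]
  for (p in parts[-1L]) {
    out <- if (startsWith(p, "-")) paste(out, "-", substring(p, 2L))
           else paste(out, "+", p)
  }
  out
}

#' @export
print.bilinear_poly <- function(x, ...) {
  cat("<bilinear> ", format(x), "\n", sep = "")
  invisible(x)
}

bilinear_equal <- function(p, q) {
  p$c_mn == q$c_mn && p$c_m == q$c_m && p$c_n == q$c_n && p$c_1 == q$c_1
}

bilinear_subtract <- function(p, q) {
  bilinear_poly(p$c_mn - q$c_mn, p$c_m - q$c_m, p$c_n - q$c_n, p$c_1 - q$c_1)
}

#' Symbolic edge partition of F[m, n]
#'
#' The three degree-pair counts as bilinear polynomials in (m, n):
#' (3,3): 24mn; (1,3): 14mn + 2m + 2n; (2,3): 4mn - 2m - 2n.
#' The last expands n(2m-2) + 2m(n-1): each of the 2mn - m - n pendant
#' fusions creates one degree-2 connector carrying two (2,3) edges.
#' The three polynomials sum to the total edge count 42mn.
#'
#' @return list of records with fields `lo`, `hi`, `poly` ([bilinear_poly]
#'   with integer coefficients).
#' @export
symbolic_partition <- function() {
  list(
    list(lo = 1L, hi = 3L, poly = bilinear_poly(14, 2, 2, 0)),
    list(lo = 2L, hi = 3L, poly = bilinear_poly(4, -2, -2, 0)),
    list(lo = 3L, hi = 3L, poly = bilinear_poly(24, 0, 0, 0))
  )
}

#' Derive the closed form of an index on F[m, n]
#'
#' Multiplies each symbolic partition count by the exact per-edge value of
#' the index at that degree pair and sums in the surd ring.  The result is
#' the index's exact bilinear closed form; evaluating it at any (m, n)
#' reproduces direct edge summation on the generated sheet exactly.
#'
#' @param spec an [index_spec] with an exact path on the pairs (1,3), (2,3),
#'   (3,3) (all supported indices qualify).
#' @return a [bilinear_poly].
#' @examples
#' derive_closed_form(index_spec("M1"))   # 220mn - 2m - 2n
#' @export
derive_closed_form <- function(spec) {
  acc <- bilinear_poly()
  for (rec in symbolic_partition()) {
    w <- edge_value_exact(spec, rec$lo, rec$hi)
    if (is.null(w))
      stop(sprintf("%s has no exact per-edge value at (%d, %d); no surd closed form",
                   spec$label, rec$lo, rec$hi))
    acc <- bilinear_poly(acc$c_mn + w * rec$poly$c_mn,
                         acc$c_m + w * rec$poly$c_m,
                         acc$c_n + w * rec$poly$c_n,
                         acc$c_1 + w * rec$poly$c_1)
  }
  acc
}

#' Fit a bilinear form to direct computations (independent numeric oracle)
#'
#' Solves the 4-coefficient linear system for basis {mn, m, n, 1} from
#' direct edge-summation values of the index on generated sheets at the
#' sample points.  This route never touches the symbolic partition, so
#' agreement with [derive_closed_form()] is a genuine cross-check.
#'
#' @param spec an [index_spec].
#' @param points a two-column matrix or data frame of (m, n) sample points;
#'   at least 4, and nonsingular in the {mn, m, n, 1} design.
#' @return a `bilinear_fit`: list with numeric `coef` (c_mn, c_m, c_n, c_1)
#'   and a `predict(m, n)` closure.
#' @export
fit_bilinear <- function(spec, points = rbind(c(1, 1), c(1, 2), c(2, 1), c(2, 2))) {
  points <- as.matrix(points)
  if (ncol(points) != 2L || nrow(points) < 4L)
    stop("need at least 4 (m, n) sample points")
  X <- cbind(mn = points[, 1L] * points[, 2L], m = points[, 1L],
             n = points[, 2L], one = 1)
  if (qr(X)$rank < 4L)
    stop("singular bilinear design for sample points: ",
         paste(sprintf("(%d,%d)", points[, 1L], points[, 2L]), collapse = " "))
  y <- apply(points, 1L, function(pt)
    compute_index(build_sheet(pt[1L], pt[2L]), spec))
  coef <- qr.solve(X, y)
  names(coef) <- c("c_mn", "c_m", "c_n", "c_1")
  structure(list(spec = spec, coef = coef,
                 predict = function(m, n) sum(coef * c(m * n, m, n, 1))),
            class = "bilinear_fit")
}

#' @export
print.bilinear_fit <- function(x, ...) {
  cat("<bilinear_fit> ", x$spec$label, ": ",
      paste(sprintf("%s=%.10g", names(x$coef), x$coef), collapse = ", "),
      "\n", sep = "")
  invisible(x)
}
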