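#' Exact numbers in the surd ring Q + Q*sqrt(2) + Q*sqrt(3) + Q*sqrt(6)
#'
#' Every per-edge index value arising on the Fuchsine sheet's three degree
#' pairs (1,3), (2,3), (3,3) lives in the ring of numbers
#' \eqn{a + b\sqrt{2} + c\sqrt{3} + d\sqrt{6}} with rational \eqn{a,b,c,d}.
#' Working in this ring makes "the closed form equals the direct sum" a
#' decidable equality rather than a floating-point tolerance check.
#'
#' A `surd` stores the four coefficients as reduced fractions.  Coefficient
#' arguments may be given as a whole number or as a length-2 vector
#' `c(numerator, denominator)`.
#'
#' @param a,b,c,d coefficients of 1, sqrt(2), sqrt(3), sqrt(6); each a whole
#'   number or `c(num, den)`.
#' @return an object of class `surd`.
#' @examples
#' x <- surd(2, 0, 0, c(1, 3))      # 2 + (1/3) sqrt(6)
#' as.numeric(x * x)                # exact square, evaluated
#' @export
surd <- function(a = 0, b = 0, c = 0, d = 0) {
  coef <- lapply(list(a, b, c, d), as_fraction)
  new_surd(vapply(coef, `[[`, 0, 1L), vapply(coef, `[[`, 0, 2L))
}

# internal constructor from numerator/denominator vectors of length 4
new_surd <- function(num, den) {
  stopifnot(length(num) == 4L, length(den) == 4L, all(den != 0))
  sgn <- ifelse(den < 0, -1, 1)
  num <- num * sgn
  den <- abs(den)
  g <- vec_gcd(abs(num), den)
  g[g == 0] <- 1
  structure(list(num = num / g, den = den / g), class = "surd")
}

# vectorized Euclid; exact for integer-valued doubles
vec_gcd <- function(a, b) {
  repeat {
    z <- b != 0
    if (!any(z)) return(a)
    t <- b[z]
    b[z] <- a[z] %% b[z]
    a[z] <- t
  }
}

as_fraction <- function(x) {
  if (inherits(x, "surd")) stop("coefficient must be rational, not a surd")
  if (length(x) == 1L) {
    if (x != round(x)) stop("non-integer coefficient must be given as c(num, den)")
    return(c(x, 1))
  }
  if (length(x) == 2L) {
    if (any(x != round(x))) stop("fraction parts must be whole numbers")
    if (x[2L] == 0) stop("zero denominator")
    return(x)
  }
  stop("coefficient must have length 1 or 2")
}

#' @export
is_surd <- function(x) inherits(x, "surd")

#' @rdname surd
#' @param x object to coerce or test.
#' @export
as_surd <- function(x) {
  if (is_surd(x)) return(x)
  if (is.numeric(x) && length(x) == 1L) {
    if (x != round(x)) stop("cannot coerce non-integer numeric to surd exactly")
    return(surd(x))
  }
  stop("cannot coerce to surd")
}

#' @export
as.double.surd <- function(x, ...) {
  sum(x$num / x$den * c(1, sqrt(2), sqrt(3), sqrt(6)))
}

#' @export
format.surd <- function(x, ...) {
  lab <- c("", "*sqrt(2)", "*sqrt(3)", "*sqrt(6)")
  parts <- character(0)
  for (i in 1:4) {
    if (x$num[i] == 0) next
    q <- if (x$den[i] == 1) format(abs(x$num[i])) else
      paste0(format(abs(x$num[i])), "/", format(x$den[i]))
    term <- paste0(q, lab[i])
    parts <- c(parts, if (x$num[i] < 0) {
      if (length(parts)) paste0("- ", term) else paste0("-", term)
    } else if (length(parts)) paste0("+ ", term) else term)
  }
  if (!length(parts)) return("0")
  paste(parts, collapse = " ")
}

#' @export
print.surd <- function(x, ...) {
  cat("<surd> ", format(x), "  (= ", format(as.numeric(x), digits = 12), ")\n",
      sep = "")
  invisible(x)
}

# rational helpers on (num, den) component vectors
frac_add <- function(n1, d1, n2, d2) list(num = n1 * d2 + n2 * d1, den = d1 * d2)

#' @export
Ops.surd <- function(e1, e2) {
  if (nargs() == 1L) {
    if (.Generic == "-") return(new_surd(-e1$num, e1$den))
    if (.Generic == "+") return(e1)
    stop("unary ", .Generic, " not defined for surd")
  }
  s1 <- as_surd(e1)
  s2 <- as_surd(e2)
  switch(.Generic,
    "+" = {
      f <- frac_add(s1$num, s1$den, s2$num, s2$den)
      new_surd(f$num, f$den)
    },
    "-" = {
      f <- frac_add(s1$num, s1$den, -s2$num, s2$den)
      new_surd(f$num, f$den)
    },
    "*" = surd_multiply(s1, s2),
    "==" = all(s1$num == s2$num & s1$den == s2$den),
    "!=" = !all(s1$num == s2$num & s1$den == s2$den),
    stop(.Generic, " not defined for surd")
  )
}

# multiplication table of the basis {1, s2, s3, s6}:
#   s2*s2 = 2, s3*s3 = 3, s6*s6 = 6, s2*s3 = s6, s2*s6 = 2*s3, s3*s6 = 3*s2
surd_multiply <- function(x, y) {
  # cross products of the coefficient fractions, routed through the table
  n <- outer(x$num, y$num)
  d <- outer(x$den, y$den)
  acc_n <- numeric(4)
  acc_d <- rep(1, 4)
  add <- function(i, nn, dd) {
    f <- frac_add(acc_n[i], acc_d[i], nn, dd)
    acc_n[i] <<- f$num
    acc_d[i] <<- f$den
  }
  # basis pair (i, j) lands on basis `target` with integer factor `mult`
  target <- matrix(c(
    1, 2, 3, 4,
    2, 1, 4, 3,
    3, 4, 1, 2,
    4, 3, 2, 1), 4, 4, byrow = TRUE)
  mult <- matrix(c(
    1, 1, 1, 1,
    1, 2, 1, 2,
    1, 1, 3, 3,
    1, 2, 3, 6), 4, 4, byrow = TRUE)
  for (i in 1:4) for (j in 1:4) {
    if (n[i, j] == 0) next
    add(target[i, j], n[i, j] * mult[i, j], d[i, j])
  }
  new_surd(acc_n, acc_d)
}

#' Exact square root of a non-negative rational, when it stays in the ring
#'
#' Returns `sqrt(num/den)` as a `surd` when the result has the form
#' `q * sqrt(r)` with rational `q` and `r` in {1, 2, 3, 6}; otherwise `NULL`.
#' `sqrt(num/den) = sqrt(num*den)/den`, so it suffices to split `num*den`
#' into its largest square factor times a remainder.
#'
#' @param num,den non-negative integer numerator and positive denominator.
#' @return a `surd`, or `NULL` if the root leaves the ring.
#' @export
surd_sqrt <- function(num, den = 1) {
  stopifnot(num >= 0, den > 0, num == round(num), den == round(den))
  if (num == 0) return(surd(0))
  k <- num * den
  s <- 1
  f <- 2
  while (f * f <= k) {
    while (k %% (f * f) == 0) {
      k <- k / (f * f)
      s <- s * f
    }
    f <- f + 1
  }
  pos <- match(k, c(1, 2, 3, 6))
  if (is.na(pos)) return(NULL)
  coef <- vector("list", 4)
  coef[1:4] <- list(0, 0, 0, 0)
  coef[[pos]] <- c(s, den)
  do.call(surd, coef)
}
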