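# Published closed forms and comparison-table cells for the F[m,n] family,
# stored exactly as printed (including defective cells/coefficients).  These
# are fixtures to be audited; direct graph computation is always the truth.

#' Published closed forms for F[m, n], as printed
#'
#' Each record holds an index label, the source of the printed form
#' ("theorem" statement or "proof" working line), and the form itself as a
#' [bilinear_poly].  Forms are stored verbatim-faithfully: known-suspect
#' coefficients are NOT corrected here.  The ambiguous ABC term "14 sqrt(2)/3"
#' is recorded under both readings: A = (14/3)*sqrt(2) (literal), and
#' B = 14*sqrt(2/3) = (14/3)*sqrt(6).
#'
#' @return named list of records with fields `label`, `source`, `poly`, `note`.
#' @export
published_formulas <- function() {
  pf <- function(label, source, c_mn, c_s, note = "") {
    list(label = label, source = source,
         poly = bilinear_poly(c_mn, c_s, c_s, 0), note = note)
  }
  list(
    M1 = pf("M1", "theorem", 220, -2),
    M2 = pf("M2", "theorem", 282, -6),
    HM_theorem = pf("HM", "theorem", 118, -18,
                    "header disagrees with its own proof line"),
    HM_proof = pf("HM", "proof", 1188, -18),
    H = pf("H", "theorem", surd(c(83, 5)), surd(c(1, 5))),
    F = pf("F", "theorem", 624, -6),
    ABC_reading_A = pf("ABC", "theorem",
                       surd(16, c(20, 3)), surd(0, c(-1, 3)),
                       "literal reading: 14*sqrt(2)/3 and 2*sqrt(2)/3"),
    ABC_reading_B = pf("ABC", "theorem",
                       surd(16, 2, 0, c(14, 3)), surd(0, -1, 0, c(2, 3)),
                       "reading sqrt(2)/3 as sqrt(2/3) = sqrt(6)/3"),
    GA = pf("GA", "theorem",
            surd(24, 0, 7, c(8, 5)), surd(0, 0, 1, c(-4, 5))),
    R1 = pf("R1", "theorem", 282, -6),
    `R-1` = pf("R-1", "theorem", 8, surd(c(1, 3))),
    `R1/2` = pf("R1/2", "theorem",
                surd(72, 0, 14, 4), surd(0, 0, 2, -2)),
    `R-1/2` = pf("R-1/2", "theorem",
                 surd(8, 0, c(14, 3), c(2, 3)), surd(2, -1, 0, 0),
                 "(m+n) coefficient printed (2 - sqrt(2)); a 1/sqrt(3) factor is missing")
  )
}

#' Compare derived closed forms with the published ones
#'
#' Derives each index's closed form from the symbolic edge partition in
#' exact surd arithmetic and classifies every published form as MATCH or
#' MISMATCH, with the coefficient-level difference for mismatches.  No
#' silent correction: both readings of the ambiguous ABC term are compared.
#'
#' @return a `published_comparison`: list of records with fields `key`,
#'   `label`, `source`, `status`, `derived`, `published`, `delta`, `note`.
#' @examples
#' compare_published()
#' @export
compare_published <- function() {
  forms <- published_formulas()
  spec_for <- function(label) {
    if (startsWith(label, "R")) {
      l <- sub("^R", "", label)
      lam <- eval(parse(text = l))
      index_spec("R", lam)
    } else index_spec(label)
  }
  out <- lapply(names(forms), function(key) {
    rec <- forms[[key]]
    derived <- derive_closed_form(spec_for(rec$label))
    match <- bilinear_equal(derived, rec$poly)
    list(key = key, label = rec$label, source = rec$source,
         status = if (match) "MATCH" else "MISMATCH",
         derived = derived, published = rec$poly,
         delta = if (match) NULL else bilinear_subtract(rec$poly, derived),
         note = rec$note)
  })
  names(out) <- names(forms)
  structure(out, class = "published_comparison")
}

#' @export
print.published_comparison <- function(x, ...) {
  cat("Derived vs published closed forms:\n")
  for (rec in x) {
    cat(sprintf("  %-14s [%s] %s\n", rec$key, rec$source, rec$status))
    if (rec$status == "MISMATCH") {
      cat("      published:", format(rec$published), "\n")
      cat("      derived:  ", format(rec$derived), "\n")
    }
    if (nzchar(rec$note)) cat("      note:", rec$note, "\n")
  }
  invisible(x)
}

# column order of the published comparison table
table_columns <- function() c("M1", "M2", "HM", "F", "ABC", "GA",
                              "R-1", "R1/2", "R-1/2", "R1")

#' Published comparison-table cells, as printed
#'
#' Rows F[k, k] for k = 1..10, ten index columns.  Cells are stored exactly
#' as printed, including cells inconsistent with every closed-form variant;
#' the audit, not this fixture, decides correctness.
#'
#' @return data frame with columns `m`, `n` and the ten index columns.
#' @export
published_index_table <- function() {
  cells <- rbind(
    c(216,   270,   1152,   612,   25,   40,   7,   103,   19,   270),
    c(874,   1104,  4680,   2472,  101,  159,  33,  419,   72,   1104),
    c(1968,  2502,  10584,  5580,  227,  359,  74,  946,   162,  2502),
    c(3504,  4464,  18864,  9936,  405,  625,  131, 1713,  286,  4464),
    c(5480,  6990,  29520,  15540, 635,  999,  203, 2637,  446,  6990),
    c(7896,  10080, 42552,  22392, 915,  1439, 340, 3800,  642,  10080),
    c(10752, 13734, 57960,  30492, 1246, 1901, 397, 5176,  873,  13734),
    c(14048, 17952, 75744,  39840, 1629, 2450, 517, 6764,  1139, 17952),
    c(17784, 22734, 95904,  50436, 2065, 3098, 654, 8564,  1441, 22734),
    c(21960, 28080, 118440, 62280, 2547, 4000, 807, 10576, 1779, 28080))
  out <- data.frame(m = 1:10, n = 1:10, cells)
  names(out) <- c("m", "n", table_columns())
  out
}

#' Compute the comparison table for arbitrary (m, n) rows
#'
#' All ten columns by direct edge summation on generated sheets; the integer
#' rendering rounds to nearest, halves away from zero.
#'
#' @param m,n equal-length vectors of positive integers.
#' @return an `index_table`: list with data frames `values` (unrounded) and
#'   `rounded` (integer rendering), each with columns `m`, `n` and the ten
#'   index columns.
#' @examples
#' make_index_table(1:3, 1:3)
#' @export
make_index_table <- function(m, n = m) {
  stopifnot(length(m) == length(n), all(m >= 1), all(n >= 1))
  cols <- table_columns()
  specs <- all_index_specs()[cols]
  vals <- t(mapply(function(mi, ni) {
    s <- build_sheet(mi, ni)
    vapply(specs, function(sp) compute_index(s, sp), 0)
  }, m, n))
  values <- data.frame(m = m, n = n, vals)
  names(values) <- c("m", "n", cols)
  rounded <- values
  rounded[cols] <- lapply(values[cols], function(x) as.integer(round_half_away(x)))
  structure(list(values = values, rounded = rounded), class = "index_table")
}

#' @export
print.index_table <- function(x, ...) {
  cat("Topological indices of F[m, n] (integer rendering):\n")
  print(x$rounded, row.names = FALSE)
  invisible(x)
}

#' Audit the published table and closed forms against direct computation
#'
#' Recomputes every cell of the published comparison table by direct edge
#' summation on the generated sheet and flags each cell whose printed
#' integer differs from the rounded computed value; also records the
#' formula-level discrepancies (hyper-Zagreb theorem header vs its own proof
#' line, the literal ABC reading, the Randic lambda = -1/2 (m+n)
#' coefficient) and the discussion-level claim that the lambda = -1/2 Randic
#' index is the largest tabulated index (computation puts the hyper-Zagreb
#' index first at every size).
#'
#' @return data frame of errata with columns `kind` ("table_cell",
#'   "formula", "discussion"), `location`, `printed`, `computed`, `note`.
#' @export
audit_errata <- function() {
  pub <- published_index_table()
  comp <- make_index_table(pub$m, pub$n)
  cols <- table_columns()
  rec <- list()
  for (i in seq_len(nrow(pub))) for (col in cols) {
    printed <- pub[[col]][i]
    got <- comp$rounded[[col]][i]
    if (printed != got) {
      rec[[length(rec) + 1L]] <- data.frame(
        kind = "table_cell",
        location = sprintf("F[%d,%d] %s", pub$m[i], pub$n[i], col),
        printed = format(printed),
        computed = format(got),
        note = sprintf("direct summation gives %.4f", comp$values[[col]][i]))
    }
  }
  cmp <- compare_published()
  for (r in cmp) if (r$status == "MISMATCH") {
    rec[[length(rec) + 1L]] <- data.frame(
      kind = "formula",
      location = sprintf("%s closed form (%s, %s)", r$label, r$source, r$key),
      printed = format(r$published),
      computed = format(r$derived),
      note = r$note)
  }
  # discussion claim: which index is maximal among the tabulated ten?
  k10 <- comp$values[cols]
  maximal <- cols[apply(k10, 1L, which.max)]
  rec[[length(rec) + 1L]] <- data.frame(
    kind = "discussion",
    location = "claim: R-1/2 is the maximum tabulated index",
    printed = "R-1/2 maximal",
    computed = paste(unique(maximal), "maximal at every tabulated size"),
    note = "computed ordering contradicts the claim; R-1 minimal claim holds at m=n=1")
  out <- do.call(rbind, rec)
  rownames(out) <- NULL
  out
}

#' Plot the tabulated indices on square sheets F[k, k]
#'
#' One line per index over k = 1..`max_k`, using computed values (never the
#' published cells).
#'
#' @param max_k largest square-sheet size (>= 2).
#' @param file optional path; when given, a PNG is written there.
#' @param log_y log-scale the value axis (the hyper-Zagreb curve dwarfs the
#'   harmonic-scale curves otherwise).
#' @return (invisibly) the `index_table` used, with rows k = 1..max_k.
#' @export
plot_comparison <- function(max_k, file = NULL, log_y = FALSE) {
  if (!(length(max_k) == 1L && max_k == round(max_k) && max_k >= 2))
    stop("max_k must be an integer >= 2")
  tab <- make_index_table(1:max_k, 1:max_k)
  cols <- table_columns()
  vals <- as.matrix(tab$values[cols])
  if (!is.null(file)) {
    grDevices::png(file, width = 900, height = 650)
    on.exit(grDevices::dev.off())
  }
  graphics::matplot(1:max_k, vals, type = "b", pch = seq_along(cols),
                    lty = 1, col = seq_along(cols),
                    log = if (log_y) "y" else "",
                    xlab = "k  (sheet F[k, k])", ylab = "index value",
                    main = "Degree-based indices on square Fuchsine sheets")
  graphics::legend("topleft", legend = cols, col = seq_along(cols),
                   pch = seq_along(cols), lty = 1, ncol = 2, bty = "n")
  invisible(tab)
}
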