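test_that("exact per-edge values on the sheet degree pairs", {
  expect_true(edge_value(index_spec("GA"), 3, 3, exact = TRUE) == surd(1))
  # ABC: sqrt(4/9) = 2/3, sqrt(3/6) = sqrt(2)/2, sqrt(2/3) = sqrt(6)/3
  abc <- index_spec("ABC")
  expect_true(edge_value(abc, 3, 3, exact = TRUE) == surd(c(2, 3)))
  expect_true(edge_value(abc, 2, 3, exact = TRUE) == surd(0, c(1, 2)))
  expect_true(edge_value(abc, 1, 3, exact = TRUE) == surd(0, 0, 0, c(1, 3)))
  expect_true(edge_value(index_spec("HM"), 2, 3, exact = TRUE) == surd(25))
  expect_true(edge_value(index_spec("H"), 1, 3, exact = TRUE) == surd(c(1, 2)))
  # reciprocal square root: 1/sqrt(6) = sqrt(6)/6
  expect_true(edge_value(index_spec("R", -0.5), 2, 3, exact = TRUE) ==
                surd(0, 0, 0, c(1, 6)))
})

test_that("exact and numeric per-edge paths agree; fallback warns", {
  specs <- all_index_specs()
  for (sp in specs) for (pair in list(c(1, 3), c(2, 3), c(3, 3), c(2, 2))) {
    ex <- edge_value(sp, pair[1], pair[2], exact = TRUE)
    expect_equal(as.numeric(ex), edge_value(sp, pair[1], pair[2]),
                 tolerance = 1e-12)
  }
  # ABC at (1,1) is 0 by definition, not an error
  expect_equal(edge_value(index_spec("ABC"), 1, 1), 0)
  expect_true(edge_value(index_spec("ABC"), 1, 1, exact = TRUE) == surd(0))
  # sqrt(5) leaves the ring -> float with a warning
  expect_warning(v <- edge_value(index_spec("R", 0.5), 1, 5, exact = TRUE),
                 "no exact surd")
  expect_equal(v, sqrt(5))
  expect_error(edge_value(index_spec("M1"), 0, 3), "positive")
})

test_that("direct summation reproduces the F[1,1] worked values", {
  s <- cached_sheet(1, 1)
  expect_equal(compute_index(s, index_spec("M1")), 216)
  expect_equal(compute_index(s, index_spec("M2")), 270)
  expect_true(compute_index(s, index_spec("H"), exact = TRUE) == surd(17))
  # brute-force float oracle over the 42 edges: 24*(2/3) + 18*sqrt(2/3)
  expect_equal(compute_index(s, index_spec("ABC")), 24 * (2 / 3) + 18 * sqrt(2 / 3),
               tolerance = 1e-12)
  expect_equal(compute_index(s, index_spec("ABC")), 30.6969, tolerance = 1e-4)
})

test_that("partition route equals direct route exactly on sheets", {
  for (mn in list(c(1, 1), c(2, 2), c(3, 1))) {
    s <- cached_sheet(mn[1], mn[2])
    p <- edge_partition(s)
    for (sp in all_index_specs()) {
      expect_true(compute_from_partition(p, sp, exact = TRUE) ==
                    compute_index(s, sp, exact = TRUE))
    }
  }
  # worked partition values
  p11 <- edge_partition(cached_sheet(1, 1))
  expect_true(compute_from_partition(p11, index_spec("M2"), exact = TRUE) == surd(270))
  p22 <- edge_partition(cached_sheet(2, 2))
  expect_true(compute_from_partition(p22, index_spec("HM"), exact = TRUE) == surd(4680))
  empty <- edge_partition(igraph::make_empty_graph(0, directed = FALSE))
  expect_equal(compute_from_partition(empty, index_spec("GA")), 0)
})

test_that("direct and partition routes agree on 50 random graphs (all indices)", {
  set.seed(31)
  for (i in 1:50) {
    g <- random_connected_graph()
    p <- edge_partition(g)
    for (sp in all_index_specs()) {
      a <- compute_index(g, sp)
      b <- compute_from_partition(p, sp)
      expect_equal(a, b, tolerance = 1e-9)
      expect_gt(a, 0)   # strictly positive on any graph with an edge
    }
  }
})

test_that("general Randic special cases", {
  s <- cached_sheet(1, 1)
  expect_equal(general_randic(s, 1), 270)
  expect_equal(general_randic(s, 1), compute_index(s, index_spec("M2")))
  expect_equal(general_randic(s, 0), 42)   # each term is 1
  expect_equal(general_randic(cached_sheet(3, 3), -1), 74)
  expect_true(compute_index(cached_sheet(3, 3), index_spec("R", -1), exact = TRUE) ==
                surd(74))
  set.seed(32)
  g <- random_connected_graph()
  expect_equal(general_randic(g, 0), igraph::ecount(g))
  expect_equal(general_randic(g, 1), compute_index(g, index_spec("M2")),
               tolerance = 1e-9)
  expect_error(index_spec("R"), "lambda")
  expect_error(index_spec("M1", lambda = 2), "only meaningful")
})

test_that("every index strictly increases in m and in n over 1..6", {
  vals <- array(dim = c(6, 6, 11))
  specs <- all_index_specs()
  for (m in 1:6) for (n in 1:6) {
    s <- cached_sheet(m, n)
    vals[m, n, ] <- vapply(specs, function(sp) compute_index(s, sp), 0)
  }
  for (k in seq_along(specs)) {
    expect_true(all(apply(vals[, , k], 2, diff) > 0),
                label = paste(names(specs)[k], "increasing in m"))
    expect_true(all(apply(vals[, , k], 1, diff) > 0),
                label = paste(names(specs)[k], "increasing in n"))
  }
})

test_that("GA per-edge value is at most 1, so GA is at most the edge count", {
  for (pair in list(c(1, 3), c(2, 3), c(3, 3), c(2, 5), c(4, 4)))
    expect_lte(edge_value(index_spec("GA"), pair[1], pair[2]), 1)
  expect_equal(edge_value(index_spec("GA"), 4, 4), 1)   # equality iff equal degrees
  set.seed(33)
  for (i in 1:10) {
    g <- random_connected_graph()
    expect_lte(compute_index(g, index_spec("GA")), igraph::ecount(g))
  }
  for (mn in list(c(1, 1), c(4, 2))) {
    s <- cached_sheet(mn[1], mn[2])
    expect_lte(compute_index(s, index_spec("GA")), igraph::ecount(s$graph))
  }
})
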