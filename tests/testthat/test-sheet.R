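test_that("canonical unit satisfies the template contract", {
  u <- canonical_unit()
  expect_identical(validate_unit_template(u), character(0))
  expect_equal(igraph::vcount(u$graph), 40)
  expect_equal(igraph::ecount(u$graph), 42)
  p <- edge_partition(u)
  expect_equal(partition_count(p, 3, 3), 24)
  expect_equal(partition_count(p, 1, 3), 18)
  deg <- degree_map(u)
  expect_true(all(deg[u$ports] == 1))
})

test_that("fuse_pendants identifies two pendants into one degree-2 vertex", {
  g <- igraph::graph_from_edgelist(rbind(c("a", "b"), c("c", "d")),
                                   directed = FALSE)
  f <- fuse_pendants(g, "b", "d")
  expect_equal(igraph::vcount(f), 3)
  expect_equal(igraph::ecount(f), 2)
  expect_equal(unname(igraph::degree(f)["b+d"]), 2)

  expect_error(fuse_pendants(g, "b", "b"), "itself")
  expect_error(fuse_pendants(triangle(), "a", "b"), "not a pendant")
  star <- igraph::graph_from_edgelist(rbind(c("h", "x"), c("h", "y")),
                                      directed = FALSE)
  expect_error(fuse_pendants(star, "x", "y"), "same vertex")
})

test_that("fusing two units through E/W ports gives the F[2,1] counts", {
  u <- canonical_unit()
  ends <- igraph::as_edgelist(u$graph, names = TRUE)
  two <- igraph::graph_from_edgelist(
    rbind(matrix(paste0("L_", ends), ncol = 2),
          matrix(paste0("R_", ends), ncol = 2)), directed = FALSE)
  f <- fuse_pendants(two, paste0("L_", u$ports[["E"]]), paste0("R_", u$ports[["W"]]))
  expect_equal(igraph::vcount(f), 79)   # 38mn + m + n at m = 2, n = 1
  expect_equal(igraph::ecount(f), 84)   # 42mn
})

test_that("build_sheet reproduces the closed-form counts for all m, n in 1..6", {
  for (m in 1:6) for (n in 1:6) {
    s <- cached_sheet(m, n)
    expect_equal(igraph::vcount(s$graph), 38 * m * n + m + n)
    expect_equal(igraph::ecount(s$graph), 42 * m * n)
    expect_identical(validate_graph(s), character(0))
    p <- edge_partition(s)
    expect_equal(partition_count(p, 3, 3), 24 * m * n)
    expect_equal(partition_count(p, 1, 3), 14 * m * n + 2 * (m + n))
    expect_equal(partition_count(p, 2, 3), n * (2 * m - 2) + 2 * m * (n - 1))
    expect_equal(sum(degree_map(s) == 2), 2 * m * n - m - n)
  }
})

test_that("sheet-level constructor rejects degenerate inputs", {
  expect_error(build_sheet(0, 1), ">= 1")
  expect_error(build_sheet(2, -1), ">= 1")
  expect_error(build_sheet(1.5, 1), ">= 1")
  broken <- canonical_unit()
  broken$ports[["W"]] <- "c0"   # port must be a pendant
  expect_error(build_sheet(1, 2, template = broken), "invalid unit template")
})

test_that("build_sheet is deterministic, with identical labelling across runs", {
  a <- build_sheet(2, 3)
  b <- build_sheet(2, 3)
  expect_identical(igraph::V(a$graph)$name, igraph::V(b$graph)$name)
  expect_identical(igraph::as_edgelist(a$graph), igraph::as_edgelist(b$graph))
})

test_that("any valid template yields the same edge partition (template independence)", {
  alt <- alternative_unit()
  expect_identical(validate_unit_template(alt), character(0))
  for (mn in list(c(1, 1), c(2, 2), c(3, 2))) {
    a <- build_sheet(mn[1], mn[2])
    b <- build_sheet(mn[1], mn[2], template = alt)
    expect_identical(as.data.frame(edge_partition(a)),
                     as.data.frame(edge_partition(b)))
  }
})

test_that("template files round-trip and violations are rejected", {
  u <- canonical_unit()
  path <- withr::local_tempfile(fileext = ".txt")
  write_template(u, path)
  v <- read_template(path)
  expect_identical(as.data.frame(edge_partition(v)),
                   as.data.frame(edge_partition(u)))
  expect_identical(unname(degree_map(v)[v$ports]), rep(1, 4))
  expect_identical(names(v$ports), c("W", "E", "N", "S"))

  # port vertex of degree 2 -> rejected
  lines <- readLines(path)
  writeLines(sub("^port W p2$", "port W c1", lines), path)
  expect_error(read_template(path), "degree")

  # wrong vertex count -> rejected with a count message
  writeLines(c(readLines(path), "edge c0 extra_vertex"), path)
  writeLines(c(sub("^port W c1$", "port W p2", readLines(path))), path)
  expect_error(read_template(path), "40 vertices")

  # malformed line reported with its line number
  writeLines(c("edge a", "port W a"), path)
  expect_error(read_template(path), "line 1")
})
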