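# Shared fixtures, all generated in code.

# cache of generated sheets so suites do not rebuild the same graphs
.sheet_cache <- new.env(parent = emptyenv())
cached_sheet <- function(m, n) {
  key <- paste(m, n, sep = "x")
  s <- get0(key, envir = .sheet_cache)
  if (is.null(s)) {
    s <- build_sheet(m, n)
    assign(key, s, envir = .sheet_cache)
  }
  s
}

# a random connected simple graph (caller fixes the RNG seed)
random_connected_graph <- function(nv = sample(4:12, 1), p = 0.4) {
  repeat {
    g <- igraph::sample_gnp(nv, p)
    if (igraph::is_connected(g) && igraph::ecount(g) > 0) {
      igraph::V(g)$name <- paste0("v", seq_len(nv))
      return(g)
    }
  }
}

# an alternative valid unit template: same 22-cycle, different chords
# (c0--c11 and c3--c14), pendants on the remaining 18 core vertices.
alternative_unit <- function() {
  core <- paste0("c", 0:21)
  cyc <- cbind(core, core[c(2:22, 1)])
  chords <- rbind(c("c0", "c11"), c("c3", "c14"))
  pend_idx <- setdiff(0:21, c(0, 3, 11, 14))
  pend <- cbind(paste0("c", pend_idx), paste0("p", pend_idx))
  g <- igraph::graph_from_edgelist(rbind(cyc, chords, pend), directed = FALSE)
  structure(list(graph = g,
                 ports = c(W = "p2", E = "p13", N = "p8", S = "p19")),
            class = "fuchsine_unit")
}

# tiny named graphs used across suites
path3 <- function() igraph::make_graph(~ a - b, b - c)
triangle <- function() igraph::make_graph(~ a - b, b - c, c - a)

expect_surd_equal <- function(x, y) {
  expect_true(is_surd(x))
  expect_true(x == as_surd_like(y))
}
as_surd_like <- function(y) if (is_surd(y)) y else surd(y)
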