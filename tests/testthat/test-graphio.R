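test_that("edge list reading canonicalizes: dedup, reciprocal collapse, self-loops", {
  tf <- withr::local_tempfile(fileext = ".edges")
  writeLines(c("# comment", "a b", "b a", "b c", "c c", "% also comment"), tf)
  g <- read_graph_file(tf)
  expect_equal(igraph::vcount(g), 3L)
  expect_equal(igraph::ecount(g), 2L)
  expect_setequal(igraph::V(g)$name, c("a", "b", "c"))
  expect_equal(apply(igraph::as_edgelist(g), 1, paste, collapse = "-"),
               c("a-b", "b-c"))

  # comma-separated dialect, extra weight column ignored
  tf2 <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("1,2,0.5", "2,3,1.5"), tf2)
  g2 <- read_graph_file(tf2)
  expect_equal(igraph::ecount(g2), 2L)
  expect_null(igraph::edge_attr(g2, "weight"))
})

test_that("malformed edge rows are reported with their line number", {
  tf <- withr::local_tempfile(fileext = ".edges")
  writeLines(c("1 2", "# ok", "justone"), tf)
  expect_error(read_graph_file(tf), "line 3")
})

test_that("MatrixMarket coordinate files read with 1-based index conversion", {
  tf <- withr::local_tempfile(fileext = ".mtx")
  writeLines(c("%%MatrixMarket matrix coordinate pattern symmetric",
               "3 3 2", "2 1", "3 2"), tf)
  g <- read_graph_file(tf)
  expect_equal(igraph::vcount(g), 3L)
  expect_equal(igraph::ecount(g), 2L)
  expect_equal(igraph::V(g)$name, c("1", "2", "3"))

  # real general variant with reciprocal entries collapses to one edge
  tf2 <- withr::local_tempfile(fileext = ".mtx")
  writeLines(c("%%MatrixMarket matrix coordinate real general",
               "2 2 2", "1 2 0.7", "2 1 0.7"), tf2)
  g2 <- read_graph_file(tf2)
  expect_equal(igraph::ecount(g2), 1L)
})

test_that("read after write is the identity on node count and edge set", {
  set.seed(42)
  g <- random_connected_graph(12, 0.3)
  g <- canonicalize_graph(g)
  for (fmt in c("edgelist", "mtx")) {
    tf <- withr::local_tempfile(fileext = paste0(".", fmt))
    write_graph_file(g, tf, fmt)
    g2 <- read_graph_file(tf)
    expect_equal(igraph::vcount(g2), igraph::vcount(g))
    expect_equal(igraph::ecount(g2), igraph::ecount(g))
    a1 <- igraph::as_adjacency_matrix(g, sparse = FALSE)
    a2 <- igraph::as_adjacency_matrix(g2, sparse = FALSE)
    expect_true(all(a1 == a2))
  }
})

test_that("canonicalization is idempotent and strips weights/directions", {
  g <- igraph::graph_from_edgelist(cbind(c(1, 2, 2, 3), c(2, 1, 3, 3)),
                                   directed = TRUE)
  igraph::E(g)$weight <- c(2, 3, 1, 9)
  c1 <- canonicalize_graph(g)
  expect_false(igraph::is_directed(c1))
  expect_equal(igraph::ecount(c1), 2L)  # loop gone, reciprocal collapsed
  expect_null(igraph::edge_attr(c1, "weight"))
  c2 <- canonicalize_graph(c1)
  expect_true(igraph::identical_graphs(c1, c2))
})

test_that("largest_component keeps the biggest component, ties by smallest label", {
  # K3 on {1,2,3}, K3 on {4,5,6}, P2 on {7,8}: tie between the triangles
  g <- igraph::graph_from_edgelist(
    cbind(c(1, 1, 2, 4, 4, 5, 7), c(2, 3, 3, 5, 6, 6, 8)),
    directed = FALSE)
  igraph::V(g)$name <- as.character(1:8)
  expect_warning(lc <- largest_component(g), "disconnected")
  expect_equal(igraph::vcount(lc), 3L)
  expect_setequal(igraph::V(lc)$name, c("1", "2", "3"))

  # unique largest: star K1,5 plus two isolated nodes
  star <- igraph::make_star(6, "undirected")
  g2 <- igraph::add_vertices(star, 2)
  expect_warning(lc2 <- largest_component(g2), "disconnected")
  expect_equal(igraph::vcount(lc2), 6L)

  # connected input returned as-is
  expect_silent(lc3 <- largest_component(star))
  expect_equal(igraph::vcount(lc3), 6L)
})

test_that("synthetic generators honor their family contracts", {
  ring <- generate_graph(synthetic_spec("regular_lattice", n = 10, k = 2,
                                        seed = 1))
  expect_equal(igraph::ecount(ring), 10L)
  expect_true(all(igraph::degree(ring) == 2))

  lat4 <- generate_graph(synthetic_spec("regular_lattice", n = 9, k = 4,
                                        seed = 1))
  expect_true(all(igraph::degree(lat4) == 4))

  sw <- generate_graph(synthetic_spec("small_world", n = 100, k = 4,
                                      p = 0.1, seed = 7))
  expect_equal(igraph::ecount(sw), 200L)  # rewiring preserves n*k/2
  expect_true(igraph::is_connected(sw))

  sf <- generate_graph(synthetic_spec("scale_free", n = 200,
                                      attachment = 3, seed = 1))
  expect_true(igraph::is_connected(sf))
  expect_equal(igraph::vcount(sf), 200L)

  er <- generate_graph(synthetic_spec("uniform_random", n = 40, p = 0.15,
                                      seed = 3))
  expect_true(igraph::is_connected(er))

  expect_error(synthetic_spec("regular_lattice", n = 9, k = 3, seed = 1),
               "even")
  expect_error(synthetic_spec("scale_free", n = 5, attachment = 5, seed = 1))
})

test_that("generation is bit-reproducible under a fixed seed and leaves RNG alone", {
  spec <- synthetic_spec("scale_free", n = 200, attachment = 3, seed = 1)
  g1 <- generate_graph(spec)
  set.seed(999)
  before <- .Random.seed
  g2 <- generate_graph(spec)
  expect_identical(.Random.seed, before)
  expect_identical(igraph::as_edgelist(g1), igraph::as_edgelist(g2))

  spec_b <- synthetic_spec("scale_free", n = 200, attachment = 3, seed = 2)
  g3 <- generate_graph(spec_b)
  expect_false(identical(igraph::as_edgelist(g1), igraph::as_edgelist(g3)))
})

test_that("trace TSV and report JSON artifacts round-trip", {
  k4 <- igraph::make_full_graph(4)
  tr <- iterative_removal(k4, "pa", snapshot_metrics = TRUE)
  tf <- withr::local_tempfile(fileext = ".tsv")
  write_trace(tr, tf)
  back <- read_trace(tf)
  expect_equal(nrow(back), 3L)
  expect_equal(back$score, tr$steps$score)
  expect_equal(back$lambda_after, tr$steps$lambda_after)

  # empty trace writes the header only
  tree <- igraph::make_tree(5, mode = "undirected")
  tr0 <- iterative_removal(tree, "cn")
  tf0 <- withr::local_tempfile(fileext = ".tsv")
  write_trace(tr0, tf0)
  expect_length(readLines(tf0), 1L)

  rep <- compare_methods(k4, list("pa", "cn"))
  tfj <- withr::local_tempfile(fileext = ".json")
  write_report(rep, tfj)
  back_rep <- read_report(tfj)
  expect_equal(back_rep$common_k, rep$common_k)
  expect_equal(back_rep$methods$lambda, rep$methods$lambda)
  expect_equal(back_rep$best_by_lambda, rep$best_by_lambda)
})
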