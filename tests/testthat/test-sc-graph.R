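test_that("knn on collinear points follows the geometry", {
  # 10+ cells required by the embedding contract: isolate 3 on the x-axis
  # far from a distant clump
  coords <- rbind(c(0, 0), c(1, 0), c(10, 0),
                  cbind(1000 + seq(0, 6), 0))
  emb <- embedding(coords, cell_ids = paste0("c", 1:10))
  nn <- knn_neighbors(emb, k = 1)
  expect_equal(unname(nn["c1", 1]), 2L)   # 0 -> 1
  expect_equal(unname(nn["c2", 1]), 1L)   # 1 -> 0
  expect_equal(unname(nn["c3", 1]), 2L)   # 10 -> 1
})

test_that("knn ties break deterministically by cell order", {
  coords <- rbind(matrix(0, 4, 2), matrix(5, 8, 2) + rnorm(16, sd = 1e-9))
  emb <- embedding(coords)
  nn1 <- knn_neighbors(emb, k = 3)
  nn2 <- knn_neighbors(emb, k = 3)
  expect_identical(nn1, nn2)
  # the four coincident points pick the lowest-index others first
  expect_equal(sort(nn1[1, ]), 2:4)
  expect_equal(sort(nn1[2, ]), c(1L, 3L, 4L))
})

test_that("knn equals the brute-force oracle on 200 random points", {
  set.seed(31)
  coords <- matrix(rnorm(200 * 8), 200, 8)
  emb <- embedding(coords)
  for (k in c(1L, 5L, 15L)) {
    expect_equal(unclass(knn_neighbors(emb, k))[, seq_len(k)],
                 oracle_knn(coords, k), ignore_attr = TRUE)
  }
})

test_that("knn input contracts", {
  set.seed(32)
  emb <- embedding(matrix(rnorm(24), 12, 2))
  expect_error(knn_neighbors(emb, 12), "k <")
  expect_error(knn_neighbors(emb, 0), "k")
  expect_error(embedding(matrix(rnorm(10), 5, 2)), ">= 10 cells")
  expect_error(embedding(matrix(c(rnorm(19), NA), 10, 2)), "missing")
  expect_error(embedding(matrix(rnorm(10), 10, 1)), ">= 2 dimensions")
})

test_that("snn jaccard weights: identical sets weigh 1, disjoint pruned", {
  # two tight pairs far apart plus filler: cells 1,2 share identical
  # neighbor sets at k=1 ({1,2} each), so their Jaccard weight is 1
  coords <- rbind(c(0, 0), c(0.001, 0), c(50, 0), c(50.001, 0),
                  cbind(seq(100, 105), 70))
  emb <- embedding(coords)
  nn <- knn_neighbors(emb, k = 1)
  g <- snn_jaccard_graph(nn, prune = 1 / 15)
  w12 <- igraph::E(g)[igraph::V(g)["cell_1"] %--% igraph::V(g)["cell_2"]]$weight
  expect_equal(w12, 1)
  # cells 1 and 3 share nothing: no edge
  expect_length(igraph::E(g)[igraph::V(g)["cell_1"] %--%
                               igraph::V(g)["cell_3"]], 0L)
})

test_that("snn graph is simple, symmetric-weighted, and within (prune, 1]", {
  set.seed(33)
  sim <- gaussian_mixture_embedding(120, k = 3, dims = 6, separation = 8,
                                    sigma = 1, seed = 34)
  nn <- knn_neighbors(sim$embedding, k = 10)
  g <- snn_jaccard_graph(nn, prune = 1 / 15)
  expect_true(igraph::is_simple(g))
  expect_equal(igraph::vcount(g), 120L)
  expect_true(all(igraph::E(g)$weight > 1 / 15))
  expect_true(all(igraph::E(g)$weight <= 1))
  # pruning monotonicity: higher prune keeps a subset of edges
  g2 <- snn_jaccard_graph(nn, prune = 0.5)
  expect_true(all(netstab:::edge_keys(g2) %in% netstab:::edge_keys(g)))
  expect_error(snn_jaccard_graph(nn, prune = 1), "\\[0, 1\\)")
})

test_that("louvain on the snn graph recovers mixture labels (10 seeds)", {
  wins <- 0L
  for (s in 1:10) {
    sim <- gaussian_mixture_embedding(150, k = 3, dims = 10,
                                      separation = 10, sigma = 1, seed = s)
    g <- snn_jaccard_graph(knn_neighbors(sim$embedding, k = 15))
    p <- detect_communities(g, detection_method("louvain"), seed = s)
    wins <- wins + (variation_of_information(p, sim$labels) < 0.2)
  }
  expect_gte(wins, 9L)
})

test_that("annotations export/read round trip and validate", {
  p <- stats::setNames(c(1L, 1L, 2L), c("c1", "c2", "c3"))
  f <- withr::local_tempfile(fileext = ".csv")
  export_annotations(p, c("c1", "c2", "c3"), f)
  df <- utils::read.csv(f)
  expect_equal(nrow(df), 3L)
  expect_named(df, c("cell_id", "cluster"))
  rt <- read_annotations(f)
  expect_equal(variation_of_information(p, rt), 0)
  expect_identical(names(rt), names(p))
  expect_error(export_annotations(p, c("c1", "c2"), f), "does not match")
  expect_error(export_annotations(p, c("c1", "c2", "c9"), f),
               "do not match")
})

test_that("embeddings round-trip through CSV", {
  sim <- gaussian_mixture_embedding(30, k = 2, dims = 3, separation = 6,
                                    sigma = 0.5, seed = 35)
  f <- withr::local_tempfile(fileext = ".csv")
  write_embedding(sim$embedding, f)
  rt <- read_embedding(f)
  expect_equal(rt$cell_ids, sim$embedding$cell_ids)
  expect_equal(rt$coords, sim$embedding$coords, tolerance = 1e-12)
})
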