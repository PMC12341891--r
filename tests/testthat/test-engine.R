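test_that("perturbation grids validate their fields", {
  g <- perturbation_grid()
  expect_equal(g$levels, seq(0.05, 0.60, by = 0.05))
  expect_equal(length(g$levels), 12L)
  expect_equal(g$replicates, 10L)
  expect_error(perturbation_grid(levels = c(0.3, 0.2)), "increasing")
  expect_error(perturbation_grid(levels = c(0, 0.5)), "\\(0, 1\\]")
  expect_error(perturbation_grid(replicates = 1), ">= 2")
  gz <- perturbation_grid(include_zero = TRUE)
  expect_equal(gz$levels[1L], 0)
})

test_that("level 0 reproduces the reference partition for deterministic methods", {
  sim <- sbm_graph(c(15L, 15L), 0.7, 0.05, seed = 2)
  grid <- perturbation_grid(levels = c(0.2), replicates = 2,
                            include_zero = TRUE)
  cs <- stability_curves(sim$graph, detection_method("fastgreedy"), grid,
                         seed = 3)
  expect_equal(cs$levels[1L], 0)
  expect_equal(unname(cs$values[1L, ]), c(0, 0))
})

test_that("curves are bounded, deterministic, and worker-invariant", {
  sim <- sbm_graph(c(20L, 20L), 0.5, 0.03, seed = 4)
  grid <- quick_grid()
  cs1 <- stability_curves(sim$graph, "louvain", grid, seed = 5, workers = 1)
  cs2 <- stability_curves(sim$graph, "louvain", grid, seed = 5, workers = 3)
  expect_identical(cs1$values, cs2$values)  # bit-identical across workers
  expect_true(all(cs1$values >= 0))
  expect_true(all(cs1$values <= log(igraph::vcount(sim$graph)) + 1e-12))
  cs3 <- stability_curves(sim$graph, "louvain", grid, seed = 6)
  expect_false(identical(cs1$values, cs3$values))
})

test_that("mean curve increases with perturbation on structured graphs", {
  rho <- vapply(1:10, function(s) {
    sim <- default_sbm(seed = s)
    cs <- stability_curves(sim$graph, "louvain", quick_grid(), seed = s)
    stats::cor(mean_curve(cs), cs$levels, method = "spearman")
  }, numeric(1))
  expect_gt(mean(rho), 0)
  expect_gte(sum(rho > 0), 9L)
})

test_that("ER graphs destabilize almost immediately (15 of 20 seeds)", {
  grid <- perturbation_grid(levels = c(0.05, 0.60), replicates = 3)
  wins <- 0L
  for (s in 1:20) {
    g <- er_graph(200, 0.05, seed = s)
    cs <- stability_curves(g, "louvain", grid, seed = s + 50)
    mc <- mean_curve(cs)
    wins <- wins + (mc[1L] > 0.5 * mc[2L])
  }
  expect_gte(wins, 15L)
})

test_that("null_robustness pairs observed and null curve sets", {
  sim <- sbm_graph(c(25L, 25L), 0.4, 0.02, seed = 7)
  res <- null_robustness(sim$graph, "louvain", quick_grid(), seed = 8)
  expect_s3_class(res, "netstab_result")
  expect_named(res$curves, c("observed", "null"))
  expect_equal(res$curves$observed$condition, "observed")
  expect_equal(res$curves$null$condition, "null")
  expect_named(res$reference, c("observed", "null"))
  rk <- rank_by_auc(res)
  expect_lt(rk$auc[rk$condition == "observed"],
            rk$auc[rk$condition == "null"])
})

test_that("star graph: observed and null processes coincide", {
  # the configuration model cannot rearrange a star, so both conditions run
  # the same generating process up to seeds
  star <- igraph::make_star(40, mode = "undirected")
  igraph::V(star)$name <- paste0("s", 1:40)
  grid <- perturbation_grid(levels = seq(0.1, 0.5, 0.1), replicates = 6)
  res <- suppressWarnings(null_robustness(star, "louvain", grid, seed = 9))
  m_obs <- mean(res$curves$observed$values)
  m_null <- mean(res$curves$null$values)
  expect_lt(abs(m_obs - m_null), 0.35)
  tst <- iwt_curve_test(res$curves$observed, res$curves$null,
                        n_perm = 400, seed = 10)
  expect_gt(min(tst$p_adjusted), 0.05)
})

test_that("compare_methods uses a paired design with shared perturbations", {
  sim <- sbm_graph(c(20L, 20L), 0.5, 0.03, seed = 11)
  expect_warning(
    res <- compare_methods(sim$graph, list("louvain", "louvain"),
                           quick_grid(), seed = 12),
    "duplicate")
  expect_identical(res$curves[[1L]]$values, res$curves[[2L]]$values)
  expect_named(res$curves, c("louvain", "louvain.1"))

  res3 <- compare_methods(sim$graph,
                          list("louvain", "labelprop", "walktrap"),
                          quick_grid(), seed = 12)
  expect_length(res3$curves, 3L)
  # paired design: louvain's curve is unchanged by adding other methods
  res2 <- compare_methods(sim$graph, list("louvain", "walktrap"),
                          quick_grid(), seed = 12)
  expect_identical(res3$curves[["louvain"]]$values,
                   res2$curves[["louvain"]]$values)
  expect_error(compare_methods(sim$graph, list("louvain"), quick_grid()),
               "at least 2")
})

test_that("results round-trip through JSON and long CSV", {
  sim <- sbm_graph(c(15L, 15L), 0.6, 0.05, seed = 13)
  res <- compare_methods(sim$graph, list("louvain", "fastgreedy"),
                         perturbation_grid(levels = c(0.2, 0.4),
                                           replicates = 3),
                         seed = 14)
  f <- withr::local_tempfile(fileext = ".json")
  write_result_json(res, f)
  rt <- read_result_json(f)
  expect_equal(rt$curves[["louvain"]]$values, res$curves[["louvain"]]$values)
  expect_equal(rt$grid$levels, res$grid$levels)
  expect_equal(rt$measure, res$measure)
  expect_equal(rt$reference[["louvain"]], res$reference[["louvain"]])
  expect_equal(rank_by_auc(rt), rank_by_auc(res))

  df <- as_curves_df(res)
  expect_equal(nrow(df), 2 * 2 * 3)
  expect_named(df, c("level", "replicate", "method", "condition", "value"))
  fc <- withr::local_tempfile(fileext = ".csv")
  write_curves_csv(res, fc)
  back <- utils::read.csv(fc)
  expect_equal(back$value, df$value)
})

test_that("null_robustness is deterministic end to end", {
  sim <- sbm_graph(c(15L, 15L), 0.6, 0.05, seed = 15)
  grid <- perturbation_grid(levels = c(0.2, 0.4), replicates = 2)
  r1 <- null_robustness(sim$graph, "louvain", grid, seed = 16)
  r2 <- null_robustness(sim$graph, "louvain", grid, seed = 16, workers = 2)
  expect_identical(r1$curves$observed$values, r2$curves$observed$values)
  expect_identical(r1$curves$null$values, r2$curves$null$values)
})
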