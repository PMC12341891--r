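# helper to wrap a levels x replicates matrix as a curve_set
make_cs <- function(values, levels = seq(0.05, 0.60, by = 0.05),
                    method = "m", condition = "observed", measure = "vi") {
  netstab:::new_curve_set(values, levels, method, condition, measure)
}

# synthetic curve sets: common smooth mean + iid noise, optional offset
sim_curves <- function(seed, reps = 10L, offset = 0, sigma = 0.02,
                       levels = seq(0.05, 0.60, by = 0.05)) {
  base <- 1.5 * levels
  withr::with_seed(seed, {
    a <- matrix(base, length(levels), reps) +
      matrix(rnorm(length(levels) * reps, sd = sigma), length(levels))
    b <- matrix(base + offset, length(levels), reps) +
      matrix(rnorm(length(levels) * reps, sd = sigma), length(levels))
    list(a = make_cs(a), b = make_cs(b))
  })
}

test_that("trapezoidal AUC matches closed forms", {
  lv <- seq(0.05, 0.60, by = 0.05)
  expect_equal(curve_auc(lv, rep(1, 12)), 0.55, tolerance = 1e-12)
  expect_equal(curve_auc(lv, rep(0, 12)), 0)
  expect_equal(curve_auc(lv, lv), (0.60^2 - 0.05^2) / 2, tolerance = 1e-12)
  expect_equal(curve_auc(lv, 3 * lv + 2), 3 * 0.17875 + 2 * 0.55,
               tolerance = 1e-12)
  expect_error(curve_auc(lv, rep(1, 5)), "same length")
  expect_error(curve_auc(c(0.2, 0.1), c(1, 1)), "increasing")
})

test_that("rank_by_auc orders ascending and breaks ties lexicographically", {
  lv <- seq(0.05, 0.60, by = 0.05)
  mk <- function(m, v) make_cs(matrix(v, 12, 2), method = m)
  res <- structure(list(kind = "comparison",
                        graph_summary = list(n_nodes = 5, n_edges = 5),
                        grid = perturbation_grid(replicates = 2),
                        measure = "vi", seed = 1, reference = list(),
                        curves = list(zeta = mk("zeta", 1),
                                      alpha = mk("alpha", 1),
                                      mid = mk("mid", 0.5))),
                   class = "netstab_result")
  rk <- rank_by_auc(res)
  expect_equal(rk$method, c("mid", "alpha", "zeta"))
  expect_equal(rk$auc, c(0.275, 0.55, 0.55))
})

test_that("gp test: identical curve sets give no evidence", {
  cs <- sim_curves(1)$a
  tst <- gp_curve_test(cs, cs, seed = 1)
  expect_lt(tst$bayes_factor, 1.05)
  expect_equal(tst$verdict, "none")
})

test_that("gp test is symmetric in its arguments", {
  s <- sim_curves(2, offset = 0.3)
  t1 <- gp_curve_test(s$a, s$b, seed = 3)
  t2 <- gp_curve_test(s$b, s$a, seed = 3)
  expect_identical(t1$bayes_factor, t2$bayes_factor)
  expect_identical(t1$log_ml_structured, t2$log_ml_structured)
})

test_that("gp test detects a clear offset (10 seeds, all strong)", {
  for (s in 1:10) {
    sim <- sim_curves(s, offset = 0.5, sigma = 0.02)
    tst <- gp_curve_test(sim$a, sim$b, seed = s)
    expect_gt(tst$bayes_factor, 100)
    expect_equal(tst$verdict, "strong")
  }
})

test_that("gp test input validation", {
  s <- sim_curves(4)
  short <- make_cs(s$a$values[1:6, ], levels = seq(0.05, 0.30, by = 0.05))
  expect_error(gp_curve_test(s$a, short), "different perturbation grids")
  mm <- s$b
  mm$measure <- "nmi"
  expect_error(gp_curve_test(s$a, mm), "different measures")
})

test_that("iwt: identical sets give all adjusted p = 1", {
  cs <- sim_curves(5)$a
  tst <- iwt_curve_test(cs, cs, n_perm = 200, seed = 6)
  expect_equal(tst$p_adjusted, rep(1, 12))
})

test_that("iwt detects a 5-sigma shift at every level", {
  sim <- sim_curves(7, offset = 5 * 0.02, sigma = 0.02)
  tst <- iwt_curve_test(sim$a, sim$b, n_perm = 1000, seed = 8)
  expect_length(tst$p_adjusted, 12L)
  expect_true(all(tst$p_adjusted <= 0.05))
})

test_that("iwt adjusted p-values dominate pointwise p-values", {
  for (s in 1:5) {
    sim <- sim_curves(s + 20, offset = 0.01, sigma = 0.02)
    tst <- iwt_curve_test(sim$a, sim$b, n_perm = 300, seed = s)
    expect_true(all(tst$p_adjusted >= tst$p_pointwise - 1e-12))
    expect_true(all(tst$p_adjusted >= 0 & tst$p_adjusted <= 1))
  }
})

test_that("iwt is invariant to replicate relabeling within groups", {
  # the observed statistic is exactly invariant; the permutation p-values
  # only in distribution, so allow Monte-Carlo slack there
  sim <- sim_curves(9, offset = 0.05)
  perm <- sim$a
  perm$values <- perm$values[, c(3, 1, 2, 10, 4:9)]
  t1 <- iwt_curve_test(sim$a, sim$b, n_perm = 500, seed = 10)
  t2 <- iwt_curve_test(perm, sim$b, n_perm = 500, seed = 10)
  expect_equal(unname(t1$statistic), unname(t2$statistic))
  expect_equal(t1$p_adjusted, t2$p_adjusted, tolerance = 0.1)
})

test_that("iwt warns for tiny permutation counts and records it", {
  sim <- sim_curves(11)
  expect_warning(tst <- iwt_curve_test(sim$a, sim$b, n_perm = 50, seed = 1),
                 "n_perm")
  expect_match(tst$warnings, "n_perm")
})

test_that("power increases with the offset for both tests", {
  offs <- c(0.01, 0.05, 0.25)
  bf <- p <- numeric(length(offs))
  for (i in seq_along(offs)) {
    sim <- sim_curves(12, offset = offs[i], sigma = 0.02)
    bf[i] <- gp_curve_test(sim$a, sim$b, seed = 13)$bayes_factor
    p[i] <- max(iwt_curve_test(sim$a, sim$b, n_perm = 500, seed = 14)$p_adjusted)
  }
  expect_true(all(diff(log(bf)) > 0))
  expect_true(all(diff(p) <= 0))
})

test_that("iwt CSV export writes one row per level", {
  sim <- sim_curves(15, offset = 0.1)
  tst <- iwt_curve_test(sim$a, sim$b, n_perm = 200, seed = 16)
  f <- withr::local_tempfile(fileext = ".csv")
  write_iwt_csv(tst, f)
  df <- utils::read.csv(f)
  expect_equal(nrow(df), 12L)
  expect_named(df, c("level", "p_adj"))
})
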