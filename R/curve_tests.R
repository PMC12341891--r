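# Deciding between stability-curve sets: trapezoidal AUC ranking, a
# Gaussian-process Bayes factor on the paired curve difference, and an
# interval-wise permutation test treating replicate curves as functional
# observations.

#' Trapezoidal area under a stability curve
#'
#' @param levels Strictly increasing perturbation fractions.
#' @param curve Mean distance per level (same length as `levels`).
#' @return Non-negative area; exact for piecewise-linear curves.
#' @export
#' @examples
#' curve_auc(seq(0.05, 0.60, by = 0.05), rep(1, 12))  # 0.55
curve_auc <- function(levels, curve) {
  if (length(levels) != length(curve)) {
    stop("`levels` and `curve` must have the same length (",
         length(levels), " vs ", length(curve), ")", call. = FALSE)
  }
  if (length(levels) < 2L || any(diff(levels) <= 0)) {
    stop("`levels` must be >= 2 strictly increasing values", call. = FALSE)
  }
  sum(diff(levels) * (utils::head(curve, -1) + utils::tail(curve, -1)) / 2)
}

#' Rank curve sets by AUC of their mean curve
#'
#' Lower AUC = more robust clustering; ties are broken by method name
#' (lexicographic), then condition.
#'
#' @param result A `netstab_result`.
#' @return Data frame `method, condition, auc`, ascending by `auc`.
#' @export
rank_by_auc <- function(result) {
  stopifnot(inherits(result, "netstab_result"))
  df <- do.call(rbind, lapply(result$curves, function(cs) {
    data.frame(method = cs$method, condition = cs$condition,
               auc = curve_auc(cs$levels, mean_curve(cs)),
               row.names = NULL)
  }))
  df <- df[order(df$auc, df$method, df$condition), , drop = FALSE]
  rownames(df) <- NULL
  df
}

check_curve_pair <- function(a, b) {
  stopifnot(inherits(a, "curve_set"), inherits(b, "curve_set"))
  if (length(a$levels) != length(b$levels) ||
      any(a$levels != b$levels)) {
    stop("curve sets are on different perturbation grids", call. = FALSE)
  }
  if (!identical(a$measure, b$measure)) {
    stop("curve sets use different measures (", a$measure, " vs ",
         b$measure, ")", call. = FALSE)
  }
}

# log marginal likelihood of y ~ N(0, K); returns -Inf on failed Cholesky
gp_lml <- function(y, K) {
  ch <- tryCatch(chol(K), error = function(e) NULL)
  if (is.null(ch)) return(-Inf)
  alpha <- backsolve(ch, backsolve(ch, y, transpose = TRUE))
  -0.5 * sum(y * alpha) - sum(log(diag(ch))) -
    0.5 * length(y) * log(2 * pi)
}

#' Gaussian-process Bayes factor between two curve sets
#'
#' Forms the paired replicate differences `d(l, r) = a[l, r] - b[l, r]` and
#' compares two zero-mean Gaussian models for `d` as a function of the
#' perturbation level: M0, white noise only, versus M1, a squared-
#' exponential Gaussian process plus white noise. Hyperparameters of M1
#' (lengthscale bounded to `[grid step, grid span]`, signal and noise
#' variances with a 1e-6 noise-sd floor) are optimized by maximizing the
#' marginal likelihood with multiple restarts; M0's noise variance has the
#' closed-form MLE. The Bayes factor `exp(LML1 - LML0)` measures the
#' evidence that the two curve processes differ; following common
#' convention, > 100 is read as strong evidence, 3-100 substantial,
#' otherwise none. Swapping `a` and `b` negates `d` and leaves the Bayes
#' factor unchanged.
#'
#' @param a,b `curve_set`s sharing grid and measure (same replicate count).
#' @param restarts Optimizer restarts for M1 (default 5).
#' @param seed Integer seed for restart initialization.
#' @return A `gp_test` object with fields `log_ml_structured`,
#'   `log_ml_noise`, `bayes_factor`, `verdict`.
#' @export
gp_curve_test <- function(a, b, restarts = 5L, seed = 1L) {
  check_curve_pair(a, b)
  if (!identical(dim(a$values), dim(b$values))) {
    stop("curve sets have different replicate counts", call. = FALSE)
  }
  d <- a$values - b$values
  x <- rep(a$levels, times = ncol(d))
  y <- as.vector(d)
  n <- length(y)

  # M0: iid zero-mean noise, variance at its MLE
  s2_floor <- 1e-12  # noise sd floor 1e-6
  s2_0 <- max(mean(y^2), s2_floor)
  lml0 <- -0.5 * n * log(2 * pi * s2_0) - sum(y^2) / (2 * s2_0)

  # M1: SE kernel + noise; optimize log hyperparameters
  dx2 <- outer(x, x, "-")^2
  span <- max(x) - min(x)
  step <- min(diff(a$levels))
  vy <- max(stats::var(y), s2_floor)
  neg_lml <- function(th) {
    ell <- exp(th[1L]); s2f <- exp(th[2L]); s2n <- exp(th[3L])
    K <- s2f * exp(-0.5 * dx2 / ell^2) + diag(s2n, n)
    v <- -gp_lml(y, K)
    if (!is.finite(v)) 1e10 else v
  }
  lower <- log(c(step, s2_floor, s2_floor))
  upper <- log(c(span, 100 * vy, 100 * vy))
  upper <- pmax(upper, lower + 1e-6)  # 2-level grids: step == span
  inits <- list(log(c(span / 3, vy, vy / 10)))
  if (restarts > 1L) {
    extra <- with_seed(substream_seed(seed, 41L), {
      lapply(seq_len(restarts - 1L), function(i) {
        lower + stats::runif(3) * (upper - lower)
      })
    })
    inits <- c(inits, extra)
  }
  best <- NULL
  for (th0 in inits) {
    th0 <- pmin(pmax(th0, lower), upper)
    fit <- tryCatch(
      stats::optim(th0, neg_lml, method = "L-BFGS-B",
                   lower = lower, upper = upper,
                   control = list(maxit = 200)),
      error = function(e) NULL)
    if (!is.null(fit) && (is.null(best) || fit$value < best$value)) {
      best <- fit
    }
  }
  if (is.null(best)) {
    stop("GP optimization failed for the structured model after ",
         restarts, " restarts", call. = FALSE)
  }
  lml1 <- -best$value
  bf <- exp(lml1 - lml0)
  verdict <- if (bf > 100) "strong" else if (bf > 3) "substantial" else "none"
  structure(list(log_ml_structured = lml1, log_ml_noise = lml0,
                 bayes_factor = bf, verdict = verdict,
                 thresholds = c(none = 3, substantial = 100),
                 n = n, hyperparameters = stats::setNames(
                   exp(best$par), c("lengthscale", "signal_var", "noise_var"))),
            class = "gp_test")
}

#' @exportS3Method
print.gp_test <- function(x, ...) {
  cat("<gp_test> Bayes factor =", format(x$bayes_factor, digits = 4),
      "->", x$verdict, "evidence\n")
  cat("  log ML: structured", format(x$log_ml_structured, digits = 6),
      "/ noise-only", format(x$log_ml_noise, digits = 6), "\n")
  invisible(x)
}

# interval index pairs (i <= j) over L levels
interval_index <- function(L) {
  idx <- which(upper.tri(matrix(0, L, L), diag = TRUE), arr.ind = TRUE)
  idx[order(idx[, "row"], idx[, "col"]), , drop = FALSE]
}

#' Interval-wise permutation test between two curve sets
#'
#' Treats each replicate curve as a functional observation on the grid.
#' The pointwise statistic is the squared difference of group means,
#' `T(l) = (mean_a(l) - mean_b(l))^2`; every contiguous interval of levels
#' gets the statistic `S(I) = sum_{l in I} T(l)`, and its p-value is the
#' permutation tail probability under `n_perm` random reassignments of
#' whole curves to the two groups. The adjusted p-value at a level is the
#' maximum interval p-value over all intervals containing that level
#' (interval-wise error control), so adjusted p-values always dominate the
#' pointwise ones.
#'
#' @inheritParams gp_curve_test
#' @param n_perm Number of permutations (default 1000; < 100 records a
#'   warning in the result).
#' @return An `iwt_test` with `p_adjusted` and `p_pointwise` (one per
#'   level), the observed `statistic`, `n_perm`, and any `warnings`.
#' @export
iwt_curve_test <- function(a, b, n_perm = 1000L, seed = 1L) {
  check_curve_pair(a, b)
  warnings <- character(0)
  if (n_perm < 100L) {
    warnings <- "n_perm < 100: permutation p-values are coarse"
    warning(warnings, call. = FALSE)
  }
  ra <- ncol(a$values)
  rb <- ncol(b$values)
  if (ra < 2L || rb < 2L) stop("each curve set needs >= 2 replicates",
                               call. = FALSE)
  L <- length(a$levels)
  X <- rbind(t(a$values), t(b$values))  # (ra+rb) x L replicate curves
  nt <- ra + rb

  t_stat <- function(ia) {
    (colMeans(X[ia, , drop = FALSE]) -
       colMeans(X[-ia, , drop = FALSE]))^2
  }
  T_obs <- t_stat(seq_len(ra))

  # group-A membership matrix for all permutations -> vectorized means
  G <- with_seed(substream_seed(seed, 17L), {
    t(vapply(seq_len(n_perm), function(i) {
      z <- numeric(nt); z[sample.int(nt, ra)] <- 1; z
    }, numeric(nt)))
  })
  mean_a <- (G %*% X) / ra
  mean_b <- ((1 - G) %*% X) / rb
  T_perm <- (mean_a - mean_b)^2  # n_perm x L

  cs_obs <- c(0, cumsum(T_obs))
  cs_perm <- cbind(0, t(apply(T_perm, 1L, cumsum)))
  if (L == 1L) cs_perm <- matrix(cs_perm, ncol = 2L)
  iv <- interval_index(L)
  p_int <- vapply(seq_len(nrow(iv)), function(k) {
    i <- iv[k, "row"]; j <- iv[k, "col"]
    s_obs <- cs_obs[j + 1L] - cs_obs[i]
    s_perm <- cs_perm[, j + 1L] - cs_perm[, i]
    (1 + sum(s_perm >= s_obs)) / (1 + n_perm)
  }, numeric(1))

  p_point <- p_int[iv[, "row"] == iv[, "col"]]
  p_adj <- vapply(seq_len(L), function(l) {
    max(p_int[iv[, "row"] <= l & iv[, "col"] >= l])
  }, numeric(1))

  structure(list(levels = a$levels, statistic = T_obs,
                 p_pointwise = p_point, p_adjusted = p_adj,
                 n_perm = as.integer(n_perm), warnings = warnings),
            class = "iwt_test")
}

#' @exportS3Method
print.iwt_test <- function(x, ...) {
  cat("<iwt_test>", x$n_perm, "permutations\n")
  print(data.frame(level = x$levels, p_adjusted = x$p_adjusted),
        row.names = FALSE)
  invisible(x)
}

#' Write adjusted p-values as CSV
#'
#' @param test An `iwt_test`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_iwt_csv <- function(test, path) {
  stopifnot(inherits(test, "iwt_test"))
  utils::write.csv(data.frame(level = test$levels, p_adj = test$p_adjusted),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
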