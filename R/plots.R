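# Base-graphics visualization: stability-curve ribbons, multi-result
# overlays, and AUC bars. Curves are plotted on the raw distance scale, so
# "lowest curve = most robust" can be read directly.

curve_palette <- function(n) {
  grDevices::hcl.colors(max(n, 2L), palette = "Dark 3")[seq_len(n)]
}

#' Plot a robustness result
#'
#' Draws, for every curve set, the replicate-mean stability curve with a
#' mean +/- SD ribbon over the perturbation levels.
#'
#' @param x A `netstab_result`.
#' @param main Plot title.
#' @param ... Passed to [graphics::matplot()].
#' @return `x`, invisibly.
#' @export
plot.netstab_result <- function(x, main = NULL, ...) {
  curves <- x$curves
  cols <- curve_palette(length(curves))
  levels <- curves[[1L]]$levels
  means <- vapply(curves, mean_curve, numeric(length(levels)))
  sds <- vapply(curves, function(cs) apply(cs$values, 1, stats::sd),
                numeric(length(levels)))
  ylim <- c(0, max(means + sds))
  graphics::matplot(levels, means, type = "n", ylim = ylim,
                    xlab = "perturbation level (fraction of edges rewired)",
                    ylab = paste0("distance (", x$measure, ")"),
                    main = main %||% paste("stability curves -", x$kind), ...)
  for (i in seq_along(curves)) {
    graphics::polygon(c(levels, rev(levels)),
                      c(means[, i] + sds[, i], rev(means[, i] - sds[, i])),
                      col = grDevices::adjustcolor(cols[i], alpha.f = 0.2),
                      border = NA)
    graphics::lines(levels, means[, i], col = cols[i], lwd = 2)
    graphics::points(levels, means[, i], col = cols[i], pch = 16, cex = 0.7)
  }
  lab <- vapply(curves, function(cs)
    paste0(cs$method, " [", cs$condition, "]"), character(1))
  graphics::legend("topleft", legend = lab, col = cols, lwd = 2, bty = "n",
                   cex = 0.8)
  invisible(x)
}

#' Overlay the mean curves of several results
#'
#' @param results List of `netstab_result`s sharing the perturbation grid.
#' @param main Plot title.
#' @return `results`, invisibly.
#' @export
plot_multi_compare <- function(results, main = "stability curves") {
  stopifnot(length(results) >= 1L)
  curves <- unlist(lapply(results, function(r) r$curves), recursive = FALSE)
  levels <- curves[[1L]]$levels
  for (cs in curves) {
    if (length(cs$levels) != length(levels) || any(cs$levels != levels)) {
      stop("results are on different perturbation grids", call. = FALSE)
    }
  }
  cols <- curve_palette(length(curves))
  means <- vapply(curves, mean_curve, numeric(length(levels)))
  graphics::matplot(levels, means, type = "b", pch = 16, lty = 1, lwd = 2,
                    col = cols, ylim = c(0, max(means)),
                    xlab = "perturbation level (fraction of edges rewired)",
                    ylab = paste0("distance (", curves[[1L]]$measure, ")"),
                    main = main)
  lab <- vapply(curves, function(cs)
    paste0(cs$method, " [", cs$condition, "]"), character(1))
  graphics::legend("topleft", legend = lab, col = cols, lwd = 2, bty = "n",
                   cex = 0.8)
  invisible(results)
}

#' Bar chart of AUC ranking
#'
#' @param result A `netstab_result`.
#' @param main Plot title.
#' @return The [rank_by_auc()] table, invisibly.
#' @export
plot_auc <- function(result, main = "area under stability curve") {
  rk <- rank_by_auc(result)
  graphics::barplot(rk$auc,
                    names.arg = paste0(rk$method, "\n[", rk$condition, "]"),
                    col = curve_palette(nrow(rk)), ylab = "AUC (lower = more robust)",
                    main = main, las = 2, cex.names = 0.7)
  invisible(rk)
}
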