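# The robustness engine: stability curves over a perturbation grid, the
# single-method validation against a configuration-model null, and the
# multi-method paired comparison.
#
# Every (level, replicate[, method]) cell draws its RNG from its own
# substream of the base seed, which makes the whole engine a pure function
# of (graph, methods, grid, measure, seed): results are bit-identical for
# any worker count or scheduling order.

# stream tags, to keep substreams of the same cell distinct by purpose
.STREAM_REWIRE <- 1L
.STREAM_DETECT <- 2L
.STREAM_NULL <- 3L

#' Define a perturbation grid
#'
#' The default grid is 12 levels, 5% to 60% in 5% steps, with 10 replicates
#' per level: rewiring more than ~60% of the edges makes any graph
#' essentially random, so higher levels carry no signal. Level 0 is a
#' degenerate diagnostic point (distance 0 for deterministic methods) and
#' is only included on request.
#'
#' @param levels Strictly increasing fractions in `(0, 1]`.
#' @param replicates Replicates per level (>= 2).
#' @param include_zero Prepend the diagnostic level 0.
#' @return A `perturbation_grid` object.
#' @export
perturbation_grid <- function(levels = seq(0.05, 0.60, by = 0.05),
                              replicates = 10L, include_zero = FALSE) {
  levels <- as.numeric(levels)
  if (length(levels) < 1L || anyNA(levels) || any(levels <= 0) ||
      any(levels > 1) || any(diff(levels) <= 0)) {
    stop("`levels` must be strictly increasing fractions in (0, 1]",
         call. = FALSE)
  }
  if (!is.numeric(replicates) || replicates < 2L) {
    stop("`replicates` must be >= 2", call. = FALSE)
  }
  if (isTRUE(include_zero)) levels <- c(0, levels)
  structure(list(levels = levels, replicates = as.integer(replicates)),
            class = "perturbation_grid")
}

#' @exportS3Method
print.perturbation_grid <- function(x, ...) {
  cat("<perturbation_grid>", length(x$levels), "levels (",
      min(x$levels), "-", max(x$levels), "),", x$replicates, "replicates\n")
  invisible(x)
}

new_curve_set <- function(values, levels, method_label, condition, measure) {
  dimnames(values) <- list(level = format(levels, trim = TRUE),
                           replicate = seq_len(ncol(values)))
  structure(list(values = values, levels = levels, method = method_label,
                 condition = condition, measure = measure),
            class = "curve_set")
}

#' @exportS3Method
print.curve_set <- function(x, ...) {
  cat("<curve_set>", x$method, "/", x$condition, "/", x$measure, ":",
      nrow(x$values), "levels x", ncol(x$values), "replicates\n")
  invisible(x)
}

#' Replicate-mean stability curve of a curve set
#'
#' @param cs A `curve_set`.
#' @return Numeric vector of per-level means.
#' @export
mean_curve <- function(cs) {
  stopifnot(inherits(cs, "curve_set"))
  rowMeans(cs$values)
}

check_grid <- function(grid) {
  if (!inherits(grid, "perturbation_grid")) {
    stop("`grid` must be built with perturbation_grid()", call. = FALSE)
  }
  grid
}

# Core loop shared by stability_curves / compare_methods: one rewired graph
# per (level, replicate) cell, every method applied to it (paired design).
run_cells <- function(graph, methods, grid, measure, seed, workers = 1L) {
  n <- igraph::vcount(graph)
  labels <- vapply(methods, function(m) m$label, character(1))
  mh <- vapply(labels, string_seed, integer(1))
  refs <- lapply(seq_along(methods), function(mi) {
    detect_communities(graph, methods[[mi]],
                       seed = substream_seed(seed, 0L, 0L, .STREAM_DETECT,
                                             mh[mi]))
  })
  one_level <- function(li) {
    lev <- grid$levels[li]
    vals <- matrix(NA_real_, length(methods), grid$replicates)
    for (r in seq_len(grid$replicates)) {
      gp <- if (lev == 0) graph else
        rewire_fraction(graph, lev,
                        seed = substream_seed(seed, li, r, .STREAM_REWIRE))
      for (mi in seq_along(methods)) {
        part <- detect_communities(gp, methods[[mi]],
                                   seed = substream_seed(seed, li, r,
                                                         .STREAM_DETECT,
                                                         mh[mi]))
        vals[mi, r] <- partition_distance(refs[[mi]], part, measure)
      }
    }
    vals
  }
  level_vals <- if (workers > 1L && .Platform$OS.type == "unix") {
    parallel::mclapply(seq_along(grid$levels), one_level,
                       mc.cores = workers, mc.preschedule = TRUE)
  } else {
    lapply(seq_along(grid$levels), one_level)
  }
  curves <- lapply(seq_along(methods), function(mi) {
    v <- t(vapply(level_vals, function(lv) lv[mi, ],
                  numeric(grid$replicates)))
    new_curve_set(v, grid$levels, labels[mi], "observed", measure)
  })
  list(curves = curves, refs = refs, labels = labels)
}

#' Stability curves of one method under edge rewiring
#'
#' For each level `l` and replicate `r`, independently rewires a fraction
#' `l` of the original graph's edges, re-runs the detection method, and
#' records the distance between the reference partition (detected on the
#' unperturbed graph) and the perturbed partition.
#'
#' @param graph A valid graph.
#' @param method A `detection_method` or method string.
#' @param grid A [perturbation_grid()].
#' @param measure Stability measure (`"vi"` default; see [as_distance()]).
#' @param seed Integer seed.
#' @param workers Number of parallel workers over levels; results are
#'   bit-identical for any value.
#' @return A `curve_set`.
#' @export
stability_curves <- function(graph, method, grid = perturbation_grid(),
                             measure = "vi", seed = 1L, workers = 1L) {
  graph <- check_graph(graph)
  check_grid(grid)
  if (is.character(method)) method <- parse_method(method)
  run_cells(graph, list(method), grid, measure, seed, workers)$curves[[1L]]
}

new_result <- function(kind, graph, grid, measure, seed, curves, refs) {
  structure(list(
    kind = kind,
    graph_summary = list(n_nodes = igraph::vcount(graph),
                         n_edges = igraph::ecount(graph)),
    grid = grid, measure = measure, seed = seed,
    reference = refs, curves = curves),
    class = "netstab_result")
}

#' @exportS3Method
print.netstab_result <- function(x, ...) {
  cat("<netstab_result>", x$kind, "on graph with",
      x$graph_summary$n_nodes, "nodes /", x$graph_summary$n_edges, "edges\n")
  cat("  grid:", length(x$grid$levels), "levels x", x$grid$replicates,
      "replicates; measure:", x$measure, "; seed:", x$seed, "\n")
  for (cs in x$curves) {
    cat(sprintf("  %-28s AUC(mean curve) = %.4f\n",
                paste0(cs$method, " [", cs$condition, "]"),
                curve_auc(cs$levels, mean_curve(cs))))
  }
  invisible(x)
}

#' Validate one method against a configuration-model null
#'
#' Runs [stability_curves()] on the observed graph and, with its own
#' reference partition, on a degree-matched configuration-model null graph.
#' If the observed communities are real, the observed curve stays below the
#' null curve: perturbation hurts a random graph's (spurious) partition
#' faster than a genuine one. The two curve sets feed [gp_curve_test()],
#' [iwt_curve_test()] and [rank_by_auc()].
#'
#' @inheritParams stability_curves
#' @param swaps_per_edge Passed to [configuration_null()].
#' @return A `netstab_result` with curve sets `observed` and `null`.
#' @export
null_robustness <- function(graph, method, grid = perturbation_grid(),
                            measure = "vi", seed = 1L, workers = 1L,
                            swaps_per_edge = 10L) {
  graph <- check_graph(graph)
  check_grid(grid)
  if (is.character(method)) method <- parse_method(method)
  gnull <- configuration_null(graph,
                              seed = substream_seed(seed, .STREAM_NULL),
                              swaps_per_edge = swaps_per_edge)
  obs <- run_cells(graph, list(method), grid, measure,
                   substream_seed(seed, 1L))
  nul <- run_cells(gnull, list(method), grid, measure,
                   substream_seed(seed, 2L), workers)
  ocs <- obs$curves[[1L]]
  ncs <- nul$curves[[1L]]
  ncs$condition <- "null"
  new_result("null_validation", graph, grid, measure, seed,
             curves = stats::setNames(list(ocs, ncs), c("observed", "null")),
             refs = list(observed = obs$refs[[1L]], null = nul$refs[[1L]]))
}

#' Compare detection methods on shared perturbed graphs
#'
#' Paired design: at each (level, replicate) cell a single rewired graph is
#' generated and every method is applied to it, which removes the
#' perturbation noise from between-method contrasts. Each method keeps its
#' own reference partition on the unperturbed graph. Rank the output with
#' [rank_by_auc()]; the lowest-AUC curve marks the most robust method (or
#' parameter setting, via [method_grid()]).
#'
#' @inheritParams stability_curves
#' @param methods List of at least two `detection_method`s (or method
#'   strings). Duplicate specifications are allowed (they yield identical
#'   curves by construction) but flagged with a warning.
#' @return A `netstab_result` with one `observed` curve set per method.
#' @export
compare_methods <- function(graph, methods, grid = perturbation_grid(),
                            measure = "vi", seed = 1L, workers = 1L) {
  graph <- check_graph(graph)
  check_grid(grid)
  methods <- lapply(methods, function(m) {
    if (is.character(m)) parse_method(m) else m
  })
  if (length(methods) < 2L) {
    stop("`compare_methods` needs at least 2 methods", call. = FALSE)
  }
  labels <- vapply(methods, function(m) m$label, character(1))
  if (anyDuplicated(labels)) {
    warning("duplicate method specification(s): ",
            paste(unique(labels[duplicated(labels)]), collapse = ", "),
            " - their curves will be identical", call. = FALSE)
  }
  run <- run_cells(graph, methods, grid, measure, seed, workers)
  names_u <- make.unique(labels)
  new_result("comparison", graph, grid, measure, seed,
             curves = stats::setNames(run$curves, names_u),
             refs = stats::setNames(run$refs, names_u))
}

#' Long-format data frame of a result's curves
#'
#' @param result A `netstab_result`.
#' @return Data frame with columns
#'   `level, replicate, method, condition, value`.
#' @export
as_curves_df <- function(result) {
  stopifnot(inherits(result, "netstab_result"))
  do.call(rbind, lapply(result$curves, function(cs) {
    data.frame(level = rep(cs$levels, ncol(cs$values)),
               replicate = rep(seq_len(ncol(cs$values)),
                               each = nrow(cs$values)),
               method = cs$method, condition = cs$condition,
               value = as.vector(cs$values), row.names = NULL)
  }))
}

#' Write a result's curves as long-format CSV
#'
#' @inheritParams as_curves_df
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_curves_csv <- function(result, path) {
  utils::write.csv(as_curves_df(result), path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

#' Serialize a result to JSON
#'
#' Full-precision, lossless round trip via [read_result_json()].
#'
#' @inheritParams as_curves_df
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_result_json <- function(result, path) {
  stopifnot(inherits(result, "netstab_result"))
  payload <- list(
    kind = result$kind,
    graph_summary = result$graph_summary,
    grid = list(levels = result$grid$levels,
                replicates = result$grid$replicates),
    measure = result$measure,
    seed = result$seed,
    reference = lapply(result$reference, function(p) {
      list(node_id = names(p), community = unname(p))
    }),
    curves = lapply(result$curves, function(cs) {
      list(method = cs$method, condition = cs$condition,
           measure = cs$measure, levels = cs$levels,
           values = unclass(unname(cs$values)))
    })
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a result written by [write_result_json()]
#'
#' @param path JSON file.
#' @return A `netstab_result`.
#' @export
read_result_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  grid <- perturbation_grid(levels = setdiff(x$grid$levels, 0),
                            replicates = x$grid$replicates,
                            include_zero = 0 %in% x$grid$levels)
  curves <- lapply(seq_len(if (is.data.frame(x$curves)) nrow(x$curves)
                           else length(x$curves)), function(i) {
    ci <- if (is.data.frame(x$curves)) lapply(x$curves, `[[`, i)
          else x$curves[[i]]
    vals <- ci$values
    if (is.list(vals)) vals <- do.call(rbind, vals)
    new_curve_set(matrix(as.numeric(vals), nrow = length(ci$levels)),
                  as.numeric(ci$levels), ci$method, ci$condition, ci$measure)
  })
  names(curves) <- names(x$curves) %||% vapply(curves, `[[`, "", "method")
  refs <- lapply(x$reference, function(p) {
    v <- p$community
    if (is.numeric(v)) v <- as.integer(v)
    stats::setNames(v, p$node_id)
  })
  structure(list(kind = x$kind,
                 graph_summary = as.list(x$graph_summary),
                 grid = grid, measure = x$measure, seed = x$seed,
                 reference = refs, curves = curves),
            class = "netstab_result")
}
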