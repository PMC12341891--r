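# Edge-rewiring perturbation and the configuration-model null.
#
# Rewiring replaces a chosen fraction of edges with uniformly random
# non-edges: node count and edge count are conserved but degrees are not.
# Degree preservation is deliberately reserved for the null model, so the
# perturbation and the null remain distinct operations.

#' Rewire a fraction of a graph's edges
#'
#' Removes exactly `k = round(fraction * |E|)` randomly chosen edges
#' (round-half-to-even) and replaces them with `k` edges drawn uniformly at
#' random from the node pairs not present in the *original* graph, so the
#' rewired graph is simple, has the same node and edge counts, and exactly
#' `k` of the original edges are absent. On weighted graphs the weight
#' multiset is conserved: weights of the removed edges are reassigned to
#' the new edges in random order; surviving edges keep their weights.
#'
#' @param graph A valid graph (see [check_graph()]).
#' @param fraction Fraction of edges to rewire, in `[0, 1]`. `fraction = 0`
#'   returns the input unchanged.
#' @param seed Integer seed; the operation is a pure function of
#'   `(graph, fraction, seed)`.
#' @return A rewired igraph object with the same vertex set and `|E|`.
#' @export
#' @examples
#' g <- er_graph(20, 0.3, seed = 1)
#' gp <- rewire_fraction(g, 0.5, seed = 7)
#' igraph::ecount(gp) == igraph::ecount(g)
rewire_fraction <- function(graph, fraction, seed = 1L) {
  graph <- check_graph(graph)
  if (!is.numeric(fraction) || length(fraction) != 1L || is.na(fraction) ||
      fraction < 0 || fraction > 1) {
    stop("`fraction` must be a single number in [0, 1]", call. = FALSE)
  }
  m <- igraph::ecount(graph)
  n <- igraph::vcount(graph)
  k <- as.integer(round(fraction * m))
  if (k == 0L) return(graph)

  orig_keys <- edge_keys(graph)
  n_pairs <- n * (n - 1) / 2
  if (n_pairs - m < k) {
    stop("graph too dense: cannot place ", k,
         " new edges among ", n_pairs - m, " absent node pairs",
         call. = FALSE)
  }

  with_seed(seed, {
    remove_idx <- sample.int(m, k)
    forbidden <- orig_keys  # all original edges are off-limits for new edges
    new_i <- integer(0)
    new_j <- integer(0)
    attempts <- 0L
    max_attempts <- 100L * k
    while (length(new_i) < k && attempts < max_attempts) {
      batch <- min(max(2L * (k - length(new_i)), 64L),
                   max_attempts - attempts)
      ci <- sample.int(n, batch, replace = TRUE)
      cj <- sample.int(n, batch, replace = TRUE)
      attempts <- attempts + batch
      ok <- ci != cj
      ci <- ci[ok]; cj <- cj[ok]
      keys <- pair_keys(ci, cj, n)
      # sequential-rejection semantics: within the batch, keep first
      # occurrences that are not forbidden
      keep <- !(keys %in% forbidden) & !duplicated(keys)
      ci <- ci[keep]; cj <- cj[keep]; keys <- keys[keep]
      take <- seq_len(min(length(keys), k - length(new_i)))
      new_i <- c(new_i, ci[take])
      new_j <- c(new_j, cj[take])
      forbidden <- c(forbidden, keys[take])
    }
    if (length(new_i) < k) {
      stop("failed to place ", k, " replacement edges after ",
           max_attempts, " attempts (graph too dense)", call. = FALSE)
    }

    el <- igraph::as_edgelist(graph, names = FALSE)
    kept <- setdiff(seq_len(m), remove_idx)
    out_el <- rbind(el[kept, , drop = FALSE], cbind(new_i, new_j))
    out <- igraph::graph_from_edgelist(out_el, directed = FALSE)
    out <- igraph::add_vertices(out, n - igraph::vcount(out))
    igraph::V(out)$name <- igraph::V(graph)$name
    if (graph_is_weighted(graph)) {
      w <- igraph::E(graph)$weight
      new_w <- if (k == 1L) w[remove_idx] else sample(w[remove_idx])
      # edge ids in `out` follow out_el's row order
      igraph::E(out)$weight <- c(w[kept], new_w)
    }
    out
  })
}

#' Degree-preserving configuration-model null graph
#'
#' Randomizes the graph by degree-preserving double-edge swaps
#' (`swaps_per_edge * |E|` attempted swaps; swaps that would create a
#' self-loop or duplicate edge are rejected), yielding a draw from the
#' simple-graph configuration model with exactly the input's degree
#' sequence. Weights, if present, are permuted uniformly over the new edge
#' set. A graph whose degree sequence admits no swap (e.g. a star) is
#' returned unchanged with a warning.
#'
#' @inheritParams rewire_fraction
#' @param swaps_per_edge Attempted swaps per edge (default 10).
#' @return An igraph object with the same degree sequence.
#' @export
#' @examples
#' sim <- sbm_graph(c(10, 10), 0.8, 0.05, seed = 1)
#' gn <- configuration_null(sim$graph, seed = 2)
#' identical(sort(igraph::degree(gn)), sort(igraph::degree(sim$graph)))
configuration_null <- function(graph, seed = 1L, swaps_per_edge = 10L) {
  graph <- check_graph(graph)
  if (!is.numeric(swaps_per_edge) || swaps_per_edge < 1) {
    stop("`swaps_per_edge` must be a positive integer", call. = FALSE)
  }
  m <- igraph::ecount(graph)
  with_seed(seed, {
    skel <- if (graph_is_weighted(graph)) {
      igraph::delete_edge_attr(graph, "weight")
    } else graph
    out <- igraph::rewire(skel, igraph::keeping_degseq(
      loops = FALSE, niter = as.integer(swaps_per_edge * m)))
    if (setequal(edge_keys(out), edge_keys(graph))) {
      warning("degree sequence admits no rearrangement; ",
              "returning the input graph topology", call. = FALSE)
    }
    if (graph_is_weighted(graph)) {
      w <- igraph::E(graph)$weight
      igraph::E(out)$weight <- if (m == 1L) w else sample(w)
    }
    out
  })
}
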