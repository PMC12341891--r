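# Synthetic generators with known ground truth: stochastic block model and
# Erdos-Renyi graphs, and Gaussian-mixture embeddings emulating a PC space.
# All are pure functions of (parameters, seed).

#' Stochastic block model graph with planted communities
#'
#' Each within-block node pair is an edge with probability `p_in`, each
#' between-block pair with probability `p_out`.
#'
#' @param block_sizes Positive integer sizes of the blocks.
#' @param p_in,p_out Within/between-block edge probabilities. `p_in <=
#'   p_out` triggers a warning (no assortative structure to recover).
#' @param seed Integer seed.
#' @return A list with `graph` (igraph, vertex names `"v1".."vn"`) and
#'   `partition` (planted block labels, named).
#' @export
#' @examples
#' sim <- sbm_graph(c(25, 25, 25, 25), p_in = 0.3, p_out = 0.02, seed = 1)
#' igraph::vcount(sim$graph)
sbm_graph <- function(block_sizes, p_in, p_out, seed = 1L) {
  block_sizes <- as.integer(block_sizes)
  if (length(block_sizes) < 1L || any(block_sizes < 1L)) {
    stop("`block_sizes` must be positive integers", call. = FALSE)
  }
  for (p in c(p_in, p_out)) {
    if (!is.numeric(p) || p < 0 || p > 1) {
      stop("edge probabilities must be in [0, 1]", call. = FALSE)
    }
  }
  if (p_in <= p_out) {
    warning("p_in <= p_out: planted blocks are not assortative",
            call. = FALSE)
  }
  n <- sum(block_sizes)
  k <- length(block_sizes)
  pm <- matrix(p_out, k, k)
  diag(pm) <- p_in
  g <- with_seed(seed, igraph::sample_sbm(n, pref.matrix = pm,
                                          block.sizes = block_sizes))
  igraph::V(g)$name <- paste0("v", seq_len(n))
  labels <- stats::setNames(rep(seq_len(k), block_sizes),
                            igraph::V(g)$name)
  list(graph = g, partition = labels)
}

#' Erdos-Renyi random graph G(n, p)
#'
#' @param n Number of nodes.
#' @param p Edge probability.
#' @param seed Integer seed.
#' @return An igraph object (vertex names `"v1".."vn"`). A graph with no
#'   edges is returned with a warning (the robustness engine rejects it).
#' @export
er_graph <- function(n, p, seed = 1L) {
  if (!is.numeric(n) || n < 1L) stop("`n` must be positive", call. = FALSE)
  if (!is.numeric(p) || p < 0 || p > 1) {
    stop("`p` must be in [0, 1]", call. = FALSE)
  }
  g <- with_seed(seed, igraph::sample_gnp(as.integer(n), p))
  igraph::V(g)$name <- paste0("v", seq_len(igraph::vcount(g)))
  if (igraph::ecount(g) == 0L) {
    warning("generated graph has no edges", call. = FALSE)
  }
  g
}

#' Gaussian-mixture embedding with known cluster labels
#'
#' Places `k` cluster centers along random directions, rescaled so the
#' closest pair of centers is exactly `separation` apart, splits the cells
#' evenly across clusters (sizes differ by at most 1), and adds isotropic
#' Gaussian noise with standard deviation `sigma`. Emulates the principal-
#' component space of a clustered single-cell dataset.
#'
#' @param n_cells Number of cells (>= 10).
#' @param k Number of clusters.
#' @param dims Embedding dimensionality (>= 2).
#' @param separation Minimum distance between cluster centers.
#' @param sigma Within-cluster noise SD.
#' @param seed Integer seed.
#' @return A list with `embedding` (an [embedding()]) and `labels`
#'   (cluster ids named by cell id).
#' @export
#' @examples
#' sim <- gaussian_mixture_embedding(60, k = 3, dims = 5,
#'                                   separation = 10, sigma = 1, seed = 1)
#' table(sim$labels)
gaussian_mixture_embedding <- function(n_cells, k, dims = 10L,
                                       separation = 10, sigma = 1,
                                       seed = 1L) {
  stopifnot(n_cells >= 10L, k >= 1L, dims >= 2L, separation > 0, sigma > 0)
  with_seed(seed, {
    centers <- matrix(stats::rnorm(k * dims), k, dims)
    if (k > 1L) {
      dmin <- min(stats::dist(centers))
      if (dmin == 0) stop("degenerate center draw", call. = FALSE)
      centers <- centers * (separation / dmin)
    }
    labels <- rep(seq_len(k), length.out = n_cells)
    labels <- sort(labels)
    coords <- centers[labels, , drop = FALSE] +
      matrix(stats::rnorm(n_cells * dims, sd = sigma), n_cells, dims)
    ids <- sprintf("cell_%04d", seq_len(n_cells))
    list(embedding = embedding(coords, cell_ids = ids),
         labels = stats::setNames(labels, ids))
  })
}
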