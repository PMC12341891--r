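# Cell-graph construction from a reduced-dimensional embedding, following
# the convention of standard single-cell pipelines: exact K nearest
# neighbors in PC space, then shared-nearest-neighbor edges weighted by the
# Jaccard overlap of the (k+1)-element neighbor sets (anchor included),
# pruned at a small threshold.

#' Construct an embedding object
#'
#' @param coords Numeric matrix, cells x dimensions (>= 2 dims, >= 10
#'   cells, no missing values). Row names, if present, become cell ids.
#' @param cell_ids Optional explicit cell identifiers.
#' @return An `embedding` object.
#' @export
embedding <- function(coords, cell_ids = NULL) {
  coords <- as.matrix(coords)
  if (!is.numeric(coords) || anyNA(coords) || any(!is.finite(coords))) {
    stop("`coords` must be a numeric matrix without missing values",
         call. = FALSE)
  }
  if (ncol(coords) < 2L) stop("embedding needs >= 2 dimensions", call. = FALSE)
  if (nrow(coords) < 10L) stop("embedding needs >= 10 cells", call. = FALSE)
  if (is.null(cell_ids)) cell_ids <- rownames(coords)
  if (is.null(cell_ids)) cell_ids <- sprintf("cell_%d", seq_len(nrow(coords)))
  if (length(cell_ids) != nrow(coords) || anyDuplicated(cell_ids)) {
    stop("`cell_ids` must be unique and match the number of rows",
         call. = FALSE)
  }
  rownames(coords) <- as.character(cell_ids)
  if (is.null(colnames(coords))) {
    colnames(coords) <- paste0("dim", seq_len(ncol(coords)))
  }
  structure(list(cell_ids = as.character(cell_ids), coords = coords),
            class = "embedding")
}

#' @exportS3Method
print.embedding <- function(x, ...) {
  cat("<embedding>", nrow(x$coords), "cells x", ncol(x$coords),
      "dimensions\n")
  invisible(x)
}

#' Read an embedding from CSV/TSV
#'
#' First column is the cell id; remaining columns are coordinates.
#'
#' @param path Delimited text file with header; the delimiter is inferred
#'   from the extension (`.tsv`/`.txt` = tab, otherwise comma).
#' @return An `embedding`.
#' @export
read_embedding <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  sep <- if (tolower(tools::file_ext(path)) %in% c("tsv", "txt")) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, check.names = FALSE)
  embedding(as.matrix(df[, -1L, drop = FALSE]), cell_ids = df[[1L]])
}

#' Write an embedding as CSV
#'
#' @param emb An `embedding`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_embedding <- function(emb, path) {
  stopifnot(inherits(emb, "embedding"))
  df <- data.frame(cell_id = emb$cell_ids, emb$coords, check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Exact K nearest neighbors in an embedding
#'
#' Brute-force Euclidean nearest neighbors (exact, not approximate),
#' excluding the cell itself; distance ties are broken deterministically by
#' cell order.
#'
#' @param emb An `embedding` (or numeric matrix).
#' @param k Number of neighbors, `1 <= k < n`.
#' @return A `knn_table`: integer matrix (cells x k) of neighbor indices,
#'   with `cell_ids` attached as an attribute and row names.
#' @export
knn_neighbors <- function(emb, k) {
  if (!inherits(emb, "embedding")) emb <- embedding(emb)
  n <- nrow(emb$coords)
  if (!is.numeric(k) || length(k) != 1L || k < 1L || k >= n) {
    stop("`k` must satisfy 1 <= k < number of cells (", n, ")",
         call. = FALSE)
  }
  k <- as.integer(k)
  D <- as.matrix(stats::dist(emb$coords))
  diag(D) <- Inf
  nn <- t(vapply(seq_len(n), function(i) {
    order(D[i, ], seq_len(n))[seq_len(k)]  # ties broken by cell order
  }, integer(k)))
  if (k == 1L) nn <- matrix(nn, ncol = 1L)
  rownames(nn) <- emb$cell_ids
  structure(nn, class = "knn_table", cell_ids = emb$cell_ids, k = k)
}

#' Shared-nearest-neighbor graph with Jaccard weights
#'
#' For every pair of cells where at least one lists the other among its K
#' nearest neighbors, the edge weight is the Jaccard similarity of their
#' neighbor sets (each set includes the cell itself, so sets have k+1
#' elements): `|N(i) & N(j)| / |N(i) | N(j)|`. Edges with weight `<= prune`
#' are dropped. This is the cell graph the robustness engine consumes.
#'
#' @param neighbors A `knn_table` from [knn_neighbors()].
#' @param prune Weight threshold (default 1/15, the common SNN pruning
#'   default).
#' @return A weighted undirected simple igraph object over all cells.
#' @export
snn_jaccard_graph <- function(neighbors, prune = 1 / 15) {
  stopifnot(inherits(neighbors, "knn_table"))
  if (!is.numeric(prune) || prune < 0 || prune >= 1) {
    stop("`prune` must be in [0, 1)", call. = FALSE)
  }
  n <- nrow(neighbors)
  k <- attr(neighbors, "k")
  ids <- attr(neighbors, "cell_ids")
  # indicator matrix of (k+1)-element neighbor sets (self included)
  M <- Matrix::sparseMatrix(
    i = c(rep(seq_len(n), k), seq_len(n)),
    j = c(as.vector(neighbors), seq_len(n)),
    x = 1, dims = c(n, n))
  inter <- Matrix::tcrossprod(M)          # |N(i) & N(j)|
  # candidate pairs: i in knn(j) or j in knn(i)
  A <- Matrix::sparseMatrix(i = rep(seq_len(n), k),
                            j = as.vector(neighbors),
                            x = 1, dims = c(n, n))
  cand <- methods::as(((A + Matrix::t(A)) > 0), "TsparseMatrix")
  sel <- cand@i < cand@j                  # upper triangle, 0-based slots
  ii <- cand@i[sel] + 1L
  jj <- cand@j[sel] + 1L
  ov <- inter[cbind(ii, jj)]
  jac <- ov / (2 * (k + 1) - ov)
  keep <- jac > prune
  g <- igraph::graph_from_edgelist(cbind(ii[keep], jj[keep]),
                                   directed = FALSE)
  g <- igraph::add_vertices(g, n - igraph::vcount(g))
  igraph::V(g)$name <- ids
  igraph::E(g)$weight <- jac[keep]
  g
}

#' Export a partition as a cell-annotation CSV
#'
#' Writes `cell_id, cluster` rows loadable by downstream single-cell
#' frameworks; the inverse of [read_annotations()].
#'
#' @param partition Cluster labels (named vector or `communities`).
#' @param cell_ids Cell identifiers, in order; must match the partition
#'   length (and its names, when named).
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
export_annotations <- function(partition, cell_ids, path) {
  p <- as_membership(partition)
  if (length(cell_ids) != length(p)) {
    stop("`cell_ids` length (", length(cell_ids),
         ") does not match partition length (", length(p), ")",
         call. = FALSE)
  }
  if (!is.null(names(p))) {
    if (!setequal(names(p), cell_ids)) {
      stop("`cell_ids` do not match the partition's names", call. = FALSE)
    }
    p <- p[as.character(cell_ids)]
  }
  utils::write.csv(data.frame(cell_id = cell_ids, cluster = unname(p)),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a cell-annotation CSV
#'
#' @param path CSV with columns `cell_id, cluster`.
#' @return Cluster labels named by cell id.
#' @export
read_annotations <- function(path) {
  df <- utils::read.csv(path, colClasses = "character")
  stats::setNames(df[[2L]], df[[1L]])
}
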