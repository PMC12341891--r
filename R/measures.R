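# Partition similarity/distance measures used as stability metrics.
#
# A partition is a vector of community labels, one per node, named by the
# node identifiers (names optional when both arguments share element
# order). All measures are computed from the contingency table of the two
# labelings; entropies use natural logarithms, so VI is reported in nats
# and bounded by log(n).

# Align two labelings and return their contingency table.
partition_table <- function(p, q) {
  p <- as_membership(p)
  q <- as_membership(q)
  if (length(p) != length(q)) {
    stop("partitions label different numbers of elements (",
         length(p), " vs ", length(q), ")", call. = FALSE)
  }
  if (!is.null(names(p)) && !is.null(names(q))) {
    if (!setequal(names(p), names(q)) || anyDuplicated(names(p))) {
      stop("partitions are over different element sets", call. = FALSE)
    }
    q <- q[names(p)]
  }
  table(p, q)
}

as_membership <- function(p) {
  if (inherits(p, "communities")) p <- igraph::membership(p)
  if (is.factor(p)) p <- as.character(p)
  if (!is.atomic(p) || length(p) < 1L || anyNA(p)) {
    stop("a partition must be a non-empty label vector without NA",
         call. = FALSE)
  }
  p
}

shannon_entropy <- function(counts) {
  pr <- counts / sum(counts)
  pr <- pr[pr > 0]
  -sum(pr * log(pr))
}

#' Variation of information between two partitions
#'
#' `VI = 2 H(p, q) - H(p) - H(q)` with natural-log entropies: a metric on
#' partitions, 0 iff identical, at most `log(n)` nats.
#'
#' @param p,q Label vectors (optionally named by node id), factors, or
#'   igraph `communities` objects over the same elements.
#' @return Non-negative distance in nats.
#' @export
#' @examples
#' variation_of_information(c(1, 1, 2, 2), c(1, 2, 1, 2))  # 2 * log(2)
variation_of_information <- function(p, q) {
  tab <- partition_table(p, q)
  v <- 2 * shannon_entropy(tab) -
    shannon_entropy(rowSums(tab)) - shannon_entropy(colSums(tab))
  max(v, 0)  # clip tiny negative rounding
}

#' Normalized mutual information between two partitions
#'
#' `NMI = I(p, q) / sqrt(H(p) H(q))`, in `[0, 1]`. When both partitions are
#' single-block (both entropies zero) the value is defined as 1; when
#' exactly one is single-block, mutual information is 0 and so is the NMI.
#'
#' @inheritParams variation_of_information
#' @return Similarity in `[0, 1]`.
#' @export
normalized_mutual_information <- function(p, q) {
  tab <- partition_table(p, q)
  hp <- shannon_entropy(rowSums(tab))
  hq <- shannon_entropy(colSums(tab))
  if (hp == 0 && hq == 0) return(1)
  if (hp == 0 || hq == 0) return(0)
  i <- hp + hq - shannon_entropy(tab)
  min(max(i / sqrt(hp * hq), 0), 1)
}

#' Adjusted Rand index between two partitions
#'
#' Permutation-model adjusted Rand index from the contingency table; 1 for
#' identical partitions, expectation 0 for independent random labelings.
#'
#' @inheritParams variation_of_information
#' @return A value `<= 1` (can be slightly negative).
#' @export
adjusted_rand <- function(p, q) {
  tab <- partition_table(p, q)
  n <- sum(tab)
  s_ij <- sum(choose(tab, 2))
  s_i <- sum(choose(rowSums(tab), 2))
  s_j <- sum(choose(colSums(tab), 2))
  tot <- choose(n, 2)
  expected <- s_i * s_j / tot
  maxi <- (s_i + s_j) / 2
  if (maxi == expected) return(1)  # both partitions trivial in the same way
  (s_ij - expected) / (maxi - expected)
}

#' Van Dongen split-join distance between two partitions
#'
#' `2n - sum_i max_j n_ij - sum_j max_i n_ij`: 0 iff identical, at most
#' `2n`.
#'
#' @inheritParams variation_of_information
#' @return Non-negative integer distance.
#' @export
split_join <- function(p, q) {
  tab <- partition_table(p, q)
  n <- sum(tab)
  2 * n - sum(apply(tab, 1, max)) - sum(apply(tab, 2, max))
}

#' Map a measure value to a distance
#'
#' Stability curves and their AUC require a distance (lower = more stable).
#' The distance measures (`vi`, `split_join`) pass through; the similarity
#' measures (`nmi`, `ari`) are mapped monotonically to `1 - value`.
#'
#' @param value Measure value.
#' @param measure One of `"vi"`, `"nmi"`, `"ari"`, `"split_join"`.
#' @param n Number of elements (unused; kept for interface symmetry with
#'   bounded measures).
#' @return Non-negative distance.
#' @export
as_distance <- function(value, measure = c("vi", "nmi", "ari", "split_join"),
                        n = NULL) {
  measure <- match.arg(measure)
  switch(measure,
    vi = value,
    split_join = value,
    nmi = 1 - value,
    ari = 1 - value)
}

measure_fun <- function(measure = c("vi", "nmi", "ari", "split_join")) {
  measure <- match.arg(measure)
  switch(measure,
    vi = variation_of_information,
    nmi = normalized_mutual_information,
    ari = adjusted_rand,
    split_join = split_join)
}

#' Distance between two partitions under a named stability measure
#'
#' Convenience wrapper: applies the measure and converts it with
#' [as_distance()]. VI is the default measure throughout the package.
#'
#' @inheritParams variation_of_information
#' @inheritParams as_distance
#' @return Non-negative distance.
#' @export
partition_distance <- function(p, q, measure = "vi") {
  as_distance(measure_fun(measure)(p, q), measure, n = length(as_membership(p)))
}

#' Write a partition as a two-column CSV
#'
#' @param partition Label vector named by node ids (or `communities`).
#' @param path Output file.
#' @param ids Optional explicit node ids (required if `partition` is
#'   unnamed); must match the partition length.
#' @return `path`, invisibly.
#' @export
write_partition <- function(partition, path, ids = NULL) {
  p <- as_membership(partition)
  if (is.null(ids)) ids <- names(p)
  if (is.null(ids)) stop("partition has no names; supply `ids`", call. = FALSE)
  if (length(ids) != length(p)) {
    stop("`ids` length (", length(ids), ") does not match partition length (",
         length(p), ")", call. = FALSE)
  }
  utils::write.csv(data.frame(node_id = ids, community = unname(p)),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a partition written by [write_partition()]
#'
#' @param path CSV with columns `node_id, community`.
#' @return Label vector named by node id.
#' @export
read_partition <- function(path) {
  df <- utils::read.csv(path, colClasses = "character")
  if (ncol(df) < 2L) stop("expected a two-column CSV", call. = FALSE)
  stats::setNames(df[[2L]], df[[1L]])
}
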