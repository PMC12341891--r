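# Independent brute-force oracles and small fixtures. These deliberately
# avoid the package's computation paths: measures are recomputed from
# explicit pair counting / elementwise probability sums, neighbor search
# from a full distance scan, and partitions are enumerated from scratch.

# ---- partition enumeration (restricted growth strings) ----

# All set partitions of n elements, as label vectors.
all_partitions <- function(n) {
  out <- list()
  grow <- function(labels, next_label) {
    i <- length(labels) + 1L
    if (i > n) {
      out[[length(out) + 1L]] <<- labels
      return(invisible())
    }
    for (lab in seq_len(next_label)) {
      grow(c(labels, lab), max(next_label, lab + 1L))
    }
  }
  grow(integer(0), 1L)
  out
}

random_partition <- function(n, max_k = n) {
  sample.int(max_k, n, replace = TRUE)
}

# ---- measure oracles ----

joint_probs <- function(p, q) {
  n <- length(p)
  pr <- matrix(0, length(unique(p)), length(unique(q)),
               dimnames = list(sort(unique(p)), sort(unique(q))))
  for (i in seq_len(n)) {
    pr[as.character(p[i]), as.character(q[i])] <-
      pr[as.character(p[i]), as.character(q[i])] + 1 / n
  }
  pr
}

# VI as conditional entropies H(X|Y) + H(Y|X), summed elementwise.
oracle_vi <- function(p, q) {
  pr <- joint_probs(p, q)
  px <- rowSums(pr)
  py <- colSums(pr)
  v <- 0
  for (i in seq_len(nrow(pr))) {
    for (j in seq_len(ncol(pr))) {
      if (pr[i, j] > 0) {
        v <- v - pr[i, j] * (log(pr[i, j] / px[i]) + log(pr[i, j] / py[j]))
      }
    }
  }
  unname(v)
}

oracle_nmi <- function(p, q) {
  pr <- joint_probs(p, q)
  px <- rowSums(pr)
  py <- colSums(pr)
  hx <- -sum(px * log(px))
  hy <- -sum(py * log(py))
  if (hx == 0 && hy == 0) return(1)
  if (hx == 0 || hy == 0) return(0)
  mi <- 0
  for (i in seq_len(nrow(pr))) {
    for (j in seq_len(ncol(pr))) {
      if (pr[i, j] > 0) mi <- mi + pr[i, j] * log(pr[i, j] / (px[i] * py[j]))
    }
  }
  unname(mi / sqrt(hx * hy))
}

# ARI by explicit enumeration of the n*(n-1)/2 element pairs.
oracle_ari <- function(p, q) {
  n <- length(p)
  a <- b <- cc <- d <- 0
  for (i in seq_len(n - 1L)) {
    for (j in seq(i + 1L, n)) {
      sp <- p[i] == p[j]
      sq <- q[i] == q[j]
      if (sp && sq) a <- a + 1
      else if (sp) b <- b + 1
      else if (sq) cc <- cc + 1
      else d <- d + 1
    }
  }
  denom <- (a + b) * (b + d) + (a + cc) * (cc + d)
  if (denom == 0) return(1)
  2 * (a * d - b * cc) / denom
}

# split-join by explicit set overlaps in both directions.
oracle_split_join <- function(p, q) {
  n <- length(p)
  dir_cost <- function(x, y) {
    tot <- 0
    for (lab in unique(x)) {
      members <- which(x == lab)
      best <- max(vapply(unique(y[members]), function(l2)
        sum(y[members] == l2), numeric(1)))
      tot <- tot + length(members) - best
    }
    tot
  }
  dir_cost(p, q) + dir_cost(q, p)
}

# ---- graph fixtures ----

triangle_graph <- function() {
  g <- igraph::make_graph(~ a - b, b - c, a - c)
  g
}

two_triangles <- function() {
  igraph::make_graph(~ a - b, b - c, a - c, d - e, e - f, d - f)
}

weighted_path <- function() {
  g <- igraph::make_graph(~ a - b, b - c, c - d)
  igraph::E(g)$weight <- c(0.5, 1.25, 3)
  g
}

# brute-force k nearest neighbors via full distance scan
oracle_knn <- function(coords, k) {
  n <- nrow(coords)
  t(vapply(seq_len(n), function(i) {
    d <- sqrt(colSums((t(coords) - coords[i, ])^2))
    d[i] <- Inf
    order(d, seq_len(n))[seq_len(k)]
  }, integer(k)))
}

default_sbm <- function(seed) sbm_graph(rep(50L, 4L), 0.3, 0.01, seed = seed)

# small grid used to keep simulation-style unit tests quick
quick_grid <- function(replicates = 3L) {
  perturbation_grid(levels = seq(0.1, 0.6, by = 0.1), replicates = replicates)
}
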