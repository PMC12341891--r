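---
title: "Methods: edge-rewiring robustness of community structure"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: edge-rewiring robustness of community structure}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The model

`netstab` treats the reliability of a graph partition as an empirical,
perturbation-based quantity. Given an undirected simple graph
$G = (V, E)$ and a community-detection method $m$, the package rewires a
fraction $p$ of the edges, re-runs $m$, and measures the distance between
the reference partition $C_m(G)$ and the perturbed partition $C_m(G_p)$.
Repeating this over a grid of levels $p$ and independent replicates
yields a *stability curve*. Two uses follow:

1. **Method comparison** (`compare_methods`): several methods (or
   parameter settings of one method) are run on the *same* perturbed
   graphs; the method whose mean curve has the lowest trapezoidal AUC is
   the most robust choice for that network.
2. **Significance validation** (`null_robustness`): the observed curve is
   compared to the same procedure run on a configuration-model null graph
   with the identical degree sequence. If the observed communities are a
   real property of the network, the observed curve sits well below the
   null curve; two formal tests quantify the evidence.

The underlying assumption is that a significant partition is recoverable
under moderate topological noise, while a spurious one drifts immediately.
Both procedures are distribution-free with respect to the graph itself;
what is modelled statistically is only the pair of curve sets.

## Perturbation and null model

`rewire_fraction(graph, fraction, seed)` removes exactly
$k = \mathrm{round}(p\,|E|)$ randomly chosen edges (round-half-to-even,
so the count is deterministic and symmetric) and adds $k$ edges drawn
uniformly from node pairs **absent from the original graph**. Node count,
edge count and — on weighted graphs — the weight multiset are conserved;
degrees are not. Candidate pairs are drawn by bounded rejection sampling
(at most $100k$ draws, then an explicit error), so dense graphs fail
loudly rather than looping.

A design point worth spelling out: the candidate pool excludes *all*
original edges, including the $k$ just removed. If removed pairs could be
re-drawn, "exactly $k$ original edges absent" would only hold in
expectation and the preserved fraction at $p = 0.6$ would be biased a few
percent above $0.4$ on typical sparse graphs. With the exclusion, the
preserved fraction equals $1 - p$ by construction, which is what the
engine's contract tests assert.

`configuration_null(graph, seed)` randomizes the topology by
degree-preserving double-edge swaps (10 attempted swaps per edge by
default; swaps creating loops or duplicates are rejected), i.e. a draw
from the simple-graph configuration model at the observed degree
sequence. Weights are permuted uniformly over the new edge set. Degree
sequences that admit no swap (stars, triangles) return the input with a
warning. Perturbation (degree-free) and null model (degree-preserving)
are deliberately distinct operations: the null asks "what do curves look
like when *only* the degree sequence is real?".

## Stability measures

All measures are computed from the contingency table of two labelings,
with natural-log entropies:

* **VI** $= 2H(X,Y) - H(X) - H(Y)$, a metric, $0 \le VI \le \ln n$ nats —
  the default everywhere, because it is a true metric and its scale
  ($\ln n$) is interpretable;
* **NMI** $= I(X,Y)/\sqrt{H(X)H(Y)}$ (defined as 1 when both partitions
  are single-block, 0 when exactly one is);
* **ARI** (permutation-model adjusted Rand);
* **split-join** (van Dongen, $2n - \sum_i \max_j n_{ij} - \sum_j \max_i
  n_{ij}$).

Similarity measures enter curves as $1 - \text{value}$ so that "lower =
more stable" holds for every measure and AUC ranking is meaningful.

## The perturbation grid

Defaults: levels $0.05, 0.10, \dots, 0.60$ (12 levels) with 10 replicates
per level. Rewiring much beyond 60% makes any graph essentially random,
so higher levels add noise, not signal. Level 0 is excluded from the
default grid: it is a degenerate point (distance 0 for deterministic
methods) and the 12 parallelizable units are the non-trivial levels; it
can be prepended with `perturbation_grid(include_zero = TRUE)` as a
diagnostic that the reference partition is reproduced.

Perturbations are generated independently per (level, replicate) from the
*original* graph — not cumulatively — so levels are directly comparable.
In `compare_methods` the perturbed graph at each (level, replicate) cell
is shared by all methods (paired design), which removes perturbation
noise from between-method contrasts; the package's tests assert the
pairing by curve identity of duplicated specifications.

## Determinism and parallelism

Every stochastic operation is a pure function of its inputs and an
integer seed. Each (level, replicate, purpose, method) cell derives its
own substream seed through a multiplicative congruential mix
(`substream_seed`), so results are bit-identical for any worker count or
scheduling order; `workers = n` parallelizes over perturbation levels
with `parallel::mclapply`. Method-specific substreams are keyed by a hash
of the method label, which is why two identical method specifications
produce identical curves (they are allowed in `compare_methods`, with a
warning, rather than rejected — the identity is itself a useful
diagnostic of the paired design).

## The two curve tests

**GP Bayes factor** (`gp_curve_test`). The test operates on the paired
replicate differences $d(\ell, r) = a_{\ell r} - b_{\ell r}$ (pairing
uses the replicate index; with the engine's seeding this aligns
replicates generated under the same substreams). Two zero-mean Gaussian
models are compared: $M_0$, white noise with variance at its closed-form
MLE, and $M_1$, a squared-exponential GP over the level axis plus white
noise, with hyperparameters maximized by L-BFGS-B under fixed bounds —
lengthscale within [grid step, grid span], noise SD floored at $10^{-6}$,
variances capped at 100× the sample variance — from 5 restarts (first
init deterministic, the rest drawn from the seed's substream; on
two-level grids, where step equals span, the bound pair is opened by
$10^{-6}$ to keep the optimizer well-posed). The reported Bayes factor is
$\exp(\mathrm{LML}_1 - \mathrm{LML}_0)$; since both models are even in
$d$, swapping the arguments leaves it unchanged exactly. Interpretation
thresholds (reported, never acted upon): $>100$ strong, $3$–$100$
substantial, otherwise none. Note this is an ML-II (empirical Bayes)
Bayes factor: $M_0$ is nested in $M_1$, so values slightly above 1 on
null data are expected and only large values are evidence.

**Interval-wise permutation test** (`iwt_curve_test`). Each replicate
curve is one functional observation. The pointwise statistic is
$T(\ell) = (\bar a_\ell - \bar b_\ell)^2$; every contiguous interval $I$
of levels gets $S(I) = \sum_{\ell \in I} T(\ell)$, with a permutation
p-value from `n_perm = 1000` random reassignments of whole curves to the
two groups (add-one correction, so the minimum attainable p is
$1/(n_{perm}+1)$). The adjusted p-value at level $\ell$ is the maximum
interval p-value over all intervals containing $\ell$, which enforces
interval-wise error control and makes adjusted p-values dominate
pointwise ones by construction. This is a grid-native variant of the
interval testing procedure: with only 12 grid points, a basis-expansion
(Fourier/B-spline) formulation would be ill-conditioned, while the
interval-max adjustment preserves the procedure's error-control logic.
This is a reasoned substitute, not a claimed replication of any specific
published implementation.

## The single-cell adapter

`knn_neighbors` computes exact (brute-force) Euclidean $K$ nearest
neighbors in the embedding — at desk scale exactness is cheap and
removes an approximation error source; ties break deterministically by
cell order. `snn_jaccard_graph` connects every pair where at least one
cell lists the other among its neighbors, weighting by the Jaccard
overlap of the two $(k{+}1)$-element neighbor sets (anchor cell
included, the common SNN convention), and prunes weights $\le 1/15$.
Defaults $k = 15$, prune $= 1/15$ follow the conventions of the standard
single-cell pipelines this construction mirrors. Normalization, feature
selection and PCA are out of scope: the adapter starts from the
embedding.

## Synthetic generators, and what a green test establishes

`sbm_graph` (planted-partition SBM), `er_graph` ($G(n,p)$) and
`gaussian_mixture_embedding` (isotropic Gaussian clusters whose closest
center pair is exactly `separation` apart, even cluster sizes) provide
ground truth for every test. The benchmark configuration used throughout
the acceptance suite — 4 blocks × 50 nodes, $p_{in} = 0.3$,
$p_{out} = 0.01$; mixtures with 3 clusters at separation $10\sigma$,
300 cells, $k = 15$ — represents a *clearly structured* regime. Green
tests therefore establish that the machinery detects strong structure,
ranks a good method (Louvain) above a fragile one (label propagation),
and controls type-I error on exchangeable curve sets. They do **not**
establish performance on real scRNA-seq graphs, which have hub
structure, batch effects, uneven cluster sizes and weight distributions
the generators do not emulate; nor do they calibrate behaviour near the
SBM detectability threshold.

## Numerical choices and degenerate inputs

* Entropies in nats everywhere; VI values clipped at 0 against rounding.
* Trapezoidal AUC over the level axis; exact for piecewise-linear curves
  (constant 1 on the default grid gives $0.55$, $v(\ell) = \ell$ gives
  $0.17875$). AUC ties in `rank_by_auc` break lexicographically by
  method name, then condition.
* Graphs entering the engine must be simple, undirected, with
  $|V| \ge 2$, $|E| \ge 1$ and strictly positive weights; violations are
  errors before any work (including before writes).
* MTX and edgelist output is written at 17 significant digits and
  round-trips exactly; GraphML goes through igraph's writer and
  round-trips to ~$10^{-15}$ relative.
* MTX carries no node names; graphs written to MTX round-trip their
  labels only when names are the indices `1..n`.
* All-zero curve differences (identical curve sets) are handled by the
  noise-variance floor; the GP test then returns BF $\approx 1$
  ("none"), and the IWT returns all adjusted p-values equal to 1.

## Known limitations

* Exact KNN and the dense distance matrix limit the adapter to
  $\sim 10^4$ cells on desk hardware.
* The GP Bayes factor uses ML-II marginal likelihoods, not a fully
  Bayesian treatment of hyperparameters; its "strong" threshold is a
  working convention.
* The rewiring null of `rewire_fraction` ignores weights topologically
  (the weight multiset is conserved but reassigned at random); whether
  perturbation should act on the weighted backbone is an open modelling
  choice, made here so that weighted and unweighted runs remain
  comparable.
* Directed graphs, multigraphs, overlapping communities and cumulative
  perturbation trajectories are out of scope.
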