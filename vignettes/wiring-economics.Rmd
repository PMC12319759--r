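---
title: "Wiring economics: models, conventions and the synthetic world"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Wiring economics: models, conventions and the synthetic world}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

This vignette is the package's own account of the science it implements:
the generative model and its assumptions, the fit criteria, the
synthetic world that stands in for restricted neuroimaging and
transcriptomic data, and every numerical convention a reader would need
to reproduce or audit a result.  It states no empirical numbers beyond
what the test suite and `scripts/acceptance.R` themselves compute.

## 1. The generative model

A connectome grows from a sparse seed, one edge per iteration.  At each
step the probability of connecting the unconnected pair $(i, j)$ is

$$P_{i,j} \propto D_{i,j}^{\eta}\,(K_{i,j} + \varepsilon)^{\gamma},$$

with $D$ the Euclidean distance matrix (fixed for the whole simulation),
$K$ the topological value under the chosen wiring rule (updated after
every addition), and both terms combined as power laws.  Growth stops
when the simulated network reaches the empirical edge count.  Sampling
is inverse-CDF over the lexicographically ordered candidate list, which
makes runs bit-reproducible across platforms for a fixed seed.

**Wiring rules.**  `spatial` sets $K \equiv 1$ (pure geometry);
`neighbours` uses the shared-neighbour count; `matching` its normalised
form — the overlap of the two neighbourhoods (excluding the pair itself)
divided by their union, defined as 0 when both exclusive neighbourhoods
are empty; `clustering_average` and `degree_average` average the two
nodal values.

**The constant $\varepsilon$.**  Its only purpose is to keep $P$ defined
when $K = 0$.  The default is $10^{-6}$, configurable via
`gnm_params()`.  It is added at *every* iteration, not only the first,
because disconnected pairs can return to zero value at any step.  For
$\gamma \approx 0.2$, $\varepsilon^\gamma \approx 0.05$, so a pair with
no shared neighbours is penalised roughly twenty-fold against a pair
with one — $\varepsilon$ therefore also sets the strength of the
homophily "gate", which is worth knowing when comparing against other
implementations.

**Incremental updates.**  The compiled core maintains adjacency, degree
and shared-neighbour counts incrementally; adding edge $(u, v)$ changes
$K$ only for pairs touching $u$ or $v$ (plus, for the clustering rule,
pairs touching common neighbours of $u$ and $v$).  A property test
verifies that the incremental path reproduces, edge for edge, a full
from-scratch recomputation along 50-step runs for all five rules.

**Parameterised nodal terms.**  With `record = TRUE`, a trace collects
per node $i$ the wiring cost $\sum_j D_{ij}^\eta$ (constant, geometric)
and the wiring value $\sum_j (K_{ij}+\varepsilon)^\gamma$ averaged over
iterations — the nodal maps later decoded against gene expression.  All
iterations contribute, whether or not the node was selected.

## 2. Fit criteria and model selection

*Energy* is the largest of four two-sample KS statistics (degree,
clustering, betweenness-centrality as nodal distributions; edge length
per existing edge).  The KS statistic is used descriptively — no
p-values.  Values within a relative $10^{-9}$ are treated as tied, so
float summation noise (betweenness sums depend on evaluation order)
cannot split a genuine tie; without this the identity
$E(G, G_\text{permuted}) = 0$ fails at machine precision.

*Topological fingerprints* are 6×6 Pearson correlation matrices of
degree, clustering, betweenness, mean incident edge length, local
efficiency and eigenvector centrality across nodes; dissimilarity is the
Frobenius norm of the difference.  A metric with zero variance across
nodes has its row and column set to 0 (diagonal kept at 1) so the shape
stays comparable across graphs.  *Spatial similarity* is the
node-matched Pearson correlation of degree.

*Grid search* uses an equally spaced grid: `build_grid(budget)` places
$\lfloor\sqrt{\text{budget}}\rfloor$ points per axis including the
endpoints, so a budget of 100,000 over $[-7,7]^2$ yields $316^2 =
99{,}856$ unique pairs and 50,000 yields $223^2 = 49{,}729$.  One
simulation per point is the default (matching large-grid practice);
with repeats the best point minimises the per-point *mean* energy.
Ties break by smaller KS sum, then lexicographically.  Each grid
point's RNG stream is derived from the parameter values, not the grid
position, so duplicated points replay identically.  The reported window
spans the lowest-energy 10% of points.

*Model selection* ranks the five rules on mean energy (ascending), mean
fingerprint dissimilarity (ascending) and mean spatial correlation
(descending) and takes the smallest rank sum, ties broken by the energy
rank.  `evaluate_params()` re-evaluates a chosen point with repeated
simulations for this purpose.

**Identifiability at small scale.**  A caution the acceptance
experiments make concrete: on 30-node targets the energy's max-of-four
construction is dominated by the KS noise floors of clustering and
betweenness (each statistic is a supremum over ~30-point empirical
CDFs), which flattens the $\eta$ profile of the landscape and biases
single-simulation argmins towards stronger penalties.  The direction of
every effect is preserved, but per-target recovery of $\eta$ to within
a fraction of a grid step is not reliably achievable at that size; at
100 nodes the floors drop and the landscape behaves.  We report this
rather than tune around it.

## 3. The synthetic world

The generators' defaults encode the conditions of the cohort the
package emulates rather than free knobs:

* **Geometry** — `generate_coordinates()` samples uniformly inside an
  ellipsoidal shell with semi-axes (110, 55, 40) mm and inner fraction
  0.3.  The elongated anterior–posterior axis mimics a hemisphere's
  centroid cloud and yields the right-skewed pairwise-distance
  distribution seen empirically; a spherical shell, by contrast, gives
  left-skewed distances.
* **Seed networks** — `make_cohort_seed()` mirrors the empirical
  pipeline: a stack of 20 distance-dependent random graphs at 13% mean
  density (the raw, pre-threshold connectome density) is thresholded at
  95% prevalence.  The exponential length scale (18 mm) was calibrated
  once so the resulting seed density reproduces the published 1.58% at
  100 nodes; seeds are spatially compact short-range cores, as in real
  cohorts.  Note that independent random graphs agree across
  "participants" far less than real brains do, so the prevalence route
  yields a seed at the empirical density only with this deliberately
  short length scale.
* **Cohorts** — participant exponents are drawn from
  $\eta \sim N(-3.007, 0.336)$ and $\gamma \sim N(0.215, 0.027)$, the
  fitted participant-level distributions; graphs grow under the
  `neighbours` rule to `round(density · n(n-1)/2)` edges (IEEE
  round-half-even: at 30 nodes and density 0.10, 43.5 rounds to 44).
  $\eta$ and $\gamma$ are drawn independently; their empirical
  covariance is not published.
* **Polygenic scores** — `generate_pgs()` builds
  $\beta\,z(\eta) + \sqrt{1-\beta^2}\,\text{noise}$, standardized, so
  the expected fully standardized slope equals the planted
  $\beta = .054$ by default.  Additive Gaussian noise matches the
  linear-model assumption of the association stage; no genotype-level
  structure is simulated.
* **Expression** — non-signal genes are Gaussian random fields over the
  region coordinates with squared-exponential covariance
  (length scale 30 mm), the simplest controllable spatial
  autocorrelation; signal genes mix a standardized target map with
  standardized field noise at mixing weight $s$, giving expected
  $|r| = s$ with the map.

What a green test does *not* establish: the generators contain no
tractography artefacts, no hemispheric asymmetries, no
subject-level registration error, and no genotype linkage structure.
They validate the machinery and the directional phenomena, not
empirical effect sizes.

## 4. Cohort-level statistics

Outlier removal drops participants with $\eta$ or $\gamma$ more than
`k_sd` (default 2) SDs from the mean, computed on the input table in a
single pass.  Extreme-group contrasts take the bottom/top `fraction`
(default 10%) of the polygenic score with group size
`ceiling(fraction·n)` and classic equal-variance t-tests,
`df = n1 + n2 - 2`; differences are reported bottom-minus-top.  (The
source cohort's printed `t(290)` and "147 per group" are mutually
inconsistent — 147 per group gives df 292; the ceiling convention wins
here.)  The continuous model standardizes both the outcome and the
score ("fully standardized β") and controls for mean framewise
displacement, sex and age; Bonferroni doubles the p-value over the two
parameters tested.

**Stochasticity experiment.**  For two parameter sets (e.g. the two
extreme-group means) it simulates `n_sims` networks each and contrasts
four consequences, reported high-minus-low: (i) per-node coefficient of
variation, across simulations, of the node's candidate wiring
probability mass averaged over iterations — the prescribed convention
for "variability of nodal wiring probabilities", noted here because the
phrase is genuinely under-determined: per-simulation variants
(across-node CV, across-iteration CV, deviation from the mean
probability trajectory) were also measured during development and none
behaves identically; (ii) embedding dissimilarity — mean pairwise
Jaccard distance between simulated edge sets over up to `max_pairs`
pairs; (iii) topological dissimilarity — pairwise fingerprint distance;
(iv) global efficiency per simulation.  Pairwise distributions share
simulations across pairs, so their t-statistics are anti-conservative;
the Cohen's d values are the quantities to read.

**Randomisation sweep.**  `scale_params()` multiplies both exponents by
a fraction (3-decimal rounding for reporting, which reproduces the
published decile values exactly, e.g. 80% of $\eta = -2.911$ is
$-2.329$).  The sweep runs the model at each fraction and tracks mean
global efficiency and mean fingerprint dissimilarity to
Maslov–Sneppen-rewired copies of the target; the rewired pool is shared
across fractions.  Rewiring itself counts *accepted* swaps with a
budget of one per edge, rejecting self-loops and multi-edges, so the
degree sequence is preserved exactly.

## 5. Transcriptomic decoding

`pls_fit()` is a NIPALS PLS with a univariate response (3 components by
default), columns centred and scaled, and each component's sign fixed
so its scores correlate positively with the response — making loadings
comparable across participants.  The reported gene "loading" is the
*structure correlation* `cor(gene, component score)`, the convention of
the imaging-transcriptomics PLS literature; the raw NIPALS projection
loadings remain available as `x_loadings`.  This choice is not
cosmetic: the projection loading $X^\top t / t^\top t$ is
anti-calibrated as a permutation statistic, because a strong observed
signal inflates $t^\top t$ and shrinks every loading below its own
permutation null.

Permutation p-values shuffle the response across regions uniformly
(`p = (1 + #\{|null| \ge |obs|\}) / (n_{perm} + 1)`).  With spatially
autocorrelated expression this simple null is anti-conservative for
genes belonging to large correlated blocks — the first component aligns
with the dominant expression gradient regardless of the response — and
the test suite measures this rather than hiding it; a
spatial-autocorrelation-preserving null is out of scope.  Aggregation
across participants keeps genes significant in *every* participant by
default (`mode = "all"`; `"any"` is exposed because both readings of
the source description exist), averages component-1 loadings, and sorts
descending with lexicographic tie-breaks.

## 6. Numerical conventions, in one place

* round-half-even (`round()`) everywhere a count is derived from a
  density or fraction;
* KS ties: relative $10^{-9}$;
* betweenness unnormalised; eigenvector centrality unit Euclidean norm;
  isolated nodes get clustering, local efficiency and mean edge length
  0; unreachable pairs contribute 0 to global efficiency;
* modularity: Louvain with a fixed internal seed (Q is partition
  dependent);
* grid/simulation RNG streams are derived from parameter values with a
  polynomial string hash below $2^{31}$;
* distance-dependent consensus: 10 equal-frequency length bins by
  default, per-bin quota equal to the mean participant edge count in
  the bin, ties broken by mean weight then node index;
* Maslov–Sneppen: budget = edge count accepted swaps, attempt cap
  200× budget, warning on stall.

## 7. Known limitations

Only power-law kernels are implemented (exponential variants,
weighted/growth models and genetically seeded variants are out of
scope).  The energy criterion's small-sample bias (Section 2) limits
per-participant parameter recovery below ~50 nodes.  The permutation
null for PLS ignores spatial autocorrelation.  The synthetic cohort
draws $\eta$ and $\gamma$ independently.  Streamline-count inputs are
taken as given; no tractography-level processing is modelled.
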