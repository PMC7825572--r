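---
title: "Methods: compositionality-aware co-occurrence networks and community statistics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: compositionality-aware co-occurrence networks and community statistics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# Scope and model

`ncoocnet` infers co-occurrence/co-exclusion networks from OTU-by-sample
count tables of N-cycle marker genes and characterizes them topologically,
alongside the standard community statistics (alpha diversity, Bray–Curtis
ordination, PERMANOVA, Mantel, diversity–environment correlations). The
inference follows the CoNet "ReBoot" scheme: a thresholded Spearman score,
a permutation null that *retains* the compositional bias by renormalizing
each shuffled sample, a bootstrap stability distribution, and
Benjamini–Hochberg control over the surviving candidates.

The central statistical idea: on relative abundances, closure (columns sum
to 1) induces spurious correlations, so "no association" must not be
represented by an r = 0 null. Instead, the null for a pair (i, j) is the
distribution of its score when both rows are independently permuted across
samples *and every sample is re-closed over all taxa*. The observed edge is
then judged by the separation between this null and the bootstrap
distribution of the observed score: z = (mean(null) − mean(boot)) /
sd(boot), two-tailed Gaussian. An edge whose null mean falls inside the
central 95% bootstrap interval is "unstable" and discarded before multiple
testing — it cannot be distinguished from its own null location.

## Assumptions

- Samples are exchangeable within a treatment group; networks are built
  per group, never across groups.
- Associations of interest are monotone (Spearman), strong (|r| ≥ 0.7),
  and pairwise; no conditional-independence modeling is attempted.
- Counts are compositional: only relative information is interpreted, and
  every null operation re-imposes closure on taxon rows. Soil
  physicochemical variables are *not* compositional and are therefore
  excluded from all renormalization.

# Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `threshold` | 0.7 | inclusive two-sided |r| cutoff for candidate edges |
| `n_permutations`, `n_bootstraps` | 1000 | iterations per candidate edge |
| `ci` | 0.95 | central bootstrap mass for the unstable-edge filter |
| `alpha` | 0.05 | significance level on BH-adjusted p-values |
| `renormalize` | TRUE | re-close shuffled samples in the permutation null |
| `exact_enumeration_max_n` | 6 | sample-size cap for exact nulls (see below) |
| `min_sum_relabund` | 1e-4 | retention rule (b): Σ over the group's samples of per-sample proportions, strict |
| `min_nodes` | 10 | size gate below which topology/keystones are skipped |

Keystone presets mirror the per-gene thresholds used for the three marker
genes: `AOA` (degree = 5, closeness = 1, betweenness = 0, exact equality),
`nirS` (> 10, > 0.354, < 0.103) and `nosZ` (> 10, > 0.311, < 0.096). The
criteria object supports strict/inclusive/equality modes per field because
published keystone rules mix "=" and ">" styles.

# Numerical and design choices

**Threshold boundary.** |r| ≥ 0.7 inclusive, two-sided. Both co-occurrence
(positive) and co-exclusion (negative) edges are candidates; the sign is
`sgn(r)`.

**Exact permutation nulls.** With five replicates per treatment — the
motivating study design — sampled permutations are heavily duplicated (only
120 row orders exist). The null is therefore enumerated exactly when
feasible. Without renormalization the statistic depends only on the
relative order of the two rows, so the n!² pair space collapses to n!
single-row orders and enumeration engages for n ≤ 6 (≤ 720 evaluations).
With renormalization the collapse is invalid (the recomputed column sums
couple the two permutations), so the full n!² pair space is enumerated only
while n!² ≤ 20 000, i.e. n ≤ 5; at n = 6 the renormalized null would need
518 400 renormalized recomputations per edge and is sampled instead. For a
taxon–metadata pair only the taxon row is renormalized, so the metadata
row's rank order is fixed and n! enumeration is again exact.

**Renormalized null is not centred at zero.** Renormalization deliberately
preserves the compositional bias: for a pair holding a large share of the
total abundance the null mean is visibly non-zero (≈ −0.16 for 2 of 10
equally abundant taxa in our measurements) and shrinks as the pair's share
falls. Tests assert centring only for the plain row-shuffle null, and a
loose bound for the renormalized null on a 50-taxon table.

**Unstable-edge rule.** "Filter unstable edges" is implemented as: unstable
iff the null mean lies within the central `ci` quantile interval (type-7
quantiles) of the bootstrap scores. This is one concrete reading of the
tool's filter; it is configurable and logged per edge in `edge_tests`.

**p-value merging.** With the single Spearman measure the Brown merge is
the identity. The multi-measure path implements Brown's scaled-χ²
approximation with the covariance of −2 log p estimated from per-measure
permutation score vectors (rank-based empirical p per iteration); without
such vectors Brown degrades to Fisher. Note one frozen oracle value: Fisher
of independent (0.5, 0.5) is `pchisq(2.7726, 4, lower = FALSE)` = 0.5966.

**Degenerate inputs.** Constant rows get missing scores and are excluded
from candidacy rather than erroring (common in 5-sample subsets); constant
metadata variables are dropped with a warning; bootstrap resamples that
collapse a row to a constant are redrawn up to 10 times and then recorded
missing, with an error if more than half of the iterations degenerate;
zero-depth samples are a hard error.

**Topology conventions.** Clustering coefficient averages local clustering
over nodes of degree ≥ 2 (the NetworkAnalyzer convention; the all-nodes
variant is a flag). Diameter and the shortest-path count use finite
distances only — the motivating networks are disconnected, so infinite
distances must be ignored (a 35-node network with diameter 2 is only
possible component-locally). Closeness is reachable-count over
distance-sum, betweenness is normalized by 2/((N′−1)(N′−2)) within each
node's component of size N′: this is what makes "closeness = 1,
betweenness = 0" attainable for a 6-clique component inside a larger
disconnected graph, as the keystone preset for the archaeal network
requires. Shortest paths are counted as ordered pairs (all published
values are even, consistent with ordered counting).

**BH scope.** Correction is applied across the stable candidates of one
network run (one treatment), never pooled across treatments, because
networks are built and reported per treatment.

# The synthetic world

The generator emulates the study design as stated: two treatment groups ×
five replicates by default, sparse compositional counts, planted monotone
taxon–taxon associations, and soil covariates linked to chosen taxa.

- **Marginals** are log-normal (meanlog 0, sdlog 1 by default): the
  standard skewed-abundance model; after multinomial sampling at finite
  depth this produces realistic sparsity without structural zeros, keeping
  the planted ground truth exact at the population level.
- **Dependence** is a Gaussian copula. Target Spearman ρ is converted to
  the latent Pearson scale by r = 2 sin(πρ/6), exact for bivariate
  normals; the monotone log-normal transform preserves Spearman. The
  pairwise target matrix is factored by its eigen square root, which
  tolerates the positive-semidefinite boundary (a comonotone ρ = 1 pair);
  an indefinite target set is repaired via nearest-PD with a warning, or
  rejected naming the offending pairs when the repair exceeds a 0.05
  entrywise tolerance.
- **Counts** are multinomial per sample with Poisson-jittered totals
  around the nominal depth (default 10 000 reads — a typical per-sample
  amplicon depth after quality control; the source study reports no
  calibrated abundance distribution, so defaults were chosen once on that
  field convention and not revisited).
- **Covariates** linked at Pearson ρ are ρ·standardized-abundance +
  √(1−ρ²)·noise, rescaled to the requested mean/sd. Note that a Pearson
  link of 0.95 to a skewed relative abundance corresponds to a *lower*
  Spearman (≈ 0.84 median at n = 40), which is the relevant scale for
  recovery through the |r| ≥ 0.7 gate.
- **Seeding**: one root seed; every stochastic sub-operation derives its
  own stream from a stable name (`derive_seed`), so outputs are
  reproducible and stable under unrelated code changes.

What a green test does **not** establish: the generator has no sequencing
error, chimeras, OTU-clustering artifacts, zero inflation (available but
off by default), taxon–taxon interactions beyond pairwise monotone
coupling, or realistic phylogenetic structure. Recovery rates measured
here speak to the statistical machinery, not to wet-lab performance on
PRJNA-scale data.

# What the tests compute

All empirical claims in this vignette are computed by the test suite or
the acceptance script, never asserted from memory: closed-form topology
identities on the six published (nodes, edges) sizes; exhaustive
brute-force agreement of all centralities on small graphs; ≥ 95%
exact-recovery of a planted ρ = 0.95 pair among 30 independent taxa at
n = 40 over 20 seeds; < 1 mean false edge per run on 50 independent taxa;
PERMANOVA and Mantel type-I rates inside the 95% binomial band at
α = 0.05 over 50 null simulations; and hand-computed Chao1 / Shannon /
Gini–Simpson toy values.

# Known limitations

- The ReBoot p-value relies on a Gaussian summary of the bootstrap; an
  empirical-tail alternative is available (`p_method = "empirical"`) but
  its resolution is bounded by the iteration count.
- With five samples, Spearman takes few distinct values and the |r| ≥ 0.7
  gate admits many ties; exact nulls mitigate but cannot remove the
  granularity.
- PERMANOVA is one-way only; no strata, covariates, or sequential terms.
- Faith's PD requires a user-supplied rooted tree; no tree inference is
  attempted.
- Structural equation modeling and flux analyses are out of scope.
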