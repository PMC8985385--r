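---
title: "Clonal fate analysis with lineage barcodes: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Clonal fate analysis with lineage barcodes: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(clonefate)
```

`clonefate` analyzes lineage-barcoding experiments in which stem cells are
tagged with transcribed lentiviral DNA barcodes before directed
differentiation, so that every differentiated descendant of one transduced
progenitor — a clone — can be recognized in single-cell RNA sequencing
data. This vignette describes the models the package implements, the
assumptions behind them, the parameters that matter, and the design
decisions taken where more than one reasonable choice existed.

## 1. Barcode recovery

### Read model

Barcodes are random 100-mers with a repeating WSN degenerate-base pattern
(W = A/T, S = G/C, N = any base). Amplicon reads carry the barcode behind a
constant anchor region; in the 10X side-reaction layout the read starts
with the 16-nt cell identifier and 12-nt UMI, in the genomic-DNA layout
with a 6-nt NHNNNN pseudo-UMI built into the library primer.

`extract_barcodes()` keeps a read only if

* the anchor is found with at most 1 mismatch (`max_anchor_mismatch`) —
  a single representative anchor with slack stands in for the tolerance
  a battery of alternative primers would give;
* the barcode region reaches `min_length` (default 30 nt, the merging
  prefix length);
* its mean Phred score is at least `min_quality` (default 30, standard
  amplicon stringency);
* it contains no homopolymer run longer than `max_homopolymer` (default
  6). The WSN design cannot produce runs longer than about 3 except
  through N positions, so long runs indicate synthesis or sequencing
  artifacts.

The quality and homopolymer cutoffs are deliberately conservative
defaults, exposed as arguments, since no single value is canonical.

### Variant merging

PCR and sequencing errors scatter each true barcode into a cloud of
near-identical sequences. `merge_barcodes()` clusters the first
`prefix_len = 30` bases of each distinct sequence by Levenshtein distance:
prefixes are visited in descending read-abundance order (lexicographic
tie-break), each joins the most abundant existing cluster center within
`max_dist`, else founds a new center. `max_dist` is 6 for 10X-mode
amplicons and 8 for genomic-DNA libraries, where longer reads accumulate
more errors. Read and UMI counts are summed per cluster and the most
abundant full-length member becomes the representative.

This greedy center scheme was chosen over reimplementing a message-passing
clusterer because, with the abundance/lexicographic ordering, it is
deterministic and invariant to input order, and on realistic error clouds
(high-abundance true centers, low-abundance satellites) it yields the same
partition — the test suite checks it against an exhaustive
distance-matrix oracle on instances of up to 50 prefixes. Distances come
from `utils::adist()`, R's standard generalized Levenshtein implementation.

WSN barcodes drawn at random differ at roughly 17 of their first 30 bases,
so thresholds of 6–8 are far below the between-barcode distance and far
above the 0–2 errors a typical read carries; merging is insensitive to the
exact value in this regime.

### Cell assignment

`assign_cells()` applies, per cell: (1) drop barcodes with fewer than
`min_umi = 2` distinct UMIs; (2) among the survivors keep barcodes with at
least `dominance_fraction = 30 %` of the cell's total UMIs; (3) keep the
cell only if exactly one barcode remains. The dominance denominator is the
cell's total UMI count *before* the UMI filter, matching the stated order
of the filtering steps (the UMI filter first, then selection against "the
total number of UMIs assigned to each individual cell"). UMIs are
deduplicated exactly as strings; no UMI error correction is attempted.

### Diversity and MOI estimators

`estimate_diversity(n1, n2, overlap)` is the Lincoln–Petersen
mark–recapture estimate `n1·n2/overlap` of library complexity from two
independent transductions; it errors on zero overlap, where the estimate
is undefined. `estimate_moi(f)` inverts the Poisson zero class,
`moi = −log(1 − f)`, from the marker-positive fraction `f`, warning above
`f = 0.40` where titration practice stops trusting the inversion.

## 2. Clone-level fate statistics

### Cluster probability distributions

A clone with `c_k` cells in expression cluster `k`, against pooled totals
`N_k`, gets `p_k = (c_k/N_k) / Σ_j (c_j/N_j)`. Dividing by `N_k` first
removes cluster-size effects, so the expected distribution of a *random*
set of cells is near-uniform over retained clusters however unbalanced the
clustering is. Clusters with no pooled cells are dropped before
normalization, and `exclude_clusters` lets the analyst remove clusters
judged uninterpretable (for instance one containing only a couple of
barcoded cells).

### Jensen-Shannon distance

`jensen_shannon_distance()` uses log-base-2 KL terms so the distance of
disjoint-support distributions is exactly 1 and of identical distributions
exactly 0. The default form is the square root of the Jensen-Shannon
divergence — the metric form, satisfying the triangle inequality, as used
in the tissue-specificity literature this analysis style descends from.
Both the root and the divergence satisfy the same 0/1 anchors in log base
2, so the bounded-scale interpretation does not distinguish them; the
divergence is available via `form = "divergence"` for sensitivity checks.
`0 · log 0` is treated as 0, and a tiny negative round-off in the
divergence is clamped before the square root.

### The resampling test

`jsd_homogeneity_test()` measures a clone against what random,
size-matched sets of cells look like:

1. **Reference**: the average normalized distribution of `n_samples`
   (default 1000) uniform *without-replacement* samples of the clone's
   size. Without-replacement subsetting of actual cells is what "random
   samples of a matched number of cells" from a dataset describes; with
   clone sizes far below the pool size the distinction from
   with-replacement sampling is negligible anyway.
2. **Null**: the JSDs of `n_samples` fresh matched-size samples from the
   same reference.
3. **p-value**: `(1 + #{null ≥ observed}) / (1 + n_samples)` — the +1
   correction keeps p strictly positive, so the smallest attainable value
   at 1000 samples is 1/1001.

The default clone-size floor is `min_cells = 20` within a differentiation
and `min_cells_per_split = 5` for cross-split comparisons; both are the
conventional cutoffs for this analysis and both are configurable.

### Cross-split comparison

`cross_split_jsd()` computes each shared clone's distribution separately
per split and the full A-versus-B JSD matrix. Cluster totals are pooled
over both splits by default (`normalization = "pooled"`): the two wells
are halves of one experiment and a common denominator keeps their
distributions on the same scale; per-split totals are available as an
option. The diagonal (same clone in both wells) against the off-diagonal
summarizes fate priming: heritable priming pulls the diagonal down, and
`diag_rank` gives each diagonal entry's rank within its row for a
nonparametric read of the same signal.

### PCA variance profile

`variance_profile()` reports the fraction of total variance explained by
each leading principal component of a cells × features matrix of
variance-stabilized values, together with a chance baseline obtained by
permuting each feature independently across cells. Independent per-feature
permutation destroys all covariance while preserving each feature's
marginal distribution — the standard "randomized data" null for deciding
how many components rise above noise.

## 3. Split-survival simulation

`simulate_split()` models the parallel-differentiation design: each
barcode's initial abundance `n_i` (pseudo-UMI count, used as a proxy for
initial cell number) is split A/B by a fair binomial, then each side is
thinned by the loss coefficient `s` — the per-unit probability of
surviving differentiation and handling. A barcode counts as present at
`presence_threshold` surviving units (default 1; raise it to model
detection limits).

`calibrate_loss()` chooses `s` so the expected fraction of initial
barcodes recovered in a split (the survival proportion) matches the
observed one. Because binomial thinning composes — a unit survives into a
given well with probability `s/2` independently — this expectation has the
closed form `mean_i(1 − pbinom(t−1, n_i, s/2))`, so the calibration
bisects a deterministic, monotone function to tolerance 0.005 rather than
averaging noisy simulations; it is the exact expectation of the simulation
it calibrates. Targets above the `s = 1` ceiling raise an error reporting
the achievable range.

`survival_randomness_test()` then asks whether the *observed* between-split
overlap is compatible with random survival: it simulates `n_simulations`
(default 1000) splits at the calibrated `s`, locates each observed
per-split overlap fraction within its simulated null (mid-p position), and
flags the experiment when either falls outside the central 95 %. One
scalar `s` serves both wells, reflecting how little the survival
proportion typically differs between them. The per-split overlap
denominator (`|A∩B|/|A|` and `|A∩B|/|B|`) matches reporting one fraction
per split; the full simulated distribution is returned so the result is
usable descriptively, not only as a verdict.

## 4. The synthetic-data generator

The generator exists so that every downstream stage can be tested against
known ground truth. It emulates:

* **Library**: unique WSN-patterned 100-mers (`generate_barcode_library`).
* **Transduction**: integrations per cell `k ~ Poisson(moi)`; cells with
  `k = 0` stay unbarcoded. Default `moi = 0.04` with 4000 founders — the
  low-MOI regime of the single-cell experiments, where multiple
  integrations are rare (≈ 2 % of barcoded cells).
* **Expansion and split**: `2^3` expansion before an even binomial split
  (3 population doublings between transduction and splitting), `2^4`
  after; the post-split count is exposed because only the pre-split
  demography is pinned by the experimental design.
* **Survival**: applied after the split — differentiation-stage death —
  either per cell (`survival_mode = "independent"`) or as one Bernoulli
  per clone (`"heritable"`), at `loss_coefficient` (default 0.5, the
  middle of the survival proportions such experiments report).
* **Fate memory**: each clone draws its distribution over `n_clusters`
  (default 14) expression clusters from
  `Dirichlet(memory_concentration × pool_cluster_weights)`. One scalar
  spans both extremes: tiny values give deterministic clone fates, huge
  values give pool-level mixing (no memory). The default of 3 (per-cluster
  concentration ≈ 0.2 at uniform weights) makes clones concentrate in a
  handful of clusters — strong but not degenerate memory, the regime such
  experiments report. `priming_mode` controls whether both splits share
  one draw (heritable priming) or draw independently.
* **Reads**: 10X-layout (cell id + UMI + anchor + barcode) and gDNA-layout
  (NHNNNN pseudo-UMI + anchor + barcode) FASTQ with iid per-base
  substitution errors (default 0.005, a typical short-read scale).
  Poisson-distributed UMIs per cell–barcode (mean 6, floored at 1) and 3
  reads per UMI give the redundancy real side reactions rely on.

Pool cluster weights default to uniform; the normalization in Section 2
makes every statistic insensitive to this choice, and unbalanced weights
are exercised in the tests.

What the generator does **not** emulate: gene-expression matrices and the
clustering step itself (cluster labels are generated directly — upstream
clustering is consumed, not reproduced); PCR amplification bias and chimera
formation; indels (substitution-only by default, so truth alignment stays
trivial while Levenshtein merging is still exercised); UMI collisions;
spatially structured growth or death. Consequently, passing tests show the
*statistical machinery* is correct under the stated model, not that any
particular biological dataset satisfies that model.

## 5. Numerical and testing choices

* All randomness flows through explicit `seed` arguments; the pipeline
  derives per-stage seeds by stable string hashing of stage names, so each
  stage reproduces independently of execution order, and all seeds stay
  below 2^31.
* Degenerate inputs fail loudly: zero-cell clones, non-normalized
  distributions (tolerance 1e−9), duplicated cell–barcode keys,
  unattainable calibration targets, zero-variance matrices, zero
  mark–recapture overlap.
* Ties in merging are broken lexicographically at equal abundance, making
  catalogs order-invariant; this is asserted by permutation tests.
* The test suite sizes its simulations to run on one CPU in a few
  minutes: type-I calibration uses 200 null clones at 1000 resamples;
  power uses clones of ≥ 20 cells at concentration 0.1; recovery round
  trips use ~100-founder experiments over 10 seeds; survival detection
  uses 300 barcodes and 1000 null simulations. These sizes give the
  binomial/KS margins quoted in the tests, and scale up linearly if
  stronger margins are wanted.

## 6. Known limitations

* The greedy prefix clusterer is quadratic in the number of distinct
  prefixes in the worst case (all prefixes founding centers); at the
  error rates and library sizes it targets, satellite prefixes join
  existing centers and the effective cost stays low. Very high error
  rates or indel-heavy data would want a specialized clusterer.
* Phantom cell identifiers created by errors in the cell-id bases inflate
  the "cells seen" count; they are filtered by the UMI floor rather than
  corrected against a whitelist, so a fraction of true reads is lost with
  them.
* The split-survival model treats pseudo-UMI counts as independent units;
  amplification correlation between units of the same barcode is not
  modeled, which makes the simulated null slightly narrow for
  heavily amplified libraries.
* The homogeneity test's null samples cells from the realized pool, so
  with few, large clones the pool itself carries clonal structure; the
  type-I calibration holds at the tested regime (clones ≈ 1/200 of the
  pool) but would degrade if a single clone dominated the dataset.
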