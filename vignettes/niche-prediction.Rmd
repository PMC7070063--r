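---
title: "Predicting microbial niches from gene content: models and methods"
author: "magniche"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting microbial niches from gene content: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of its science: the models and
procedures it implements, the assumptions behind them, the parameters that
matter, what the synthetic-data generator does and does not emulate, and
the numerical and design choices made where the design was genuinely open.
It states no empirical result that the test suite or
`scripts/acceptance.R` does not itself compute.

## The question and the pipeline

A prokaryote's genome encodes its metabolic and physiological repertoire,
so gene content should constrain the *fundamental niche* — the region of
environmental-condition space where the organism can persist. Operationally
we cannot observe fundamental niches; what shotgun metagenomics gives us is
the *realized distribution*: how abundant each species-level genome cluster
is across samples spanning environmental gradients. The pipeline therefore
works with three objects per cluster, each reduced to a pairwise
dissimilarity or a low-dimensional placement:

* an **abundance profile** (coverage per million mapped read-pairs across
  samples), summarizing realized ecology;
* a **gene profile** (counts of orthologous-group labels), summarizing
  encoded capability;
* a **phylogenetic position** (patristic distances on a reference tree),
  summarizing vertical descent.

The scientific contrast is: *does gene content predict ecological
placement beyond what phylogeny already explains?* Two instruments answer
it. Cross-validated regression predicts each cluster's placement (niche
gradient values, or principal-coordinate scores of the "virtual niche
space") from its gene profile, while Brownian-motion ancestral-state
estimation predicts the same placement from the tree alone; their
out-of-fold Spearman correlations are compared. Independently, partial
Mantel tests ask whether abundance dissimilarity remains associated with
gene-profile dissimilarity when phylogenetic distance is held fixed, and
vice versa.

## Catalogue construction

Bins pass quality control at completeness ≥ 75% and contamination ≤ 5%
(both inclusive — the boundary bin is kept). MAGs are clustered at 96.5%
ANI with average linkage on d = 1 − ANI; the dendrogram is cut at height
0.035, *inclusive*: the source convention (merge while linkage height does
not exceed the cut) is unstated in the methods this package follows, and
inclusive was chosen and is tested against a brute-force linkage oracle
under exactly that convention. Cluster labels are assigned by
lexicographically smallest member, and all tie-breaks throughout the
package are lexicographic, so outputs are deterministic functions of their
inputs. Each cluster is represented by the member maximizing completeness
minus contamination. Clusters containing any MAG with ANI strictly above
0.95 to another cluster are excluded from prediction analyses: pseudo-
alignment-based quantification cannot reliably separate near-identical
genomes, so their abundance profiles would be cross-contaminated.

## Profiles and dissimilarities

Gene profiles count orthologous-group labels with the exact suffix
`@NOG`; a gene carrying several such labels increments each. Cluster
profiles are member means (absent labels count as zero), so they are
real-valued. Before regression, labels present in fewer than 10% of
clusters are dropped (`ceiling(0.1 n)`, "at least 10%").

Both gene and abundance dissimilarities use `(1 − ρ)/2` with Spearman's ρ
computed with mid-ranks. Two conventions deserve note because the source
procedure leaves them open. First, ties: mid-ranks are the standard of the
analysis environment this mirrors. Second, zero-count labels are *part of
the rank vector* — profiles are compared on the full (filtered) label set
with absences as zeros, which is forced by the fixed post-filter
dimensionality; whether unfiltered profiles should be used instead for the
gene-vs-phylogeny comparison is configurable by passing either matrix
(default in all package analyses: filtered). A constant profile has no
defined ρ; the pair's entry is set to missing and flagged rather than
silently imputed.

## The virtual niche space

Principal coordinates analysis double-centers −D²/2 and eigendecomposes.
`(1 − ρ)/2` dissimilarities are generally non-Euclidean, so negative
eigenvalues appear; the Cailliez correction finds the *smallest* additive
constant c (largest real eigenvalue of the standard 2n × 2n companion
matrix) such that D + c (off-diagonal) embeds exactly. The package
verifies, as an invariant, that the full-rank embedding reconstructs
D + c to 1e-6 and that an already-Euclidean D receives c = 0. Axis signs
are arbitrary in PCoA; the package orients each axis so its
largest-magnitude score is positive, making predicted-vs-observed plots
reproducible. Ten axes are retained by default. Environmental arrows use
a two-stage Spearman procedure: correlate each cluster's abundance with
each measured variable across samples (pairwise-complete over missing
values), then correlate those coefficients with axis scores across
clusters; endpoints are therefore bounded by ±1.

A priori gradients are abundance log-ratios. Group mode (salinity): log of
the ratio of group means. Paired mode (depth, filter size): mean of
per-pair log ratios. Natural log is used, with a pseudocount ε = 0.001
coverage per million read-pairs added inside every ratio: zeros occur
below the detection limit, so some zero-handling is mandatory, the source
is silent on both base and pseudocount, and ε was set one order below the
smallest inclusion threshold (and is configurable). Clusters whose maximum
abundance over the involved samples does not exceed the gradient's
threshold (0.01, 0.05, 0.01 coverage per million read-pairs for
salinity-, depth- and size-style gradients) are excluded — their ratios
would be pseudocount noise.

## Prediction models

**Ridge** (L2-penalized least squares, the `alpha = 0` convention):
features standardized by training-fold statistics, response centered,
solved in SVD form so that λ = 0 reproduces ordinary least squares
exactly. λ is tuned by 5-fold inner cross-validation on the training set
only, over 100 log-spaced values in [1e-4, 1e4] on the standardized
scale, minimizing mean squared error.

**Random forest**: 2000 trees, p/3 features per split, minimum node size
5, validated out-of-bag — each observation predicted only by trees whose
bootstrap excluded it. **Gradient boosting**: squared-error loss, 10000
stages at learning rate 0.001, trees grown best-first to 2 splits with a
minimum of 1 observation per leaf, no row or feature subsampling (so the
fit is deterministic given the data). Both are implemented in C++ in this
package because no reference implementation is available in the target
environment; the boosting configuration reproduces the reference tool's
documented semantics (interaction depth = number of splits). These
hyperparameters were, in the procedure this package follows, tuned
manually on the evaluation target itself (first-axis prediction success);
that circularity is reproduced as documented, not endorsed.

**Phylogenetic prediction** is the exact Brownian-motion conditional
expectation (phylogenetic kriging): with C the shared-path-length
covariance and μ̂ the generalized-least-squares root-state estimate from
training tips, `E[y_test | y_train] = μ̂ + C_to C_oo⁻¹ (y_train − μ̂)`.
This was chosen over re-implementing a specific package's tip-insertion
heuristic because both are Brownian-motion estimators and the GLS form has
a closed-form conditional-normal oracle against which the implementation
is verified to 1e-8. A singular covariance (duplicated zero-length tips
among the training set) triggers a logged diagonal jitter. Degenerate
limits are tested: a held-out tip at distance zero inherits its neighbor's
value; on a star tree the prediction is the training mean.

Cross-validation partitions the clusters into 10 near-equal random folds
(seeded); each cluster is predicted exactly once by a model that never saw
it. Ridge, boosting and the phylogenetic model share the same folds;
random forests use out-of-bag validation instead. All evaluations use
Spearman's ρ with the large-sample p approximation.

### The permutation control

Shuffling the target and re-running the cross-validation should yield
out-of-fold correlations near zero; systematic positive ρ would indicate
fold contamination. One subtlety matters: any model that shrinks toward
the training mean acquires, under a permuted target, a *negative* bias —
each held-out observation is anti-correlated with its own fold's training
mean — which inflates |ρ| without any leakage (with inner-CV-tuned ridge
the null 95th percentile of |ρ| measured ≈ 0.28 at n = 200). The package
therefore runs the control with ridge at a fixed penalty, which exercises
the identical fold machinery, has a measured null mean ρ ≈ 0 and exposes
genuine leakage as positive correlation. The acceptance criterion
(95th percentile of |ρ| < 0.2 over 100 permutations at n = 200) is
checked against this control.

## Association tests

Patristic distances are sums of branch lengths along tip-to-tip paths
(node depths and lowest common ancestors, verified against an independent
cophenetic oracle). Pairs spanning the bacterial/archaeal domain boundary,
which no common tree connects, receive the fixed constant 5 — higher than
any within-domain distance.

The Mantel statistic is Spearman's ρ over the n(n−1)/2 upper-triangle
entries; the null permutes rows and columns of one matrix simultaneously.
Tests are one-sided (positive association) with the add-one rule
p = (1 + #{ρ_perm ≥ ρ_obs}) / (1 + n_perm), so the minimum p is
1/(n_perm + 1); the source's reporting (a minimal p at 10⁴ permutations,
and p = 1 for a negative partial correlation) is consistent with either
add convention, and add-one is chosen for validity. The partial statistic
is the standard first-order partial correlation of rank vectors; the null
permutes the first matrix (raw-matrix method). Sampled p-values are
verified against exhaustive enumeration (all 120 relabelings at n = 5) and
the test's type-I error is calibrated over 500 null replicates.

## The synthetic world

The generator produces everything the pipeline consumes, with known truth.
Its defaults are the desk-scale stated world of the acceptance checks:
300 taxa, 500 genes (40 niche-determining), 100 samples.

* **Tree**: birth–death (rates 1 and 0.5) conditioned on the number of
  surviving tips, rescaled to unit height; gene rates are per tree height.
* **Gene content**: each gene is a two-state presence/absence Markov chain
  (gain 0.3, loss 0.7 per tree height; stationary prevalence 0.3) run from
  a stationary root state. 10% of genes carry copy numbers above one via a
  per-gene Poisson mark shared by all carrying tips, so counts — not just
  presence — flow through the profile machinery. The designated niche
  genes evolve with a 5× rate multiplier: fast turnover decouples their
  tip pattern from vertical descent (the lateral-transfer regime in which
  gene content can out-predict phylogeny) while leaving same-species tips
  (patristic < 0.01) near-identical.
* **Niche traits**: each of 4 trait dimensions is
  `sqrt(beta) ×` (standardized linear combination of niche genes)
  `+ sqrt(1−beta) ×` (standardized Brownian trait). `beta` is the fraction
  of niche variance that is gene-determined — an artifact knob spanning
  the hypotheses, not an empirical quantity; no effect-size scale exists
  to anchor it, so tests sweep it over {0, 0.5, 1}.
* **Environment**: sample positions form a permuted even grid over
  [−2, 2] per dimension. Observed metadata (salinity, depth, temperature,
  oxygen, nutrients, chlorophyll, DOC) are noisy monotone maps of
  dimensions 1–2 spanning realistic brackish-sea ranges (salinity ~2–30
  PSU, depth ~1–210 m); dimensions 3–4 are latent drivers with no
  observed proxy, so lower-rank ordination axes need not correlate with
  any measured variable — as seen in real surveys.
* **Abundance**: expected log-abundance is `peak − ||z_t − e_s||²/n_dims`
  (a Gaussian niche response on standardized traits; peak = 2), plus
  Normal(0, 0.3) noise, exponentiated, with values below the detection
  limit 0.01 set to zero. The noise level is anchored to the observed
  reproducibility of within-species abundance profiles (rank correlation
  ≈ 0.9–0.95 between near-identical taxa); zeros arise from the detection
  limit only — the simplest mechanism consistent with coverage data.
* **ANI**: `0.7 + 0.3 exp(−15 D)` plus Normal(0, 0.002) noise, clipped to
  [0.7, 1]. The decay rate places the 96.5% species boundary at patristic
  ≈ 0.008 (< 1% of tree height), so species clusters are shallow and
  non-trivial. No generative model of ANI exists in the source; this is a
  monotone transform chosen for structural realism.
* **Contigs and quality**: 5–50 contigs per genome (20–200 kb) with
  lognormal coverage factors normalized so the length-weighted mean
  factor is 1 — the contig decomposition conserves each taxon's abundance
  exactly, which the round-trip tests exploit at 1e-9. Completeness is
  drawn in [80, 100] and contamination in [0, 5] so the default world
  passes quality control intact.

Everything is a deterministic function of the configuration seed
(sub-seeds are derived per stage), and the materialized on-disk world
round-trips losslessly through the package readers.

### What a green test does and does not establish

The generator emulates the statistical structure the pipeline's claims
rest on: phylogenetically autocorrelated gene content, partly
gene-determined niche traits, gradient-structured abundances with noise
and detection limits, and species clusters induced by an ANI-distance
relationship. It does **not** simulate reads, assembly or binning error,
genome incompleteness or contamination at the sequence level,
compositionality of relative abundances, seasonal dynamics, or viral and
eukaryotic fractions. A green acceptance run therefore establishes that
the pipeline's machinery is correct and that it can discriminate
gene-driven from phylogeny-driven ecology *when the world matches its
assumptions* — not that any particular real dataset has those properties.

## Numerical choices and degenerate inputs

Symmetry of input matrices is enforced to 1e-9; eigenvalues below −1e-8
after Cailliez correction raise a warning; dissimilarities are clamped to
[0, 1] against eps-overshoot of correlation routines; constant feature
columns are dropped using training-fold statistics; constant targets or
profiles raise errors rather than returning NaN; empty clusters, empty
worlds, missing pair members and asymmetric matrices are explicit errors.
Random forests flag (rare) observations that were in-bag for every tree
instead of silently imputing. The ridge λ = 0 path uses the minimum-norm
pseudoinverse, making the OLS oracle test exact on full-rank designs.

## Known limitations

* One MAG per taxon: multi-MAG clusters arise only from near-zero
  phylogenetic divergence, so synthetic clusters are smaller than
  real-world clusters built from hundreds of samples.
* The taxon-restricted analysis recomputes the prevalence filter within
  the subset (the source convention is unstated; this is the documented
  default).
* Whether salinity-gradient group means should cover exactly two samples
  per group is left to configuration; the package takes arbitrary group
  definitions.
* The boosting implementation forgoes feature subsampling, matching the
  reference default as closely as documented; exact tree-for-tree
  equality with other boosting software is not claimed — oracle tests
  cover its limiting behavior (zero stages/learning rate → training mean)
  and its predictive performance.
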