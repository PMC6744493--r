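---
title: "From tumour-specific causal assignments to survival-stratified subgroups"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From tumour-specific causal assignments to survival-stratified subgroups}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

A tumour's transcriptome is perturbed by a handful of driver somatic genome
alterations (SGAs) acting through signalling pathways, but most observed
SGAs are passengers, and the same pathway can be hit by different SGAs in
different patients. `oncomodules` starts from *tumour-specific causal
assignments* — a table stating, for each tumour, which SGA is the inferred
cause of each differentially expressed gene (DEG), with a posterior
probability, under the constraint that each DEG has exactly one assigned
cause per tumour. Upstream Bayesian inference producing such tables is
consumed here purely as an input contract.

From these assignments the package derives, in order:

1. **Significant drivers and relationships** — four filtering standards.
2. **A DEG co-regulation network** — DEGs linked when a common SGA causes
   both in the same tumour.
3. **DEG modules** — spectral consensus clustering of that network; each
   module is read as the expression signature of one perturbed pathway.
4. **Dominant drivers per module** and hypergeometric gene-set overlap.
5. **Patient features** — per-module mean expression plus clinical
   covariates, z-scored.
6. **Patient subgroups** — PAM (k-medoids) consensus clustering.
7. **Survival evaluation** — Kaplan–Meier curves, log-rank tests, Cox
   models with Wald tests and Harrell's concordance index.

## Filtering standards

With thresholds from `filter_thresholds()`:

1. An assignment is *valid* if its posterior strictly exceeds
   `posterior_floor` (default 0.5). The floor stands in for a
   permutation-calibrated threshold, which would require re-running the
   upstream inference; it may be set globally and is configurable. Duplicate
   (tumour, SGA, DEG) rows are collapsed to their maximum posterior with a
   warning.
2. An SGA is a *driver in a tumour* if it causes ≥ 5 distinct DEGs there.
3. An SGA is a *significant driver* if it is a driver in ≥ 30 tumours
   **and** in ≥ 25% of the tumours where it is observed (a conjunction).
4. A pair is a *significant relationship* if the SGA is a significant
   driver **and** the DEG is caused by it in ≥ 50 tumours **or** in ≥ 20%
   of the SGA's driver tumours (a disjunction).

All count comparisons are inclusive (≥); the posterior floor is strict.
One caveat worth knowing: the pipeline is *not* globally monotone in every
threshold. Raising `posterior_floor` or `min_degs_per_driver` shrinks the
set of driver calls, which is the **denominator** of the relationship
fraction in standard 4, so a relationship can become significant under a
stricter upstream threshold. Drivers themselves are monotone in every
threshold; the test suite pins down exactly which monotonicities hold.

## Network and modules

Nodes are DEGs appearing in strictly more than 10% of the tumours that
retain at least one significant assignment. An edge's weight is the number
of *distinct tumours* in which the pair was co-regulated by a common SGA;
every co-regulation instance (tumour × SGA × DEG pair) is retained as edge
provenance. A `min_edge_weight` option can additionally require a minimum
tumour count per edge, for users who prefer to read the 10% rule as an
edge-level threshold; the node-level reading is the default because it is
the operative procedural description of the construction.

Weights convert to pseudo-distances `D = 1/W` (absent edge → infinite),
then to affinities `A = exp(-D² / 2σ²)`. The kernel formula is implemented
with the negative exponent — short distances must map to high affinities.
By default `σ` is the median finite off-diagonal pseudo-distance, which
puts the kernel shoulder at the typical observed distance; any fixed value
(e.g. 0.05 or 0.1) can be supplied instead.

Clustering follows the normalized-spectral recipe: symmetric degree
normalization `D⁻¹ᐟ²AD⁻¹ᐟ²`, top-`k` eigenvectors, unit-length row
normalization, then k-means. Numerical conventions, all chosen so a seed
reproduces a partition bit for bit:

- eigenvector signs fixed (first non-negligible component positive);
- k-means uses plain random distinct-row centre initialization — its
  sensitivity to initialization is deliberate, since the consensus step
  averages over it — with nearest-centre ties broken to the lowest index,
  empty clusters re-seeded at the point farthest from its centre, 300
  iterations maximum, squared-shift tolerance 1e-6;
- zero-degree nodes cannot enter the degree normalization and are placed
  in a sink module labelled `k + 1`, with a warning.

### Choosing the number of modules

For each candidate `k`, `consensus_modules()` repeats the k-means stage
(default 100 runs) and records co-clustering frequencies;
`consensus_stability()` scores the consensus matrix as the fraction of
pairs outside the ambiguity band [0.1, 0.9] (one minus the proportion of
ambiguous clustering, PAC). Two empirical facts shaped the selection rule
in `select_module_count()`:

- Below the true module count, merges can be *stable*: with few blocks the
  optimal merge is often unique, so stability alone cannot reject small
  `k`.
- Above it, stability degrades but slowly in absolute terms — splitting
  one true module of `m` nodes perturbs only ~`m²/n²` of the matrix — so
  "largest k above a floor" systematically over-selects.

The rule therefore scans candidates in ascending order, starts at the
first candidate reaching the stability floor (default 0.8), advances while
stability is non-decreasing, and stops at the first drop: the selected `k`
is the last point at which adding modules does not hurt reproducibility.
The full score table is returned for audit. The floor and band are
configuration, not dogma; they were fixed once against planted synthetic
networks (below) and left alone. On genuinely structureless input no
candidate reaches the floor and the smallest candidate is returned.

A known limitation: when a block is small and tight, its optimal split can
itself be unique and hence reproducible, in which case stability cannot
distinguish `k` from `k + 1`; with the module sizes the generator plants
(~40 nodes) the over-split is reliably unstable, but very small planted
blocks (~10 nodes) occasionally fool the criterion.

## Module annotation and features

An SGA is a *dominant* driver of a module when it contributes strictly
more than 10% of the co-regulation instances whose DEG pair lies wholly
inside the module. Instances are counted (tumour × pair), not collapsed to
tumours, and each instance carries exactly one SGA, so proportions within
a module sum to one. Gene-set overlap uses the upper-tail hypergeometric
probability `P(X ≥ overlap)`; the default universe is the network's node
set, since the background the original analyses used is not stated; raw
p-values rank the sets, mirroring top-10 overlap tables.

Each module's patient feature is the mean expression of its *effective*
DEGs — members present on the expression platform. Features (module and
clinical) are z-scored with the sample (n−1) standard deviation; constant
features are dropped with a warning; missing-data policy is complete-case
by default. Clinical covariates must arrive numerically encoded; the
package does not guess encodings.

## Patient subgroups

PAM is used as the base clusterer (via `cluster::pam`) on Euclidean
dissimilarities of the z-scored features: deterministic given the data,
robust to outliers, and it returns medoids with which new patients could
be classified. Consensus is built by subsampling patients without
replacement (fraction 0.8, a convention of the consensus-clustering
literature; the choice is configurable) for 100 resamples by default; a
pair's consensus is its co-clustering count over its co-sampling count.

Group-count selection combines two signals per candidate `k`: the area
under the consensus CDF (AUCDFC) — which grows as more pairs are split —
and consensus stability. A candidate qualifies when its relative AUCDFC
gain over the previous candidate is at least 0.03 and stability clears the
floor (0.8); the chosen `k` is the stability peak of the initial
qualifying run, by the same ascending-scan logic as for modules. Both
feature regimes are always clustered: all features, and module features
only, yielding two labelings.

## Survival analysis

Kaplan–Meier estimation, the g-sample log-rank test and Cox proportional
hazards all come from the `survival` package behind thin, validated
wrappers. Ties use Efron's correction by default (the survival package's
own default; a `ties` argument exposes Breslow, under which the partial
likelihood is exactly invariant to dataset duplication — a property the
test suite uses). Times are in days and compared exactly for risk sets.
Constant and collinear covariates are rejected by name before fitting.
Wald p-values are two-sided with significance at 0.05. Harrell's C is
computed over comparable pairs with 0.5 credit for tied scores; models are
fitted pooled and per patient group.

## The synthetic cohort generator

`generate_cohort()` emulates the statistical structure every stage
assumes, with defaults that are the package's reference study conditions:
200 tumours, 5 pathways, 2 interchangeable drivers per pathway, 40
signature DEGs per pathway (disjoint by default; a controlled overlap
option exists), 30 passenger SGAs.

- **Mechanism archetypes.** Patients belong to one of 4 archetypal
  disease mechanisms — binary pathway-activation profiles in a fixed
  balanced design (each pathway active in exactly half the archetypes,
  pairwise Hamming distance ≥ 3) — and deviate from their archetype by
  independent per-pathway flips with probability 0.05. Archetypes are what
  make "patient subgroups" a planted ground truth: with independent
  activations there is nothing for patient clustering to recover. The
  flip rate was fixed once so that the planted subgroups remain
  recoverable from module features (higher rates leave a large minority
  of patients genuinely off-mechanism); it is a spec field, not a tuned
  constant.
- **Assignments.** In a tumour with an active pathway, one of its drivers
  is observed and assigned as the cause of a random ≥ 5-gene subset of
  the signature (each gene with probability 0.6), posterior ~ U(0.7, 1).
  Observed passengers (rate 0.15/tumour) cause 1–3 DEGs with posterior
  ~ U(0, 0.4), so the posterior floor, the per-tumour DEG count, and the
  recurrence standards each do real work. The one-cause rule is enforced
  by construction and asserted.
- **Expression.** Signature genes shift by 2.0 in activated patients over
  N(0, 1) noise; 10% of DEGs are withheld from the platform to exercise
  effective-DEG handling.
- **Survival.** Exponential times with log-hazard linear in the activation
  vector (coefficients 0.8, 0.6, −0.5, 0.4, −0.6 across the five
  pathways); censoring uniform on a horizon tuned by bisection to a 30%
  censored fraction. Clinical covariates are age plus two binary markers,
  one associated with pathway-1 activation.

What the generator does **not** emulate: correlated copy-number segments,
expression platform batch effects, non-proportional hazards, informative
censoring, and the long-tailed SGA frequency spectrum of real cohorts.
Passing tests therefore demonstrate algorithmic correctness and
recoverability under the planted model, not clinical performance on real
data.

## Problem sizes used in the shipped checks

The test-suite and the acceptance script run the consensus machinery at
reduced sizes chosen as comfortable demonstrations of the same behaviour:
30 spectral-consensus runs over candidate module counts 2–8, 40 patient
resamples over candidate group counts 2–8, with 10 generator seeds for
the recovery and end-to-end properties. Package defaults remain 100 runs,
100 resamples and group candidates 2–15.

## Known limitations

- Stability-based model selection can be fooled when an over-split of a
  small tight module is itself unique (see above).
- PAM is a local (BUILD + SWAP) optimizer; on unstructured data it can
  miss the global medoid configuration, which is inherent to the
  algorithm and surfaces in the tests as a local-optimality assertion
  rather than global optimality.
- A single global posterior floor is supported; per-pair permutation
  thresholds would require the upstream inference.
- The hypergeometric universe choice materially affects overlap p-values;
  the network-node default is conservative and explicit.
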