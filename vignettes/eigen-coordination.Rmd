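---
title: "Eigen-spectrum coordination analysis of gene sets"
author: "eigenCoord"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Eigen-spectrum coordination analysis of gene sets}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(eigenCoord)
```

## The statistic

Given a small gene set (say, three hub genes from a protein–protein
interaction network plus a pathway anchor such as *MAPT* or *APP*) and a
genes-by-samples expression matrix on the log2 scale, the coordination
statistic is built in four steps, per sample group:

1. **Z-score standardization.** Each gene row is centered to mean 0 and
   scaled to standard deviation 1 across the group's samples.
2. **Inner-product (Gram) matrix.** With standardized rows stacked into
   $X$ ($n$ genes $\times$ $m$ samples), form
   $R = XX^\top$, whose entry $(i, j)$ is the inner product
   $a_i \cdot a_j = \sum_{s=1}^m x_{is} x_{js}$.  Because the rows are
   standardized under sd divisor $d$ ($m$ or $m-1$), $R = d\,C$ where
   $C$ is the sample correlation matrix, so $R$ is symmetric positive
   semi-definite with every diagonal entry equal to $d$.
3. **Eigendecomposition and normalization.** $R = Q \Lambda Q^\top$
   (for a symmetric matrix the eigenvector matrix is orthogonal, so its
   inverse is its transpose).  The eigenvalues are normalized,
   $\lambda_i \leftarrow \lambda_i / \sum_k \lambda_k$, giving a
   descending, unit-sum spectrum in $[0,1]$.
4. **Between-group comparison.** The per-rank difference of the two
   groups' spectra.  A positive delta at rank 1 means the gene set
   co-varies more tightly — is more *coordinated* — in the second group.

The normalized spectrum is a measure of eigenvalue concentration: a
perfectly coordinated $n$-gene set (all pairwise correlations 1) has
spectrum $(1, 0, \dots, 0)$, fully independent genes approach
$(1/n, \dots, 1/n)$.  For an equicorrelated set with coefficient $\rho$
the population spectrum is known in closed form,
$\big(\tfrac{1 + (n-1)\rho}{n}, \tfrac{1-\rho}{n}, \dots\big)$, which
the package uses as its analytic oracle throughout the test suite.

### Assumptions

* Expression values are on a log-like scale where Z-scoring is
  meaningful; the method consumes normalized expression, not raw counts.
* Coordination is summarized through second moments only; the statistic
  sees correlation structure, not higher-order dependence.
* Both groups contribute the same gene set, so the spectra are
  comparable rank by rank.
* No sampling distribution is attached to the spectrum deltas.  The
  method is descriptive; a permutation test over group labels would be a
  natural extension but is deliberately not bundled with the statistic.

### Invariances (all tested)

* The normalized spectrum is invariant to multiplying the data by any
  $c > 0$ and to the choice of sd divisor ($m$ vs $m-1$), since either
  rescales $R$ by a constant that cancels in the normalization.
* The spectrum of the Gram matrix of Z-scored rows equals the
  normalized spectrum of the sample correlation matrix computed by an
  independent route.
* Spectra sum to 1 and comparison deltas sum to 0 by construction.
* Increasing $\rho$ never decreases the population leading eigenvalue.

## Tunable parameters

| parameter | where | default | rationale |
|---|---|---|---|
| `sdDivisor` | `zscoreRows()` | `"m-1"` | sample sd convention; the normalized spectrum is invariant to it, so the choice is cosmetic and exposed only for exact reproduction of intermediate matrices |
| `scope` | `coordinationAnalysis()` | `"within"` | each group is standardized separately, matching the definition of per-group standardized matrices; `"global"` is provided for sensitivity analysis |
| `refGroup` | `coordinationAnalysis()` | first group alphabetically | deltas are reported as (other − reference); set it explicitly in case/control studies |
| `lfcThresh`, `pThresh` | `callDEGs()` | 1.5, 0.05 | conventional effect-size and significance cut-offs for log2 expression; both strict inequalities, so a gene exactly on a threshold is not called |
| `useAdjusted` | `callDEGs()` | `TRUE` | the 0.05 threshold is applied to BH-adjusted p-values; a flag switches to raw p because published workflows are often ambiguous about which was thresholded |
| `minScore` | `readEdgeList()` | 0 | interaction-confidence filter; high-confidence PPI analyses typically use 0.99 (scores in [0,1]; a [0,1000] dialect is auto-detected) |
| `weights` | `softVote()` | RF 2, SVM 2, GMM 1, LM 1 | favors the two stronger learners; the ensemble is invariant to rescaling all weights |
| `trainFraction` | `trainTestSplit()` | 0.8 | the usual 80/20 split; stratified and seeded by default |
| `threshold` | `predictLabels()` | 0.5 | probability cut; an exact tie goes to the negative class so calls are deterministic |

## What the synthetic generator emulates — and what it does not

`syntheticDesign()` / `simulateExpression()` draw each group from a
multivariate normal on the log2-expression scale whose correlation
matrix is block-diagonal over user-defined gene modules: each module is
equicorrelated with a group-specific $\rho$, genes outside any module
are independent, and a chosen gene subset receives an additive mean
shift in one designated group.  Multivariate normality is the minimal
generative model consistent with a method built from Z-scores and inner
products, and equicorrelated blocks give closed-form target spectra for
parameter-recovery tests.  Noise is folded into the covariance scale
(`noiseSd` multiplies the unit-variance blocks) rather than added as a
second stage; under Z-scoring the two are equivalent and one stage is
simpler to reason about.

The default design mirrors a small two-group expression study: 10 case
and 9 control samples and one four-gene module that is strongly
coordinated in cases ($\rho = 0.9$) and weakly in controls
($\rho = 0.1$), with unit noise.

The generator deliberately does **not** emulate several features of
real data: RNA-seq count noise and library-size effects (the method
consumes normalized expression), heavy tails and outlier samples,
batch or covariate structure (age, sex), probe-to-gene collapsing
ambiguity in microarray data, and correlation between modules.  Tests
passing on this generator therefore demonstrate correctness of the
computations and the direction/recovery behavior of the statistic under
its own model — not robustness to those real-data complications.  In
particular, exact reproduction of any published spectrum from public
microarray data additionally depends on unstated preprocessing choices
(probe collapsing, standardization scope) and is out of the package's
scope.

A companion generator, `simulateEdgeList()`, plants hub nodes of exact
prescribed degree in an otherwise sparse undirected graph (every
non-hub ends with strictly smaller degree) and attaches uniform
confidence scores in [0.5, 1], so that degree ranking has a known
ground truth.

## Numerical choices

* **Eigensolver.** `eigen(symmetric = TRUE)`, i.e. a dedicated
  symmetric solver; the decomposition is $Q\Lambda Q^\top$ with
  orthogonal $Q$, never a general inverse.
* **PSD clamping.** Floating point routinely yields eigenvalues like
  $-10^{-15}$ on rank-deficient Gram matrices.  Eigenvalues in
  $[-10^{-8}\,\mathrm{tr}(R),\, 0)$ are clamped to zero before
  normalization; anything below that tolerance is a genuine PSD
  violation and raises an error, as does a non-positive eigenvalue sum.
* **Sorting and ties.** Spectra are sorted descending; hub rankings
  break degree ties by lexicographic node ID; classifier probability
  ties at exactly 0.5 go to the negative class.  All outputs are
  deterministic given a seed.
* **Degenerate inputs.** Zero-variance genes make Z-scoring undefined
  and raise an error naming the gene (with `dropConstant = TRUE` to
  drop them instead); unlabeled samples, mismatched gene sets and
  out-of-range p-values or scores all fail fast with informative
  messages.
* **Seeding.** One global seed feeds a single generator stream; groups
  are drawn sequentially in sorted order, so identical designs give
  bit-identical matrices.

## Design choices where the design was open

* **Per-group standardization is the default.**  The statistic is
  defined on per-group standardized matrices; standardizing globally
  mixes between-group mean differences into the correlation structure.
  Both are available (`scope`), and for strong contrasts they agree in
  direction.
* **Welch's t-test as the differential-expression engine.**  The DEG
  stage is a simplified stand-in: per-gene Welch t with Satterthwaite
  degrees of freedom, no information borrowing across genes.  Moderated
  empirical-Bayes statistics are a mature published methodology in
  their own right and are intentionally not re-implemented here; for
  the well-powered simulated designs this package targets, the per-gene
  test recovers planted effects exactly (tested).  Covariate
  adjustment is likewise out of scope.
* **BH through `stats::p.adjust`.**  The step-up procedure is standard
  library territory; the package validates inputs, delegates, and keeps
  an independent brute-force implementation in its test suite as the
  oracle.
* **Base learners behind a contract.**  The ensemble's contribution is
  the weighted soft-vote aggregation and its evaluation, not the
  learners.  Random forest and radial-kernel SVM come from their
  standard implementations; the "GMM" is interpreted as per-class
  Gaussian class-conditional densities (diagonal covariance, empirical
  priors, Bayes posterior), and the "LM" as a logistic linear model —
  the two simplest readings of those labels in a supervised
  probability-emitting role.  Any function mapping a feature matrix to
  a valid probability matrix can replace them.
* **ROC/AUC from scratch.**  The threshold-sweep ROC staircase and
  trapezoidal AUC are implemented directly and proven equal to the
  Mann–Whitney pair-counting statistic (and to an established ROC
  library) in tests, rather than delegated — they are part of the
  evaluated surface.
* **No significance test on spectrum deltas.**  None is defined for
  the statistic; attaching one silently would overstate what the
  method provides.

## Problem sizes

The test suite and the acceptance script run entirely on simulated
data at sizes chosen to make Monte-Carlo noise small relative to the
tested tolerances while keeping a full run to seconds: 10,000 samples
per group for moment/parameter recovery (tolerances 0.02–0.05), 1,000
per group for spectrum-direction checks, 100 per group for classifier
evaluation (40 test samples after the 80/20 split), 1,000 random draws
for the AUC and BH oracle equivalences, and 50–100 random matrices for
the spectrum invariance suite.

## Known limitations

* The spectrum comparison is descriptive; rank-1 deltas have no
  attached p-value.
* The DEG stand-in ignores covariates and mean–variance trends, so its
  calls on real RNA-seq data will differ from moderated-statistic
  pipelines.
* Hub ranking implements unweighted degree only — the one centrality
  the workflow calls for — not other centralities.
* The equicorrelation oracle covers exchangeable blocks; spectra of
  arbitrary correlation structures are validated only against the
  generic solver route.
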