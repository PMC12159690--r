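---
title: "Single-subject molecular network perturbation: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Single-subject molecular network perturbation: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

molpert turns a table of regional molecular-imaging measurements — one row
per subject, one column per brain region, for example FDOPA PET SUVr values
over an 83-region anatomical parcellation — into *single-subject* network
deviation profiles. This vignette describes the statistical model, the
choices behind every tunable parameter, what the bundled synthetic-data
generator does and does not emulate, and the known limitations.

## The model

**Reference network.** Molecular connectivity is defined across subjects: two
regions are "connected" when their measurements covary over a reference
(control) cohort. `reference_network()` residualizes every region column
against an intercept, age and sex (ordinary least squares), then computes
Pearson correlations between the residualized columns. For this fixed design
that equals the partial correlation given the covariates. The result is an
m×m matrix `PCC` with the cohort size n attached. Edges with |PCC| within
1e-12 of 1 abort the build: they indicate duplicated or collinear regions,
and the deviation variance below degenerates to zero there.

**Single-subject perturbation.** A new subject cannot have a correlation
matrix of its own. Instead the subject is appended to the reference cohort,
the covariate regression is refitted on all n+1 rows, and the network is
rebuilt. The edge-wise change `d = PCC_perturbed − PCC` is standardized by
its approximate null scale,

    z = d * (n − 1) / (1 − PCC²),

which is the first-order variance of the change in a sample correlation when
one observation from the same population is added. The z-matrix (diagonal
forced to zero) is the subject's deviation profile; `edge_pvalues()` maps it
through the two-tailed standard-normal tail.

Two modelling decisions are worth making explicit:

* the covariate regression is *refitted* on the augmented sample rather than
  reusing the reference coefficients — the perturbed network is defined as a
  full network build on n+1 subjects. The alternative would freeze the
  reference regression; we expose no option for it because the refit is the
  defining property of the perturbation construction.
* the denominator uses the reference n, not n+1, and makes no
  degrees-of-freedom correction for the covariates. A corrected variant
  (`dof_adjust = TRUE` in `reference_network()`) rescales z by
  (n−1−k)/(n−1); it is off by default.

**Calibration of z, and a caveat.** The z-score is asymptotically centred
and scaled correctly, but it is *not* asymptotically normal in its tails:
conditionally on the reference network, z at an edge is a quadratic form in
the added subject's residuals (at PCC = 0 it is exactly a product of two
standard normals). Its tails are heavier than Gaussian. Numerically, the
two-tailed exceedance of the nominal 5% threshold is about 6.5% — within a
factor-two band — while the exceedance of the nominal 1% threshold is about
3.2%, i.e. more than twice nominal. The exact limit at an uncorrelated edge
is P(|uv| > 2.576) = 0.0318 for independent standard normals u, v. Users
should treat per-edge p-values near 0.01 as approximate; the package's own
test suite asserts the 5% band and documents the 1% behaviour rather than
pretending it calibrates.

**Extreme-deviation metrics.** Deviation matrices are thresholded at
|z| > τ with τ = 4.13 by default, the value corresponding to a
Bonferroni-corrected 0.05 level for the edge count of an 83-region network.
τ is kept as a fixed constant rather than recomputed from m, so results on
the default parcellation match the published convention; pass another τ
where appropriate. The inequality is strict, and entries at exactly τ are
zeroed.

* `sed()` — subject extreme deviations: the sum of absolute surviving
  z-scores over the strict lower triangle divided by the number of edges
  C = m(m−1)/2. Because magnitudes (each > τ) are summed, SED can exceed 1;
  a `count = TRUE` variant divides the number of surviving edges by C
  instead and is a true proportion.
* `red()` — regional extreme deviations: for each region, the mean of the
  absolute thresholded z-scores in that region's row, with divisor m (the
  zero diagonal counts in the divisor). Absolute values make RED
  non-negative and comparable between groups whose deviations have opposite
  signs; a `signed = TRUE` variant preserves direction.

## The downstream battery

Group comparisons use the Wilcoxon rank-sum test (exact for small tie-free
samples), the one-tailed Wilcoxon signed-rank test for paired
baseline/follow-up designs (zero differences dropped; for up to 14
informative pairs the p-value is computed by enumerating sign patterns of
the mid-ranks, which stays exact under ties), Kruskal–Wallis with Dunn's
post-hoc z-tests on pooled ranks, Benjamini–Hochberg FDR correction, and
Cohen's d with the plain pooled SD. Region-wise scans treat a constant
region as p = 1 rather than aborting an 83-region analysis. The "top 10%"
region selection takes floor(0.10·m) regions by mean RED (8 of 83),
breaking ties by region index.

Classification is a linear SVM (margin parameter C = 1) under stratified
5-fold cross-validation: each fold tests on a held-out 20% after training
on 80%, which is the reading under which "5-fold CV" and "80/20 split" are
simultaneously true; a single fixed stratified 80/20 split is available via
`mode = "split"`. Features are either the vectorized strict lower triangle
of the *raw* z-matrix (3403 features at m = 83; thresholded variants via a
flag) or the RED vector (m features). Standardization uses training-fold
statistics only, and SMOTE (hand-implemented, k = 5 neighbours, convex
interpolation) is applied inside training folds only, so no information
leaks from test folds. The permutation test re-runs the cross-validated
pipeline on label permutations with the add-one p-value
(1 + #{null ≥ observed}) / (1 + n_perm); because the fold standardization does
not depend on labels, the per-fold feature representations are precomputed
once and reused across permutations — identical results, much faster. With
more features than subjects the fold's standardized feature matrix is
replaced by an n×n factor R with RRᵀ equal to the linear Gram matrix; the
linear SVM depends on the data only through that Gram, so the fit is
identical while each solve shrinks from thousands of columns to n. AUC is the rank (Mann–Whitney) AUC of the
pairwise decision values, macro-averaged over class pairs in the one-vs-one
multiclass mode.

Fingerprinting correlates strict-lower-triangle vectors between baseline
and follow-up deviation matrices and matches by argmax (ties broken by
lowest index — a measure-zero event made deterministic). Stability
resampling rebuilds the network on random subsets (default 8 to 64 subjects
in steps of 4, 20 repetitions each, subsampling without replacement,
per-cell seed substreams) and correlates the strict lower triangle against
the full-cohort network; the diagonal is excluded because it is constant 1.
A small random subsample can be single-sex; the rebuild then drops the
constant covariate column instead of failing.

## The synthetic cohort generator

Real FDOPA PET cohorts of this kind are access-restricted, so the package
ships a generator whose defaults emulate the statistical structure the
method assumes; every downstream stage is tested against it.

**Correlation structure.** The default 83-region target correlation is
deliberately bimodal: a densely inter-correlated subcortical/monoaminergic
core (regions 1–40 at 0.75, with the striatal sub-block 1–12 at 0.85),
homologous left/right pairs at 0.9, cortical lobe blocks at 0.4–0.5, and a
global background of 0.2. This mirrors two robust features of real SUVr
covariance: division by a common reference region induces a positive
correlation floor everywhere, and striatal/homologous FDOPA signal is very
strongly inter-correlated. A consequence worth knowing: the wide spread of
true edge correlations is what makes subsampled networks correlate highly
with the full-cohort network, reproducing the qualitative stability
behaviour (mean correlation above 0.9 from around 36 subjects on a
71-subject cohort) that motivates reference cohorts of a few dozen
controls. Region means default to 2.5 SUVr (SD 0.25) in the striatal block
and 1.2 (SD 0.15) elsewhere; age enters at −0.004 SUVr/year around the
mid-age, sex as +0.05 SUVr for males, ages uniform over 20–65. Infeasible
block overlays are repaired to the nearest PSD correlation matrix by
eigenvalue clipping with renormalization, and the repair is recorded.

**Patient perturbations.** A single subject has no covariance of its own,
so group-level network perturbations must be induced through each patient's
*position* relative to the reference covariance. The default mechanism is a
mean displacement along an eigenvector of the affected block's covariance:

* *strengthen* — along the leading axis. A subject displaced along the
  dominant covariance pattern reinforces the block's correlations, so its
  deviation z-scores on block edges are positive.
* *weaken* — along the trailing (minor) axis. Note that displacing a
  subject *against* the leading axis does not weaken anything: the induced
  correlation change is an even function of a displacement along any fixed
  axis, so both signs of a leading-axis shift strengthen. A displacement
  that contradicts the covariance pattern — the minor axis — is what drags
  correlations down and produces negative z-scores. This asymmetry is a
  property of covariance perturbation, not of the implementation.

The displacement length is `magnitude` times the mean regional SD of the
affected block. The default magnitude of 5 emulates clinically overt
disease: striatal FDOPA loss in Parkinsonian neurodegeneration is on the
order of 40–50% of signal, several regional SDs, and group separations at
this scale reproduce the near-ceiling classification performance seen in
clearly separated clinical groups. Milder stages (first-episode or at-risk
states) are emulated with magnitudes 2–3. An alternative `rescale` mode
draws patients from a distribution whose within-block correlations are
moved towards 0.97 (strengthen) or 0 (weaken).

**Longitudinal pairs.** `simulate_longitudinal()` draws baseline and
follow-up jointly: the subject-specific noise component is shared across
timepoints with correlation `stability_rho`, the perturbation displacement
is multiplied by `treatment_shrink` at follow-up, and independent
measurement noise (`noise_sd`, default 0.02 SUVr) is added at follow-up.
With `stability_rho = 1`, `treatment_shrink = 1` and `noise_sd = 0` the
follow-up equals the baseline exactly. The generator needs the generative
decomposition (mean + displacement + subject noise), which is why it
produces both tables itself instead of accepting a finished baseline table.

**What the generator does not emulate.** Gaussian marginals (real SUVr is
mildly skewed), site/scanner batch effects, atlas misparcellation,
partial-volume effects, non-linear age trajectories, and any voxel-level
structure. Passing tests on these cohorts shows the pipeline is correct and
well calibrated under its own assumptions, not that the method is validated
on clinical data.

## Experiment designs used by the test suite and acceptance script

These designs are part of the package's own evaluation and are fixed
choices, not tuning knobs:

* *Recovery study*: strengthen on the striatal block (1:12 — localized,
  neurodegeneration-like) versus weaken on the subcortical core (1:40 —
  diffuse, psychosis-like), 30 patients each at default magnitude, linear
  SVM on edge features with a 1000-permutation null. This mirrors the
  qualitative contrast between localized nigrostriatal and broader
  psychosis-spectrum deviations.
* *Threshold robustness*: a 30-patient cohort spanning a severity spectrum
  (weaken-core magnitudes 1, 3, 5, 7, 9; six patients each). Cross-threshold
  consistency of SED/RED (Pearson r > 0.9 between τ = 2 and τ = 4.13) is
  carried by between-subject severity heterogeneity; a cohort with a single
  fixed magnitude is homogeneous in deviation burden and the correlation
  becomes seed-fragile. Clinical cohorts have severity spread, so the graded
  design is the faithful emulation.
* *Fingerprinting*: 18 longitudinal pairs (the Study-3-sized first-episode
  design) with `stability_rho = 0.7`, `treatment_shrink = 0.5`, and a mild
  weaken-core perturbation (magnitude 2, matching a minimally treated
  early-stage group). The chance-level control (`stability_rho = 0`) is run
  on a covariate-free cohort and reference: with demographics left in,
  identification sits a few points above 1/n because age and sex are
  themselves subject-stable signal, and because the per-subject covariate
  refit leaves a small subject-stable imprint in z. Both channels are real
  properties of the methodology; the clean configuration is statistically
  at chance.
* *Null false-positive scan*: one fixed 71-subject reference, a pool of
  3000 held-out null subjects' RED rows, and 500 replicates each drawing
  two disjoint 30-subject groups from the pool. Marginally every replicate
  is a valid null comparison; pooling trades some cross-replicate
  independence for a several-fold faster run.
* *Problem sizes*: reference cohorts of 71 (matching the application
  design) and 200 (calibration), 500 held-out null subjects, 30 patients
  per group, 83 regions throughout, 1000 label permutations, and the
  8–64-in-steps-of-4 × 20-repetition stability grid.

## Numerical choices and degenerate inputs

* Determinism: every stochastic routine takes a seed; nested experiments
  derive per-cell substream seeds with a small integer hash kept below
  2^31. Fixed seed in, identical output out — including CSV bytes, which
  are written with 17 significant digits.
* Missing values are rejected outright (the intended data have none, and no
  imputation is performed); zero-variance regions, duplicate labels and
  rank-deficient covariate designs are build-time errors that name the
  offending column.
* Subject covariates outside the reference range are allowed but warn about
  extrapolation.
* Ties: mid-ranks everywhere; signed-rank zero differences dropped; argmax
  ties by lowest index; top-decile ties by region index.

## Limitations

The deviation z-scores are approximate in their extreme tails (see the
calibration caveat above); the reference network is a full-rank marginal
partial-correlation estimate, with no shrinkage or sparse precision
estimation, so very small reference cohorts (below ~20 subjects for 83
regions) give noisy networks; and all conclusions from the bundled
synthetic cohorts are statements about the pipeline's behaviour under its
own generative assumptions, not clinical validation.
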