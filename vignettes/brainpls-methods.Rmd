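---
title: "Methods: transcriptome-neuroimaging PLS with spatial nulls"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: transcriptome-neuroimaging PLS with spatial nulls}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`brainpls` links a parcellated map of longitudinal gray-matter-volume (GMV)
change to regional gene expression with partial least squares (PLS)
regression, and carries the resulting gene ranking into cell-type
enrichment. This vignette is the package's own account of the models, the
parameters that matter, the numerical choices, and what the synthetic-data
tests do and do not establish.

## The model chain and its assumptions

The analysis assumes: (1) regional expression and the change map live on
the same left-hemisphere parcellation, with parcel centroids on (or near) a
common sphere; (2) the change map is a per-region statistic computed from
an independent subject sample; (3) association, not causation — the PLS
component describes spatial covariation between two maps measured in
different populations (patients for the imaging map, donors for
expression), so all inference is about spatial pattern similarity.

### Regional expression matrix

Donor microarray tables pass through six steps: annotation filter,
intensity filter, differential-stability (DS) probe selection, nearest-
centroid sample assignment, per-donor scaled-robust-sigmoid (SRS)
normalization, and two-stage regional averaging. Choices the method
leaves open, fixed here:

* **Intensity filter pooling.** "At/below background in ≥ 50 % of samples"
  is evaluated over samples *pooled across donors* (a probe dim in one
  donor but bright in five survives); `pool_donors = FALSE` applies the
  rule per donor. The boundary case (exactly 50 % below) *drops* the
  probe.
* **DS level.** DS is computed on parcel-level profiles (mean expression
  per assigned parcel), restricted per donor pair to parcels both donors
  cover, averaging the pairwise Spearman correlations that are defined;
  genes with no defined pair anywhere are dropped and reported. Probe ties
  break to the smallest probe id, which makes probe selection
  deterministic.
* **SRS constant.** `y = 1/(1 + exp(-(x - median)/(IQR/1.35)))`, then
  min–max rescaled to [0, 1]. The 1.35 factor converts the IQR to a
  normal-equivalent SD; a zero IQR returns 0.5 everywhere (a flat gene
  carries no regional information, and 0.5 keeps it neutral).
* **Normalization order.** SRS is applied per donor per gene *across that
  donor's assigned samples*, before any averaging, so that donor-specific
  intensity scales never mix.
* **Coverage.** Regions sampled by only some donors are averaged over the
  donors that have them (no imputation); regions sampled by none are
  dropped and listed in the provenance. The emitted matrix has no missing
  values.
* **Assignment ties.** A sample exactly equidistant from two centroids
  (within 1e-12 mm) goes to the smaller parcel id.

### Change map

"Paired t-test with TIV as a covariate" is operationalized as the
difference-score model `Δ_s = β0 + β1 (TIV_s − mean TIV)` per region, with
the t of `β0` on `n − 2` df. A literal paired t-test admits no covariate;
the difference-score ANCOVA is the standard reading, and with a centered
covariate `β0` is exactly the mean change, so the sign convention (positive
t = increase) is automatic. TIV is a single per-subject value (the
pre-treatment scan); no multiple-comparison correction is applied to the
map itself because the downstream PLS consumes the full uncorrected map.

### PLS and its nulls

Both `X` columns and `y` are z-scored before fitting; without this the gene
weights would be dominated by expression-scale differences and the
bootstrap Z would not be comparable across genes. The first component is
the dominant singular direction of `Xᵀy` (for a single response this is
`Xᵀy` normalized — an identity the test suite asserts against an
independent closed-form oracle on random problems). Sign is fixed by
`corr(scores, y) ≥ 0`; PLS components are sign-indeterminate and every
bootstrap replicate is re-aligned to the original weights by dot product
before standard errors are taken. Explained variance is
`corr(scores, y)²`; for one component this coincides with the regression
R² of `y` on the scores.

The spin null draws rotations uniformly from SO(3) (QR of a Gaussian
matrix with sign correction, a column flip mapping improper rotations back
to SO(3)), rotates all centroids, and relabels each region to the nearest
original centroid. Duplicates are permitted — the bijective variant is a
different estimator and out of scope. An exactly-identity relabeling is
rejected. Because rotations are isometries, the relabeled maps preserve
the empirical spatial autocorrelation; the package also exposes a naive
(unrestricted shuffling) null precisely to demonstrate, in tests, that it
over-rejects on smooth maps while the spin null stays near nominal level.
All permutation p-values use the add-one rule
`(1 + #{null ≥ obs})/(n_perm + 1)` and are therefore never zero and
reproducible given the seed.

Degenerate inputs: zero-variance predictor columns are dropped with a
warning at fit time (and zero-filled inside bootstrap resamples so that
replicate weight vectors keep their length); a zero-variance response is an
error; genes with zero bootstrap SE are flagged and excluded from the
signed lists rather than given infinite Z.

The clinical PLS treats subjects as observations and regional GMV change as
predictors. Its permutation shuffles the outcome across subjects: a
spatial rotation is undefined over subjects, so subject exchangeability is
the only available null. With ~180 regions and ~24 subjects the in-sample
score–outcome correlation is strongly inflated for *any* outcome
(overfitting in the p ≫ n regime); the permutation null absorbs exactly
this inflation, which means the permutation p has limited power at these
dimensions and the planted clinical signal is better recovered through the
bootstrap region Z ranking — the behavior the test suite checks.

### Enrichment

The ORA universe is the set of genes present in the expression matrix, not
the genome: only measured genes can enter a PLS list, and a genomic
universe would inflate significance. The hypergeometric upper tail comes
from `stats::phyper`; a brute-force combinatorial oracle (exact in double
precision for the sizes tested) pins it in the tests. GSEA permutes *gene
labels* (one ranked list exists; there are no sample classes to permute),
normalizes ES by the mean |null ES| of the same sign ("NES", accounting
for set size), and takes the add-one same-sign tail as p. When no
same-sign null exists the NES is flagged unreliable and p floors at
`1/(n_perm + 1)`. The default hit-weighting exponent is 1; exponent 0 is
kept because its walk is hand-checkable (and is asserted against an exact
4-gene example and against the interleaving bound `|ES| ≤ 2/N` for an
alternating half-universe set). FDR across the seven sets uses
Benjamini–Hochberg step-up via `stats::p.adjust`.

## The synthetic-data generator

The generator defines the study conditions for every test:

* **Geometry.** Left-hemisphere centroids are a Fibonacci lattice on a
  100 mm sphere — quasi-uniform, and exactly spherical so rotations are
  exact isometries of the frame. The right hemisphere is the mirror
  lattice and exists so the left-only restriction downstream is exercised,
  not assumed. The right hemisphere carries its own expression signal
  (hemispheric asymmetry); exact mirroring would create artificial exact
  ties between hemispheric profiles.
* **Expression.** A regions × genes signal (log2-intensity scale,
  mean 7, SD 1), optionally Gaussian-kernel-smoothed over centroids to
  inject spatial autocorrelation. Six donors scatter samples within 0.5 mm
  of randomly chosen centroids; exactly two donors also sample the right
  hemisphere. Each gene is read through `probes_per_gene` probes with a
  fixed per-probe offset and Gaussian noise; a planted 5 % of probes fail
  the background rule (below background ~70 % of the time) and a planted
  5 % carry no gene annotation.
* **Study.** The planted change map is
  `δ_r = effect_scale · Σ_g β_g z(signal)_rg` with β = ±1 on
  `n_causal_genes` genes (half positive). Pre-treatment GMV is a regional
  baseline (4000–4800 mm³) plus a subject offset (SD 200 mm³) plus a small
  TIV association (0.002 mm³/mm³ around a 1.5 × 10⁶ mm³ mean TIV) — there
  for the covariate to absorb; the post scan adds `δ_r` and noise
  (SD 30 mm³). Symptom improvement is a sparse linear readout of regional
  change (loading 0.05 on the ten largest-|δ| regions, signed to
  contribute positively) plus noise (SD 2).
* **Defaults as conditions.** 24 subjects, 180 left parcels, 6 donors with
  2 bilateral are the study conditions this package emulates. The free
  effect magnitudes were set once so that the default study is recovered
  with high power at n = 24 — the design target for the defaults — which
  led to concentrating the planted effect on 20 causal genes at
  `effect_scale = 3.5`: per-gene association strength scales as
  `1/sqrt(n_causal)`, and spreading the same map over many genes makes
  individual genes unrecoverable at realistic noise even when the map
  itself is recovered. Gene count (500) is a reduced-scale transcriptome;
  the processing chain is scale-free in the gene dimension.

What the generator does **not** emulate: measurement-level microarray
artifacts (batch, dye, spatial chip effects), donor-specific expression
differences beyond noise (every donor shares one regional signal),
realistic GMV covariance across regions (noise is independent across
parcels), integer-valued symptom scores, and medication or other treatment
confounds. Passing recovery tests therefore shows the estimators are
correct and well-calibrated under these conditions — not that real
microarray or MRI data meet them.

## Problem sizes and tolerances in the shipped tests

The test suite exercises: oracle equivalence of PLS weights at 1e-10 over
50 random problems; spin-test calibration with 500 replicates of 199
permutations over 180 parcels (exact binomial 95 % band around 0.05);
spin-versus-naive separation with 200 replicates on 40 mm-smoothed maps;
full default-scale recovery (change-map correlation > 0.8, causal-gene AUC
> 0.9, directional NES with q < 0.05 at 10,000 permutations); and a
byte-identity rerun of the full pipeline at reduced size (40 parcels, 60
genes). These sizes keep the whole suite under a minute while leaving each
check statistically meaningful; the acceptance script runs the
default-scale study at the full permutation counts (1000 spins, 1000
bootstraps, 10,000 GSEA permutations).

## Known limitations

* Single-component inference only; no cross-validated component selection.
* The spin relabeling permits duplicates; map values at duplicated parcels
  are reused, which can make the test mildly conservative or liberal
  depending on the map's autocorrelation.
* DS requires at least two donors with overlapping coverage; with one
  donor the package falls back to deterministic probe choice (smallest
  probe id) since stability is undefined.
* No right-hemisphere expression analysis (mirroring strategies are a
  non-goal); regions never sampled by any donor are dropped, not imputed.
* The clinical permutation test is honest but weak when regions far
  outnumber subjects (see above); interpret its p alongside the bootstrap
  region Z-scores.
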