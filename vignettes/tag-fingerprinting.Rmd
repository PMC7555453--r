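---
title: "TAG fingerprint chemometrics for meat authentication: models and design"
author: "tagprint"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{TAG fingerprint chemometrics for meat authentication}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tagprint)
```

## The problem

Replacing or diluting an expensive meat (beef, pork) with cheap chicken is a
common economically motivated adulteration. Ambient mass spectrometry of a
hexane extract gives, in seconds, a triacylglycerol (TAG) fingerprint: a set
of `[M+NH4]+` ion intensities in the m/z 800–1000 window. The three species
share most TAG ions but differ strongly and reproducibly in their *ratios* —
chicken fat is dominated by the ions at m/z 848.7682, 874.7837 and 900.7996,
pork by 850.7836, 876.7995 and 902.8148, beef by 850.7836, 876.7995 and
904.8306. `tagprint` implements the full screening workflow around this
signal: ion annotation, pretreatment, a supervised classification model with
its validation apparatus, a formal "suspicious sample" boundary, and the
companion PCR-call label-compliance logic used to confirm suspects.

## Ion annotation

A curated library of 15 characteristic TAG ions (`markerLibrary()`) stores,
per compound, the TAG shorthand (e.g. `C 52:3` = 52 acyl carbons, 3 double
bonds), the composite ammonium-adduct elemental formula, and the curated
annotated m/z. Theoretical m/z values are computed from hard-coded
most-abundant-isotope atomic masses (one constants file, >= 7 decimals), with
one electron mass subtracted per positive charge; the electron correction is
configurable because instrument software conventions differ.

Matching (`annotatePeaks()`) assigns each library compound to the nearest
centroid within a ppm tolerance whose intensity clears a cps threshold, each
peak being used at most once (globally nearest-ppm first; exact ties go to
the lower-m/z entry). Defaults: 5 ppm and 1000 cps. The 5 ppm default covers
the largest curated mass error (4.8 ppm) with margin; the 1000 cps threshold
is the detection floor that defines the ~40 observable TAG ions in a typical
fingerprint.

One numerical subtlety drives a design choice: the curated annotated m/z of
TAG `C 52:0` lies about 9 ppm below the value computed from its elemental
formula, while the other 14 annotations sit within 5 ppm of theory. Matching
therefore uses the *annotated* m/z as the canonical reference (falling back
to theory when no annotation exists): the curated values carry the
calibration of the instrument they were read from, and peaks acquired on
that calibration must not be orphaned by a theory offset. The theoretical
m/z is kept alongside for mass-error diagnostics.

## Pretreatment

Two steps, in enforced order (`raw -> normalized -> pareto`):

1. **Constant row-sum normalization** (`rowSumNormalize()`): each sample's
   ion intensities are divided by their total. DART-type sources have no
   internal standard and a strongly varying global signal level;
   normalization removes exactly that nuisance scale, which is why the
   generator's per-sample scale factor (below) must not affect any
   downstream statistic.
2. **Pareto scaling** (`paretoScale()`): each ion is centered and divided by
   the square root of its (n−1) standard deviation — intermediate between no
   scaling and unit variance, damping the dominance of high-intensity ions
   without amplifying noise ions to full weight. Constant ions map to zeros
   rather than erroring (an absent ion in a single-class subset is
   legitimate). The centers and divisors are stored so unknowns are
   projected with *training* parameters (`applyPretreatment()`), and
   cross-validation re-derives them inside each training fold — the row-sum
   step is per-sample and leaks nothing.

By default the statistical matrix is restricted to the 15 curated markers
(the selected-ion table that the workflow's statistics are defined on);
`buildFeatureMatrix(ionSubset=)` can widen this to the full panel.

## PCA and PLS-DA

`fitPca()` is an SVD of the scaled matrix with a deterministic sign
convention (largest-magnitude loading element positive). `fitPlsda()` is a
NIPALS PLS2 regression of the scaled matrix on class indicator columns, with
deflation, reporting cumulative explained variance R2X (X block) and R2Y
(dummy block). The default number of components is `max(classes − 1, 2)`.
Classification is by argmax of the predicted dummy responses; exact ties
resolve to the first class in sorted order with margin 0.

Model quality follows the conventional apparatus:

* **Q2** (`q2Cv()`): `1 − PRESS/SS` under seeded, stratified 7-fold
  cross-validation with in-fold re-scaling. `k = n` reduces exactly to
  leave-one-out (verified against a brute-force loop in the tests). A model
  is conventionally acceptable when Q2 > 0.5, and Q2 must not exceed R2Y.
  The CV policy is deliberately strict and fully specified (proprietary
  chemometrics suites leave their internal CV unstated): stratified folds,
  per-fold Pareto re-derivation, a single integer seed controlling the
  split.
* **Recognition / prediction ability**: percent correct on the training
  samples, and pooled percent correct over the held-out folds.
* **Permutation test** (`permutationTest()`): Q2 recomputed under `nPerm`
  seeded label permutations; empirical p-value
  `(1 + #{permuted Q2 >= observed}) / (nPerm + 1)`. We report this empirical
  p rather than an R2/Q2-intercept plot; the permuted R2Y values are
  returned for anyone who wants the regression diagnostic.
* **VIP** (`vipScores()`): per-ion importance with the algebraic identity
  `mean(VIP^2) = 1`; VIP > 1 is the conventional marker-selection cut.
* **S-plot** (`sPlot()`): per-ion covariance and correlation with the first
  latent score; the most remote ions (largest combined rank of |p1| and
  |p(corr)1|, default top 4) are flagged as candidate markers.
  `variableLinePlot()` exports the per-class normalized intensity series
  that confirm a marker's direction.

## Screening unknowns

The reference workflow draws a boundary around the authentic cluster in
score space and sends everything beyond it to confirmatory PCR.
`screenSamples()` formalizes that boundary reproducibly: a product declared
as class *c* is **suspicious** if (a) its Hotelling T² distance to class
*c*'s training scores exceeds the F critical value at `alpha` (0.05 default,
new-observation form), or (b) its predicted class differs from the declared
one, or (c) its classification margin is below `marginMin` (0 by default,
i.e. disabled). Verdicts are deterministic. This is a statistical
formalization of a boundary that is, in practice, drawn with the benefit of
PCR ground truth — it is a design choice of this package, not a reproduction
of any particular hand-drawn line.

## The synthetic generator

No raw spectra are published for this kind of screening study, so the
package ships a generator (`defaultProfiles()`, `generatePure()`,
`generateProduct()`) whose defaults *are* the study conditions the package
is tested under:

* a 40-ion panel: the 15 markers plus 25 filler TAGs (even-carbon species
  from C 48 to C 58 not on the marker list, all inside m/z 800–1000);
* per-species mean profiles chosen once to respect every qualitative
  dominance statement above: each species' three dominant ions are its
  intensity top-3, every panel ion exceeds the 1000 cps floor in every
  species, non-dominant markers sit at 5–40% of the dominant scale, and the
  chicken-vs-pork contrast is carried most strongly by the printed marker
  ions (874.7837 and 848.7682 on the chicken side, 876.7995 on the pork
  side), so the S-plot extremes reproduce the expected marker structure;
* multiplicative noise: per-ion lognormal with sigma `log(1 + cv)`
  (cv = 0.15) times a shared per-sample lognormal scale factor
  (sigma = 0.3) emulating shot-to-shot DART variability, both mean-1; m/z
  jitter of 1 ppm;
* blends are exact convex combinations of the species profiles at the mean
  level, with an optional low background placed far (>> 20 ppm) off the
  marker grid — hexane extraction discriminates against polar ingredient
  signals, and the background knob exists to test robustness, not to model
  a matrix;
* acquisition sequences (`buildSequence()`): seeded random run order, a
  pooled-QC injection (arithmetic mean spectrum) leading the run and after
  every 10 test samples, blanks at both ends.

**Sensitivity anchor.** The strongest species-specific marker of chicken
(TAG C 52:3) and beef (TAG C 54:2) is not hand-set: its mean is the analytic
solution of the detection model. Writing `s² = log(1+cv)² + scaleSigma²`,
the anchor mean is `threshold/f × exp(s²/2 + z(0.975) × s)` with
`f = 0.03` — the mean intensity at which a 3% admixture's contribution to
that ion clears the 1000 cps floor with 97.5% per-replicate probability.
`detectionLimit()` then declares a fraction detectable when ≥ 95% of
replicates clear the floor; the anchor is placed at the 97.5% point rather
than 95% so that a finite-replicate estimate of the limit concentrates on
the 3% anchor instead of flipping between adjacent grid points on binomial
noise. With defaults, the estimated chicken-in-pork detection limit is 3%.
Detection is evaluated on the generator's exact per-species component
decomposition (the spike's share of each ion, carrying the same noise
realization as the blend) — in a real spectrum this contribution is not
observable, which is precisely why the limit is a property of the
calibrated generator, not a measurement.

**What the generator does not emulate:** isotope envelopes, TAG positional
isomers (the panel works at summary-formula level), in-source fragments,
ionization suppression beyond the global scale factor, time drift within a
sequence, and real biological variation between animals, breeds and feeding
regimes. Passing tests on synthetic data therefore demonstrate the
correctness and internal consistency of the statistical machinery under the
declared noise model — not field performance on retail samples.

## PCR compliance logic

`parseSpeciesCalls()` merges declared compositions with endpoint
mitochondrial multiplex (mPCR) and real-time genomic multiplex (mqPCR)
calls; `checkCompliance()` takes the gDNA calls as authoritative — white
adipose tissue is mitochondria-poor, so fat-rich processed products (canned
luncheon meat in particular) produce mitochondrial false negatives — and
flags any mPCR/mqPCR disagreement as a discrepancy. Chicken and turkey are
one call category in the mitochondrial panel, so declared poultry is
satisfied by the combined call. Declared percentages are carried but not
enforced: the assays are qualitative. On the packaged 27-product
transcription, all 27 products are label-compliant on the gDNA basis and
exactly five (four luncheon meats and one meat in natural juices) are
mtDNA/gDNA-discrepant.

## Problem sizes, tolerances and reproducibility

The shipped tests and the acceptance script run the models at 10 samples
per species (30 training samples for the three-class model, 25 for the
two-class model), 7-fold cross-validation, 99-permutation tests, and
200 replicates per fraction for the detection-limit grid (1–10% in 1%
steps) — sizes at which every fingerprint statistic in this workflow is
stable and a full run takes well under a minute. NIPALS iterates to a
relative tolerance of 1e-12 (cap 500 iterations); component extraction
stops early, with a warning, at rank exhaustion. Every stochastic stage
(generation, fold splits, permutations, run order) takes an explicit
integer seed, and equal seeds give bit-identical results; the RNG state of
the calling session is never disturbed.

## Known limitations

* The suspicious-sample boundary (T² at `alpha` plus class-mismatch and
  margin rules) is this package's formalization; tuning `alpha` trades
  false suspects against missed adulteration and should be validated on
  real products.
* The `C 52:0` annotated m/z is ~9 ppm from its formula's theoretical
  value; the library treats curated annotations as canonical (see above),
  and mass-error diagnostics for that ion should be read against the
  annotation, not theory.
* Quantitative admixture estimation is out of scope: the workflow is a
  qualitative screen, and the detection limit is an anchored property of
  the synthetic model.
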