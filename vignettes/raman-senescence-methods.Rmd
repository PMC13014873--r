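---
title: "Models and methods behind ramansen"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind ramansen}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`ramansen` analyses Raman spectra of senescing deciduous leaf tissue
across six visual classes (HOL, MinSOL-H, ModSOL-H, MinSOL, ModSOL,
SOL). This vignette is the package's account of its science: the model
behind the synthetic-data generator, the parameters that matter, the
numerical choices, and the limits of what a green test run establishes.

## The synthetic stated world

Instrument spectra for this problem are not publicly deposited, so the
package carries a generator whose *defaults are a stated world*: a fixed
set of conditions that downstream analyses are tested against, not a
dial to be tuned per experiment.

A simulated spectrum on the 690–1655 cm⁻¹ grid (default step 1 cm⁻¹) is

$$I(\nu) = \frac{s}{Z}\Big(\sum_k a_k m_k L(\nu; c_k, w_k) + b(\nu)\Big)
          + \varepsilon(\nu) + \text{spikes}(\nu)$$

* **Peaks.** $L$ is a peak-height-normalised Lorentzian — the generic
  solid-state Raman line shape; the originating study never states a
  shape, so Lorentzian with default FWHM $w_k = 12$ cm⁻¹ was fixed once.
  Centres $c_k$ are the assignment-table bands of common leaf
  biomolecules (carotenoids 1003/1157/1525, celluloses 898/907/1462/1481,
  chlorophyll-a 700/1147/1226/1328, lignin 917/1606, pectins 744/854,
  xylan 1128, α-D-glucose 1272, aliphatics/α-amyrin 1288–1456, …). The
  crowded CH₂ scissoring cluster (1451–1494 cm⁻¹) uses FWHM 8 cm⁻¹ so the
  amorphous/crystalline cellulose doublet at 1462/1481 cm⁻¹ stays
  resolved; without that the crystallinity index of any template is
  squeezed towards 0.5 by band overlap.
* **Class multipliers** $m_k$ encode the qualitative trends the study
  reports rather than its printed means (which depend on undeposited
  data): carotenoid and chlorophyll bands decay towards SOL;
  907/1020/1128/1272 cm⁻¹ grow towards SOL; 854 cm⁻¹ rises to ModSOL and
  then falls; and the 1481:1462 amplitude ratio rises monotonically so
  the crystallinity index runs 0.170 → 0.594 (the SOL value matches the
  printed 0.594). The three visually green classes are given small
  (≈5–10 %) multiplier differences: they are distinct tissue, and
  without any shape difference their separability would rest entirely on
  intensity.
* **Fluorescence scale** $s$: chlorophyll-a retains residual fluorescence
  under 830 nm excitation, so healthier tissue is globally brighter. $s$
  is drawn per spectrum as the target spectrum *maximum* (a.u.):
  HOL 3375.18 ± 541.57, MinSOL-H 5317.59 ± 542.38, ModSOL-H
  4239.02 ± 718.79 (the printed class maxima); MinSOL 3571.92 ± 551.66
  and ModSOL 1341.41 ± 518.55 (the printed intensity statistics of the
  clusters those classes dominate); SOL is a two-component mixture,
  9942.69 ± 2224.98 and 14493.02 ± 2345.05 with weights 0.52/0.48 — the
  study's two senesced k-means clusters. This *bimodal SOL intensity
  mode* is what makes SOL split across clusters in PCA + k-means. Draws
  are floored at 2 % of the component mean to keep intensities physical;
  the Gaussian left tail still produces the occasional SOL spectrum at
  healthy-class brightness (≈ 2nd percentile near 4000 a.u.), which is
  the single genuinely hard SOL case the SOM occasionally misroutes.
  $Z$ normalises the clean template to unit maximum so that the spectrum
  maximum equals the draw.
* **Baseline** $b$: a low-order polynomial in $u = (\nu-690)/965$
  (default $0.12 + 0.10u - 0.06u^2$, relative to the peak sum) scaled by
  the same fluorescence draw — the background and the global intensity
  have the same physical source.
* **Noise and spikes**: additive Gaussian noise (default SD 20 a.u.,
  a realistic floor for 50 s total integration) and cosmic rays as
  single-grid-point deltas of 5–20 × the local signal with
  Poisson(0.3) count per spectrum.
* **Structure**: `n_per_class` (default 100) spectra per class, grouped
  into maps of `acquisitions_per_map` (default 10) — 10 maps × 10
  acquisitions; the map count is exposed because only the product is
  documented in the originating study.

Absorbance at 600 nm follows $A(t) = 1.67\,e^{-bt}$ over stage index
$t \in \{0,1,2,3\}$ for HOL/MinSOL/ModSOL/SOL with $b$ fixed by the SOL
endpoint 0.298 a.u.; the green subclasses sit at $t = 1/3, 2/3$.
Replicate noise is 2.5 % of the mean, the relative dispersion of both
printed endpoints. RGB patches use class mean triples (green-dominant
healthy tissue, all-channels-raised yellowing ModSOL, red-above-green
browned SOL, Gaussian pixel noise SD 12); the exact channel means are
not printed anywhere, so they were chosen once as plausible values and
only their *orderings* are asserted.

**What the generator does not emulate:** instrument wavenumber
calibration error, detector etaloning, water/fluorescence photobleaching
drift within a map, spatial correlation between acquisitions of one map,
peak-position shifts between classes, and any real catabolite bands. A
green recovery test therefore establishes that the pipeline recovers the
structure *this model* plants — not that it would reproduce the printed
accuracies on the undeposited instrument data.

## Preprocessing

* **Cosmic-ray removal**: a local maximum whose full width above half
  its local prominence spans ≤ `max_feature_width` grid points (default
  2) is replaced by linear interpolation across its footprint. Genuine
  bands (FWHM ≥ 8 cm⁻¹ on a 1 cm⁻¹ grid) are far wider than the
  threshold and pass through bit-identically.
* **Baseline**: an order-11 polynomial (orthogonal basis, for
  conditioning at high order) fitted by iteratively excluding points
  more than 1.5 × residual SD *above* the current fit. Exclusion is
  one-sided because Raman bands are positive — the ModPoly family
  convention. Whether the published "noise tolerance" multiplies a
  residual SD is not documented; the SD-multiplier reading is the
  default and the knob is exposed. Iteration stops when the excluded set
  is stable, when the fit interpolates to numerical precision, or at
  `max_iterations` (100); hitting the cap flags (not fails) the result.
  Applying the correction twice changes the result by < 1 % RMS.
* **Peak lookup**: every named wavenumber resolves to the nearest grid
  point, ties toward the lower wavenumber, everywhere in the package.
* **Normalisation** at 1003 cm⁻¹ is used for fingerprint comparison and
  region areas (matching how the fingerprint figures are presented);
  classification deliberately uses baseline-subtracted,
  *non-normalised* spectra because the between-class intensity scale is
  itself discriminative. Region areas on normalised spectra are the
  default, with the raw option a flag away, since the normalisation
  state of the printed areas is not recorded.

## Analytics choices

* **Relative region area** divides by the full 690–1655 cm⁻¹ Simpson
  area. "Relative" is not defined in the source; this denominator was
  chosen because the four printed per-class fractions each sum to < 1.
* **R²** of exponential trend fits is computed on the original scale
  (1 − SS_res/SS_tot after back-transforming), not the log scale; the
  source does not say which it used.
* **Box-and-whisker** summaries use median/quartiles/1.5 IQR whiskers.
* Simpson integration handles an even point count with a trapezoid on
  the final interval; it is exact for cubics on a uniform grid.

## Statistics

Kruskal–Wallis uses the tie-corrected H with a χ² reference on k − 1
degrees of freedom; complete ties return H = 0, p = 1. Dunn's z
statistics use pooled mean ranks with the tie-corrected variance.
Bonferroni is the default multiplicity adjustment (the usual pairing
with Dunn's test); the source's adjustment is unstated and its printed
p-values look unadjusted, so `none` is selectable. Labels follow
ns > 0.05, * < 0.05, ** < 0.01, *** < 0.005.

## SOM and SOMDI

Training is classic online Kohonen learning: winner-take-all with a
Gaussian neighbourhood on a hexagonal grid, learning rate 0.5 → 0.01 and
radius half-the-grid-diagonal → 1, both decaying linearly over
`rlen` epochs (default 20). Neurons take the majority class of the
training samples they win; neurons that win nothing inherit the nearest
labelled neuron's class so the map is class-covered, and evaluation
additionally reroutes samples whose winner is unlabelled.

The discriminant index has no published formula, so the package defines
its SOMDI contract: scale each labelled neuron's weight vector to unit
Euclidean norm, take the per-class mean minus the overall labelled mean,
clip negatives to zero, and rank features by the result. Unit-norming
makes the profile invariant to global intensity scaling even though
training is not.

`split_and_cv()` reports, per repeated run, a stratified 80/20 split,
k-fold cross-validation on the training portion (training accuracy =
mean fold accuracy), a final model evaluated on the held-out 20 %
(testing accuracy), and the unweighted mean of the two as the overall
model accuracy — the convention in which training 95.51 % and testing
88.50 % summarise to 92.01 %. Map size and epochs are model-selection
parameters: the method they re-implement prescribes adjusting neurons
and iterations "until separation", and the recovery suite fixes
10 × 10 / 25 epochs for the default six-class world on that basis.

## Comparator classifiers

Features are the 20 peaks-of-interest intensities, autoscaled before
PLS-DA and PCA (the upstream tool's scaling is undocumented; autoscaling
is its default behaviour). PLS-DA is NIPALS PLS2 against one-hot labels;
Q² = 1 − PRESS/TSS with stratified 5-fold folds;
VIP²s average to 1 exactly by construction. k-means uses k-means++
initialisation and Lloyd iterations on (PC1, PC2) with the objective
recorded per step. The random forest grows Gini CART trees to purity
with mtry = 7 (the documented "7 predictors", not √p); importance is
mean decrease in OOB accuracy under per-feature permutation; proximity
is the co-terminal-leaf fraction; the outlier score is
$n / \sum_{j \in \text{class}(i)} \text{prox}(i,j)^2$, median/MAD
normalised within class with a mean-absolute-deviation fallback when a
cleanly separated class has MAD exactly 0.

## Catabolite line lists

Line lists are consumed as JSON (mode, wavenumber, Raman activity in
Å⁴/AMU); the quantum-chemistry stage that produces them is out of scope.
Filtering is range → five highest activities → discard < 30 a.u., in
that order. Rendering assigns each line a *unit-area* profile times its
activity, so total activity is conserved to < 1 % for in-range lines; no
frequency scaling is applied by default (`scale_factor = 1`) because the
source applies none, with the knob available for standard hybrid-DFT
scaling experiments. The packaged filtered-peak table transcribes 44
rows (29 early, 6 mid, 9 late); the published tally implies one
additional mid-stage row missing from the available transcription, and
the table carries both the superscript stage and a refined stage (the
C-E ring derivative is quasi-mid). Band grouping is single-linkage with
a 2 cm⁻¹ collision tolerance; "spatially unique" is an annotation
carried from upstream force-vector analysis, not recomputed.

## Known limitations

* Printed headline accuracies (SOM testing 88.50 %, RF OOB 7.75 %,
  exact region-area and ratio means) are not reproducible without the
  undeposited spectra; the package targets their qualitative structure.
* RGB patches are homogeneous colour fields, not leaf images.
* The random forest is a faithful but compact implementation (no class
  weights, no case-weighted sampling).
* Images are written as plain-text PPM rather than PNG: the analysis
  environment carries no PNG encoder, and PPM keeps fixtures
  text-only. The in-memory contract (integer h × w × 3 in [0, 255]) is
  unchanged.
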