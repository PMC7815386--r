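---
title: "FT-NIR chemometrics for herbal quality assessment: models, choices, and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{FT-NIR chemometrics for herbal quality assessment}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`nirchemo` implements the chemometric workflow that underpins rapid FT-NIR
quality assessment of powdered herbal materials such as Angelicae Sinensis
Radix (ASR, danggui): a *qualitative* arm that classifies geographic origin
with a grid-searched RBF-kernel support vector machine, and a *quantitative*
arm that calibrates partial least squares regressions of marker-metabolite
content (ferulic acid, Z-ligustilide, mg/g) on the spectra, sharpened by
synergy-interval variable selection. This vignette explains the models, the
defaults, and what the synthetic validation data can and cannot show.

## The measurement model and its synthetic emulation

Over 10,000-4,000 cm^-1^ a diffuse-reflectance NIR absorbance spectrum of a
powder is, to first order, a Beer-Lambert mixture distorted by scatter:

$$ x_i(\nu) \;=\; g_i \Big( \textstyle\sum_a c_{ia} S_a(\nu) + B_{k(i)}(\nu) \Big) + b_i(\nu) + \varepsilon_i(\nu), $$

with analyte concentrations $c_{ia}$, unit-concentration analyte spectra
$S_a$, a class-dependent matrix background $B_k$, a per-scan multiplicative
gain $g_i$ (particle size, packing), a smooth additive baseline $b_i$, and
white noise $\varepsilon_i$. `generate_nir_dataset()` simulates exactly this
model. Because the experimental spectra behind the workflow are not publicly
deposited, the simulator is the package's ground-truth instrument; it is
first-class, tested code, not a throwaway fixture.

Generator defaults (all overridable via `synth_config()`):

* **Design**: 99 samples — Gansu 54, Yunnan 25, Qinghai 20 — scanned in
  triplicate; replicate scans share the truth and differ only in gain,
  baseline and noise. Triplicates are averaged with `average_replicates()`
  before modelling.
* **Grid**: 1557 points from 10,000 to 4,000 cm^-1^ (spacing ~3.8560 cm^-1^,
  the point density of an 8 cm^-1^-resolution FT instrument). With 20
  equidistant intervals this grid puts interval 16 at 5488.4-5191.5 cm^-1^
  and makes intervals 18-20 one point narrower than 1-17, the structure the
  interval-selection arm reports.
* **Concentrations**: per-class uniform ranges whose union spans
  0.4730-2.7307 mg/g (ferulic acid) and 2.2710-19.6627 mg/g (Z-ligustilide);
  classes differ in mean (Gansu highest), so the same dataset exercises both
  the classifier and the regressors.
* **Bands**: Gaussian background bands at the common ASR absorption
  positions (8350, 6961, 6736, 6323, 5917, 5788, 5712, 4813, 4313 cm^-1^),
  modulated a few percent per class; ferulic-acid bands at 5340 and
  4440 cm^-1^ (intervals 16 and 19 of 20), Z-ligustilide bands at 5250, 4520
  and 4150 cm^-1^ (intervals 16, 19 and 20). Published per-band intensities
  do not exist, so amplitudes are free parameters scaled to contribute
  ~0.1-0.2 AU at the top of each concentration range — chosen once, as
  plausible for minor constituents over a strong matrix.
* **Artefacts**: gain ~ Uniform(0.9, 1.1); linear baseline with coefficients
  ~ Uniform(-0.03, 0.03) AU; noise sd 0.002 AU — the artefact classes that
  MSC/SNV and derivatives exist to remove, at magnitudes typical of a
  bench FT-NIR instrument.

What the simulation does **not** contain: nonlinear radiative-transfer
effects, instrument line-shape and wavelength-axis drift, temperature and
moisture effects, and analyte-matrix band overlap beyond simple Gaussian
superposition. Consequently the synthetic task is *easier* than the real
one — pretreated synthetic models reach R^2^~0.999 where real ASR models
reach ~0.9 — and passing the recovery tests demonstrates correctness of the
algorithms and sane behaviour of the pipeline, not field performance.

## Pretreatments

Eight standard pretreatments are provided as `+`-joined tokens
(`raw`, `msc`, `snv`, `1d`, `2d`, `msc+1d`, `msc+2d`, `snv+1d`, `snv+2d`),
applied in the order the name reads (scatter correction before derivative).
Design choices:

* **MSC reference** = mean calibration spectrum; prediction spectra are
  corrected against the *calibration* reference (`apply_pretreatment()`
  enforces the fit/apply split, so nothing leaks from prediction spectra).
* **Savitzky-Golay** derivatives default to an 11-point window; the
  polynomial order is not fixed by convention everywhere, so the common
  chemometrics default of 2 is used and exposed. Edge points come from the
  boundary polynomial fits rather than truncation, keeping the matrix width
  constant. Derivatives are taken with respect to the variable *index*: on
  a uniform grid this is the analytic derivative up to a constant factor
  (and a sign, given the descending axis), which centred models absorb.
* The instrument-software "ordinate normalization" step is available as
  optional per-spectrum min-max scaling (`normalize = TRUE`), off by
  default since its exact definition is vendor-specific.

## Calibration-set selection

`spxy_split()` implements SPXY: pairwise Euclidean distances in X and
absolute differences in y, each normalized by its maximum and summed;
selection seeds with the most distant pair and grows by max-min distance.
Although such partitioning is sometimes described loosely as "random", the
algorithm is deterministic; the package keeps it deterministic (ties broken
toward the lowest index) and offers `random_split()` separately for
ablation. For the classification arm y is categorical and SPXY's y-distance
is undefined, so a stratified X-only Kennard-Stone split is used
(`stratified_split()`, largest-remainder quotas: 54/25/20 at a 2:1 ratio
gives 36/17/13), keeping every origin in both sets. The 2:1 ratio on 99
samples yields the 66/33 design all defaults assume.

## Origin classification

The classifier is a C-SVC with RBF kernel
$k(x,z) = \exp(-g\,\lVert x-z\rVert^2)$ on the full pretreated spectrum (no
feature compression — pretreatment choice is the feature engineering). The
quadratic-programming solver is libsvm via `e1071`, treated as an external
contract; everything around it — the log2 candidate grid
($\log_2 C \in [-5,20]$, $\log_2 g \in [-20,-5]$, step 0.5, hence 1581
candidates including $C = 2^{5.5} = 45.2548$ and $g = 2^{-11} = 0.00048828$),
seeded stratified 10-fold cross-validation with one fold assignment shared
by all candidates, pooled-percent scoring, and the smaller-C-then-smaller-g
tie-break — is implemented here. Internal libsvm feature scaling is
disabled so the pretreatment alone defines the representation.

## Quantification

`pls_nipals()` is PLS1 by NIPALS with mean-centring only (no unit-variance
scaling of wavenumber channels, the standard NIR practice): weights
proportional to $X^\top y$, score/loading extraction, rank-one deflation,
and coefficients assembled for every truncation so one fit serves all
latent-variable counts. The latent-variable count is selected by 7-fold
cross-validated RMSE (`pls_select_lv()`, cap 15, ties to the smaller
count); folds are y-stratified (consecutive response-rank blocks spread
over folds, seeded) so every fold covers the concentration range.

Figures of merit (`pls_evaluate()`):

* $R^2_C = 1 - SSE_{cal}/SST_{cal}$ and $R^2_P = 1 - SSE_{pred}/SST_{pred}$,
  each SST about its own set mean. A squared-Pearson variant is available
  (`r2_method = "cor"`) since some software reports that instead.
* $RMSEE = \sqrt{SSE_{cal}/(n_{cal}-1-A)}$ — the degrees-of-freedom
  convention of multivariate-calibration software; $RMSEP =
  \sqrt{SSE_{pred}/n_{pred}}$.
* $RPD = s_{all}/RMSEP$ with $s_{all}$ the SD of the reference values of
  the **whole** sample set. This denominator choice is deliberate: it is
  the only convention under which a total-set SD, divided by each tabulated
  RMSEP of the workflow's reference results, reproduces every tabulated
  RPD to ~1e-4 (the test suite carries this identity). RPD > 2 is read, as
  is conventional, as a usable quantitative model.

## Synergy-interval PLS

`sipls_search()` tiles the pretreated axis into 20 equidistant intervals
(remainder points to the leading, high-wavenumber intervals), evaluates a
PLS model on **every** k-interval union, and ranks combinations by
cross-validated RMSE on the calibration set only — "minimum prediction
error by cross-validation" is deliberately read as internal CV, never the
held-out prediction set, to avoid selection leakage. Defaults: 5 CV
segments, LV cap 15 per combination (never above the subset's width),
combination sizes k ∈ {2, 3, 4}. Classical descriptions pair intervals two
at a time, but reported optima in this workflow's reference results have 3
and 4 intervals, so the default evaluates all three sizes; ties break
toward fewer intervals, then the lexicographically smallest tuple.
`sipls_refit()` refits the winner and reports the interval wavenumber
bounds alongside the full metric set.

## Reference-method arithmetic

`fit_calibration_curve()`, `quantify_content()`, `rsd()` and `recovery()`
cover the external-standard HPLC bookkeeping: OLS area-vs-concentration
curves, inversion to mg/g at the 0.2 g / 20 mL extraction scale, relative
standard deviations for precision/repeatability/stability, and spike
recovery at the customary 50/100/150% levels. Chromatogram processing
itself is out of scope.

## Reproducibility and problem sizes

Every stochastic step (generator, fold construction, random split) takes an
explicit seed, and `run_nir_pipeline()` fans one global seed out to
per-stage seeds by fixed offsets so stages are individually reproducible;
rerunning with the same configuration reproduces the output tables
byte-for-byte. The test suite exercises the full 99-sample, 1557-point
design for the recovery checks (PLS accuracy, classifier separation, siPLS
interval recovery over five generator seeds with pairwise combinations) and
reduced designs (26 samples, 220 points; coarser SVM grids) elsewhere, a
balance between coverage and a test run that completes in about a minute;
the full 1581-candidate grid search is exercised through its grid
construction and reduced-grid searches, and runs in full via
`run_nir_pipeline()` defaults when wanted.

## Known limitations

* The simulator's scatter model (global gain + linear baseline) is exactly
  what MSC assumes, so MSC-based pretreatments look better on synthetic
  data than they may on real spectra with wavelength-dependent scatter.
* PLS1 only — one response per model; no PLS2, kernel PLS, or uncertainty
  intervals.
* siPLS cost grows as $\sum_k \binom{20}{k}$; k ∈ {2,3,4} (6175
  combinations) is practical, larger k or finer tilings are not attempted.
* The RBF-SVM arm exposes no probability calibration and no alternative
  kernels beyond libsvm's pass-through.
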