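---
title: "Serum metabolic fingerprint diagnostics: models, assumptions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Serum metabolic fingerprint diagnostics: models, assumptions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# Scope

`smfdx` is a desk-scale workbench for a serum-metabolomics diagnostic
pipeline built on nanoparticle-assisted laser desorption/ionization mass
spectrometry (NPLDI-MS). One microliter of native serum yields a low-mass
(100–1000 Da) spectrum whose peaks — largely Na+/K+ adducts of circulating
metabolites — form a *serum metabolic fingerprint* (SMF). The package
implements the complete in-silico half of such a study:

1. a seeded synthetic-cohort generator (raw spectra plus clinical
   metadata) standing in for patient data, with known ground truth;
2. spectrum preprocessing: Gaussian smoothing, fixed-width m/z binning,
   morphological white top-hat baseline removal, local-maxima peak
   detection, and assembly of an aligned feature matrix;
3. residual fully-connected neural classifiers: Met-NN (fingerprints
   only) and MP-NN (fingerprints fused with the CEA protein tumor marker);
4. the published Mayo Clinic and Veterans Affairs nodule-malignancy
   logistic equations, and the clinical 5 ng/mL CEA cutoff;
5. MPI-RF: a grid-searched, cross-validated random-forest late fusion of
   the MP-NN score with an image-AI malignancy score;
6. an evaluation suite: ROC/AUC with DeLong variance machinery, Youden
   operating points, detection rates at fixed specificity, permutation
   overfitting tests, Hanley–McNeil AUC power analysis, and secondary
   tests (Wilcoxon, chi-square and trend, Hosmer–Lemeshow, Pearson).

Because no public cohort accompanies this assay family, all end-to-end
claims in this package are statements about the *synthetic* world; what a
green test does and does not establish is discussed at the end.

# The synthetic world

## Spectra

Each cohort shares one planted peak panel: `n_peaks` (default 300) base
m/z positions drawn with a minimum spacing of max(1.2 Da, 6 sigma) over
the configured range, each rendered as a Gaussian bump of width
`peak_sigma` plus Na+ and K+ adduct copies at +21.9819 and +37.9559 Da at
fixed relative intensities (0.5, 0.3). Peak apex heights are log2-normal
across the panel (meanlog2 8, sdlog2 1.2 — apexes of roughly 50–6,500
counts) with per-subject log2 noise of sd 1.0. The baseline is a smooth
exponential decay (amplitude 200 counts, length scale 150 Da) and the
additive noise is Gaussian (sd 5 counts), truncated at zero. The raw grid
is uniform in m/z with ~125,000 points by default; real TOF grids are
uniform in time — a documented simplification, as is the absence of
isotope envelopes and matrix cluster ions.

Disease signal: `n_discriminative` peaks (default 40) carry a log2
fold-change in LUAD whose magnitude is drawn around `effect_size`
(default 1.0), with half the peaks elevated and half depressed, scaled by
stage as `1 + 0.15 * stage_index`. This stage law qualitatively reproduces
the usual score-by-stage trend in serum diagnostics; it is a modelling
choice, not an inference about any particular dataset.

## Clinical covariates

CEA is log-normal per class; the defaults (controls around 1.8–2.0 ng/mL
with sdlog ~0.6; LUAD meanlog log 2.6, sdlog 0.8) give roughly 20%
sensitivity at the clinical 5 ng/mL cutoff at ~96% specificity —
deliberately matching the familiar clinical picture of CEA as a specific
but insensitive marker. The image-AI malignancy score is Beta(8,3) for
malignant and Beta(3,8) for benign nodules, conditionally independent of
the metabolic signal given the label, so that late fusion has something
to gain. All LBD subjects carry benign nodules, all LUAD subjects
malignant ones, and healthy controls none; diameters, age, smoking,
spiculation and lobe location are drawn with realistic class separation
so the Mayo/VA equations behave like weak-but-real baselines.

A `covariate_signal = FALSE` switch (used by `null_cohort_config()`)
makes every covariate distribution class-identical. This matters for
null-calibration testing: "zero effect size" must silence *all* channels,
including the clinical equations, or chance-level behavior cannot be
expected of them.

## Desk scale versus full scale

Full-scale defaults (125,000-point grids, 0.08 Da peaks, 0.05 Da bins,
6×1024 networks, 1000 epochs) are faithful to the instrument-scale
setting but too slow for multi-seed test loops. The desk-scale
counterparts (`desk_cohort_config()`, `desk_preprocess_config()`, the
`run_config()` defaults) state a coarser world once: 5,000-point grids,
0.4 Da peaks, 0.2 Da bins, a 51-bin (~10 Da) top-hat element, 2×64
networks with dropout 0.2, learning rate 1e-3 and tens of epochs, and a
reduced fusion grid. Multi-seed acceptance tests run at desk scale; the
parameter-recovery test runs at full scale.

# Preprocessing choices

* **Binning aggregates by maximum** (not sum): the feature value is meant
  to be a peak apex height, and a max survives later baseline subtraction
  coherently. Sum aggregation is exposed as an option.
* **Smoothing sigma is in raw-grid index units**, following the
  convention of the standard 1-D Gaussian filter implementations; the
  kernel is truncated at radius 4 sigma and renormalized, with reflect
  boundaries.
* **The top-hat element** defaults to 201 bins (~10 Da at 0.05 Da bins):
  wider than any metabolite peak, narrower than baseline undulation. The
  white top-hat (signal minus its opening) removes any structure wider
  than the element and passes narrower structure unchanged; it is exact,
  idempotent on its own output, and is tested against a brute-force
  sliding-min/max oracle.
* **Peak acceptance** requires a strict local maximum over ±`peak_window`
  bins (ties resolve to the lower index) *and* a height above
  `snr_threshold` (default 3) times the MAD of the corrected spectrum
  scaled to an SD. The MAD is a robust noise scale because peaks occupy a
  tiny fraction of the bins.
* **Features** are bins hosting a detected peak in at least
  `feature_prevalence` (default 5%) of samples; absent peaks contribute
  zeros. TIC normalization divides each sample by its total corrected ion
  count and rescales by the cohort median TIC. In the pipeline driver,
  feature selection and the TIC reference are computed on the training
  split only and then frozen, to keep the blind test blind.
* Bin coordinates are half-open intervals anchored at 100.0 Da; bin count
  is `ceiling(span/width)`, e.g. 18,000 bins for 100–1000 Da at 0.05 Da.
  The package asserts the arithmetic, not any particular published count:
  how many features a real cohort yields is data-dependent.

# The neural classifiers

Met-NN and MP-NN share a metabolite-scoring trunk: an affine projection
of the standardized fingerprint to 1024 hidden units (the first residual
skip is undefined when the input dimension differs from the width, so a
linear projection precedes the stack), then six residual blocks of the
form `h + LeakyReLU(Dropout(affine(h)))` — fully connected, dropout, then
activation, in that order — and a final affine map squashed to a score in
(0,1). MP-NN appends a fusion layer: one affine map of (metabolite score,
transformed CEA) through a logistic squash, trained end to end. The two
models share topology but never weights.

Training minimizes binary cross-entropy with Adam (lr 1e-4, beta1 0.9,
beta2 0.999) for a fixed number of epochs, with no early stopping and no
validation split. Feature columns are z-scored and CEA is log1p-then-z-
scored on training statistics only; the statistics travel with the model.
Dropout (default rate 0.5, slope 0.01, batch 64 — implementation
defaults, since only the architecture skeleton is fixed) and minibatch
shuffling draw from a stream derived from the training seed, making
training bit-reproducible. The fusion layer initializes near the identity
on the metabolite score (weights ~(1, 0), bias −0.5) so the fused model
starts aligned with its trunk rather than inverted. Backpropagation is
hand-derived matrix algebra and is verified against central differences
to a relative error below 1e-4 in the test suite.

# The fusion forest

MPI-RF consumes exactly two columns — the MP-NN score and the image-AI
score; CEA reaches it only through MP-NN. Trees are grown on bootstrap
samples with Gini splits, `floor(sqrt(p))` features tried per split, and
hyperparameters (minimum leaf size, maximum depth, number of trees)
chosen by stratified 10-fold cross-validation maximizing mean out-of-fold
AUC, with ties broken toward parsimony (fewer trees, then shallower,
then larger leaves). The default grid is leaf {1,2,5,10} × depth
{2,3,5,∞} × trees {100,300,500}; only the searched parameter *names* are
fixed by the study design, so the values are package defaults. The
forest probability is the mean of per-tree leaf class frequencies.
Forests serialize to JSON with explicit node tables, so a stored model
is portable and predicts identically after reload. The forest is
hand-rolled rather than wrapped because no random-forest package is
available in the supported environment and explicit trees make the
serialization contract trivial to honor.

# Evaluation statistics

* **AUC** is the Mann–Whitney concordance with ties counted one half;
  its variance and CIs come from DeLong placement values, and correlated
  models are compared with the DeLong z-test.
* **Operating points**: Youden-maximizing thresholds are computed on the
  training cohort and carried to the test cohort; positive calls use
  `score >= threshold` (the boundary convention is documented and the
  CEA cutoff is strict `>`, both configurable). When pinning specificity
  at a level, the smallest observed threshold attaining it is used and
  the sensitivity there is reported; symmetrically for pinned
  sensitivity.
* **Permutation overfitting test**: evaluation labels are permuted
  (`p = (1 + #{null >= observed}) / (n_perm + 1)`); the model is *not*
  retrained per permutation — retraining is exposed as an option but the
  label-only variant is the default and the one used in the pipeline.
* **Power analysis**: the one-sided test that the true AUC exceeds a null
  value uses the Hanley–McNeil variance
  `V(A) = [A(1−A) + (m−1)(Q1−A²) + (n−1)(Q2−A²)]/(mn)` with
  `Q1 = A/(2−A)`, `Q2 = 2A²/(1+A)`, and
  `power = Φ((A1 − A0 − z_{1−α}·SE0)/SE1)`. A Monte-Carlo cross-check
  simulates scores and applies the same test. Two score models are
  offered: *exponential* (the bi-negative-exponential model from which
  Q1/Q2 derive — use this to validate the closed form; agreement is
  within ~0.003 at the design points used in the tests) and *binormal*.
  Under a binormal world the Hanley–McNeil variance is conservative, and
  the simulated power can exceed the closed form by ~0.05 at high AUC;
  this is a property of the approximation, not a bug, and is why the
  cross-check in the acceptance material uses the model-consistent
  simulation.
* **Hosmer–Lemeshow** uses ten quantile groups with `g − 2` degrees of
  freedom. That df convention presumes the probabilities come from a
  fitted model; the calibration null in the tests therefore refits a
  one-parameter recalibration before grouping.
* **Stage trend**: the detection-by-stage association defaults to a
  Pearson chi-square on the contingency table, with a Cochran–Armitage
  trend test as an option. No multiple-testing correction is applied
  anywhere; p-values are reported raw.

# Numerical conventions

Morphology and local-maxima windows use reflect boundaries with edge
repetition. Seeds: every stochastic operation takes an explicit seed;
pipeline stages derive child seeds from one master seed via a fixed
affine map mod 2^31−1, and the caller's RNG state is always restored.
Degenerate inputs fail loudly: single-class labels, empty mass windows,
even structuring elements, non-finite covariates, negative intensities
and mismatched bin grids are errors naming the offending field, not
warnings.

# What a green test establishes

The synthetic generator emulates peak multiplicity, adduct structure,
baseline drift, heteroscedastic peak intensities, stage-graded effect
sizes, an insensitive-but-specific protein marker and an informative
image score. It does **not** emulate batch effects, mass-calibration
drift, isotope structure, peak-shape asymmetry, censored clinical
covariates, or any correlation between image features and metabolism
beyond the shared label. Consequently, a passing model-ordering test
shows that the pipeline *can* recover a fusion hierarchy from
complementary signals of realistic strength — not that any published
cohort-level number is reproduced. Published real-cohort performance is
out of reach by construction (the data are not deposited), and the only
externally anchored quantities reproduced here are the two power-analysis
design points, which are fully self-contained. The multi-seed acceptance
checks are stochastic by design; their pass thresholds leave roughly a
five-percent chance of a false red under the stated worlds, which is the
price of refusing to tune seeds.

# Known limitations

* The raw m/z grid is uniform and peak widths are constant in Da; real
  TOF data have m/z-dependent resolution.
* The hand-rolled networks run on one CPU thread via BLAS; the full
  1000-epoch, 1024-wide configuration is supported but slow, and the
  desk-scale defaults are the intended test vehicle.
* The binormal/exponential disagreement in the power cross-check (above)
  is inherent to the Hanley–McNeil approximation.
* `read_spectrum()` supports two-column CSV and uncompressed 64-bit
  mzML only; vendor formats and compressed mzML are out of scope.
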