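---
title: "Multimodal OCT texture and Raman band analysis: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multimodal OCT texture and Raman band analysis: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The scientific problem

Skin and subcutaneous tumors are among the most common neoplasms of dogs and
cats, and the clinically decisive distinction — malignant (mast cell tumor,
soft tissue sarcoma) versus benign (lipoma, healthy skin) — is usually made
by fine-needle cytology, an invasive method with operator-dependent
accuracy. Two optical modalities carry complementary information: OCT
B-scans resolve tissue micro-architecture (adipose honeycomb, dense cellular
tumors, layered skin), while Raman spectra report molecular composition
(lipid versus protein and nucleic-acid bands). `octraman` implements a
complete analysis chain for this setting: texture features from masked
B-scans, band features from baseline-corrected spectra, linear discriminant
classification with leave-one-out cross-validation (LOOCV), and
nonparametric significance testing.

# The OCT texture model

A B-scan is an 8-bit grayscale matrix with row 1 at the top (background
above the tissue surface). Feature extraction assumes a binary tissue mask,
built in a fixed, normative order:

1. **Threshold.** Otsu's histogram criterion by default, with a fixed-level
   override. The threshold operates on stored pixel values as-is; whether
   acquisition software exported linear or log-scaled intensities is outside
   the package's control, and no rescaling is attempted.
2. **Void filling.** Background regions *not* 4-connected to the image
   border become tissue. This treats the dark honeycomb voids of lipomas as
   part of the structure — which is exactly what makes lipoma texture
   distinctive — while leaving the true background untouched.
   4-connectivity prevents diagonal leakage through one-pixel tissue walls.
3. **Saturation-column removal.** Strong back-reflections produce
   full-height bright columns that threshold as tissue. The top
   `n_top_rows` (default 15) rows of the mask should image only background,
   so the top block is summed per column and any column with a positive sum
   is zeroed over the full height. The stage order matters and is tested:
   filling before removal differs from the reverse whenever a void touches
   a flagged column.

A 15 × 15 px window (~53 × 53 µm at the nominal pixel pitch) slides at
stride 1. A position is admitted only if **all** 225 pixels are masked;
windows partially covering background would mix two intensity populations
and bias every statistic, so full coverage is required rather than
center-pixel coverage. Each admitted window yields μ, σ (population,
divisor n — a deliberate convention, documented because the divisor affects
nothing downstream but must be fixed for reproducibility), range, and
CV = σ/μ with CV ≡ 0 at μ = 0 (an all-zero window carries no texture
information). The four per-image distributions are summarized by mean,
sample standard deviation, and median (even-length medians average the
middle pair), giving 12 features per image, averaged per sample because
classification operates per sample.

# The Raman band model

Spectra cover 920–2070 cm⁻¹ and are linearly resampled to a canonical
1 cm⁻¹ grid so band averages are grid-independent. Processing is:

1. **Baseline.** Tissue autofluorescence is a smooth background under the
   Raman peaks. The package uses iterative modified polynomial fitting
   (default order 7, `tol = 1e-6 × max`, `max_iter = 100`): fit, clip the
   working spectrum at the fit, refit. Because the converged envelope is
   biased low by construction (it hugs the lower wiggle envelope), it is
   used only to *flag* peak points; the final baseline is an ordinary
   polynomial fit to the unflagged points of the original spectrum, with
   flagging and refitting iterated until the flagged set stabilizes. On
   synthetic truth this recovers peak areas to well under 1% at zero noise.
   Output is clipped at zero.
2. **Normalization.** Dividing by a class-dependent anchor peak (1437 cm⁻¹
   for lipid-dominated, 1446–1448 cm⁻¹ for protein-dominated tissue) would
   leak the class label at prediction time. The package instead divides by
   the maximum within 1425–1460 cm⁻¹, which selects the correct anchor
   automatically and is label-free. This is a deliberate deviation from a
   per-class anchor and is the package's recommended default.
3. **Band parameters.** p1–p7 are means of the normalized intensity over
   925–970, 1060–1160, 1180–1280, 1310–1380, 1451–1509, 1845–1880, and
   2050–2080 cm⁻¹, endpoints inclusive. The last band extends past the
   acquisition range; a band only needs to contain at least one grid point,
   so p7 effectively averages 2050–2070 cm⁻¹. p8 is the mean absolute
   intensity over the full grid, computed on the baseline-subtracted but
   unnormalized spectrum so it reflects Raman signal strength rather than
   fluorescence. Multiplying a raw spectrum by any gain g > 0 leaves p1–p7
   unchanged and scales p8 by exactly g.

Per-sample features are the mean over the sample's spectra; averaging
before classification (rather than classifying single spectra) matches the
per-sample LOOCV unit, and the significance matrices default to the same
per-sample values.

# Classification and testing

`tissue_lda()` is a classic Fisher discriminant: features are z-scored
(center/scale estimated from the training data only — OCT intensities and
normalized band ratios live on incommensurate scales), the pooled
within-class covariance and between-class scatter are formed, and the
discriminant axes are the leading generalized eigenvectors, at most
n_classes − 1 of them. Prediction uses the shared-covariance Gaussian
score with **equal priors**: the observed class frequencies of any ex vivo
collection reflect sampling convenience, not prevalence. Ties are broken
toward the canonical class order (skin, lipoma, MCT, STS) for determinism.
If the pooled covariance is singular (constant or collinear features), a
small ridge (10⁻⁶ of the mean pooled variance) is added and the fit is
flagged; with `regularize = FALSE` the fit fails naming the degenerate
features.

LOOCV refits the model n times, re-estimating standardization within each
training fold; the held-out prediction is compared with the true label.
The discriminant coordinates attached to the prediction table come from the
full-data fit and serve plotting only — they are deliberately separated
from the cross-validated metrics so the scatter plot is never mistaken for
a cross-validated result. Merging MCT and STS into one malignant class
relabels both the true and the predicted column, so confusing the two
malignant classes still counts as a correct malignant call; coarsening can
therefore never create new errors, and merged accuracy is provably at least
the 4-class accuracy.

Mann–Whitney tests are two-sided, exact when both groups have ≤ 8
untied observations and normal-approximated with tie correction otherwise,
with `***`/`**`/`*`/`NS` at 0.001/0.01/0.05. No multiple-testing correction
is applied — the matrices are descriptive, mirroring common practice for
this kind of feature screen, and the choice is stated rather than hidden.

# The synthetic data generator

The original ex vivo measurements are not publicly deposited, so the
package generates data with the same statistical structure the analysis
assumes:

* **OCT.** Gaussian speckle at a class-specific mean/spread on a dark
  background; lipomas get hard disk-shaped voids at background level
  (density 0.004/px, radius 4 px); skin gets a bright 3-row surface band
  (stratum corneum); saturation artifacts are 1–3 px wide full-height
  columns at maximum intensity with random vertical gaps (they appear as
  periodic patches, not solid lines), stamped with per-image probability
  0.15–0.2. Images are 8-bit — the bit depth of real exports is a
  convention choice, made concrete so range/CV scales are defined — and
  100 × 140 px by default, a desk-scale size at which one image still
  yields ~10⁴ windows.
* **Raman.** Sums of Gaussian peaks on a polynomial fluorescence background
  with additive Gaussian noise, clipped at zero. Lipoma carries the lipid
  set (1076, 1300, 1437, 1656 cm⁻¹); skin the dermal protein set (935,
  1000, 1031, 1127, 1343, 1448, 1544, 1586, 1656, 1885, 2067 cm⁻¹); MCT and
  STS share the protein set plus the 1241 cm⁻¹ nucleic-acid band and a
  1480 cm⁻¹ band, with the lipid 1437 cm⁻¹ shoulder reduced and the anchor
  at 1446 cm⁻¹. MCT and STS are given *identical* normalized spectral
  shapes — their real band features show no significant contrasts — and
  differ only in overall gain, which survives solely in p8.
* **Sample structure.** Ten samples per class, four B-scans and eight
  spectra per sample by default. Between-sample variability enters as a
  Gaussian shift of the tissue mean (sd 8 intensity levels), a lognormal
  spectral gain factor (sdlog 0.1), and a lognormal peak-width factor
  (sdlog 0.06) shared by a sample's measurements; the width factor makes
  band features co-vary across bands within a sample, as instrument focus
  and pressure variation do in practice.
* **`class_gap`.** A single knob in [0, 1] shrinks every class's texture
  mean, void density, surface-line boost, clean spectral signal and
  log-gain toward the pooled cross-class average. At 1 the configured
  contrasts apply; near 0 the classes coincide and LOOCV accuracy falls
  toward chance. The monotone effect of this knob on downstream accuracy is
  tested (20 repetitions at two settings).

The generator reproduces the *direction* of the published contrasts —
lipoma has the highest σ, range, and CV and the lowest μ; malignant
classes separate from lipoma on every band and from skin on the
1451–1509 cm⁻¹ band; MCT and STS stay indistinguishable on p1–p7 — and at
the default gap the classes are fully separable, so leave-one-out metrics
saturate at 1.0. What passing tests therefore show is that the pipeline
preserves and exploits the structure the generator encodes; they do not
show that real formalin-fixed tissue reaches any particular accuracy. Real
OCT speckle is multiplicative and correlated, real fluorescence varies
nonpolynomially, photon noise is Poisson, and real class boundaries
overlap — none of which the generator claims to model.

# Numerical and degenerate-input conventions

* Window sums use summed-area tables; windowed extrema use separable
  running min/max. Both are validated against naive per-position
  recomputation to 10⁻¹⁰.
* A window larger than the image yields empty distributions (flagged, not
  fatal); an image with zero admissible windows raises an "unfeaturable
  image" error at summary time.
* Otsu on a constant image marks nothing as foreground (a blank scan
  produces an empty mask rather than an arbitrary split).
* CV at μ = 0 is 0; σ = 0 ⇔ range = 0 holds exactly because 8-bit sums are
  integer-exact in doubles.
* The exact Mann–Whitney path requires untied pools; tied small samples
  fall back to the corrected normal approximation, and the exact path is
  verified against exhaustive enumeration for all group sizes ≤ 7.
* LOOCV requires every class to have ≥ 2 samples and rejects otherwise,
  naming the offending class.

# Problem sizes

The default test and acceptance conditions are 10 samples/class × (4 images
of 100 × 140 px + 8 spectra of 1151 points), chosen so a full pipeline run
takes seconds and a 25-repetition stability experiment minutes on a single
core. Property tests use a reduced 5 samples/class, 60 × 80 px
configuration.

# Known limitations

* The generator's realism limits are listed above; in particular, perfect
  synthetic separability means the package's headline metrics say nothing
  quantitative about real tissue.
* Masking has no tilt correction, surface flattening, or speckle
  denoising; scans are assumed roughly horizontal with background above.
* Band definitions, the anchor window, and the polynomial order are
  configurable but the defaults are not tuned per instrument.
* No multiple-testing correction in the significance matrices.
* The LOOCV reading of "compare the held-out sample against the model
  trained on the rest" is the standard one; resubstitution-style
  alternatives are not offered because they overstate accuracy.
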