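---
title: "Quantifying focal liver lesions on CEUS: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying focal liver lesions on CEUS: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`ceusradiomics` characterizes focal liver lesions (FLLs) as benign or
malignant from short (~60 s) contrast-enhanced ultrasound (CEUS) cine
loops. This vignette explains the model behind each stage, the
parameters that matter, what the bundled simulator does and does not
emulate, and the design choices made where several reasonable options
existed.

## The problem and the processing chain

CEUS records the transit of an intravascular microbubble bolus through
the liver. In the arterial phase (~10-45 s post injection) malignant
lesions tend to enhance earlier, stronger and more heterogeneously than
the surrounding parenchyma; the portal-venous inflow then overlaps the
arterial wash-out, and probe/respiratory motion corrupts an appreciable
fraction of frames. The package therefore avoids two fragile steps:
TIC model fitting (unreliable under phase overlap and motion) and
motion compensation (unreliable under out-of-plane motion). Instead it
extracts features designed to be robust to motion:

1. **Linearization** (`linearize()`): scanner gray levels are inverted
   to relative echo power, `power = 10^(DR (g/G - 1) / 10)`, so that
   pixel values are proportional to local microbubble concentration.
2. **ROI construction** (`square_roi()`): a square analysis box centered
   on the center of mass of 1-3 manual lesion masks, deliberately larger
   than the lesion so parenchymal context enters the statistics.
3. **Valid-frame filtering and fiducial frames**
   (`valid_frames()`, `fiducial_frames()`): frames whose B-mode ROI
   correlates with the radiologist's reference frame above 0.8 are kept;
   wash-in/peak/wash-out frames are selected from the smoothed
   lesion-mean TIC by the two-line intersection construction, then
   refined to the most reference-correlated frames in their windows.
4. **Parametric maps** (137 per lesion): 5 per-pixel TIC parameter maps
   (`perfusion_map_stack()`), 3 ring-kernel similarity maps
   (`similarity_map_stack()`), and 43 moving-window texture maps at each
   of the three fiducial frames (`texture_at_fiducials()`).
5. **Feature table** (`build_feature_table()`): median, interquartile
   range and skewness of every map over the ROI — 411 features.
6. **Filtering and classification** (`correlation_prune()`,
   `adaptive_select()`, `nested_cv()`): redundancy pruning, per-set
   adaptive univariate selection, and an imbalance-aware repeated nested
   cross-validation bench with permutation importance and a corrected
   resampled t-test.

## Parameters and their defaults

| Parameter | Default | Units | Rationale |
|---|---|---|---|
| Dynamic range `DR` | 60 | dB | typical clinical CEUS log compression; echo-power convention (divisor 10) |
| Gray maximum `G` | 255 | levels | 8-bit export; configurable for other bit depths |
| TIC smoothing window | 5 | s | suppresses frame-to-frame speckle/motion noise without displacing the peak |
| Valid-frame threshold | 0.8 | Pearson r | empirical threshold separating in-plane from corrupted frames |
| Appearance threshold | 10% of peak | — | robust early-arrival marker on noisy TICs |
| Wash-in fit band | 5-50% of peak | — | the quasi-linear rising limb |
| Peak search window | -20/+50 | frames | asymmetric: wash-out is slower than wash-in |
| Wash-in/out frame offsets | +5/-5, +10 | frames | keeps texture frames away from transition points |
| Ring kernel radii | 1 / 2.5 | mm | brackets the ~1.25 mm avascular tumor limit (angiogenic switch) |
| Similarity window | 20 | s | arterial phase only; avoids portal-phase confounding |
| Texture window / stride | 21 / 3 | px | balances map noise vs. smoothing of distinct textures |
| Gray levels for texture | 64 | levels | standard radiomics quantization |
| ROI sizing | 2 x bbox, clamp 200-278 | px | includes surrounding parenchyma at clinical resolution |
| Correlation pruning | 0.9 | `abs(r)` | removes near-duplicate features |
| PCA variance target | 95% | — | sizes the per-set selection adaptively |
| SMOTE / undersampling | 0.5 / 0.7 | ratios | balances training folds without touching test data |
| CV layout | 4 folds x 5 repeats | — | 20 evaluations; 4 folds keep several benign lesions per test fold |

The wash-in rate is defined as peak intensity divided by the wash-in
time (peak time minus appearance time). Because "time-to-peak" is also
used in the literature for the peak time itself, the denominator is
configurable (`rate_denominator = "peak_time"`); the wash-in-time
convention is the default since it measures the slope of the enhancement
actually observed between appearance and peak.

## Similarity analysis

Each pixel TIC is compared with all TICs in an annular (ring) kernel.
Linear similarity is measured in the time domain by Pearson correlation
and in the frequency domain by Welch magnitude-squared coherence:
detrended, Hann-tapered segments of half the window length at 50%
overlap, coherence averaged over all bins below Nyquist (DC excluded).
Band-averaging to a scalar was chosen because a scalar per pixel is what
the parametric map needs; the band cutoff is configurable. Nonlinear
similarity is a plug-in mutual-information estimate on equal-frequency
bins with `ceiling(sqrt(n))` bins per variable; this estimator is biased
upward on small windows, which is acceptable because the values are
used comparatively (lesion vs. parenchyma, lesion vs. lesion). The
analysis window starts at the **lesion-level** appearance time (from the
lesion-mean TIC), not per pixel, so all pixels share one time support —
otherwise pixel-wise windows would make coherence values incomparable.
Speckle is first regularized by an edge-preserving diffusion filter
(Perona-Malik, 10 iterations, conductance set to 10% of the intensity
range); its flux form conserves total intensity exactly.

## Texture analysis

Texture is computed on linearized intensities with a 21 x 21 window
moved at stride 3 over the ROI; each window is quantized to 64 levels
over its own min-max range, which makes all matrix-based features
invariant to affine intensity rescaling. The four matrix families
follow the standard 2-D conventions: GLCM and GLRLM pool counts over
the four in-plane directions before normalization, GLSZM uses
8-connected constant-level zones, NGTDM uses 8-neighbor means over
interior pixels. Run and zone percentages are normalized by
`directions x pixels` and `pixels` respectively so both lie in (0, 1].
Stride-grid maps are upsampled to the pixel grid by nearest neighbor so
all 137 maps share one support. Two degenerate-input conventions are
fixed deliberately: constant windows give zero skewness/kurtosis, and
the NGTDM coarseness denominator carries an epsilon of 1e-6. A note on
connectivity: under 8-connectivity a two-level checkerboard forms two
diagonal zones, not 441 singletons; a singleton-zone pattern requires at
least four levels. The test suite pins both behaviors, with slow pure-R
brute-force enumerations as the source of truth for every family.

## The classification bench

The bench mirrors a cautious small-cohort workflow: stratified outer
4-fold cross validation repeated over 5 random splits (20 evaluations);
training folds are SMOTE-oversampled (benign to half the malignant
count) and the malignant class randomly undersampled to 70%; backward
sequential feature selection and an inner 4-fold grid search run on
training data only; the most frequent hyperparameters across folds are
fixed for the final evaluation pass; test folds are never resampled.
Four base models (ridge-logistic regression, SVM with Platt
probabilities, random forest, k-NN) are combined by equal-weight soft
voting with probability ties resolved to malignant (the conservative
clinical direction). Balanced accuracy drives all optimization because
the benign class is small and a specific error (missed benign) and a
sensitive error (missed cancer) are both costly.

Feature filtering is by default fit once on the full table before CV
(pooled mode), the common small-cohort practice; this leaks label
information into the filter, so the bench also offers
`filter_in_folds = TRUE` (leak-free mode) which re-fits pruning and
selection inside every training fold. Pooled mode stays the default so
results are comparable with that practice; the leak-free switch is one
line.

Model comparison uses the corrected resampled t-test: with per-repetition
differences `p`, `t = mean(p) / sqrt((1/n + n2/n1) var(p))`, degrees of
freedom `n - 1`. The correction ratio is test/train (`n2/n1`) by
default — the variance inflation that accounts for training-set overlap
across repetitions — with the reciprocal available as a configuration
switch. Setting the ratio to zero recovers the uncorrected resampled
t-test exactly, which the suite asserts numerically. A constant nonzero
difference makes the variance estimate zero; this is reported as a
degenerate infinite-t rejection rather than an error.

## The simulator: what it emulates, what it does not

`generate_cine()` produces dual-view cines with known ground truth:
log-normal bolus kinetics with a delayed sigmoid portal plateau,
multiplicative gamma speckle low-pass filtered to a configurable
correlation length, rigid integer-pixel translations applied jointly to
both panes, and out-of-plane "dropout" frames whose texture is an
independent draw (the lesion vanishes from the contrast pane). The
malignant phenotype used for end-to-end tests — earlier onset, twice the
peak amplitude, per-pixel jitter of the log-normal shape — is a
simulator convention chosen to make the cohort separable, not a
clinical claim. Consequently, a high balanced accuracy on synthetic
cohorts demonstrates that the pipeline preserves and recovers the
kinetic contrast it was given; it says nothing about clinical
performance, where lesion contrast is far subtler and confounded.
The simulator also does not model nonlinear microbubble response,
attenuation, depth-dependent gain, or non-rigid motion.

Default kinetic parameters place the bolus onset near 15 s and the
lesion-mean peak near 35 s of a 70 s recording at 1 frame/s, with the
portal plateau from ~40 s, consistent with arterial-phase liver CEUS;
the default pane is 300 x 300 px at 0.137 mm/px so the automatic ROI
lands at the 200 px clinical floor.

## Problem sizes used by the tests and the acceptance script

Map extraction cost scales with ROI area times kernel size, so the
validation runs use two scales: a clinical-scale single lesion
(300 x 300 pane, 200 px ROI, 70 frames) to pin the per-lesion contract
and runtime, and a reduced scale (80 x 80 pane, ~50 px ROI, 0.3 mm/px,
60-lesion cohorts) for the cohort-level bench, where the backward-SFS
stage is disabled (`sfs_target = NULL`) because its calibration
properties are established separately by the dedicated selection tests;
SFS-in-the-loop integration is exercised on a smaller table. The bench
defaults (`cv_config()`) keep SFS at 12 features, matching the
feature-count sweep's lower end (`feature_count_sweep()` reproduces the
full experiment when wanted).

## Numerical choices and degenerate inputs

* Quantization ties: the window quantizer uses a relative epsilon so the
  maximum always maps to level `L`; constant windows map to level 1.
* Zero-variance TICs (pre-arrival pixels) are flagged missing in the
  similarity maps; pixels with under half their ring inside the ROI are
  missing; map summary statistics require 8 valid pixels.
* Missing feature values are imputed by training-fold medians inside the
  bench (and by column medians in the one-shot filter).
* Probability outputs are clamped to [0, 1] and non-finite values fall
  back to indifference (0.5) — relevant for Platt calibration on tiny
  folds.
* Parallel wash-in/wash-out fits (possible on degenerate TICs) fall back
  to the TIC argmax as the peak guess, with a message.
* All stochastic stages (simulation, resampling, fold splits, model
  seeds, MI jitter) flow from explicit seeds; reports are bitwise
  reproducible given the seed.

## Known limitations

* No DICOM reader: cines enter as TIFF/PNG stacks with a YAML sidecar,
  or in memory.
* Pixel TICs are taken at fixed coordinates; slow drift below the
  valid-frame threshold biases per-pixel (not lesion-mean) parameters.
* The MI estimators (pairwise and feature-label) are biased at these
  sample sizes; rankings are meaningful, absolute values are not.
* The simulator's benign/malignant contrast is optimistic by design;
  clinical validation requires clinical data.
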