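---
title: "Methods: deciding whether a midsagittal pelvic-floor ultrasound was captured correctly"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: deciding whether a midsagittal pelvic-floor ultrasound was captured correctly}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(planeqc)
```

## The problem

Transperineal pelvic-floor ultrasound is standardized on the midsagittal
plane, the one acquisition plane that shows the pubic symphysis, urethra,
urinary bladder, vagina, uterus, anus, rectum and levator ani muscle
simultaneously. A dynamic study records this plane at rest and during the
Valsalva maneuver. Capturing and holding the plane is operator-dependent:
anteroposterior probe displacement loses the dorsocaudal structures (anus,
rectum, levator ani), and rotation of the image additionally loses the
uterus. A video in which any of the eight structures is missing is an
incorrectly captured plane, and measurements made on it are unreliable.

`planeqc` implements a quality-control pipeline for this decision. Its
input is not the raw ultrasound but the output of an upstream
segmentation network: for every frame and every organ, a probability map
giving each pixel's confidence of belonging to that organ. From these maps
the package decides, per organ and per video, whether the organ was
correctly captured, and declares the plane correct only if all eight organs
were. Verdicts are validated against a reference rater with the agreement
statistics standard in inter-rater studies.

## Pipeline

### Per-frame features

For each organ in each frame, 17 features are computed from the probability
map:

* **Full-map confidence** (4): mean, standard deviation, maximum, minimum of
  all pixel probabilities.
* **Thresholded confidence** (4): the same statistics restricted to pixels
  with probability strictly greater than 0.5.
* **Bounding-box geometry** (9): over the same `> 0.5` binarization, the
  row/column minima and maxima, the box centroid, width, height and area.

The contrast between the first two groups is the confidence signal: when
the segmenter is certain, pixels outside the organ get very low values, so
the thresholded statistics sit far above the full-map ones. When the two
groups are similar, high confidence has leaked outside the organ and the
segmentation is unreliable. The box features capture whether the organ's
location, size and aspect ratio are consistent with its anatomy.

Numerical choices, made once and frozen:

* Standard deviations are population form (divide by the pixel count), so
  single-pixel sets are well-defined with SD 0.
* The threshold is strict (`> 0.5`); a pixel at exactly 0.5 is excluded.
* An empty thresholded set yields zeros for all thresholded and box
  features plus an `thr_empty` flag carried alongside (not one of the 17):
  boosting input must be finite, and 0 is maximally distinct from any
  valid confident statistic, which necessarily exceeds 0.5.
* The centroid is the box center (midpoint of the extremes), not the mask's
  center of mass; width and height are inclusive pixel counts
  (`max − min + 1`); area is box area, not qualifying-pixel count.
* Pixel coordinates are 0-based `(row, column)` with the origin top-left.

### Window aggregation

Frame features are aggregated over windows of `N` consecutive frames
(default `N = 60`) by their mean, population SD, maximum and minimum,
giving `17 × 4 = 68` features per row; one row per (patient, organ,
window). Windowing is a data-augmentation device: a long video contributes
several rows per organ rather than one. The stride defaults to `N`
(non-overlapping), but is configurable since overlapping windows are an
equally defensible convention. Trailing frames short of a full window are
discarded so that every row summarizes exactly `N` frames; a video shorter
than `N` falls back to a single whole-video window rather than silently
dropping the patient. The 68-column order is frozen
(`aggregated_feature_names()`) and serialized with every dataset so trained
models are portable.

### Classification

One gradient-boosted tree model (xgboost, logistic objective) is trained
per organ — matching the per-organ framing of the decision and the
per-organ reporting of agreement studies — rather than one joint model with
the organ as a categorical input. Hyperparameters are tuned by random
search: tree count 50–500, depth 2–8, learning rate log-uniform on
0.01–0.3, row and column subsampling 0.6–1, L2 weight 0–5, with 50 sampled
configurations by default — standard ranges sized for datasets of a few
hundred to a few thousand rows. The selection metric is balanced accuracy,
robust to the per-organ class imbalance. Because several rows share a
patient, evaluation uses **grouped** 5-fold cross-validation: all of a
patient's rows fall in exactly one validation fold, so no patient ever
informs both sides of a boundary. The train/test split is likewise by
patient (first 60 / last 30 by default).

At prediction time an organ's probability for a video is the mean of its
window-row probabilities, thresholded at 0.5 (majority voting would be the
obvious alternative; mean-then-threshold uses the calibrated scores and is
the package's default). The plane verdict is the conjunction of the eight
organ verdicts, by the definition of a correct plane.

In simulated cohorts some organs are never lost (displacement and rotation
both spare the pubis, urethra, bladder and vagina), so their training
labels are single-class. There is nothing for a classifier to learn there:
those organs get an explicit constant-verdict model and are reported as
degenerate, not dropped. The plane verdict is then carried entirely by the
informative organs, which is also where real disagreement lives.

### Concordance statistics

Verdicts are compared endpoint by endpoint (plane + 8 organs) against a
reference rater:

* **Cohen's kappa** `(po − pe)/(1 − pe)`, with the asymptotic Fleiss–Cohen
  standard error for the 95% CI and the null-hypothesis standard error for
  the two-sided p-value (normal approximation). Both formulas were
  cross-checked against an independent implementation during development.
* **Agreement bands**: poor (≤ 0.20), weak (0.20–0.40], moderate
  (0.40–0.60], good (0.60–0.80], very good (> 0.80). The conventional
  bands leave 0.20–0.21 and 0.80–0.81 uncovered; half-open intervals at the
  printed boundaries close the gaps and assign every published value its
  published category.
* **Exact McNemar test** on the discordant counts `(b, c)`:
  `p = min(1, 2·P(X ≤ min(b, c)))`, `X ~ Binomial(b + c, ½)`; vacuous
  (p = 1) without discordant pairs. Small agreement tables make the exact
  binomial form the right default; the chi-square approximation is not
  used.
* **Not-estimable kappa**: when both raters are constant and identical,
  chance agreement is 1 and kappa is undefined. It is reported as a
  distinct missing state — never as 0 — matching how agreement tables
  print such endpoints.
* **t-based descriptive CIs** `mean ± t(0.975, n−1)·sd/√n` for cohort
  characteristics given as mean ± SD.

## The simulator

No segmentation maps of real ultrasounds are distributed, so the package
ships a generator with the statistical structure the classifier assumes:

* Each present organ is an axis-aligned elliptical blob at probability
  `blob_confidence` (default 0.9) with a linear fall-off over a ~2-pixel
  rim, composited over i.i.d. uniform background noise with mean
  `background_noise` and width `2·min(noise, 1 − noise)` — i.e.
  `[0, 2·background_noise]` for means up to 0.5 (default mean 0.1), and a
  correspondingly narrowing band above it so the mean interpretation holds
  across the whole unit interval. The default contrast (0.9 vs 0.1) makes
  present and absent organs separable — the regime in which an upstream
  segmenter that works at all would operate.
* The organ layout (centroid and half-axes per organ, as image fractions)
  is fixed per cohort; per-video size jitter is ±10% and per-frame centroid
  jitter is Gaussian with `jitter_sd = 2` px. Valsalva dynamics are modeled
  only as a slow monotone caudal drift totalling 2–10% of image height per
  video; the classifier uses no motion features, so richer dynamics would
  add nothing the model can see.
* Defect modes reproduce the two acquisition failures: *displacement*
  removes anus, rectum, levator ani; *rotation* removes the uterus as well
  and doubles the background noise of everything else (a rotated image
  degrades the segmenter's certainty overall). "Removed" organs render as
  pure background — the organ is simply not visualized — rather than as
  displaced blobs.
* Cohort defaults are 45 correct + 45 incorrect videos of 60 frames at
  64×64 px, labels derived from the defect mode, patient ids `P001…`,
  everything reproducible from a single seed.

What the simulator does **not** emulate: speckle, shadowing, anatomical
shape variation, and — most importantly — the unknown failure morphology of
a real segmenter on a bad plane (diffuse low confidence vs. confident
mislocalization). Background-noise inflation is the exposed knob for
degrading certainty, but it is an assumption. Passing end-to-end tests on
simulated cohorts therefore demonstrates that the pipeline recovers the
generating structure under its assumptions; it does not certify performance
on clinical data.

## Problem sizes and verification

The test suite verifies the feature extractor against an independent
pixel-loop oracle on random 8×8 maps (exact for extrema and bounds, 1e-12
for means and SDs), kappa against an item-level reconstruction and McNemar
against term-by-term binomial tails on every 2×2 table with n ≤ 12, and the
descriptive CIs against published cohort rows reproduced to their printed
precision. End-to-end checks run the full pipeline on the default 90-video
cohort (60 train / 30 test, one 60-frame window per video, 720 rows):
under the default separable regime the recovered plane-verdict kappa
against ground truth exceeds 0.8, and raising `background_noise` toward
`blob_confidence` strictly degrades the median plane kappa over five
seeds — the direction a confidence-based detector must respond in. That
degradation check runs on the grid 0.55, 0.70, 0.85 (overlap explicitly
allowed), i.e. in the regime where background noise genuinely interferes
with the blob signal. Below it the relationship is not monotone — as the
background mean first crosses the 0.5 threshold, absent organs acquire
scattered supra-threshold pixels whose whole-image bounding boxes make
them *easier* to tell from compact blobs, before rising noise drowns the
contrast — so a monotonicity test is only meaningful in the interfering
regime. These sizes keep a full run on one CPU within a few minutes while
preserving the study geometry.

## Known limitations

* The number of windows per video in the original study setting depends on
  unpublished frame counts and stride; row totals beyond the one-window
  case are therefore configuration-dependent by design.
* Probabilities from the boosted models are used uncalibrated; the 0.5
  verdict threshold is conventional.
* Kappa CIs use the asymptotic SE, adequate at n = 30 but approximate for
  very sparse discordance; the exact McNemar test covers that regime for
  the hypothesis test.
* A constant-verdict model extrapolates a degenerate training cohort; on
  data where such an organ *can* fail, it must be retrained on a cohort
  containing failures.
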