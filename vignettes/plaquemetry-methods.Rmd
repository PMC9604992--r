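---
title: "Planimetric plaque measurement: models, calibration and validation"
author: "plaquemetry"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Planimetric plaque measurement: models, calibration and validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(plaquemetry)
```

## The measurement model

Planimetry quantifies dental plaque as an area fraction instead of an
ordinal clinical index. The input is a raster image of a single tooth,
cropped onto a pure-black background, on which plaque has been disclosed
with a red-staining agent. Two filters classify every pixel:

1. **Background filter.** A pixel belongs to the black matte when all three
   8-bit channels are at or below `blackTol`. The default `blackTol = 0`
   is the exact rule — background iff RGB = (0,0,0) — which is correct for
   losslessly stored crops (PNG). JPEG compression smears the matte border;
   for JPEG input `blackTol = 8` keeps the halo out of the tooth area (the
   package's tests measure the resulting P% drift at quality 95 and show it
   staying within a few percentage points, versus a large error with the
   exact rule).
2. **Plaque filter.** Among the remaining (tooth) pixels, a pixel is plaque
   when each channel is **at or above** its threshold. Green and blue
   thresholds default to 0, so in practice the red threshold alone decides.
   The comparison is inclusive: a closed rule must put the boundary pixel
   somewhere, and we count it as plaque so that threshold 0 labels every
   tooth pixel plaque and threshold 256 labels none.

The result is P%, the percentage of tooth pixels labelled plaque:
`100 * n_plaque / n_tooth`. The quantity is dimensionless, so pixel pitch
and magnification cancel as long as the whole tooth is in frame. An
all-background image has no denominator and is reported as an *empty crop*
error rather than 0.

### Raw vs. normalized channels

Whether the red criterion should act on the raw 8-bit red channel or on the
red *share* `R/(R+G+B)` is genuinely open — both are defensible readings of
a "3-component vector" decomposition. The package provides both
(`channelMode` in `thresholdConfig()`), with **raw** as the default. The
normalized mode divides by the channel sum, which makes the rule exactly
invariant to multiplicative brightness changes — a useful property on
unevenly lit photographs (demonstrated in the test suite), at the cost of
being a different statistic than the plain red intensity an examiner
calibrates against. The normalized thresholds live in [0, 1].

### Calibration

In interactive use the threshold is tuned until the blue overlay
(`renderOverlay()`: sub-threshold tooth pixels painted pure blue, plaque
kept, matte black) matches the visual impression of the stained area. Two
programmatic stand-ins are provided:

* `thresholdSweep()` computes P% along an ascending threshold grid; the
  curve is non-increasing by construction and anchors at 100 (threshold 0)
  and 0 (threshold 256).
* `calibrateRedThreshold()` picks the cut maximising the between-class
  variance of the tooth-pixel red histogram (Otsu's criterion). On an image
  whose stain and enamel red distributions are separated this lands in the
  valley between the modes — where visual calibration converges. It
  requires plaque to actually be present: on an (almost) plaque-free tooth
  there is no second mode and the criterion splits the enamel noise
  instead. The scan workflow therefore calibrates once on a well-stained
  image and applies that threshold to the whole batch
  (`batchMeasure()` with a shared config); per-image recalibration is the
  camera workflow, where uneven illumination makes a shared threshold
  invalid (`overrides` in `batchMeasure()`).

## The synthetic scene generator

`generateScene()` provides ground truth the clinical images cannot: a
pixel-exact label mask. It emulates exactly the features the classifier
sees:

* a **superellipse** of enamel-coloured pixels (default exponent 2.5, the
  slightly squared outline of a crown) on an exactly-(0,0,0) matte with a
  2-pixel margin;
* **plaque blobs** — random ellipses intersected with the tooth — grown or
  shrunk by a closed-loop area controller (bisection on a global radius
  scale) until the plaque fraction is within 0.01 of `targetFraction`;
  exact placement is over-constrained on a pixel grid, and
  `realizedFraction()` recomputes the achieved value from the mask on every
  call rather than caching it;
* per-channel **Gaussian colour noise** (sd 5 by default), truncated to
  [0, 255];
* **illumination**: homogeneous (scan-like) or a multiplicative lateral
  gradient (camera-like).

Default colours are enamel (205, 200, 190) and stain (235, 60, 90). The
stain red mean sits 30 channel units above the enamel red mean: disclosed
plaque must be separable from enamel in the channel the classifier
thresholds, otherwise no calibrating threshold exists in raw mode — the
separability that visual calibration of real disclosed plaque presumes.
With sd 5 on both distributions the overlap at the midpoint threshold is
negligible, which is why calibrated measurement recovers the truth fraction
to well under half a percentage point (the acceptance suite checks ±0.5 pp
over 50 scenes at fractions 0.05–0.5).

What the generator deliberately does **not** emulate: surface texture and
specular highlights, gingiva and soft tissue at the crop boundary, partial
staining intensity gradients, 3D geometry. Passing the recovery tests
therefore shows the *classifier and statistics* are correct, not that the
threshold rule segments arbitrary clinical photographs; on real data the
separability assumption is the examiner's responsibility.

### The camera view

`renderCameraView()` models the two ways an intraoral photograph differs
from a scanner rendering: brightness scaled by
`1 − gradientStrength · x / width` along the image, and a **proximal crop**
— a strip of `proximalCropFraction` of the tooth width at each lateral
margin set to background in image *and* mask, the surfaces a frontal
photograph cannot see because of the convexity of the crown. Both
parameters at 0 give the identity. With plaque concentrated proximally
(where it accumulates in reality) and a 15% crop, the camera systematically
reads lower than the scan; the acceptance suite reproduces this negative
camera-minus-scan median log difference end to end through the classifier.
A crop fraction ≥ 0.5 would remove the whole tooth and is rejected.

### The longitudinal study fixture

`generateLongitudinalStudy()` draws a complete study — subjects × the six
Ramfjord teeth (FDI 16, 21, 24, 36, 41, 44) × vestibular/oral × T1/T2/T3 —
from a lognormal model: a stable per-(subject, tooth, surface) baseline
(log-sd 0.6 around the per-surface baseline median), a per-timepoint
multiplicative effect, and within-site noise (log-sd 0.35). Defaults:
vestibular baseline median 7.0 P% with multipliers 2.3 (T2) and 0.75 (T3);
oral baseline 9.4 with 1.28 and 1.26 — a vestibular rise-then-fall with a
nearly flat oral course, the asymmetry tooth brushing produces. Values are
truncated to [0.1, 70] P%, keeping them in the range the blob controller
can also render (`render = TRUE` generates one scene per record). Setting
all multipliers to 1 yields a null study for type-I-error checks. At 20
subjects the default effects give essentially full power for the
vestibular comparisons at the Bonferroni-adjusted levels while the null
study rejects at the nominal rate (both measured over 200 replicates in the
acceptance suite).

## Statistical procedures

All procedures are implemented from their definitions; only distribution
functions (`pt`, `pnorm`, `qf`) and the asymptotic one-sample KS test come
from base R. Each one is checked against an explicit-loop or
full-enumeration oracle in the tests.

* **Bland–Altman** (`blandAltman()`): bias = mean difference
  (reference − test), limits of agreement = bias ± 1.96 sd. With
  `useLog = TRUE` the *measurements* are log-transformed before
  differencing, so differences are log ratios. (Logarithmising the
  differences themselves is impossible once any difference is negative;
  the log-measurement reading is the only self-consistent one, and it makes
  the analysis invariant to a common rescaling of both methods.)
  Systematic bias: one-sample t of the differences against 0 (undefined,
  reported `NA`, when the differences are constant). Proportional bias:
  least-squares slope of differences on pairwise means.
* **ICC(A,1)** (`iccA1()`): single-rating absolute-agreement coefficient
  from the two-way ANOVA mean squares,
  `(MSR − MSE) / (MSR + (k−1)MSE + (k/n)(MSC − MSE))`, with the
  McGraw–Wong F-based 95% CI. Identical rater columns give ICC = 1 with a
  collapsed interval; a constant matrix has no variance to apportion and is
  an error. Absolute agreement charges rater offsets to disagreement:
  shifting one rater's column lowers the coefficient, shifting all ratings
  does not.
* **Wilcoxon signed-rank** (`wilcoxonSignedRank()`): zero differences
  dropped, average ranks for ties. Exact mode builds the full null
  distribution over all 2^m sign assignments (by convolution over doubled
  ranks, so ties are handled exactly); `auto` uses it up to m = 20 and the
  normal approximation with continuity and tie corrections beyond.
* **Spearman** (`spearmanRho()`): product-moment correlation of average
  ranks, p from the t approximation.
* **Bootstrap median CI** (`bootstrapMedianCI()`): 2000 simple resamples by
  default, percentile 2.5/97.5 bounds (R's default quantile type 7),
  explicit seed, degenerate input collapses the interval. Coverage at
  n = 50 Gaussian data is within 93–97% (measured over 1000 replicates).
* **KS normality screen** (`ksNormality()`): D against a normal with the
  sample mean/sd; the default asymptotic p matches common statistics
  packages but is anti-conservative with estimated parameters (the
  Lilliefors caveat) — a Monte-Carlo Lilliefors p is available.
* **Bonferroni schedule**: subject-level comparisons use m = 6
  (adjusted level .0083, conventionally printed .008), site-level m = 24
  (.0021, printed .002) — the divisors consistent with those printed
  levels; both are arguments, not constants.

In the study layer, the subject-level unit is the mean of the six per-tooth
P% values of one surface; missing sites are an error, never silently
averaged. Site-level tables report median, percentile bootstrap CI, min and
max per (tooth, surface, timepoint), plus pooled "All" rows. Overall
percent changes are computed from the pooled medians and displayed rounded
half-away-from-zero to integers (means are available but not the default;
the medians reproduce the reference worked example: overall medians
7.0 → 10.3 → 5.9 give a 47% increase and a 43% decrease). Method agreement
is reported per molar (the only sites with camera references) with
camera − scan orientation, so a scan that reads higher appears as a
negative bias.

## Numerical choices and degenerate inputs

* Threshold comparisons are inclusive (`>=`); strict vs. inclusive is not
  observable through calibration, but the closed rule must pick one side.
* The blob-area bisection runs at most 40 iterations and errors if the
  best achievable fraction misses the target by more than 0.01.
* Channel arithmetic is done in doubles and rounded once to 8 bits;
  gradient invariance of the normalized mode therefore holds up to
  rounding (the tests allow 1.5 pp of residual).
* `withSeed()`-style seeding saves and restores the caller's RNG state, so
  seeded generators neither disturb nor depend on the session stream.
* Display rounding is half-away-from-zero (`round()`'s banker's rounding
  would turn 46.5 into 46); full precision is retained in all returned
  objects and JSON.
* Validation problem sizes — 50 recovery scenes at 128×128, 100 sweep
  images, 10 000 Bland–Altman pairs, 1000 bootstrap replicates, 200 study
  replicates at 20 subjects — were chosen to keep Monte-Carlo error well
  below the asserted margins while the whole suite runs in a few minutes.

## Known limitations

* The classifier is a global threshold rule; it cannot represent spatially
  varying stain intensity, and on gradient-lit images a single raw
  threshold (even recalibrated) leaves a residual error that the tests
  quantify comparatively rather than bound absolutely.
* `calibrateRedThreshold()` assumes a bimodal red histogram; it
  mis-calibrates on plaque-free teeth (use a batch threshold or an explicit
  config there).
* The ICC confidence interval is the F-based approximation; near the
  boundaries (ICC → 1) it degenerates and is reported collapsed.
* The asymptotic KS p-value is anti-conservative with estimated
  parameters, as documented; the Monte-Carlo option is the honest version.
* Camera records are modelled only for the vestibular molar sites, the
  sites where a clinical camera reference exists; the record validator
  enforces this rather than generalising beyond it.
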