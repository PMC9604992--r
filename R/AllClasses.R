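#' @import methods
NULL

## Pixel label codes shared by PixelClassMap and SyntheticScene truth masks.
.LBL_BACKGROUND <- 0L
.LBL_PLAQUE <- 1L
.LBL_CLEAN <- 2L

.labelNames <- c(background = .LBL_BACKGROUND, plaque = .LBL_PLAQUE,
                 tooth_clean = .LBL_CLEAN)

#' RasterImage: an 8-bit RGB pixel grid
#'
#' The unit of all image computation: a row-major grid (origin top-left) of
#' RGB triples, each channel an integer in 0--255. Stored as an integer array
#' of dimension \code{height x width x 3}.
#'
#' @slot pixels integer array, \code{dim = c(height, width, 3)}, values 0--255.
#'
#' @seealso [RasterImage()], [readToothImage()], [classifyPixels()]
#' @export
setClass("RasterImage", representation(pixels = "array"))

setValidity("RasterImage", function(object) {
  px <- object@pixels
  if (!is.array(px) || length(dim(px)) != 3L || dim(px)[3L] != 3L)
    return("'pixels' must be a height x width x 3 array")
  if (dim(px)[1L] < 1L || dim(px)[2L] < 1L)
    return("width and height must both be >= 1")
  if (!is.integer(px))
    return("'pixels' must have integer storage")
  if (anyNA(px) || min(px) < 0L || max(px) > 255L)
    return("channel values must be integers in [0, 255]")
  TRUE
})

#' ThresholdConfig: the two-filter classification settings
#'
#' Settings for the pixel classifier: the background (black-matte) filter and
#' the red-dominance plaque filter. In \code{"raw"} mode the thresholds are
#' compared against the 8-bit channels directly (valid range 0--256, where 256
#' can never be reached so nothing passes); in \code{"normalized"} mode each
#' channel is first divided by the pixel's R+G+B sum and thresholds lie in
#' [0, 1]. Threshold comparisons are inclusive (\code{>=}).
#'
#' @slot redMin,greenMin,blueMin numeric minimum channel values for the plaque
#'   label; green and blue default to 0 as in the standard calibration.
#' @slot channelMode `"raw"` or `"normalized"`.
#' @slot blackTol integer per-channel tolerance for the background filter;
#'   0 keeps the exact RGB = (0,0,0) rule, 8 is suggested for JPEG input whose
#'   compression perturbs the black matte.
#'
#' @seealso [thresholdConfig()], [classifyPixels()]
#' @export
setClass("ThresholdConfig", representation(
  redMin = "numeric", greenMin = "numeric", blueMin = "numeric",
  channelMode = "character", blackTol = "numeric"))

setValidity("ThresholdConfig", function(object) {
  if (length(object@channelMode) != 1L ||
      !object@channelMode %in% c("raw", "normalized"))
    return("channelMode must be \"raw\" or \"normalized\"")
  hi <- if (object@channelMode == "raw") 256 else 1
  for (nm in c("redMin", "greenMin", "blueMin")) {
    v <- slot(object, nm)
    if (length(v) != 1L || is.na(v) || v < 0 || v > hi)
      return(sprintf("%s must be a single value in [0, %s]", nm, hi))
  }
  tl <- object@blackTol
  if (length(tl) != 1L || is.na(tl) || tl < 0 || tl > 255)
    return("blackTol must be a single value in [0, 255]")
  TRUE
})

#' PixelClassMap: per-pixel classification labels
#'
#' Result of [classifyPixels()]: one label per pixel, coded 0 = background,
#' 1 = plaque, 2 = tooth_clean, in a matrix matching the source image.
#'
#' @slot labels integer matrix (height x width) of label codes.
#'
#' @seealso [classifyPixels()], [labelCounts()], [renderOverlay()]
#' @export
setClass("PixelClassMap", representation(labels = "matrix"))

setValidity("PixelClassMap", function(object) {
  lb <- object@labels
  if (!is.integer(lb)) return("'labels' must have integer storage")
  if (anyNA(lb) || !all(lb %in% .labelNames))
    return("labels must be 0 (background), 1 (plaque) or 2 (tooth_clean)")
  TRUE
})

#' PlanimetryResult: pixel counts and P% for one tooth image
#'
#' P% is the percentage of tooth pixels (non-background) classified as
#' plaque-covered: \code{100 * n_plaque / n_tooth}. The \code{method} slot
#' carries the method alias (`"scan"` for P%S, `"camera"` for P%C) as
#' metadata; the formula is identical for both.
#'
#' @slot nTotal,nBackground,nTooth,nPlaque pixel counts;
#'   \code{nTooth = nTotal - nBackground}.
#' @slot pPercent percentage in [0, 100].
#' @slot method character alias (`"scan"`, `"camera"`, or `NA`).
#'
#' @seealso [measurePlaque()]
#' @export
setClass("PlanimetryResult", representation(
  nTotal = "integer", nBackground = "integer", nTooth = "integer",
  nPlaque = "integer", pPercent = "numeric", method = "character"))

setValidity("PlanimetryResult", function(object) {
  if (object@nBackground + object@nTooth != object@nTotal)
    return("n_background + n_tooth must equal n_total")
  if (object@nPlaque > object@nTooth)
    return("n_plaque cannot exceed n_tooth")
  if (object@pPercent < 0 || object@pPercent > 100)
    return("p_percent must lie in [0, 100]")
  TRUE
})

#' SyntheticSceneSpec: parameters of a generated tooth scene
#'
#' Describes a tooth-on-black scene: a superellipse of whitish enamel pixels
#' on a pure-black matte, with red-dominant stained-plaque blobs covering a
#' controllable fraction of the tooth, under homogeneous (scan-like) or
#' laterally graded (camera-like) illumination.
#'
#' @slot width,height canvas size in pixels.
#' @slot toothSemiAxes numeric length-2, superellipse semi-axes (x, y) in px.
#' @slot toothExponent superellipse exponent (2 = ellipse, larger = squarer).
#' @slot enamelColor,stainColor mean RGB triples in [0, 255].
#' @slot enamelSd,stainSd per-channel Gaussian noise sd (truncated to [0,255]).
#' @slot targetFraction plaque fraction of tooth pixels in [0, 1].
#' @slot nBlobs number of plaque regions (>= 1 when targetFraction > 0).
#' @slot placement `"uniform"` or `"proximal"` (concentrated near the
#'   mesial/distal tooth margins).
#' @slot illumination `"homogeneous"` or `"gradient"`.
#' @slot gradientStrength brightness falloff in [0, 1] across the x axis
#'   (used when illumination is `"gradient"`).
#' @slot seed integer RNG seed; identical specs give byte-identical scenes.
#'
#' @seealso [sceneSpec()], [generateScene()]
#' @export
setClass("SyntheticSceneSpec", representation(
  width = "integer", height = "integer",
  toothSemiAxes = "numeric", toothExponent = "numeric",
  enamelColor = "numeric", enamelSd = "numeric",
  stainColor = "numeric", stainSd = "numeric",
  targetFraction = "numeric", nBlobs = "integer",
  placement = "character", illumination = "character",
  gradientStrength = "numeric", seed = "integer"))

setValidity("SyntheticSceneSpec", function(object) {
  if (object@width < 8L || object@height < 8L)
    return("canvas must be at least 8 x 8")
  if (length(object@toothSemiAxes) != 2L || any(object@toothSemiAxes <= 0))
    return("toothSemiAxes must be two positive semi-axes")
  if (object@toothExponent <= 0) return("toothExponent must be positive")
  for (nm in c("enamelColor", "stainColor")) {
    v <- slot(object, nm)
    if (length(v) != 3L || any(v < 0) || any(v > 255))
      return(sprintf("%s must be an RGB triple in [0, 255]", nm))
  }
  if (object@targetFraction < 0 || object@targetFraction > 1)
    return("targetFraction must lie in [0, 1]")
  if (object@targetFraction > 0 && object@nBlobs < 1L)
    return("nBlobs must be >= 1 when targetFraction > 0")
  if (!object@placement %in% c("uniform", "proximal"))
    return("placement must be \"uniform\" or \"proximal\"")
  if (!object@illumination %in% c("homogeneous", "gradient"))
    return("illumination must be \"homogeneous\" or \"gradient\"")
  if (object@gradientStrength < 0 || object@gradientStrength > 1)
    return("gradientStrength must lie in [0, 1]")
  TRUE
})

#' SyntheticScene: generated image plus pixel-level ground truth
#'
#' @slot image a [RasterImage-class].
#' @slot truthMask integer matrix of ground-truth labels (same coding as
#'   [PixelClassMap-class]).
#'
#' The realized plaque fraction is not stored: [realizedFraction()] recomputes
#' it from the truth mask so it can never go stale.
#'
#' @seealso [generateScene()], [renderCameraView()], [realizedFraction()]
#' @export
setClass("SyntheticScene", representation(
  image = "RasterImage", truthMask = "matrix"))

setValidity("SyntheticScene", function(object) {
  d <- dim(object@image@pixels)
  if (!identical(dim(object@truthMask), d[1:2]))
    return("truth mask dimensions must match the image")
  if (!is.integer(object@truthMask) || !all(object@truthMask %in% .labelNames))
    return("truth mask labels must be 0/1/2")
  TRUE
})

#' CameraRenderSpec: camera-style degradation of a scene
#'
#' Emulates two ways an intraoral-camera photograph differs from a
#' scanner-rendered view: uneven brightness (a multiplicative lateral
#' gradient) and convexity foreshortening that hides a proximal strip of the
#' tooth at each mesial/distal margin. Both parameters at 0 give the identity
#' transform.
#'
#' @slot gradientStrength brightness falloff in [0, 1] across the image.
#' @slot proximalCropFraction fraction in [0, 0.4) of the tooth width removed
#'   at each lateral margin.
#' @slot seed integer seed (reserved; the transform is deterministic).
#'
#' @seealso [cameraRenderSpec()], [renderCameraView()]
#' @export
setClass("CameraRenderSpec", representation(
  gradientStrength = "numeric", proximalCropFraction = "numeric",
  seed = "integer"))

setValidity("CameraRenderSpec", function(object) {
  if (object@gradientStrength < 0 || object@gradientStrength > 1)
    return("gradientStrength must lie in [0, 1]")
  if (object@proximalCropFraction < 0)
    return("proximalCropFraction must be >= 0")
  if (object@proximalCropFraction >= 0.5)
    return("proximalCropFraction >= 0.5 removes the whole tooth")
  TRUE
})

#' PairedSeries: paired two-method measurements
#'
#' Holds one measurement per unit from each of two methods; by convention
#' \code{valuesA} is the reference method (the camera P%C role) and
#' \code{valuesB} the test method (the scan P%S role).
#'
#' @slot ids character unit labels, unique.
#' @slot valuesA,valuesB numeric measurements, equal length >= 3.
#'
#' @seealso [pairedSeries()], [blandAltman()]
#' @export
setClass("PairedSeries", representation(
  ids = "character", valuesA = "numeric", valuesB = "numeric"))

setValidity("PairedSeries", function(object) {
  n <- length(object@ids)
  if (n < 3L) return("need at least 3 pairs")
  if (length(object@valuesA) != n || length(object@valuesB) != n)
    return("ids, valuesA and valuesB must have equal length")
  if (anyDuplicated(object@ids)) return("ids must be unique")
  if (anyNA(object@valuesA) || anyNA(object@valuesB))
    return("missing values are not allowed")
  TRUE
})

#' BlandAltmanResult: agreement between two measurement methods
#'
#' Bias is the mean of the per-pair differences (reference minus test; on the
#' log scale a mean log ratio), the limits of agreement are
#' bias +/- 1.96 * sd of the differences, the systematic-bias p-value is a
#' one-sample t-test of the differences against 0, and proportional bias is
#' the slope of regressing differences on pairwise means.
#'
#' @slot scale `"raw"` or `"log"`.
#' @slot n number of pairs.
#' @slot bias,sdDiff,loaLow,loaHigh agreement summary.
#' @slot systematicBiasP one-sample t p-value (NA when sdDiff = 0).
#' @slot proportionalSlope,proportionalP regression slope of differences on
#'   means and its p-value.
#'
#' @seealso [blandAltman()]
#' @export
setClass("BlandAltmanResult", representation(
  scale = "character", n = "integer", bias = "numeric", sdDiff = "numeric",
  loaLow = "numeric", loaHigh = "numeric", systematicBiasP = "numeric",
  proportionalSlope = "numeric", proportionalP = "numeric"))

setValidity("BlandAltmanResult", function(object) {
  if (object@loaLow > object@bias || object@bias > object@loaHigh)
    return("limits of agreement must bracket the bias")
  TRUE
})

#' ICCResult: intraclass correlation, single rating, absolute agreement
#'
#' ICC(A,1) under a two-way mixed-effects model, with the two-way ANOVA mean
#' squares it was computed from and a 95% F-based confidence interval.
#'
#' @slot icc estimate in [-1, 1].
#' @slot ciLow,ciHigh 95% confidence bounds.
#' @slot msRows,msCols,msError two-way ANOVA mean squares (subjects, raters,
#'   residual).
#' @slot nSubjects,nRaters design size.
#' @slot model model tag.
#'
#' @seealso [iccA1()]
#' @export
setClass("ICCResult", representation(
  icc = "numeric", ciLow = "numeric", ciHigh = "numeric",
  msRows = "numeric", msCols = "numeric", msError = "numeric",
  nSubjects = "integer", nRaters = "integer", model = "character"))

#' HypothesisTestResult: a generic test outcome
#'
#' @slot method test name.
#' @slot statistic test statistic.
#' @slot pValue two-sided p-value in [0, 1].
#' @slot n effective sample size (for the Wilcoxon test, the number of
#'   nonzero differences).
#' @slot exact logical; TRUE when an exact null distribution was enumerated.
#' @slot alphaAdjusted Bonferroni-adjusted significance level when one
#'   applies, otherwise NA.
#'
#' @export
setClass("HypothesisTestResult", representation(
  method = "character", statistic = "numeric", pValue = "numeric",
  n = "integer", exact = "logical", alphaAdjusted = "numeric"))

setValidity("HypothesisTestResult", function(object) {
  p <- object@pValue
  if (!is.na(p) && (p < 0 || p > 1)) return("p-value must lie in [0, 1]")
  TRUE
})

#' BootstrapCI: percentile bootstrap confidence interval for a median
#'
#' Simple (uniform with replacement) resampling; the interval is the
#' 2.5/97.5 percentile of the resample medians.
#'
#' @slot point sample median.
#' @slot ciLow,ciHigh percentile bounds.
#' @slot nBoot number of resamples.
#' @slot seed RNG seed used.
#' @slot sampling sampling tag, always `"simple"`.
#'
#' @seealso [bootstrapMedianCI()]
#' @export
setClass("BootstrapCI", representation(
  point = "numeric", ciLow = "numeric", ciHigh = "numeric",
  nBoot = "integer", seed = "integer", sampling = "character"))

setValidity("BootstrapCI", function(object) {
  if (object@ciLow > object@ciHigh)
    return("ciLow must not exceed ciHigh")
  TRUE
})

#' StudySummary: site- and subject-level study tables
#'
#' @slot siteTable per-(tooth, surface, timepoint) medians with bootstrap CI,
#'   min and max, plus the pooled "All" rows.
#' @slot subjectTable per-(surface, timepoint) medians of subject means with
#'   bootstrap CI.
#' @slot changes overall percent changes between consecutive timepoints.
#' @slot tests timepoint comparison results with adjusted alphas.
#'
#' @seealso [summarizeStudy()]
#' @export
setClass("StudySummary", representation(
  siteTable = "data.frame", subjectTable = "data.frame",
  changes = "data.frame", tests = "data.frame"))

#' ReproducibilityReport: blinded re-evaluation agreement
#'
#' @slot medianDiff [BootstrapCI-class] of the per-site first-minus-second
#'   differences.
#' @slot minDiff,maxDiff range of the differences.
#' @slot icc [ICCResult-class] on the two-column rating matrix.
#' @slot n number of paired sites.
#'
#' @seealso [reproducibilityReport()]
#' @export
setClass("ReproducibilityReport", representation(
  medianDiff = "BootstrapCI", minDiff = "numeric", maxDiff = "numeric",
  icc = "ICCResult", n = "integer"))
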