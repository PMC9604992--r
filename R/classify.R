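#' Create a threshold configuration
#'
#' The classifier applies two filters. The first removes the black background
#' matte: a pixel is background when every channel is \code{<= blackTol}
#' (with the default \code{blackTol = 0} this is the exact RGB = (0,0,0)
#' rule). The second labels the remaining tooth pixels as plaque when each
#' channel is at or above its threshold; green and blue default to 0 so the
#' red threshold alone decides, which is the standard calibration for
#' red-stained (disclosed) plaque.
#'
#' @param redMin red threshold; channel units in [0, 256] for `"raw"` mode,
#'   a proportion in [0, 1] for `"normalized"` mode.
#' @param greenMin,blueMin green/blue thresholds, default 0.
#' @param channelMode `"raw"` compares the 8-bit channels directly;
#'   `"normalized"` divides each channel by the pixel's R+G+B sum first, which
#'   makes the rule invariant to multiplicative brightness changes.
#' @param blackTol background tolerance per channel (0 = exact black; 8 is a
#'   practical value for JPEG input).
#' @return a [ThresholdConfig-class].
#' @examples
#' cfg <- thresholdConfig(redMin = 120)
#' @export
thresholdConfig <- function(redMin, greenMin = 0, blueMin = 0,
                            channelMode = c("raw", "normalized"),
                            blackTol = 0) {
  channelMode <- match.arg(channelMode)
  new("ThresholdConfig", redMin = as.numeric(redMin),
      greenMin = as.numeric(greenMin), blueMin = as.numeric(blueMin),
      channelMode = channelMode, blackTol = as.numeric(blackTol))
}

setMethod("show", "ThresholdConfig", function(object) {
  cat(sprintf(
    "ThresholdConfig: R >= %g, G >= %g, B >= %g (%s channels, blackTol %g)\n",
    object@redMin, object@greenMin, object@blueMin, object@channelMode,
    object@blackTol))
})

#' Classify every pixel of a tooth image
#'
#' Applies the two-filter rule of [thresholdConfig()] to each pixel:
#' background where all channels are within \code{blackTol} of 0, then plaque
#' among the remaining pixels where red, green and blue are all at or above
#' their thresholds (inclusive), otherwise tooth_clean. Classification is
#' total: every pixel receives exactly one label.
#'
#' @param image a [RasterImage-class].
#' @param config a [ThresholdConfig-class].
#' @return a [PixelClassMap-class].
#' @seealso [measurePlaque()], [renderOverlay()], [labelCounts()]
#' @export
classifyPixels <- function(image, config) {
  stopifnot(is(image, "RasterImage"), is(config, "ThresholdConfig"))
  validObject(config)
  px <- image@pixels
  r <- px[, , 1L, drop = TRUE]
  g <- px[, , 2L, drop = TRUE]
  b <- px[, , 3L, drop = TRUE]
  if (is.null(dim(r))) { d <- dim(px)[1:2]; dim(r) <- dim(g) <- dim(b) <- d }
  bg <- r <= config@blackTol & g <= config@blackTol & b <= config@blackTol
  if (config@channelMode == "normalized") {
    s <- r + g + b
    s[s == 0L] <- 1L                   # only exact black; always background
    rc <- r / s; gc <- g / s; bc <- b / s
  } else {
    rc <- r; gc <- g; bc <- b
  }
  plaque <- !bg & rc >= config@redMin & gc >= config@greenMin &
    bc >= config@blueMin
  labels <- matrix(.LBL_CLEAN, nrow = nrow(r), ncol = ncol(r))
  labels[bg] <- .LBL_BACKGROUND
  labels[plaque] <- .LBL_PLAQUE
  storage.mode(labels) <- "integer"
  new("PixelClassMap", labels = labels)
}

#' Label counts of a classification
#'
#' @param x a [PixelClassMap-class] or a truth mask from a
#'   [SyntheticScene-class].
#' @return named integer vector with counts for background, plaque and
#'   tooth_clean; the counts always sum to width x height.
#' @export
labelCounts <- function(x) {
  lb <- if (is(x, "PixelClassMap")) x@labels
  else if (is(x, "SyntheticScene")) x@truthMask
  else x
  c(background = sum(lb == .LBL_BACKGROUND),
    plaque = sum(lb == .LBL_PLAQUE),
    tooth_clean = sum(lb == .LBL_CLEAN))
}

setMethod("show", "PixelClassMap", function(object) {
  d <- dim(object@labels)
  cnt <- labelCounts(object)
  cat(sprintf("PixelClassMap %d x %d: %d background, %d plaque, %d clean\n",
              d[2L], d[1L], cnt[["background"]], cnt[["plaque"]],
              cnt[["tooth_clean"]]))
})

.planimetryFromCounts <- function(cnt, method = NA_character_) {
  nTooth <- cnt[["plaque"]] + cnt[["tooth_clean"]]
  if (nTooth == 0L)
    stop("empty crop: image contains no non-background pixels")
  new("PlanimetryResult",
      nTotal = as.integer(sum(cnt)), nBackground = as.integer(cnt[["background"]]),
      nTooth = as.integer(nTooth), nPlaque = as.integer(cnt[["plaque"]]),
      pPercent = 100 * cnt[["plaque"]] / nTooth, method = method)
}

#' Measure the plaque-covered percentage of a tooth image
#'
#' Classifies the image with [classifyPixels()] and reports P%: the
#' percentage of tooth (non-background) pixels labelled plaque,
#' \code{100 * n_plaque / n_tooth}.
#'
#' @param image a [RasterImage-class] with at least one non-background pixel.
#' @param config a [ThresholdConfig-class].
#' @param method optional method alias stored as metadata (`"scan"` for P%S,
#'   `"camera"` for P%C).
#' @return a [PlanimetryResult-class].
#' @examples
#' img <- RasterImage(array(rep(c(0L, 200L, 130L, 90L), 3), dim = c(2, 2, 3)))
#' measurePlaque(img, thresholdConfig(redMin = 120))
#' @export
measurePlaque <- function(image, config, method = NA_character_) {
  cm <- classifyPixels(image, config)
  .planimetryFromCounts(labelCounts(cm), method = method)
}

setMethod("show", "PlanimetryResult", function(object) {
  alias <- if (is.na(object@method)) "P%"
  else if (object@method == "scan") "P%S" else if (object@method == "camera")
    "P%C" else paste0("P% (", object@method, ")")
  cat(sprintf(
    "PlanimetryResult: %s = %.2f  (%d plaque / %d tooth px, %d background)\n",
    alias, object@pPercent, object@nPlaque, object@nTooth, object@nBackground))
})

#' @describeIn measurePlaque coerce a result to a one-row data.frame with the
#'   standard result columns (id, n_total, n_background, n_tooth, n_plaque,
#'   p_percent).
#' @param x a \code{PlanimetryResult}.
#' @param row.names,optional,... ignored, for the generic's signature.
#' @export
as.data.frame.PlanimetryResult <- function(x, row.names = NULL,
                                           optional = FALSE, ...) {
  data.frame(n_total = x@nTotal, n_background = x@nBackground,
             n_tooth = x@nTooth, n_plaque = x@nPlaque,
             p_percent = x@pPercent)
}

#' Render the blue calibration overlay
#'
#' Reproduces the visual-calibration rendering: every tooth pixel below the
#' plaque threshold (tooth_clean) is coloured pure blue (0,0,255), plaque
#' pixels keep their original colour, and the background stays black. The
#' overlay lets an examiner judge whether the demarcation matches the visual
#' impression of the stained area.
#'
#' @param image a [RasterImage-class].
#' @param classmap a matching [PixelClassMap-class].
#' @return a new [RasterImage-class].
#' @export
renderOverlay <- function(image, classmap) {
  stopifnot(is(image, "RasterImage"), is(classmap, "PixelClassMap"))
  if (!identical(dim(image@pixels)[1:2], dim(classmap@labels)))
    stop("image and class map dimensions differ")
  px <- image@pixels
  clean <- classmap@labels == .LBL_CLEAN
  bg <- classmap@labels == .LBL_BACKGROUND
  r <- px[, , 1L]; g <- px[, , 2L]; b <- px[, , 3L]
  r[clean] <- 0L; g[clean] <- 0L; b[clean] <- 255L
  r[bg] <- 0L; g[bg] <- 0L; b[bg] <- 0L
  RasterImage(array(c(r, g, b), dim = dim(px)))
}

#' Sweep the red threshold across an image
#'
#' Programmatic counterpart of the interactive calibration loop: computes P%
#' at each of an ascending sequence of red thresholds with green and blue
#' held at 0. Because the plaque rule is an inclusive lower bound on red,
#' the resulting P% sequence is non-increasing, with P% = 100 at threshold 0
#' and P% = 0 at 256.
#'
#' @param image a [RasterImage-class] with at least one tooth pixel.
#' @param redValues strictly increasing numeric thresholds.
#' @param blackTol background tolerance passed to the classifier.
#' @return a data.frame with columns \code{threshold} and \code{p_percent}.
#' @export
thresholdSweep <- function(image, redValues, blackTol = 0) {
  stopifnot(is(image, "RasterImage"))
  if (length(redValues) < 1L || is.unsorted(redValues, strictly = TRUE))
    stop("redValues must be strictly increasing")
  px <- image@pixels
  r <- px[, , 1L]; g <- px[, , 2L]; b <- px[, , 3L]
  tooth <- !(r <= blackTol & g <= blackTol & b <= blackTol)
  nTooth <- sum(tooth)
  if (nTooth == 0L) stop("empty crop: image contains no non-background pixels")
  red <- r[tooth]
  p <- vapply(redValues, function(t) 100 * sum(red >= t) / nTooth, numeric(1))
  data.frame(threshold = redValues, p_percent = p)
}

#' Calibrate a red threshold from the image itself
#'
#' Chooses the red threshold by Otsu's criterion on the red-channel histogram
#' of the tooth (non-background) pixels: the cut that maximises the
#' between-class variance of the two resulting groups. On a disclosed-plaque
#' image whose stain and enamel red distributions are separated, this lands
#' in the valley between the two modes — the same place the interactive
#' visual calibration converges to. Used per image in camera mode, where
#' uneven illumination prevents one shared threshold.
#'
#' @param image a [RasterImage-class].
#' @param blackTol background tolerance.
#' @param channelMode `"raw"` or `"normalized"` (see [thresholdConfig()]).
#' @return a [ThresholdConfig-class] with the calibrated \code{redMin}.
#' @export
calibrateRedThreshold <- function(image, blackTol = 0,
                                  channelMode = c("raw", "normalized")) {
  channelMode <- match.arg(channelMode)
  stopifnot(is(image, "RasterImage"))
  px <- image@pixels
  r <- px[, , 1L]; g <- px[, , 2L]; b <- px[, , 3L]
  tooth <- !(r <= blackTol & g <= blackTol & b <= blackTol)
  if (!any(tooth)) stop("empty crop: image contains no non-background pixels")
  if (channelMode == "normalized") {
    s <- (r + g + b)[tooth]
    vals <- round(255 * r[tooth] / s)
  } else {
    vals <- r[tooth]
  }
  h <- tabulate(vals + 1L, nbins = 256L)
  w <- cumsum(h)
  m <- cumsum(h * (0:255))
  total <- w[256L]; mtot <- m[256L]
  w0 <- w[1:255]; w1 <- total - w0
  valid <- w0 > 0 & w1 > 0
  mu0 <- m[1:255] / w0
  mu1 <- (mtot - m[1:255]) / w1
  between <- w0 * w1 * (mu0 - mu1)^2
  between[!valid] <- -Inf
  cut <- which.max(between)            # classes {0..cut-1} vs {cut..255}
  redMin <- if (channelMode == "normalized") cut / 255 else cut
  thresholdConfig(redMin = redMin, channelMode = channelMode,
                  blackTol = blackTol)
}

#' Batch-measure a set of tooth images
#'
#' Measures every image with one shared configuration — the scan workflow,
#' where homogeneous scanner illumination lets the same settings serve all
#' images — or with per-image overrides, the camera workflow where the
#' threshold must be adjusted for each photograph individually. An empty crop
#' is reported in the per-id \code{error} column rather than failing the
#' whole batch.
#'
#' @param images named list of [RasterImage-class] objects; names are the
#'   unique image ids.
#' @param config shared [ThresholdConfig-class].
#' @param overrides optional named list of [ThresholdConfig-class] objects
#'   replacing the shared config for those ids.
#' @return a data.frame with columns id, n_total, n_background, n_tooth,
#'   n_plaque, p_percent, error, in input order.
#' @export
batchMeasure <- function(images, config, overrides = NULL) {
  ids <- names(images)
  if (is.null(ids) || any(!nzchar(ids))) stop("images must be a named list")
  if (anyDuplicated(ids)) stop("duplicate image ids")
  if (!is.null(overrides)) {
    bad <- setdiff(names(overrides), ids)
    if (length(bad)) stop("override ids not in batch: ",
                          paste(bad, collapse = ", "))
  }
  rows <- lapply(ids, function(id) {
    cfg <- if (!is.null(overrides) && id %in% names(overrides))
      overrides[[id]] else config
    res <- tryCatch(measurePlaque(images[[id]], cfg), error = identity)
    if (inherits(res, "error"))
      data.frame(id = id, n_total = NA_integer_, n_background = NA_integer_,
                 n_tooth = NA_integer_, n_plaque = NA_integer_,
                 p_percent = NA_real_, error = conditionMessage(res))
    else
      cbind(data.frame(id = id), as.data.frame(res),
            data.frame(error = NA_character_))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
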