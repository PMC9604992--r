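#' Specify a synthetic tooth scene
#'
#' Builds the parameter object for [generateScene()]. The defaults draw a
#' superellipse of whitish enamel on a pure-black matte with red-dominant
#' stain blobs covering a quarter of the tooth under homogeneous, scan-like
#' illumination. The default stain red mean sits 30 channel units above the
#' enamel red mean so that a calibrating raw red threshold exists between the
#' two distributions — the separability a visual calibration of disclosed
#' plaque presumes.
#'
#' @param width,height canvas size in pixels.
#' @param toothSemiAxes superellipse semi-axes (x, y) in pixels; the shape
#'   must fit the canvas with at least a 2-pixel black margin.
#' @param toothExponent superellipse exponent (2 = ellipse; larger values
#'   give the squarer outline of a molar crown).
#' @param enamelColor,enamelSd mean RGB of clean enamel and per-channel
#'   Gaussian noise sd.
#' @param stainColor,stainSd mean RGB of stained plaque and noise sd.
#' @param targetFraction plaque fraction of tooth pixels in [0, 1].
#' @param nBlobs number of plaque regions.
#' @param placement `"uniform"` over the tooth, or `"proximal"` to
#'   concentrate plaque near the mesial/distal (left/right) margins.
#' @param illumination `"homogeneous"` (scan-like) or `"gradient"`
#'   (camera-like lateral brightness falloff).
#' @param gradientStrength falloff in [0, 1] when illumination is
#'   `"gradient"`.
#' @param seed integer RNG seed.
#' @return a [SyntheticSceneSpec-class].
#' @examples
#' sc <- generateScene(sceneSpec(targetFraction = 0.3, seed = 7))
#' realizedFraction(sc)
#' @export
sceneSpec <- function(width = 128L, height = 128L,
                      toothSemiAxes = c(46, 54), toothExponent = 2.5,
                      enamelColor = c(205, 200, 190), enamelSd = 5,
                      stainColor = c(235, 60, 90), stainSd = 5,
                      targetFraction = 0.25, nBlobs = 3L,
                      placement = c("uniform", "proximal"),
                      illumination = c("homogeneous", "gradient"),
                      gradientStrength = 0.35, seed = 1L) {
  new("SyntheticSceneSpec",
      width = as.integer(width), height = as.integer(height),
      toothSemiAxes = as.numeric(toothSemiAxes),
      toothExponent = as.numeric(toothExponent),
      enamelColor = as.numeric(enamelColor), enamelSd = as.numeric(enamelSd),
      stainColor = as.numeric(stainColor), stainSd = as.numeric(stainSd),
      targetFraction = as.numeric(targetFraction), nBlobs = as.integer(nBlobs),
      placement = match.arg(placement),
      illumination = match.arg(illumination),
      gradientStrength = as.numeric(gradientStrength), seed = as.integer(seed))
}

# Union of nBlobs ellipses at global scale s, clipped to the tooth mask.
.blobMask <- function(s, centers, radii, aspect, X, Y, tooth) {
  m <- matrix(FALSE, nrow = nrow(X), ncol = ncol(X))
  for (i in seq_len(nrow(centers))) {
    rx <- s * radii[i]
    ry <- s * radii[i] * aspect[i]
    m <- m | (((X - centers[i, 1L]) / rx)^2 +
              ((Y - centers[i, 2L]) / ry)^2 <= 1)
  }
  m & tooth
}

#' Generate a tooth-on-black scene with ground truth
#'
#' Draws the scene described by a [sceneSpec()]: superellipse tooth, plaque
#' blobs grown or shrunk by a closed-loop area controller until the plaque
#' fraction of tooth pixels is within 0.01 of \code{targetFraction} (exact
#' placement is over-constrained on a pixel grid), Gaussian per-channel
#' colour noise truncated to [0, 255], and an optional lateral brightness
#' gradient. The background is exactly (0,0,0). The same spec (including
#' seed) always yields a byte-identical scene.
#'
#' @param spec a [SyntheticSceneSpec-class].
#' @return a [SyntheticScene-class].
#' @seealso [realizedFraction()], [renderCameraView()]
#' @export
generateScene <- function(spec) {
  stopifnot(is(spec, "SyntheticSceneSpec"))
  validObject(spec)
  w <- spec@width; h <- spec@height
  a <- spec@toothSemiAxes[1L]; b <- spec@toothSemiAxes[2L]
  if (a + 2 >= w / 2 || b + 2 >= h / 2)
    stop("tooth shape exceeds the canvas (needs a >= 2 px black margin)")
  cx <- (w + 1) / 2; cy <- (h + 1) / 2
  X <- matrix(rep(seq_len(w), each = h), nrow = h)   # column coordinate
  Y <- matrix(rep(seq_len(h), times = w), nrow = h)  # row coordinate
  p <- spec@toothExponent
  tooth <- (abs((X - cx) / a)^p + abs((Y - cy) / b)^p) <= 1
  nTooth <- sum(tooth)
  if (nTooth == 0L) stop("tooth shape contains no pixels")

  withSeed(spec@seed, {
    plaque <- matrix(FALSE, h, w)
    if (spec@targetFraction > 0) {
      cand <- if (spec@placement == "proximal")
        which(tooth & abs(X - cx) >= 0.55 * a) else which(tooth)
      if (length(cand) == 0L) stop("no candidate pixels for plaque placement")
      k <- spec@nBlobs
      idx <- cand[sample.int(length(cand), k, replace = k > length(cand))]
      centers <- cbind(X[idx], Y[idx])
      radii <- stats::runif(k, 0.6, 1.4)
      aspect <- stats::runif(k, 0.5, 1.5)
      target <- spec@targetFraction
      frac <- function(s)
        sum(.blobMask(s, centers, radii, aspect, X, Y, tooth)) / nTooth
      hi <- sqrt(target * nTooth / (pi * k))
      while (frac(hi) < target && hi < 2 * (w + h)) hi <- hi * 2
      lo <- 0
      for (it in seq_len(40L)) {
        mid <- (lo + hi) / 2
        if (frac(mid) < target) lo <- mid else hi <- mid
        if (hi - lo < 1e-3) break
      }
      sBest <- hi
      if (abs(frac(lo) - target) < abs(frac(hi) - target)) sBest <- lo
      plaque <- .blobMask(sBest, centers, radii, aspect, X, Y, tooth)
      if (abs(sum(plaque) / nTooth - target) > 0.01)
        stop("infeasible plaque fraction for this blob configuration")
    }
    clean <- tooth & !plaque

    chan <- function(mask, mean, sd) {
      v <- matrix(0, h, w)
      n <- sum(mask)
      if (n > 0L) v[mask] <- mean + stats::rnorm(n, sd = sd)
      v
    }
    arr <- array(0, dim = c(h, w, 3L))
    for (ch in 1:3) {
      arr[, , ch] <- chan(clean, spec@enamelColor[ch], spec@enamelSd) +
        chan(plaque, spec@stainColor[ch], spec@stainSd)
    }
    if (spec@illumination == "gradient" && spec@gradientStrength > 0) {
      scale <- 1 - spec@gradientStrength * (X - 1) / w
      for (ch in 1:3) arr[, , ch] <- arr[, , ch] * scale
    }
    px <- clamp8(arr)
    px[!array(tooth, dim = dim(px))] <- 0L   # matte stays exactly black

    labels <- matrix(.LBL_BACKGROUND, h, w)
    labels[clean] <- .LBL_CLEAN
    labels[plaque] <- .LBL_PLAQUE
    storage.mode(labels) <- "integer"
    new("SyntheticScene", image = RasterImage(px), truthMask = labels)
  })
}

#' Realized plaque fraction of a scene
#'
#' Recomputed from the truth mask on every call (never cached): the ratio of
#' plaque pixels to tooth pixels.
#'
#' @param scene a [SyntheticScene-class].
#' @return fraction in [0, 1].
#' @export
realizedFraction <- function(scene) {
  stopifnot(is(scene, "SyntheticScene"))
  cnt <- labelCounts(scene@truthMask)
  nTooth <- cnt[["plaque"]] + cnt[["tooth_clean"]]
  if (nTooth == 0L) stop("scene has no tooth pixels")
  cnt[["plaque"]] / nTooth
}

setMethod("show", "SyntheticScene", function(object) {
  d <- dim(object@image)
  cat(sprintf("SyntheticScene %d x %d, plaque fraction %.3f\n",
              d[2L], d[1L], realizedFraction(object)))
})

#' Specify a camera-style degradation
#'
#' @param gradientStrength lateral brightness falloff in [0, 1].
#' @param proximalCropFraction fraction in [0, 0.5) of the tooth width hidden
#'   at each mesial/distal margin (convexity foreshortening of a frontal
#'   photograph).
#' @param seed integer seed (reserved; the transform is deterministic).
#' @return a [CameraRenderSpec-class].
#' @export
cameraRenderSpec <- function(gradientStrength = 0, proximalCropFraction = 0,
                             seed = 1L) {
  new("CameraRenderSpec", gradientStrength = as.numeric(gradientStrength),
      proximalCropFraction = as.numeric(proximalCropFraction),
      seed = as.integer(seed))
}

#' Render the camera view of a scene
#'
#' Applies the two camera artefacts to a scan-like scene: pixel brightness is
#' scaled multiplicatively by \code{1 - gradientStrength * x / width} along
#' the x axis, and a strip of \code{proximalCropFraction} of the tooth width
#' at each lateral margin is set to background in both the image and the
#' truth mask — the proximal surfaces a frontal photograph cannot see because
#' of the convexity of the tooth. With both parameters 0 the scene is
#' returned unchanged.
#'
#' @param scene a [SyntheticScene-class].
#' @param cam a [CameraRenderSpec-class].
#' @return a new [SyntheticScene-class]; its [realizedFraction()] reflects
#'   the remaining (visible) tooth pixels.
#' @export
renderCameraView <- function(scene, cam) {
  stopifnot(is(scene, "SyntheticScene"), is(cam, "CameraRenderSpec"))
  validObject(cam)
  px <- scene@image@pixels
  labels <- scene@truthMask
  h <- nrow(labels); w <- ncol(labels)
  if (cam@gradientStrength > 0) {
    scale <- matrix(rep(1 - cam@gradientStrength * (seq_len(w) - 1) / w,
                        each = h), nrow = h)
    arr <- array(0, dim = dim(px))
    for (ch in 1:3) arr[, , ch] <- px[, , ch] * scale
    px <- clamp8(arr)
    px[labels == .LBL_BACKGROUND] <- 0L
  }
  if (cam@proximalCropFraction > 0) {
    toothCols <- which(colSums(labels != .LBL_BACKGROUND) > 0)
    if (length(toothCols) == 0L) stop("scene has no tooth pixels")
    cmin <- min(toothCols); cmax <- max(toothCols)
    nCrop <- floor(cam@proximalCropFraction * (cmax - cmin + 1L))
    if (nCrop > 0L) {
      cropCols <- c(seq(cmin, length.out = nCrop),
                    seq(cmax - nCrop + 1L, length.out = nCrop))
      hide <- matrix(FALSE, h, w)
      hide[, cropCols] <- TRUE
      hide <- hide & labels != .LBL_BACKGROUND
      labels[hide] <- .LBL_BACKGROUND
      px[array(hide, dim = dim(px))] <- 0L
    }
    if (!any(labels != .LBL_BACKGROUND))
      stop("proximal crop removed the whole tooth")
  }
  new("SyntheticScene", image = RasterImage(px), truthMask = labels)
}
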