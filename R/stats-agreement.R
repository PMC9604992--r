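#' Construct a paired two-method series
#'
#' @param valuesA reference-method measurements (the camera P%C role).
#' @param valuesB test-method measurements (the scan P%S role).
#' @param ids unit labels, unique; defaults to the sequence.
#' @return a [PairedSeries-class].
#' @export
pairedSeries <- function(valuesA, valuesB, ids = as.character(seq_along(valuesA))) {
  new("PairedSeries", ids = as.character(ids),
      valuesA = as.numeric(valuesA), valuesB = as.numeric(valuesB))
}

#' Bland-Altman method agreement
#'
#' Agreement analysis of paired two-method measurements: the per-pair
#' differences (reference minus test) are summarised by their mean (bias),
#' sd, and 95% limits of agreement \code{bias +/- 1.96 sd}; a one-sample
#' t-test of the differences against 0 screens for systematic bias, and a
#' least-squares regression of the differences on the pairwise means screens
#' for proportional bias (agreement depending on magnitude). With
#' \code{useLog = TRUE} both series are natural-log transformed before
#' differencing, so the differences are log ratios and the analysis is
#' invariant to a common positive rescaling of both methods — the
#' appropriate scale when raw differences are skewed, as percentage
#' measurements typically are.
#'
#' @param pairs a [PairedSeries-class].
#' @param useLog analyse on the natural-log scale (requires strictly
#'   positive values).
#' @return a [BlandAltmanResult-class].
#' @export
blandAltman <- function(pairs, useLog = FALSE) {
  stopifnot(is(pairs, "PairedSeries"))
  validObject(pairs)
  a <- pairs@valuesA; b <- pairs@valuesB
  if (useLog) {
    if (any(a <= 0) || any(b <= 0))
      stop("log transform requires strictly positive values")
    a <- log(a); b <- log(b)
  }
  d <- a - b
  m <- (a + b) / 2
  n <- length(d)
  bias <- mean(d)
  sdDiff <- stats::sd(d)
  sysP <- if (sdDiff <= 1e-12 * (abs(bias) + 1)) NA_real_ else
    oneSampleT(d, 0)@pValue
  if (stats::var(m) == 0 || sdDiff <= 1e-12 * (abs(bias) + 1)) {
    # constant differences (or constant means): no proportional trend exists
    slope <- 0; slopeP <- NA_real_
  } else {
    fit <- stats::lm(d ~ m)
    cf <- suppressWarnings(summary(fit))$coefficients
    slope <- unname(cf["m", "Estimate"])
    slopeP <- unname(cf["m", "Pr(>|t|)"])
    if (is.nan(slopeP)) slopeP <- NA_real_
  }
  new("BlandAltmanResult",
      scale = if (useLog) "log" else "raw", n = as.integer(n),
      bias = bias, sdDiff = sdDiff,
      loaLow = bias - 1.96 * sdDiff, loaHigh = bias + 1.96 * sdDiff,
      systematicBiasP = sysP, proportionalSlope = slope,
      proportionalP = slopeP)
}

setMethod("show", "BlandAltmanResult", function(object) {
  cat(sprintf(
    paste0("Bland-Altman (%s scale, n = %d)\n",
           "  bias %.4g, LoA [%.4g, %.4g]\n",
           "  systematic bias p = %.4g; proportional slope %.4g (p = %.4g)\n"),
    object@scale, object@n, object@bias, object@loaLow, object@loaHigh,
    object@systematicBiasP, object@proportionalSlope, object@proportionalP))
})

#' Plot a Bland-Altman analysis
#'
#' Differences against pairwise means with the bias (solid) and 95% limits
#' of agreement (broken lines).
#'
#' @param pairs a [PairedSeries-class].
#' @param useLog analyse and plot on the natural-log scale.
#' @param ... passed to [graphics::plot()].
#' @return the [BlandAltmanResult-class], invisibly.
#' @export
plotBlandAltman <- function(pairs, useLog = FALSE, ...) {
  res <- blandAltman(pairs, useLog = useLog)
  a <- pairs@valuesA; b <- pairs@valuesB
  if (useLog) { a <- log(a); b <- log(b) }
  graphics::plot((a + b) / 2, a - b,
                 xlab = if (useLog) "mean of log measurements" else
                   "mean of measurements",
                 ylab = if (useLog) "difference of log measurements" else
                   "difference", ...)
  graphics::abline(h = res@bias, lty = 1)
  graphics::abline(h = c(res@loaLow, res@loaHigh), lty = 2)
  invisible(res)
}

#' Intraclass correlation ICC(A,1)
#'
#' Single-rating, absolute-agreement ICC under a two-way mixed-effects
#' model, computed from the two-way ANOVA mean squares:
#' \deqn{ICC(A,1) = \frac{MS_R - MS_E}{MS_R + (k-1) MS_E + \frac{k}{n}(MS_C - MS_E)}}
#' where \eqn{MS_R}, \eqn{MS_C} and \eqn{MS_E} are the subject, rater and
#' residual mean squares for n subjects and k raters. The 95% confidence
#' interval uses the F-based construction of McGraw and Wong. Absolute
#' agreement charges rater offsets to disagreement: adding a constant to a
#' single rater's column lowers the coefficient, while adding the same
#' constant to every rating leaves it unchanged.
#'
#' @param ratings numeric matrix, n subjects x k raters, no missing cells,
#'   n >= 3 and k >= 2.
#' @param ciLevel confidence level, default 0.95.
#' @return an [ICCResult-class].
#' @export
iccA1 <- function(ratings, ciLevel = 0.95) {
  ratings <- as.matrix(ratings)
  if (anyNA(ratings)) stop("missing cells are not allowed")
  n <- nrow(ratings); k <- ncol(ratings)
  if (n < 3L) stop("need at least 3 subjects")
  if (k < 2L) stop("need at least 2 raters")
  gm <- mean(ratings)
  rowM <- rowMeans(ratings)
  colM <- colMeans(ratings)
  SSR <- k * sum((rowM - gm)^2)
  SSC <- n * sum((colM - gm)^2)
  SST <- sum((ratings - gm)^2)
  SSE <- SST - SSR - SSC
  MSR <- SSR / (n - 1)
  MSC <- SSC / (k - 1)
  MSE <- SSE / ((n - 1) * (k - 1))
  denom <- MSR + (k - 1) * MSE + (k / n) * (MSC - MSE)
  if (abs(denom) < .Machine$double.eps * max(1, abs(MSR)))
    stop("zero total variance: ICC undefined")
  icc <- (MSR - MSE) / denom

  alpha <- 1 - ciLevel
  if (MSE <= 0 && MSC <= 0) {
    ciLow <- ciHigh <- icc              # degenerate: identical rater columns
  } else {
    aa <- (k * icc) / (n * (1 - icc))
    bb <- 1 + (k * icc * (n - 1)) / (n * (1 - icc))
    if (!is.finite(aa) || !is.finite(bb)) {
      ciLow <- ciHigh <- icc
    } else {
      v <- (aa * MSC + bb * MSE)^2 /
        ((aa * MSC)^2 / (k - 1) + (bb * MSE)^2 / ((n - 1) * (k - 1)))
      FL <- stats::qf(1 - alpha / 2, n - 1, v)
      FU <- stats::qf(1 - alpha / 2, v, n - 1)
      ciLow <- n * (MSR - FL * MSE) /
        (FL * (k * MSC + (k * n - k - n) * MSE) + n * MSR)
      ciHigh <- n * (FU * MSR - MSE) /
        (k * MSC + (k * n - k - n) * MSE + n * FU * MSR)
    }
  }
  new("ICCResult", icc = icc, ciLow = ciLow, ciHigh = ciHigh,
      msRows = MSR, msCols = MSC, msError = MSE,
      nSubjects = as.integer(n), nRaters = as.integer(k),
      model = "two-way mixed, single rating, absolute agreement")
}

setMethod("show", "ICCResult", function(object) {
  cat(sprintf("ICC(A,1) = %.4f (95%% CI %.4f; %.4f), %d subjects x %d raters\n  %s\n",
              object@icc, object@ciLow, object@ciHigh, object@nSubjects,
              object@nRaters, object@model))
})
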