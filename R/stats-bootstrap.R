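#' Percentile bootstrap confidence interval for a median
#'
#' Draws \code{nBoot} simple resamples (uniform, with replacement, size n)
#' and takes the 2.5 and 97.5 percentiles of the resample medians as the
#' 95% interval. The non-Gaussian, bounded P% distributions of plaque data
#' make this the interval of choice for their medians. Deterministic under
#' the given seed; constant input collapses the interval to the constant.
#'
#' @param values numeric series, n >= 2.
#' @param nBoot number of resamples (default 2000).
#' @param seed integer RNG seed.
#' @param level confidence level, default 0.95.
#' @return a [BootstrapCI-class].
#' @examples
#' bootstrapMedianCI(c(2.1, 3.5, 4.2, 5.9, 8.0), seed = 42)
#' @export
bootstrapMedianCI <- function(values, nBoot = 2000L, seed = 1L,
                              level = 0.95) {
  n <- length(values)
  if (n < 2L) stop("need at least 2 observations")
  nBoot <- as.integer(nBoot)
  meds <- withSeed(seed, {
    idx <- matrix(sample.int(n, n * nBoot, replace = TRUE), nrow = n)
    apply(matrix(values[idx], nrow = n), 2L, stats::median)
  })
  alpha <- 1 - level
  q <- stats::quantile(meds, c(alpha / 2, 1 - alpha / 2), names = FALSE)
  new("BootstrapCI", point = stats::median(values),
      ciLow = q[1L], ciHigh = q[2L], nBoot = nBoot,
      seed = as.integer(seed), sampling = "simple")
}

setMethod("show", "BootstrapCI", function(object) {
  cat(sprintf("median %.4g (95%% bootstrap CI %.4g; %.4g, %d resamples, %s sampling)\n",
              object@point, object@ciLow, object@ciHigh, object@nBoot,
              object@sampling))
})
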