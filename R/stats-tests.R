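.testResult <- function(method, statistic, pValue, n, exact = NA,
                        alphaAdjusted = NA_real_) {
  new("HypothesisTestResult", method = method,
      statistic = as.numeric(statistic), pValue = as.numeric(pValue),
      n = as.integer(n), exact = as.logical(exact),
      alphaAdjusted = as.numeric(alphaAdjusted))
}

setMethod("show", "HypothesisTestResult", function(object) {
  cat(sprintf("%s: statistic = %.4g, p = %.4g (n = %d%s)%s\n",
              object@method, object@statistic, object@pValue, object@n,
              if (isTRUE(object@exact)) ", exact" else "",
              if (!is.na(object@alphaAdjusted))
                sprintf(", adjusted alpha = %.4g", object@alphaAdjusted)
              else ""))
})

#' One-sample t-test
#'
#' Tests whether the mean of a series equals \code{mu0}:
#' \code{t = (mean - mu0) / (sd / sqrt(n))} with n - 1 degrees of freedom,
#' two-sided. Used to detect a systematic bias in the mean of paired-method
#' differences.
#'
#' @param values numeric series, n >= 2, nonzero variance.
#' @param mu0 null-hypothesis mean.
#' @return a [HypothesisTestResult-class].
#' @export
oneSampleT <- function(values, mu0 = 0) {
  n <- length(values)
  if (n < 2L) stop("need at least 2 observations")
  s <- stats::sd(values)
  if (s == 0) stop("zero variance: t statistic undefined")
  t <- (mean(values) - mu0) / (s / sqrt(n))
  p <- 2 * stats::pt(-abs(t), df = n - 1)
  .testResult("one-sample t", t, p, n)
}

#' Spearman rank correlation
#'
#' Computes rho as the product-moment correlation of the two rank vectors
#' (average ranks for ties) with a two-sided p-value from the t
#' approximation \code{t = rho * sqrt((n-2)/(1-rho^2))}.
#'
#' @param x,y numeric series of equal length >= 3; neither may be constant.
#' @return a [HypothesisTestResult-class] with rho as the statistic.
#' @export
spearmanRho <- function(x, y) {
  n <- length(x)
  if (length(y) != n) stop("series lengths differ")
  if (n < 3L) stop("need at least 3 pairs")
  if (length(unique(x)) == 1L || length(unique(y)) == 1L)
    stop("constant series: rank correlation undefined")
  rx <- rank(x); ry <- rank(y)
  rho <- sum((rx - mean(rx)) * (ry - mean(ry))) /
    sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
  if (abs(rho) >= 1) {
    p <- 0
  } else {
    t <- rho * sqrt((n - 2) / (1 - rho^2))
    p <- 2 * stats::pt(-abs(t), df = n - 2)
  }
  .testResult("Spearman rank correlation", rho, p, n)
}

# Exact null distribution of the doubled signed-rank statistic by dynamic
# programming: counts[w + 1] = number of sign assignments with sum w.
.signedRankNullCounts <- function(ranks2) {
  total <- sum(ranks2)
  counts <- numeric(total + 1L)
  counts[1L] <- 1
  for (r in ranks2) {
    shifted <- c(numeric(r), counts[seq_len(total + 1L - r)])
    counts <- counts + shifted
  }
  counts
}

#' Wilcoxon signed-rank test for paired series
#'
#' Two-sided paired test on the differences \code{valuesA - valuesB}. Zero
#' differences are dropped (classic signed-rank policy); absolute
#' differences are ranked with average ranks for ties. In exact mode the
#' full null distribution over all 2^m sign assignments of the m nonzero
#' differences is computed (ties included); the approximate mode uses the
#' normal approximation with continuity correction and the tie correction
#' to the variance. Mode `"auto"` is exact for m <= 20.
#'
#' @param valuesA,valuesB paired numeric series of equal length.
#' @param zeroPolicy only `"drop"` is provided.
#' @param mode `"auto"`, `"exact"` or `"approx"`.
#' @return a [HypothesisTestResult-class]; the statistic is V, the sum of
#'   ranks of the positive differences, and \code{n} the number of nonzero
#'   differences.
#' @export
wilcoxonSignedRank <- function(valuesA, valuesB = NULL,
                               zeroPolicy = c("drop"),
                               mode = c("auto", "exact", "approx")) {
  zeroPolicy <- match.arg(zeroPolicy)
  mode <- match.arg(mode)
  d <- if (is.null(valuesB)) valuesA else {
    if (length(valuesA) != length(valuesB)) stop("series lengths differ")
    valuesA - valuesB
  }
  d <- d[d != 0]
  m <- length(d)
  if (m == 0L) stop("no nonzero pairs")
  r <- rank(abs(d))
  W <- sum(r[d > 0])
  exact <- switch(mode, exact = TRUE, approx = FALSE, auto = m <= 20L)
  if (exact) {
    ranks2 <- as.integer(round(2 * r))
    counts <- .signedRankNullCounts(ranks2)
    w2 <- as.integer(round(2 * W))
    totalAssignments <- 2^m
    pLess <- sum(counts[seq_len(w2 + 1L)]) / totalAssignments
    pGreater <- sum(counts[seq.int(w2 + 1L, length(counts))]) /
      totalAssignments
    p <- min(1, 2 * min(pLess, pGreater))
  } else {
    mu <- m * (m + 1) / 4
    tie <- table(r)
    sigma2 <- m * (m + 1) * (2 * m + 1) / 24 - sum(tie^3 - tie) / 48
    if (sigma2 <= 0) stop("all absolute differences tied at a single value")
    z <- (W - mu - 0.5 * sign(W - mu)) / sqrt(sigma2)
    if (W == mu) z <- 0
    p <- 2 * stats::pnorm(-abs(z))
    p <- min(1, p)
  }
  .testResult("Wilcoxon signed rank", W, p, m, exact = exact)
}

# One-sample KS statistic against N(mean(x), sd(x)).
.ksStatNormal <- function(x) {
  n <- length(x)
  z <- sort(stats::pnorm(x, mean = mean(x), sd = stats::sd(x)))
  max(seq_len(n) / n - z, z - (seq_len(n) - 1) / n)
}

#' Kolmogorov-Smirnov normality screen
#'
#' One-sample KS test of a series against a normal distribution with the
#' sample mean and sd. The default p-value uses the asymptotic KS
#' distribution, matching common statistics-package behaviour, but note that
#' with estimated parameters this p is anti-conservative (the Lilliefors
#' caveat): true deviations from normality are flagged less often than the
#' nominal level suggests. The `"monte_carlo"` method draws the Lilliefors
#' null distribution by simulation instead.
#'
#' @param values numeric series, n >= 5, nonzero variance.
#' @param method `"asymptotic"` or `"monte_carlo"`.
#' @param nSim Monte-Carlo replicates.
#' @param seed RNG seed for the Monte-Carlo method.
#' @return a [HypothesisTestResult-class] with the KS D statistic.
#' @export
ksNormality <- function(values, method = c("asymptotic", "monte_carlo"),
                        nSim = 2000L, seed = 1L) {
  method <- match.arg(method)
  n <- length(values)
  if (n < 5L) stop("need at least 5 observations")
  if (stats::sd(values) == 0) stop("constant input")
  if (method == "asymptotic") {
    kt <- suppressWarnings(
      stats::ks.test(values, "pnorm", mean(values), stats::sd(values)))
    .testResult("Kolmogorov-Smirnov normality (asymptotic)",
                kt$statistic, kt$p.value, n)
  } else {
    D <- .ksStatNormal(values)
    Dnull <- withSeed(seed, vapply(seq_len(nSim), function(i)
      .ksStatNormal(stats::rnorm(n)), numeric(1)))
    p <- (1 + sum(Dnull >= D)) / (nSim + 1)
    .testResult("Kolmogorov-Smirnov normality (Lilliefors Monte-Carlo)",
                D, p, n)
  }
}

#' Bonferroni-adjusted significance level
#'
#' @param baseAlpha family-wise level in (0, 1).
#' @param m number of comparisons (>= 1).
#' @return \code{baseAlpha / m}. With a base level of 0.05, m = 6 gives
#'   0.00833 (reported rounded as .008) and m = 24 gives 0.00208 (.002).
#' @export
bonferroniAlpha <- function(baseAlpha, m) {
  if (baseAlpha <= 0 || baseAlpha >= 1) stop("baseAlpha must be in (0, 1)")
  if (m < 1) stop("m must be >= 1")
  baseAlpha / m
}
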