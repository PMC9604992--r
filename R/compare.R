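#' Bonferroni-adjusted Wilcoxon timepoint comparisons
#'
#' Paired Wilcoxon signed-rank tests of T1 vs T2 and T2 vs T3.
#' At \code{level = "subject"} the units are the per-subject surface means
#' (one test per surface and comparison; default m = 6 comparisons, adjusted
#' alpha .0083, reported rounded .008). At \code{level = "site"} the units
#' are subjects within each (tooth, surface) site (12 sites x 2 comparisons;
#' default m = 24, adjusted alpha .0021, reported .002).
#' \code{"oral_vs_vestibular_subject"} instead compares the oral against the
#' vestibular subject means at each timepoint (m = 3). The divisors are the
#' ones consistent with those adjusted levels and can be overridden.
#'
#' @param records validated records; scan measurements only.
#' @param level `"subject"`, `"site"` or `"oral_vs_vestibular_subject"`.
#' @param baseAlpha family-wise level, default 0.05.
#' @param m Bonferroni divisor; defaults to 6, 24 or 3 by level.
#' @param mode Wilcoxon mode, see [wilcoxonSignedRank()].
#' @return data.frame with columns level, unit, comparison, n, statistic,
#'   p_value, alpha_adjusted, significant.
#' @export
compareTimepoints <- function(records,
                              level = c("subject", "site",
                                        "oral_vs_vestibular_subject"),
                              baseAlpha = 0.05, m = NULL,
                              mode = c("auto", "exact", "approx")) {
  level <- match.arg(level)
  mode <- match.arg(mode)
  records <- validateRecords(records)
  if (is.null(m))
    m <- switch(level, subject = 6L, site = 24L,
                oral_vs_vestibular_subject = 3L)
  alpha <- bonferroniAlpha(baseAlpha, m)

  pairTest <- function(a, b, unit, comparison) {
    if (length(a) != length(b)) stop("unpaired units for ", unit)
    if (length(a) < 2L) stop("need at least 2 paired units for ", unit)
    ht <- wilcoxonSignedRank(a, b, mode = mode)
    data.frame(level = level, unit = unit, comparison = comparison,
               n = ht@n, statistic = ht@statistic, p_value = ht@pValue,
               alpha_adjusted = alpha, significant = ht@pValue <= alpha)
  }
  wide <- function(df, valueCol = "p_percent") {
    # subjects x timepoints, aligned
    sp <- split(df[[valueCol]], df$timepoint)
    ids <- split(df$subject_id, df$timepoint)
    for (tp in names(sp)) {
      o <- order(ids[[tp]]); sp[[tp]] <- sp[[tp]][o]; ids[[tp]] <- ids[[tp]][o]
    }
    if (!all(vapply(ids, identical, logical(1), ids[[1L]])))
      stop("unpaired subjects across timepoints")
    sp
  }

  rows <- list()
  if (level == "subject") {
    for (sf in .SURFACES) {
      mm <- .subjectMeans(records, sf)
      sp <- wide(mm, "mean_p")
      rows <- c(rows, list(
        pairTest(sp$T1, sp$T2, sf, "T1 vs T2"),
        pairTest(sp$T2, sp$T3, sf, "T2 vs T3")))
    }
  } else if (level == "site") {
    sel <- records[records$method == "scan", ]
    for (sf in .SURFACES) for (tt in .RAMFJORD) {
      g <- sel[sel$surface == sf & sel$tooth == tt, ]
      if (nrow(g) == 0L) stop("no records for site ", tt, "/", sf)
      sp <- wide(g)
      unit <- paste0(tt, "/", sf)
      rows <- c(rows, list(
        pairTest(sp$T1, sp$T2, unit, "T1 vs T2"),
        pairTest(sp$T2, sp$T3, unit, "T2 vs T3")))
    }
  } else {
    mv <- .subjectMeans(records, "vestibular")
    mo <- .subjectMeans(records, "oral")
    spv <- wide(mv, "mean_p"); spo <- wide(mo, "mean_p")
    for (tp in .TIMEPOINTS)
      rows <- c(rows, list(
        pairTest(spo[[tp]], spv[[tp]], tp, "oral vs vestibular")))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Method agreement between scan and camera measurements
#'
#' Restricted to the sites where both methods exist (vestibular surfaces of
#' teeth 16 and 36): pairs the scan (P%S) and camera (P%C) values per
#' (subject, timepoint) and runs, per tooth, a log-scale Bland-Altman
#' analysis with the camera as reference (differences are camera minus scan
#' log values, so plaque reading higher on the scan gives a negative bias)
#' and a Spearman rank correlation between the two methods.
#'
#' @param records validated records containing both methods.
#' @param useLog analyse agreement on the natural-log scale (default TRUE).
#' @return named list (by tooth) of lists with elements \code{blandAltman}
#'   ([BlandAltmanResult-class]), \code{spearman}
#'   ([HypothesisTestResult-class]) and \code{n}.
#' @export
methodAgreementReport <- function(records, useLog = TRUE) {
  records <- validateRecords(records)
  out <- list()
  for (tt in c("16", "36")) {
    g <- records[records$tooth == tt & records$surface == "vestibular", ]
    scan <- g[g$method == "scan", ]
    cam <- g[g$method == "camera", ]
    key <- function(df) paste(df$subject_id, df$timepoint, sep = "|")
    ks <- key(scan); kc <- key(cam)
    if (length(kc) == 0L) stop("no camera records for tooth ", tt)
    if (!setequal(ks, kc) || length(ks) != length(kc))
      stop("scan/camera pairs incomplete for tooth ", tt)
    cam <- cam[match(ks, kc), ]
    pairs <- pairedSeries(valuesA = cam$p_percent, valuesB = scan$p_percent,
                          ids = ks)
    out[[tt]] <- list(blandAltman = blandAltman(pairs, useLog = useLog),
                      spearman = spearmanRho(scan$p_percent, cam$p_percent),
                      n = length(ks))
  }
  out
}

#' Reproducibility of a blinded re-evaluation
#'
#' Agreement between a first and a second, blinded evaluation of the same
#' material: per-site differences (first minus second) summarised by their
#' median with a percentile bootstrap 95% CI and their range, plus ICC(A,1)
#' on the two-column rating matrix. Identical repeats give a median
#' difference of 0 and ICC 1.
#'
#' @param first,second record data.frames with identical
#'   (subject, tooth, surface, timepoint, method) key sets.
#' @param nBoot,seed bootstrap settings.
#' @return a [ReproducibilityReport-class].
#' @export
reproducibilityReport <- function(first, second, nBoot = 2000L, seed = 1L) {
  first <- validateRecords(first)
  second <- validateRecords(second)
  key <- function(df) paste(df$subject_id, df$tooth, df$surface,
                            df$timepoint, df$method, sep = "|")
  k1 <- key(first); k2 <- key(second)
  if (!setequal(k1, k2) || length(k1) != length(k2))
    stop("first and second evaluations must cover identical sites")
  second <- second[match(k1, k2), ]
  d <- first$p_percent - second$p_percent
  ci <- bootstrapMedianCI(d, nBoot = nBoot, seed = seed)
  icc <- iccA1(cbind(first = first$p_percent, second = second$p_percent))
  new("ReproducibilityReport", medianDiff = ci, minDiff = min(d),
      maxDiff = max(d), icc = icc, n = length(d))
}

setMethod("show", "ReproducibilityReport", function(object) {
  cat(sprintf(
    paste0("ReproducibilityReport (%d sites)\n",
           "  median difference %.3g (95%% CI %.3g; %.3g), range [%.3g, %.3g]\n"),
    object@n, object@medianDiff@point, object@medianDiff@ciLow,
    object@medianDiff@ciHigh, object@minDiff, object@maxDiff))
  show(object@icc)
})
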