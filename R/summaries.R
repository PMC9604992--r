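# Per-subject means of the six per-tooth P% values of one surface.
# Errors when any subject misses a tooth at a timepoint: missing sites must
# never be silently averaged over.
.subjectMeans <- function(records, surface) {
  records <- validateRecords(records)
  sel <- records[records$method == "scan" & records$surface == surface, ]
  if (nrow(sel) == 0L) stop("empty selection for surface ", surface)
  out <- do.call(rbind, lapply(split(sel, sel[c("subject_id", "timepoint")],
                                     drop = TRUE), function(g) {
    missing <- setdiff(.RAMFJORD, g$tooth)
    if (length(missing))
      stop(sprintf("subject %s, %s surface, %s: missing teeth %s",
                   g$subject_id[1L], surface, g$timepoint[1L],
                   paste(missing, collapse = ", ")))
    data.frame(subject_id = g$subject_id[1L], timepoint = g$timepoint[1L],
               mean_p = mean(g$p_percent))
  }))
  rownames(out) <- NULL
  out[order(out$subject_id, out$timepoint), ]
}

#' Subject-level plaque summary
#'
#' The total plaque amount of each subject is the arithmetic mean of the six
#' per-tooth P% values of the requested surface, computed separately for the
#' vestibular and oral surfaces. Across subjects, each timepoint is
#' summarised by the median of these subject means with a percentile
#' bootstrap 95% CI.
#'
#' @param records validated records (see [validateRecords()]); only scan
#'   measurements enter the whole-mouth summary.
#' @param surface `"vestibular"` or `"oral"`.
#' @param nBoot,seed bootstrap settings, see [bootstrapMedianCI()].
#' @return list with \code{subjectMeans} (subject_id, timepoint, mean_p) and
#'   \code{timepointSummary} (timepoint, n, median, ci_low, ci_high).
#' @export
subjectLevelSummary <- function(records, surface = c("vestibular", "oral"),
                                nBoot = 2000L, seed = 1L) {
  surface <- match.arg(surface)
  means <- .subjectMeans(records, surface)
  summ <- do.call(rbind, lapply(split(means, means$timepoint), function(g) {
    ci <- bootstrapMedianCI(g$mean_p, nBoot = nBoot, seed = seed)
    data.frame(timepoint = g$timepoint[1L], n = nrow(g),
               median = ci@point, ci_low = ci@ciLow, ci_high = ci@ciHigh)
  }))
  rownames(summ) <- NULL
  list(subjectMeans = means, timepointSummary = summ)
}

#' Site-level summary table
#'
#' For every (tooth, surface, timepoint) cell across subjects: median,
#' percentile bootstrap 95% CI, minimum and maximum — the shape of a
#' site-level results table — plus pooled "All" rows per timepoint combining
#' every site of both surfaces.
#'
#' @param records validated records; scan measurements only.
#' @param nBoot,seed bootstrap settings.
#' @return data.frame with columns tooth, surface, timepoint, n, median,
#'   ci_low, ci_high, min, max. The pooled rows carry tooth = "All",
#'   surface = "all".
#' @export
siteLevelSummary <- function(records, nBoot = 2000L, seed = 1L) {
  records <- validateRecords(records)
  sel <- records[records$method == "scan", ]
  if (nrow(sel) == 0L) stop("no scan records")
  cellRow <- function(values, tooth, surface, timepoint) {
    if (length(values) < 3L)
      stop(sprintf("cell %s/%s/%s has fewer than 3 subjects",
                   tooth, surface, timepoint))
    ci <- bootstrapMedianCI(values, nBoot = nBoot, seed = seed)
    data.frame(tooth = tooth, surface = surface, timepoint = timepoint,
               n = length(values), median = ci@point, ci_low = ci@ciLow,
               ci_high = ci@ciHigh, min = min(values), max = max(values))
  }
  cells <- expand.grid(tooth = .RAMFJORD, surface = .SURFACES,
                       timepoint = .TIMEPOINTS, KEEP.OUT.ATTRS = FALSE,
                       stringsAsFactors = FALSE)
  rows <- lapply(seq_len(nrow(cells)), function(i) {
    v <- sel$p_percent[sel$tooth == cells$tooth[i] &
                         sel$surface == cells$surface[i] &
                         sel$timepoint == cells$timepoint[i]]
    cellRow(v, cells$tooth[i], cells$surface[i], cells$timepoint[i])
  })
  pooled <- lapply(.TIMEPOINTS, function(tp)
    cellRow(sel$p_percent[sel$timepoint == tp], "All", "all", tp))
  out <- do.call(rbind, c(pooled, rows))
  rownames(out) <- NULL
  out
}

#' Percent change between two timepoint values
#'
#' An increase is expressed relative to the earlier value,
#' \code{100 (to - from) / from}; a decrease is also expressed relative to
#' the earlier (larger) value, \code{100 (from - to) / from}. The result is
#' rounded half-away-from-zero to an integer percentage for display; keep
#' the unrounded inputs for any further arithmetic.
#'
#' @param valueFrom,valueTo values at the earlier and later timepoint.
#' @param direction `"increase"` or `"decrease"`.
#' @return integer percent.
#' @examples
#' percentChange(7.0, 10.3, "increase")   # 47
#' percentChange(10.3, 5.9, "decrease")   # 43
#' @export
percentChange <- function(valueFrom, valueTo,
                          direction = c("increase", "decrease")) {
  direction <- match.arg(direction)
  if (valueFrom <= 0) stop("zero or negative base value")
  raw <- if (direction == "increase") 100 * (valueTo - valueFrom) / valueFrom
  else 100 * (valueFrom - valueTo) / valueFrom
  as.integer(roundHalfAway(raw))
}

#' Summarise a whole study
#'
#' Assembles the full study summary: the site-level table, the subject-level
#' per-surface medians, the overall percent changes T1 to T2 (increase) and
#' T2 to T3 (decrease) computed from the pooled "All" medians, and the
#' Bonferroni-adjusted Wilcoxon timepoint comparisons at both levels.
#'
#' @param records validated records.
#' @param nBoot,seed bootstrap settings.
#' @return a [StudySummary-class].
#' @export
summarizeStudy <- function(records, nBoot = 2000L, seed = 1L) {
  records <- validateRecords(records)
  site <- siteLevelSummary(records, nBoot = nBoot, seed = seed)
  subj <- do.call(rbind, lapply(.SURFACES, function(sf) {
    s <- subjectLevelSummary(records, sf, nBoot = nBoot, seed = seed)
    cbind(surface = sf, s$timepointSummary)
  }))
  rownames(subj) <- NULL
  allMed <- function(tp) site$median[site$tooth == "All" &
                                       site$timepoint == tp]
  changes <- data.frame(
    comparison = c("T1->T2", "T2->T3"),
    direction = c("increase", "decrease"),
    percent = c(percentChange(allMed("T1"), allMed("T2"), "increase"),
                percentChange(allMed("T2"), allMed("T3"), "decrease")))
  tests <- rbind(compareTimepoints(records, "subject"),
                 compareTimepoints(records, "site"))
  new("StudySummary", siteTable = site, subjectTable = subj,
      changes = changes, tests = tests)
}

setMethod("show", "StudySummary", function(object) {
  cat("StudySummary\n")
  cat(sprintf("  overall medians (All): %s\n",
              paste(sprintf("%s %.1f", object@siteTable$timepoint[
                object@siteTable$tooth == "All"],
                object@siteTable$median[object@siteTable$tooth == "All"]),
                collapse = ", ")))
  for (i in seq_len(nrow(object@changes)))
    cat(sprintf("  %s: %d%% %s\n", object@changes$comparison[i],
                object@changes$percent[i], object@changes$direction[i]))
  nSig <- sum(object@tests$significant)
  cat(sprintf("  %d of %d timepoint comparisons significant at adjusted alpha\n",
              nSig, nrow(object@tests)))
})
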