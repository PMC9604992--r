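.RAMFJORD <- c("16", "21", "24", "36", "41", "44")
.SURFACES <- c("vestibular", "oral")
.TIMEPOINTS <- c("T1", "T2", "T3")

#' Default per-surface plaque distribution parameters
#'
#' Lognormal model of true site-level P% values: the baseline (T1) median per
#' surface, a between-(subject, site) log-sd for the stable individual plaque
#' level, and a within-site log-sd for timepoint-to-timepoint variation. The
#' defaults emulate a disclosed-plaque regrowth design in young adults:
#' vestibular baseline median 7 P%, oral 9.4 P%, with right-skewed site
#' distributions.
#'
#' @return a named list with one parameter list per surface.
#' @seealso [generateLongitudinalStudy()]
#' @export
defaultFractionModel <- function() {
  list(
    vestibular = list(baselineMedian = 7.0, sdlogBetween = 0.6,
                      sdlogWithin = 0.35),
    oral = list(baselineMedian = 9.4, sdlogBetween = 0.6,
                sdlogWithin = 0.35))
}

#' Default timepoint effect multipliers
#'
#' Multiplicative effects on the true P% at T2 (after plaque regrowth
#' without oral hygiene) and T3 (after tooth brushing), relative to the T1
#' baseline, per surface: vestibular plaque roughly doubles and then falls
#' below baseline, oral plaque changes little — the asymmetry brushing
#' produces on the easily reached vs. tongue-side surfaces.
#'
#' @return a named list of c(T2=, T3=) multipliers per surface.
#' @seealso [generateLongitudinalStudy()]
#' @export
defaultEffectMultipliers <- function() {
  list(vestibular = c(T2 = 2.3, T3 = 0.75),
       oral = c(T2 = 1.28, T3 = 1.26))
}

#' Generate a longitudinal whole-mouth study fixture
#'
#' Draws a complete Ramfjord-teeth study: for every subject, the six index
#' teeth, both surfaces and three timepoints, a true site-level P% is drawn
#' from the lognormal fraction model with the per-surface timepoint
#' multipliers applied. Values are truncated to [0.1, 70] P%. Optionally each
#' record is rendered as a synthetic scene whose plaque fraction matches the
#' drawn truth, so the full image-to-statistics pipeline can be exercised.
#'
#' @param nSubjects number of subjects (>= 2).
#' @param fractionModel per-surface distribution parameters, see
#'   [defaultFractionModel()].
#' @param effectMultipliers per-surface T2/T3 multipliers, see
#'   [defaultEffectMultipliers()]; all must be positive. Setting every
#'   multiplier to 1 gives a null study.
#' @param seed integer RNG seed; the same seed reproduces the study exactly.
#' @param render if TRUE, also generate one [SyntheticScene-class] per
#'   record (slow for large studies).
#' @param renderSpec template [SyntheticSceneSpec-class] whose
#'   \code{targetFraction} and \code{seed} are replaced per record.
#' @return a list with \code{records} (data.frame: subject_id, tooth,
#'   surface, timepoint, method = "scan", p_percent = true P%) and
#'   \code{scenes} (named list keyed subject_tooth_surface_timepoint, or
#'   NULL).
#' @examples
#' st <- generateLongitudinalStudy(nSubjects = 4, seed = 11)
#' nrow(st$records)  # 4 subjects x 6 teeth x 2 surfaces x 3 timepoints
#' @export
generateLongitudinalStudy <- function(nSubjects,
                                      fractionModel = defaultFractionModel(),
                                      effectMultipliers = defaultEffectMultipliers(),
                                      seed = 1L, render = FALSE,
                                      renderSpec = sceneSpec()) {
  if (nSubjects < 2L) stop("need at least 2 subjects")
  for (sf in .SURFACES) {
    fm <- fractionModel[[sf]]
    if (is.null(fm) || fm$baselineMedian <= 0 || fm$sdlogBetween < 0 ||
        fm$sdlogWithin < 0)
      stop("invalid distribution parameters for surface ", sf)
    em <- effectMultipliers[[sf]]
    if (is.null(em) || any(em <= 0) ||
        !all(c("T2", "T3") %in% names(em)))
      stop("effect multipliers must be positive and named T2, T3 (", sf, ")")
  }
  subjects <- sprintf("S%02d", seq_len(nSubjects))
  grid <- expand.grid(timepoint = .TIMEPOINTS, tooth = .RAMFJORD,
                      surface = .SURFACES, subject_id = subjects,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  grid <- grid[, c("subject_id", "tooth", "surface", "timepoint")]

  records <- withSeed(seed, {
    # one stable baseline per (subject, tooth, surface) ...
    siteKey <- paste(grid$subject_id, grid$tooth, grid$surface)
    sites <- unique(siteKey)
    baseLog <- numeric(length(sites))
    names(baseLog) <- sites
    for (sf in .SURFACES) {
      m <- fractionModel[[sf]]
      sel <- grepl(paste0(" ", sf, "$"), sites)
      baseLog[sel] <- log(m$baselineMedian) +
        stats::rnorm(sum(sel), sd = m$sdlogBetween)
    }
    # ... times the timepoint effect, plus within-site noise
    logMult <- mapply(function(sf, tp) {
      if (tp == "T1") 0 else log(effectMultipliers[[sf]][[tp]])
    }, grid$surface, grid$timepoint)
    sdW <- vapply(grid$surface,
                  function(sf) fractionModel[[sf]]$sdlogWithin, numeric(1))
    v <- exp(baseLog[siteKey] + logMult + stats::rnorm(nrow(grid), sd = sdW))
    grid$method <- "scan"
    grid$p_percent <- pmin(pmax(v, 0.1), 70)
    rownames(grid) <- NULL
    grid
  })

  scenes <- NULL
  if (render) {
    scenes <- vector("list", nrow(records))
    names(scenes) <- paste(records$subject_id, records$tooth,
                           records$surface, records$timepoint, sep = "_")
    for (i in seq_len(nrow(records))) {
      sp <- renderSpec
      sp@targetFraction <- records$p_percent[i] / 100
      sp@seed <- as.integer((as.integer(seed) + 7919 * i) %% 2147483647)
      scenes[[i]] <- generateScene(sp)
    }
  }
  list(records = records, scenes = scenes)
}
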