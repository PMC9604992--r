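#' Validate site-level P% records
#'
#' Checks a record table against the study schema: one P% value per
#' (subject, FDI tooth, surface, timepoint, method). Teeth are restricted to
#' the Ramfjord set (16, 21, 24, 36, 41, 44); camera measurements exist only
#' for the vestibular surfaces of the first molars 16 and 36 (the reference
#' sites a frontal intraoral photograph can capture); P% must lie in
#' [0, 100]; keys must be unique. All violations are reported together with
#' their row numbers.
#'
#' @param records data.frame with columns subject_id, tooth, surface,
#'   timepoint, method, p_percent.
#' @return the validated records (tooth coerced to character), invisibly
#'   usable downstream.
#' @seealso [loadRecords()]
#' @export
validateRecords <- function(records) {
  needed <- c("subject_id", "tooth", "surface", "timepoint", "method",
              "p_percent")
  missingCols <- setdiff(needed, names(records))
  if (length(missingCols))
    stop("missing columns: ", paste(missingCols, collapse = ", "))
  records$tooth <- as.character(records$tooth)
  records$subject_id <- as.character(records$subject_id)
  problems <- character(0)
  note <- function(rows, msg) {
    if (length(rows))
      problems <<- c(problems, sprintf("row %d: %s", rows, msg))
  }
  note(which(!records$tooth %in% .RAMFJORD), "not a Ramfjord tooth")
  note(which(!records$surface %in% .SURFACES),
       "surface must be vestibular or oral")
  note(which(!records$timepoint %in% .TIMEPOINTS),
       "timepoint must be T1, T2 or T3")
  note(which(!records$method %in% c("scan", "camera")),
       "method must be scan or camera")
  note(which(records$method == "camera" &
               !(records$tooth %in% c("16", "36") &
                   records$surface == "vestibular")),
       "camera records only allowed for teeth 16/36, vestibular surface")
  note(which(!is.finite(records$p_percent) | records$p_percent < 0 |
               records$p_percent > 100),
       "p_percent must lie in [0, 100]")
  key <- paste(records$subject_id, records$tooth, records$surface,
               records$timepoint, records$method)
  note(which(duplicated(key)), "duplicate (subject, tooth, surface, timepoint, method) key")
  if (length(problems))
    stop("invalid records:\n", paste(problems, collapse = "\n"))
  records
}

#' Load site-level P% records from CSV
#'
#' Reads a UTF-8 CSV with header columns subject_id, tooth, surface,
#' timepoint, method, p_percent and validates it with [validateRecords()].
#'
#' @param path CSV file path.
#' @return validated records data.frame.
#' @export
loadRecords <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  records <- utils::read.csv(path, stringsAsFactors = FALSE,
                             colClasses = c(tooth = "character"))
  validateRecords(records)
}

#' Write site-level P% records to CSV
#'
#' @param records validated records data.frame.
#' @param path output CSV path.
#' @return the path, invisibly.
#' @export
writeRecords <- function(records, path) {
  records <- validateRecords(records)
  utils::write.csv(records, path, row.names = FALSE)
  invisible(path)
}

#' Reference site-level P%S medians
#'
#' The published site-level medians of the clinical validation study this
#' method derives from: median P%S per Ramfjord tooth, surface and timepoint
#' for 20 subjects (T1 habitual plaque, T2 after 72 h without oral hygiene,
#' T3 after tooth brushing), plus the pooled "All" row. Used as the worked
#' example for [percentChange()]: the overall medians 7.0 (T1), 10.3 (T2)
#' and 5.9 (T3) give the 47% increase and 43% decrease.
#'
#' @return data.frame with columns tooth, surface, timepoint, median.
#' @export
referenceSiteMedians <- function() {
  path <- system.file("extdata", "reference_site_medians.csv",
                      package = "plaquemetry", mustWork = TRUE)
  utils::read.csv(path, stringsAsFactors = FALSE,
                  colClasses = c(tooth = "character"))
}
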