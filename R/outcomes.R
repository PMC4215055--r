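#' @include AllClasses.R utils.R
NULL

.PHQ9_LEVELS <- c("minimal", "mild", "moderate", "moderately_severe", "severe")
.PHQ9_BREAKS <- c(0, 5, 10, 15, 20, 28)  # [0,4] [5,9] [10,14] [15,19] [20,27]

#' PHQ-9 severity level
#'
#' Maps total PHQ-9 scores (0-27) to the standard severity bins:
#' 0-4 minimal, 5-9 mild, 10-14 moderate, 15-19 moderately severe,
#' 20-27 severe.
#'
#' @param score integer vector of PHQ-9 totals in [0, 27].
#' @return Ordered factor over the five severity levels.
#' @examples
#' phq9Severity(c(4, 5, 19, 20))
#' @export
phq9Severity <- function(score) {
  if (anyNA(score) || any(score < 0 | score > 27) ||
      any(score != floor(score)))
    stop("PHQ-9 scores must be integers in [0, 27]")
  cut(score, breaks = .PHQ9_BREAKS, labels = .PHQ9_LEVELS,
      right = FALSE, ordered_result = TRUE)
}

#' Label treatment response
#'
#' Improvement is a decrease of at least five points in the PHQ-9 total
#' between the start of treatment and follow-up. (A five-point drop does
#' not always change severity level -- e.g. 27 to 22 stays severe -- so
#' the point rule, not the level rule, is the definition.)
#'
#' @param baseline,followup PHQ-9 totals in [0, 27] (vectorized).
#' @return Logical vector: \code{baseline - followup >= 5}.
#' @export
labelImprovement <- function(baseline, followup) {
  if (any(c(baseline, followup) < 0 | c(baseline, followup) > 27,
          na.rm = TRUE))
    stop("PHQ-9 scores must lie in [0, 27]")
  (baseline - followup) >= 5
}

#' First treatment episodes
#'
#' Reduces a treatments table to one episode per patient: the earliest
#' treatment start. When medication and psychotherapy start on the same
#' earliest day the modality is \code{both}; such patients are flagged for
#' exclusion from single-modality response models. The baseline PHQ-9 is
#' taken from the first treatment only. If the follow-up score is not
#' supplied directly, it is looked up among \code{phq9} events as the
#' score closest to \code{start + followupDays} within
#' \code{followupWindow} days.
#'
#' @param data an \linkS4class{EHRData} with a non-empty treatments table,
#'   or a treatments data.frame.
#' @param followupDays nominal follow-up interval (default 90 days).
#' @param followupWindow half-width of the acceptance window around the
#'   nominal follow-up day when the score must be found among events
#'   (default 30 days).
#' @return data.frame with one row per patient: patient_id, modality,
#'   start_day, baseline_phq9, followup_phq9, improved.
#' @export
firstTreatmentEpisodes <- function(data, followupDays = 90L,
                                   followupWindow = 30L) {
  tr <- if (is(data, "EHRData")) treatments(data) else as.data.frame(data)
  if (!nrow(tr)) stop("no treatment records")
  dt <- data.table::as.data.table(tr)
  first <- dt[, list(start_day = min(start_day)), by = "patient_id"]
  dt <- merge(dt, first, by = c("patient_id", "start_day"))
  ep <- dt[, list(
    modality = if (length(unique(modality)) > 1L) "both" else modality[1L],
    baseline_phq9 = baseline_phq9[1L],
    followup_phq9 = followup_phq9[1L]), by = c("patient_id", "start_day")]

  needLookup <- is.na(ep$followup_phq9)
  if (any(needLookup) && is(data, "EHRData")) {
    ev <- events(data)
    phq <- data.table::as.data.table(ev[ev$event_type == "phq9", ,
                                        drop = FALSE])
    for (i in which(needLookup)) {
      cand <- phq[phq$patient_id == ep$patient_id[i], ]
      off <- abs(cand$date - (ep$start_day[i] + followupDays))
      ok <- off <= followupWindow
      if (any(ok))
        ep$followup_phq9[i] <- cand$value[ok][which.min(off[ok])]
    }
  }
  ep <- as.data.frame(ep)
  ep$improved <- ifelse(is.na(ep$followup_phq9), NA,
                        labelImprovement(ep$baseline_phq9, ep$followup_phq9))
  ep[order(ep$patient_id),
     c("patient_id", "modality", "start_day", "baseline_phq9",
       "followup_phq9", "improved")]
}
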