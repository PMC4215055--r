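#' @include AllClasses.R
NULL

#' Age in whole years at a given day offset
#'
#' Dates are integer day offsets from a fixed epoch (day 0 = Jan 1,
#' 2000). Age is computed from year of birth only, as
#' \code{(epoch_year + day \%/\% 365) - birth_year}; matching uses this
#' same convention so age strata are exact.
#'
#' @param birthYear integer year of birth.
#' @param day integer day offset.
#' @return integer age in years.
#' @export
ageAt <- function(birthYear, day) {
  (.EPOCH_YEAR + day %/% 365L) - as.integer(birthYear)
}

# Inverse of ageAt: birth year giving a target age at `day`.
.birthYearForAge <- function(age, day) {
  (.EPOCH_YEAR + day %/% 365L) - as.integer(age)
}

# Zipf-like rank sampling: P(rank r) proportional to 1/r over 1..n.
.sampleZipf <- function(k, n, exponent = 1) {
  w <- (1 / seq_len(n))^exponent
  sample.int(n, size = k, replace = TRUE, prob = w)
}

# Run `expr` under a locally scoped RNG seed, restoring the caller's RNG.
.withSeed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv()))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv()))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(as.integer(seed))
  }
  force(expr)
}

# Canonical empty tables, so EHRData slots always have the right columns.
.emptyEvents <- function() {
  data.frame(patient_id = character(), date = integer(),
             event_type = character(), code = character(),
             negated = logical(), family_history = logical(),
             value = numeric(), stringsAsFactors = FALSE)
}

.emptyTreatments <- function() {
  data.frame(patient_id = character(), start_day = integer(),
             modality = character(), baseline_phq9 = numeric(),
             followup_phq9 = numeric(), stringsAsFactors = FALSE)
}

#' Construct an EHRData container
#'
#' @param patients data.frame with patient_id, birth_year, gender.
#' @param events event table (see \linkS4class{EHRData}); will be sorted by
#'   patient then date.
#' @param treatments optional treatments table.
#' @return An \linkS4class{EHRData} object.
#' @export
EHRData <- function(patients, events = .emptyEvents(),
                    treatments = .emptyTreatments()) {
  events <- as.data.frame(events)[.EVENT_COLS]
  events <- events[order(events$patient_id, events$date), , drop = FALSE]
  rownames(events) <- NULL
  new("EHRData", patients = as.data.frame(patients), events = events,
      treatments = as.data.frame(treatments))
}

# Per-patient first/last visit day and visit counts; patients without a
# visit event get NA span. Returns a data.table keyed by patient_id.
.visitSpans <- function(events) {
  dt <- data.table::as.data.table(events)
  v <- dt[dt$event_type == "visit",
          list(first_visit = min(date), last_visit = max(date),
               n_visits = .N),
          by = "patient_id"]
  v$history_days <- v$last_visit - v$first_visit
  v
}
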