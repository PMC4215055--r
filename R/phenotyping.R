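#' @include AllClasses.R utils.R terminology.R simulate.R
NULL

#' Construct a phenotyping configuration
#'
#' Holds the depression case definition constants: the ICD-9 code set
#' (bracket families expanded at load), the depression term set, the
#' antidepressant ingredient set, the minimum pre-index visit history
#' (1.5 years = 548 days), the maximum gap between first depression code
#' and first antidepressant mention (100 days, a capture heuristic that
#' drops patients likely diagnosed before their record begins), the
#' control:case match ratio (6) and the history-length bin width for
#' matching (6 months = 183 days).
#'
#' @param icd9Codes depression ICD-9 codes or bracket patterns.
#' @param depressionTerms character vector or \linkS4class{TermSet}.
#' @param antidepressantIngredients character vector of ingredient ids.
#' @param minHistoryDays,maxCodeDrugGapDays,historyBinDays durations in
#'   days.
#' @param matchRatio controls per case.
#' @return A validated \linkS4class{PhenotypeConfig}.
#' @export
phenotypeConfig <- function(icd9Codes = defaultDepressionCodes(),
                            depressionTerms = NULL,
                            antidepressantIngredients = NULL,
                            minHistoryDays = 548L,
                            maxCodeDrugGapDays = 100L,
                            matchRatio = 6L, historyBinDays = 183L) {
  if (is.null(depressionTerms))
    depressionTerms <- concepts(defaultDepressionTermSet())
  if (is(depressionTerms, "TermSet"))
    depressionTerms <- concepts(depressionTerms)
  if (is.null(antidepressantIngredients))
    antidepressantIngredients <- defaultAntidepressants()
  new("PhenotypeConfig",
      icd9Codes = expandIcd9Families(icd9Codes),
      depressionTerms = depressionTerms,
      antidepressantIngredients = antidepressantIngredients,
      minHistoryDays = as.integer(minHistoryDays),
      maxCodeDrugGapDays = as.integer(maxCodeDrugGapDays),
      matchRatio = as.integer(matchRatio),
      historyBinDays = as.integer(historyBinDays))
}

# Normalize an ICD-9 code for set membership: codes in the 296.2x/296.3x
# major-depression families match on the first four digits, so a fifth
# digit outside the enumerated range still matches after truncation.
.icd9Matches <- function(code, codeSet) {
  hit <- code %in% codeSet
  trunc5 <- substr(code, 1L, 5L)
  hit | (trunc5 %in% c("296.2", "296.3") &
           trunc5 %in% unique(substr(codeSet, 1L, 5L)))
}

# Per-patient criterion table: first qualifying dates for each of the
# three case criteria. Returns a data.table keyed by patient_id with
# first_code, first_term, first_drug (NA when the criterion is unmet).
.criterionDates <- function(events, config) {
  dt <- data.table::as.data.table(events)
  firstBy <- function(sub, name) {
    if (!nrow(sub)) {
      out <- data.table::data.table(patient_id = character())
      out[[name]] <- integer(0)
      return(out)
    }
    out <- sub[, list(d = min(date)), by = "patient_id"]
    data.table::setnames(out, "d", name)
    out
  }
  code <- firstBy(dt[dt$event_type == "icd9" &
                       .icd9Matches(dt$code, config@icd9Codes), ],
                  "first_code")
  usable <- dt[!dt$negated & !dt$family_history, ]
  term <- firstBy(usable[usable$event_type == "term" &
                           usable$code %in% config@depressionTerms, ],
                  "first_term")
  drug <- firstBy(usable[usable$event_type %in% c("drug_mention", "term") &
                           usable$code %in%
                             config@antidepressantIngredients, ],
                  "first_drug")
  merge(merge(code, term, by = "patient_id", all = TRUE),
        drug, by = "patient_id", all = TRUE)
}

#' Case criteria for depression
#'
#' A patient meets the case definition iff the record contains (i) a
#' depression-related ICD-9 code, (ii) an assertive (non-negated,
#' non-family-history) depression disorder term, and (iii) an assertive
#' antidepressant-ingredient mention. The 296.2x/296.3x families match
#' with the fifth digit truncated.
#'
#' @param record an \linkS4class{EHRData} restricted to one patient, or
#'   an event data.frame for one patient.
#' @param config a \linkS4class{PhenotypeConfig}.
#' @return list with \code{meets} (logical) and \code{breakdown}, a named
#'   logical vector over criteria \code{icd9}, \code{term}, \code{drug}.
#' @export
meetsCaseCriteria <- function(record, config = phenotypeConfig()) {
  ev <- if (is(record, "EHRData")) events(record) else as.data.frame(record)
  stopifnot(length(unique(ev$patient_id)) <= 1L)
  cd <- .criterionDates(ev, config)
  breakdown <- c(icd9 = nrow(cd) > 0 && !is.na(cd$first_code[1L]),
                 term = nrow(cd) > 0 && !is.na(cd$first_term[1L]),
                 drug = nrow(cd) > 0 && !is.na(cd$first_drug[1L]))
  list(meets = all(breakdown), breakdown = breakdown)
}

#' First-diagnosis (index) date
#'
#' The earliest date by which both a depression ICD-9 code and an
#' antidepressant-ingredient mention have occurred, i.e. the later of the
#' two first occurrences.
#'
#' @inheritParams meetsCaseCriteria
#' @return Integer day offset.
#' @export
firstDiagnosisDate <- function(record, config = phenotypeConfig()) {
  ev <- if (is(record, "EHRData")) events(record) else as.data.frame(record)
  stopifnot(length(unique(ev$patient_id)) <= 1L)
  cd <- .criterionDates(ev, config)
  if (!nrow(cd) || is.na(cd$first_code[1L]) || is.na(cd$first_drug[1L]))
    stop("record does not meet the case criteria; no index date")
  max(cd$first_code[1L], cd$first_drug[1L])
}

#' History and capture exclusions for cases
#'
#' A case is excluded with reason \code{short_history} when less than
#' \code{minHistoryDays} of visits precede the index date, and with
#' reason \code{late_capture} when more than \code{maxCodeDrugGapDays}
#' separate the first depression code from the first antidepressant
#' mention (unsigned gap) -- patients likely diagnosed before their
#' record began.
#'
#' @inheritParams meetsCaseCriteria
#' @param indexDate the case's index date (day offset).
#' @return \code{"retain"} or \code{"excluded:<reason>"}.
#' @export
applyExclusions <- function(record, indexDate, config = phenotypeConfig()) {
  ev <- if (is(record, "EHRData")) events(record) else as.data.frame(record)
  firstVisit <- min(ev$date[ev$event_type == "visit"])
  if (indexDate - firstVisit < config@minHistoryDays)
    return("excluded:short_history")
  cd <- .criterionDates(ev, config)
  if (abs(cd$first_code[1L] - cd$first_drug[1L]) > config@maxCodeDrugGapDays)
    return("excluded:late_capture")
  "retain"
}

#' Control eligibility
#'
#' A patient is control-eligible iff the record contains no depression
#' ICD-9 code and no depression term mention of any flag state -- a
#' negated or family-history mention still disqualifies (the strict
#' any-mention reading; a record discussing depression at all is not a
#' clean control).
#'
#' @inheritParams meetsCaseCriteria
#' @return logical.
#' @export
isControlEligible <- function(record, config = phenotypeConfig()) {
  ev <- if (is(record, "EHRData")) events(record) else as.data.frame(record)
  !any(ev$event_type == "icd9" & .icd9Matches(ev$code, config@icd9Codes)) &&
    !any(ev$event_type == "term" & ev$code %in% config@depressionTerms)
}

#' Match controls to cases on age and history length
#'
#' For each case, draws \code{matchRatio} controls uniformly at random,
#' without replacement across the whole cohort, from the pool members
#' with identical integer age at index and identical
#' \code{floor(history_length / historyBinDays)} bin. Matching on history
#' length keeps a missing depression diagnosis from being an artifact of
#' a short record. Cases whose stratum has fewer than \code{matchRatio}
#' unused candidates are reported unmatched (with the shortfall), never
#' silently dropped, and consume no controls.
#'
#' @param cases data.frame with patient_id, index_date, age, history_days.
#' @param pool data.frame of control-eligible patients with patient_id,
#'   age (at end of history), history_days.
#' @param config a \linkS4class{PhenotypeConfig}.
#' @param seed RNG seed for reproducible draws.
#' @return list with \code{matches} (data.frame patient_id, matched_case)
#'   and \code{unmatched} (data.frame patient_id, n_found, n_needed).
#' @export
matchControls <- function(cases, pool, config = phenotypeConfig(),
                          seed = NULL) {
  if (!nrow(pool)) stop("control pool is empty")
  ratio <- config@matchRatio
  bin <- function(h) h %/% config@historyBinDays
  caseKey <- paste(cases$age, bin(cases$history_days))
  poolKey <- paste(pool$age, bin(pool$history_days))
  .withSeed(seed, {
    matches <- vector("list", nrow(cases))
    shortfall <- list()
    byStratum <- split(seq_len(nrow(pool)), poolKey)
    ## shuffle each stratum once; cases then consume candidates in order,
    ## which is a uniform without-replacement draw for every case
    byStratum <- lapply(byStratum, function(ix) ix[sample.int(length(ix))])
    used <- stats::setNames(rep(0L, length(byStratum)), names(byStratum))
    for (i in seq_len(nrow(cases))) {
      key <- caseKey[i]
      avail <- byStratum[[key]]
      got <- if (is.null(avail)) 0L else length(avail) - used[[key]]
      if (got < ratio) {
        shortfall[[length(shortfall) + 1L]] <- data.frame(
          patient_id = cases$patient_id[i], n_found = max(0L, got),
          n_needed = ratio, stringsAsFactors = FALSE)
        warning("case ", cases$patient_id[i], " matched only ", got,
                " of ", ratio, " controls in its stratum", call. = FALSE)
        next
      }
      take <- avail[used[[key]] + seq_len(ratio)]
      used[[key]] <- used[[key]] + ratio
      matches[[i]] <- data.frame(patient_id = pool$patient_id[take],
                                 matched_case = cases$patient_id[i],
                                 stringsAsFactors = FALSE)
    }
    list(matches = if (length(m <- Filter(Negate(is.null), matches)))
           do.call(rbind, m)
         else data.frame(patient_id = character(),
                         matched_case = character()),
         unmatched = if (length(shortfall)) do.call(rbind, shortfall)
         else data.frame(patient_id = character(), n_found = integer(),
                         n_needed = integer()))
  })
}

#' Assemble the case-control cohort
#'
#' Runs the full phenotyping stage over an \linkS4class{EHRData}: applies
#' the three case criteria, derives each case's first-diagnosis index
#' date, enforces the history and capture exclusions, determines control
#' eligibility (strict any-mention reading), and matches
#' \code{matchRatio} controls per case on exact age at index and
#' history-length bin. Patients that are neither retained cases nor
#' matched controls are labelled excluded with a machine-readable reason
#' (\code{short_history}, \code{late_capture}, \code{partial_criteria},
#' \code{ineligible_control}, \code{unmatched_case}, \code{not_selected}).
#'
#' @param data an \linkS4class{EHRData}.
#' @param config a \linkS4class{PhenotypeConfig}.
#' @param seed RNG seed for the matching draw.
#' @param nCases optionally subsample this many retained cases (uniformly)
#'   before matching, as when a cohort is downsized for tractability.
#' @return A \linkS4class{CohortAssignment}.
#' @export
buildCohort <- function(data, config = phenotypeConfig(), seed = 1L,
                        nCases = NULL) {
  ev <- events(data)
  spans <- .visitSpans(ev)
  cd <- .criterionDates(ev, config)
  cd <- merge(cd, spans, by = "patient_id", all = TRUE)

  allIds <- patients(data)$patient_id
  label <- stats::setNames(rep("excluded", length(allIds)), allIds)
  reason <- stats::setNames(rep(NA_character_, length(allIds)), allIds)
  indexDate <- stats::setNames(rep(NA_real_, length(allIds)), allIds)
  matchedCase <- stats::setNames(rep(NA_character_, length(allIds)), allIds)

  isCase <- !is.na(cd$first_code) & !is.na(cd$first_term) &
    !is.na(cd$first_drug)
  someCriterion <- !is.na(cd$first_code) | !is.na(cd$first_term) |
    !is.na(cd$first_drug)
  reason[cd$patient_id[someCriterion & !isCase]] <- "partial_criteria"

  caseTab <- cd[isCase & !is.na(cd$first_visit), ]
  caseTab$index <- pmax(caseTab$first_code, caseTab$first_drug)
  short <- caseTab$index - caseTab$first_visit < config@minHistoryDays
  late <- abs(caseTab$first_code - caseTab$first_drug) >
    config@maxCodeDrugGapDays
  reason[caseTab$patient_id[short]] <- "short_history"
  reason[caseTab$patient_id[late & !short]] <- "late_capture"
  retained <- caseTab[!short & !late, ]
  indexDate[retained$patient_id] <- retained$index

  ## control pool: no depression code, no depression mention of any kind
  dtEv <- data.table::as.data.table(ev)
  anyCode <- unique(dtEv$patient_id[dtEv$event_type == "icd9" &
                                      .icd9Matches(dtEv$code,
                                                   config@icd9Codes)])
  anyTerm <- unique(dtEv$patient_id[dtEv$event_type == "term" &
                                      dtEv$code %in% config@depressionTerms])
  eligible <- setdiff(allIds, union(anyCode, union(anyTerm,
                                                   cd$patient_id[isCase])))
  reason[setdiff(setdiff(allIds, cd$patient_id[isCase]), eligible)] <-
    ifelse(is.na(reason[setdiff(setdiff(allIds, cd$patient_id[isCase]),
                                eligible)]), "ineligible_control",
           reason[setdiff(setdiff(allIds, cd$patient_id[isCase]), eligible)])

  caseDf <- data.frame(
    patient_id = retained$patient_id,
    index_date = retained$index,
    age = ageAt(patients(data)$birth_year[match(retained$patient_id,
                                                allIds)], retained$index),
    history_days = retained$history_days, stringsAsFactors = FALSE)
  selected <- caseDf
  if (!is.null(nCases) && nCases < nrow(caseDf)) {
    pick <- .withSeed(seed, sample.int(nrow(caseDf), nCases))
    selected <- caseDf[pick, , drop = FALSE]
    reason[setdiff(caseDf$patient_id, selected$patient_id)] <- "not_selected"
  }

  poolSpan <- spans[match(eligible, spans$patient_id), ]
  poolDf <- data.frame(
    patient_id = eligible,
    age = ageAt(patients(data)$birth_year[match(eligible, allIds)],
                poolSpan$last_visit),
    history_days = poolSpan$history_days, stringsAsFactors = FALSE)
  poolDf <- poolDf[!is.na(poolDf$history_days), , drop = FALSE]
  indexDate[poolDf$patient_id] <- poolSpan$last_visit[
    match(poolDf$patient_id, poolSpan$patient_id)]

  mm <- matchControls(selected, poolDf, config, seed = seed)
  matchedIds <- mm$matches$patient_id
  label[matchedIds] <- "control"
  matchedCase[matchedIds] <- mm$matches$matched_case
  okCases <- setdiff(selected$patient_id, mm$unmatched$patient_id)
  label[okCases] <- "case"
  reason[mm$unmatched$patient_id] <- "unmatched_case"
  stillNa <- is.na(reason) & label == "excluded"
  reason[stillNa] <- "not_selected"

  new("CohortAssignment",
      assignments = data.frame(
        patient_id = allIds, label = unname(label[allIds]),
        index_date = unname(indexDate[allIds]),
        matched_case = unname(matchedCase[allIds]),
        exclusion_reason = ifelse(label[allIds] == "excluded",
                                  unname(reason[allIds]), NA_character_),
        stringsAsFactors = FALSE),
      unmatched = mm$unmatched)
}

#' Cohort composition summary
#'
#' @param cohort a \linkS4class{CohortAssignment}.
#' @return list with case and control counts and the depressed percentage
#'   of the assembled (case + matched control) cohort, rounded to one
#'   decimal.
#' @export
cohortComposition <- function(cohort) {
  a <- assignments(cohort)
  nCase <- sum(a$label == "case")
  nCtrl <- sum(a$label == "control")
  list(n_cases = nCase, n_controls = nCtrl, n_total = nCase + nCtrl,
       pct_depressed = round(100 * nCase / (nCase + nCtrl), 1))
}
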