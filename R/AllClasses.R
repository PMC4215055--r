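#' @import methods
#' @importFrom S4Vectors DataFrame metadata
NULL

.EVENT_TYPES <- c("visit", "icd9", "term", "drug_mention", "rx", "cpt", "phq9")
.EVENT_COLS <- c("patient_id", "date", "event_type", "code",
                 "negated", "family_history", "value")

## Day offsets are integers counted from a fixed epoch (day 0 = Jan 1 of the
## epoch year, 2000); no calendar arithmetic anywhere in the package.
.EPOCH_YEAR <- 2000L

#' Longitudinal EHR dataset
#'
#' Container for a simulated or imported EHR extract: a patients table
#' (one row per patient: \code{patient_id}, \code{birth_year},
#' \code{gender}), a date-ordered clinical event table (one row per
#' timestamped fact: visit, ICD-9 code, annotated note term with
#' negation/family-history flags, drug-ingredient mention, PHQ-9 score),
#' and, for treated cohorts, a treatments table (\code{patient_id},
#' \code{start_day}, \code{modality}, \code{baseline_phq9},
#' \code{followup_phq9}).
#'
#' All dates are integer day offsets from a fixed epoch. PHQ-9 events carry
#' their score in \code{value}; negation and family-history flags are only
#' meaningful for term and drug-mention events.
#'
#' @slot patients data.frame with columns patient_id, birth_year, gender.
#' @slot events data.frame with columns patient_id, date, event_type, code,
#'   negated, family_history, value, sorted by patient then date.
#' @slot treatments data.frame (possibly empty) with columns patient_id,
#'   start_day, modality, baseline_phq9, followup_phq9.
#' @exportClass EHRData
setClass("EHRData",
  slots = c(patients = "data.frame",
            events = "data.frame",
            treatments = "data.frame"))

setValidity("EHRData", function(object) {
  msgs <- character()
  p <- object@patients
  e <- object@events
  if (!all(c("patient_id", "birth_year", "gender") %in% names(p)))
    msgs <- c(msgs, "patients must have patient_id, birth_year, gender")
  if (!all(.EVENT_COLS %in% names(e)))
    msgs <- c(msgs, sprintf("events must have columns: %s",
                            paste(.EVENT_COLS, collapse = ", ")))
  else {
    if (!all(e$event_type %in% .EVENT_TYPES))
      msgs <- c(msgs, "unknown event_type present")
    if (anyNA(e$date) || !is.numeric(e$date))
      msgs <- c(msgs, "event dates must be non-missing numbers")
    phq <- e$value[e$event_type == "phq9"]
    if (length(phq) && (anyNA(phq) || any(phq < 0 | phq > 27)))
      msgs <- c(msgs, "phq9 events must carry value in [0, 27]")
    if (!all(unique(e$patient_id) %in% p$patient_id))
      msgs <- c(msgs, "events reference unknown patients")
    if (nrow(e) > 1L) {
      sameP <- e$patient_id[-1L] == e$patient_id[-nrow(e)]
      if (any(sameP & diff(e$date) < 0))
        msgs <- c(msgs, "events must be date-ordered within each patient")
    }
  }
  if (anyDuplicated(p$patient_id))
    msgs <- c(msgs, "duplicate patient_id in patients table")
  if (length(msgs)) msgs else TRUE
})

#' Simulation configuration for a PAMF-like diagnosis cohort
#'
#' Parameters of the synthetic generator for a mixed depressed /
#' non-depressed population with prodromal signal. See
#' \code{\link{pamfSimConfig}} for defaults and their rationale.
#'
#' @exportClass PamfSimConfig
setClass("PamfSimConfig",
  slots = c(nPatients = "integer", prevalence = "numeric",
            prodromeDays = "integer", signalStrength = "numeric",
            nSignalFeatures = "integer", vocabSizeCodes = "integer",
            vocabSizeTerms = "integer", visitRateMean = "numeric",
            followupYearsMean = "numeric", negationRate = "numeric",
            familyHistoryRate = "numeric", signalBaseRate = "numeric",
            backgroundCodesPerVisit = "numeric",
            backgroundTermsPerVisit = "numeric",
            caseWindowDays = "integer", matchedMode = "logical",
            femaleFraction = "numeric",
            depressionCodes = "character", depressionTerms = "character",
            antidepressants = "character", seed = "integer"))

setValidity("PamfSimConfig", function(object) {
  msgs <- character()
  if (object@prevalence < 0 || object@prevalence > 1)
    msgs <- c(msgs, "prevalence must lie in [0, 1]")
  counts <- c(nPatients = object@nPatients, prodromeDays = object@prodromeDays,
              nSignalFeatures = object@nSignalFeatures,
              vocabSizeCodes = object@vocabSizeCodes,
              vocabSizeTerms = object@vocabSizeTerms)
  if (any(counts < 1L))
    msgs <- c(msgs, sprintf("counts must be >= 1 (%s)",
                            paste(names(counts)[counts < 1L], collapse = ", ")))
  if (object@signalStrength < 1)
    msgs <- c(msgs, "signalStrength must be >= 1 (odds multiplier)")
  if (object@visitRateMean <= 0) msgs <- c(msgs, "visitRateMean must be > 0")
  if (object@followupYearsMean <= 0)
    msgs <- c(msgs, "followupYearsMean must be > 0")
  for (f in c("negationRate", "familyHistoryRate", "signalBaseRate",
              "femaleFraction")) {
    v <- slot(object, f)
    if (v < 0 || v > 1) msgs <- c(msgs, sprintf("%s must lie in [0, 1]", f))
  }
  if (round(object@nPatients * object@prevalence) < 1)
    msgs <- c(msgs, "prevalence x nPatients must be at least 1 case")
  if (length(msgs)) msgs else TRUE
})

#' Simulation configuration for a GHRI-like treated cohort
#'
#' Parameters of the synthetic generator for a population treated for
#' depression with PHQ-9 scores at treatment start and after a fixed
#' follow-up. See \code{\link{ghriSimConfig}}.
#'
#' @exportClass GhriSimConfig
setClass("GhriSimConfig",
  slots = c(nPatients = "integer", baselinePhq9Distribution = "numeric",
            modalityMedication = "numeric", modalityBoth = "numeric",
            improvementLogitIntercept = "numeric",
            improvementLogitBaselineCoef = "numeric",
            modalityLogOdds = "numeric",
            plantedModerator = "list",
            followupDays = "integer",
            nHistoryFeatures = "integer", nSeverityFeatures = "integer",
            severitySlope = "numeric",
            visitRateMean = "numeric", historyYearsMean = "numeric",
            femaleFraction = "numeric", seed = "integer"))

setValidity("GhriSimConfig", function(object) {
  msgs <- character()
  d <- object@baselinePhq9Distribution
  if (length(d) != 5L || any(d < 0))
    msgs <- c(msgs, "baselinePhq9Distribution must be 5 non-negative masses")
  if (abs(sum(d) - 1) > 1e-9)
    msgs <- c(msgs, "baselinePhq9Distribution must sum to 1 within 1e-9")
  if (object@followupDays <= 0L) msgs <- c(msgs, "followupDays must be > 0")
  if (object@modalityMedication < 0 || object@modalityBoth < 0 ||
      object@modalityMedication + object@modalityBoth > 1)
    msgs <- c(msgs, "modality fractions must be a sub-probability pair")
  pm <- object@plantedModerator
  if (length(pm) &&
      !all(c("feature", "logOdds", "prevalence") %in% names(pm)))
    msgs <- c(msgs, "plantedModerator needs feature, logOdds, prevalence")
  if (length(msgs)) msgs else TRUE
})

#' Curated concept set with provenance
#'
#' A set of concept identifiers (e.g. depression disorder terms) together
#' with the round of the is-a expansion at which each entered the set
#' (\code{seed}, \code{expansion_round_1}, ...) and any concepts removed by
#' a curation blocklist.
#'
#' @slot concepts character vector of concept identifiers.
#' @slot provenance character vector parallel to \code{concepts}.
#' @slot removed character vector of concepts dropped by
#'   \code{\link{filterTerms}} (provenance \code{removed_by_filter}).
#' @exportClass TermSet
setClass("TermSet",
  slots = c(concepts = "character", provenance = "character",
            removed = "character"))

setValidity("TermSet", function(object) {
  msgs <- character()
  if (length(object@concepts) != length(object@provenance))
    msgs <- c(msgs, "provenance must parallel concepts")
  if (anyDuplicated(object@concepts))
    msgs <- c(msgs, "duplicate concepts")
  seed <- object@concepts[object@provenance == "seed"]
  if (length(intersect(object@concepts, object@removed)))
    msgs <- c(msgs, "removed concepts must not remain in the set")
  if (length(msgs)) msgs else TRUE
})

#' Directed acyclic is-a ontology
#'
#' An edge list of child-to-parent is-a relations over opaque concept
#' identifiers. Validity enforces acyclicity (checked by leaf stripping).
#'
#' @slot child,parent parallel character vectors; each element states
#'   \code{child} is-a \code{parent}.
#' @exportClass OntologyGraph
setClass("OntologyGraph",
  slots = c(child = "character", parent = "character"))

setValidity("OntologyGraph", function(object) {
  msgs <- character()
  if (length(object@child) != length(object@parent))
    msgs <- c(msgs, "edge vectors must be parallel")
  if (anyNA(object@child) || anyNA(object@parent))
    msgs <- c(msgs, "edge endpoints must be non-missing")
  if (!length(msgs) && .hasCycle(object@child, object@parent))
    msgs <- c(msgs, "is-a graph must be acyclic")
  if (length(msgs)) msgs else TRUE
})

# Kahn-style cycle detection on the edge list.
.hasCycle <- function(child, parent) {
  edges <- unique(data.frame(child = child, parent = parent,
                             stringsAsFactors = FALSE))
  repeat {
    if (!nrow(edges)) return(FALSE)
    # strip edges into sink nodes (parents that are never a child themselves)
    keep <- edges$parent %in% edges$child
    if (all(keep)) return(TRUE)
    edges <- edges[keep, , drop = FALSE]
  }
}

#' Drug indication table
#'
#' Toy stand-in for a drug indications database joined to an
#' ingredient normalization: one row per drug with its active-ingredient
#' set and primary-indication set.
#'
#' @slot drugs data.frame with columns drug_id (character), ingredients
#'   (list of character), indications (list of character).
#' @exportClass DrugIndicationTable
setClass("DrugIndicationTable", slots = c(drugs = "data.frame"))

setValidity("DrugIndicationTable", function(object) {
  d <- object@drugs
  msgs <- character()
  if (!all(c("drug_id", "ingredients", "indications") %in% names(d)))
    msgs <- c(msgs, "drugs needs drug_id, ingredients, indications")
  else {
    if (any(lengths(d$ingredients) == 0L))
      msgs <- c(msgs, "ingredient sets must be non-empty")
    if (anyDuplicated(d$drug_id)) msgs <- c(msgs, "duplicate drug_id")
  }
  if (length(msgs)) msgs else TRUE
})

#' Phenotyping configuration
#'
#' Houses the constants of the depression case definition: the ICD-9 code
#' set (bracket families expanded to explicit codes), the depression term
#' set, the antidepressant ingredient set, the minimum pre-index history
#' (default 548 days, i.e. 1.5 years), the maximum gap between first code
#' and first drug mention (default 100 days), the control:case match ratio
#' (default 6) and the history-length matching bin width (default 183
#' days, i.e. 6 months).
#'
#' @exportClass PhenotypeConfig
setClass("PhenotypeConfig",
  slots = c(icd9Codes = "character", depressionTerms = "character",
            antidepressantIngredients = "character",
            minHistoryDays = "integer", maxCodeDrugGapDays = "integer",
            matchRatio = "integer", historyBinDays = "integer"))

setValidity("PhenotypeConfig", function(object) {
  msgs <- character()
  if (object@minHistoryDays <= 0L || object@maxCodeDrugGapDays <= 0L ||
      object@historyBinDays <= 0L)
    msgs <- c(msgs, "all durations must be > 0")
  if (object@matchRatio < 1L) msgs <- c(msgs, "matchRatio must be >= 1")
  if (length(msgs)) msgs else TRUE
})

#' Cohort assignment
#'
#' Output of the phenotyping stage: per patient a label (\code{case},
#' \code{control}, or \code{excluded}), the index date (first-diagnosis
#' date for cases; end of medical history for controls), the matched case
#' for each matched control, and a machine-readable exclusion reason.
#' Cases that could not be matched at the requested ratio are reported in
#' \code{unmatched}, never silently dropped.
#'
#' @slot assignments data.frame with columns patient_id, label, index_date,
#'   matched_case, exclusion_reason.
#' @slot unmatched data.frame with columns patient_id, n_found, n_needed.
#' @exportClass CohortAssignment
setClass("CohortAssignment",
  slots = c(assignments = "data.frame", unmatched = "data.frame"))

setValidity("CohortAssignment", function(object) {
  a <- object@assignments
  msgs <- character()
  need <- c("patient_id", "label", "index_date", "matched_case",
            "exclusion_reason")
  if (!all(need %in% names(a)))
    msgs <- c(msgs, sprintf("assignments needs columns: %s",
                            paste(need, collapse = ", ")))
  else {
    if (!all(a$label %in% c("case", "control", "excluded")))
      msgs <- c(msgs, "labels must be case/control/excluded")
    if (anyNA(a$index_date[a$label == "case"]))
      msgs <- c(msgs, "every case must carry an index_date")
    bad <- a$label == "excluded" &
      (is.na(a$exclusion_reason) | a$exclusion_reason == "")
    if (any(bad))
      msgs <- c(msgs, "excluded patients must carry one reason code")
  }
  if (length(msgs)) msgs else TRUE
})

#' Binary EHR feature matrix
#'
#' A \linkS4class{SummarizedExperiment} with features as rows and patients
#' as columns; the single assay \code{present} holds 0/1 indicators
#' (demographic rows such as \code{demo:age} and \code{demo:baseline_phq9}
#' may be non-binary). \code{rowData} carries the feature namespace
#' (\code{demo}, \code{visit_bin}, \code{icd9}, \code{term}, \code{cui},
#' \code{drug}); \code{colData} carries the cohort label and index date.
#' Metadata records the truncation cutoff applied and the features removed
#' because they define the phenotype.
#'
#' @exportClass EHRFeatureMatrix
setClass("EHRFeatureMatrix", contains = "SummarizedExperiment")

setValidity("EHRFeatureMatrix", function(object) {
  msgs <- character()
  if (!"present" %in% SummarizedExperiment::assayNames(object))
    msgs <- c(msgs, "assay 'present' required")
  if (!"namespace" %in% names(SummarizedExperiment::rowData(object)))
    msgs <- c(msgs, "rowData must carry feature namespace")
  else {
    ns <- SummarizedExperiment::rowData(object)$namespace
    a <- SummarizedExperiment::assay(object, "present")
    nonDemo <- which(ns != "demo")
    if (length(nonDemo)) {
      v <- a[nonDemo, , drop = FALSE]
      vals <- if (inherits(v, "sparseMatrix")) v@x else as.vector(v)
      if (length(vals) && !all(vals %in% c(0, 1)))
        msgs <- c(msgs, "non-demographic entries must be 0/1")
    }
  }
  if (length(msgs)) msgs else TRUE
})

#' Fitted L1-penalized logistic model
#'
#' Sparse coefficient vector at the selected penalty, with the feature
#' standard deviations recorded so features can be ranked on a
#' standardized scale.
#'
#' @exportClass ModelFit
setClass("ModelFit",
  slots = c(coefficients = "numeric", intercept = "numeric",
            lambda = "numeric", rule = "character",
            featureSd = "numeric", nObs = "integer"))

setValidity("ModelFit", function(object) {
  if (length(object@coefficients) &&
      is.null(names(object@coefficients)))
    "coefficients must be named by feature" else TRUE
})

#' ROC evaluation result
#'
#' Empirical ROC curve, trapezoidal AUC, DeLong 95% confidence interval
#' and sensitivities interpolated at requested specificities.
#'
#' @exportClass RocResult
setClass("RocResult",
  slots = c(curve = "data.frame", auc = "numeric",
            ciLow = "numeric", ciHigh = "numeric",
            sensitivityAt = "numeric", nPos = "integer", nNeg = "integer",
            ciMethod = "character"))

setValidity("RocResult", function(object) {
  msgs <- character()
  cv <- object@curve
  if (!all(c("fpr", "tpr") %in% names(cv)))
    msgs <- c(msgs, "curve needs fpr and tpr")
  else if (is.unsorted(cv$fpr) || is.unsorted(cv$tpr))
    msgs <- c(msgs, "curve must be monotone non-decreasing")
  if (object@auc < 0 || object@auc > 1) msgs <- c(msgs, "auc must be in [0,1]")
  if (!(object@ciLow <= object@auc + 1e-12 &&
        object@auc <= object@ciHigh + 1e-12))
    msgs <- c(msgs, "ciLow <= auc <= ciHigh violated")
  if (length(msgs)) msgs else TRUE
})

#' Treatment-moderator screening report
#'
#' Per candidate feature: information gain (bits) for the screening
#' outcome, the main-effect and feature-by-treatment interaction
#' coefficients from the joint logistic model, raw Wald and
#' Benjamini-Hochberg adjusted p-values for the interaction, and the
#' information-gain rank.
#'
#' @exportClass ModeratorReport
setClass("ModeratorReport", slots = c(table = "data.frame"))

setValidity("ModeratorReport", function(object) {
  t <- object@table
  msgs <- character()
  need <- c("feature", "information_gain", "main_coef", "interaction_coef",
            "interaction_p", "interaction_p_adj", "rank", "estimable")
  if (!all(need %in% names(t)))
    msgs <- c(msgs, sprintf("table needs columns: %s",
                            paste(need, collapse = ", ")))
  else {
    if (any(t$information_gain < -1e-12))
      msgs <- c(msgs, "information gain must be non-negative")
    if (!setequal(t$rank, seq_len(nrow(t))))
      msgs <- c(msgs, "ranks must be a permutation of 1..k")
  }
  if (length(msgs)) msgs else TRUE
})
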