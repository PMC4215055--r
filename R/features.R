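#' @include AllClasses.R utils.R phenotyping.R
NULL

#' Truncate a history at a prediction cutoff
#'
#' Retains events dated at or before \code{indexDate + offset}. Offsets
#' are non-positive: 0 truncates at the index itself, -183 six months
#' before, -365 one year before. For controls the index is the end of the
#' medical history.
#'
#' @param events event data.frame (or \linkS4class{EHRData}, in which
#'   case all patients are truncated at their own index).
#' @param indexDate integer day offset of the index date.
#' @param offset cutoff offset in days (<= 0).
#' @return The retained events, order preserved.
#' @export
truncateHistory <- function(events, indexDate, offset = 0L) {
  stopifnot(offset <= 0)
  ev <- if (is(events, "EHRData")) events(events) else events
  ev[ev$date <= indexDate + offset, , drop = FALSE]
}

#' Average visits per year
#'
#' Number of visit events divided by the record span in days (floored at
#' one day, so a single-visit record is rated as 365 visits/year),
#' multiplied by 365. Rates a patient with two visits a month apart
#' higher than one with two visits a year apart.
#'
#' @param events event data.frame for one patient (or
#'   \linkS4class{EHRData} with one patient).
#' @return visits per year (numeric).
#' @export
visitRate <- function(events) {
  ev <- if (is(events, "EHRData")) events(events) else events
  v <- ev$date[ev$event_type == "visit"]
  if (!length(v)) stop("visit rate undefined: record has no visit events")
  length(v) / max(1, max(v) - min(v)) * 365
}

#' Bin a visit rate
#'
#' Equal-width bins of 2 visits/year: [0,2), [2,4), ..., with the last
#' bin [18, Inf) unbounded; returns the 0-based bin index
#' \code{min(floor(rate / 2), 9)}.
#'
#' @param rate visits per year (vectorized, >= 0).
#' @return integer bin index in 0..9.
#' @export
binVisitRate <- function(rate) {
  stopifnot(all(rate >= 0))
  pmin(as.integer(rate %/% 2), 9L)
}

#' Remove the pre-treatment blackout window
#'
#' Drops events dated in \code{(start - blackoutDays, start]}: the
#' interval between (approximately) diagnosis and the start of treatment,
#' so models assess the patient's history without the clinician's initial
#' evaluation. Events at or before \code{start - blackoutDays} are kept.
#'
#' @param events event data.frame.
#' @param treatmentStart treatment start day offset.
#' @param blackoutDays window length (default 10).
#' @return The retained events, order preserved.
#' @export
applyPretreatmentBlackout <- function(events, treatmentStart,
                                      blackoutDays = 10L) {
  ev <- if (is(events, "EHRData")) events(events) else events
  drop <- ev$date > treatmentStart - blackoutDays & ev$date <= treatmentStart
  ev[!drop, , drop = FALSE]
}

.FEATURE_NS <- c(visit = NA_character_, icd9 = "icd9", term = "term",
                 drug_mention = "drug", rx = "cui", cpt = "cui",
                 phq9 = NA_character_)

# Assemble a sparse features x patients indicator matrix from (patient,
# feature) pairs plus dense demographic rows, aligned to `featureIds`
# when a training dictionary is supplied.
.assembleMatrix <- function(pairs, patientIds, demoRows, featureIds = NULL) {
  indicatorIds <- sort(unique(pairs$feature))
  if (!is.null(featureIds)) {
    demoIds <- rownames(demoRows)
    indicatorIds <- setdiff(featureIds, demoIds)
    pairs <- pairs[pairs$feature %in% indicatorIds, , drop = FALSE]
  }
  i <- match(pairs$feature, indicatorIds)
  j <- match(pairs$patient_id, patientIds)
  ind <- Matrix::sparseMatrix(
    i = i, j = j, x = 1,
    dims = c(length(indicatorIds), length(patientIds)),
    dimnames = list(indicatorIds, patientIds))
  ind@x[] <- 1  # collapse duplicate (feature, patient) pairs to presence
  full <- rbind(Matrix::Matrix(demoRows, sparse = TRUE), ind)
  if (!is.null(featureIds)) full <- full[featureIds, , drop = FALSE]
  full
}

#' Build the diagnosis-task feature matrix
#'
#' One column per cohort patient (cases and matched controls), one row
#' per feature. Indicator rows are the ICD-9 codes, assertive note terms
#' and drug-ingredient mentions present in the truncated history
#' (truncation at \code{index + cutoff}; each control's index is the end
#' of its history); \code{visit_bin:k} rows one-hot the binned average
#' visits/year of the truncated record; \code{demo:gender_female} encodes
#' gender. Every feature used to define the phenotype (the depression
#' ICD-9 set, depression terms, antidepressant ingredients) is removed
#' and logged in \code{metadata(x)$excluded_features}, as are negated and
#' family-history-flagged mentions (dropped, not logged per mention).
#'
#' @param data an \linkS4class{EHRData}.
#' @param cohort a \linkS4class{CohortAssignment}; only case/control rows
#'   enter the matrix.
#' @param config the \linkS4class{PhenotypeConfig} defining the phenotype
#'   features to exclude.
#' @param cutoff truncation offset in days (<= 0), applied to every
#'   patient relative to its own index.
#' @param featureIds optional training-dictionary row names; the result
#'   is aligned to exactly these rows (absent features all-zero).
#' @param truncate set FALSE to keep full histories (used for controls in
#'   the training asymmetry).
#' @return An \linkS4class{EHRFeatureMatrix}.
#' @export
buildFeatureMatrix <- function(data, cohort, config = phenotypeConfig(),
                               cutoff = 0L, featureIds = NULL,
                               truncate = TRUE) {
  a <- assignments(cohort)
  a <- a[a$label %in% c("case", "control"), , drop = FALSE]
  if (!nrow(a)) stop("cohort has no case/control patients")
  ev <- data.table::as.data.table(events(data))
  ev <- ev[ev$patient_id %in% a$patient_id, ]
  idx <- a$index_date[match(ev$patient_id, a$patient_id)]
  if (truncate) ev <- ev[ev$date <= idx + cutoff, ]

  ## indicator features from usable annotations; coded events keep all
  keep <- ev$event_type %in% c("icd9", "rx", "cpt") |
    (ev$event_type %in% c("term", "drug_mention") &
       !ev$negated & !ev$family_history)
  feats <- ev[keep & ev$event_type %in% names(.FEATURE_NS), ]
  ns <- .FEATURE_NS[feats$event_type]
  feats <- feats[!is.na(ns), ]
  ns <- ns[!is.na(ns)]
  pairs <- unique(data.frame(patient_id = feats$patient_id,
                             feature = paste0(ns, ":", feats$code),
                             namespace = ns, code = feats$code,
                             stringsAsFactors = FALSE))

  ## remove phenotype-defining features
  isPheno <- (pairs$namespace == "icd9" &
                .icd9Matches(pairs$code, config@icd9Codes)) |
    (pairs$namespace %in% c("term", "drug") &
       pairs$code %in% c(config@depressionTerms,
                         config@antidepressantIngredients))
  excluded <- unique(data.frame(
    feature = pairs$feature[isPheno],
    reason = rep("phenotype_defining", sum(isPheno)),
    stringsAsFactors = FALSE))
  pairs <- pairs[!isPheno, , drop = FALSE]

  ## visit-rate bins from the truncated record
  vis <- ev[ev$event_type == "visit",
            list(rate = .N / max(1, max(date) - min(date)) * 365),
            by = "patient_id"]
  vbin <- data.frame(patient_id = vis$patient_id,
                     feature = sprintf("visit_bin:%d",
                                       binVisitRate(vis$rate)),
                     stringsAsFactors = FALSE)
  pairs <- rbind(pairs[c("patient_id", "feature")], vbin)

  pats <- patients(data)
  demo <- matrix(as.numeric(pats$gender[match(a$patient_id,
                                              pats$patient_id)] == "F"),
                 nrow = 1, dimnames = list("demo:gender_female",
                                           a$patient_id))
  m <- .assembleMatrix(pairs, a$patient_id, demo, featureIds)
  nsOut <- sub(":.*$", "", rownames(m))
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(present = m),
    rowData = S4Vectors::DataFrame(namespace = nsOut,
                                   row.names = rownames(m)),
    colData = S4Vectors::DataFrame(
      label = a$label, index_date = a$index_date,
      matched_case = a$matched_case, row.names = a$patient_id))
  out <- new("EHRFeatureMatrix", se)
  S4Vectors::metadata(out) <- list(cutoff = cutoff,
                                   excluded_features = excluded)
  out
}

#' Build the treatment-task feature matrix
#'
#' One column per treatment episode patient. History rows are the
#' assertive term/code indicators present strictly before the
#' pre-treatment blackout (events after \code{start - blackoutDays} are
#' removed). Demographic rows are age at treatment start, gender, and --
#' unless \code{includeBaselinePhq9 = FALSE}, as the severity task
#' requires -- the baseline PHQ-9 score. PHQ-9-derived event features are
#' always removed and logged.
#'
#' @param data an \linkS4class{EHRData} (GHRI-mode).
#' @param episodes data.frame from \code{\link{firstTreatmentEpisodes}}.
#' @param blackoutDays pre-treatment exclusion window (default 10).
#' @param includeBaselinePhq9 include \code{demo:baseline_phq9}?
#' @param featureIds optional training-dictionary alignment.
#' @return An \linkS4class{EHRFeatureMatrix} whose colData carries
#'   modality, baseline score and the improvement label.
#' @export
buildTreatmentFeatureMatrix <- function(data, episodes, blackoutDays = 10L,
                                        includeBaselinePhq9 = TRUE,
                                        featureIds = NULL) {
  ev <- data.table::as.data.table(events(data))
  ev <- ev[ev$patient_id %in% episodes$patient_id, ]
  start <- episodes$start_day[match(ev$patient_id, episodes$patient_id)]
  ## truncate at treatment start, then drop the blackout (start-10, start]
  ev <- ev[ev$date <= start - blackoutDays, ]

  keep <- ev$event_type %in% c("icd9", "rx", "cpt") |
    (ev$event_type %in% c("term", "drug_mention") &
       !ev$negated & !ev$family_history)
  feats <- ev[keep & ev$event_type %in% names(.FEATURE_NS), ]
  ns <- .FEATURE_NS[feats$event_type]
  ok <- !is.na(ns)
  pairs <- unique(data.frame(patient_id = feats$patient_id[ok],
                             feature = paste0(ns[ok], ":", feats$code[ok]),
                             stringsAsFactors = FALSE))
  excluded <- data.frame(feature = character(), reason = character(),
                         stringsAsFactors = FALSE)
  phqFeat <- grepl("phq", pairs$feature, ignore.case = TRUE)
  if (any(phqFeat)) {
    excluded <- rbind(excluded,
                      data.frame(feature = unique(pairs$feature[phqFeat]),
                                 reason = "phq9_derived",
                                 stringsAsFactors = FALSE))
    pairs <- pairs[!phqFeat, , drop = FALSE]
  }

  pats <- patients(data)
  pidx <- match(episodes$patient_id, pats$patient_id)
  demo <- rbind(
    "demo:age" = as.numeric(ageAt(pats$birth_year[pidx],
                                  episodes$start_day)),
    "demo:gender_female" = as.numeric(pats$gender[pidx] == "F"))
  if (includeBaselinePhq9)
    demo <- rbind(demo,
                  "demo:baseline_phq9" = as.numeric(episodes$baseline_phq9))
  else
    excluded <- rbind(excluded,
                      data.frame(feature = "demo:baseline_phq9",
                                 reason = "direct_severity_measure",
                                 stringsAsFactors = FALSE))
  colnames(demo) <- episodes$patient_id

  m <- .assembleMatrix(pairs, episodes$patient_id, demo, featureIds)
  nsOut <- sub(":.*$", "", rownames(m))
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(present = m),
    rowData = S4Vectors::DataFrame(namespace = nsOut,
                                   row.names = rownames(m)),
    colData = S4Vectors::DataFrame(
      modality = episodes$modality,
      baseline_phq9 = episodes$baseline_phq9,
      improved = episodes$improved,
      start_day = episodes$start_day,
      row.names = episodes$patient_id))
  out <- new("EHRFeatureMatrix", se)
  S4Vectors::metadata(out) <- list(cutoff = -as.integer(blackoutDays),
                                   excluded_features = excluded)
  out
}

#' Predictor matrix for model fitting
#'
#' @param fm an \linkS4class{EHRFeatureMatrix}.
#' @return Sparse patients x features matrix (the transposed assay).
#' @export
featureMatrixToX <- function(fm) {
  Matrix::t(SummarizedExperiment::assay(fm, "present"))
}
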