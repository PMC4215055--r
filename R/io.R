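#' @include AllClasses.R utils.R
NULL

#' Read and write the canonical tables
#'
#' CSV round-trip for the canonical event table (patient_id, date,
#' event_type, code, negated 0/1, family_history 0/1, value), the
#' patients table, the treatments table and a cohort assignment.
#' \code{writeEHRData}/\code{readEHRData} bundle the tables of an
#' \linkS4class{EHRData} in a directory.
#'
#' @param data,cohort the object to write.
#' @param path,dir file or directory path.
#' @return Readers return the object; writers return the path invisibly.
#' @name depredict-io
NULL

#' @rdname depredict-io
#' @export
writeEHRData <- function(data, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  ev <- events(data)
  ev$negated <- as.integer(ev$negated)
  ev$family_history <- as.integer(ev$family_history)
  data.table::fwrite(ev, file.path(dir, "events.csv"))
  data.table::fwrite(patients(data), file.path(dir, "patients.csv"))
  if (nrow(treatments(data)))
    data.table::fwrite(treatments(data), file.path(dir, "treatments.csv"))
  invisible(dir)
}

#' @rdname depredict-io
#' @export
readEHRData <- function(dir) {
  ev <- as.data.frame(data.table::fread(file.path(dir, "events.csv"),
                                        na.strings = c("", "NA")))
  ev$negated <- as.logical(ev$negated)
  ev$family_history <- as.logical(ev$family_history)
  ev$code <- as.character(ev$code)
  ev$value <- as.numeric(ev$value)
  pats <- as.data.frame(data.table::fread(file.path(dir, "patients.csv")))
  trPath <- file.path(dir, "treatments.csv")
  tr <- if (file.exists(trPath))
    as.data.frame(data.table::fread(trPath)) else .emptyTreatments()
  EHRData(pats, ev, tr)
}

#' @rdname depredict-io
#' @export
writeCohort <- function(cohort, path) {
  data.table::fwrite(assignments(cohort), path)
  invisible(path)
}

#' Write a feature matrix as sparse triplets
#'
#' Two CSVs: \code{<stem>_triplets.csv} (patient_id, feature_id, value)
#' and \code{<stem>_features.csv} (feature_id, namespace), plus the
#' applied cutoff in the feature dictionary header-free metadata column.
#'
#' @param fm an \linkS4class{EHRFeatureMatrix}.
#' @param stem path stem for the two files.
#' @return The stem, invisibly.
#' @export
writeFeatureMatrix <- function(fm, stem) {
  m <- SummarizedExperiment::assay(fm, "present")
  tm <- Matrix::summary(methods::as(m, "TsparseMatrix"))
  trip <- data.frame(patient_id = colnames(m)[tm$j],
                     feature_id = rownames(m)[tm$i],
                     value = tm$x, stringsAsFactors = FALSE)
  data.table::fwrite(trip, paste0(stem, "_triplets.csv"))
  data.table::fwrite(
    data.frame(feature_id = rownames(m),
               namespace = SummarizedExperiment::rowData(fm)$namespace,
               cutoff = S4Vectors::metadata(fm)$cutoff,
               stringsAsFactors = FALSE),
    paste0(stem, "_features.csv"))
  invisible(stem)
}

#' Write a fitted model as JSON
#'
#' Coefficients (nonzero only), intercept, penalty and selection rule.
#'
#' @param fit a \linkS4class{ModelFit}.
#' @param path output path.
#' @return The path, invisibly.
#' @export
writeModelFit <- function(fit, path) {
  co <- fit@coefficients
  jsonlite::write_json(
    list(intercept = fit@intercept, lambda = fit@lambda, rule = fit@rule,
         n_nonzero = sum(co != 0),
         coefficients = as.list(co[co != 0])),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Write ROC curve points and summary
#'
#' The curve as CSV (threshold, fpr, tpr) and, alongside it, a JSON
#' summary with AUC, its confidence interval and the interpolated
#' sensitivities.
#'
#' @param roc a \linkS4class{RocResult}.
#' @param stem path stem; writes \code{<stem>_roc.csv} and
#'   \code{<stem>_summary.json}.
#' @return The stem, invisibly.
#' @export
writeRocResult <- function(roc, stem) {
  utils::write.csv(rocCurve(roc), paste0(stem, "_roc.csv"),
                   row.names = FALSE)
  jsonlite::write_json(
    list(auc = auc(roc), ci_low = roc@ciLow, ci_high = roc@ciHigh,
         ci_method = roc@ciMethod,
         sensitivity_at = as.list(sensitivityAt(roc)),
         n_pos = roc@nPos, n_neg = roc@nNeg),
    paste0(stem, "_summary.json"), auto_unbox = TRUE, digits = NA)
  invisible(stem)
}
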