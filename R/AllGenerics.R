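#' @include AllClasses.R
NULL

#' Accessors for depredict containers
#'
#' Small accessor family: \code{patients}, \code{events} and
#' \code{treatments} extract the component tables of an
#' \linkS4class{EHRData}; \code{concepts} and \code{conceptProvenance}
#' extract a \linkS4class{TermSet}; \code{assignments} and
#' \code{unmatchedCases} extract a \linkS4class{CohortAssignment};
#' \code{auc}, \code{aucCi}, \code{rocCurve} and \code{sensitivityAt}
#' extract a \linkS4class{RocResult}; \code{nNonzero} counts the nonzero
#' coefficients of a \linkS4class{ModelFit}; \code{moderatorTable}
#' extracts a \linkS4class{ModeratorReport}.
#'
#' @param object an object of the respective class.
#' @return The underlying table or scalar.
#' @name accessors
#' @aliases patients events treatments concepts conceptProvenance
#'   assignments unmatchedCases auc aucCi rocCurve sensitivityAt nNonzero
#'   moderatorTable
NULL

#' @rdname accessors
#' @export
setGeneric("patients", function(object) standardGeneric("patients"))
#' @rdname accessors
#' @export
setGeneric("events", function(object) standardGeneric("events"))
#' @rdname accessors
#' @export
setGeneric("treatments", function(object) standardGeneric("treatments"))
#' @rdname accessors
#' @export
setGeneric("concepts", function(object) standardGeneric("concepts"))
#' @rdname accessors
#' @export
setGeneric("conceptProvenance",
           function(object) standardGeneric("conceptProvenance"))
#' @rdname accessors
#' @export
setGeneric("assignments", function(object) standardGeneric("assignments"))
#' @rdname accessors
#' @export
setGeneric("unmatchedCases", function(object) standardGeneric("unmatchedCases"))
#' @rdname accessors
#' @export
setGeneric("auc", function(object) standardGeneric("auc"))
#' @rdname accessors
#' @export
setGeneric("aucCi", function(object) standardGeneric("aucCi"))
#' @rdname accessors
#' @export
setGeneric("rocCurve", function(object) standardGeneric("rocCurve"))
#' @rdname accessors
#' @export
setGeneric("sensitivityAt", function(object) standardGeneric("sensitivityAt"))
#' @rdname accessors
#' @export
setGeneric("nNonzero", function(object) standardGeneric("nNonzero"))
#' @rdname accessors
#' @export
setGeneric("moderatorTable", function(object) standardGeneric("moderatorTable"))

#' @rdname accessors
setMethod("patients", "EHRData", function(object) object@patients)
#' @rdname accessors
setMethod("events", "EHRData", function(object) object@events)
#' @rdname accessors
setMethod("treatments", "EHRData", function(object) object@treatments)
#' @rdname accessors
setMethod("concepts", "TermSet", function(object) object@concepts)
#' @rdname accessors
setMethod("conceptProvenance", "TermSet", function(object) {
  c(stats::setNames(object@provenance, object@concepts),
    stats::setNames(rep("removed_by_filter", length(object@removed)),
                    object@removed))
})
#' @rdname accessors
setMethod("assignments", "CohortAssignment", function(object)
  object@assignments)
#' @rdname accessors
setMethod("unmatchedCases", "CohortAssignment", function(object)
  object@unmatched)
#' @rdname accessors
setMethod("auc", "RocResult", function(object) object@auc)
#' @rdname accessors
setMethod("aucCi", "RocResult", function(object)
  c(low = object@ciLow, high = object@ciHigh))
#' @rdname accessors
setMethod("rocCurve", "RocResult", function(object) object@curve)
#' @rdname accessors
setMethod("sensitivityAt", "RocResult", function(object) object@sensitivityAt)
#' @rdname accessors
setMethod("nNonzero", "ModelFit", function(object)
  sum(object@coefficients != 0))
#' @rdname accessors
setMethod("moderatorTable", "ModeratorReport", function(object) object@table)

#' @describeIn accessors coefficients of a fitted L1 model (named vector,
#'   intercept under \code{"(Intercept)"}).
#' @exportMethod coefficients
setMethod("coefficients", "ModelFit", function(object, ...)
  c("(Intercept)" = object@intercept, object@coefficients))

setMethod("show", "EHRData", function(object) {
  cat("EHRData:", nrow(object@patients), "patients,",
      nrow(object@events), "events")
  if (nrow(object@treatments))
    cat(",", nrow(object@treatments), "treatment records")
  cat("\n")
  tab <- table(object@events$event_type)
  cat("  event types:",
      paste(sprintf("%s=%d", names(tab), as.integer(tab)), collapse = ", "),
      "\n")
})

setMethod("show", "TermSet", function(object) {
  cat("TermSet:", length(object@concepts), "concepts (",
      sum(object@provenance == "seed"), "seed ),",
      length(object@removed), "removed by filter\n")
})

setMethod("show", "CohortAssignment", function(object) {
  tab <- table(object@assignments$label)
  cat("CohortAssignment:",
      paste(sprintf("%s=%d", names(tab), as.integer(tab)), collapse = ", "),
      "\n")
  if (nrow(object@unmatched))
    cat("  unmatched cases:", nrow(object@unmatched), "\n")
})

setMethod("show", "RocResult", function(object) {
  cat(sprintf("RocResult: AUC %.3f (95%% CI %.3f-%.3f, %s), %d pos / %d neg\n",
              object@auc, object@ciLow, object@ciHigh, object@ciMethod,
              object@nPos, object@nNeg))
  if (length(object@sensitivityAt))
    cat("  sensitivity at specificity:",
        paste(sprintf("%s -> %.3f", names(object@sensitivityAt),
                      object@sensitivityAt), collapse = ", "), "\n")
})

setMethod("show", "ModelFit", function(object) {
  cat(sprintf(
    "ModelFit: L1 logistic, lambda %.4g (%s), %d nonzero of %d features\n",
    object@lambda, object@rule, sum(object@coefficients != 0),
    length(object@coefficients)))
})

setMethod("show", "ModeratorReport", function(object) {
  t <- object@table
  cat("ModeratorReport:", nrow(t), "candidate features;",
      sum(t$interaction_p_adj < 0.05, na.rm = TRUE),
      "BH-significant interactions at 0.05\n")
})
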