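#' @include AllClasses.R features.R roc.R outcomes.R
NULL

#' Fit an L1-penalized (LASSO) logistic model
#'
#' Cross-validated LASSO logistic regression: the penalty is selected by
#' k-fold cross-validation on the training data with the one-standard-
#' error rule by default (the sparser model within one SE of the minimum
#' deviance). Features with no predictive value receive exactly zero
#' weight. Feature standard deviations are stored so coefficients can be
#' ranked on a standardized scale.
#'
#' @param x patients x features matrix (dense or sparse), or an
#'   \linkS4class{EHRFeatureMatrix}.
#' @param y 0/1 or logical outcome, one per row of \code{x}.
#' @param nfolds cross-validation folds (default 10).
#' @param rule \code{"lambda.1se"} (default) or \code{"lambda.min"}.
#' @param seed optional seed controlling the fold assignment.
#' @return A \linkS4class{ModelFit}.
#' @export
fitL1Logistic <- function(x, y, nfolds = 10L,
                          rule = c("lambda.1se", "lambda.min"),
                          seed = NULL) {
  rule <- match.arg(rule)
  if (is(x, "EHRFeatureMatrix")) x <- featureMatrixToX(x)
  y <- as.numeric(y)
  if (length(unique(y)) < 2L)
    stop("training outcome has a single class; cannot fit")
  .withSeed(seed, {
    ## bounded penalty path: with n > p glmnet's default descends to
    ## lambda.min.ratio = 1e-4, spending most of the time on near-
    ## unpenalized fits the selection rules never choose
    cv <- glmnet::cv.glmnet(x, y, family = "binomial", nfolds = nfolds,
                            nlambda = 60, lambda.min.ratio = 0.01)
    lam <- if (rule == "lambda.1se") cv$lambda.1se else cv$lambda.min
    co <- as.numeric(stats::coef(cv, s = lam))
    nm <- rownames(stats::coef(cv, s = lam))
    n <- nrow(x)
    mu <- Matrix::colMeans(x)
    sds <- sqrt(pmax(0, (Matrix::colMeans(x^2) - mu^2) * n / (n - 1)))
    new("ModelFit",
        coefficients = stats::setNames(co[-1L], nm[-1L]),
        intercept = co[1L], lambda = lam, rule = rule,
        featureSd = stats::setNames(as.numeric(sds), colnames(x)),
        nObs = nrow(x))
  })
}

#' Predicted risk scores
#'
#' @param fit a \linkS4class{ModelFit}.
#' @param x patients x features matrix or \linkS4class{EHRFeatureMatrix};
#'   columns are aligned to the fit's features by name (missing features
#'   contribute zero).
#' @return numeric vector of predicted probabilities.
#' @export
predictRisk <- function(fit, x) {
  if (is(x, "EHRFeatureMatrix")) x <- featureMatrixToX(x)
  feats <- names(fit@coefficients)
  common <- intersect(feats, colnames(x))
  eta <- rep(fit@intercept, nrow(x))
  if (length(common))
    eta <- eta + as.numeric(x[, common, drop = FALSE] %*%
                              fit@coefficients[common])
  stats::plogis(eta)
}

#' Rank model features by standardized coefficient size
#'
#' Coefficients are compared as \code{|beta_j| * sd(x_j)} so binary
#' indicators and wide-range numeric features (age, baseline PHQ-9) are
#' on a common scale.
#'
#' @param fit a \linkS4class{ModelFit}.
#' @return data.frame of nonzero features sorted by standardized effect.
#' @export
rankCoefficients <- function(fit) {
  co <- fit@coefficients
  nz <- co[co != 0]
  if (!length(nz))
    return(data.frame(feature = character(), coef = numeric(),
                      std_effect = numeric(), stringsAsFactors = FALSE))
  eff <- abs(nz) * fit@featureSd[names(nz)]
  o <- order(eff, decreasing = TRUE)
  data.frame(feature = names(nz)[o], coef = unname(nz[o]),
             std_effect = unname(eff[o]), stringsAsFactors = FALSE)
}

# Case-unit 80/20 split: sample cases, their matched controls follow.
.splitCohort <- function(cohort, trainFraction, seed) {
  a <- assignments(cohort)
  caseIds <- a$patient_id[a$label == "case"]
  .withSeed(seed, {
    trainCases <- sample(caseIds, size = floor(trainFraction *
                                                 length(caseIds)))
    testCases <- setdiff(caseIds, trainCases)
    ctrl <- a[a$label == "control", ]
    list(train = c(trainCases,
                   ctrl$patient_id[ctrl$matched_case %in% trainCases]),
         test = c(testCases,
                  ctrl$patient_id[ctrl$matched_case %in% testCases]))
  })
}

.subsetCohort <- function(cohort, ids) {
  a <- assignments(cohort)
  new("CohortAssignment",
      assignments = a[a$patient_id %in% ids, , drop = FALSE],
      unmatched = unmatchedCases(cohort))
}

#' Prediction-horizon experiment for depression diagnosis
#'
#' Trains one LASSO model and evaluates it on test sets truncated at
#' each cutoff. The split is by case unit (a case and its matched
#' controls stay together); one shared train/test partition serves all
#' cutoffs. Training uses the published asymmetry: case histories
#' truncated at the index date, control histories complete. Each test
#' set truncates every patient (cases at index + cutoff, controls
#' relative to end of history).
#'
#' @param data an \linkS4class{EHRData}.
#' @param cohort a \linkS4class{CohortAssignment} from
#'   \code{\link{buildCohort}}.
#' @param config a \linkS4class{PhenotypeConfig}.
#' @param cutoffs truncation offsets in days (default 0, -183, -365).
#' @param trainFraction training fraction of cases (default 0.8).
#' @param seed RNG seed for split and cross-validation.
#' @param nfolds cross-validation folds for the penalty search.
#' @return list with \code{fit} (the \linkS4class{ModelFit}),
#'   \code{roc} (named list of \linkS4class{RocResult}, one per cutoff)
#'   and \code{split} (the patient partition).
#' @export
runHorizonExperiment <- function(data, cohort, config = phenotypeConfig(),
                                 cutoffs = c(0L, -183L, -365L),
                                 trainFraction = 0.8, seed = 1L,
                                 nfolds = 10L) {
  stopifnot(trainFraction > 0, trainFraction < 1)
  split <- .splitCohort(cohort, trainFraction, seed)
  stopifnot(!length(intersect(split$train, split$test)))
  trainFm <- buildFeatureMatrix(data, .subsetCohort(cohort, split$train),
                                config, cutoff = 0L)
  labTrain <- as.numeric(SummarizedExperiment::colData(trainFm)$label ==
                           "case")
  fit <- fitL1Logistic(trainFm, labTrain, nfolds = nfolds, seed = seed)
  dict <- rownames(trainFm)
  testCohort <- .subsetCohort(cohort, split$test)
  roc <- lapply(cutoffs, function(off) {
    fm <- buildFeatureMatrix(data, testCohort, config, cutoff = off,
                             featureIds = dict)
    lab <- as.numeric(SummarizedExperiment::colData(fm)$label == "case")
    evaluateRoc(predictRisk(fit, fm), lab)
  })
  names(roc) <- as.character(cutoffs)
  list(fit = fit, roc = roc, split = split)
}

# Shared GHRI-task scaffolding: episodes -> matrix -> split -> fit -> roc.
.runGhriTask <- function(data, episodes, labels, includeBaselinePhq9,
                         trainFraction, seed, nfolds,
                         rule = "lambda.1se") {
  fm <- buildTreatmentFeatureMatrix(data, episodes,
                                    includeBaselinePhq9 =
                                      includeBaselinePhq9)
  if (!includeBaselinePhq9 &&
      any(grepl("phq", rownames(fm), ignore.case = TRUE)))
    stop("PHQ-9-derived feature present in a severity matrix")
  x <- featureMatrixToX(fm)
  n <- nrow(x)
  idx <- .withSeed(seed, sample.int(n, floor(trainFraction * n)))
  test <- setdiff(seq_len(n), idx)
  fit <- fitL1Logistic(x[idx, , drop = FALSE], labels[idx],
                       nfolds = nfolds, rule = rule, seed = seed)
  roc <- evaluateRoc(predictRisk(fit, x[test, , drop = FALSE]),
                     labels[test])
  list(fit = fit, roc = roc, ranked = rankCoefficients(fit),
       matrix = fm, train = idx, test = test)
}

#' Treatment-response experiment
#'
#' For one modality, restricts to patients whose first treatment is
#' exactly that modality (patients starting medication and psychotherapy
#' together are excluded), labels improvement as a PHQ-9 drop of at
#' least 5 points, and fits a LASSO model on age, gender, baseline
#' PHQ-9 and post-blackout history indicators. Reports test-set ROC and
#' the feature ranking by standardized coefficient.
#'
#' @param data a GHRI-mode \linkS4class{EHRData}.
#' @param modality \code{"medication"} or \code{"psychotherapy"}.
#' @param trainFraction training fraction (default 0.8).
#' @param seed,nfolds as in \code{\link{fitL1Logistic}}.
#' @param rule penalty rule; default \code{"lambda.min"} here because the
#'   response task's purpose is ranking predictive features, and at this
#'   effect size the 1-SE rule often returns the empty model, which can
#'   rank nothing.
#' @return list with fit, roc, ranked coefficients and the top feature.
#' @export
runResponseExperiment <- function(data,
                                  modality = c("medication",
                                               "psychotherapy"),
                                  trainFraction = 0.8, seed = 1L,
                                  nfolds = 10L, rule = "lambda.min") {
  modality <- match.arg(modality)
  ep <- firstTreatmentEpisodes(data)
  ep <- ep[ep$modality == modality & !is.na(ep$improved), , drop = FALSE]
  if (nrow(ep) < 20L) stop("too few ", modality, " episodes")
  res <- .runGhriTask(data, ep, as.numeric(ep$improved),
                      includeBaselinePhq9 = TRUE,
                      trainFraction, seed, nfolds, rule = rule)
  res$topFeature <- if (nrow(res$ranked)) res$ranked$feature[1L]
  else NA_character_
  res$modality <- modality
  res
}

#' Baseline-severity experiment
#'
#' Detects severe baseline depression (PHQ-9 > 19) against minimal/mild
#' (PHQ-9 <= 9) at first treatment; moderate and moderately-severe
#' patients are excluded from the task. The baseline PHQ-9 feature is a
#' direct measure of the target and is excluded from the matrix; the
#' fit aborts if any PHQ-9-derived column survives.
#'
#' @inheritParams runResponseExperiment
#' @return list with fit, roc and ranked coefficients.
#' @export
runSeverityExperiment <- function(data, trainFraction = 0.8, seed = 1L,
                                  nfolds = 10L) {
  ep <- firstTreatmentEpisodes(data)
  sev <- phq9Severity(ep$baseline_phq9)
  keep <- sev %in% c("minimal", "mild", "severe")
  ep <- ep[keep, , drop = FALSE]
  y <- as.numeric(ep$baseline_phq9 > 19)
  res <- .runGhriTask(data, ep, y, includeBaselinePhq9 = FALSE,
                      trainFraction, seed, nfolds)
  res$nSevere <- sum(y == 1)
  res$nMinimalMild <- sum(y == 0)
  res
}

#' Nonzero coefficient counts over repeated random splits
#'
#' Model size in a penalized fit varies with the training split; reported
#' feature counts ("n features on average") are therefore means over
#' repeated random splits. Runs the response experiment \code{repeats}
#' times with derived seeds and collects the nonzero coefficient count of
#' each fit.
#'
#' @inheritParams runResponseExperiment
#' @param repeats number of random splits (default 10).
#' @param ... passed to \code{\link{runResponseExperiment}}.
#' @return integer vector of nonzero counts, one per repeat; summarize
#'   with \code{mean()}.
#' @export
repeatedNonzeroCounts <- function(data, modality = "medication",
                                  repeats = 10L, seed = 1L, ...) {
  vapply(seq_len(repeats), function(r) {
    fit <- runResponseExperiment(data, modality,
                                 seed = seed + r * 101L, ...)$fit
    sum(fit@coefficients != 0)
  }, integer(1))
}
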