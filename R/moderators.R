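#' @include AllClasses.R prediction.R
NULL

.entropyBits <- function(counts) {
  p <- counts / sum(counts)
  p <- p[p > 0]
  -sum(p * log2(p))
}

#' Information gain of a feature for a binary outcome
#'
#' \code{H(outcome) - sum_v P(feature = v) H(outcome | feature = v)} with
#' base-2 entropy and the \code{0 log 0 = 0} convention. Non-negative;
#' equals \code{H(outcome)} iff the feature determines the outcome, 0 for
#' a constant or independent feature.
#'
#' @param feature vector (any discrete coding; typically 0/1).
#' @param outcome binary vector of the same length.
#' @return information gain in bits.
#' @export
informationGain <- function(feature, outcome) {
  stopifnot(length(feature) == length(outcome), length(outcome) >= 1L)
  h <- .entropyBits(table(outcome))
  tab <- table(feature, outcome)
  nv <- rowSums(tab)
  cond <- sum(nv / sum(nv) *
                apply(tab, 1L, .entropyBits))
  max(0, h - cond)
}

#' Screen the top-k outcome predictors by information gain
#'
#' Ranks every feature column by information gain for the screening
#' outcome and returns the top \code{k}; ties are broken by column order
#' (fixed feature-id order, so the screen is deterministic).
#'
#' @param x patients x features matrix (binary columns) or
#'   \linkS4class{EHRFeatureMatrix}.
#' @param outcome binary vector, one per patient.
#' @param k number of predictors to keep (default 100).
#' @return data.frame with feature, information_gain and rank, in rank
#'   order.
#' @export
screenTopK <- function(x, outcome, k = 100L) {
  if (is(x, "EHRFeatureMatrix")) x <- featureMatrixToX(x)
  if (ncol(x) < k)
    stop("need at least k = ", k, " features, have ", ncol(x))
  ig <- vapply(seq_len(ncol(x)),
               function(j) informationGain(as.numeric(x[, j]), outcome),
               numeric(1))
  o <- order(-ig, seq_along(ig))[seq_len(k)]
  data.frame(feature = colnames(x)[o], information_gain = ig[o],
             rank = seq_len(k), stringsAsFactors = FALSE)
}

#' Interaction-term moderator analysis
#'
#' One joint logistic model of the screening outcome on the candidate
#' features, the boolean treatment vector (1 = medication, 0 =
#' psychotherapy), and every feature-by-treatment product. A feature
#' whose interaction term is significant predicts differential response
#' to medication versus psychotherapy -- a treatment moderator. Wald
#' p-values on the interaction terms are reported raw and
#' Benjamini-Hochberg adjusted. Features with unstable (separated)
#' estimates are flagged non-estimable and excluded from the adjustment.
#'
#' @param x patients x features matrix of the screened candidates (binary
#'   columns, named).
#' @param treatment logical/0-1 vector: 1 for medication.
#' @param outcome logical/0-1 screening outcome (e.g. an absolute PHQ-9
#'   change of at least 5 points).
#' @param screen optional data.frame from \code{\link{screenTopK}}
#'   supplying information gain and rank; computed afresh otherwise.
#' @return A \linkS4class{ModeratorReport}, ordered by adjusted p.
#' @export
interactionAnalysis <- function(x, treatment, outcome, screen = NULL) {
  if (is(x, "EHRFeatureMatrix")) x <- featureMatrixToX(x)
  x <- as.matrix(x)
  treatment <- as.numeric(treatment)
  outcome <- as.numeric(outcome)
  stopifnot(nrow(x) == length(treatment), nrow(x) == length(outcome),
            all(treatment %in% c(0, 1)), all(outcome %in% c(0, 1)))
  k <- ncol(x)
  feats <- colnames(x)
  if (is.null(feats)) feats <- sprintf("f%03d", seq_len(k))

  inter <- x * treatment
  colnames(inter) <- paste0(feats, ":treatment")
  design <- cbind(x, treatment = treatment, inter)
  ## structural zeros (e.g. a severity stratum that can never improve)
  ## make IRLS report non-convergence while leaving the remaining
  ## coefficients usable; separation is detected and flagged below
  fit <- suppressWarnings(stats::glm.fit(cbind(1, design), outcome,
                                         family = stats::binomial()))
  co <- fit$coefficients[-1L]
  ## Wald SEs from the unscaled covariance of the IRLS fit
  cov <- tryCatch(chol2inv(fit$qr$qr[seq_len(fit$rank),
                                     seq_len(fit$rank), drop = FALSE]),
                  error = function(e) NULL)
  se <- rep(NA_real_, length(co) + 1L)
  if (!is.null(cov)) {
    piv <- fit$qr$pivot[seq_len(fit$rank)]
    se[piv] <- sqrt(diag(cov))
  }
  se <- se[-1L]
  names(se) <- names(co)

  mainCoef <- co[feats]
  intCoef <- co[paste0(feats, ":treatment")]
  intSe <- se[paste0(feats, ":treatment")]
  estimable <- is.finite(intCoef) & is.finite(intSe) &
    abs(intCoef) < 15 & intSe < 100
  z <- intCoef / intSe
  p <- ifelse(estimable, 2 * stats::pnorm(-abs(z)), NA_real_)
  padj <- rep(NA_real_, k)
  padj[estimable] <- stats::p.adjust(p[estimable], method = "BH")

  if (is.null(screen)) {
    ig <- vapply(seq_len(k),
                 function(j) informationGain(x[, j], outcome), numeric(1))
    rk <- rank(-ig, ties.method = "first")
  } else {
    ig <- screen$information_gain[match(feats, screen$feature)]
    rk <- screen$rank[match(feats, screen$feature)]
  }

  tab <- data.frame(feature = feats, information_gain = ig,
                    main_coef = unname(mainCoef),
                    interaction_coef = unname(intCoef),
                    interaction_se = unname(intSe),
                    interaction_p = unname(p),
                    interaction_p_adj = padj,
                    rank = rk, estimable = estimable,
                    stringsAsFactors = FALSE)
  tab <- tab[order(is.na(tab$interaction_p_adj), tab$interaction_p_adj), ]
  rownames(tab) <- NULL
  new("ModeratorReport", table = tab)
}

#' End-to-end moderator screen
#'
#' The published procedure: screen the top \code{k} predictors of an
#' absolute PHQ-9 change of at least 5 points (in either direction, the
#' default; set \code{outcome = "improvement"} for the one-sided
#' improvement label) by information gain over medication-only and
#' psychotherapy-only first episodes, then run the joint
#' interaction-term logistic model against the boolean treatment vector.
#' Candidates are the response-model features (baseline PHQ-9, gender,
#' history indicators); including the dominant outcome driver (baseline
#' severity) in the joint model keeps the interaction estimates from
#' being attenuated by omitted-variable non-collapsibility.
#'
#' @param data a GHRI-mode \linkS4class{EHRData}.
#' @param k number of screened predictors (default 100, reduced to the
#'   available feature count when smaller).
#' @param outcome \code{"abs_change"} (default, |change| >= 5) or
#'   \code{"improvement"} (drop >= 5).
#' @return list with \code{report} (\linkS4class{ModeratorReport}),
#'   \code{screen}, and the episode table used.
#' @export
runModeratorAnalysis <- function(data, k = 100L,
                                 outcome = c("abs_change",
                                             "improvement")) {
  outcome <- match.arg(outcome)
  ep <- firstTreatmentEpisodes(data)
  ep <- ep[ep$modality %in% c("medication", "psychotherapy") &
             !is.na(ep$improved), , drop = FALSE]
  fm <- buildTreatmentFeatureMatrix(data, ep, includeBaselinePhq9 = FALSE)
  x <- featureMatrixToX(fm)
  ## candidate set = the response-model features: baseline severity,
  ## gender and the history indicators. Severity enters as its standard
  ## bin indicators (reference: mild) rather than the raw score -- the
  ## minimal bin cannot improve 5 points at all (PHQ-9 floor), a
  ## structural zero a linear logit cannot represent and which would
  ## otherwise attenuate every coefficient in the joint model. Age is
  ## dropped from the information-gain screen (near-continuous, so
  ## empirical IG is biased upward).
  sev <- phq9Severity(ep$baseline_phq9)
  lev <- setdiff(levels(sev), "mild")
  bins <- vapply(lev, function(l) as.numeric(sev == l),
                 numeric(length(sev)))
  colnames(bins) <- paste0("demo:severity_", lev)
  x <- cbind(as.matrix(x[, setdiff(colnames(x), "demo:age"),
                         drop = FALSE]), bins)
  y <- if (outcome == "abs_change")
    as.numeric(abs(ep$baseline_phq9 - ep$followup_phq9) >= 5)
  else as.numeric(ep$improved)
  kUse <- min(k, ncol(x))
  sc <- screenTopK(x, y, k = kUse)
  rep <- interactionAnalysis(x[, sc$feature, drop = FALSE],
                             ep$modality == "medication", y, screen = sc)
  list(report = rep, screen = sc, episodes = ep, outcome = outcome)
}
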