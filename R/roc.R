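#' @include AllClasses.R
NULL

# Mann-Whitney AUC with half-credit for ties, via midranks.
.aucRank <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  m <- length(pos); n <- length(neg)
  r <- rank(c(pos, neg), ties.method = "average")
  (sum(r[seq_len(m)]) - m * (m + 1) / 2) / (m * n)
}

# DeLong variance of the AUC via the midrank formulation (placement
# values V10 for positives and V01 for negatives).
.delongVariance <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  m <- length(pos); n <- length(neg)
  r <- rank(c(pos, neg), ties.method = "average")
  rp <- rank(pos, ties.method = "average")
  rn <- rank(neg, ties.method = "average")
  v10 <- (r[seq_len(m)] - rp) / n
  v01 <- 1 - (r[m + seq_len(n)] - rn) / m
  s10 <- if (m > 1) stats::var(v10) else 0
  s01 <- if (n > 1) stats::var(v01) else 0
  s10 / m + s01 / n
}

# Empirical ROC curve over descending score thresholds, anchored at
# (0,0) and (1,1).
.rocPoints <- function(scores, labels) {
  o <- order(scores, decreasing = TRUE)
  s <- scores[o]; y <- labels[o]
  ## collapse tied scores into single thresholds
  last <- c(s[-1] != s[-length(s)], TRUE)
  tp <- cumsum(y)[last]
  fp <- cumsum(1 - y)[last]
  data.frame(threshold = c(Inf, s[last]),
             fpr = c(0, fp / sum(1 - y)),
             tpr = c(0, tp / sum(y)))
}

#' Evaluate ROC performance
#'
#' Computes the empirical ROC curve, the AUC by the trapezoidal rule
#' (equivalently the Mann-Whitney concordance with half-credit for tied
#' scores), a 95\% confidence interval by the DeLong method, and
#' sensitivity at requested specificities by linear interpolation along
#' the curve.
#'
#' @param scores numeric risk scores (higher = more case-like).
#' @param labels 0/1 (or logical) outcome labels; both classes must be
#'   present.
#' @param specificities specificities at which to interpolate
#'   sensitivity (default 0.8 and 0.9).
#' @param conf confidence level (default 0.95).
#' @return A \linkS4class{RocResult}.
#' @examples
#' evaluateRoc(c(.9, .8, .7, .6, .5, .4), c(1, 1, 0, 1, 0, 0))
#' @export
evaluateRoc <- function(scores, labels, specificities = c(0.8, 0.9),
                        conf = 0.95) {
  labels <- as.numeric(labels)
  if (length(scores) != length(labels) || anyNA(scores) || anyNA(labels))
    stop("scores and labels must be complete and of equal length")
  if (length(unique(labels)) < 2L || !all(labels %in% c(0, 1)))
    stop("labels must contain both classes (0 and 1)")
  curve <- .rocPoints(scores, labels)
  a <- .aucRank(scores, labels)
  v <- .delongVariance(scores, labels)
  z <- stats::qnorm(1 - (1 - conf) / 2)
  lo <- max(0, a - z * sqrt(v))
  hi <- min(1, a + z * sqrt(v))
  sens <- vapply(specificities, function(sp) {
    stats::approx(curve$fpr, curve$tpr, xout = 1 - sp, ties = max)$y
  }, numeric(1))
  new("RocResult", curve = curve, auc = a,
      ciLow = min(lo, a), ciHigh = max(hi, a),
      sensitivityAt = stats::setNames(sens, specificities),
      nPos = as.integer(sum(labels == 1)),
      nNeg = as.integer(sum(labels == 0)), ciMethod = "delong")
}
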