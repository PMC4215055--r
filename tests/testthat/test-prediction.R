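test_that("AUC equals all-pairs concordance with half-credit ties", {
  ## six hand-listed (score, label) pairs, including a tie across classes
  scores <- c(0.9, 0.8, 0.7, 0.7, 0.4, 0.1)
  labels <- c(1, 0, 1, 0, 1, 0)
  concordance <- function(s, y) {
    pos <- s[y == 1]; neg <- s[y == 0]
    (sum(outer(pos, neg, ">")) + 0.5 * sum(outer(pos, neg, "=="))) /
      (length(pos) * length(neg))
  }
  r <- evaluateRoc(scores, labels)
  expect_equal(auc(r), concordance(scores, labels), tolerance = 1e-12)
  set.seed(9)
  for (rep in 1:10) {
    s <- round(runif(40), 2)  # rounding forces ties
    y <- rbinom(40, 1, 0.4)
    if (length(unique(y)) < 2) next
    expect_equal(auc(evaluateRoc(s, y)), concordance(s, y),
                 tolerance = 1e-12)
  }
})

test_that("ROC handles perfect, null and degenerate inputs", {
  lab <- c(1, 1, 0, 1, 0, 0)
  expect_equal(auc(evaluateRoc(lab, lab)), 1.0)
  set.seed(10)
  r <- evaluateRoc(runif(4000), rbinom(4000, 1, 0.5))
  expect_lt(abs(auc(r) - 0.5), 0.03)
  expect_error(evaluateRoc(runif(5), rep(1, 5)), "both classes")
})

test_that("AUC obeys label-flip symmetry", {
  set.seed(12)
  for (rep in 1:10) {
    s <- rnorm(60); y <- rbinom(60, 1, 0.5)
    if (length(unique(y)) < 2) next
    expect_equal(auc(evaluateRoc(s, y)) + auc(evaluateRoc(s, 1 - y)), 1,
                 tolerance = 1e-12)
  }
})

test_that("DeLong interval brackets the AUC and shrinks like 1/sqrt(n)", {
  set.seed(13)
  widths <- vapply(c(100, 400, 1600), function(n) {
    y <- rep(c(0, 1), n / 2)
    s <- rnorm(n, mean = y)  # moderate separation
    r <- evaluateRoc(s, y)
    expect_gte(auc(r), aucCi(r)["low"])
    expect_lte(auc(r), aucCi(r)["high"])
    diff(aucCi(r))
  }, numeric(1))
  expect_true(all(diff(widths) < 0))
  ## quadrupling n should roughly halve the width
  expect_lt(widths[3], widths[1] / 2 * 1.4)
  ## monotone curve invariant
  cv <- rocCurve(evaluateRoc(rnorm(200), rbinom(200, 1, 0.5)))
  expect_false(is.unsorted(cv$fpr))
  expect_false(is.unsorted(cv$tpr))
})

test_that("sensitivity at specificity interpolates along the curve", {
  ## scores equal to labels: at any specificity < 1, sensitivity is 1
  r <- evaluateRoc(c(1, 1, 1, 0, 0, 0), c(1, 1, 1, 0, 0, 0))
  expect_equal(unname(sensitivityAt(r)[["0.9"]]), 1)
  set.seed(14)
  y <- rbinom(500, 1, 0.5); s <- rnorm(500, y)
  r2 <- evaluateRoc(s, y, specificities = c(0.5, 0.8, 0.95))
  sens <- sensitivityAt(r2)
  expect_true(all(diff(sens) <= 0))  # higher specificity, lower sensitivity
})

test_that("LASSO fits are sparse under noise and find planted separators", {
  set.seed(15)
  n <- 2000
  xNoise <- matrix(rbinom(n * 60, 1, 0.3), n, 60,
                   dimnames = list(NULL, paste0("f", 1:60)))
  y <- rbinom(n, 1, 0.5)
  fit <- fitL1Logistic(xNoise, y, seed = 1)
  expect_lte(nNonzero(fit), 3)  # pure noise: near-empty model at 1-SE

  ## one perfectly separating feature among 100 noise features
  x <- cbind(sep = y, matrix(rbinom(n * 100, 1, 0.3), n, 100,
                             dimnames = list(NULL, paste0("g", 1:100))))
  fit2 <- fitL1Logistic(x, y, seed = 1)
  expect_identical(rankCoefficients(fit2)$feature[1], "sep")

  ## stronger penalty never uses more features
  fitMin <- fitL1Logistic(x, y, rule = "lambda.min", seed = 1)
  expect_lte(nNonzero(fit2), nNonzero(fitMin))
  expect_error(fitL1Logistic(xNoise, rep(1, n)), "single class")
})

test_that("horizon experiment keeps train and test disjoint and seeded", {
  d <- smallPamf(n = 350, seed = 7)
  co <- buildCohort(d, seed = 7)
  hz <- runHorizonExperiment(d, co, seed = 7, nfolds = 5)
  expect_length(intersect(hz$split$train, hz$split$test), 0)
  expect_named(hz$roc, c("0", "-183", "-365"))
  hz2 <- runHorizonExperiment(d, co, seed = 7, nfolds = 5)
  expect_identical(vapply(hz$roc, auc, numeric(1)),
                   vapply(hz2$roc, auc, numeric(1)))
})

test_that("severity task rejects leaked PHQ-9 features and excludes the
          moderate strata", {
  g <- smallGhri(n = 1400, seed = 3)
  res <- runSeverityExperiment(g, seed = 3, nfolds = 5)
  expect_length(grep("phq", rownames(res$matrix), ignore.case = TRUE), 0)
  ep <- firstTreatmentEpisodes(g)
  sev <- phq9Severity(ep$baseline_phq9)
  expect_identical(res$nSevere + res$nMinimalMild,
                   sum(sev %in% c("minimal", "mild", "severe")))
  expect_gt(auc(res$roc), 0.5)  # severity-linked history features exist
})

test_that("single-modality response cohorts exclude both-treatment
          patients", {
  g <- smallGhri(n = 1400, seed = 4)
  res <- runResponseExperiment(g, "medication", seed = 4, nfolds = 5)
  ep <- firstTreatmentEpisodes(g)
  expect_identical(res$matrix@colData@nrows,
                   sum(ep$modality == "medication" & !is.na(ep$improved)))
  expect_false(any(ep$patient_id[ep$modality == "both"] %in%
                     rownames(SummarizedExperiment::colData(res$matrix))))
})

test_that("model and ROC results serialize to JSON/CSV", {
  set.seed(16)
  n <- 400
  x <- cbind(sig = rbinom(n, 1, 0.5),
             matrix(rbinom(n * 10, 1, 0.3), n, 10,
                    dimnames = list(NULL, paste0("b", 1:10))))
  y <- rbinom(n, 1, plogis(-0.5 + 1.5 * x[, "sig"]))
  fit <- fitL1Logistic(x, y, seed = 2)
  dir <- withr::local_tempdir()
  writeModelFit(fit, file.path(dir, "fit.json"))
  back <- jsonlite::read_json(file.path(dir, "fit.json"))
  expect_equal(back$n_nonzero, nNonzero(fit))
  r <- evaluateRoc(predictRisk(fit, x), y)
  writeRocResult(r, file.path(dir, "m"))
  summ <- jsonlite::read_json(file.path(dir, "m_summary.json"))
  expect_equal(summ$auc, auc(r))
  expect_identical(nrow(utils::read.csv(file.path(dir, "m_roc.csv"))),
                   nrow(rocCurve(r)))
})

test_that("repeated splits report a distribution of model sizes", {
  g <- smallGhri(n = 700, seed = 5)
  nz <- repeatedNonzeroCounts(g, "medication", repeats = 2L, seed = 5,
                              nfolds = 5L)
  expect_length(nz, 2L)
  expect_true(all(nz >= 0))
})
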