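test_that("history truncation keeps events up to index + offset", {
  ev <- evRow("P1", c(0, 100, 500, 864, 865, 1000), "icd9", "401.9")
  expect_identical(nrow(truncateHistory(ev, 1000L, 0L)), 6L)
  ## offset -365 from index 1229: day 864 kept, 865 dropped
  got <- truncateHistory(ev, 1229L, -365L)
  expect_identical(max(got$date), 864L)
  set.seed(5)
  for (rep in 1:10) {
    days <- sample(0:2000, 50, replace = TRUE)
    ev <- evRow("P1", days, "term", "t")
    idx <- sample(500:1500, 1); off <- -sample(0:400, 1)
    expect_identical(truncateHistory(ev, idx, off),
                     ev[ev$date <= idx + off, , drop = FALSE])
  }
})

test_that("visit rate is visits per day times 365", {
  twoMonth <- makeRecord("P1", c(0, 30))
  expect_equal(visitRate(twoMonth), 2 / 30 * 365, tolerance = 1e-12)
  twoYear <- makeRecord("P1", c(0, 365))
  expect_equal(visitRate(twoYear), 2.0, tolerance = 1e-12)
  single <- makeRecord("P1", 100L)
  expect_equal(visitRate(single), 365)  # degenerate span floored at 1 day
  expect_error(visitRate(evRow("P1", 1, "icd9", "x")), "no visit")
})

test_that("visit-rate binning partitions [0, Inf) into 2-wide bins", {
  expect_identical(binVisitRate(c(0, 1.99, 2, 17.99, 18, 400)),
                   c(0L, 0L, 1L, 8L, 9L, 9L))
  set.seed(6)
  r <- c(runif(200, 0, 40), 0, 2, 4, 18)
  b <- binVisitRate(r)
  expect_true(all(b >= 0 & b <= 9))
  ## left-closed right-open: rate lies in [2b, 2b+2) except the top bin
  low <- b < 9
  expect_true(all(r[low] >= 2 * b[low] & r[low] < 2 * b[low] + 2))
  expect_true(all(r[!low] >= 18))
})

test_that("pre-treatment blackout removes (start-10, start]", {
  ev <- evRow("P1", c(80, 89, 90, 95, 100, 101), "term", "t")
  got <- applyPretreatmentBlackout(ev, 100L)
  ## half-open window: start - 10 itself is kept, start is removed
  expect_setequal(got$date, c(80, 89, 90, 101))
  set.seed(8)
  days <- sample(0:200, 80, replace = TRUE)
  ev <- evRow("P1", days, "term", "t")
  got <- applyPretreatmentBlackout(ev, 150L, 10L)
  expect_identical(got, ev[!(ev$date > 140 & ev$date <= 150), , drop = FALSE])
})

test_that("feature matrices carry exactly the observed usable indicators", {
  pats <- data.frame(patient_id = c("A", "B"), birth_year = 1970L,
                     gender = c("F", "M"))
  ev <- rbind(
    makeRecord("A", c(0, 600), evRow("A", 100, "icd9", "401.9"),
               evRow("A", 200, "term", "T1")),
    makeRecord("B", c(0, 600), evRow("B", 100, "term", "T2",
                                     negated = TRUE)))
  cohort <- new("CohortAssignment", assignments = data.frame(
    patient_id = c("A", "B"), label = c("case", "control"),
    index_date = c(600, 600), matched_case = c(NA, "A"),
    exclusion_reason = NA_character_, stringsAsFactors = FALSE),
    unmatched = data.frame(patient_id = character(), n_found = integer(),
                           n_needed = integer()))
  fm <- buildFeatureMatrix(EHRData(pats, ev), cohort)
  m <- SummarizedExperiment::assay(fm)
  expect_true(all(c("icd9:401.9", "term:T1") %in% rownames(m)))
  expect_false("term:T2" %in% rownames(m))  # only mention is negated
  expect_identical(m["icd9:401.9", "A"], 1)
  expect_identical(m["demo:gender_female", ], c(A = 1, B = 0))
  ## one visit bin set per patient
  vb <- m[grep("^visit_bin", rownames(m)), , drop = FALSE]
  expect_identical(unname(Matrix::colSums(vb)), c(1, 1))
})

test_that("phenotype-defining features never enter any matrix", {
  d <- smallPamf(n = 140, seed = 4)
  co <- buildCohort(d, seed = 4)
  cfg <- phenotypeConfig()
  for (off in c(0L, -183L)) {
    fm <- buildFeatureMatrix(d, co, cfg, cutoff = off)
    feats <- rownames(fm)
    expect_length(grep("^icd9:(296|298\\.0|300\\.4|311)", feats), 0)
    expect_length(intersect(paste0("term:", cfg@depressionTerms), feats), 0)
    expect_length(intersect(paste0("drug:", cfg@antidepressantIngredients),
                            feats), 0)
    exc <- S4Vectors::metadata(fm)$excluded_features
    expect_true(all(exc$reason == "phenotype_defining"))
    ## markers sit at the index, so they are only seen (and logged) at 0
    if (off == 0L) expect_gt(nrow(exc), 0)
  }
})

test_that("feature sets nest across truncation cutoffs per patient", {
  d <- smallPamf(n = 140, seed = 5)
  co <- buildCohort(d, seed = 5)
  fms <- lapply(c(0L, -183L, -365L), function(off)
    buildFeatureMatrix(d, co, cutoff = off))
  common <- Reduce(intersect, lapply(fms, rownames))
  ind <- common[!grepl("^(demo|visit_bin)", common)]
  m0 <- SummarizedExperiment::assay(fms[[1]])[ind, ]
  m183 <- SummarizedExperiment::assay(fms[[2]])[ind, ]
  m365 <- SummarizedExperiment::assay(fms[[3]])[ind, ]
  expect_true(all(m365 <= m183))
  expect_true(all(m183 <= m0))
  ## and features present only deeper in history cannot appear at -365
  only365 <- setdiff(rownames(fms[[3]]), rownames(fms[[1]]))
  expect_length(grep("^(demo|visit_bin)", only365, invert = TRUE), 0)
})

test_that("treatment matrices exclude PHQ-9-derived columns on demand", {
  g <- smallGhri(n = 350, seed = 2)
  ep <- firstTreatmentEpisodes(g)
  fmWith <- buildTreatmentFeatureMatrix(g, ep)
  expect_true("demo:baseline_phq9" %in% rownames(fmWith))
  fmWithout <- buildTreatmentFeatureMatrix(g, ep,
                                           includeBaselinePhq9 = FALSE)
  expect_length(grep("phq", rownames(fmWithout), ignore.case = TRUE), 0)
  exc <- S4Vectors::metadata(fmWithout)$excluded_features
  expect_true("demo:baseline_phq9" %in% exc$feature)
  ## blackout: no history indicator may postdate start - 10
  ev <- events(g)
  keep <- ev$event_type == "term"
  start <- ep$start_day[match(ev$patient_id, ep$patient_id)]
  late <- unique(paste0("term:", ev$code[keep & ev$date > start - 10]))
  m <- SummarizedExperiment::assay(fmWith)
  lateOnly <- setdiff(late, unique(paste0("term:",
                                          ev$code[keep & ev$date <=
                                                    start - 10])))
  expect_length(intersect(rownames(m), lateOnly), 0)
})

test_that("EHR tables and feature matrices round-trip to disk", {
  d <- smallPamf(n = 70, seed = 6)
  dir <- withr::local_tempdir()
  writeEHRData(d, dir)
  back <- readEHRData(dir)
  expect_identical(patients(back), patients(d))
  expect_identical(events(back)$date, events(d)$date)
  expect_identical(events(back)$negated, events(d)$negated)

  co <- buildCohort(d, seed = 6)
  fm <- buildFeatureMatrix(d, co)
  stem <- file.path(dir, "fm")
  writeFeatureMatrix(fm, stem)
  trip <- utils::read.csv(paste0(stem, "_triplets.csv"))
  m <- SummarizedExperiment::assay(fm)
  expect_identical(nrow(trip), Matrix::nnzero(m))
  expect_true(all(trip$value == 1 |
                    grepl("^demo", trip$feature_id)))
})
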