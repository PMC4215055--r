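test_that("identical config and seed give identical populations", {
  a <- smallPamf(n = 140, seed = 21)
  b <- smallPamf(n = 140, seed = 21)
  expect_identical(events(a), events(b))
  expect_identical(patients(a), patients(b))
  c <- smallPamf(n = 140, seed = 22)
  expect_false(identical(events(a), events(c)))
  g1 <- smallGhri(n = 140, seed = 21)
  g2 <- smallGhri(n = 140, seed = 21)
  expect_identical(events(g1), events(g2))
  expect_identical(treatments(g1), treatments(g2))
})

test_that("every generated case passes the phenotyping criteria", {
  d <- smallPamf(n = 700, seed = 1)
  co <- buildCohort(d, seed = 1)
  a <- assignments(co)
  ## deterministic stratified prevalence: 100 cases out of 700, all
  ## retained as cases and fully matched at 1:6
  expect_identical(sum(a$label == "case"), 100L)
  expect_identical(sum(a$label == "control"), 600L)
  expect_identical(cohortComposition(co)$pct_depressed, 14.3)
  ## per-record check of the three criteria on a sample of cases
  ev <- events(d)
  caseIds <- utils::head(a$patient_id[a$label == "case"], 10)
  for (pid in caseIds) {
    rec <- ev[ev$patient_id == pid, ]
    expect_true(meetsCaseCriteria(rec)$meets, label = pid)
  }
})

test_that("config validation rejects impossible worlds", {
  expect_error(pamfSimConfig(nPatients = 5, prevalence = 0.01),
               "at least 1 case")
  expect_error(pamfSimConfig(signalStrength = 0.5), "signalStrength")
  expect_error(pamfSimConfig(prevalence = 1.2), "prevalence")
  expect_error(ghriSimConfig(baselinePhq9Distribution = rep(0.2, 4)),
               "5 non-negative")
  expect_error(ghriSimConfig(baselinePhq9Distribution =
                               c(0.3, 0.3, 0.3, 0.05, 0.06)), "sum to 1")
  expect_error(ghriSimConfig(followupDays = 0), "followupDays")
})

test_that("all event dates lie inside each patient's visit span", {
  d <- smallPamf(n = 140, seed = 23)
  ev <- events(d)
  v <- ev[ev$event_type == "visit", ]
  first <- tapply(v$date, v$patient_id, min)
  last <- tapply(v$date, v$patient_id, max)
  expect_true(all(ev$date >= first[ev$patient_id]))
  expect_true(all(ev$date <= last[ev$patient_id]))
  ## case index dates precede the last visit by >= 0 days
  co <- buildCohort(d, seed = 23)
  a <- assignments(co)
  cases <- a[a$label == "case", ]
  expect_true(all(cases$index_date <= last[cases$patient_id]))
})

test_that("null signal strength leaves prodromal features independent of
          case status", {
  ## chi-square p-values over replicate seeds should look uniform
  pvals <- vapply(1:8, function(s) {
    d <- simulatePamfPopulation(pamfSimConfig(
      nPatients = 350, seed = 100 + s, signalStrength = 1,
      nSignalFeatures = 5))
    ev <- events(d)
    co <- buildCohort(d, seed = s)
    a <- assignments(co)
    isCase <- setNames(a$label == "case", a$patient_id)
    has <- unique(ev$patient_id[ev$code %in% "SIG001"])
    tab <- table(case = isCase[a$patient_id],
                 feat = a$patient_id %in% has)
    suppressWarnings(stats::chisq.test(tab)$p.value)
  }, numeric(1))
  expect_gt(stats::ks.test(pvals, "punif")$p.value, 0.01)
  expect_gt(min(pvals), 1e-4)
})

test_that("GHRI improvement follows the logistic model with the PHQ-9
          floor", {
  ## symmetric null away from the floor: all mass in the 15-19 bin,
  ## intercept tuned so P(improve) = 0.5 at every baseline
  g <- simulateGhriPopulation(ghriSimConfig(
    nPatients = 10000, seed = 31,
    baselinePhq9Distribution = c(0, 0, 0, 1, 0),
    improvementLogitIntercept = 0, improvementLogitBaselineCoef = 0,
    modalityLogOdds = 0))
  ep <- firstTreatmentEpisodes(g)
  expect_lt(abs(mean(ep$improved) - 0.5), 3 * sqrt(0.25 / 10000) + 0.005)

  ## negative slope: empirical bin rates track the closed-form curve and
  ## decrease strictly over the four bins where improvement is possible
  g2 <- simulateGhriPopulation(ghriSimConfig(nPatients = 20000, seed = 32))
  ep2 <- firstTreatmentEpisodes(g2)
  psy <- ep2[ep2$modality == "psychotherapy", ]
  bin <- as.integer(phq9Severity(psy$baseline_phq9))
  rates <- tapply(psy$improved, bin, mean)
  expect_identical(unname(rates[["1"]]), 0)  # floor: minimal bin
  expect_true(all(diff(rates[as.character(2:5)]) < 0))
  closed <- function(b) plogis(2.589 - 0.2 * b)
  for (k in 2:5) {
    b <- psy$baseline_phq9[bin == k]
    expect_lt(abs(rates[[as.character(k)]] - mean(closed(b))),
              4 * sqrt(0.25 / length(b)))
  }
})

test_that("treatment tables are internally consistent", {
  g <- smallGhri(n = 700, seed = 33)
  tr <- treatments(g)
  expect_true(all(tr$baseline_phq9 >= 0 & tr$baseline_phq9 <= 27))
  expect_true(all(tr$followup_phq9 >= 0 & tr$followup_phq9 <= 27))
  ep <- firstTreatmentEpisodes(g)
  expect_identical(ep$improved,
                   ep$baseline_phq9 - ep$followup_phq9 >= 5)
  ## patients treated with both modalities start both the same day
  both <- ep$patient_id[ep$modality == "both"]
  sub <- tr[tr$patient_id %in% both, ]
  expect_true(all(tapply(sub$start_day, sub$patient_id,
                         function(x) length(unique(x))) == 1))
})

test_that("planted null moderators are recovered as null", {
  g <- simulateGhriPopulation(ghriSimConfig(
    nPatients = 2000, seed = 34,
    plantedModerator = list(feature = "MOD1", logOdds = 0,
                            prevalence = 0.3)))
  res <- runModeratorAnalysis(g, k = 20)
  tab <- moderatorTable(res$report)
  if ("term:MOD1" %in% tab$feature) {
    est <- tab[tab$feature == "term:MOD1", ]
    expect_gt(est$interaction_p, 0.001)
    expect_lt(abs(est$interaction_coef), 1)
  }
  expect_identical(sum(tab$interaction_p_adj < 0.05, na.rm = TRUE), 0L)
})
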