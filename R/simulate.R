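#' @include AllClasses.R utils.R terminology.R
NULL

#' Default depression ICD-9 code set
#'
#' The standard depression code families -- major depressive disorder,
#' single (296.2x) and recurrent (296.3x) episode with fifth digits 0-6,
#' atypical depressive disorder (296.82), depressive type psychosis
#' (298.0), dysthymic disorder (300.4) and depressive disorder NEC (311)
#' -- with bracket families expanded to explicit dotted codes.
#'
#' @return Character vector of ICD-9 codes.
#' @export
defaultDepressionCodes <- function() {
  expandIcd9Families(c("296.2[0-6]", "296.3[0-6]", "296.82", "298.0",
                       "300.4", "311"))
}

#' Expand ICD-9 bracket families
#'
#' Turns patterns like \code{"296.2[0-6]"} into the explicit enumeration
#' \code{"296.20" ... "296.26"}; plain codes pass through unchanged.
#'
#' @param patterns character vector of codes and bracket patterns.
#' @return Character vector of explicit codes.
#' @export
expandIcd9Families <- function(patterns) {
  out <- lapply(patterns, function(p) {
    m <- regmatches(p, regexec("^(.*)\\[([0-9])-([0-9])\\]$", p))[[1]]
    if (!length(m)) return(p)
    paste0(m[2], seq.int(as.integer(m[3]), as.integer(m[4])))
  })
  unique(unlist(out))
}

#' Built-in toy depression terminology
#'
#' \code{defaultDepressionTermSet} expands the seed disorder concepts two
#' rounds down the toy is-a ontology shipped with the package and applies
#' the toy curation blocklist; \code{defaultAntidepressants} derives the
#' depression-specific ingredient set from the toy drug indication table.
#' These stand in for the licensed terminologies (UMLS, RxNorm,
#' Medi-Span) that real deployments would use.
#'
#' @param rounds expansion rounds (default 2).
#' @return \code{defaultDepressionTermSet}: a \linkS4class{TermSet};
#'   \code{defaultAntidepressants}: character vector of ingredient ids.
#' @export
defaultDepressionTermSet <- function(rounds = 2L) {
  ont <- readOntology(system.file("extdata", "ontology_toy.tsv",
                                  package = "depredict", mustWork = TRUE))
  seed <- c("depressive_disorder", "major_depressive_disorder",
            "depression_adverse_event", "depressive_disorder_nec")
  block <- readLines(system.file("extdata", "term_blocklist_toy.txt",
                                 package = "depredict", mustWork = TRUE))
  filterTerms(expandSeedTerms(seed, ont, rounds = rounds), block)
}

#' @rdname defaultDepressionTermSet
#' @export
defaultAntidepressants <- function() {
  tab <- readDrugTable(system.file("extdata", "drug_indications_toy.csv",
                                   package = "depredict", mustWork = TRUE))
  deriveAntidepressantIngredients(tab, "depression")
}

#' Configuration for the PAMF-like diagnosis-cohort generator
#'
#' Defaults emulate the published cohort aggregates: prevalence 1/7
#' (14.3\% depressed after 1:6 matching), mean follow-up 8.02 years,
#' about 4.2 visits per patient-year (1.18 million encounters over 35 000
#' patients), 55.2\% female. The prodrome is a 400-day window before the
#' latent index date in which each of \code{nSignalFeatures} note terms
#' fires per visit with its odds multiplied by \code{signalStrength}
#' (baseline per-visit probability \code{signalBaseRate}).
#'
#' @param nPatients total patients to simulate.
#' @param prevalence depressed fraction; cases are assigned by
#'   deterministic stratified rounding (\code{round(n * prevalence)}).
#' @param prodromeDays length of the pre-index signal window.
#' @param signalStrength odds multiplier (>= 1) for prodromal features in
#'   cases inside the window; 1 means no planted signal.
#' @param nSignalFeatures number of prodromal note-term features.
#' @param vocabSizeCodes,vocabSizeTerms background vocabulary sizes; codes
#'   and terms are drawn from a power-law (Zipf) rank distribution.
#' @param visitRateMean visits per patient-year (homogeneous Poisson).
#' @param followupYearsMean mean span between first and last visit.
#' @param negationRate,familyHistoryRate per-mention flag probabilities
#'   for note terms.
#' @param signalBaseRate per-visit firing probability of a signal feature
#'   outside the prodrome window (and in controls).
#' @param backgroundCodesPerVisit,backgroundTermsPerVisit mean background
#'   events per visit.
#' @param caseWindowDays maximum gap between the first depression code
#'   and first antidepressant mention in a case (kept under the 100-day
#'   capture rule so generated cases are retainable).
#' @param matchedMode if TRUE (default), controls are generated in blocks
#'   that replicate each case's exact age-at-index and history-length
#'   bin, so 1:6 matching always succeeds when controls/cases >= 6.
#' @param femaleFraction probability a patient is female.
#' @param depressionCodes,depressionTerms,antidepressants the concept sets
#'   the generator plants in case records (defaults: the built-in toy
#'   terminology).
#' @param seed integer RNG seed; identical config and seed give
#'   byte-identical output.
#' @return A validated \linkS4class{PamfSimConfig}.
#' @export
pamfSimConfig <- function(nPatients = 7000L, prevalence = 1 / 7,
                          prodromeDays = 400L, signalStrength = 4,
                          nSignalFeatures = 120L, vocabSizeCodes = 300L,
                          vocabSizeTerms = 300L, visitRateMean = 4.2,
                          followupYearsMean = 8.02, negationRate = 0.10,
                          familyHistoryRate = 0.03, signalBaseRate = 0.04,
                          backgroundCodesPerVisit = 1.5,
                          backgroundTermsPerVisit = 1.5,
                          caseWindowDays = 60L, matchedMode = TRUE,
                          femaleFraction = 0.552,
                          depressionCodes = defaultDepressionCodes(),
                          depressionTerms = NULL,
                          antidepressants = NULL, seed = 1L) {
  if (is.null(depressionTerms))
    depressionTerms <- concepts(defaultDepressionTermSet())
  if (is.null(antidepressants)) antidepressants <- defaultAntidepressants()
  new("PamfSimConfig",
      nPatients = as.integer(nPatients), prevalence = prevalence,
      prodromeDays = as.integer(prodromeDays),
      signalStrength = signalStrength,
      nSignalFeatures = as.integer(nSignalFeatures),
      vocabSizeCodes = as.integer(vocabSizeCodes),
      vocabSizeTerms = as.integer(vocabSizeTerms),
      visitRateMean = visitRateMean, followupYearsMean = followupYearsMean,
      negationRate = negationRate, familyHistoryRate = familyHistoryRate,
      signalBaseRate = signalBaseRate,
      backgroundCodesPerVisit = backgroundCodesPerVisit,
      backgroundTermsPerVisit = backgroundTermsPerVisit,
      caseWindowDays = as.integer(caseWindowDays),
      matchedMode = matchedMode, femaleFraction = femaleFraction,
      depressionCodes = depressionCodes, depressionTerms = depressionTerms,
      antidepressants = antidepressants, seed = as.integer(seed))
}

.ev <- function(pid, date, type, code, negated = FALSE,
                family_history = FALSE, value = NA_real_) {
  k <- length(pid)
  data.frame(patient_id = pid, date = as.integer(date),
             event_type = rep_len(type, k), code = rep_len(code, k),
             negated = rep_len(negated, k),
             family_history = rep_len(family_history, k),
             value = rep_len(value, k), stringsAsFactors = FALSE)
}

#' Simulate a PAMF-like mixed population
#'
#' Generates a seeded population of depressed cases and non-depressed
#' controls with the structure the downstream phenotyping, matching and
#' horizon experiments assume. Each case record carries at least one
#' depression ICD-9 code, one assertive (non-negated, non-family-history)
#' depression term and one antidepressant-ingredient mention, clustered
#' within \code{caseWindowDays} of the latent index date, placed at least
#' 600 days after the first visit so the 1.5-year history rule passes.
#' Prodromal signal terms fire with elevated odds inside the prodrome
#' window only. Controls carry neither depression codes nor depression
#' terms. Background codes and terms follow a Zipf rank distribution;
#' visit counts are homogeneous Poisson at \code{visitRateMean}.
#'
#' @param config a \linkS4class{PamfSimConfig}.
#' @return An \linkS4class{EHRData}.
#' @examples
#' d <- simulatePamfPopulation(pamfSimConfig(nPatients = 70, seed = 7))
#' d
#' @export
simulatePamfPopulation <- function(config) {
  validObject(config)
  .withSeed(config@seed, {
    n <- config@nPatients
    nCases <- as.integer(round(n * config@prevalence))
    if (nCases < 1L)
      stop("prevalence x nPatients must yield at least one case")
    nCtrl <- n - nCases
    caseIdx <- seq_len(nCases)
    ctrlIdx <- nCases + seq_len(nCtrl)
    pid <- sprintf("P%06d", seq_len(n))

    ## record spans: gamma with CV 0.5 around the published mean span
    ## (only the mean is reported; moderate dispersion assumed)
    rawDays <- pmax(120L, as.integer(round(
      stats::rgamma(n, shape = 4, scale = config@followupYearsMean *
                      365.25 / 4))))
    ## short post-index tail: no analysis stage uses post-index data, and
    ## a long tail builds an exposure asymmetry into the truncated
    ## case-vs-control comparison that has no real-data analogue
    postDays <- as.integer(round(stats::runif(nCases, 7, 30)))
    hist <- rawDays
    hist[caseIdx] <- pmax(rawDays[caseIdx], 600L + postDays)
    firstVisit <- sample.int(3650L, n, replace = TRUE)

    index <- rep(NA_integer_, n)
    index[caseIdx] <- firstVisit[caseIdx] + hist[caseIdx] - postDays
    age <- integer(n)
    age[caseIdx] <- sample(18:85, nCases, replace = TRUE)
    birthYear <- integer(n)
    birthYear[caseIdx] <- .birthYearForAge(age[caseIdx], index[caseIdx])

    if (config@matchedMode && nCtrl > 0L) {
      tmpl <- ((seq_len(nCtrl) - 1L) %% nCases) + 1L
      hist[ctrlIdx] <- hist[tmpl]
      endDay <- firstVisit[ctrlIdx] + hist[ctrlIdx]
      age[ctrlIdx] <- age[tmpl]
      birthYear[ctrlIdx] <- .birthYearForAge(age[ctrlIdx], endDay)
    } else if (nCtrl > 0L) {
      age[ctrlIdx] <- sample(18:85, nCtrl, replace = TRUE)
      birthYear[ctrlIdx] <- .birthYearForAge(
        age[ctrlIdx], firstVisit[ctrlIdx] + hist[ctrlIdx])
    }
    gender <- ifelse(stats::runif(n) < config@femaleFraction, "F", "M")

    ## visit process: endpoints fixed, interior days uniform over the span
    years <- hist / 365.25
    nInterior <- stats::rpois(n, pmax(0, config@visitRateMean * years - 2))
    vp <- rep.int(seq_len(n), nInterior)
    vd <- firstVisit[vp] + 1L +
      as.integer(floor(stats::runif(length(vp)) * pmax(1L, hist[vp] - 1L)))
    visitOwner <- c(seq_len(n), seq_len(n), vp)
    visitDay <- c(firstVisit, firstVisit + hist, vd)

    ## case phenotype markers: code + antidepressant mention within the
    ## capture window, assertive depression term shortly before index
    gap <- as.integer(round(stats::runif(nCases, 0, config@caseWindowDays)))
    codeFirst <- stats::runif(nCases) < 0.5
    codeDay <- ifelse(codeFirst, index[caseIdx] - gap, index[caseIdx])
    drugDay <- ifelse(codeFirst, index[caseIdx], index[caseIdx] - gap)
    termDay <- index[caseIdx] -
      as.integer(round(stats::runif(nCases, 0, 30)))
    extraDay <- index[caseIdx] +
      as.integer(floor(stats::runif(nCases) * pmax(1L, postDays - 1L)))

    markerEvents <- rbind(
      .ev(pid[caseIdx], codeDay, "icd9",
          sample(config@depressionCodes, nCases, replace = TRUE)),
      .ev(pid[caseIdx], drugDay, "drug_mention",
          sample(config@antidepressants, nCases, replace = TRUE)),
      .ev(pid[caseIdx], termDay, "term",
          sample(config@depressionTerms, nCases, replace = TRUE)),
      .ev(pid[caseIdx], extraDay, "icd9",
          sample(config@depressionCodes, nCases, replace = TRUE)))
    visitOwner <- c(visitOwner, rep.int(caseIdx, 3L))
    visitDay <- c(visitDay, codeDay, drugDay, termDay)

    visits <- .ev(pid[visitOwner], visitDay, "visit", NA_character_)

    ## prodromal signal terms: per-visit Bernoulli, odds multiplied by
    ## signalStrength inside [index - prodromeDays, index] for cases
    p0 <- config@signalBaseRate
    o1 <- (p0 / (1 - p0)) * config@signalStrength
    p1 <- o1 / (1 + o1)
    inWindow <- !is.na(index[visitOwner]) &
      visitDay >= index[visitOwner] - config@prodromeDays &
      visitDay <= index[visitOwner]
    pSig <- ifelse(inWindow, p1, p0)
    nv <- length(visitOwner)
    sigList <- vector("list", config@nSignalFeatures)
    for (j in seq_len(config@nSignalFeatures)) {
      hit <- stats::runif(nv) < pSig
      if (any(hit))
        sigList[[j]] <- .ev(
          pid[visitOwner[hit]], visitDay[hit], "term",
          sprintf("SIG%03d", j),
          negated = stats::runif(sum(hit)) < config@negationRate,
          family_history = stats::runif(sum(hit)) <
            config@familyHistoryRate)
    }

    ## background codes and terms, power-law rank frequencies; background
    ## vocabulary is disjoint from the depression concept sets
    nbgC <- stats::rpois(nv, config@backgroundCodesPerVisit)
    bgOwner <- rep.int(visitOwner, nbgC)
    bgDay <- rep.int(visitDay, nbgC)
    bgCodes <- .ev(pid[bgOwner], bgDay, "icd9",
                   sprintf("C%03d", .sampleZipf(length(bgOwner),
                                                config@vocabSizeCodes)))
    nbgT <- stats::rpois(nv, config@backgroundTermsPerVisit)
    btOwner <- rep.int(visitOwner, nbgT)
    btDay <- rep.int(visitDay, nbgT)
    kT <- length(btOwner)
    bgTerms <- .ev(pid[btOwner], btDay, "term",
                   sprintf("T%03d", .sampleZipf(kT, config@vocabSizeTerms)),
                   negated = stats::runif(kT) < config@negationRate,
                   family_history = stats::runif(kT) <
                     config@familyHistoryRate)

    ev <- data.table::rbindlist(
      c(list(visits, markerEvents, bgCodes, bgTerms),
        Filter(Negate(is.null), sigList)))
    pats <- data.frame(patient_id = pid, birth_year = birthYear,
                       gender = gender, stringsAsFactors = FALSE)
    EHRData(pats, as.data.frame(ev))
  })
}

#' Configuration for the GHRI-like treated-cohort generator
#'
#' Defaults emulate the published treated cohort: 5651 patients, baseline
#' PHQ-9 severity distributed by the printed bin proportions, first
#' treatments split between medication, psychotherapy and both, PHQ-9
#' scored at treatment start and after 90 days, mean record span 2.5
#' years, 70.3\% female. The probability of improvement (a PHQ-9 drop of
#' at least 5 points) follows a logistic model in the baseline score with
#' a medication main effect; the default intercept, baseline slope
#' (-0.2 per point, higher baseline = worse outcome) and modality
#' log-odds are calibrated so the expected improvement rates at the mean
#' baseline approximate the printed 63.8\% (medication) and 36.9\%
#' (psychotherapy).
#'
#' @param nPatients number of treated patients.
#' @param baselinePhq9Distribution probability vector over the five
#'   severity bins (minimal..severe); must sum to 1.
#' @param modalityMedication,modalityBoth fractions of first treatments
#'   that are medication-only and simultaneous medication+psychotherapy;
#'   the remainder is psychotherapy-only.
#' @param improvementLogitIntercept,improvementLogitBaselineCoef logistic
#'   model for P(improve): intercept and per-PHQ-9-point slope.
#' @param modalityLogOdds additive log-odds of improvement under
#'   medication (vs psychotherapy).
#' @param plantedModerator optional
#'   \code{list(feature=, logOdds=, prevalence=)}: a binary history
#'   feature whose interaction log-odds apply only under medication.
#' @param followupDays nominal follow-up interval (default 90).
#' @param nHistoryFeatures background CUI feature count (Zipf-decaying
#'   per-patient prevalences).
#' @param nSeverityFeatures history features whose prevalence rises with
#'   baseline severity (what the severity model can learn from).
#' @param severitySlope per-PHQ-9-point logit slope of those features.
#' @param visitRateMean visits per patient-year.
#' @param historyYearsMean mean record span in years.
#' @param femaleFraction probability a patient is female.
#' @param seed integer RNG seed.
#' @return A validated \linkS4class{GhriSimConfig}.
#' @export
ghriSimConfig <- function(nPatients = 5651L,
                          baselinePhq9Distribution =
                            c(267, 747, 1294, 1652, 1301) / 5261,
                          modalityMedication = 2472 / 5651,
                          modalityBoth = 778 / 5651,
                          improvementLogitIntercept = 2.589,
                          improvementLogitBaselineCoef = -0.2,
                          modalityLogOdds = 1.511,
                          plantedModerator = list(),
                          followupDays = 90L,
                          nHistoryFeatures = 60L, nSeverityFeatures = 10L,
                          severitySlope = 0.12,
                          visitRateMean = 8, historyYearsMean = 2.5,
                          femaleFraction = 0.703, seed = 1L) {
  new("GhriSimConfig",
      nPatients = as.integer(nPatients),
      baselinePhq9Distribution = baselinePhq9Distribution,
      modalityMedication = modalityMedication, modalityBoth = modalityBoth,
      improvementLogitIntercept = improvementLogitIntercept,
      improvementLogitBaselineCoef = improvementLogitBaselineCoef,
      modalityLogOdds = modalityLogOdds,
      plantedModerator = plantedModerator,
      followupDays = as.integer(followupDays),
      nHistoryFeatures = as.integer(nHistoryFeatures),
      nSeverityFeatures = as.integer(nSeverityFeatures),
      severitySlope = severitySlope, visitRateMean = visitRateMean,
      historyYearsMean = historyYearsMean,
      femaleFraction = femaleFraction, seed = as.integer(seed))
}

#' Simulate a GHRI-like treated population
#'
#' Every patient has a first treatment with a modality, a baseline PHQ-9
#' at treatment start and a follow-up PHQ-9 near
#' \code{start + followupDays}. Improvement (a drop of at least 5 points)
#' is Bernoulli with probability
#' \code{plogis(intercept + baselineCoef * baseline + modalityLogOdds *
#' medication [+ moderator interaction])}; the drop magnitude beyond the
#' 5-point threshold is unidentified noise. Baselines below 5 cannot
#' mechanically improve by 5 points and are forced non-improved (floor
#' effect). Patients assigned modality \code{both} get medication and
#' psychotherapy records starting the same day. History term events
#' (background CUIs, severity-linked features, the optional planted
#' moderator) are placed before the 10-day pre-treatment blackout; a few
#' distractor events inside the blackout window exercise the exclusion.
#'
#' @param config a \linkS4class{GhriSimConfig}.
#' @return An \linkS4class{EHRData} with a populated treatments table.
#' @export
simulateGhriPopulation <- function(config) {
  validObject(config)
  .withSeed(config@seed, {
    n <- config@nPatients
    pid <- sprintf("G%06d", seq_len(n))
    binLo <- c(0L, 5L, 10L, 15L, 20L)
    binHi <- c(4L, 9L, 14L, 19L, 27L)
    bin <- sample.int(5L, n, replace = TRUE,
                      prob = config@baselinePhq9Distribution)
    baseline <- binLo[bin] +
      as.integer(floor(stats::runif(n) * (binHi[bin] - binLo[bin] + 1L)))

    pPsy <- 1 - config@modalityMedication - config@modalityBoth
    modality <- sample(c("medication", "psychotherapy", "both"), n,
                       replace = TRUE,
                       prob = c(config@modalityMedication, pPsy,
                                config@modalityBoth))

    preDays <- as.integer(round(stats::runif(n, 60, 540)))
    rawDays <- pmax(120L, as.integer(round(
      stats::rgamma(n, shape = 2,
                    scale = config@historyYearsMean * 365.25 / 2))))
    hist <- pmax(rawDays, preDays + config@followupDays + 30L)
    firstVisit <- sample.int(3650L, n, replace = TRUE)
    start <- firstVisit + preDays
    age <- sample(18:85, n, replace = TRUE)
    birthYear <- .birthYearForAge(age, start)
    gender <- ifelse(stats::runif(n) < config@femaleFraction, "F", "M")

    ## planted moderator feature
    pm <- config@plantedModerator
    modFeat <- if (length(pm))
      stats::runif(n) < pm$prevalence else rep(FALSE, n)
    interaction <- if (length(pm)) pm$logOdds else 0

    lin <- config@improvementLogitIntercept +
      config@improvementLogitBaselineCoef * baseline +
      config@modalityLogOdds * (modality != "psychotherapy") +
      interaction * (modFeat & modality == "medication")
    improved <- stats::runif(n) < stats::plogis(lin)
    improved[baseline < 5L] <- FALSE  # floor: a 5-point drop is impossible
    extra <- stats::rpois(n, 2)
    worsen <- pmin(4L, as.integer(round(stats::rnorm(n, 0, 2))))
    followupScore <- ifelse(improved,
                            pmax(0L, baseline - 5L - extra),
                            pmin(27L, pmax(0L, baseline - worsen)))

    ## visits: endpoints, treatment start, follow-up, interior Poisson
    years <- hist / 365.25
    nInterior <- stats::rpois(n, pmax(0, config@visitRateMean * years - 4))
    vp <- rep.int(seq_len(n), nInterior)
    vd <- firstVisit[vp] + 1L +
      as.integer(floor(stats::runif(length(vp)) * pmax(1L, hist[vp] - 1L)))
    visits <- .ev(pid[c(seq_len(n), seq_len(n), seq_len(n), seq_len(n), vp)],
                  c(firstVisit, firstVisit + hist, start,
                    start + config@followupDays, vd),
                  "visit", NA_character_)

    ## PHQ-9 scored at start and near start + followupDays
    jitter <- as.integer(pmax(-10, pmin(10, round(stats::rnorm(n, 0, 4)))))
    phq <- rbind(
      .ev(pid, start, "phq9", "phq9_total", value = as.numeric(baseline)),
      .ev(pid, start + config@followupDays + jitter, "phq9", "phq9_total",
          value = as.numeric(followupScore)))

    ## pre-treatment history features (all strictly before the blackout)
    histList <- list()
    .histDay <- function(who)
      start[who] - 11L - as.integer(floor(
        stats::runif(length(who)) * pmax(1L, preDays[who] - 12L)))
    for (j in seq_len(config@nHistoryFeatures)) {
      q <- 0.5 * j^(-0.3)
      who <- which(stats::runif(n) < q)
      if (length(who))
        histList[[length(histList) + 1L]] <-
          .ev(pid[who], .histDay(who), "term", sprintf("CUI%03d", j))
    }
    for (j in seq_len(config@nSeverityFeatures)) {
      pj <- stats::plogis(-2.2 + config@severitySlope * baseline)
      who <- which(stats::runif(n) < pj)
      if (length(who))
        histList[[length(histList) + 1L]] <-
          .ev(pid[who], .histDay(who), "term", sprintf("SEV%02d", j))
    }
    if (length(pm) && any(modFeat)) {
      who <- which(modFeat)
      histList[[length(histList) + 1L]] <-
        .ev(pid[who], .histDay(who), "term", pm$feature)
    }
    ## distractors inside the 10-day blackout window
    who <- which(stats::runif(n) < 0.3)
    blackoutEv <- .ev(pid[who],
                      start[who] - as.integer(floor(stats::runif(
                        length(who)) * 10)),
                      "term", "CUI001")

    ev <- data.table::rbindlist(c(list(visits, phq, blackoutEv), histList))

    ## treatments table; `both` patients get two records starting the
    ## same day, which the episode builder resolves to modality "both"
    tr <- data.frame(patient_id = pid, start_day = start,
                     modality = modality,
                     baseline_phq9 = as.numeric(baseline),
                     followup_phq9 = as.numeric(followupScore),
                     stringsAsFactors = FALSE)
    isBoth <- tr$modality == "both"
    if (any(isBoth)) {
      med <- tr[isBoth, ]; med$modality <- "medication"
      psy <- tr[isBoth, ]; psy$modality <- "psychotherapy"
      tr <- rbind(tr[!isBoth, ], med, psy)
    }
    tr <- tr[order(tr$patient_id, tr$start_day, tr$modality), ]
    rownames(tr) <- NULL

    pats <- data.frame(patient_id = pid, birth_year = birthYear,
                       gender = gender, stringsAsFactors = FALSE)
    EHRData(pats, as.data.frame(ev), tr)
  })
}
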