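# Small record builders used across tests.

evRow <- function(pid, date, type, code, negated = FALSE, fh = FALSE,
                  value = NA_real_) {
  data.frame(patient_id = pid, date = as.integer(date), event_type = type,
             code = code, negated = negated, family_history = fh,
             value = value, stringsAsFactors = FALSE)
}

# A record as a plain event data.frame: visits spanning the given days
# plus arbitrary extra event rows.
makeRecord <- function(pid = "P1", visitDays = c(0L, 1000L), ...) {
  rows <- list(evRow(pid, visitDays, "visit", NA_character_))
  extra <- list(...)
  do.call(rbind, c(rows, extra))
}

# A case record satisfying all three phenotype criteria, with the index
# markers placed at the given days.
makeCaseRecord <- function(pid = "P1", firstVisit = 0L, lastVisit = 1200L,
                           codeDay = 700L, drugDay = 720L, termDay = 690L,
                           code = "296.30", term = "major_depressive_disorder",
                           drug = "fluoxetine") {
  makeRecord(pid, c(firstVisit, codeDay, drugDay, termDay, lastVisit),
             evRow(pid, codeDay, "icd9", code),
             evRow(pid, termDay, "term", term),
             evRow(pid, drugDay, "drug_mention", drug))
}

# Tiny deterministic toy drug table.
toyDrugTable <- function() {
  DrugIndicationTable(
    drug_id = c("d1", "d2", "d3"),
    ingredients = list("X", c("X", "Y"), "Z"),
    indications = list("depression", "pain", "depression"))
}

smallPamf <- function(n = 700L, seed = 1L, ...) {
  simulatePamfPopulation(pamfSimConfig(nPatients = n, seed = seed, ...))
}

smallGhri <- function(n = 1400L, seed = 1L, ...) {
  simulateGhriPopulation(ghriSimConfig(nPatients = n, seed = seed, ...))
}
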