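# In-code fixtures shared across test files.

# Long-format cohort table for hand-built toy cohorts. Grades default to 0,
# one scan per patient, no contrast.
toyTable <- function(patient_id, level, vbmd, fracture = 0L, degeneration = 0L,
                     age = 60, sex = "M", scanner = "s1", phase = "none",
                     hu = NA_real_) {
  data.frame(
    patient_id = patient_id, age = age, sex = sex, scanner_id = scanner,
    contrast_phase = phase, level = level, vbmd_mgml = vbmd, hu = hu,
    fracture_grade = as.integer(fracture),
    degeneration_grade = as.integer(degeneration),
    stringsAsFactors = FALSE
  )
}

toyCohort <- function(...) cohortFromTable(toyTable(...))

# Cohort where each patient's L1-L3 and one target level lie exactly on a
# configured line level = a * lumbar + b (for exact-fit tests).
lineCohort <- function(lumbar, level = "C6", a = 1.138, b = 80.98) {
  n <- length(lumbar)
  ids <- sprintf("Q%03d", seq_len(n))
  df <- rbind(
    toyTable(rep(ids, each = 3), rep(c("L1", "L2", "L3"), n),
             rep(lumbar, each = 3)),
    toyTable(ids, level, a * lumbar + b)
  )
  cohortFromTable(df)
}

# QC + reference in one step (the standard preamble of analysis tests).
prepCohort <- function(cohort, useDegenerationRule = TRUE) {
  computeLumbarReference(applyExclusions(cohort), useDegenerationRule)
}
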