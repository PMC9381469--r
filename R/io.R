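# File contracts. CSV interchange (RFC 4180, "." decimal separator, UTF-8,
# mandatory header), YAML run configuration (fail-closed on unknown keys),
# JSON QC reports.

.COHORT_COLUMNS <- c("patient_id", "age", "sex", "scanner_id",
                     "contrast_phase", "level", "vbmd_mgml", "hu",
                     "fracture_grade", "degeneration_grade")

# Canonical CSV writer: full-precision numbers, "" for NA, no quoting,
# LF line endings. Deterministic byte-for-byte for identical input.
writeCsvCanonical <- function(df, path) {
  out <- df
  for (j in seq_along(out)) {
    if (is.numeric(out[[j]])) out[[j]] <- formatNumCsv(out[[j]])
    out[[j]][is.na(out[[j]])] <- ""
  }
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(paste(colnames(out), collapse = ","), con)
  if (nrow(out) > 0) {
    writeLines(do.call(paste, c(unname(as.list(out)), sep = ",")), con)
  }
  invisible(path)
}

#' Read a cohort CSV file
#'
#' Strict parser for the per-vertebra interchange contract: one row per
#' (patient, level), columns `patient_id, age, sex {F,M,U}, scanner_id,
#' contrast_phase, level, vbmd_mgml, hu, fracture_grade {0-3},
#' degeneration_grade {0-3}`; at least one of `vbmd_mgml`/`hu` non-blank per
#' row. Levels parse case-insensitively and serialize canonically. Schema
#' violations are aggregated and reported together with their row numbers
#' (not first-failure); duplicate (patient, level) pairs are hard errors.
#'
#' @param path CSV file path.
#' @return A [SpineCohort-class].
#' @export
readCohort <- function(path) {
  if (!file.exists(path)) dataError(sprintf("cohort file not found: %s", path))
  raw <- read.csv(path, colClasses = "character", stringsAsFactors = FALSE,
                  check.names = FALSE)
  extra <- setdiff(colnames(raw), .COHORT_COLUMNS)
  miss <- setdiff(.COHORT_COLUMNS, colnames(raw))
  if (length(extra) > 0 || length(miss) > 0) {
    dataError(sprintf(
      "cohort file schema mismatch%s%s",
      if (length(miss)) sprintf("; missing column(s): %s",
                                paste(miss, collapse = ", ")) else "",
      if (length(extra)) sprintf("; unknown column(s): %s",
                                 paste(extra, collapse = ", ")) else ""))
  }
  n <- nrow(raw)
  if (n == 0) dataError("cohort file has no data rows")
  rowno <- seq_len(n) + 1L  # header is line 1
  problems <- character(0)
  note <- function(rows, msg) {
    if (length(rows) > 0) {
      problems <<- c(problems, sprintf("row %d: %s", rows, msg))
    }
  }
  num <- function(x) suppressWarnings(as.numeric(ifelse(x == "", NA, x)))
  age <- num(raw$age)
  note(rowno[is.na(age) | age < 18 | age > 100],
       "age must be a number in [18, 100]")
  note(rowno[!raw$sex %in% c("F", "M", "U")], "sex must be F, M or U")
  lvOk <- toupper(trimws(raw$level)) %in% .LEVEL_NAMES
  note(rowno[!lvOk], sprintf("unknown level '%s'", raw$level[!lvOk]))
  vbmdv <- num(raw$vbmd_mgml)
  huv <- num(raw$hu)
  note(rowno[raw$vbmd_mgml == "" & raw$hu == ""],
       "at least one of vbmd_mgml, hu must be non-blank")
  note(rowno[!is.na(vbmdv) & vbmdv < 0], "vbmd_mgml must be non-negative")
  for (g in c("fracture_grade", "degeneration_grade")) {
    bad <- !raw[[g]] %in% as.character(0:3)
    note(rowno[bad], sprintf("%s must be an integer 0-3", g))
  }
  key <- paste(raw$patient_id, toupper(trimws(raw$level)))
  key[!lvOk] <- NA
  dup <- !is.na(key) & (duplicated(key) | duplicated(key, fromLast = TRUE))
  if (any(dup)) {
    for (k in unique(key[dup])) {
      rows <- rowno[!is.na(key) & key == k]
      problems <- c(problems, sprintf(
        "rows %s: duplicate (patient_id, level) pair (%s)",
        paste(rows, collapse = " and "), k))
    }
  }
  if (length(problems) > 0) {
    dataError(paste0("cohort file violates the CohortFile contract:\n  ",
                     paste(problems, collapse = "\n  ")))
  }
  df <- data.frame(
    patient_id = raw$patient_id, age = age, sex = raw$sex,
    scanner_id = raw$scanner_id, contrast_phase = raw$contrast_phase,
    level = parseLevel(raw$level), vbmd_mgml = vbmdv, hu = huv,
    fracture_grade = as.integer(raw$fracture_grade),
    degeneration_grade = as.integer(raw$degeneration_grade),
    stringsAsFactors = FALSE
  )
  cohortFromTable(df, provenance = list(source = "file", path = path))
}

#' Write a cohort CSV file
#'
#' Serializes a [SpineCohort-class] under the interchange contract, levels in
#' canonical craniocaudal order within each patient, numbers at full
#' precision. `writeCohort(readCohort(f), f2)` is byte-identical to `f` for
#' canonical files.
#'
#' @param cohort a [SpineCohort-class].
#' @param path output CSV path.
#' @return the path, invisibly.
#' @export
writeCohort <- function(cohort, path) {
  writeCsvCanonical(asCohortTable(cohort), path)
  invisible(path)
}

# ---- run configuration ------------------------------------------------------

.CONFIG_KEYS <- c("seed", "output_dir", "cohort_file", "simulation",
                  "scanner_calibrations", "contrast_corrections",
                  "lumbar_cutoffs", "policy", "exclusion")
.SIM_KEYS <- c("n_patients", "seed", "age_mean", "age_sd", "age_range",
               "female_fraction", "lumbar_between_sd",
               "lumbar_level_noise_sd", "level_noise_sd",
               "cervical_coverage", "generate_hu", "disable_fracture",
               "disable_degeneration", "disable_contrast")
.POLICY_KEYS <- c("name", "aggregation")
.EXCLUSION_KEYS <- c("use_degeneration_rule")

#' Read and validate a run configuration
#'
#' YAML, fail-closed: any unknown key at the top level or inside a known
#' section is a configuration error. Recognised sections: `seed`,
#' `output_dir`, `cohort_file`, `simulation` (generator overrides),
#' `scanner_calibrations`, `contrast_corrections`, `lumbar_cutoffs`,
#' `policy` (`name`, `aggregation`), `exclusion`
#' (`use_degeneration_rule`).
#'
#' @param path YAML file path.
#' @return validated config list (class `spineCalibRunConfig`).
#' @export
readRunConfig <- function(path) {
  if (!file.exists(path)) configError(sprintf("config file not found: %s", path))
  cfg <- yaml::read_yaml(path)
  if (!is.list(cfg)) configError("config file must be a YAML mapping")
  checkKeys <- function(x, allowed, where) {
    unknown <- setdiff(names(x), allowed)
    if (length(unknown) > 0) {
      configError(sprintf("unknown %s key(s): %s (fail-closed)", where,
                          paste(unknown, collapse = ", ")))
    }
  }
  checkKeys(cfg, .CONFIG_KEYS, "config")
  if (!is.null(cfg$simulation)) checkKeys(cfg$simulation, .SIM_KEYS, "simulation")
  if (!is.null(cfg$policy)) checkKeys(cfg$policy, .POLICY_KEYS, "policy")
  if (!is.null(cfg$exclusion)) checkKeys(cfg$exclusion, .EXCLUSION_KEYS, "exclusion")
  if (is.null(cfg$cohort_file) && is.null(cfg$simulation)) {
    configError("config must provide either cohort_file or a simulation section")
  }
  if (!is.null(cfg$lumbar_cutoffs)) {
    checkKeys(cfg$lumbar_cutoffs, c("osteoporosis", "osteopenia"),
              "lumbar_cutoffs")
  }
  structure(cfg, class = c("spineCalibRunConfig", "list"))
}

#' Materialise a SimulationConfig from a run configuration
#'
#' Translates the `simulation` section of a [readRunConfig()] list into a
#' validated [SimulationConfig-class] (snake_case keys; components can be
#' switched off with `disable_fracture` / `disable_degeneration` /
#' `disable_contrast`).
#'
#' @param cfg a run-config list.
#' @return A [SimulationConfig-class].
#' @export
simulationConfigFromRun <- function(cfg) {
  s <- cfg$simulation
  args <- list(
    nPatients = s$n_patients %||% 260,
    seed = s$seed %||% cfg$seed %||% 1
  )
  map <- c(age_mean = "ageMean", age_sd = "ageSD", age_range = "ageRange",
           female_fraction = "femaleFraction",
           lumbar_between_sd = "lumbarBetweenSD",
           lumbar_level_noise_sd = "lumbarLevelNoiseSD",
           level_noise_sd = "levelNoiseSD",
           cervical_coverage = "cervicalCoverage",
           generate_hu = "generateHU")
  for (k in names(map)) {
    if (!is.null(s[[k]])) args[[map[[k]]]] <- unlist(s[[k]])
  }
  # assigning NULL into a list drops the element, hence the list(NULL) forms
  if (isTRUE(s$disable_fracture)) args["fractureModel"] <- list(NULL)
  if (isTRUE(s$disable_degeneration)) args["degenerationModel"] <- list(NULL)
  if (isTRUE(s$disable_contrast)) args["contrastModel"] <- list(NULL)
  do.call(simulationConfig, args)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
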