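# Pipeline orchestration, mirroring the measurement path:
# convert -> correct -> QC -> lumbar reference -> correlate -> fit ->
# thresholds -> classify.

#' Run the full threshold-transfer pipeline
#'
#' Executes every stage on a cohort read from `cohort_file` or simulated from
#' the config's `simulation` section, and writes the artifact set to
#' `outDir`: `qc_report.json`, `correlations_before.csv`,
#' `correlations_after.csv`, `calibrations.csv`, `thresholds.csv`,
#' `classifications.csv`, `resolved_config.yaml` and `pipeline.log`.
#' Running twice with an identical configuration produces byte-identical
#' CSV output. Any stage error aborts with the stage name attached.
#'
#' @param config a config list from [readRunConfig()], or a YAML path.
#' @param outDir output directory (created if needed; default: the config's
#'   `output_dir`, else a tempdir).
#' @param quiet suppress per-stage log messages to the console.
#' @return invisibly, a list with the artifact paths plus the in-memory
#'   `cohort`, `calibrations` and `thresholds`.
#' @export
runPipeline <- function(config, outDir = NULL, quiet = FALSE) {
  if (is.character(config)) config <- readRunConfig(config)
  outDir <- outDir %||% config$output_dir %||% tempfile("spinecalib_run_")
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  logPath <- file.path(outDir, "pipeline.log")
  logLines <- character(0)
  logmsg <- function(stage, fmt, ...) {
    line <- sprintf("[%s] %s", stage, sprintf(fmt, ...))
    logLines <<- c(logLines, line)
    if (!quiet) message(line)
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      writeLines(c(logLines, sprintf("[%s] ERROR: %s", name,
                                     conditionMessage(e))), logPath)
      rlang::abort(sprintf("pipeline stage '%s' failed: %s", name,
                           conditionMessage(e)),
                   class = class(e)[1], parent = e)
    })
  }

  cohort <- stage("input", {
    if (!is.null(config$cohort_file)) {
      co <- readCohort(config$cohort_file)
      logmsg("input", "read %d patients / %d measured vertebrae from %s",
             ncol(co), sum(measuredMask(co)), config$cohort_file)
      co
    } else {
      sim <- simulationConfigFromRun(config)
      co <- simulateCohort(sim)
      logmsg("input", "simulated %d patients (seed %d)", ncol(co), sim@seed)
      co
    }
  })

  cohort <- stage("densitometry", {
    cal <- NULL
    if (!is.null(config$scanner_calibrations)) {
      sc <- do.call(rbind, lapply(config$scanner_calibrations, as.data.frame))
      cal <- scannerCalibrationTable(sc$scanner_id, sc$slope, sc$intercept)
    }
    corr <- NULL
    phases <- unique(colData(cohort)$contrast_phase)
    if (!is.null(config$contrast_corrections)) {
      cc <- do.call(rbind, lapply(config$contrast_corrections, as.data.frame))
      corr <- contrastCorrectionTable(cc$phase, cc$slope, cc$intercept)
    } else if (any(phases != "none")) {
      # identity defaults: no clinical correction coefficients are bundled
      corr <- contrastCorrectionTable(setdiff(phases, "none"), 1, 0)
      logmsg("densitometry",
             "WARNING: identity contrast correction assumed for phase(s) %s (no coefficients configured)",
             paste(setdiff(phases, "none"), collapse = ", "))
    }
    co <- applyDensitometry(cohort, cal, corr)
    logmsg("densitometry", "vbmd available for %d vertebrae",
           sum(!is.na(vbmd(co))))
    co
  })

  useDeg <- config$exclusion$use_degeneration_rule %||% TRUE
  cohort <- stage("qc", {
    co <- applyExclusions(cohort)
    rep <- qcReport(co)
    logmsg("qc", "vertebrae in: %d; excluded fracture: %d; excluded degeneration: %d",
           rep@nVertebrae, rep@nExcludedFracture, rep@nExcludedDegeneration)
    co
  })
  cohort <- stage("reference", {
    co <- computeLumbarReference(cohort, useDegenerationRule = useDeg)
    logmsg("reference", "lumbar reference present for %d/%d patients",
           sum(!is.na(lumbarReference(co))), ncol(co))
    co
  })

  corBefore <- stage("correlate",
                     suppressWarnings(pearsonByLevel(cohort, FALSE)))
  corAfter <- stage("correlate",
                    suppressWarnings(pearsonByLevel(cohort, TRUE)))
  logmsg("correlate", "median r before/after exclusion: %.3f / %.3f",
         median(corBefore$r, na.rm = TRUE), median(corAfter$r, na.rm = TRUE))

  calibrations <- stage("fit", {
    cal <- suppressWarnings(fitAllCalibrations(cohort))
    logmsg("fit", "calibrated %d levels (n = %d-%d patients)",
           nrow(cal), min(cal$n), max(cal$n))
    cal
  })

  cutoffs <- c(
    osteoporosis = config$lumbar_cutoffs$osteoporosis %||% 80,
    osteopenia = config$lumbar_cutoffs$osteopenia %||% 120
  )
  thresholds <- stage("thresholds", {
    th <- deriveThresholds(calibrations, lumbarCutoffs = cutoffs)
    logmsg("thresholds", "derived thresholds at cut-offs %g/%g mg/ml",
           cutoffs[["osteoporosis"]], cutoffs[["osteopenia"]])
    th
  })

  classifications <- stage("classify", {
    polName <- config$policy$name %||% "table2"
    pol <- if (polName == "table2") {
      classificationPolicy("table2", thresholds = thresholds)
    } else {
      classificationPolicy(polName)
    }
    agg <- config$policy$aggregation %||% "worst"
    cls <- suppressWarnings(classifyCohort(cohort, pol, aggregation = agg))
    logmsg("classify", "policy %s/%s: %s", polName, agg,
           paste(sprintf("%s=%d", names(table(cls$category)),
                         as.integer(table(cls$category))), collapse = " "))
    cls
  })

  artifacts <- stage("write", {
    paths <- list(
      qc_report = file.path(outDir, "qc_report.json"),
      correlations_before = file.path(outDir, "correlations_before.csv"),
      correlations_after = file.path(outDir, "correlations_after.csv"),
      calibrations = file.path(outDir, "calibrations.csv"),
      thresholds = file.path(outDir, "thresholds.csv"),
      classifications = file.path(outDir, "classifications.csv"),
      resolved_config = file.path(outDir, "resolved_config.yaml"),
      log = logPath
    )
    qcReportToJson(qcReport(cohort), paths$qc_report)
    writeCsvCanonical(corBefore, paths$correlations_before)
    writeCsvCanonical(corAfter, paths$correlations_after)
    writeCsvCanonical(calibrations, paths$calibrations)
    writeThresholds(thresholds, paths$thresholds)
    writeCsvCanonical(classifications, paths$classifications)
    resolved <- unclass(config)
    resolved$lumbar_cutoffs <- as.list(cutoffs)
    resolved$exclusion <- list(use_degeneration_rule = useDeg)
    yaml::write_yaml(resolved, paths$resolved_config)
    logmsg("write", "artifacts written to %s", outDir)
    paths
  })
  writeLines(logLines, logPath)

  invisible(c(artifacts, list(cohort = cohort, calibrations = calibrations,
                              thresholds = thresholds)))
}
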