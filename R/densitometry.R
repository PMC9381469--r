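# Scanner-specific HU -> vBMD conversion and contrast-phase correction.
#
# Phantom-derived conversion coefficients are site-specific configuration,
# never constants: the bundled defaults are the identity with an explicit
# provenance note, because no clinical calibration should ever be fabricated.

#' Scanner calibration and contrast-correction tables
#'
#' `scannerCalibrationTable()` builds a validated table of per-scanner linear
#' HU->vBMD coefficients (`vbmd = slope * hu + intercept`, slope > 0).
#' `contrastCorrectionTable()` builds a validated table of per-phase linear
#' corrections in vBMD space (`corrected = slope * measured + intercept`);
#' the phase `"none"` is always the identity and is appended if absent.
#' Lookup is by bit-exact, case-sensitive string match.
#'
#' @param scanner_id,phase character keys.
#' @param slope,intercept linear coefficients.
#' @return a data.frame with one row per key.
#' @export
#' @examples
#' scannerCalibrationTable("scannerA", slope = 0.8, intercept = 2)
#' contrastCorrectionTable("venous", slope = 1, intercept = -15)
scannerCalibrationTable <- function(scanner_id, slope, intercept) {
  df <- data.frame(scanner_id = as.character(scanner_id),
                   slope = as.numeric(slope),
                   intercept = as.numeric(intercept),
                   stringsAsFactors = FALSE)
  if (anyDuplicated(df$scanner_id)) {
    configError("duplicate scanner_id in calibration table")
  }
  if (any(!is.finite(df$slope)) || any(df$slope <= 0)) {
    configError("scanner calibration slopes must be positive")
  }
  df
}

#' @rdname scannerCalibrationTable
#' @export
contrastCorrectionTable <- function(phase, slope, intercept) {
  df <- data.frame(phase = as.character(phase),
                   slope = as.numeric(slope),
                   intercept = as.numeric(intercept),
                   stringsAsFactors = FALSE)
  if (!"none" %in% df$phase) {
    df <- rbind(df, data.frame(phase = "none", slope = 1, intercept = 0))
  }
  none <- df[df$phase == "none", ]
  if (any(none$slope != 1) || any(none$intercept != 0)) {
    configError("the 'none' contrast phase must be the identity correction")
  }
  if (anyDuplicated(df$phase)) configError("duplicate phase in correction table")
  df
}

#' Convert Hounsfield units to trabecular vBMD
#'
#' Applies the scanner's phantom-derived linear conversion
#' `vbmd = slope * hu + intercept`, truncated below at 0 mg/ml.
#'
#' @param hu numeric vector of Hounsfield units.
#' @param scanner_id scanner key(s), recycled against `hu`.
#' @param calibrations table from [scannerCalibrationTable()].
#' @return vBMD in mg/ml (non-negative).
#' @export
#' @examples
#' cal <- scannerCalibrationTable("s1", 0.8, 2)
#' huToVbmd(150, "s1", cal)
huToVbmd <- function(hu, scanner_id, calibrations) {
  scanner_id <- rep_len(scanner_id, length(hu))
  i <- match(scanner_id, calibrations$scanner_id)
  if (anyNA(i[!is.na(hu)])) {
    missing <- unique(scanner_id[is.na(i) & !is.na(hu)])
    configError(sprintf(
      "no HU-to-vBMD calibration for scanner(s): %s (no silent default is applied)",
      paste(sQuote(missing), collapse = ", ")))
  }
  pmax(calibrations$slope[i] * hu + calibrations$intercept[i], 0)
}

#' Correct contrast-phase bias in vBMD space
#'
#' Applies the per-phase linear correction fitted between enhanced and
#' reference measurements. The `"none"` phase is a no-op. Corrected values
#' below 0 are truncated to 0 with a warning.
#'
#' @param vbmd measured vBMD, mg/ml.
#' @param phase contrast-phase label(s), recycled against `vbmd`.
#' @param corrections table from [contrastCorrectionTable()].
#' @return corrected vBMD, mg/ml.
#' @export
#' @examples
#' corr <- contrastCorrectionTable("venous", 1, -15)
#' correctContrast(130, "venous", corr)
correctContrast <- function(vbmd, phase, corrections) {
  phase <- rep_len(phase, length(vbmd))
  i <- match(phase, corrections$phase)
  if (anyNA(i[!is.na(vbmd)])) {
    missing <- unique(phase[is.na(i) & !is.na(vbmd)])
    configError(sprintf(
      "no contrast correction for phase(s): %s; known phases: %s",
      paste(sQuote(missing), collapse = ", "),
      paste(sQuote(corrections$phase), collapse = ", ")))
  }
  out <- corrections$slope[i] * vbmd + corrections$intercept[i]
  neg <- !is.na(out) & out < 0
  if (any(neg)) {
    warning(sprintf("%d corrected vBMD value(s) < 0 truncated to 0", sum(neg)))
    out[neg] <- 0
  }
  out
}

#' Fit a contrast-phase correction by ordinary least squares
#'
#' Regresses reference (unenhanced) vBMD on enhanced vBMD to obtain the
#' linear correction `corrected = slope * enhanced + intercept` for one
#' contrast phase.
#'
#' @param enhanced,reference paired vBMD values, mg/ml (>= 3 complete pairs).
#' @param phase label stored with the fitted correction.
#' @return a one-row data.frame as from [contrastCorrectionTable()] (plus the
#'   identity `"none"` row), with `n` and `residual_sd` attributes.
#' @export
fitContrastCorrection <- function(enhanced, reference, phase = "enhanced") {
  ok <- complete.cases(enhanced, reference)
  x <- enhanced[ok]; y <- reference[ok]
  if (length(x) < 3) {
    dataError(sprintf("need >= 3 paired values to fit a contrast correction (got %d)",
                      length(x)))
  }
  if (sd(x) == 0) {
    dataError("zero variance in enhanced values; correction is unidentifiable")
  }
  fit <- lm(y ~ x)
  out <- contrastCorrectionTable(phase,
                                 slope = unname(coef(fit)[2]),
                                 intercept = unname(coef(fit)[1]))
  attr(out, "n") <- length(x)
  attr(out, "residual_sd") <- sqrt(sum(residuals(fit)^2) / (length(x) - 2))
  out
}

#' Apply the densitometry stage to a cohort
#'
#' Canonical measurement path: HU -> vBMD conversion for scans that carry raw
#' HU but no vBMD, then contrast-phase correction in vBMD space. Refuses
#' cells that carry both a vBMD and an HU value (conflicting inputs must be
#' resolved upstream).
#'
#' @param cohort a [SpineCohort-class].
#' @param calibrations [scannerCalibrationTable()], or `NULL` to skip
#'   conversion (an error if any cell has HU but no vBMD).
#' @param corrections [contrastCorrectionTable()], or `NULL` to skip
#'   correction (an error if any scan has a phase other than `"none"`).
#' @return the cohort with a complete `vbmd` assay.
#' @export
applyDensitometry <- function(cohort, calibrations = NULL, corrections = NULL) {
  stopifnot(is(cohort, "SpineCohort"))
  hu <- hounsfield(cohort)
  hasVbmd <- "vbmd" %in% assayNames(cohort)
  vb <- if (hasVbmd) vbmd(cohort) else
    matrix(NA_real_, nrow = nrow(cohort), ncol = ncol(cohort),
           dimnames = dimnames(cohort))
  if (!is.null(hu)) {
    conflict <- !is.na(hu) & !is.na(vb)
    if (any(conflict)) {
      idx <- which(conflict, arr.ind = TRUE)
      dataError(sprintf(
        "conflicting inputs: both vbmd and hu present for %d cell(s), e.g. (%s, %s)",
        sum(conflict), colnames(vb)[idx[1, 2]], rownames(vb)[idx[1, 1]]))
    }
    need <- !is.na(hu) & is.na(vb)
    if (any(need)) {
      if (is.null(calibrations)) {
        configError("cohort carries raw HU but no scanner calibrations were supplied")
      }
      sc <- colData(cohort)$scanner_id
      for (j in which(colSums(need) > 0)) {
        rows <- which(need[, j])
        vb[rows, j] <- huToVbmd(hu[rows, j], rep(sc[j], length(rows)),
                                calibrations)
      }
    }
  }
  phase <- colData(cohort)$contrast_phase
  if (any(phase != "none")) {
    if (is.null(corrections)) {
      configError(sprintf(
        "cohort contains contrast-enhanced scans (phases: %s) but no contrast corrections were supplied",
        paste(sQuote(unique(phase[phase != "none"])), collapse = ", ")))
    }
    for (j in which(phase != "none")) {
      rows <- which(!is.na(vb[, j]))
      vb[rows, j] <- correctContrast(vb[rows, j], rep(phase[j], length(rows)),
                                     corrections)
    }
  }
  SummarizedExperiment::assays(cohort, withDimnames = FALSE)[["vbmd"]] <- vb
  validObject(cohort)
  cohort
}
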