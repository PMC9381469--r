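# Statistical core: per-level Pearson correlation with the lumbar reference,
# per-level OLS calibration, and transfer of the lumbar diagnostic cut-offs
# to level-specific thresholds by evaluating the fitted lines.

#' Per-level Pearson correlation with the lumbar reference
#'
#' For every cervicothoracic level present in the cohort, the Pearson
#' correlation between that level's measured vBMD and the per-patient lumbar
#' reference, over patients having both. With `respectExclusions = TRUE`
#' (the post-QC analysis) excluded vertebrae are dropped from the level side;
#' the lumbar reference always honours its own rule regardless. Levels with
#' fewer than 3 usable pairs get `NA` with a warning.
#'
#' @param cohort a QC-flagged cohort with lumbar references computed.
#' @param respectExclusions drop excluded vertebrae from the level side.
#' @return data.frame with columns `level`, `r`, `n`.
#' @export
pearsonByLevel <- function(cohort, respectExclusions = TRUE) {
  ref <- lumbarReference(cohort)
  if (all(is.na(ref))) {
    dataError("no lumbar references present; call computeLumbarReference() first")
  }
  mask <- if (respectExclusions) usableMask(cohort) else measuredMask(cohort)
  vb <- vbmd(cohort)
  levels <- intersect(cervicothoracicLevels(), rownames(cohort))
  res <- lapply(levels, function(l) {
    y <- vb[l, ]
    y[!mask[l, ]] <- NA_real_
    ok <- !is.na(y) & !is.na(ref)
    n <- sum(ok)
    r <- if (n >= 3) cor(y[ok], ref[ok]) else NA_real_
    data.frame(level = l, r = r, n = as.integer(n), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  if (any(is.na(out$r))) {
    warning(sprintf("levels with n < 3 usable pairs, r not computed: %s",
                    paste(out$level[is.na(out$r)], collapse = ", ")))
  }
  out
}

#' Compare two per-level correlation profiles
#'
#' Paired two-sided t test on Fisher z-transformed coefficients across
#' levels (the same levels must be present in both profiles), with medians
#' of the raw r values reported. Degenerate cases (zero variance of the
#' paired differences) resolve to p = 1 for identical profiles and p = 0
#' for a constant nonzero shift.
#'
#' @param before,after data.frames as returned by [pearsonByLevel()].
#' @return list with `median_before`, `median_after`, `statistic`,
#'   `p.value`, `n_levels`.
#' @export
compareCorrelationProfiles <- function(before, after) {
  if (!setequal(before$level, after$level)) {
    dataError(sprintf(
      "profiles cover different levels; only in 'before': %s; only in 'after': %s",
      paste(setdiff(before$level, after$level), collapse = ", "),
      paste(setdiff(after$level, before$level), collapse = ", ")))
  }
  m <- merge(before, after, by = "level", suffixes = c("_before", "_after"))
  m <- m[!is.na(m$r_before) & !is.na(m$r_after), ]
  if (nrow(m) < 3) dataError("need >= 3 levels with r in both profiles")
  zb <- atanh(m$r_before); za <- atanh(m$r_after)
  d <- za - zb
  if (sd(d) < 1e-12) {
    p <- if (abs(mean(d)) < 1e-12) 1 else 0
    stat <- if (abs(mean(d)) < 1e-12) 0 else Inf * sign(mean(d))
  } else {
    tt <- t.test(za, zb, paired = TRUE)
    p <- tt$p.value
    stat <- unname(tt$statistic)
  }
  list(median_before = median(m$r_before),
       median_after = median(m$r_after),
       statistic = stat, p.value = p, n_levels = nrow(m))
}

#' Fit one level's linear calibration against the lumbar reference
#'
#' Ordinary least squares of the level's measured vBMD on the per-patient
#' lumbar reference, over non-excluded vertebrae:
#' `E[vBMD_level] = slope * lumbar + intercept`.
#'
#' @param cohort a QC-flagged cohort with lumbar references computed.
#' @param level a cervicothoracic level name.
#' @return a [LevelCalibration-class].
#' @export
fitLevelCalibration <- function(cohort, level) {
  level <- parseLevel(level)
  if (!level %in% rownames(cohort)) {
    dataError(sprintf("level %s is not present in the cohort", level))
  }
  ref <- lumbarReference(cohort)
  mask <- usableMask(cohort)
  y <- vbmd(cohort)[level, ]
  y[!mask[level, ]] <- NA_real_
  ok <- !is.na(y) & !is.na(ref)
  n <- sum(ok)
  if (n < 3) {
    dataError(sprintf("level %s has only %d usable patients (need >= 3)", level, n))
  }
  x <- ref[ok]; y <- y[ok]
  if (sd(x) == 0) {
    dataError("zero variance in the lumbar reference; calibration is unidentifiable")
  }
  fit <- lm(y ~ x)
  r <- cor(x, y)
  new("LevelCalibration",
      level = level,
      slope = unname(coef(fit)[2]),
      intercept = unname(coef(fit)[1]),
      r = r, r2 = r^2, n = as.integer(n),
      residualSD = sqrt(sum(residuals(fit)^2) / (n - 2)))
}

#' Fit calibrations for a set of levels
#'
#' @param cohort a QC-flagged cohort with lumbar references computed.
#' @param levels level names (default: all cervicothoracic levels present).
#' @return data.frame with one row per successfully fitted level: `level`,
#'   `slope`, `intercept`, `r`, `r2`, `n`, `residual_sd`. Levels that cannot
#'   be fitted (too few patients) are skipped with a warning.
#' @export
fitAllCalibrations <- function(cohort,
                               levels = intersect(cervicothoracicLevels(),
                                                  rownames(cohort))) {
  rows <- list()
  skipped <- character(0)
  for (l in levels) {
    cal <- tryCatch(fitLevelCalibration(cohort, l),
                    spineCalib_data_error = function(e) NULL)
    if (is.null(cal)) {
      skipped <- c(skipped, l)
      next
    }
    rows[[l]] <- data.frame(level = cal@level, slope = cal@slope,
                            intercept = cal@intercept, r = cal@r,
                            r2 = cal@r2, n = cal@n,
                            residual_sd = cal@residualSD,
                            stringsAsFactors = FALSE)
  }
  if (length(skipped) > 0) {
    warning(sprintf("calibration skipped for level(s) with too few usable patients: %s",
                    paste(skipped, collapse = ", ")))
  }
  if (length(rows) == 0) dataError("no level could be calibrated")
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

setMethod("show", "LevelCalibration", function(object) {
  cat(sprintf(
    "LevelCalibration %s: vBMD = %.4g * lumbar + %.4g (r2 = %.4f, n = %d, residual SD = %.1f mg/ml)\n",
    object@level, object@slope, object@intercept, object@r2, object@n,
    object@residualSD))
})

#' Transfer lumbar cut-offs to level-specific thresholds
#'
#' Evaluates each level's calibration line at the lumbar cut-offs:
#' `threshold_x(level) = slope_level * cutoff_x + intercept_level`. This is
#' calibration transfer by evaluation, deliberately NOT inversion of the
#' fitted line -- the two differ whenever r2 < 1 and only evaluation is
#' consistent with predicting the level's value for a patient sitting exactly
#' at the lumbar cut-off. Lumbar reference levels (L1--L3) are carried with
#' the cut-offs themselves. Levels with slope <= 0 or r2 below `r2Floor` are
#' flagged unreliable (the threshold ordering invariant is unverifiable
#' there) and reported with a warning rather than silently emitted.
#'
#' @param calibrations data.frame with columns `level`, `slope`, `intercept`
#'   (optionally `r2`, `n`), as from [fitAllCalibrations()] or
#'   [referenceCalibrations()]; or a list of [LevelCalibration-class].
#' @param lumbarCutoffs named numeric, mg/ml.
#' @param r2Floor reliability floor on r2 (default 0.3).
#' @param provenance `"fitted"` or `"bundled"`.
#' @return A [ThresholdTable-class] (full precision; see
#'   [displayThresholds()] for one-decimal display).
#' @export
#' @examples
#' deriveThresholds(data.frame(level = "C4", slope = 1.35, intercept = 101.2))
deriveThresholds <- function(calibrations,
                             lumbarCutoffs = c(osteoporosis = 80,
                                               osteopenia = 120),
                             r2Floor = 0.3,
                             provenance = "fitted") {
  if (is.list(calibrations) && !is.data.frame(calibrations) &&
      all(vapply(calibrations, is, logical(1), "LevelCalibration"))) {
    calibrations <- do.call(rbind, lapply(calibrations, function(c) {
      data.frame(level = c@level, slope = c@slope, intercept = c@intercept,
                 r2 = c@r2, n = c@n, stringsAsFactors = FALSE)
    }))
  }
  if (!all(c("level", "slope", "intercept") %in% colnames(calibrations))) {
    configError("calibrations need columns level, slope, intercept")
  }
  if (any(lumbarCutoffs <= 0) ||
      lumbarCutoffs["osteopenia"] <= lumbarCutoffs["osteoporosis"]) {
    configError("cutoffs must be positive with osteopenia > osteoporosis")
  }
  cal <- calibrations
  cal$level <- parseLevel(cal$level)
  if (!"r2" %in% colnames(cal)) cal$r2 <- NA_real_
  if (!"n" %in% colnames(cal)) cal$n <- NA_integer_
  tb <- data.frame(
    level = cal$level,
    region = regionOf(cal$level),
    slope = cal$slope,
    intercept = cal$intercept,
    r2 = cal$r2,
    n = as.integer(cal$n),
    threshold_osteopenia = cal$slope * lumbarCutoffs[["osteopenia"]] + cal$intercept,
    threshold_osteoporosis = cal$slope * lumbarCutoffs[["osteoporosis"]] + cal$intercept,
    stringsAsFactors = FALSE
  )
  tb$reliable <- tb$slope > 0 & (is.na(tb$r2) | tb$r2 >= r2Floor)
  if (any(!tb$reliable)) {
    warning(sprintf(
      "threshold(s) flagged unreliable (slope <= 0 or r2 < %.2f): %s",
      r2Floor, paste(tb$level[!tb$reliable], collapse = ", ")))
  }
  # lumbar reference levels carry the cut-offs themselves (identity line)
  lum <- data.frame(
    level = lumbarReferenceLevels(),
    region = "lumbar", slope = 1, intercept = 0, r2 = NA_real_,
    n = NA_integer_,
    threshold_osteopenia = lumbarCutoffs[["osteopenia"]],
    threshold_osteoporosis = lumbarCutoffs[["osteoporosis"]],
    reliable = TRUE, stringsAsFactors = FALSE
  )
  lum <- lum[!lum$level %in% tb$level, ]
  tb <- rbind(tb, lum)
  tb <- tb[order(match(tb$level, .LEVEL_NAMES)), ]
  rownames(tb) <- NULL
  obj <- new("ThresholdTable", table = tb,
             lumbarCutoffs = lumbarCutoffs[c("osteoporosis", "osteopenia")],
             provenance = provenance)
  validObject(obj)
  obj
}

#' Threshold table accessors
#'
#' `thresholdTable()` returns the full-precision table;
#' `displayThresholds()` the display convention (thresholds rounded half-up
#' to one decimal); `lumbarCutoffs()` the lumbar cut-offs.
#'
#' @param x a [ThresholdTable-class].
#' @param includeLumbar keep the L1--L3 rows (default `TRUE`).
#' @return data.frame (or named numeric for `lumbarCutoffs`).
#' @export
thresholdTable <- function(x, includeLumbar = TRUE) {
  stopifnot(is(x, "ThresholdTable"))
  tb <- x@table
  if (!includeLumbar) tb <- tb[tb$region != "lumbar", ]
  rownames(tb) <- NULL
  tb
}

#' @rdname thresholdTable
#' @export
displayThresholds <- function(x, includeLumbar = TRUE) {
  tb <- thresholdTable(x, includeLumbar)
  tb$threshold_osteopenia <- roundHalfUp(tb$threshold_osteopenia, 1)
  tb$threshold_osteoporosis <- roundHalfUp(tb$threshold_osteoporosis, 1)
  tb
}

#' @rdname thresholdTable
#' @export
lumbarCutoffs <- function(x) {
  stopifnot(is(x, "ThresholdTable"))
  x@lumbarCutoffs
}

setMethod("show", "ThresholdTable", function(object) {
  tb <- displayThresholds(object)
  cat(sprintf(
    "ThresholdTable (%s): %d levels; lumbar cut-offs osteoporosis < %g, osteopenia < %g mg/ml\n",
    object@provenance, nrow(tb), object@lumbarCutoffs["osteoporosis"],
    object@lumbarCutoffs["osteopenia"]))
  print(tb[, c("level", "slope", "intercept", "r2",
               "threshold_osteopenia", "threshold_osteoporosis")],
        row.names = FALSE)
})

#' Bundled reference calibration coefficients and thresholds
#'
#' `referenceCalibrations()` returns the shipped per-level calibration table
#' (C2--T12: r2, slope, intercept and the published one-decimal thresholds).
#' `referenceThresholds()` rebuilds a [ThresholdTable-class] from those
#' coefficients at the standard lumbar cut-offs (80 / 120 mg/ml).
#'
#' @return data.frame, or [ThresholdTable-class] for `referenceThresholds()`.
#' @export
referenceCalibrations <- function() {
  path <- system.file("extdata", "table2_reference.csv",
                      package = "SpineCalib", mustWork = TRUE)
  read.csv(path, stringsAsFactors = FALSE)
}

#' @rdname referenceCalibrations
#' @export
referenceThresholds <- function() {
  ref <- referenceCalibrations()
  suppressWarnings(
    deriveThresholds(ref[, c("level", "r2", "slope", "intercept")],
                     provenance = "bundled")
  )
}

#' Write a threshold table as CSV
#'
#' One row per level: `level, slope, intercept, r2, n, threshold_osteopenia,
#' threshold_osteoporosis`, full precision.
#'
#' @param x a [ThresholdTable-class].
#' @param path output file.
#' @param includeLumbar keep the L1--L3 rows (default `FALSE`: the
#'   cervicothoracic calibration targets only).
#' @return the file path, invisibly.
#' @export
writeThresholds <- function(x, path, includeLumbar = FALSE) {
  tb <- thresholdTable(x, includeLumbar)
  tb <- tb[, c("level", "slope", "intercept", "r2", "n",
               "threshold_osteopenia", "threshold_osteoporosis")]
  writeCsvCanonical(tb, path)
  invisible(path)
}
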