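# Diagnostic classification. Boundary convention throughout: strict "<"
# enters the worse category (matching the "vBMD < 80 mg/ml" cut-off
# phrasing); equality at a boundary is the better category.

.CATEGORIES <- c("normal", "osteopenia", "osteoporosis")

#' Create a classification policy
#'
#' @param name `"table2"` (level-specific thresholds), `"rounded_regional"`
#'   (rounded regional osteoporosis constants) or `"lumbar_acr"` (lumbar
#'   cut-offs, lumbar levels only). See [ClassificationPolicy-class].
#' @param thresholds a [ThresholdTable-class] for the `table2` policy
#'   (default: the bundled reference table).
#' @param regionalOsteoporosis named numeric per region for
#'   `rounded_regional` (mg/ml).
#' @param regionalOsteopenia optional named numeric per region; when empty
#'   the rounded policy only separates osteoporosis from not-osteoporosis.
#' @param lumbarCutoffs cut-offs for `lumbar_acr` (mg/ml).
#' @return A [ClassificationPolicy-class].
#' @export
#' @examples
#' classificationPolicy("lumbar_acr")
classificationPolicy <- function(name = c("table2", "rounded_regional",
                                          "lumbar_acr"),
                                 thresholds = NULL,
                                 regionalOsteoporosis = c(cervical = 200,
                                                          thoracic = 100,
                                                          lumbar = 80),
                                 regionalOsteopenia = numeric(0),
                                 lumbarCutoffs = c(osteoporosis = 80,
                                                   osteopenia = 120)) {
  name <- match.arg(name)
  if (name == "table2" && is.null(thresholds)) {
    thresholds <- referenceThresholds()
  }
  if (name == "table2" && !is(thresholds, "ThresholdTable")) {
    configError("the table2 policy requires a ThresholdTable")
  }
  if (name == "rounded_regional" &&
      !all(c("cervical", "thoracic", "lumbar") %in% names(regionalOsteoporosis))) {
    configError("regionalOsteoporosis must name cervical, thoracic and lumbar")
  }
  if (name == "lumbar_acr") {
    thresholds <- NULL
  }
  new("ClassificationPolicy", name = name, thresholds = thresholds,
      regionalOsteoporosis = regionalOsteoporosis,
      regionalOsteopenia = regionalOsteopenia)
}

# Per-level (osteoporosis, osteopenia) bounds under a policy; NA osteopenia
# bound means the policy draws no osteopenia line at that level.
.policyBounds <- function(policy, levels) {
  levels <- parseLevel(levels)
  if (policy@name == "table2") {
    tb <- thresholdTable(policy@thresholds)
    i <- match(levels, tb$level)
    if (anyNA(i)) {
      configError(sprintf("level(s) not covered by the table2 policy: %s",
                          paste(unique(levels[is.na(i)]), collapse = ", ")))
    }
    data.frame(op = tb$threshold_osteoporosis[i],
               pe = tb$threshold_osteopenia[i])
  } else if (policy@name == "rounded_regional") {
    reg <- regionOf(levels)
    pe <- if (length(policy@regionalOsteopenia) > 0) {
      unname(policy@regionalOsteopenia[reg])
    } else rep(NA_real_, length(levels))
    data.frame(op = unname(policy@regionalOsteoporosis[reg]), pe = pe)
  } else { # lumbar_acr
    reg <- regionOf(levels)
    if (any(reg != "lumbar")) {
      configError(sprintf(
        "the lumbar_acr policy covers lumbar levels only; got: %s",
        paste(unique(levels[reg != "lumbar"]), collapse = ", ")))
    }
    cut <- c(osteoporosis = 80, osteopenia = 120)
    if (!is.null(policy@thresholds)) cut <- lumbarCutoffs(policy@thresholds)
    data.frame(op = rep(cut[["osteoporosis"]], length(levels)),
               pe = rep(cut[["osteopenia"]], length(levels)))
  }
}

#' Classify vertebrae by measured vBMD
#'
#' Assigns `osteoporosis` when `vbmd < threshold_osteoporosis(level)`,
#' `osteopenia` when `threshold_osteoporosis <= vbmd <
#' threshold_osteopenia`, otherwise `normal`. Under a policy without an
#' osteopenia line (default `rounded_regional`), values at or above the
#' osteoporosis threshold are `normal` (i.e. not-osteoporosis).
#'
#' @param vbmd non-negative vBMD values, mg/ml.
#' @param level level names, recycled against `vbmd`.
#' @param policy a [ClassificationPolicy-class].
#' @return ordered factor with levels `normal < osteopenia < osteoporosis`.
#' @export
#' @examples
#' classifyVertebra(c(79.9, 80, 120), "L1", classificationPolicy("lumbar_acr"))
classifyVertebra <- function(vbmd, level, policy) {
  stopifnot(is(policy, "ClassificationPolicy"))
  if (any(vbmd < 0, na.rm = TRUE)) dataError("vbmd must be non-negative")
  n <- max(length(vbmd), length(level))
  vbmd <- rep_len(vbmd, n)
  level <- rep_len(parseLevel(level), n)
  b <- .policyBounds(policy, level)
  out <- rep(NA_character_, n)
  ok <- !is.na(vbmd)
  out[ok & vbmd < b$op] <- "osteoporosis"
  out[ok & vbmd >= b$op & !is.na(b$pe) & vbmd < b$pe] <- "osteopenia"
  out[ok & is.na(out)] <- "normal"
  factor(out, levels = .CATEGORIES, ordered = TRUE)
}

#' Classify every patient of a cohort
#'
#' Per-patient aggregation over the measured, non-excluded vertebrae whose
#' levels the policy covers:
#'
#' * `"worst"` (default): the most severe per-vertebra category -- screening
#'   intent (flag, don't diagnose);
#' * `"median"`: the category of the median per-level category under the
#'   ordering normal < osteopenia < osteoporosis (lower rank on ties).
#'
#' Patients with no usable vertebra get `NA` with a warning;
#' [classifyPatient()] raises an explicit unclassifiable error instead.
#'
#' @param cohort a QC-flagged [SpineCohort-class].
#' @param policy a [ClassificationPolicy-class].
#' @param aggregation `"worst"` or `"median"`.
#' @return data.frame: `patient_id`, `policy`, `aggregation`, `category`,
#'   `n_levels`, `contributing_levels` (per-level categories, `level:cat`
#'   semicolon-joined).
#' @export
classifyCohort <- function(cohort, policy, aggregation = c("worst", "median")) {
  aggregation <- match.arg(aggregation)
  ok <- usableMask(cohort)
  vb <- vbmd(cohort)
  covered <- vapply(rownames(cohort), function(l) {
    !inherits(tryCatch(.policyBounds(policy, l), error = identity), "error")
  }, logical(1))
  ok <- ok & covered
  ids <- colnames(cohort)
  rows <- lapply(seq_along(ids), function(j) {
    lv <- rownames(cohort)[ok[, j] & !is.na(vb[, j])]
    if (length(lv) == 0) {
      return(data.frame(patient_id = ids[j], policy = policy@name,
                        aggregation = aggregation, category = NA_character_,
                        n_levels = 0L, contributing_levels = "",
                        stringsAsFactors = FALSE))
    }
    cats <- classifyVertebra(vb[lv, j], lv, policy)
    agg <- if (aggregation == "worst") {
      .CATEGORIES[max(as.integer(cats))]
    } else {
      .CATEGORIES[floor(median(as.integer(cats)))]
    }
    data.frame(patient_id = ids[j], policy = policy@name,
               aggregation = aggregation, category = agg,
               n_levels = length(lv),
               contributing_levels = paste(sprintf("%s:%s", lv, cats),
                                           collapse = ";"),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (any(is.na(out$category))) {
    warning(sprintf("%d patient(s) had no usable vertebra under policy '%s'",
                    sum(is.na(out$category)), policy@name))
  }
  out
}

#' Classify a single patient scan
#'
#' @param cohort a QC-flagged [SpineCohort-class].
#' @param patient_id one patient id present in the cohort.
#' @inheritParams classifyCohort
#' @return the patient's [classifyCohort()] row (error if unclassifiable).
#' @export
classifyPatient <- function(cohort, patient_id, policy,
                            aggregation = c("worst", "median")) {
  if (!patient_id %in% colnames(cohort)) {
    dataError(sprintf("unknown patient_id: %s", patient_id))
  }
  out <- suppressWarnings(
    classifyCohort(cohort[, patient_id], policy, aggregation)
  )
  if (is.na(out$category)) {
    dataError(sprintf(
      "patient %s is unclassifiable: no measured, non-excluded vertebra covered by policy '%s'",
      patient_id, policy@name))
  }
  out
}

setMethod("show", "ClassificationPolicy", function(object) {
  cat(sprintf("ClassificationPolicy '%s'\n", object@name))
  if (object@name == "table2") {
    cat(sprintf("  thresholds: %s table, %d levels\n",
                object@thresholds@provenance,
                nrow(thresholdTable(object@thresholds))))
  } else if (object@name == "rounded_regional") {
    cat("  osteoporosis constants:",
        paste(sprintf("%s < %g", names(object@regionalOsteoporosis),
                      object@regionalOsteoporosis), collapse = ", "), "\n")
    if (length(object@regionalOsteopenia) == 0) {
      cat("  (no osteopenia analogue: osteoporosis vs not-osteoporosis only)\n")
    }
  }
})
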