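# Exclusion-rule quality control and the per-patient lumbar reference.
#
# Exclusion is flag-based and idempotent: records are never deleted, so the
# "before exclusion" correlation analysis can run on the same object.

#' Apply the exclusion rules to a cohort
#'
#' Flags every measured vertebra with Genant fracture grade >= 1
#' (`excludedFracture`) and every vertebra with degeneration grade >= 2
#' (`excludedDegeneration`). Grades must be present on every measured
#' vertebra; a missing grade is an error naming the patient and level, never
#' assumed 0. A [QCReport-class] is stored in the cohort metadata
#' (retrieve with [qcReport()]); the report's dropped-patient count refers to
#' patients with no L1--L3 vertebra surviving both rules.
#'
#' @param cohort a [SpineCohort-class].
#' @return the flagged cohort.
#' @export
applyExclusions <- function(cohort) {
  stopifnot(is(cohort, "SpineCohort"))
  meas <- measuredMask(cohort)
  fg <- fractureGrade(cohort)
  dg <- degenerationGrade(cohort)
  missing <- meas & (is.na(fg) | is.na(dg))
  if (any(missing)) {
    idx <- which(missing, arr.ind = TRUE)
    who <- sprintf("(%s, %s)", colnames(cohort)[idx[, 2]],
                   rownames(cohort)[idx[, 1]])
    dataError(sprintf(
      "missing fracture/degeneration grade on %d measured vertebra(e): %s",
      nrow(idx), paste(utils::head(who, 10), collapse = ", ")))
  }
  exF <- ifelse(meas, fg >= 1L, NA)
  exD <- ifelse(meas, dg >= 2L, NA)
  SummarizedExperiment::assays(cohort, withDimnames = FALSE)[["excludedFracture"]] <- exF
  SummarizedExperiment::assays(cohort, withDimnames = FALSE)[["excludedDegeneration"]] <- exD

  lumbar <- intersect(lumbarReferenceLevels(), rownames(cohort))
  survives <- meas & !exF & !exD
  dropped <- if (length(lumbar) > 0) {
    sum(colSums(survives[lumbar, , drop = FALSE]) == 0)
  } else ncol(cohort)
  perLevel <- data.frame(
    level = rownames(cohort),
    n = as.integer(rowSums(meas)),
    excluded_fracture = as.integer(rowSums(exF, na.rm = TRUE)),
    excluded_degeneration = as.integer(rowSums(exD, na.rm = TRUE)),
    stringsAsFactors = FALSE
  )
  report <- new("QCReport",
                nVertebrae = as.integer(sum(meas)),
                nExcludedFracture = as.integer(sum(exF, na.rm = TRUE)),
                nExcludedDegeneration = as.integer(sum(exD, na.rm = TRUE)),
                nPatientsDropped = as.integer(dropped),
                perLevel = perLevel)
  metadata(cohort)$qcReport <- report
  metadata(cohort)$qcApplied <- TRUE
  validObject(cohort)
  cohort
}

# Logical matrix of vertebrae usable for analysis after QC.
usableMask <- function(cohort, useDegenerationRule = TRUE) {
  if (!qcApplied(cohort)) {
    dataError("exclusions have not been applied; call applyExclusions() first")
  }
  meas <- measuredMask(cohort)
  exF <- assay(cohort, "excludedFracture")
  exD <- assay(cohort, "excludedDegeneration")
  ok <- meas & !exF
  if (useDegenerationRule) ok <- ok & !exD
  ok & !is.na(ok)
}

#' Compute the per-patient lumbar reference
#'
#' Arithmetic mean of the measured vBMD over the L1--L3 vertebrae surviving
#' QC. By default the degeneration rule (grade >= 2 exclusion) is honoured in
#' addition to the fracture rule; `useDegenerationRule = FALSE` preserves the
#' literal non-fractured-only reading. Patients with no surviving L1--L3
#' vertebra get an absent (`NA`) reference -- absence is a value, not an
#' error -- and are dropped from calibration fits downstream.
#'
#' @param cohort a QC-flagged [SpineCohort-class].
#' @param useDegenerationRule also exclude degeneration grade >= 2 vertebrae
#'   from the reference (default `TRUE`).
#' @return the cohort with `colData(.)$lumbar_reference` filled.
#' @export
computeLumbarReference <- function(cohort, useDegenerationRule = TRUE) {
  ok <- usableMask(cohort, useDegenerationRule)
  lumbar <- intersect(lumbarReferenceLevels(), rownames(cohort))
  vb <- vbmd(cohort)
  ref <- rep(NA_real_, ncol(cohort))
  if (length(lumbar) > 0) {
    use <- ok[lumbar, , drop = FALSE]
    v <- vb[lumbar, , drop = FALSE]
    v[!use] <- NA_real_
    k <- colSums(use)
    ref <- ifelse(k > 0, colMeans(v, na.rm = TRUE), NA_real_)
  }
  colData(cohort)$lumbar_reference <- unname(ref)
  cohort
}

#' Compare lumbar reference vBMD between patient groups
#'
#' Two-sided unpaired Welch t test on the per-patient lumbar reference.
#' Groupings:
#'
#' * `"fracture"` -- patients carrying >= 1 fractured vertebra vs none;
#' * `"sex"` -- women vs men after 1:1 greedy nearest-age matching within a
#'   caliper (default 5 years; deterministic tie-break by patient id).
#'   Patients of unknown sex are excluded from the sex comparison.
#'
#' @param cohort a cohort with lumbar references computed.
#' @param grouping `"fracture"` or `"sex"`.
#' @param caliper age-matching caliper in years (sex grouping only).
#' @return list with `groups` (data.frame: group, n, mean, sd), `p.value`,
#'   `statistic` and `grouping`.
#' @export
groupCompare <- function(cohort, grouping = c("fracture", "sex"), caliper = 5) {
  grouping <- match.arg(grouping)
  ref <- lumbarReference(cohort)
  cd <- as.data.frame(colData(cohort))
  if (grouping == "fracture") {
    fg <- fractureGrade(cohort)
    hasFrac <- colSums(fg >= 1L, na.rm = TRUE) > 0
    g1 <- ref[hasFrac]; g2 <- ref[!hasFrac]
    labels <- c("fractured", "non-fractured")
  } else {
    women <- which(cd$sex == "F" & !is.na(ref))
    men <- which(cd$sex == "M" & !is.na(ref))
    if (length(women) == 0 || length(men) == 0) {
      dataError("sex comparison requires at least one woman and one man with a lumbar reference")
    }
    pairs <- greedyAgeMatch(cd$age[women], cd$age[men],
                            cd$patient_id[women], cd$patient_id[men], caliper)
    if (nrow(pairs) < 2) {
      dataError("fewer than 2 age-matched pairs within the caliper")
    }
    g1 <- ref[women[pairs$i]]; g2 <- ref[men[pairs$j]]
    labels <- c("women", "men")
  }
  g1 <- g1[!is.na(g1)]; g2 <- g2[!is.na(g2)]
  if (length(g1) < 2 || length(g2) < 2) {
    dataError("each group needs >= 2 patients with a lumbar reference")
  }
  tt <- t.test(g1, g2, var.equal = FALSE)
  list(
    grouping = grouping,
    groups = data.frame(group = labels, n = c(length(g1), length(g2)),
                        mean = c(mean(g1), mean(g2)),
                        sd = c(sd(g1), sd(g2)), stringsAsFactors = FALSE),
    statistic = unname(tt$statistic),
    p.value = tt$p.value
  )
}

# Greedy 1:1 nearest-age matching. Women are processed in order (age, id);
# each takes the unmatched man with the smallest |age difference|, ties
# broken by the man's patient id; pairs beyond the caliper are skipped.
greedyAgeMatch <- function(ageW, ageM, idW, idM, caliper) {
  ordW <- order(ageW, idW)
  freeM <- rep(TRUE, length(ageM))
  out <- list()
  for (i in ordW) {
    d <- abs(ageM - ageW[i])
    d[!freeM] <- Inf
    j <- which(d == min(d))
    if (length(j) > 1) j <- j[order(idM[j])][1]
    if (is.finite(d[j]) && d[j] <= caliper) {
      freeM[j] <- FALSE
      out[[length(out) + 1L]] <- c(i = i, j = j)
    }
  }
  if (length(out) == 0) {
    return(data.frame(i = integer(0), j = integer(0)))
  }
  as.data.frame(do.call(rbind, out))
}

setMethod("show", "QCReport", function(object) {
  cat(sprintf("QCReport: %d measured vertebrae\n", object@nVertebrae))
  cat(sprintf("  excluded by fracture rule (Genant >= 1): %d\n",
              object@nExcludedFracture))
  cat(sprintf("  excluded by degeneration rule (grade >= 2): %d\n",
              object@nExcludedDegeneration))
  cat(sprintf("  patients without usable lumbar reference: %d\n",
              object@nPatientsDropped))
})

#' Serialize a QCReport to JSON
#'
#' @param report a [QCReport-class].
#' @param path optional file path; when `NULL` the JSON string is returned.
#' @return JSON string (invisibly when written to a file).
#' @export
qcReportToJson <- function(report, path = NULL) {
  stopifnot(is(report, "QCReport"))
  x <- list(
    n_vertebrae_total = report@nVertebrae,
    n_excluded_fracture = report@nExcludedFracture,
    n_excluded_degeneration = report@nExcludedDegeneration,
    n_patients_dropped = report@nPatientsDropped,
    per_level = report@perLevel
  )
  js <- jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  if (!is.null(path)) {
    writeLines(js, path)
    return(invisible(js))
  }
  js
}
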