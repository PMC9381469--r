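#' @importFrom SummarizedExperiment SummarizedExperiment assay assays
#'   assayNames colData rowData colData<- assays<-
#' @importFrom S4Vectors DataFrame metadata metadata<-
NULL

#' Construct a SpineCohort from assay matrices
#'
#' Rows of every matrix must be named with canonical vertebral levels and
#' columns with patient ids matching `colData$patient_id`.
#'
#' @param vbmd numeric matrix of measured trabecular vBMD (mg/ml), or `NULL`.
#' @param hu numeric matrix of raw Hounsfield units, or `NULL`.
#' @param fractureGrade,degenerationGrade integer matrices of grades 0--3
#'   (`NA` where a level is not covered).
#' @param colData data.frame with columns `patient_id`, `age`, `sex`,
#'   `scanner_id`, `contrast_phase` (and optionally `lumbar_reference`).
#' @param vbmdTrue optional matrix of bias-free vBMD (simulated cohorts).
#' @param provenance list recorded in `metadata()$provenance`.
#' @return A [SpineCohort-class].
#' @export
SpineCohort <- function(vbmd = NULL, hu = NULL, fractureGrade,
                        degenerationGrade, colData, vbmdTrue = NULL,
                        provenance = list(source = "constructed")) {
  proto <- if (!is.null(vbmd)) vbmd else hu
  if (is.null(proto)) dataError("at least one of vbmd or hu must be supplied")
  lv <- orderLevels(parseLevel(rownames(proto)))
  reorder <- function(m) if (is.null(m)) NULL else m[lv, , drop = FALSE]
  assaysList <- list()
  if (!is.null(vbmd)) assaysList$vbmd <- reorder(vbmd)
  if (!is.null(hu)) assaysList$hu <- reorder(hu)
  if (!is.null(vbmdTrue)) assaysList$vbmdTrue <- reorder(vbmdTrue)
  assaysList$fractureGrade <- reorder(fractureGrade)
  assaysList$degenerationGrade <- reorder(degenerationGrade)
  flag <- matrix(NA, nrow = length(lv), ncol = ncol(proto),
                 dimnames = list(lv, colnames(proto)))
  assaysList$excludedFracture <- flag
  assaysList$excludedDegeneration <- flag

  cd <- as.data.frame(colData, stringsAsFactors = FALSE)
  if (!"lumbar_reference" %in% colnames(cd)) cd$lumbar_reference <- NA_real_
  rownames(cd) <- cd$patient_id
  rd <- DataFrame(region = regionOf(lv),
                  ordinal = match(lv, .LEVEL_NAMES),
                  row.names = lv)
  se <- SummarizedExperiment(
    assays = assaysList,
    rowData = rd,
    colData = DataFrame(cd, check.names = FALSE)
  )
  obj <- new("SpineCohort", se)
  metadata(obj)$provenance <- provenance
  metadata(obj)$qcApplied <- FALSE
  validObject(obj)
  obj
}

#' Build a SpineCohort from a long per-vertebra table
#'
#' One row per (patient, level). Expected columns: `patient_id`, `age`,
#' `sex`, `scanner_id`, `contrast_phase`, `level`, `vbmd_mgml`, `hu`,
#' `fracture_grade`, `degeneration_grade` (the CSV interchange contract used
#' by [readCohort()]).
#'
#' @param df data.frame in long format.
#' @param provenance list recorded in the cohort metadata.
#' @return A [SpineCohort-class].
#' @export
cohortFromTable <- function(df, provenance = list(source = "table")) {
  df$level <- parseLevel(df$level)
  dup <- duplicated(df[, c("patient_id", "level")])
  if (any(dup)) {
    dataError(sprintf("duplicate (patient_id, level) pairs: %s",
                      paste(unique(sprintf("(%s, %s)", df$patient_id[dup],
                                           df$level[dup])), collapse = ", ")))
  }
  pts <- unique(df$patient_id)
  lv <- orderLevels(unique(df$level))
  mk <- function(col, mode = "numeric") {
    m <- matrix(if (mode == "integer") NA_integer_ else NA_real_,
                nrow = length(lv), ncol = length(pts),
                dimnames = list(lv, pts))
    m[cbind(df$level, df$patient_id)] <- df[[col]]
    m
  }
  cd <- df[!duplicated(df$patient_id),
           c("patient_id", "age", "sex", "scanner_id", "contrast_phase")]
  SpineCohort(
    vbmd = if (any(!is.na(df$vbmd_mgml))) mk("vbmd_mgml") else NULL,
    hu = if (any(!is.na(df$hu))) mk("hu") else NULL,
    fractureGrade = mk("fracture_grade", "integer"),
    degenerationGrade = mk("degeneration_grade", "integer"),
    colData = cd,
    provenance = provenance
  )
}

#' Export a SpineCohort as a long per-vertebra table
#'
#' Inverse of [cohortFromTable()]: one row per measured (patient, level),
#' levels in canonical craniocaudal order within each patient.
#'
#' @param cohort a [SpineCohort-class].
#' @return data.frame in the CSV interchange column order.
#' @export
asCohortTable <- function(cohort) {
  stopifnot(is(cohort, "SpineCohort"))
  cd <- as.data.frame(colData(cohort))
  lv <- rownames(cohort)
  getA <- function(nm) {
    if (nm %in% assayNames(cohort)) assay(cohort, nm) else
      matrix(NA_real_, nrow = length(lv), ncol = ncol(cohort),
             dimnames = dimnames(cohort))
  }
  vb <- getA("vbmd"); hu <- getA("hu")
  fg <- getA("fractureGrade"); dg <- getA("degenerationGrade")
  measured <- !is.na(vb) | !is.na(hu)
  idx <- which(measured, arr.ind = TRUE)
  # canonical order: patient (column) major, then craniocaudal level
  idx <- idx[order(idx[, 2], idx[, 1]), , drop = FALSE]
  data.frame(
    patient_id = cd$patient_id[idx[, 2]],
    age = cd$age[idx[, 2]],
    sex = cd$sex[idx[, 2]],
    scanner_id = cd$scanner_id[idx[, 2]],
    contrast_phase = cd$contrast_phase[idx[, 2]],
    level = lv[idx[, 1]],
    vbmd_mgml = vb[idx],
    hu = hu[idx],
    fracture_grade = as.integer(fg[idx]),
    degeneration_grade = as.integer(dg[idx]),
    stringsAsFactors = FALSE
  )
}

# ---- accessors --------------------------------------------------------------

#' Assay and column accessors for SpineCohort
#'
#' `vbmd()` returns the measured vBMD matrix, `hounsfield()` the raw HU
#' matrix (or `NULL`), `fractureGrade()` / `degenerationGrade()` the grade
#' matrices, `measuredMask()` the logical matrix of covered (patient, level)
#' cells, `lumbarReference()` the per-patient L1--L3 reference (NA until
#' [computeLumbarReference()] has run) and `qcReport()` the [QCReport-class]
#' stored by [applyExclusions()].
#'
#' @param x a [SpineCohort-class].
#' @return matrix, numeric vector or [QCReport-class] as described.
#' @name cohort-accessors
NULL

#' @rdname cohort-accessors
#' @export
vbmd <- function(x) assay(x, "vbmd")

#' @rdname cohort-accessors
#' @export
hounsfield <- function(x) {
  if ("hu" %in% assayNames(x)) assay(x, "hu") else NULL
}

#' @rdname cohort-accessors
#' @export
fractureGrade <- function(x) assay(x, "fractureGrade")

#' @rdname cohort-accessors
#' @export
degenerationGrade <- function(x) assay(x, "degenerationGrade")

#' @rdname cohort-accessors
#' @export
measuredMask <- function(x) {
  m <- if ("vbmd" %in% assayNames(x)) !is.na(assay(x, "vbmd")) else
    matrix(FALSE, nrow = nrow(x), ncol = ncol(x), dimnames = dimnames(x))
  if ("hu" %in% assayNames(x)) m <- m | !is.na(assay(x, "hu"))
  m
}

#' @rdname cohort-accessors
#' @export
lumbarReference <- function(x) {
  setNames(colData(x)$lumbar_reference, colData(x)$patient_id)
}

#' @rdname cohort-accessors
#' @export
qcReport <- function(x) metadata(x)$qcReport

#' @rdname cohort-accessors
#' @export
qcApplied <- function(x) isTRUE(metadata(x)$qcApplied)

setMethod("show", "SpineCohort", function(object) {
  cat(sprintf("SpineCohort: %d patients x %d vertebral levels (%s)\n",
              ncol(object), nrow(object),
              paste(range(rownames(object)[c(1, nrow(object))]),
                    collapse = "-")))
  meas <- sum(measuredMask(object))
  cat(sprintf("  measured vertebrae: %d | assays: %s\n", meas,
              paste(assayNames(object), collapse = ", ")))
  prov <- metadata(object)$provenance
  if (!is.null(prov$source)) cat(sprintf("  source: %s\n", prov$source))
  cat(sprintf("  QC applied: %s | lumbar references: %d/%d\n",
              qcApplied(object),
              sum(!is.na(colData(object)$lumbar_reference)), ncol(object)))
})
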