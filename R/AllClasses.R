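#' @import methods
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
NULL

#' SpineCohort: per-vertebra densitometry for a patient cohort
#'
#' A [SummarizedExperiment::SummarizedExperiment]-backed container in which
#' rows are vertebral levels (canonically ordered subset of C2--C7, T1--T12,
#' L1--L5) and columns are patient scans. Assays (all levels x patients,
#' `NA` where a level is not covered by the scan):
#'
#' * `vbmd` -- measured trabecular vBMD in mg/ml (non-negative),
#' * `hu` -- raw Hounsfield units (optional),
#' * `vbmdTrue` -- bias-free vBMD, only present for simulated cohorts,
#' * `fractureGrade` -- Genant semiquantitative fracture grade 0--3,
#' * `degenerationGrade` -- degeneration grade 0--3,
#' * `excludedFracture`, `excludedDegeneration` -- QC flags, set by
#'   [applyExclusions()] (records are flagged, never deleted).
#'
#' Column data carries `patient_id` (unique), `age` (years), `sex`
#' (`"F"`/`"M"`/`"U"`), `scanner_id`, `contrast_phase` (`"none"` or a phase
#' label) and `lumbar_reference` (mg/ml, filled by
#' [computeLumbarReference()]). Metadata carries provenance (source, seed,
#' config hash) and QC state.
#'
#' @seealso [SpineCohort()], [cohortFromTable()], [applyExclusions()]
#' @export
setClass("SpineCohort", contains = "SummarizedExperiment")

setValidity("SpineCohort", function(object) {
  msgs <- character(0)
  rn <- rownames(object)
  if (is.null(rn) || anyDuplicated(rn)) {
    msgs <- c(msgs, "duplicate or missing vertebral level rownames")
  } else if (!all(rn %in% .LEVEL_NAMES)) {
    msgs <- c(msgs, sprintf("invalid level name(s): %s",
                            paste(setdiff(rn, .LEVEL_NAMES), collapse = ", ")))
  }
  cd <- SummarizedExperiment::colData(object)
  need <- c("patient_id", "age", "sex", "scanner_id", "contrast_phase",
            "lumbar_reference")
  miss <- setdiff(need, colnames(cd))
  if (length(miss) > 0) {
    msgs <- c(msgs, sprintf("missing colData column(s): %s",
                            paste(miss, collapse = ", ")))
  } else {
    if (anyDuplicated(cd$patient_id)) {
      msgs <- c(msgs, "patient_id values must be unique within a cohort")
    }
    if (!all(cd$sex %in% c("F", "M", "U"))) {
      msgs <- c(msgs, "sex must be one of 'F', 'M', 'U'")
    }
  }
  an <- SummarizedExperiment::assayNames(object)
  if (!"vbmd" %in% an && !"hu" %in% an) {
    msgs <- c(msgs, "at least one of the 'vbmd' or 'hu' assays is required")
  }
  for (g in intersect(c("fractureGrade", "degenerationGrade"), an)) {
    v <- SummarizedExperiment::assay(object, g)
    if (!all(is.na(v) | (v %in% 0:3))) {
      msgs <- c(msgs, sprintf("%s values must be in 0..3 or NA", g))
    }
  }
  if ("vbmd" %in% an) {
    v <- SummarizedExperiment::assay(object, "vbmd")
    if (any(v < 0, na.rm = TRUE)) {
      msgs <- c(msgs, "vbmd values must be non-negative")
    }
  }
  if (length(msgs) > 0) msgs else TRUE
})

#' Quality-control report
#'
#' Tallies produced by [applyExclusions()]: total measured vertebrae, counts
#' excluded by the fracture rule (Genant grade >= 1) and the degeneration rule
#' (grade >= 2), patients left without a usable L1--L3 lumbar reference, and
#' per-level exclusion tallies. A vertebra failing both rules is counted in
#' both tallies but excluded once.
#'
#' @slot nVertebrae total measured vertebrae in the cohort.
#' @slot nExcludedFracture vertebrae with fracture grade >= 1.
#' @slot nExcludedDegeneration vertebrae with degeneration grade >= 2.
#' @slot nPatientsDropped patients with no surviving L1--L3 vertebra.
#' @slot perLevel per-level data.frame of tallies.
#' @export
setClass("QCReport", representation(
  nVertebrae = "integer",
  nExcludedFracture = "integer",
  nExcludedDegeneration = "integer",
  nPatientsDropped = "integer",
  perLevel = "data.frame"
))

#' Per-level linear calibration against the lumbar reference
#'
#' Ordinary-least-squares fit of one cervicothoracic level's vBMD on the
#' patient-wise lumbar reference: `E[vBMD_level] = slope * lumbar + intercept`.
#'
#' @slot level canonical level name (C2--T12).
#' @slot slope dimensionless regression slope.
#' @slot intercept mg/ml.
#' @slot r Pearson correlation coefficient.
#' @slot r2 coefficient of determination (`r^2`).
#' @slot n number of patients used.
#' @slot residualSD residual standard deviation, mg/ml.
#' @export
setClass("LevelCalibration", representation(
  level = "character",
  slope = "numeric",
  intercept = "numeric",
  r = "numeric",
  r2 = "numeric",
  n = "integer",
  residualSD = "numeric"
))

setValidity("LevelCalibration", function(object) {
  msgs <- character(0)
  if (length(object@level) != 1 || !object@level %in% .LEVEL_NAMES) {
    msgs <- c(msgs, "level must be a single valid level name")
  }
  if (!is.na(object@r) && abs(object@r) > 1 + 1e-12) {
    msgs <- c(msgs, "|r| must be <= 1")
  }
  if (!is.na(object@r) && !is.na(object@r2) &&
      abs(object@r2 - object@r^2) > 1e-8) {
    msgs <- c(msgs, "r2 must equal r^2")
  }
  if (object@n < 3L) msgs <- c(msgs, "n must be >= 3")
  if (length(msgs) > 0) msgs else TRUE
})

#' Level-specific diagnostic threshold table
#'
#' Thresholds obtained by evaluating each level's calibration line at the
#' lumbar cut-offs (threshold transfer): `threshold_x(level) = slope_level *
#' cutoff_x + intercept_level`. Values are kept at full precision; use
#' [displayThresholds()] for the one-decimal display convention.
#'
#' @slot table data.frame with columns `level`, `region`, `slope`,
#'   `intercept`, `r2`, `n`, `threshold_osteopenia`, `threshold_osteoporosis`,
#'   `reliable`.
#' @slot lumbarCutoffs named numeric: `osteoporosis`, `osteopenia` (mg/ml).
#' @slot provenance `"fitted"` or `"bundled"` (shipped reference table).
#' @export
setClass("ThresholdTable", representation(
  table = "data.frame",
  lumbarCutoffs = "numeric",
  provenance = "character"
))

setValidity("ThresholdTable", function(object) {
  msgs <- character(0)
  cut <- object@lumbarCutoffs
  if (!all(c("osteoporosis", "osteopenia") %in% names(cut))) {
    msgs <- c(msgs, "lumbarCutoffs must name 'osteoporosis' and 'osteopenia'")
  } else if (any(cut <= 0) || cut["osteopenia"] <= cut["osteoporosis"]) {
    msgs <- c(msgs, "cutoffs must be positive with osteopenia > osteoporosis")
  }
  tb <- object@table
  need <- c("level", "region", "slope", "intercept", "r2", "n",
            "threshold_osteopenia", "threshold_osteoporosis", "reliable")
  if (!all(need %in% colnames(tb))) {
    msgs <- c(msgs, "threshold table is missing required columns")
  } else {
    ok <- tb$reliable & !is.na(tb$slope) & tb$slope > 0
    bad <- ok & tb$threshold_osteopenia <= tb$threshold_osteoporosis
    if (any(bad)) {
      msgs <- c(msgs, "osteopenia threshold must exceed osteoporosis threshold")
    }
  }
  if (length(msgs) > 0) msgs else TRUE
})

#' Generative parameterization of a synthetic cohort
#'
#' Full description of the simulated study population: demographics, the
#' latent lumbar density model, per-level linear couplings and residual
#' noise, fracture / degeneration / contrast-enhancement models, and the
#' scanner pool. Fixing `seed` fixes the generated cohort bit-for-bit.
#' Construct with [simulationConfig()], which supplies defaults emulating the
#' reference study population.
#'
#' @slot nPatients number of patients.
#' @slot seed RNG seed (single integer).
#' @slot ageMean,ageSD,ageRange truncated-normal age model (years).
#' @slot femaleFraction probability a patient is female.
#' @slot lumbarModel data.frame (`sex`, `intercept18`, `declinePerYear`):
#'   sex-specific latent lumbar vBMD at age 18 and linear decline per year.
#' @slot lumbarBetweenSD between-patient SD of the latent lumbar vBMD, mg/ml.
#' @slot lumbarLevelNoiseSD residual SD of each L1--L3 measurement around the
#'   latent value, mg/ml.
#' @slot levelCoupling data.frame (`level`, `slope`, `intercept`) giving
#'   `E[vBMD_level | lumbar]` for C2--T12.
#' @slot levelNoiseSD named numeric, per-level residual SD, mg/ml.
#' @slot fractureModel list; empty list disables fractures.
#' @slot degenerationModel list; empty list disables degeneration.
#' @slot contrastModel list; empty list disables contrast enhancement.
#' @slot scannerPool data.frame (`scanner_id`, `weight`, `slope`,
#'   `intercept`) of synthetic HU<->vBMD coefficients.
#' @slot cervicalCoverage fraction of scans covering the cervical spine.
#' @slot generateHU also emit a raw-HU assay via the scanner pool.
#' @export
setClass("SimulationConfig", representation(
  nPatients = "integer",
  seed = "integer",
  ageMean = "numeric",
  ageSD = "numeric",
  ageRange = "numeric",
  femaleFraction = "numeric",
  lumbarModel = "data.frame",
  lumbarBetweenSD = "numeric",
  lumbarLevelNoiseSD = "numeric",
  levelCoupling = "data.frame",
  levelNoiseSD = "numeric",
  fractureModel = "list",
  degenerationModel = "list",
  contrastModel = "list",
  scannerPool = "data.frame",
  cervicalCoverage = "numeric",
  generateHU = "logical"
))

setValidity("SimulationConfig", function(object) {
  msgs <- character(0)
  if (object@nPatients < 1L) msgs <- c(msgs, "nPatients must be positive")
  if (object@ageSD <= 0) msgs <- c(msgs, "ageSD must be positive")
  if (length(object@ageRange) != 2 || diff(object@ageRange) <= 0) {
    msgs <- c(msgs, "ageRange must be an increasing pair")
  }
  probs <- c(object@femaleFraction, object@cervicalCoverage)
  if (any(probs < 0 | probs > 1)) {
    msgs <- c(msgs, "femaleFraction and cervicalCoverage must lie in [0, 1]")
  }
  if (object@lumbarBetweenSD < 0 || object@lumbarLevelNoiseSD < 0 ||
      any(object@levelNoiseSD < 0)) {
    msgs <- c(msgs, "all standard deviations must be >= 0")
  }
  lc <- object@levelCoupling
  if (!all(c("level", "slope", "intercept") %in% colnames(lc))) {
    msgs <- c(msgs, "levelCoupling needs columns level, slope, intercept")
  } else if (!setequal(lc$level, cervicothoracicLevels())) {
    msgs <- c(msgs, "levelCoupling must cover exactly C2-T12")
  } else if (!all(cervicothoracicLevels() %in% names(object@levelNoiseSD))) {
    msgs <- c(msgs, "levelNoiseSD must name every level C2-T12")
  }
  fm <- object@fractureModel
  if (length(fm) > 0) {
    rp <- fm$regionProbs
    if (is.null(rp) || abs(sum(rp) - 1) > 1e-8 || any(rp < 0)) {
      msgs <- c(msgs, "fracture regionProbs must be non-negative and sum to 1")
    }
    gp <- fm$gradeProbs
    if (is.null(gp) || abs(sum(gp) - 1) > 1e-8 || any(gp < 0)) {
      msgs <- c(msgs, "fracture gradeProbs must be non-negative and sum to 1")
    }
  }
  dm <- object@degenerationModel
  if (length(dm) > 0) {
    pr <- c(dm$severeFraction, dm$mildFraction)
    if (any(pr < 0 | pr > 1)) {
      msgs <- c(msgs, "degeneration fractions must lie in [0, 1]")
    }
  }
  cm <- object@contrastModel
  if (length(cm) > 0) {
    if (cm$fraction < 0 || cm$fraction > 1) {
      msgs <- c(msgs, "contrast fraction must lie in [0, 1]")
    }
    ph <- cm$phases
    if (is.null(ph) || abs(sum(ph$prob) - 1) > 1e-8 || any(ph$prob < 0) ||
        any(ph$biasSD < 0)) {
      msgs <- c(msgs, "contrast phase probabilities/SDs are invalid")
    }
  }
  sp <- object@scannerPool
  if (!all(c("scanner_id", "weight", "slope", "intercept") %in% colnames(sp)) ||
      any(sp$weight < 0) || sum(sp$weight) <= 0 || any(sp$slope <= 0)) {
    msgs <- c(msgs, "scannerPool needs positive weights and slopes")
  }
  if (length(msgs) > 0) msgs else TRUE
})

#' Diagnostic classification policy
#'
#' Determines the diagnostic category (`normal` / `osteopenia` /
#' `osteoporosis`) of any (vBMD, level) pair. Three named policies:
#'
#' * `table2` -- level-specific thresholds from a [ThresholdTable-class]
#'   (default: the bundled reference table, C2--T12 plus L1--L3);
#' * `rounded_regional` -- rounded regional osteoporosis constants
#'   (cervical < 200, thoracic < 100, lumbar < 80 mg/ml). No osteopenia
#'   analogue is defined unless regional osteopenia constants are supplied,
#'   so by default this policy only separates osteoporosis from
#'   not-osteoporosis;
#' * `lumbar_acr` -- the lumbar cut-offs (80 / 120 mg/ml), lumbar levels only.
#'
#' @slot name policy name.
#' @slot thresholds [ThresholdTable-class] or `NULL`.
#' @slot regionalOsteoporosis named numeric per region (mg/ml).
#' @slot regionalOsteopenia named numeric per region, possibly empty.
#' @export
setClass("ClassificationPolicy", representation(
  name = "character",
  thresholds = "ANY",
  regionalOsteoporosis = "numeric",
  regionalOsteopenia = "numeric"
))
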