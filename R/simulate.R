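# Synthetic cohort generator. A single latent lumbar vBMD per patient (linear
# in age, sex-specific, plus between-patient scatter) drives every vertebral
# level through per-level linear couplings; fracture, degeneration and
# contrast-enhancement processes add the measurement biases that the QC and
# correction stages are designed to remove.

#' Default component models of the synthetic cohort
#'
#' `defaultFractureModel()`: a patient carries at least one fracture with
#' logistic probability in the latent lumbar vBMD (low density -> higher
#' risk, calibrated to ~60/260 fractured patients and a fractured-patient
#' lumbar mean near 80 mg/ml); the number of fractured vertebrae is
#' `1 + Poisson(meanExtra)` (~158/60 per fractured patient); fractures are
#' placed thoracic/lumbar/cervical with probabilities 0.65/0.34/0.01 and
#' graded uniformly over Genant 1--3 (no published breakdown; an assumption).
#' Fractured vertebrae receive a positive measured-vBMD bias (compression).
#'
#' `defaultDegenerationModel()`: per-vertebra probability of moderate-to-severe
#' degeneration (grade >= 2) logistic in age (calibrated to ~530/4874
#' vertebrae), split 70/30 over grades 2/3; mild grade 1 occurs independently;
#' grade >= 2 vertebrae receive a positive measured-vBMD bias
#' (osteophytes/sclerosis).
#'
#' `defaultContrastModel()`: 46/260 scans are contrast-enhanced, split evenly
#' between arterial and venous phases, each adding a positive per-vertebra
#' enhancement bias.
#'
#' `defaultScannerPool()`: eight scanners with the study's sampling weights
#' and synthetic HU<->vBMD linear coefficients (placeholders -- real phantom
#' calibrations are site-specific and not published).
#'
#' @return a list (or data.frame for the scanner pool) of model parameters.
#' @export
defaultFractureModel <- function() {
  list(
    intercept = 2.36,            # logit scale
    slopePerMgMl = -0.03,        # per mg/ml latent lumbar vBMD
    meanExtra = 1.6,             # Poisson mean of additional fractured levels
    regionProbs = c(cervical = 0.01, thoracic = 0.65, lumbar = 0.34),
    gradeProbs = c("1" = 1 / 3, "2" = 1 / 3, "3" = 1 / 3),
    biasMean = 30, biasSD = 20   # mg/ml, truncated at 0
  )
}

#' @rdname defaultFractureModel
#' @export
defaultDegenerationModel <- function() {
  list(
    intercept = -4.585,          # logit scale
    slopePerYear = 0.04,
    severeFraction = 0.3,        # grade 3 share among grade >= 2
    mildFraction = 0.15,         # grade 1 probability among grade < 2
    biasMean = 40, biasSD = 15   # mg/ml, truncated at 0
  )
}

#' @rdname defaultFractureModel
#' @export
defaultContrastModel <- function() {
  list(
    fraction = 46 / 260,
    phases = data.frame(
      phase = c("arterial", "venous"),
      prob = c(0.5, 0.5),
      biasMean = c(10, 17),
      biasSD = c(4, 5),
      stringsAsFactors = FALSE
    )
  )
}

#' @rdname defaultFractureModel
#' @export
defaultScannerPool <- function() {
  data.frame(
    scanner_id = c("Philips_Iqon", "Philips_Brilliance64", "Philips_iCT",
                   "Siemens_Definition_AS_Plus", "Siemens_Definition_AS",
                   "Siemens_Sensation_Cardiac64", "Siemens_Biograph128",
                   "Siemens_Biograph64"),
    weight = c(29, 43, 26, 85, 57, 11, 23, 26),
    slope = c(0.82, 0.79, 0.85, 0.80, 0.81, 0.77, 0.83, 0.80),
    intercept = c(1.2, -0.8, 0.5, 0.0, 0.9, -1.5, 0.4, -0.2),
    stringsAsFactors = FALSE
  )
}

# Sex-specific latent lumbar line: value at age 18 and decline per year,
# anchored to the printed C4 age/sex group means mapped through the C4
# coupling, the sex-matched lumbar means and the fractured/non-fractured
# lumbar means (see the methods vignette).
defaultLumbarModel <- function() {
  data.frame(
    sex = c("F", "M"),
    intercept18 = c(171.7, 172.0),
    declinePerYear = c(1.5714, 1.0),
    stringsAsFactors = FALSE
  )
}

#' Create a synthetic-cohort configuration
#'
#' Defaults emulate the reference study population: 260 patients (105 women),
#' age 59.7 +/- 18.3 years truncated to 18--96, level couplings equal to the
#' bundled reference calibration coefficients, and per-level residual noise
#' derived from the bundled r-squared profile so that the model-implied
#' per-level Pearson correlation reproduces the post-exclusion profile
#' (r rising from ~0.76 at C2 to ~0.96 at T12) by construction.
#'
#' @param nPatients number of patients.
#' @param seed single integer fixing the cohort bit-for-bit.
#' @param ageMean,ageSD,ageRange truncated-normal age model (years).
#' @param femaleFraction probability a patient is female.
#' @param lumbarModel sex-specific latent lumbar line (see
#'   [SimulationConfig-class]).
#' @param lumbarBetweenSD between-patient latent SD, mg/ml.
#' @param lumbarLevelNoiseSD per-measurement SD of L1--L3 around the latent
#'   value, mg/ml.
#' @param levelCoupling data.frame (`level`, `slope`, `intercept`) for
#'   C2--T12; defaults to the bundled reference coefficients.
#' @param levelNoiseSD per-level residual SD: a named vector, a scalar
#'   recycled to all levels, or `NULL` to derive from `targetR2`.
#' @param targetR2 named per-level r-squared used to derive `levelNoiseSD`
#'   when the latter is `NULL`; defaults to the bundled reference profile.
#' @param fractureModel,degenerationModel,contrastModel component models
#'   (`NULL` disables the component).
#' @param scannerPool scanner ids, sampling weights and synthetic HU
#'   coefficients.
#' @param cervicalCoverage fraction of scans that include C2--C7.
#' @param generateHU also emit a raw-HU assay.
#' @return A validated [SimulationConfig-class].
#' @export
#' @examples
#' cfg <- simulationConfig(nPatients = 50, seed = 1)
#' cohort <- simulateCohort(cfg)
simulationConfig <- function(nPatients = 260,
                             seed = 1,
                             ageMean = 59.7, ageSD = 18.3,
                             ageRange = c(18, 96),
                             femaleFraction = 105 / 260,
                             lumbarModel = defaultLumbarModel(),
                             lumbarBetweenSD = 35,
                             lumbarLevelNoiseSD = 8,
                             levelCoupling = NULL,
                             levelNoiseSD = NULL,
                             targetR2 = NULL,
                             fractureModel = defaultFractureModel(),
                             degenerationModel = defaultDegenerationModel(),
                             contrastModel = defaultContrastModel(),
                             scannerPool = defaultScannerPool(),
                             cervicalCoverage = 212 / 260,
                             generateHU = FALSE) {
  if (length(nPatients) != 1 || is.na(nPatients) || nPatients < 1) {
    configError("nPatients must be a positive integer")
  }
  ref <- referenceCalibrations()
  if (is.null(levelCoupling)) {
    levelCoupling <- ref[, c("level", "slope", "intercept")]
  }
  ct <- cervicothoracicLevels()
  if (is.null(levelNoiseSD)) {
    if (is.null(targetR2)) targetR2 <- setNames(ref$r2, ref$level)
    # sigma_l = a * sigma_L * sqrt(1/r^2 - 1) makes the model-implied r
    # equal the target profile given the latent lumbar SD.
    sigmaL <- .latentLumbarSDFrom(lumbarModel, lumbarBetweenSD, femaleFraction,
                                  ageMean, ageSD, ageRange)
    a <- setNames(levelCoupling$slope, levelCoupling$level)[ct]
    r2 <- targetR2[ct]
    levelNoiseSD <- a * sigmaL * sqrt(1 / r2 - 1)
  } else if (length(levelNoiseSD) == 1 && is.null(names(levelNoiseSD))) {
    levelNoiseSD <- setNames(rep(levelNoiseSD, length(ct)), ct)
  }
  cfg <- new("SimulationConfig",
             nPatients = as.integer(nPatients),
             seed = as.integer(seed),
             ageMean = ageMean, ageSD = ageSD, ageRange = ageRange,
             femaleFraction = femaleFraction,
             lumbarModel = lumbarModel,
             lumbarBetweenSD = lumbarBetweenSD,
             lumbarLevelNoiseSD = lumbarLevelNoiseSD,
             levelCoupling = levelCoupling,
             levelNoiseSD = levelNoiseSD[ct],
             fractureModel = if (is.null(fractureModel)) list() else fractureModel,
             degenerationModel = if (is.null(degenerationModel)) list() else degenerationModel,
             contrastModel = if (is.null(contrastModel)) list() else contrastModel,
             scannerPool = scannerPool,
             cervicalCoverage = cervicalCoverage,
             generateHU = generateHU)
  validObject(cfg)
  cfg
}

# Marginal SD of the latent lumbar vBMD across patients: age-driven variance
# (truncated-normal moments), between-sex mean spread, and the between-patient
# residual. Ignores the (rare) clamp of the latent at 0.
.latentLumbarSDFrom <- function(lumbarModel, betweenSD, femaleFraction,
                                ageMean, ageSD, ageRange) {
  tm <- truncnormMoments(ageMean, ageSD, ageRange[1], ageRange[2])
  w <- c(F = femaleFraction, M = 1 - femaleFraction)
  lm <- lumbarModel[match(c("F", "M"), lumbarModel$sex), ]
  meanBySex <- lm$intercept18 - lm$declinePerYear * (tm$mean - 18)
  varAge <- sum(w * lm$declinePerYear^2) * tm$var
  varSex <- sum(w * meanBySex^2) - sum(w * meanBySex)^2
  sqrt(varAge + varSex + betweenSD^2)
}

#' Marginal SD of the latent lumbar vBMD implied by a configuration
#'
#' @param config a [SimulationConfig-class].
#' @return SD in mg/ml.
#' @export
latentLumbarSD <- function(config) {
  stopifnot(is(config, "SimulationConfig"))
  .latentLumbarSDFrom(config@lumbarModel, config@lumbarBetweenSD,
                      config@femaleFraction, config@ageMean, config@ageSD,
                      config@ageRange)
}

#' Model-implied Pearson correlation of a level with the latent lumbar vBMD
#'
#' Closed form under the generative model:
#' `r = a * sigma_L / sqrt(a^2 * sigma_L^2 + sigma_level^2)`, where `a` is the
#' level's coupling slope, `sigma_L` the marginal latent lumbar SD and
#' `sigma_level` the level's residual SD.
#'
#' @param config a [SimulationConfig-class].
#' @param level a cervicothoracic level name (C2--T12).
#' @return the implied Pearson r.
#' @export
expectedLevelCorrelation <- function(config, level) {
  stopifnot(is(config, "SimulationConfig"))
  level <- parseLevel(level)
  if (regionOf(level) == "lumbar") {
    configError("expectedLevelCorrelation is defined for C2-T12 only; the lumbar reference correlates with itself by definition")
  }
  a <- config@levelCoupling$slope[match(level, config@levelCoupling$level)]
  sL <- latentLumbarSD(config)
  sl <- config@levelNoiseSD[[level]]
  a * sL / sqrt(a^2 * sL^2 + sl^2)
}

#' Simulate a synthetic cohort
#'
#' Draws a full cohort under the configured generative model. Every scan
#' carries T1--T12 and L1--L3; a `cervicalCoverage` fraction also carries
#' C2--C7. Each measured vertebra carries a bias-free value (`vbmdTrue`
#' assay) and the measured value (`vbmd` assay) with degeneration, fracture
#' and contrast biases applied and truncated below at 0 mg/ml. Fixing the
#' config seed fixes the cohort bit-for-bit.
#'
#' @param config a [SimulationConfig-class].
#' @return A [SpineCohort-class] with provenance recording the seed and a
#'   hash of the configuration.
#' @export
simulateCohort <- function(config) {
  stopifnot(is(config, "SimulationConfig"))
  validObject(config)
  n <- config@nPatients
  lv <- c(cervicothoracicLevels(), lumbarReferenceLevels())
  withSeed(config@seed, {
    sex <- ifelse(runif(n) < config@femaleFraction, "F", "M")
    age <- rtruncnorm(n, config@ageMean, config@ageSD,
                      config@ageRange[1], config@ageRange[2])
    lm <- config@lumbarModel
    i <- match(sex, lm$sex)
    latent <- lm$intercept18[i] - lm$declinePerYear[i] * (age - 18) +
      rnorm(n, 0, config@lumbarBetweenSD)
    latent <- pmax(latent, 0)

    sp <- config@scannerPool
    scanner <- sample(sp$scanner_id, n, replace = TRUE,
                      prob = sp$weight / sum(sp$weight))
    phase <- rep("none", n)
    cm <- config@contrastModel
    if (length(cm) > 0 && cm$fraction > 0) {
      enh <- runif(n) < cm$fraction
      if (any(enh)) {
        phase[enh] <- sample(cm$phases$phase, sum(enh), replace = TRUE,
                             prob = cm$phases$prob)
      }
    }
    hasCerv <- runif(n) < config@cervicalCoverage

    # true values: per-level linear response to the latent lumbar density
    a <- setNames(config@levelCoupling$slope, config@levelCoupling$level)
    b <- setNames(config@levelCoupling$intercept, config@levelCoupling$level)
    true <- matrix(NA_real_, nrow = length(lv), ncol = n,
                   dimnames = list(lv, NULL))
    for (l in cervicothoracicLevels()) {
      true[l, ] <- a[[l]] * latent + b[[l]] +
        rnorm(n, 0, config@levelNoiseSD[[l]])
    }
    for (l in lumbarReferenceLevels()) {
      true[l, ] <- latent + rnorm(n, 0, config@lumbarLevelNoiseSD)
    }
    true <- pmax(true, 0)
    cervRows <- which(regionOf(lv) == "cervical")
    true[cervRows, !hasCerv] <- NA_real_
    present <- !is.na(true)

    # degeneration grades: P(grade >= 2) logistic in age, per vertebra
    dg <- matrix(NA_integer_, nrow = length(lv), ncol = n,
                 dimnames = list(lv, NULL))
    dm <- config@degenerationModel
    nm <- sum(present)
    dg[present] <- 0L
    if (length(dm) > 0) {
      pAge <- plogis(dm$intercept + dm$slopePerYear * age)
      p2 <- matrix(rep(pAge, each = length(lv)), nrow = length(lv))
      u1 <- matrix(runif(length(lv) * n), nrow = length(lv))
      u2 <- matrix(runif(length(lv) * n), nrow = length(lv))
      g <- ifelse(u1 < p2,
                  ifelse(u2 < dm$severeFraction, 3L, 2L),
                  ifelse(u2 < dm$mildFraction, 1L, 0L))
      dg[present] <- g[present]
    }

    # fractures: patient-level risk logistic in latent lumbar vBMD, then
    # regional placement over the levels present on the scan
    fg <- matrix(NA_integer_, nrow = length(lv), ncol = n,
                 dimnames = list(lv, NULL))
    fg[present] <- 0L
    fm <- config@fractureModel
    if (length(fm) > 0) {
      pFrac <- plogis(fm$intercept + fm$slopePerMgMl * latent)
      fractured <- which(runif(n) < pFrac)
      regions <- regionOf(lv)
      grades <- as.integer(names(fm$gradeProbs))
      for (j in fractured) {
        k <- 1L + rpois(1, fm$meanExtra)
        avail <- split(which(present[, j]), regions[present[, j]])
        rp <- fm$regionProbs[names(fm$regionProbs) %in% names(avail)]
        rp <- rp / sum(rp)
        drawn <- sample(names(rp), k, replace = TRUE, prob = rp)
        for (r in unique(drawn)) {
          rows <- avail[[r]]
          m <- min(sum(drawn == r), length(rows))
          pick <- if (length(rows) == 1) rows else sample(rows, m)
          fg[pick, j] <- sample(grades, m, replace = TRUE,
                                prob = fm$gradeProbs)
        }
      }
    }

    # measured = true + degeneration bias + fracture bias + contrast bias
    measured <- true
    if (length(dm) > 0) {
      cells <- which(present & dg >= 2L)
      measured[cells] <- measured[cells] +
        pmax(rnorm(length(cells), dm$biasMean, dm$biasSD), 0)
    }
    if (length(fm) > 0) {
      cells <- which(present & fg >= 1L)
      measured[cells] <- measured[cells] +
        pmax(rnorm(length(cells), fm$biasMean, fm$biasSD), 0)
    }
    if (length(cm) > 0) {
      for (ph in cm$phases$phase) {
        cols <- which(phase == ph)
        if (length(cols) == 0) next
        pr <- cm$phases[cm$phases$phase == ph, ]
        cells <- which(present[, cols, drop = FALSE])
        sub <- measured[, cols, drop = FALSE]
        sub[cells] <- sub[cells] +
          pmax(rnorm(length(cells), pr$biasMean, pr$biasSD), 0)
        measured[, cols] <- sub
      }
    }
    measured <- pmax(measured, 0)

    ids <- sprintf("P%04d", seq_len(n))
    colnames(true) <- colnames(measured) <- colnames(fg) <- colnames(dg) <- ids
    hu <- NULL
    if (config@generateHU) {
      si <- match(scanner, sp$scanner_id)
      hu <- sweep(sweep(measured, 2, sp$intercept[si], "-"),
                  2, sp$slope[si], "/")
    }

    SpineCohort(
      vbmd = measured, hu = hu, vbmdTrue = true,
      fractureGrade = fg, degenerationGrade = dg,
      colData = data.frame(
        patient_id = ids, age = age, sex = sex, scanner_id = scanner,
        contrast_phase = phase, stringsAsFactors = FALSE
      ),
      provenance = list(
        source = "simulated", seed = config@seed,
        configHash = rlang::hash(lapply(slotNames(config),
                                        function(s) slot(config, s))),
        generator = "SpineCalib simulateCohort v1"
      )
    )
  })
}

setMethod("show", "SimulationConfig", function(object) {
  cat(sprintf("SimulationConfig: %d patients, seed %d\n",
              object@nPatients, object@seed))
  cat(sprintf("  age %.1f +/- %.1f y in [%g, %g], female fraction %.3f\n",
              object@ageMean, object@ageSD, object@ageRange[1],
              object@ageRange[2], object@femaleFraction))
  cat(sprintf("  latent lumbar SD %.1f mg/ml; level noise %.1f-%.1f mg/ml\n",
              latentLumbarSD(object), min(object@levelNoiseSD),
              max(object@levelNoiseSD)))
  cat(sprintf("  components: fracture=%s degeneration=%s contrast=%s huAssay=%s\n",
              length(object@fractureModel) > 0,
              length(object@degenerationModel) > 0,
              length(object@contrastModel) > 0, object@generateHU))
})
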