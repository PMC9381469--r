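test_that("simulateCohort honours the count and coverage contracts", {
  co <- simulateCohort(simulationConfig(nPatients = 260, seed = 7))
  expect_equal(ncol(co), 260L)
  expect_lte(nrow(co), 21L)
  perScan <- colSums(measuredMask(co))
  expect_true(all(perScan %in% c(15L, 21L)))  # with/without cervical coverage
  prov <- S4Vectors::metadata(co)$provenance
  expect_equal(prov$source, "simulated")
  expect_equal(prov$seed, 7L)
  expect_true(nzchar(prov$configHash))
})

test_that("the same seed reproduces the cohort bit-for-bit and leaves the RNG alone", {
  cfg <- simulationConfig(nPatients = 40, seed = 123)
  set.seed(999)
  before <- .Random.seed
  a <- simulateCohort(cfg)
  expect_identical(.Random.seed, before)
  b <- simulateCohort(cfg)
  expect_identical(SummarizedExperiment::assays(a), SummarizedExperiment::assays(b))
  expect_identical(SummarizedExperiment::colData(a), SummarizedExperiment::colData(b))
  c2 <- simulateCohort(simulationConfig(nPatients = 40, seed = 124))
  expect_false(identical(vbmd(a), vbmd(c2)))
})

test_that("invalid configurations are rejected before any sampling", {
  expect_error(simulationConfig(nPatients = 0), "positive")
  fm <- defaultFractureModel()
  fm$regionProbs <- c(cervical = 0.5, thoracic = 0.5, lumbar = 0.5)
  expect_error(simulationConfig(fractureModel = fm), "sum to 1")
  cm <- defaultContrastModel()
  cm$fraction <- 1.5
  expect_error(simulationConfig(contrastModel = cm), "\\[0, 1\\]")
})

test_that("noiseless generation is exactly linear: r = 1 and couplings recovered", {
  cfg <- simulationConfig(nPatients = 150, seed = 5,
                          levelNoiseSD = 0, lumbarLevelNoiseSD = 0,
                          fractureModel = NULL, degenerationModel = NULL,
                          contrastModel = NULL)
  co <- prepCohort(simulateCohort(cfg))
  pr <- pearsonByLevel(co)
  expect_true(all(abs(pr$r - 1) < 1e-9))
  for (l in c("C2", "C6", "T12")) {
    cal <- fitLevelCalibration(co, l)
    i <- match(l, cfg@levelCoupling$level)
    expect_equal(cal@slope, cfg@levelCoupling$slope[i], tolerance = 1e-6)
    expect_equal(cal@intercept, cfg@levelCoupling$intercept[i],
                 tolerance = 1e-6)
  }
})

test_that("expectedLevelCorrelation matches its closed form and rejects lumbar levels", {
  # sigma_level = 0 gives r = 1
  cfg0 <- simulationConfig(nPatients = 10, seed = 1, levelNoiseSD = 0)
  expect_equal(expectedLevelCorrelation(cfg0, "C5"), 1.0)
  # a = 1, sigma_level = sigma_L gives 1/sqrt(2): flatten the age/sex
  # structure so the latent SD is exactly the between-patient SD
  flat <- data.frame(sex = c("F", "M"), intercept18 = c(150, 150),
                     declinePerYear = c(0, 0))
  lc <- referenceCalibrations()[, c("level", "slope", "intercept")]
  lc$slope <- 1
  cfg1 <- simulationConfig(nPatients = 10, seed = 1, lumbarModel = flat,
                           lumbarBetweenSD = 35, levelCoupling = lc,
                           levelNoiseSD = 35)
  expect_equal(latentLumbarSD(cfg1), 35)
  expect_equal(expectedLevelCorrelation(cfg1, "T4"), 1 / sqrt(2),
               tolerance = 1e-12)
  expect_error(expectedLevelCorrelation(cfg0, "L1"), "lumbar")
})

test_that("defaults imply the published correlation profile shape (r_T12 > r_C2)", {
  cfg <- simulationConfig(nPatients = 10, seed = 1)
  rC2 <- expectedLevelCorrelation(cfg, "C2")
  rT12 <- expectedLevelCorrelation(cfg, "T12")
  expect_gt(rT12, rC2)
  expect_equal(rC2, sqrt(0.5772), tolerance = 1e-3)
  expect_equal(rT12, sqrt(0.9268), tolerance = 1e-3)
  # Monte-Carlo confirmation on the latent scale at large n
  co <- prepCohort(simulateCohort(simulationConfig(nPatients = 20000, seed = 42)))
  pr <- pearsonByLevel(co)
  expect_gt(pr$r[pr$level == "T12"], pr$r[pr$level == "C2"])
})

test_that("empirical per-level correlation matches the closed form within 0.03", {
  cfg <- simulationConfig(nPatients = 2000, seed = 17)
  co <- prepCohort(simulateCohort(cfg))
  pr <- pearsonByLevel(co)
  expected <- vapply(pr$level, function(l) expectedLevelCorrelation(cfg, l),
                     numeric(1))
  expect_true(all(abs(pr$r - expected) <= 0.03))
})

test_that("fracture placement follows the regional distribution", {
  # pool fractured vertebrae across seeds until >= 10,000
  regions <- character(0)
  for (s in 1:3) {
    co <- simulateCohort(simulationConfig(nPatients = 6000, seed = 100 + s))
    fg <- fractureGrade(co)
    regions <- c(regions, regionOf(rownames(co))[row(fg)[which(fg >= 1L)]])
    if (length(regions) >= 10000) break
  }
  expect_gte(length(regions), 10000L)
  p <- c(cervical = 0.01, thoracic = 0.65, lumbar = 0.34)
  obs <- table(factor(regions, names(p))) / length(regions)
  bound <- qnorm(0.995) * sqrt(p * (1 - p) / length(regions))
  # cervical placement renormalises away on scans without cervical coverage,
  # so allow that bound plus the coverage-induced shift
  shift <- c(cervical = 0.01 * 0.2, thoracic = 0.01, lumbar = 0.01)
  expect_true(all(abs(as.numeric(obs) - p) <= bound + shift))
  # grades are drawn from {1,2,3}
  fg <- fractureGrade(co)
  expect_setequal(unique(fg[fg >= 1 & !is.na(fg)]), 1:3)
})

test_that("degenerated vertebrae carry the configured positive measurement bias", {
  cfg <- simulationConfig(nPatients = 2000, seed = 31,
                          fractureModel = NULL, contrastModel = NULL)
  co <- simulateCohort(cfg)
  err <- vbmd(co) - SummarizedExperiment::assay(co, "vbmdTrue")
  dg <- degenerationGrade(co)
  biasDeg <- mean(err[dg >= 2 & !is.na(dg)])
  biasNone <- mean(err[dg < 2 & !is.na(dg)])
  # truncated-at-0 normal with mean 40, sd 15 has mean ~= 40.11
  expect_equal(biasDeg - biasNone, 40.1, tolerance = 0.05 * 40.1)
  expect_lt(abs(biasNone), 0.5)
})
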