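test_that("pearsonByLevel matches hand values and the brute-force oracle", {
  # exact anticorrelation
  lumbar <- c(40, 30, 20, 10)
  ids <- sprintf("P%d", 1:4)
  df <- rbind(
    toyTable(rep(ids, each = 3), rep(c("L1", "L2", "L3"), 4),
             rep(lumbar, each = 3)),
    toyTable(ids, "T5", c(10, 20, 30, 40))
  )
  co <- prepCohort(cohortFromTable(df))
  pr <- pearsonByLevel(co)
  expect_equal(pr$r[pr$level == "T5"], -1, tolerance = 1e-12)
  expect_equal(pr$n[pr$level == "T5"], 4L)
  # 5-point set with an outlier vs direct summation formula
  lum2 <- c(60, 90, 120, 150, 180)
  y2 <- c(130, 150, 170, 320, 210)
  df2 <- rbind(
    toyTable(rep(sprintf("Q%d", 1:5), each = 3), rep(c("L1", "L2", "L3"), 5),
             rep(lum2, each = 3)),
    toyTable(sprintf("Q%d", 1:5), "C4", y2)
  )
  co2 <- prepCohort(cohortFromTable(df2))
  pr2 <- pearsonByLevel(co2)
  expect_equal(pr2$r[pr2$level == "C4"], pearsonBrute(lum2, y2),
               tolerance = 1e-12)
})

test_that("levels with n < 3 get NA r and a warning", {
  df <- rbind(
    toyTable(rep(c("P1", "P2", "P3"), each = 3),
             rep(c("L1", "L2", "L3"), 3), rep(c(80, 100, 120), each = 3)),
    toyTable(c("P1", "P2", "P3"), "T8", c(90, 100, 110)),
    toyTable(c("P1", "P2"), "C3", c(200, 210))
  )
  co <- prepCohort(cohortFromTable(df))
  expect_warning(pr <- pearsonByLevel(co), "C3")
  expect_true(is.na(pr$r[pr$level == "C3"]))
  expect_false(is.na(pr$r[pr$level == "T8"]))
})

test_that("respect_exclusions drops only the level side; the reference keeps its rule", {
  lumbar <- c(60, 90, 120, 150, 180, 210)
  ids <- sprintf("P%d", 1:6)
  df <- rbind(
    toyTable(rep(ids, each = 3), rep(c("L1", "L2", "L3"), 6),
             rep(lumbar, each = 3)),
    toyTable(ids, "T7", 0.8 * lumbar + 30 + c(0, 120, 0, -40, 0, 90),
             degeneration = c(0L, 3L, 0L, 2L, 0L, 3L))
  )
  co <- prepCohort(cohortFromTable(df))
  rAfter <- pearsonByLevel(co, respectExclusions = TRUE)
  rBefore <- pearsonByLevel(co, respectExclusions = FALSE)
  expect_equal(rAfter$n[rAfter$level == "T7"], 3L)
  expect_equal(rBefore$n[rBefore$level == "T7"], 6L)
  expect_equal(rAfter$r[rAfter$level == "T7"], 1, tolerance = 1e-12)
  expect_lt(rBefore$r[rBefore$level == "T7"], 1)
})

test_that("fitLevelCalibration reproduces an exact line and the OLS oracle", {
  # exact line with the C6 published coefficients
  lumbar <- c(40, 70, 100, 130, 160, 190)
  co <- prepCohort(lineCohort(lumbar, "C6", a = 1.138, b = 80.98))
  cal <- fitLevelCalibration(co, "C6")
  expect_equal(cal@slope, 1.138, tolerance = 1e-9)
  expect_equal(cal@intercept, 80.98, tolerance = 1e-9)
  expect_equal(cal@r2, 1, tolerance = 1e-12)
  expect_equal(cal@residualSD, 0, tolerance = 1e-9)
  # random <= 10-point inputs vs the normal-equation oracle
  set.seed(88)
  for (k in 1:8) {
    n <- sample(3:10, 1)
    x <- runif(n, 40, 220)
    y <- 0.9 * x + 20 + rnorm(n, 0, 25)
    ids <- sprintf("R%d", seq_len(n))
    df <- rbind(
      toyTable(rep(ids, each = 3), rep(c("L1", "L2", "L3"), n),
               rep(x, each = 3)),
      toyTable(ids, "T3", pmax(y, 0))
    )
    co <- prepCohort(cohortFromTable(df))
    cal <- fitLevelCalibration(co, "T3")
    oracle <- olsBrute(x, pmax(y, 0))
    expect_equal(cal@slope, unname(oracle["slope"]), tolerance = 1e-9)
    expect_equal(cal@intercept, unname(oracle["intercept"]), tolerance = 1e-9)
    expect_equal(cal@r, pearsonBrute(x, pmax(y, 0)), tolerance = 1e-9)
  }
})

test_that("fitLevelCalibration r agrees with pearsonByLevel to 1e-12", {
  co <- prepCohort(simulateCohort(simulationConfig(nPatients = 120, seed = 2)))
  pr <- pearsonByLevel(co)
  for (l in c("C2", "C6", "T6", "T12")) {
    cal <- fitLevelCalibration(co, l)
    expect_equal(cal@r, pr$r[pr$level == l], tolerance = 1e-12)
    expect_equal(cal@n, pr$n[pr$level == l])
  }
})

test_that("degenerate fits are rejected", {
  df <- rbind(
    toyTable(rep(c("P1", "P2"), each = 3), rep(c("L1", "L2", "L3"), 2),
             rep(c(100, 120), each = 3)),
    toyTable(c("P1", "P2"), "T1", c(90, 100))
  )
  co <- prepCohort(cohortFromTable(df))
  expect_error(fitLevelCalibration(co, "T1"), ">= 3")
  # zero variance in the reference
  df2 <- rbind(
    toyTable(rep(c("P1", "P2", "P3"), each = 3),
             rep(c("L1", "L2", "L3"), 3), 100),
    toyTable(c("P1", "P2", "P3"), "T1", c(90, 100, 95))
  )
  co2 <- prepCohort(cohortFromTable(df2))
  expect_error(fitLevelCalibration(co2, "T1"), "variance")
})

test_that("compareCorrelationProfiles handles identical, shifted and mismatched profiles", {
  base <- data.frame(level = cervicothoracicLevels(),
                     r = seq(0.76, 0.96, length.out = 18), n = 100L)
  same <- compareCorrelationProfiles(base, base)
  expect_equal(same$p.value, 1)
  expect_equal(same$median_before, same$median_after)
  # uniform z-shift +0.2 with tiny jitter; verified against a permutation oracle
  set.seed(55)
  shifted <- base
  shifted$r <- tanh(atanh(base$r) + 0.2 + rnorm(18, 0, 0.005))
  res <- compareCorrelationProfiles(base, shifted)
  expect_lt(res$p.value, 1e-3)
  expect_gt(res$median_after, res$median_before)
  pperm <- permutePairedP(atanh(shifted$r) - atanh(base$r))
  expect_lt(pperm, 1e-3)
  bad <- base[base$level != "C2", ]
  expect_error(compareCorrelationProfiles(bad, base), "C2")
})

test_that("exclusions raise the correlation profile on bias-afflicted cohorts", {
  co <- prepCohort(simulateCohort(simulationConfig(nPatients = 800, seed = 77)))
  before <- pearsonByLevel(co, respectExclusions = FALSE)
  after <- pearsonByLevel(co, respectExclusions = TRUE)
  cmp <- compareCorrelationProfiles(before, after)
  expect_gt(cmp$median_after, cmp$median_before)
  expect_lt(cmp$p.value, 0.05)
})

test_that("derive_thresholds evaluates the calibration line at the cut-offs", {
  th <- deriveThresholds(data.frame(level = "C4", slope = 1.350,
                                    intercept = 101.2))
  tb <- displayThresholds(th)
  expect_equal(tb$threshold_osteoporosis[tb$level == "C4"], 209.2)
  # identity calibration maps the lumbar cut-off to itself
  thI <- deriveThresholds(data.frame(level = "T12", slope = 1, intercept = 0))
  tbI <- thresholdTable(thI)
  expect_equal(tbI$threshold_osteoporosis[tbI$level == "T12"], 80)
  # published T12 osteopenia value
  thT <- deriveThresholds(data.frame(level = "T12", slope = 0.9303,
                                     intercept = 9.346))
  expect_equal(displayThresholds(thT)$threshold_osteopenia[1], 121.0)
})

test_that("thresholds are monotone in the cut-off and ordered within level", {
  ref <- referenceCalibrations()
  for (cuts in list(c(osteoporosis = 60, osteopenia = 100),
                    c(osteoporosis = 80, osteopenia = 120),
                    c(osteoporosis = 100, osteopenia = 140))) {
    tb <- thresholdTable(deriveThresholds(ref, lumbarCutoffs = cuts))
    expect_true(all(tb$threshold_osteopenia > tb$threshold_osteoporosis))
  }
  t80 <- thresholdTable(deriveThresholds(ref))$threshold_osteoporosis
  t90 <- thresholdTable(deriveThresholds(
    ref, lumbarCutoffs = c(osteoporosis = 90, osteopenia = 120)
  ))$threshold_osteoporosis
  expect_true(all(t90 > t80))
})

test_that("non-positive slopes and weak fits are flagged, not silently emitted", {
  cal <- data.frame(level = c("C2", "C3"), slope = c(-0.2, 1.1),
                    intercept = c(150, 90), r2 = c(0.9, 0.1))
  expect_warning(th <- deriveThresholds(cal), "C2, C3")
  tb <- thresholdTable(th)
  expect_false(tb$reliable[tb$level == "C2"])
  expect_false(tb$reliable[tb$level == "C3"])
  expect_true(all(tb$reliable[tb$region == "lumbar"]))
})

test_that("bundled reference thresholds satisfy the regional summary", {
  tb <- thresholdTable(referenceThresholds(), includeLumbar = FALSE)
  expect_true(all(tb$threshold_osteoporosis[tb$region == "cervical"] >= 150))
  expect_true(all(tb$threshold_osteoporosis[tb$region == "thoracic"] <= 125))
  expect_equal(nrow(tb), 18L)
})
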