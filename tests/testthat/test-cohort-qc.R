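test_that("exclusion rules flag exactly the graded vertebrae", {
  # 3 patients x 5 vertebrae; one grade-2 fracture, one grade-3 degeneration,
  # one grade-1 degeneration (retained)
  lv <- c("T10", "T11", "T12", "L1", "L2")
  df <- rbind(
    toyTable("P1", lv, 100 + 1:5, fracture = c(0, 2, 0, 0, 0)),
    toyTable("P2", lv, 100 + 1:5, degeneration = c(0, 0, 3, 0, 0)),
    toyTable("P3", lv, 100 + 1:5, degeneration = c(1, 0, 0, 0, 0))
  )
  co <- applyExclusions(cohortFromTable(df))
  rep <- qcReport(co)
  expect_equal(rep@nVertebrae, 15L)
  expect_equal(rep@nExcludedFracture, 1L)
  expect_equal(rep@nExcludedDegeneration, 1L)   # grade-1 degeneration retained
  expect_equal(rep@nPatientsDropped, 0L)
  pl <- rep@perLevel
  expect_equal(pl$excluded_fracture[pl$level == "T11"], 1L)
  expect_equal(pl$excluded_degeneration[pl$level == "T12"], 1L)
  expect_equal(sum(pl$n), rep@nVertebrae)
})

test_that("all-grade-0 cohorts pass QC untouched; dual-rule vertebrae count in both tallies", {
  co0 <- applyExclusions(toyCohort(rep("P1", 3), c("L1", "L2", "L3"),
                                   c(100, 110, 120)))
  expect_equal(qcReport(co0)@nExcludedFracture, 0L)
  expect_equal(qcReport(co0)@nExcludedDegeneration, 0L)
  # fracture grade 3 AND degeneration grade 3: both tallies, excluded once
  co2 <- applyExclusions(toyCohort("P1", "T12", 100,
                                   fracture = 3L, degeneration = 3L))
  expect_equal(qcReport(co2)@nExcludedFracture, 1L)
  expect_equal(qcReport(co2)@nExcludedDegeneration, 1L)
  expect_equal(sum(!SpineCalib:::usableMask(co2)), 1L)
})

test_that("a missing grade is an error naming patient and level, never assumed 0", {
  df <- toyTable(c("P1", "P1"), c("L1", "L2"), c(100, 110))
  df$degeneration_grade[2] <- NA_integer_
  expect_error(applyExclusions(cohortFromTable(df)), "\\(P1, L2\\)")
})

test_that("exclusion flagging is idempotent and non-destructive", {
  co <- simulateCohort(simulationConfig(nPatients = 60, seed = 3))
  once <- applyExclusions(co)
  twice <- applyExclusions(once)
  expect_identical(SummarizedExperiment::assays(once),
                   SummarizedExperiment::assays(twice))
  expect_equal(dim(once), dim(co))            # records flagged, never deleted
})

test_that("the lumbar reference averages surviving L1-L3 and is order-invariant", {
  co <- prepCohort(toyCohort(rep("P1", 3), c("L1", "L2", "L3"),
                             c(100, 110, 120)))
  expect_equal(unname(lumbarReference(co)["P1"]), 110)
  # L1 fractured (grade 2): mean of the survivors
  co2 <- prepCohort(toyCohort(rep("P1", 3), c("L1", "L2", "L3"),
                              c(150, 90, 70), fracture = c(2L, 0L, 0L)))
  expect_equal(unname(lumbarReference(co2)["P1"]), 80)
  # order of rows must not matter
  co3 <- prepCohort(toyCohort(rep("P1", 3), c("L3", "L1", "L2"),
                              c(70, 150, 90), fracture = c(0L, 2L, 0L)))
  expect_equal(lumbarReference(co3), lumbarReference(co2))
})

test_that("patients with no surviving lumbar level get an absent reference", {
  df <- rbind(
    toyTable("P1", c("L1", "L2", "L3"), c(100, 110, 120), fracture = 2L),
    toyTable("P2", c("L1", "L2", "L3"), c(100, 110, 120))
  )
  co <- prepCohort(cohortFromTable(df))
  expect_true(is.na(lumbarReference(co)["P1"]))
  expect_equal(unname(lumbarReference(co)["P2"]), 110)
  expect_equal(qcReport(co)@nPatientsDropped, 1L)
})

test_that("the degeneration rule on the reference is switchable", {
  df <- toyTable(rep("P1", 3), c("L1", "L2", "L3"), c(200, 100, 100),
                 degeneration = c(3L, 0L, 0L))
  strict <- prepCohort(cohortFromTable(df), useDegenerationRule = TRUE)
  literal <- prepCohort(cohortFromTable(df), useDegenerationRule = FALSE)
  expect_equal(unname(lumbarReference(strict)["P1"]), 100)
  expect_equal(unname(lumbarReference(literal)["P1"]), 400 / 3)
})

test_that("groupCompare: identical groups give p ~ 1, separated groups p < 1e-4", {
  # identical groups
  df <- rbind(
    toyTable(sprintf("A%d", 1:4), "L1", c(100, 110, 120, 130),
             sex = "F", age = c(40, 50, 60, 70)),
    toyTable(sprintf("B%d", 1:4), "L1", c(100, 110, 120, 130),
             sex = "M", age = c(40, 50, 60, 70))
  )
  co <- prepCohort(cohortFromTable(df))
  gs <- groupCompare(co, "sex")
  expect_equal(gs$p.value, 1, tolerance = 1e-9)
  expect_equal(diff(gs$groups$mean), 0)
  # two groups ~ N(110,10) vs N(80,10), n = 50: d = 3, p < 1e-4 across seeds
  for (s in 1:5) {
    set.seed(4000 + s)
    dfp <- rbind(
      toyTable(sprintf("F%02d", 1:50), "L1", rnorm(50, 110, 10),
               sex = "F", age = round(runif(50, 40, 80))),
      toyTable(sprintf("M%02d", 1:50), "L1", rnorm(50, 80, 10),
               sex = "M", age = round(runif(50, 40, 80)))
    )
    gp <- groupCompare(prepCohort(cohortFromTable(dfp)), "sex")
    expect_lt(gp$p.value, 1e-4)
  }
})

test_that("fractured patients have lower lumbar references on simulated cohorts", {
  co <- prepCohort(simulateCohort(simulationConfig(nPatients = 800, seed = 21)))
  gf <- groupCompare(co, "fracture")
  expect_equal(gf$groups$group, c("fractured", "non-fractured"))
  expect_lt(gf$groups$mean[1], gf$groups$mean[2])
  expect_lt(gf$p.value, 1e-4)
})

test_that("age matching is greedy, within-caliper and deterministic", {
  df <- rbind(
    toyTable(c("W1", "W2"), "L1", c(100, 120), sex = "F", age = c(50, 80)),
    toyTable(c("M1", "M2", "M3"), "L1", c(90, 95, 99), sex = "M",
             age = c(52, 49, 95))
  )
  co <- prepCohort(cohortFromTable(df))
  # W1(50) matches M2(49, |d|=1); W2(80) has no man within 5y -> 1 pair only
  expect_error(groupCompare(co, "sex"), "fewer than 2")
  pairs <- SpineCalib:::greedyAgeMatch(c(50, 80), c(52, 49, 95),
                                       c("W1", "W2"), c("M1", "M2", "M3"), 5)
  expect_equal(nrow(pairs), 1L)
  expect_equal(pairs$j, 2L)
})

test_that("QC removes measurement bias: retained vertebrae sit closer to truth", {
  co <- prepCohort(simulateCohort(simulationConfig(nPatients = 500, seed = 13)))
  err <- abs(vbmd(co) - SummarizedExperiment::assay(co, "vbmdTrue"))
  ok <- SpineCalib:::usableMask(co)
  meas <- measuredMask(co)
  expect_lt(mean(err[ok]), mean(err[meas]))
})
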