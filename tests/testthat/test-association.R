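test_that("an exact linear relation gives beta = 2 with vanishing residual se", {
  d <- c(0, 1, 2, 0, 1, 2, 0, 1)
  r <- linearAssoc(2 * d, d)
  expect_equal(r$beta, 2, tolerance = 1e-10)
  expect_lt(r$se, 1e-10)
  expect_gt(r$p, 0)          # floored, never exactly zero
  expect_lt(r$p, 1e-12)
})

test_that("linear association matches the normal-equations oracle on the toy fixture", {
  df <- toyRegressionData()
  r <- linearAssoc(df$y, df$dosage, df[, c("x1", "x2")])
  X <- cbind(1, df$dosage, df$x1, df$x2)
  o <- olsOracle(df$y, X)
  expect_equal(r$beta, o$beta[2], tolerance = 1e-10)
  expect_equal(r$se, o$se[2], tolerance = 1e-10)
  expect_equal(r$stat, o$stat[2], tolerance = 1e-10)
  expect_equal(r$p, o$p[2], tolerance = 1e-10)

  # no covariates
  r0 <- linearAssoc(df$y, df$dosage)
  o0 <- olsOracle(df$y, cbind(1, df$dosage))
  expect_equal(r0$beta, o0$beta[2], tolerance = 1e-10)
  expect_equal(r0$se, o0$se[2], tolerance = 1e-10)
})

test_that("adding a constant to the trait shifts only the intercept", {
  df <- toyRegressionData()
  r1 <- linearAssoc(df$y, df$dosage, df[, c("x1", "x2")])
  r2 <- linearAssoc(df$y + 100, df$dosage, df[, c("x1", "x2")])
  expect_equal(r1$beta, r2$beta, tolerance = 1e-10)
  expect_equal(r1$se, r2$se, tolerance = 1e-10)
})

test_that("degenerate linear designs are skipped or rejected with names", {
  df <- toyRegressionData()
  r <- linearAssoc(df$y, rep(1, 12), df[, c("x1", "x2")])
  expect_identical(r$status, "skipped_low_frequency")
  expect_true(is.na(r$beta))
  expect_error(
    linearAssoc(df$y, df$dosage, cbind(x1 = df$x1, x1b = df$x1)),
    "x1b")
  expect_error(linearAssoc(df$y[1:3], df$dosage[1:3], df[1:3, c("x1", "x2")]),
               "too few")
  expect_error(linearAssoc(df$y, df$dosage[1:3]), "equal length")
})

test_that("linear type-I error is nominal under the null", {
  set.seed(201)
  reps <- 400
  hits <- 0
  for (i in seq_len(reps)) {
    d <- rbinom(300, 2, 0.2)
    pcs <- matrix(rnorm(300 * 10), 300)
    y <- rnorm(300)
    hits <- hits + (linearAssoc(y, d, pcs)$p < 0.05)
  }
  se <- sqrt(0.05 * 0.95 / reps)
  expect_lt(abs(hits / reps - 0.05), 3 * se)
})

test_that("logistic association reproduces the 2x2 cross-product odds ratio", {
  # 40/160 cases/controls among exposed, 20/180 among unexposed
  present <- c(rep(1, 40), rep(0, 160), rep(1, 20), rep(0, 180))
  exposure <- c(rep(1, 200), rep(0, 200))
  r <- logisticAssoc(present, exposure)
  expect_identical(r$status, "ok")
  expect_equal(r$or, crossProductOR(40, 160, 20, 180), tolerance = 1e-6)
  expect_equal(r$or, 2.25, tolerance = 1e-6)
  expect_equal(r$beta, log(2.25), tolerance = 1e-6)
})

test_that("rare outcomes are skipped under the minimum-case rule", {
  d <- rbinom(200, 2, 0.2)
  expect_identical(logisticAssoc(rep(0, 200), d)$status,
                   "skipped_low_frequency")
  few <- c(rep(1, 5), rep(0, 195))
  expect_identical(logisticAssoc(few, d)$status, "skipped_low_frequency")
  # enough cases overall but too few among carriers
  set.seed(7)
  y <- c(rep(1, 30), rep(0, 170))
  dos <- c(rep(0, 28), rep(1, 2), rbinom(170, 2, 0.3))
  expect_identical(logisticAssoc(y, dos, minCases = 10)$status,
                   "skipped_low_frequency")
})

test_that("perfect separation is flagged without an estimate", {
  present <- c(rep(1, 30), rep(0, 170))
  dosage <- c(rep(2, 30), rep(0, 170))
  r <- logisticAssoc(present, dosage)
  expect_identical(r$status, "failed_separation")
  expect_true(is.na(r$beta))
})

test_that("logistic type-I error is nominal under the null", {
  set.seed(202)
  reps <- 300
  hits <- 0
  for (i in seq_len(reps)) {
    d <- rbinom(500, 2, 0.3)
    y <- rbinom(500, 1, 0.3)
    r <- logisticAssoc(y, d)
    hits <- hits + (r$status == "ok" && r$p < 0.05)
  }
  se <- sqrt(0.05 * 0.95 / reps)
  expect_lt(abs(hits / reps - 0.05), 3 * se)
})

test_that("the topic scan covers every topic-wave pair on disjoint subjects", {
  cfg <- simulationConfig(nSubjectsPerWave = c(60, 60, 60, 60),
                          nTopicsTrue = 3, nCodes = 15)
  cohort <- simulateCohort(cfg, seed = 21)
  sim <- simulateCodeCounts(cohort, cfg, seed = 22)
  scan <- runTopicScan(sim$truth$theta, cohort)
  expect_identical(nrow(scan), 3L * 4L)
  expect_identical(sort(unique(scan$wave)), sort(unique(cohort$wave)))
  ns <- tapply(scan$n, scan$wave, unique)
  expect_equal(as.numeric(ns[sort(names(ns))]),
               as.numeric(table(cohort$wave)[sort(names(ns))]))
  # small waves are flagged, not dropped
  small <- simulateCohort(simulationConfig(nSubjectsPerWave = c(60, 20),
                                           nTopicsTrue = 3, nCodes = 15),
                          seed = 23)
  simS <- simulateCodeCounts(small,
                             simulationConfig(nSubjectsPerWave = c(60, 20),
                                              nTopicsTrue = 3,
                                              nCodes = 15), seed = 24)
  scanS <- runTopicScan(simS$truth$theta, small,
                        covariateCols = character(0))
  expect_true(all(scanS$small_wave[scanS$wave == "wave2"]))
  expect_identical(nrow(scanS), 6L)
})
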