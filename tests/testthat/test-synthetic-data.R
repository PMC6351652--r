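test_that("simulated genotypes follow binomial(2, maf) moments and HWE proportions", {
  expect_error(simulateGenotypes(4, maf = 0), "maf")
  expect_error(simulateGenotypes(4, maf = 0.7), "maf")

  d <- simulateGenotypes(10000, maf = 0.079, seed = 11)
  se <- sqrt(2 * 0.079 * (1 - 0.079) / 10000)
  expect_lt(abs(mean(d) - 2 * 0.079), 3 * se)

  d5 <- simulateGenotypes(10000, maf = 0.5, seed = 12)
  props <- tabulate(d5 + 1, 3) / 10000
  expected <- c(0.25, 0.5, 0.25)
  for (g in 1:3) {
    se <- sqrt(expected[g] * (1 - expected[g]) / 10000)
    expect_lt(abs(props[g] - expected[g]), 3 * se)
  }
})

test_that("simulated genotypes show no systematic HWE departure", {
  # p-values under repeated simulation should not pile up near zero
  ps <- vapply(1:60, function(s) {
    hweTest(genotypeCounts(simulateGenotypes(2000, 0.2, seed = 1000 + s)))
  }, numeric(1))
  expect_gt(min(ps), 1e-6)
  expect_gt(mean(ps > 0.05), 0.8)
})

test_that("generated theta is a probability simplex and counts conserve document lengths", {
  cfg <- simulationConfig(nSubjectsPerWave = c(50, 50), nTopicsTrue = 4,
                          nCodes = 20)
  sim <- simulateCodeCounts(simulateCohort(cfg, seed = 1), cfg, seed = 2)
  th <- sim$truth$theta
  expect_true(all(th >= 0))
  expect_lt(max(abs(rowSums(th) - 1)), 1e-12)
  expect_true(all(sim$truth$phi >= 0))
  expect_lt(max(abs(rowSums(sim$truth$phi) - 1)), 1e-12)
  expect_equal(unname(Matrix::rowSums(codeCounts(sim$counts))),
               as.numeric(sim$truth$docLengths))
})

test_that("the planted effect makes mean risk-topic weight increase with dosage", {
  cfg <- simulationConfig(nSubjectsPerWave = c(250, 250), maf = 0.3,
                          nTopicsTrue = 2, nCodes = 10, alpha0 = 0.1,
                          effectSize = 5, riskTopic = 1)
  cohort <- simulateCohort(cfg, seed = 3)
  sim <- simulateCodeCounts(cohort, cfg, seed = 4)
  means <- tapply(sim$truth$theta[, 1], cohort$dosage, mean)
  expect_true(all(diff(means[c("0", "1", "2")]) > 0))
})

test_that("effectSize = 0 leaves the risk topic exchangeable with the others", {
  cfg <- simulationConfig(nSubjectsPerWave = c(300, 300), effectSize = 0,
                          nTopicsTrue = 5, nCodes = 25)
  cohort <- simulateCohort(cfg, seed = 5)
  sim <- simulateCodeCounts(cohort, cfg, seed = 6)
  r <- linearAssoc(sim$truth$theta[, cfg$riskTopic], cohort$dosage)
  expect_gt(r$p, 0.001)
  # all topics share the same marginal mean 1/K under the null
  expect_equal(unname(colMeans(sim$truth$theta)), rep(0.2, 5),
               tolerance = 0.05)
})

test_that("fixed seeds give bit-identical simulation output", {
  cfg <- simulationConfig(nSubjectsPerWave = c(40, 40))
  c1 <- simulateCohort(cfg, seed = 7)
  c2 <- simulateCohort(cfg, seed = 7)
  expect_identical(c1, c2)
  s1 <- simulateCodeCounts(c1, cfg, seed = 8)
  s2 <- simulateCodeCounts(c2, cfg, seed = 8)
  expect_identical(codeCounts(s1$counts), codeCounts(s2$counts))
  expect_identical(s1$truth$theta, s2$truth$theta)
})

test_that("simulationConfig rejects degenerate parameters", {
  expect_error(simulationConfig(maf = 0.6), "maf")
  expect_error(simulationConfig(alpha0 = 0), "positive")
  expect_error(simulationConfig(effectSize = -1), "effectSize")
  expect_error(simulationConfig(riskTopic = 99), "riskTopic")
  expect_error(simulationConfig(nSubjectsPerWave = c(10, 1)), "at least 2")
  expect_error(simulateCodeCounts(data.frame(), simulationConfig()), "empty")
})

test_that("writeCohort emits all formats and round-trips through the readers", {
  cfg <- simulationConfig(nSubjectsPerWave = c(20, 20), nTopicsTrue = 3,
                          nCodes = 12, dosageNoiseSd = 0.05)
  cohort <- simulateCohort(cfg, seed = 9)
  sim <- simulateCodeCounts(cohort, cfg, seed = 10)
  dir <- withr::local_tempdir()
  paths <- writeCohort(cohort, sim$counts, dir)
  expect_true(all(file.exists(paths)))

  dVcf <- readDosageVcf(paths["vcf"])
  expect_identical(unname(dVcf[cohort$subject_id]), cohort$dosage)
  dTsv <- readDosageTsv(paths["dosage"])
  expect_identical(unname(dTsv[cohort$subject_id]), cohort$dosage)

  mMtx <- readCodeCounts(paths["mtx"])
  expect_identical(as.matrix(codeCounts(mMtx)),
                   as.matrix(codeCounts(sim$counts)))
  mTrip <- readCodeCounts(paths["triplet"],
                          subjects = subjectIds(sim$counts),
                          codes = codeVocab(sim$counts))
  expect_identical(as.matrix(codeCounts(mTrip)),
                   as.matrix(codeCounts(sim$counts)))

  cv <- readCovariates(paths["covariates"])
  expect_identical(cv$subject_id, cohort$subject_id)
  expect_identical(cv$bmi, cohort$bmi)
  expect_identical(cv$PC1, cohort$PC1)
})

test_that("the triplet file has one row per nonzero entry", {
  m <- matrix(0L, 3, 2, dimnames = list(c("s1", "s2", "s3"), c("c1", "c2")))
  m["s1", "c1"] <- 2L
  m["s3", "c2"] <- 1L
  cohort <- data.frame(subject_id = rownames(m), wave = "wave1",
                       dosage = c(0, 1, 2), bmi = c(25, 26, 27))
  dir <- withr::local_tempdir()
  paths <- writeCohort(cohort, CodeCountMatrix(m), dir)
  trip <- read.delim(paths["triplet"])
  expect_identical(nrow(trip), 2L)
  expect_error(writeCohort(data.frame(), CodeCountMatrix(m), dir), "empty")
})

test_that("missing genotypes in a VCF are excluded on read", {
  dir <- withr::local_tempdir()
  vcf <- file.path(dir, "gt.vcf")
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\ts1\ts2\ts3",
    "4\t103188709\tv1\tA\tT\t.\tPASS\t.\tGT\t0/1\t./.\t1|1"), vcf)
  expect_message(d <- readDosageVcf(vcf), "excluded")
  expect_identical(d, c(s1 = 1, s3 = 2))
})
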