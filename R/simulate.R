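#' Configuration for the synthetic genotype + EHR cohort generator
#'
#' Bundles and validates all parameters of the synthetic cohort. Defaults
#' describe a four-wave biobank cohort at one tenth of the study's wave
#' sizes, a single biallelic variant at minor allele frequency 0.079 in
#' Hardy-Weinberg proportions, ten ancestry principal components, BMI
#' correlated with genotype, and diagnostic code counts drawn from the
#' LDA generative model with an additive per-allele shift `effectSize`
#' on the Dirichlet concentration of one "risk" topic.
#'
#' @param nSubjectsPerWave integer vector of wave sizes (all >= 2).
#' @param maf minor allele frequency in (0, 0.5].
#' @param nTopicsTrue number of true topics K in the generative model.
#' @param nCodes vocabulary size V.
#' @param alpha0 baseline Dirichlet concentration per topic (> 0).
#' @param betaPhi Dirichlet concentration for topic-code distributions (> 0).
#' @param effectSize additive per-allele shift delta applied to the risk
#'   topic's concentration (>= 0; 0 gives the global null).
#' @param riskTopic index of the planted-effect topic in 1..K.
#' @param codesPerSubjectMean Poisson mean of the per-subject code-token
#'   count (document length); a floor of 1 token is enforced.
#' @param bmiMean,bmiSd population BMI mean and SD (kg/m^2).
#' @param bmiGenotypeSlope per-allele shift in mean BMI (kg/m^2).
#' @param nPcs number of principal-component covariates.
#' @param dosageNoiseSd SD of Gaussian noise added to hard-call dosages
#'   (then clamped to \[0, 2\]) to emulate imputed fractional dosages;
#'   0 keeps hard calls.
#' @param pcConfounding if > 0, PC1 shifts both the genotype frequency
#'   (on the logit scale) and the risk topic's concentration by this
#'   amount, creating deliberate population-stratification confounding
#'   for stress tests. Default 0 (PCs independent of everything).
#' @return a validated list of class `SimulationConfig`.
#' @examples
#' cfg <- simulationConfig(effectSize = 0)   # global null
#' @export
simulationConfig <- function(nSubjectsPerWave = c(360L, 333L, 355L, 310L),
                             maf = 0.079,
                             nTopicsTrue = 10L,
                             nCodes = 60L,
                             alpha0 = 0.5,
                             betaPhi = 0.1,
                             effectSize = 1.0,
                             riskTopic = 1L,
                             codesPerSubjectMean = 30,
                             bmiMean = 27.6, bmiSd = 6.1,
                             bmiGenotypeSlope = 0.5,
                             nPcs = 10L,
                             dosageNoiseSd = 0,
                             pcConfounding = 0) {
  nSubjectsPerWave <- as.integer(nSubjectsPerWave)
  if (!length(nSubjectsPerWave) || any(nSubjectsPerWave < 2L))
    stop("every wave must have at least 2 subjects")
  if (!is.numeric(maf) || maf <= 0 || maf > 0.5)
    stop("maf must lie in (0, 0.5]")
  if (nTopicsTrue < 2L) stop("nTopicsTrue must be >= 2")
  if (nCodes < 2L) stop("nCodes must be >= 2")
  if (alpha0 <= 0 || betaPhi <= 0)
    stop("Dirichlet concentrations must be strictly positive")
  if (effectSize < 0) stop("effectSize must be >= 0")
  if (riskTopic < 1L || riskTopic > nTopicsTrue)
    stop("riskTopic must index a true topic (1..nTopicsTrue)")
  if (codesPerSubjectMean <= 0) stop("codesPerSubjectMean must be positive")
  if (bmiSd <= 0) stop("bmiSd must be positive")
  if (nPcs < 0L) stop("nPcs must be nonnegative")
  if (dosageNoiseSd < 0) stop("dosageNoiseSd must be nonnegative")
  structure(list(nSubjectsPerWave = nSubjectsPerWave, maf = maf,
                 nTopicsTrue = as.integer(nTopicsTrue),
                 nCodes = as.integer(nCodes), alpha0 = alpha0,
                 betaPhi = betaPhi, effectSize = effectSize,
                 riskTopic = as.integer(riskTopic),
                 codesPerSubjectMean = codesPerSubjectMean,
                 bmiMean = bmiMean, bmiSd = bmiSd,
                 bmiGenotypeSlope = bmiGenotypeSlope,
                 nPcs = as.integer(nPcs),
                 dosageNoiseSd = dosageNoiseSd,
                 pcConfounding = pcConfounding),
            class = "SimulationConfig")
}

#' Simulate biallelic genotype dosages
#'
#' Draws hard-call minor-allele counts for `n` subjects as
#' Binomial(2, maf), i.e. Hardy-Weinberg proportions.
#'
#' @param n number of subjects.
#' @param maf minor allele frequency in (0, 0.5].
#' @param seed optional integer seed (the caller's RNG stream is
#'   preserved when a seed is given).
#' @return integer vector of dosages in \{0, 1, 2\}.
#' @examples
#' table(simulateGenotypes(1000, maf = 0.079, seed = 1))
#' @export
simulateGenotypes <- function(n, maf, seed = NULL) {
  if (!is.numeric(maf) || length(maf) != 1L || maf <= 0 || maf > 0.5)
    stop("maf must lie in (0, 0.5]")
  if (n < 1) stop("n must be a positive integer")
  withSeed(seed, rbinom(n, 2L, maf))
}

#' Simulate a multi-wave genotyped cohort
#'
#' Generates subject ids, wave labels, genotype dosages, principal
#' components and BMI according to a [simulationConfig()]. BMI is drawn
#' as Normal(bmiMean + bmiGenotypeSlope * dosage, bmiSd), mirroring the
#' known genotype-BMI association at the study variant.
#'
#' @param config a `SimulationConfig`.
#' @param seed optional integer seed.
#' @return data.frame with columns `subject_id`, `wave`, `dosage`,
#'   `PC1`..`PCn`, `bmi` — the cohort table consumed by the association
#'   stage.
#' @examples
#' cohort <- simulateCohort(simulationConfig(), seed = 1)
#' table(cohort$wave)
#' @export
simulateCohort <- function(config = simulationConfig(), seed = NULL) {
  stopifnot(inherits(config, "SimulationConfig"))
  withSeed(seed, {
    n <- sum(config$nSubjectsPerWave)
    w <- length(config$nSubjectsPerWave)
    wave <- rep(sprintf("wave%d", seq_len(w)), times = config$nSubjectsPerWave)
    pcs <- matrix(rnorm(n * config$nPcs), nrow = n,
                  dimnames = list(NULL, if (config$nPcs)
                    sprintf("PC%d", seq_len(config$nPcs)) else NULL))
    if (config$pcConfounding > 0 && config$nPcs >= 1L) {
      p <- stats::plogis(stats::qlogis(config$maf) +
                           config$pcConfounding * pcs[, 1])
      dosage <- rbinom(n, 2L, p)
    } else {
      dosage <- rbinom(n, 2L, config$maf)
    }
    if (config$dosageNoiseSd > 0)
      dosage <- pmin(2, pmax(0, dosage + rnorm(n, 0, config$dosageNoiseSd)))
    bmi <- rnorm(n, config$bmiMean + config$bmiGenotypeSlope * dosage,
                 config$bmiSd)
    out <- data.frame(subject_id = sprintf("S%05d", seq_len(n)),
                      wave = wave, dosage = as.numeric(dosage),
                      stringsAsFactors = FALSE)
    if (config$nPcs) out <- cbind(out, as.data.frame(pcs))
    out$bmi <- bmi
    out
  })
}

#' Simulate LDA-structured diagnostic code counts with a planted effect
#'
#' Draws a subject-by-code count matrix from the generative model that
#' LDA assumes: topic-code distributions phi_k ~ Dirichlet(betaPhi),
#' per-subject topic weights theta_i ~ Dirichlet(alpha_i) with
#' alpha_i\[k\] = alpha0 except alpha_i\[riskTopic\] = alpha0 +
#' effectSize * dosage_i, document lengths L_i ~ max(1,
#' Poisson(codesPerSubjectMean)), and each code token drawn topic-first.
#' The true parameters are returned for recovery testing.
#'
#' @param cohort cohort data.frame from [simulateCohort()] (needs
#'   `subject_id` and `dosage`).
#' @param config a `SimulationConfig`.
#' @param seed optional integer seed.
#' @return list with elements `counts` (a [CodeCountMatrix-class]) and
#'   `truth`: list(phi, theta, riskTopic, effectSize, docLengths).
#' @examples
#' cfg <- simulationConfig(nSubjectsPerWave = c(30, 30),
#'                         nTopicsTrue = 3, nCodes = 12)
#' sim <- simulateCodeCounts(simulateCohort(cfg, seed = 1), cfg, seed = 2)
#' dim(sim$counts)
#' @export
simulateCodeCounts <- function(cohort, config = simulationConfig(),
                               seed = NULL) {
  stopifnot(inherits(config, "SimulationConfig"))
  if (!NROW(cohort)) stop("cohort is empty")
  if (config$effectSize < 0) stop("effectSize must be >= 0")
  withSeed(seed, {
    n <- nrow(cohort)
    k <- config$nTopicsTrue
    v <- config$nCodes
    vocab <- sprintf("C%03d", seq_len(v))
    phi <- rdirichlet(k, config$betaPhi, k = v)
    colnames(phi) <- vocab
    alphaMat <- matrix(config$alpha0, n, k)
    alphaMat[, config$riskTopic] <- config$alpha0 +
      config$effectSize * cohort$dosage
    if (config$pcConfounding > 0 && "PC1" %in% names(cohort))
      alphaMat[, config$riskTopic] <- pmax(1e-6,
        alphaMat[, config$riskTopic] + config$pcConfounding * cohort$PC1)
    theta <- rdirichlet(n, alphaMat)
    rownames(theta) <- cohort$subject_id
    len <- pmax(1L, rpois(n, config$codesPerSubjectMean))
    # token-level draws collapsed: topic totals ~ Multinomial(L_i, theta_i),
    # then code totals per topic ~ Multinomial(n_k, phi_k)
    ii <- integer(0); jj <- integer(0); xx <- integer(0)
    for (i in seq_len(n)) {
      zk <- as.integer(rmultinom(1, len[i], theta[i, ]))
      cnt <- integer(v)
      for (topic in which(zk > 0))
        cnt <- cnt + as.integer(rmultinom(1, zk[topic], phi[topic, ]))
      nz <- which(cnt > 0)
      ii <- c(ii, rep.int(i, length(nz))); jj <- c(jj, nz)
      xx <- c(xx, cnt[nz])
    }
    m <- sparseMatrix(i = ii, j = jj, x = xx, dims = c(n, v),
                      dimnames = list(cohort$subject_id, vocab))
    list(counts = CodeCountMatrix(m),
         truth = list(phi = phi, theta = theta,
                      riskTopic = config$riskTopic,
                      effectSize = config$effectSize,
                      docLengths = len))
  })
}

#' Write a simulated cohort to disk in standard interchange formats
#'
#' Emits, under `dir`: the genotype as a minimal single-variant VCF 4.2
#' with a DS FORMAT field (`genotype.vcf`) and as a two-column TSV
#' (`dosage.tsv`); the code counts as a sparse triplet TSV
#' (`counts_triplet.tsv`), as MatrixMarket coordinate format
#' (`counts.mtx`) with subject and code index sidecars
#' (`counts_subjects.txt`, `counts_codes.txt`); and the covariates as
#' `covariates.tsv`. All files are UTF-8 with LF line endings and
#' round-trip bit-identically through [readDosageVcf()],
#' [readDosageTsv()], [readCodeCounts()] and [readCovariates()].
#'
#' @param cohort cohort data.frame ([simulateCohort()]).
#' @param counts a [CodeCountMatrix-class] aligned to the cohort.
#' @param dir output directory (created if absent).
#' @param variantId id written in the VCF record.
#' @return invisibly, the named character vector of file paths.
#' @export
writeCohort <- function(cohort, counts, dir,
                        variantId = "var_synthetic_1") {
  if (!NROW(cohort)) stop("cohort is empty")
  stopifnot(is(counts, "CodeCountMatrix"))
  if (!dir.exists(dir) && !dir.create(dir, recursive = TRUE))
    stop("cannot create output directory: ", dir)
  paths <- c(vcf = file.path(dir, "genotype.vcf"),
             dosage = file.path(dir, "dosage.tsv"),
             triplet = file.path(dir, "counts_triplet.tsv"),
             mtx = file.path(dir, "counts.mtx"),
             subjects = file.path(dir, "counts_subjects.txt"),
             codes = file.path(dir, "counts_codes.txt"),
             covariates = file.path(dir, "covariates.tsv"))

  # minimal single-variant VCF 4.2 with DS genotype dosages
  hdr <- c("##fileformat=VCFv4.2",
           "##FORMAT=<ID=DS,Number=1,Type=Float,Description=\"Estimated alternate allele dosage\">",
           paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                   "INFO", "FORMAT", cohort$subject_id), collapse = "\t"))
  rec <- paste(c("4", "103188709", variantId, "A", "T", ".", "PASS", ".",
                 "DS", fmtNum(cohort$dosage)), collapse = "\t")
  writeLines(c(hdr, rec), paths["vcf"], sep = "\n", useBytes = TRUE)

  writeTsv(data.frame(subject_id = cohort$subject_id,
                      dosage = cohort$dosage), paths["dosage"])

  m <- codeCounts(counts)
  trip <- Matrix::summary(m)
  trip <- trip[order(trip$i, trip$j), , drop = FALSE]
  writeTsv(data.frame(subject_id = rownames(m)[trip$i],
                      code = colnames(m)[trip$j],
                      count = as.integer(trip$x)), paths["triplet"])

  Matrix::writeMM(m, paths["mtx"])
  writeLines(rownames(m), paths["subjects"], useBytes = TRUE)
  writeLines(colnames(m), paths["codes"], useBytes = TRUE)

  writeTsv(cohort[, setdiff(names(cohort), "dosage"), drop = FALSE],
           paths["covariates"])
  invisible(paths)
}
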