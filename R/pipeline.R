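#' Pipeline configuration
#'
#' Collects file paths and analysis parameters for [runPipeline()].
#' Defaults mirror the analysis this package implements: 50 topics,
#' symmetric priors alpha = 50/K and beta = 0.1, codes occurring in
#' fewer than 0.5% of subjects eliminated, follow-up codes at topic
#' weight >= 0.01, per-wave logistic fits skipped below 10 cases, and an
#' experiment-wide Bonferroni threshold of 0.05/K.
#'
#' @param genotypeFile single-variant VCF (`.vcf`) or dosage TSV.
#' @param countsFile sparse counts as `.mtx` (with sidecars) or triplet
#'   TSV.
#' @param covariatesFile covariates TSV (`subject_id`, `wave`, PCs,
#'   optional `bmi`).
#' @param outDir output directory.
#' @param codeMapFile optional ICD-9 to PheWAS map TSV; NULL means the
#'   counts are already at PheWAS level.
#' @param K,alpha,beta,nIterations,burnIn,thin LDA settings ([fitLda()]).
#' @param minPrevalence code prevalence filter ([frequencyFilter()]).
#' @param minWeight follow-up code weight threshold ([topCodes()]).
#' @param minCases per-wave logistic case floor ([logisticAssoc()]).
#' @param fwer family-wise error rate for the Bonferroni threshold.
#' @param seed integer seed driving the LDA fit.
#' @return a list of class `PipelineConfig`.
#' @export
pipelineConfig <- function(genotypeFile, countsFile, covariatesFile,
                           outDir, codeMapFile = NULL, K = 50L,
                           alpha = 50 / K, beta = 0.1,
                           nIterations = 500L, burnIn = 200L,
                           thin = 10L, minPrevalence = 0.005,
                           minWeight = 0.01, minCases = 10L,
                           fwer = 0.05, seed = 1L) {
  cfg <- list(genotypeFile = genotypeFile, countsFile = countsFile,
              covariatesFile = covariatesFile, outDir = outDir,
              codeMapFile = codeMapFile, K = as.integer(K),
              alpha = alpha, beta = beta,
              nIterations = as.integer(nIterations),
              burnIn = as.integer(burnIn), thin = as.integer(thin),
              minPrevalence = minPrevalence, minWeight = minWeight,
              minCases = as.integer(minCases), fwer = fwer,
              seed = if (is.null(seed)) NULL else as.integer(seed))
  for (f in c("genotypeFile", "countsFile", "covariatesFile"))
    if (!file.exists(cfg[[f]])) stop(f, " does not exist: ", cfg[[f]])
  if (!is.null(codeMapFile) && !file.exists(codeMapFile))
    stop("codeMapFile does not exist: ", codeMapFile)
  structure(cfg, class = "PipelineConfig")
}

#' Read a pipeline configuration from YAML
#'
#' YAML keys use snake_case (`genotype_file`, `counts_file`,
#' `covariates_file`, `out_dir`, `code_map_file`, `k`, `alpha`, `beta`,
#' `n_iterations`, `burn_in`, `thin`, `min_prevalence`, `min_weight`,
#' `min_cases`, `fwer`, `seed`); missing keys take the
#' [pipelineConfig()] defaults.
#'
#' @param path YAML file.
#' @return a `PipelineConfig`.
#' @export
readPipelineConfig <- function(path) {
  y <- yaml::read_yaml(path)
  key <- c(genotype_file = "genotypeFile", counts_file = "countsFile",
           covariates_file = "covariatesFile", out_dir = "outDir",
           code_map_file = "codeMapFile", k = "K", alpha = "alpha",
           beta = "beta", n_iterations = "nIterations",
           burn_in = "burnIn", thin = "thin",
           min_prevalence = "minPrevalence", min_weight = "minWeight",
           min_cases = "minCases", fwer = "fwer", seed = "seed")
  args <- setNames(y[names(key)[names(key) %in% names(y)]],
                   key[names(key) %in% names(y)])
  do.call(pipelineConfig, args)
}

#' Topic-based PheWAS, in memory
#'
#' The analysis core behind [runPipeline()]: code rollup (optional) ->
#' prevalence filter -> LDA fit -> per-wave topic score scan ->
#' fixed-effects meta-analysis -> Bonferroni selection -> per-code
#' logistic follow-up of significant topics (PC-adjusted, then
#' PC+BMI-adjusted when a `bmi` column is present) -> report table and
#' Manhattan data.
#'
#' @param counts a [CodeCountMatrix-class] (ICD-9 level if `codeMap`
#'   given, PheWAS level otherwise).
#' @param cohort cohort data.frame (`subject_id`, `wave`, `dosage`,
#'   `PC*`, optional `bmi`). Subjects present in only one of
#'   `counts`/`cohort` are dropped at the join with a message.
#' @param codeMap optional `PhewasCodeMap`.
#' @param K,ldaAlpha,ldaBeta,nIterations,burnIn,thin,seed LDA settings.
#' @param minPrevalence,minWeight,minCases,fwer analysis thresholds (see
#'   [pipelineConfig()]).
#' @param verbose emit per-stage messages (default TRUE).
#' @return list of class `TopicPhewasResult`: `fit`
#'   ([TopicModelFit-class]), `counts` (filtered), `cohort`, `qc`,
#'   `removedCodes`, `scan`, `meta`, `threshold`,
#'   `significantTopics`, `followUp` (per-topic list with `codes`,
#'   `codeScan`, `codeMeta`, `codeScanBmi`, `codeMetaBmi`, `report`),
#'   `manhattan`.
#' @export
topicPhewas <- function(counts, cohort, codeMap = NULL, K = 50L,
                        ldaAlpha = 50 / K, ldaBeta = 0.1,
                        nIterations = 500L, burnIn = 200L, thin = 10L,
                        minPrevalence = 0.005, minWeight = 0.01,
                        minCases = 10L, fwer = 0.05, seed = NULL,
                        verbose = TRUE) {
  say <- if (verbose) message else function(...) invisible(NULL)
  stopifnot(is(counts, "CodeCountMatrix"))

  # subjects join by id; sorting makes every stage invariant to input
  # row order
  ids <- sort(intersect(cohort$subject_id, subjectIds(counts)))
  if (!length(ids)) stop("no subjects shared between genotype and counts")
  if (nrow(cohort) > length(ids) || dim(counts)[1] > length(ids))
    say("join: ", nrow(cohort) - length(ids), " cohort / ",
        dim(counts)[1] - length(ids), " count subjects dropped")
  cohort <- cohort[match(ids, cohort$subject_id), , drop = FALSE]
  counts <- CodeCountMatrix(codeCounts(counts)[ids, , drop = FALSE])
  say("cohort: ", nrow(cohort), " subjects, ",
      length(unique(cohort$wave)), " waves")

  if (!is.null(codeMap)) {
    counts <- mapCodes(counts, codeMap)
    say("rollup: ", dim(counts)[2], " PheWAS codes (",
        attr(counts, "nUnmappedDropped"), " ICD-9 codes unmapped)")
  }
  filt <- frequencyFilter(counts, minPrevalence)
  say("frequency filter: ", dim(filt$counts)[2], " codes retained, ",
      length(filt$removed), " removed, ", length(filt$zeroSubjects),
      " subjects left without codes")
  if (!dim(filt$counts)[2])
    stop("no codes survive the prevalence filter; cannot fit a topic model")

  qc <- genotypeQcSummary(cohort)
  fit <- fitLda(filt$counts, K = K, alpha = ldaAlpha, beta = ldaBeta,
                nIterations = nIterations, burnIn = burnIn, thin = thin,
                seed = seed)
  say("LDA: ", K, " topics fitted over ", dim(filt$counts)[2],
      " codes (", nIterations, " sweeps)")
  scores <- topicScores(fit)
  scan <- runTopicScan(scores, cohort)
  threshold <- bonferroniThreshold(K, fwer)
  meta <- metaAnalyzeScan(scan, threshold)
  sig <- selectSignificantTopics(meta, threshold)
  say("association: ", nrow(scan), " per-wave tests; ", length(sig),
      " topic(s) significant at p < ", format(threshold))

  pcCols <- grep("^PC", names(cohort), value = TRUE)
  hasBmi <- "bmi" %in% names(cohort)
  followUp <- list()
  for (tr in sig) {
    k <- match(tr, colnames(scores))
    codes <- topCodes(fit, k, minWeight)
    say("follow-up ", tr, ": ", nrow(codes), " codes with weight >= ",
        minWeight)
    if (!nrow(codes)) next
    cs <- runCodeScan(filt$counts, cohort, codes$code,
                      covariateCols = pcCols, minCases = minCases)
    cm <- metaAnalyzeScan(cs, threshold = fwer)
    csB <- cmB <- NULL
    if (hasBmi) {
      csB <- runCodeScan(filt$counts, cohort, codes$code,
                         covariateCols = c(pcCols, "bmi"),
                         minCases = minCases)
      cmB <- metaAnalyzeScan(csB, threshold = fwer)
    }
    followUp[[tr]] <- list(
      codes = codes, codeScan = cs, codeMeta = cm,
      codeScanBmi = csB, codeMetaBmi = cmB,
      report = buildReportTable(filt$counts, cohort, codes, cs, cm,
                                cmB, codeMap))
  }

  structure(list(fit = fit, counts = filt$counts, cohort = cohort,
                 qc = qc, removedCodes = filt$removed,
                 zeroSubjects = filt$zeroSubjects, scan = scan,
                 meta = meta, threshold = threshold,
                 significantTopics = sig, followUp = followUp,
                 manhattan = manhattanData(meta, threshold)),
            class = "TopicPhewasResult")
}

# PheWAS-style follow-up table: one row per follow-up code, sorted by
# pooled p ascending; per-wave ORs, then the BMI-adjusted pool. The
# closest-match annotation column is left blank for manual curation.
buildReportTable <- function(counts, cohort, codes, codeScan, codeMeta,
                             codeMetaBmi = NULL, codeMap = NULL) {
  m <- codeCounts(counts)
  idx <- match(cohort$subject_id, rownames(m))
  waves <- sort(unique(cohort$wave))
  label <- codes$code
  if (!is.null(codeMap)) {
    i <- match(codes$code, codeMap$phewas_code)
    label[!is.na(i)] <- codeMap$label[i[!is.na(i)]]
  }
  rep <- data.frame(diagnosis = label, code = codes$code,
                    frequency = Matrix::colMeans(m[idx, codes$code,
                                                   drop = FALSE] >= 1),
                    weight_in_topic = codes$weight,
                    stringsAsFactors = FALSE)
  mi <- match(codes$code, codeMeta$trait_id)
  rep$p <- codeMeta$p[mi]
  rep$or <- exp(codeMeta$beta_pooled[mi])
  for (w in waves) {
    rows <- codeScan[codeScan$wave == w, , drop = FALSE]
    ri <- match(codes$code, rows$trait_id)
    orw <- ifelse(rows$status[ri] == "ok", exp(rows$beta[ri]), NA_real_)
    rep[[paste0("or_", w)]] <- orw
  }
  if (!is.null(codeMetaBmi)) {
    bi <- match(codes$code, codeMetaBmi$trait_id)
    rep$p_bmi_adjusted <- codeMetaBmi$p[bi]
    rep$or_bmi_adjusted <- exp(codeMetaBmi$beta_pooled[bi])
  }
  rep$icd10_closest_match <- ""
  rep <- rep[order(rep$p), , drop = FALSE]
  rownames(rep) <- NULL
  rep
}

#' Manhattan-plot data for the topic scan
#'
#' @param meta meta-analysis table ([metaAnalyzeScan()]).
#' @param threshold experiment-wide threshold; its -log10 is attached as
#'   attribute `thresholdLine`.
#' @return data.frame `topic`, `neg_log10_p`, `above_threshold` (strict
#'   `p < threshold`).
#' @export
manhattanData <- function(meta, threshold) {
  if (!nrow(meta)) stop("meta table is empty")
  out <- data.frame(topic = meta$trait_id,
                    neg_log10_p = -log10(meta$p),
                    above_threshold = !is.na(meta$p) & meta$p < threshold,
                    stringsAsFactors = FALSE)
  attr(out, "thresholdLine") <- -log10(threshold)
  out
}

#' Plot the topic Manhattan data
#'
#' @param mh output of [manhattanData()].
#' @param ... passed to [graphics::plot()].
#' @return invisibly, `mh`.
#' @export
plotManhattan <- function(mh, ...) {
  x <- seq_len(nrow(mh))
  graphics::plot(x, mh$neg_log10_p, pch = 19,
                 col = ifelse(mh$above_threshold, "red", "grey30"),
                 xlab = "topic", ylab = expression(-log[10](p)), ...)
  graphics::abline(h = attr(mh, "thresholdLine"), col = "red", lty = 2)
  invisible(mh)
}

#' @export
print.TopicPhewasResult <- function(x, ...) {
  cat("Topic-based PheWAS result\n")
  cat(sprintf("  %d subjects, %d waves, %d codes after filtering\n",
              nrow(x$cohort), length(unique(x$cohort$wave)),
              dim(x$counts)[2]))
  cat(sprintf("  %d topics; Bonferroni threshold p < %g\n",
              nTopics(x$fit), x$threshold))
  if (length(x$significantTopics))
    cat("  significant:", paste(x$significantTopics, collapse = ", "), "\n")
  else cat("  no experiment-wide significant topic\n")
  invisible(x)
}

#' Run the full pipeline from files on disk
#'
#' Reads the genotype (VCF or dosage TSV), covariates and counts named
#' in the config, joins subjects by id, executes [topicPhewas()], and
#' writes all result tables plus a YAML manifest under the output
#' directory: `qc.yaml`, `topic_scan.tsv`, `topic_meta.tsv`,
#' `manhattan.tsv`, `removed_codes.tsv`, the serialised topic model
#' (`topic_model/`), and per significant topic
#' `report_<topic>.tsv` with the accompanying code-level scan/meta
#' tables. Stage progress goes to stderr and to `run.log`. Failure at
#' any stage writes a manifest marked incomplete, then rethrows the
#' error prefixed with the stage name. Rerunning with the same inputs
#' and seed reproduces the outputs byte-identically.
#'
#' @param config a `PipelineConfig` ([pipelineConfig()],
#'   [readPipelineConfig()]).
#' @return invisibly, the `TopicPhewasResult`.
#' @export
runPipeline <- function(config) {
  stopifnot(inherits(config, "PipelineConfig"))
  if (!dir.exists(config$outDir) &&
      !dir.create(config$outDir, recursive = TRUE))
    stop("cannot create output directory: ", config$outDir)
  logFile <- file.path(config$outDir, "run.log")
  if (file.exists(logFile)) unlink(logFile)
  logLine <- function(...) {
    msg <- paste0(...)
    message(msg)
    cat(msg, "\n", sep = "", file = logFile, append = TRUE)
  }
  manifest <- list(complete = FALSE, stages = list(),
                   config = unclass(config))
  writeManifest <- function()
    yaml::write_yaml(manifest, file.path(config$outDir, "MANIFEST.yaml"))
  stage <- function(name, expr) {
    res <- tryCatch(expr, error = function(e) {
      logLine("FAILED at stage ", name, ": ", conditionMessage(e))
      manifest$stages[[name]] <<- "failed"
      writeManifest()
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
    manifest$stages[[name]] <<- "ok"
    res
  }

  dosage <- stage("read_genotype", {
    d <- if (grepl("\\.vcf(\\.gz)?$", config$genotypeFile))
      readDosageVcf(config$genotypeFile)
    else readDosageTsv(config$genotypeFile)
    logLine("read_genotype: ", length(d), " samples")
    d
  })
  covs <- stage("read_covariates", {
    cv <- readCovariates(config$covariatesFile)
    logLine("read_covariates: ", nrow(cv), " subjects, ",
            ncol(cv) - 2L, " covariate columns")
    cv
  })
  counts <- stage("read_counts", {
    ct <- readCodeCounts(config$countsFile)
    logLine("read_counts: ", dim(ct)[1], " subjects x ", dim(ct)[2],
            " codes")
    ct
  })
  codeMap <- if (!is.null(config$codeMapFile))
    stage("read_code_map", readCodeMap(config$codeMapFile)) else NULL

  cohort <- stage("join_subjects", {
    ids <- intersect(covs$subject_id, names(dosage))
    logLine("join_subjects: ", length(ids), " subjects with genotype ",
            "and covariates (", nrow(covs) - length(ids), " + ",
            length(dosage) - length(ids), " dropped)")
    ch <- covs[match(ids, covs$subject_id), , drop = FALSE]
    ch$dosage <- unname(dosage[ids])
    ch
  })

  res <- stage("analysis",
               topicPhewas(counts, cohort, codeMap = codeMap,
                           K = config$K, ldaAlpha = config$alpha,
                           ldaBeta = config$beta,
                           nIterations = config$nIterations,
                           burnIn = config$burnIn, thin = config$thin,
                           minPrevalence = config$minPrevalence,
                           minWeight = config$minWeight,
                           minCases = config$minCases,
                           fwer = config$fwer, seed = config$seed))

  stage("write_outputs", {
    out <- config$outDir
    writeTsv(res$qc, file.path(out, "qc.tsv"))
    yaml::write_yaml(split(res$qc[, -1], res$qc$wave),
                     file.path(out, "qc.yaml"))
    writeTsv(res$scan, file.path(out, "topic_scan.tsv"))
    writeTsv(res$meta, file.path(out, "topic_meta.tsv"))
    mh <- res$manhattan
    mh$threshold_line <- attr(res$manhattan, "thresholdLine")
    writeTsv(mh, file.path(out, "manhattan.tsv"))
    writeTsv(data.frame(code = res$removedCodes),
             file.path(out, "removed_codes.tsv"))
    writeTopicModel(res$fit, file.path(out, "topic_model"))
    for (tr in names(res$followUp)) {
      fu <- res$followUp[[tr]]
      writeTsv(fu$report, file.path(out, sprintf("report_%s.tsv", tr)))
      writeTsv(fu$codeScan, file.path(out, sprintf("code_scan_pc_%s.tsv", tr)))
      writeTsv(fu$codeMeta, file.path(out, sprintf("code_meta_pc_%s.tsv", tr)))
      if (!is.null(fu$codeScanBmi)) {
        writeTsv(fu$codeScanBmi,
                 file.path(out, sprintf("code_scan_bmi_%s.tsv", tr)))
        writeTsv(fu$codeMetaBmi,
                 file.path(out, sprintf("code_meta_bmi_%s.tsv", tr)))
      }
    }
    logLine("write_outputs: results under ", out)
  })

  manifest$complete <- TRUE
  manifest$significant_topics <- res$significantTopics
  writeManifest()
  invisible(res)
}
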