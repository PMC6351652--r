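# Per-wave association of a trait with allele dosage under the additive
# allelic model. Results are one-row data.frames with a common schema so
# waves/traits rbind into the scan tables the meta-analysis consumes.

assocRow <- function(traitId, wave, n, beta = NA_real_, se = NA_real_,
                     stat = NA_real_, p = NA_real_, model, covariates,
                     status = "ok", smallWave = FALSE) {
  data.frame(trait_id = traitId, wave = wave, n = as.integer(n),
             beta = beta, se = se, stat = stat, p = p, model = model,
             covariates = paste(covariates, collapse = ","),
             status = status, small_wave = smallWave,
             stringsAsFactors = FALSE)
}

checkDesign <- function(X) {
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    bad <- colnames(X)[qrX$pivot[seq(qrX$rank + 1L, ncol(X))]]
    stop("design matrix is rank deficient; collinear column(s): ",
         paste(bad, collapse = ", "))
  }
  invisible(TRUE)
}

#' Linear association of a quantitative trait with allele dosage
#'
#' Ordinary least squares of the trait on intercept, dosage and
#' covariates; the reported effect is the dosage coefficient (per minor
#' allele), with Wald t test on n - p - 1 residual degrees of freedom.
#' This is the model used for topic membership scores treated as
#' quantitative traits.
#'
#' @param y numeric trait vector.
#' @param dosage numeric allele dosage in \[0, 2\] (fractional allowed).
#' @param covariates optional numeric matrix / data.frame of adjustment
#'   covariates (e.g. the first 10 principal components).
#' @param wave label recorded in the result row.
#' @param traitId trait identifier recorded in the result row.
#' @return one-row data.frame: `trait_id`, `wave`, `n`, `beta`, `se`,
#'   `stat`, `p`, `model`, `covariates`, `status`, `small_wave`. A
#'   constant dosage yields `status = "skipped_low_frequency"` with NA
#'   estimates; p-values are floored at the smallest positive double.
#' @examples
#' set.seed(1)
#' d <- rbinom(200, 2, 0.2)
#' linearAssoc(0.1 * d + rnorm(200), d)
#' @export
linearAssoc <- function(y, dosage, covariates = NULL, wave = "all",
                        traitId = "trait") {
  n <- length(y)
  if (length(dosage) != n)
    stop("y and dosage must have equal length")
  covNames <- character(0)
  X <- cbind(`(Intercept)` = rep(1, n), dosage = dosage)
  if (!is.null(covariates)) {
    covariates <- as.matrix(covariates)
    if (nrow(covariates) != n)
      stop("covariates must have one row per subject")
    if (is.null(colnames(covariates)))
      colnames(covariates) <- sprintf("X%d", seq_len(ncol(covariates)))
    covNames <- colnames(covariates)
    X <- cbind(X, covariates)
  }
  p <- ncol(X) - 1L
  if (stats::var(dosage) == 0)
    return(assocRow(traitId, wave, n, model = "linear",
                    covariates = covNames,
                    status = "skipped_low_frequency"))
  if (n <= p + 2L)
    stop("too few observations for the requested model (need n > p + 2)")
  checkDesign(X)
  fit <- lm(y ~ X - 1)
  # summary warns on essentially perfect fits; the p floor handles them
  cf <- suppressWarnings(summary(fit)$coefficients)
  i <- which(rownames(cf) == "Xdosage")
  beta <- cf[i, 1]; se <- cf[i, 2]; tval <- cf[i, 3]
  pval <- floorP(2 * pt(-abs(tval), df = n - p - 1L))
  assocRow(traitId, wave, n, beta, se, tval, pval,
           model = "linear", covariates = covNames,
           smallWave = n < 30L)
}

#' Logistic association of code presence with allele dosage
#'
#' Logistic regression (IRLS via [stats::glm()]) of a binary
#' presence/absence phenotype on intercept, dosage and covariates. The
#' effect is the per-allele log odds ratio; `exp(beta)` is the OR. Codes
#' too rare to support the model — fewer than `minCases` cases, or fewer
#' than `minCases` cases among minor-allele carriers — are skipped
#' rather than fitted, the rule behind "NA: frequency too low for
#' regression result" entries in per-wave report tables. Complete or
#' quasi-complete separation is detected and flagged without an
#' estimate.
#'
#' @param present binary (0/1 or logical) phenotype vector.
#' @param dosage numeric allele dosage.
#' @param covariates optional numeric matrix / data.frame.
#' @param minCases minimum case support (default 10).
#' @param wave,traitId labels recorded in the result row.
#' @return one-row data.frame as [linearAssoc()], with `model =
#'   "logistic"` and an extra column `or` (= exp(beta)); `status` is one
#'   of `ok`, `skipped_low_frequency`, `failed_separation`.
#' @examples
#' set.seed(1)
#' d <- rbinom(400, 2, 0.3)
#' y <- rbinom(400, 1, plogis(-1 + 0.5 * d))
#' logisticAssoc(y, d)
#' @export
logisticAssoc <- function(present, dosage, covariates = NULL,
                          minCases = 10L, wave = "all",
                          traitId = "trait") {
  present <- as.integer(as.logical(present))
  n <- length(present)
  if (length(dosage) != n)
    stop("present and dosage must have equal length")
  covNames <- character(0)
  df <- data.frame(present = present, dosage = dosage)
  if (!is.null(covariates)) {
    covariates <- as.matrix(covariates)
    if (nrow(covariates) != n)
      stop("covariates must have one row per subject")
    if (is.null(colnames(covariates)))
      colnames(covariates) <- sprintf("X%d", seq_len(ncol(covariates)))
    covNames <- colnames(covariates)
    df <- cbind(df, as.data.frame(covariates))
  }
  nCases <- sum(present == 1L)
  nCarrierCases <- sum(present == 1L & dosage > 0)
  skipRow <- function() {
    out <- assocRow(traitId, wave, n, model = "logistic",
                    covariates = covNames,
                    status = "skipped_low_frequency",
                    smallWave = n < 30L)
    out$or <- NA_real_
    out
  }
  if (nCases < minCases || nCarrierCases < minCases ||
      sum(present == 0L) < minCases) return(skipRow())
  if (stats::var(dosage) == 0) return(skipRow())

  sepWarn <- FALSE
  fit <- withCallingHandlers(
    glm(present ~ ., data = df, family = binomial()),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w)) ||
          grepl("algorithm did not converge", conditionMessage(w)))
        sepWarn <<- TRUE
      invokeRestart("muffleWarning")
    })
  cf <- summary(fit)$coefficients
  i <- grep("^dosage$", rownames(cf))
  beta <- cf[i, 1]; se <- cf[i, 2]; zval <- cf[i, 3]
  if ((sepWarn && (abs(beta) > 10 || se > 100)) || !fit$converged) {
    out <- assocRow(traitId, wave, n, model = "logistic",
                    covariates = covNames, status = "failed_separation",
                    smallWave = n < 30L)
    out$or <- NA_real_
    return(out)
  }
  pval <- floorP(2 * pnorm(-abs(zval)))
  out <- assocRow(traitId, wave, n, beta, se, zval, pval,
                  model = "logistic", covariates = covNames,
                  smallWave = n < 30L)
  out$or <- exp(beta)
  out
}

#' Per-wave association scan of all topic scores
#'
#' For every topic and every genotyping wave, runs [linearAssoc()] of
#' the topic membership score on allele dosage within that wave's
#' subjects, adjusted for the wave's principal components. Waves are
#' analysed on disjoint subject sets; waves with fewer than 30 subjects
#' are flagged (`small_wave`), never dropped.
#'
#' @param scores N x K topic score matrix with subject ids as rownames
#'   ([topicScores()]).
#' @param cohort cohort data.frame with `subject_id`, `wave`, `dosage`
#'   and covariate columns.
#' @param covariateCols names of adjustment covariate columns (default:
#'   all `PC*` columns present).
#' @return data.frame of K x (number of waves) association rows.
#' @export
runTopicScan <- function(scores, cohort,
                         covariateCols = grep("^PC", names(cohort),
                                              value = TRUE)) {
  if (is.null(rownames(scores)))
    stop("scores must carry subject ids as rownames")
  idx <- match(cohort$subject_id, rownames(scores))
  if (anyNA(idx))
    stop("every cohort subject must have a topic score row")
  scores <- scores[idx, , drop = FALSE]
  topics <- colnames(scores)
  if (is.null(topics)) topics <- sprintf("topic%02d", seq_len(ncol(scores)))
  waves <- sort(unique(cohort$wave))
  out <- vector("list", length(topics) * length(waves))
  r <- 0L
  for (k in seq_along(topics)) {
    for (w in waves) {
      sel <- cohort$wave == w
      r <- r + 1L
      out[[r]] <- linearAssoc(scores[sel, k], cohort$dosage[sel],
                              cohort[sel, covariateCols, drop = FALSE],
                              wave = w, traitId = topics[k])
    }
  }
  do.call(rbind, out)
}

#' Per-wave logistic scan of code presence
#'
#' For each code in `codes`, tests presence/absence (count >= 1) against
#' dosage within each wave via [logisticAssoc()], adjusted for
#' `covariateCols`. Used for the individual-code follow-up of
#' significant topics, first PC-adjusted and then PC+BMI-adjusted.
#'
#' @param counts a [CodeCountMatrix-class].
#' @param cohort cohort data.frame.
#' @param codes character vector of codes to test (subset of the
#'   vocabulary).
#' @param covariateCols adjustment covariate column names.
#' @param minCases minimum case support per wave (default 10).
#' @return data.frame of association rows (codes x waves).
#' @export
runCodeScan <- function(counts, cohort, codes,
                        covariateCols = grep("^PC", names(cohort),
                                             value = TRUE),
                        minCases = 10L) {
  stopifnot(is(counts, "CodeCountMatrix"))
  m <- codeCounts(counts)
  missing <- setdiff(codes, colnames(m))
  if (length(missing))
    stop("codes absent from the matrix: ", paste(missing, collapse = ", "))
  idx <- match(cohort$subject_id, rownames(m))
  if (anyNA(idx))
    stop("every cohort subject must have a count row")
  waves <- sort(unique(cohort$wave))
  out <- list()
  for (code in codes) {
    present <- as.integer(m[idx, code] >= 1)
    for (w in waves) {
      sel <- cohort$wave == w
      out[[length(out) + 1L]] <-
        logisticAssoc(present[sel], cohort$dosage[sel],
                      cohort[sel, covariateCols, drop = FALSE],
                      minCases = minCases, wave = w, traitId = code)
    }
  }
  do.call(rbind, out)
}
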