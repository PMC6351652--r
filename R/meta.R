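#' Inverse-variance-weighted fixed-effects meta-analysis
#'
#' Pools per-wave effect estimates for one trait with weights
#' `w_i = 1 / se_i^2`: `beta_pooled = sum(w_i beta_i) / sum(w_i)`,
#' `se_pooled = 1 / sqrt(sum(w_i))`, `z = beta_pooled / se_pooled`, and
#' a two-sided p from the standard normal. Cochran's heterogeneity
#' statistic `Q = sum(w_i (beta_i - beta_pooled)^2)` on
#' `n_waves_used - 1` degrees of freedom is reported alongside (an
#' extension beyond the pooled test itself). Waves whose association was
#' skipped or failed are excluded from the pool and counted.
#'
#' @param results data.frame of per-wave association rows for a single
#'   trait ([linearAssoc()] / [logisticAssoc()] schema: needs `beta`,
#'   `se`, `status`, optionally `trait_id`, `n`).
#' @return one-row data.frame: `trait_id`, `n_waves_used`, `n_total`,
#'   `beta_pooled`, `se_pooled`, `z`, `p`, `q_het`, `df_het`, `p_het`,
#'   `status` ("ok", or "no_usable_waves" with NA estimates).
#' @examples
#' waves <- rbind(
#'   data.frame(trait_id = "t", beta = 1, se = 1, status = "ok", n = 100),
#'   data.frame(trait_id = "t", beta = 3, se = 1, status = "ok", n = 100))
#' fixedEffectsMeta(waves)  # pooled beta 2, se sqrt(0.5), Q = 2
#' @export
fixedEffectsMeta <- function(results) {
  stopifnot(is.data.frame(results), all(c("beta", "se") %in% names(results)))
  traitId <- if ("trait_id" %in% names(results) && nrow(results))
    results$trait_id[1] else NA_character_
  if ("trait_id" %in% names(results) &&
      length(unique(results$trait_id)) > 1L)
    stop("fixedEffectsMeta pools waves for a single trait; got several trait_ids")
  ok <- if ("status" %in% names(results)) results$status == "ok"
        else rep(TRUE, nrow(results))
  ok <- ok & is.finite(results$beta) & is.finite(results$se) &
    results$se > 0
  nTotal <- if ("n" %in% names(results)) sum(results$n[ok]) else NA_integer_
  if (!any(ok))
    return(data.frame(trait_id = traitId, n_waves_used = 0L,
                      n_total = 0L, beta_pooled = NA_real_,
                      se_pooled = NA_real_, z = NA_real_, p = NA_real_,
                      q_het = NA_real_, df_het = NA_integer_,
                      p_het = NA_real_, status = "no_usable_waves",
                      stringsAsFactors = FALSE))
  b <- results$beta[ok]; se <- results$se[ok]
  w <- 1 / se^2
  bp <- sum(w * b) / sum(w)
  sp <- 1 / sqrt(sum(w))
  z <- bp / sp
  p <- floorP(2 * pnorm(-abs(z)))
  q <- sum(w * (b - bp)^2)
  dfh <- sum(ok) - 1L
  data.frame(trait_id = traitId, n_waves_used = as.integer(sum(ok)),
             n_total = as.integer(nTotal), beta_pooled = bp,
             se_pooled = sp, z = z, p = p, q_het = q,
             df_het = dfh,
             p_het = if (dfh > 0) pchisq(q, dfh, lower.tail = FALSE) else NA_real_,
             status = "ok", stringsAsFactors = FALSE)
}

#' Pool a full per-wave scan by trait
#'
#' Applies [fixedEffectsMeta()] to each trait in a stacked per-wave
#' association table and flags significance against a threshold.
#'
#' @param scan data.frame of association rows for several traits.
#' @param threshold experiment-wide significance threshold (strict `<`).
#' @return data.frame, one row per trait, in first-appearance order,
#'   with a logical `significant` column.
#' @export
metaAnalyzeScan <- function(scan, threshold = bonferroniThreshold(
                              length(unique(scan$trait_id)))) {
  traits <- unique(scan$trait_id)
  out <- do.call(rbind, lapply(traits, function(tr)
    fixedEffectsMeta(scan[scan$trait_id == tr, , drop = FALSE])))
  out$significant <- !is.na(out$p) & out$p < threshold
  attr(out, "threshold") <- threshold
  out
}

#' Bonferroni experiment-wide threshold
#'
#' @param nTests number of tests (>= 1); 50 topics give 0.05/50 = 0.001.
#' @param alpha family-wise error rate in (0, 1) (default 0.05).
#' @return `alpha / nTests`.
#' @examples
#' bonferroniThreshold(50)  # 0.001
#' @export
bonferroniThreshold <- function(nTests, alpha = 0.05) {
  if (!is.numeric(nTests) || length(nTests) != 1L || nTests < 1 ||
      nTests != round(nTests))
    stop("nTests must be a positive integer")
  if (!is.numeric(alpha) || length(alpha) != 1L || alpha <= 0 || alpha >= 1)
    stop("alpha must lie in (0, 1)")
  alpha / nTests
}

#' Select experiment-wide significant traits
#'
#' @param meta meta-analysis table ([metaAnalyzeScan()]).
#' @param threshold significance threshold in (0, 1); selection is
#'   strict (`p < threshold`), so a p exactly at the threshold is not
#'   selected.
#' @return character vector of trait ids sorted by pooled p ascending.
#' @export
selectSignificantTopics <- function(meta, threshold) {
  if (!is.numeric(threshold) || threshold <= 0 || threshold >= 1)
    stop("threshold must lie in (0, 1)")
  sel <- meta[!is.na(meta$p) & meta$p < threshold, , drop = FALSE]
  sel$trait_id[order(sel$p)]
}
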