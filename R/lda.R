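#' Fit an LDA topic model to a code count matrix
#'
#' Runs a collapsed Gibbs sampler over token-level topic assignments (a
#' count of c for a code contributes c tokens) and returns posterior-mean
#' estimates of the topic-code distributions phi and the subject topic
#' membership scores theta, averaged over retained sweeps:
#' `phi[k, v] = (n_kv + beta) / (n_k + V beta)`,
#' `theta[i, k] = (n_ik + alpha) / (n_i + K alpha)`.
#' Subjects with no codes sit exactly at the symmetric prior mean 1/K.
#'
#' @param counts a [CodeCountMatrix-class] (subjects x codes) with at
#'   least one nonzero entry.
#' @param K number of topics (>= 2; default 50).
#' @param alpha symmetric Dirichlet prior on theta (default 50/K).
#' @param beta symmetric Dirichlet prior on phi (default 0.1).
#' @param nIterations total Gibbs sweeps (default 500).
#' @param burnIn sweeps discarded before averaging (default 200).
#' @param thin keep every `thin`-th post-burn-in sweep (default 10).
#' @param seed optional integer seed; fixing it makes the fit
#'   bit-identical across runs on the same platform.
#' @return a [TopicModelFit-class]. The attribute `tokenCounts` holds the
#'   final-sweep sufficient statistics (`ndk`, `nkv`, `docLengths`) for
#'   conservation diagnostics.
#' @examples
#' cfg <- simulationConfig(nSubjectsPerWave = c(40, 40), nTopicsTrue = 3,
#'                         nCodes = 15)
#' sim <- simulateCodeCounts(simulateCohort(cfg, seed = 1), cfg, seed = 2)
#' fit <- fitLda(sim$counts, K = 3, nIterations = 100, burnIn = 50,
#'               seed = 3)
#' fit
#' @export
fitLda <- function(counts, K = 50L, alpha = 50 / K, beta = 0.1,
                   nIterations = 500L, burnIn = 200L, thin = 10L,
                   seed = NULL) {
  stopifnot(is(counts, "CodeCountMatrix"))
  m <- codeCounts(counts)
  if (!nrow(m) || !ncol(m) || !length(m@x) || sum(m@x) == 0)
    stop("count matrix is empty: nothing to fit a topic model to")
  K <- as.integer(K)
  if (K < 2L) stop("K must be >= 2")
  if (alpha <= 0 || beta <= 0) stop("Dirichlet priors must be positive")
  nIterations <- as.integer(nIterations); burnIn <- as.integer(burnIn)
  thin <- as.integer(thin)
  if (burnIn >= nIterations)
    stop("burnIn must be smaller than nIterations")
  if (thin < 1L) stop("thin must be >= 1")
  if (ncol(m) < K)
    warning("vocabulary smaller than the topic count (V < K); ",
            "topics cannot all be distinct")

  trip <- Matrix::summary(m)
  # canonicalise the token stream by subject id and code string so the
  # fit is equivariant under row/column permutations of the input
  trip <- trip[order(rownames(m)[trip$i], colnames(m)[trip$j]), ,
               drop = FALSE]
  reps <- as.integer(trip$x)
  doc <- rep.int(as.integer(trip$i) - 1L, reps)
  word <- rep.int(as.integer(trip$j) - 1L, reps)

  res <- withSeed(seed, lda_gibbs_cpp(doc, word, nrow(m), ncol(m), K,
                                      alpha, beta, nIterations, burnIn,
                                      thin))
  theta <- res$theta; phi <- res$phi
  rownames(theta) <- rownames(m)
  colnames(theta) <- sprintf("topic%02d", seq_len(K))
  rownames(phi) <- colnames(theta)
  colnames(phi) <- colnames(m)
  fit <- new("TopicModelFit", phi = phi, theta = theta,
             alpha = alpha, beta = beta,
             nIterations = nIterations, burnIn = burnIn, thin = thin,
             seed = if (is.null(seed)) NA_integer_ else as.integer(seed),
             logLik = as.numeric(res$loglik))
  attr(fit, "tokenCounts") <- list(ndk = res$ndk, nkv = res$nkv,
                                   docLengths = res$doc_lengths)
  fit
}

#' Codes loading onto a topic above a weight threshold
#'
#' Returns the codes whose probability under the given topic meets the
#' threshold, sorted by weight descending (ties broken by code string
#' ascending). The default threshold 0.01 selects codes whose presence
#' is associated with at least a 1% probability of membership in the
#' topic, the criterion used to pick follow-up codes for significant
#' topics.
#'
#' @param fit a [TopicModelFit-class].
#' @param topic topic index in 1..K.
#' @param minWeight weight threshold (default 0.01).
#' @param comparison `">="` (default) or `">"`: whether codes exactly at
#'   the threshold are included.
#' @return data.frame with columns `code` and `weight`.
#' @export
topCodes <- function(fit, topic, minWeight = 0.01,
                     comparison = c(">=", ">")) {
  stopifnot(is(fit, "TopicModelFit"))
  comparison <- match.arg(comparison)
  topic <- as.integer(topic)
  if (length(topic) != 1L || is.na(topic) || topic < 1L ||
      topic > nTopics(fit))
    stop("topic must be a single index in 1..", nTopics(fit))
  w <- codeDistributions(fit)[topic, ]
  keep <- if (comparison == ">=") w >= minWeight else w > minWeight
  w <- w[keep]
  ord <- order(-w, names(w))
  data.frame(code = names(w)[ord], weight = unname(w[ord]),
             stringsAsFactors = FALSE)
}

#' Serialise / load a topic model fit
#'
#' `writeTopicModel` writes `phi.tsv` (K x V), `theta.tsv` (N x K) and
#' `meta.yaml` (priors, schedule, seed) to a directory;
#' `readTopicModel` reconstructs the [TopicModelFit-class].
#'
#' @param fit a [TopicModelFit-class].
#' @param dir directory to write to / read from.
#' @return `writeTopicModel` the directory invisibly; `readTopicModel`
#'   a [TopicModelFit-class] (without the log-likelihood trace).
#' @export
writeTopicModel <- function(fit, dir) {
  stopifnot(is(fit, "TopicModelFit"))
  if (!dir.exists(dir) && !dir.create(dir, recursive = TRUE))
    stop("cannot create output directory: ", dir)
  phi <- as.data.frame(codeDistributions(fit))
  phi <- cbind(topic = rownames(codeDistributions(fit)), phi)
  writeTsv(phi, file.path(dir, "phi.tsv"))
  th <- as.data.frame(topicScores(fit))
  th <- cbind(subject_id = rownames(topicScores(fit)), th)
  writeTsv(th, file.path(dir, "theta.tsv"))
  yaml::write_yaml(list(n_topics = nTopics(fit), alpha = fit@alpha,
                        beta = fit@beta, n_iterations = fit@nIterations,
                        burn_in = fit@burnIn, thin = fit@thin,
                        seed = fit@seed),
                   file.path(dir, "meta.yaml"))
  invisible(dir)
}

#' @rdname writeTopicModel
#' @export
readTopicModel <- function(dir) {
  meta <- yaml::read_yaml(file.path(dir, "meta.yaml"))
  phiDf <- readTsv(file.path(dir, "phi.tsv"), check.names = FALSE)
  phi <- as.matrix(phiDf[, -1, drop = FALSE])
  rownames(phi) <- phiDf[[1]]
  thDf <- readTsv(file.path(dir, "theta.tsv"), check.names = FALSE)
  theta <- as.matrix(thDf[, -1, drop = FALSE])
  rownames(theta) <- thDf[[1]]
  new("TopicModelFit", phi = phi, theta = theta,
      alpha = meta$alpha, beta = meta$beta,
      nIterations = as.integer(meta$n_iterations),
      burnIn = as.integer(meta$burn_in), thin = as.integer(meta$thin),
      seed = if (is.null(meta$seed)) NA_integer_ else as.integer(meta$seed),
      logLik = numeric(0))
}
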