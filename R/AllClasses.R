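#' Sparse subject-by-code count matrix
#'
#' Container for a subject x diagnostic-code count matrix. Rows are
#' subjects (unique ids in `rownames`), columns are codes (the vocabulary,
#' in `colnames`), entries are nonnegative integer counts stored sparsely.
#'
#' @slot counts a `dgCMatrix` (subjects x codes) with complete, unique
#'   dimnames and no negative entries.
#'
#' @seealso [CodeCountMatrix()] constructor, [mapCodes()],
#'   [frequencyFilter()], [fitLda()]
#' @export
setClass("CodeCountMatrix", slots = c(counts = "dgCMatrix"))

setValidity("CodeCountMatrix", function(object) {
  m <- object@counts
  msgs <- character(0)
  if ((nrow(m) && is.null(rownames(m))) ||
      (ncol(m) && is.null(colnames(m))))
    msgs <- c(msgs, "counts must carry subject ids (rownames) and code vocabulary (colnames)")
  else {
    if (anyDuplicated(rownames(m))) msgs <- c(msgs, "subject ids must be unique")
    if (anyDuplicated(colnames(m))) msgs <- c(msgs, "code vocabulary must be unique")
  }
  if (length(m@x) && min(m@x) < 0) msgs <- c(msgs, "counts must be nonnegative")
  if (length(m@x) && any(m@x != round(m@x))) msgs <- c(msgs, "counts must be integers")
  if (length(msgs)) msgs else TRUE
})

#' Construct a CodeCountMatrix
#'
#' @param counts a base matrix or `dgCMatrix` of nonnegative integer
#'   counts, subjects in rows (rownames = subject ids), codes in columns
#'   (colnames = code vocabulary).
#' @return a [CodeCountMatrix-class] object.
#' @examples
#' m <- matrix(c(2L, 0L, 1L, 3L), 2, 2,
#'             dimnames = list(c("s1", "s2"), c("250.2", "290")))
#' CodeCountMatrix(m)
#' @export
CodeCountMatrix <- function(counts) {
  m <- as(as(as(counts, "dMatrix"), "generalMatrix"), "CsparseMatrix")
  new("CodeCountMatrix", counts = m)
}

#' Fitted LDA topic model
#'
#' Result of [fitLda()]: posterior-mean topic-code distributions and
#' per-subject topic membership scores from a collapsed Gibbs sampler,
#' together with the priors, sampler settings and the per-iteration
#' collapsed log-likelihood trace.
#'
#' @slot phi K x V row-stochastic matrix; `phi[k, v]` is the probability
#'   of code v under topic k (colnames = code vocabulary).
#' @slot theta N x K row-stochastic matrix of subject topic membership
#'   scores (rownames = subject ids).
#' @slot alpha symmetric Dirichlet prior on theta.
#' @slot beta symmetric Dirichlet prior on phi.
#' @slot nIterations,burnIn,thin Gibbs sweep schedule.
#' @slot seed integer seed used for the fit (NA if none supplied).
#' @slot logLik per-iteration collapsed log-likelihood.
#'
#' @seealso [fitLda()], [topicScores()], [topCodes()]
#' @export
setClass("TopicModelFit",
         slots = c(phi = "matrix", theta = "matrix",
                   alpha = "numeric", beta = "numeric",
                   nIterations = "integer", burnIn = "integer",
                   thin = "integer", seed = "integer",
                   logLik = "numeric"))

setValidity("TopicModelFit", function(object) {
  msgs <- character(0)
  if (nrow(object@phi) < 2) msgs <- c(msgs, "a topic model needs K >= 2 topics")
  if (nrow(object@phi) != ncol(object@theta))
    msgs <- c(msgs, "phi and theta disagree on the number of topics")
  if (length(object@phi) && (min(object@phi) < 0 ||
      max(abs(rowSums(object@phi) - 1)) > 1e-8))
    msgs <- c(msgs, "phi rows must be probability vectors")
  if (length(object@theta) && (min(object@theta) < 0 ||
      max(abs(rowSums(object@theta) - 1)) > 1e-8))
    msgs <- c(msgs, "theta rows must be probability vectors")
  if (object@alpha <= 0 || object@beta <= 0)
    msgs <- c(msgs, "Dirichlet priors must be strictly positive")
  if (length(msgs)) msgs else TRUE
})

setMethod("show", "CodeCountMatrix", function(object) {
  m <- object@counts
  cat(sprintf("CodeCountMatrix: %d subjects x %d codes, %d nonzero entries\n",
              nrow(m), ncol(m), length(m@x)))
  cat(sprintf("  total code tokens: %.0f\n", sum(m)))
  invisible(object)
})

setMethod("show", "TopicModelFit", function(object) {
  cat(sprintf("TopicModelFit: %d topics over %d codes, %d subjects\n",
              nrow(object@phi), ncol(object@phi), nrow(object@theta)))
  cat(sprintf("  priors alpha = %g, beta = %g; %d sweeps (burn-in %d, thin %d)\n",
              object@alpha, object@beta, object@nIterations,
              object@burnIn, object@thin))
  if (length(object@logLik))
    cat(sprintf("  final collapsed log-likelihood: %.2f\n",
                object@logLik[length(object@logLik)]))
  invisible(object)
})
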