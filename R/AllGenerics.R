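#' @name accessors
#' @title Accessors for topicPheWAS objects
#' @param object a [CodeCountMatrix-class] or [TopicModelFit-class].
#' @param ... unused.
#' @return `subjectIds`/`codeVocab` return character vectors;
#'   `codeCounts` the underlying `dgCMatrix`; `topicScores` the N x K
#'   theta matrix; `codeDistributions` the K x V phi matrix; `nTopics`
#'   the topic count; `logLikTrace` the per-iteration collapsed
#'   log-likelihood.
NULL

#' @rdname accessors
#' @export
setGeneric("subjectIds", function(object, ...) standardGeneric("subjectIds"))
#' @rdname accessors
#' @export
setGeneric("codeVocab", function(object, ...) standardGeneric("codeVocab"))
#' @rdname accessors
#' @export
setGeneric("codeCounts", function(object, ...) standardGeneric("codeCounts"))
#' @rdname accessors
#' @export
setGeneric("topicScores", function(object, ...) standardGeneric("topicScores"))
#' @rdname accessors
#' @export
setGeneric("codeDistributions", function(object, ...) standardGeneric("codeDistributions"))
#' @rdname accessors
#' @export
setGeneric("nTopics", function(object, ...) standardGeneric("nTopics"))
#' @rdname accessors
#' @export
setGeneric("logLikTrace", function(object, ...) standardGeneric("logLikTrace"))

#' @rdname accessors
#' @export
setMethod("subjectIds", "CodeCountMatrix", function(object, ...)
  rownames(object@counts))
#' @rdname accessors
#' @export
setMethod("codeVocab", "CodeCountMatrix", function(object, ...)
  colnames(object@counts))
#' @rdname accessors
#' @export
setMethod("codeCounts", "CodeCountMatrix", function(object, ...)
  object@counts)

#' @rdname accessors
#' @export
setMethod("subjectIds", "TopicModelFit", function(object, ...)
  rownames(object@theta))
#' @rdname accessors
#' @export
setMethod("codeVocab", "TopicModelFit", function(object, ...)
  colnames(object@phi))
#' @rdname accessors
#' @export
setMethod("topicScores", "TopicModelFit", function(object, ...) {
  if (!nrow(object@theta)) stop("topic model has not been fitted to any subjects")
  object@theta
})
#' @rdname accessors
#' @export
setMethod("codeDistributions", "TopicModelFit", function(object, ...)
  object@phi)
#' @rdname accessors
#' @export
setMethod("nTopics", "TopicModelFit", function(object, ...)
  nrow(object@phi))
#' @rdname accessors
#' @export
setMethod("logLikTrace", "TopicModelFit", function(object, ...)
  object@logLik)

#' @rdname accessors
#' @export
setMethod("dim", "CodeCountMatrix", function(x) dim(x@counts))
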