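# Internal helpers shared across modules.

# Evaluate `expr` under a temporary RNG state seeded with `seed`; the
# caller's RNG stream is restored afterwards. seed = NULL leaves the
# global stream untouched (draws advance it as usual).
withSeed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# n draws from Dirichlet(alpha); rows are probability vectors.
# alpha may be a scalar (symmetric, length k) or a vector/matrix of
# per-draw concentrations.
rdirichlet <- function(n, alpha, k = length(alpha)) {
  if (is.matrix(alpha)) {
    stopifnot(nrow(alpha) == n)
    g <- matrix(rgamma(length(alpha), shape = as.vector(t(alpha))),
                nrow = n, byrow = TRUE)
  } else {
    if (length(alpha) == 1L) alpha <- rep(alpha, k)
    g <- matrix(rgamma(n * k, shape = alpha), nrow = n, byrow = TRUE)
  }
  sw <- rowSums(g)
  # all-zero rows can occur for tiny concentrations; fall back to uniform
  bad <- sw == 0
  if (any(bad)) {
    g[bad, ] <- 1
    sw[bad] <- ncol(g)
  }
  g / sw
}

#' Greedily align two sets of topic-code distributions
#'
#' LDA is identified only up to topic relabelling. `matchTopics` pairs the
#' rows of two row-stochastic matrices (e.g. true and estimated phi) by
#' repeatedly matching the pair with the largest cosine similarity among
#' the rows not yet matched.
#'
#' @param phiRef reference K x V row-stochastic matrix.
#' @param phiEst estimated K x V matrix to align to `phiRef`.
#' @return data.frame with columns `ref`, `est` (row indices) and
#'   `cosine`, one row per matched pair, in matching order.
#' @export
matchTopics <- function(phiRef, phiEst) {
  stopifnot(ncol(phiRef) == ncol(phiEst))
  k1 <- nrow(phiRef); k2 <- nrow(phiEst)
  nrmR <- sqrt(rowSums(phiRef^2)); nrmE <- sqrt(rowSums(phiEst^2))
  sim <- (phiRef %*% t(phiEst)) / outer(pmax(nrmR, 1e-300), pmax(nrmE, 1e-300))
  out <- data.frame(ref = integer(0), est = integer(0), cosine = numeric(0))
  for (i in seq_len(min(k1, k2))) {
    ij <- arrayInd(which.max(sim), dim(sim))
    out <- rbind(out, data.frame(ref = ij[1], est = ij[2],
                                 cosine = sim[ij[1], ij[2]]))
    sim[ij[1], ] <- -Inf
    sim[, ij[2]] <- -Inf
  }
  out
}

# p-values are never reported as exactly zero.
floorP <- function(p) pmax(p, .Machine$double.xmin)

# Format a numeric vector so that read.delim()/as.numeric round-trips
# bit-identically (17 significant digits suffices for IEEE doubles).
fmtNum <- function(x) {
  ifelse(is.na(x), "NA",
         ifelse(x == round(x) & abs(x) < 1e15,
                sprintf("%.0f", x), sprintf("%.17g", x)))
}

# write.table wrapper used for all TSV output: UTF-8, LF, no quoting,
# numeric columns at full precision.
writeTsv <- function(df, path) {
  out <- df
  for (j in seq_along(out)) {
    if (is.numeric(out[[j]]) && !is.integer(out[[j]]))
      out[[j]] <- fmtNum(out[[j]])
  }
  con <- file(path, open = "wb")
  on.exit(close(con))
  write.table(out, con, sep = "\t", quote = FALSE, row.names = FALSE,
              na = "NA", eol = "\n", fileEncoding = "UTF-8")
  invisible(path)
}

readTsv <- function(path, ...) {
  read.delim(path, sep = "\t", stringsAsFactors = FALSE, ...)
}
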