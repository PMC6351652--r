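# Independent oracles used to cross-check the package's estimators.
# They are deliberately written along different computational paths than
# the implementation.

# OLS via explicit normal equations: beta = (X'X)^-1 X'y, Wald t on
# n - p residual df (p = columns of X including intercept).
olsOracle <- function(y, X) {
  XtX <- crossprod(X)
  beta <- solve(XtX, crossprod(X, y))
  res <- y - X %*% beta
  df <- length(y) - ncol(X)
  sigma2 <- sum(res^2) / df
  se <- sqrt(diag(solve(XtX)) * sigma2)
  tval <- beta / se
  p <- 2 * pt(-abs(tval), df)
  list(beta = drop(beta), se = se, stat = drop(tval), p = drop(p))
}

# 2x2 cross-product odds ratio: cases/controls by exposure.
crossProductOR <- function(casesExp, controlsExp, casesUnexp, controlsUnexp) {
  (casesExp * controlsUnexp) / (controlsExp * casesUnexp)
}

# Scalar inverse-variance fixed-effects pool, written as an explicit
# loop over waves.
metaOracle <- function(betas, ses) {
  sw <- 0; swb <- 0
  for (i in seq_along(betas)) {
    w <- 1 / ses[i]^2
    sw <- sw + w
    swb <- swb + w * betas[i]
  }
  bp <- swb / sw
  q <- 0
  for (i in seq_along(betas)) q <- q + (betas[i] - bp)^2 / ses[i]^2
  list(beta = bp, se = 1 / sqrt(sw), q = q,
       z = bp * sqrt(sw), p = 2 * pnorm(-abs(bp * sqrt(sw))))
}

# Exact HWE p by brute-force enumeration over all admissible
# heterozygote counts, with probabilities built from the Wigginton
# ratio recurrence (a different path than direct log-gamma evaluation).
hweEnumOracle <- function(nAA, nAa, naa) {
  n <- nAA + nAa + naa
  nA <- 2 * nAA + nAa
  na <- nAa + 2 * naa
  rare <- min(nA, na)
  hets <- seq(rare %% 2, rare, by = 2)
  prob <- numeric(length(hets))
  mid <- which.max(hets >= rare * (rare / (2 * n)))  # start near the mode
  prob[mid] <- 1
  if (mid < length(hets)) {
    for (j in mid:(length(hets) - 1)) {
      h <- hets[j]
      homR <- (rare - h) / 2
      homC <- n - h - homR
      # P(h+2) / P(h) = 4 homR homC / ((h+1)(h+2))
      prob[j + 1] <- prob[j] * 4 * homR * homC / ((h + 1) * (h + 2))
    }
  }
  if (mid > 1) {
    for (j in mid:2) {
      h <- hets[j]
      homR <- (rare - h) / 2
      homC <- n - h - homR
      # P(h-2) / P(h) = h (h-1) / (4 (homR+1)(homC+1))
      prob[j - 1] <- prob[j] * h * (h - 1) / (4 * (homR + 1) * (homC + 1))
    }
  }
  prob <- prob / sum(prob)
  obs <- which(hets == nAa)
  sum(prob[prob <= prob[obs] * (1 + 1e-10)])
}

# Tiny deterministic 12-subject dataset for regression oracle checks.
toyRegressionData <- function() {
  data.frame(
    y = c(1.2, 0.8, 2.3, 1.9, 0.4, 1.1, 2.8, 0.2, 1.6, 2.1, 0.9, 1.4),
    dosage = c(0, 1, 2, 1, 0, 0, 2, 0, 1, 2, 1, 0),
    x1 = c(0.5, -0.2, 1.1, 0.3, -0.8, 0.0, 0.9, -1.2, 0.4, 0.7, -0.5, 0.1),
    x2 = c(-1.0, 0.6, 0.2, -0.4, 1.3, 0.8, -0.6, 0.3, -0.9, 1.1, 0.5, -0.3))
}

# Two-block separable corpus: subjects use codes only from block A or
# only from block B.
blockCorpus <- function(nPerBlock = 40, codesPerBlock = 8,
                        tokensPerSubject = 25, seed = 42) {
  withr::with_seed(seed, {
    vocab <- sprintf("C%02d", seq_len(2 * codesPerBlock))
    n <- 2 * nPerBlock
    m <- matrix(0L, n, 2 * codesPerBlock,
                dimnames = list(sprintf("S%03d", seq_len(n)), vocab))
    for (i in seq_len(n)) {
      block <- if (i <= nPerBlock) seq_len(codesPerBlock)
               else codesPerBlock + seq_len(codesPerBlock)
      draw <- table(sample(block, tokensPerSubject, replace = TRUE))
      m[i, as.integer(names(draw))] <- as.integer(draw)
    }
    list(counts = CodeCountMatrix(m),
         block = rep(c("A", "B"), each = nPerBlock))
  })
}
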