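#' Genotype class counts from hard-call dosages
#'
#' @param dosage vector of dosages; values are rounded to the nearest
#'   hard call for counting.
#' @return named integer vector `c(n_AA, n_Aa, n_aa)` where `a` is the
#'   allele counted by the dosage.
#' @export
genotypeCounts <- function(dosage) {
  d <- round(dosage)
  if (any(is.na(d)) || any(d < 0 | d > 2))
    stop("dosages must lie in [0, 2]")
  c(n_AA = sum(d == 0), n_Aa = sum(d == 1), n_aa = sum(d == 2))
}

#' Minor allele frequency
#'
#' `(n_Aa + 2 n_aa) / (2 n)`. If the counted allele turns out to be the
#' major one (frequency > 0.5) the labels are swapped with a warning so
#' the returned value is always a minor allele frequency in \[0, 0.5\].
#'
#' @param counts genotype counts as from [genotypeCounts()] (order
#'   AA, Aa, aa).
#' @return frequency in \[0, 0.5\].
#' @examples
#' minorAlleleFrequency(c(90, 9, 1))  # 0.055
#' @export
minorAlleleFrequency <- function(counts) {
  counts <- as.numeric(counts)
  if (length(counts) != 3L || any(counts < 0))
    stop("counts must be three nonnegative genotype class counts")
  n <- sum(counts)
  if (n < 1) stop("empty genotype counts")
  f <- (counts[2] + 2 * counts[3]) / (2 * n)
  if (f > 0.5) {
    warning("counted allele is the major allele; swapping labels")
    f <- 1 - f
  }
  f
}

#' Hardy-Weinberg equilibrium test
#'
#' Tests the observed genotype class counts against the Hardy-Weinberg
#' proportions p^2, 2pq, q^2. `method = "exact"` (default, standard for
#' genotyping QC) conditions on the observed allele counts and sums the
#' probabilities of all heterozygote counts at most as probable as the
#' observed one; `method = "chi_square"` is the 1-df goodness-of-fit
#' test.
#'
#' @param counts genotype counts (AA, Aa, aa).
#' @param method `"exact"` or `"chi_square"`.
#' @return p-value in (0, 1\]. A monomorphic variant returns p = 1 with
#'   a warning.
#' @examples
#' hweTest(c(25, 50, 25))                       # perfect proportions
#' hweTest(c(50, 0, 50), method = "exact")      # extreme het deficit
#' @export
hweTest <- function(counts, method = c("exact", "chi_square")) {
  method <- match.arg(method)
  counts <- as.numeric(counts)
  if (length(counts) != 3L || any(counts < 0) ||
      any(counts != round(counts)))
    stop("counts must be three nonnegative integer genotype class counts")
  n <- sum(counts)
  if (n < 1) stop("empty genotype counts")
  nA <- 2 * counts[1] + counts[2]
  na <- counts[2] + 2 * counts[3]
  if (nA == 0 || na == 0) {
    warning("monomorphic variant; HWE p set to 1")
    return(1)
  }
  if (method == "chi_square") {
    p <- nA / (2 * n)
    expd <- n * c(p^2, 2 * p * (1 - p), (1 - p)^2)
    stat <- sum((counts - expd)^2 / expd)
    return(floorP(pchisq(stat, df = 1, lower.tail = FALSE)))
  }
  exactHwe(counts[2], nA, na)
}

# Exact HWE p-value conditional on allele counts: probabilities of all
# admissible heterozygote counts (same parity as the minor allele count)
# computed in log space, summing those <= the observed probability.
exactHwe <- function(nHet, nA, na) {
  n <- (nA + na) / 2
  rare <- min(nA, na)
  hets <- seq(rare %% 2, rare, by = 2)
  logProb <- vapply(hets, function(h) {
    nHomRare <- (rare - h) / 2
    nHomCommon <- n - h - nHomRare
    lgamma(n + 1) - lgamma(nHomRare + 1) - lgamma(h + 1) -
      lgamma(nHomCommon + 1) + h * log(2) +
      lgamma(nA + 1) + lgamma(na + 1) - lgamma(2 * n + 1)
  }, numeric(1))
  prob <- exp(logProb - max(logProb))
  prob <- prob / sum(prob)
  obs <- which(hets == nHet)
  if (!length(obs)) stop("heterozygote count inconsistent with allele counts")
  min(1, sum(prob[prob <= prob[obs] * (1 + 1e-10)]))
}

#' Per-wave genotype QC summary
#'
#' Computes minor allele frequency and the HWE test per wave and
#' overall; optionally writes the summary as YAML.
#'
#' @param cohort cohort data.frame with `wave` and `dosage`.
#' @param method HWE test method ([hweTest()]).
#' @param file optional YAML output path.
#' @return data.frame with columns `wave`, `n`, `maf`, `hwe_p`.
#' @export
genotypeQcSummary <- function(cohort, method = "exact", file = NULL) {
  waves <- c(as.list(split(seq_len(nrow(cohort)), cohort$wave)),
             list(all = seq_len(nrow(cohort))))
  out <- do.call(rbind, lapply(names(waves), function(w) {
    gc <- genotypeCounts(cohort$dosage[waves[[w]]])
    data.frame(wave = w, n = sum(gc),
               maf = minorAlleleFrequency(gc),
               hwe_p = hweTest(gc, method = method),
               stringsAsFactors = FALSE)
  }))
  if (!is.null(file))
    yaml::write_yaml(split(out[, -1], out$wave), file)
  out
}
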