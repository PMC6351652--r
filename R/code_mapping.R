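#' Read an ICD-9 to PheWAS code mapping table
#'
#' @param path TSV with header columns `icd9`, `phewas_code`, `label`.
#' @return data.frame of class `PhewasCodeMap`.
#' @export
readCodeMap <- function(path) {
  map <- readTsv(path, colClasses = "character")
  need <- c("icd9", "phewas_code", "label")
  if (!all(need %in% names(map)))
    stop("code map must have columns: ", paste(need, collapse = ", "))
  phewasCodeMap(map$icd9, map$phewas_code, map$label)
}

#' Construct a PheWAS code map
#'
#' @param icd9 character vector of ICD-9 codes (unique).
#' @param phewasCode character vector of target PheWAS codes (nonempty).
#' @param label optional human-readable labels for the PheWAS codes.
#' @return data.frame of class `PhewasCodeMap` with columns `icd9`,
#'   `phewas_code`, `label`.
#' @export
phewasCodeMap <- function(icd9, phewasCode, label = phewasCode) {
  icd9 <- as.character(icd9); phewasCode <- as.character(phewasCode)
  if (!length(icd9)) stop("code map is empty")
  if (anyDuplicated(icd9)) stop("icd9 codes must be unique within the map")
  if (any(!nzchar(phewasCode))) stop("phewas_code entries must be nonempty")
  structure(data.frame(icd9 = icd9, phewas_code = phewasCode,
                       label = as.character(label),
                       stringsAsFactors = FALSE),
            class = c("PhewasCodeMap", "data.frame"))
}

#' Fallback rollup for synthetic vocabularies
#'
#' Builds a `PhewasCodeMap` that truncates each ICD-9 string to its first
#' three characters before the dot — a crude stand-in for the phecode
#' table when only synthetic codes are available.
#'
#' @param vocab character vector of ICD-9 codes.
#' @return a `PhewasCodeMap`.
#' @examples
#' truncationCodeMap(c("250.01", "250.2", "290"))
#' @export
truncationCodeMap <- function(vocab) {
  stem <- sub("\\..*$", "", vocab)
  stem <- substr(stem, 1, 3)
  phewasCodeMap(vocab, stem)
}

#' Roll up ICD-9 code counts to PheWAS codes
#'
#' Sums, per subject, the counts of all ICD-9 codes mapping to the same
#' PheWAS code. ICD-9 codes absent from the map are dropped (default,
#' with the dropped-column count recorded) or kept verbatim.
#'
#' @param raw a [CodeCountMatrix-class] over an ICD-9 vocabulary.
#' @param map a `PhewasCodeMap` ([phewasCodeMap()], [readCodeMap()]).
#' @param unmappedPolicy `"drop"` (default) or `"keep"`.
#' @return a [CodeCountMatrix-class] over the PheWAS vocabulary, with
#'   attributes `unmappedCodes` (character) and `nUnmappedDropped`.
#' @examples
#' m <- CodeCountMatrix(matrix(c(2L, 3L), 1,
#'        dimnames = list("s1", c("290.0", "290.1"))))
#' merged <- mapCodes(m, phewasCodeMap(c("290.0", "290.1"), c("290", "290")))
#' codeCounts(merged)
#' @export
mapCodes <- function(raw, map, unmappedPolicy = c("drop", "keep")) {
  stopifnot(is(raw, "CodeCountMatrix"))
  if (!inherits(map, "PhewasCodeMap")) stop("map must be a PhewasCodeMap")
  if (!nrow(map)) stop("code map is empty")
  unmappedPolicy <- match.arg(unmappedPolicy)
  m <- codeCounts(raw)
  vocab <- colnames(m)
  target <- map$phewas_code[match(vocab, map$icd9)]
  unmapped <- vocab[is.na(target)]
  if (unmappedPolicy == "keep") {
    target[is.na(target)] <- vocab[is.na(target)]
  } else if (length(unmapped)) {
    message(length(unmapped), " unmapped ICD-9 code(s) dropped")
  }
  keep <- !is.na(target)
  outVocab <- sort(unique(target[keep]))
  # column aggregation as a sparse indicator product: (N x V) %*% (V x P)
  ind <- sparseMatrix(i = which(keep),
                      j = match(target[keep], outVocab),
                      x = 1, dims = c(length(vocab), length(outVocab)),
                      dimnames = list(vocab, outVocab))
  out <- CodeCountMatrix(m %*% ind)
  attr(out, "unmappedCodes") <- unmapped
  attr(out, "nUnmappedDropped") <-
    if (unmappedPolicy == "drop") length(unmapped) else 0L
  out
}

#' Eliminate low-prevalence codes
#'
#' Retains exactly the codes present (count >= 1) in at least
#' `minPrevalence` of the subjects in the matrix; codes occurring in
#' fewer subjects are eliminated. Prevalence is computed on the pooled
#' subject set. Subjects left with all-zero rows are retained and
#' reported.
#'
#' @param counts a [CodeCountMatrix-class].
#' @param minPrevalence prevalence threshold in \[0, 1\] (default 0.005,
#'   i.e. codes occurring in fewer than 0.5% of subjects are removed).
#' @return list with `counts` (filtered [CodeCountMatrix-class]),
#'   `removed` (character vector of eliminated codes) and `zeroSubjects`
#'   (ids of subjects with no remaining codes).
#' @examples
#' m <- CodeCountMatrix(matrix(c(1L, 0L, 1L, 1L), 2,
#'        dimnames = list(c("s1", "s2"), c("rare", "common"))))
#' frequencyFilter(m, minPrevalence = 0.6)$removed
#' @export
frequencyFilter <- function(counts, minPrevalence = 0.005) {
  stopifnot(is(counts, "CodeCountMatrix"))
  if (minPrevalence < 0 || minPrevalence > 1)
    stop("minPrevalence must lie in [0, 1]")
  m <- codeCounts(counts)
  presence <- Matrix::colSums(m >= 1)
  keep <- (presence / nrow(m)) >= minPrevalence
  removed <- colnames(m)[!keep]
  out <- CodeCountMatrix(m[, keep, drop = FALSE])
  zero <- rownames(m)[Matrix::rowSums(codeCounts(out)) == 0]
  list(counts = out, removed = removed, zeroSubjects = zero)
}
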