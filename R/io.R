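# Readers for the external interchange formats. Every reader keys its
# output by subject id; downstream stages join on ids, never on row
# position.

#' Read a single-variant dosage VCF
#'
#' Reads a VCF containing exactly one variant record and returns the
#' per-sample additive dosage: the DS FORMAT field when present,
#' otherwise the minor-allele count derived from GT. Samples with
#' missing genotype (`./.` or missing DS) are excluded with a message.
#'
#' @param path VCF file (plain or bgzipped).
#' @return named numeric vector of dosages keyed by sample id.
#' @export
readDosageVcf <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  if (nrow(v@fix) != 1L)
    stop("expected exactly one variant record, found ", nrow(v@fix),
         " (this pipeline is single-locus by design)")
  ds <- tryCatch(vcfR::extract.gt(v, element = "DS", as.numeric = TRUE),
                 error = function(e) NULL)
  if (!is.null(ds) && any(!is.na(ds))) {
    out <- ds[1, ]
  } else {
    gt <- vcfR::extract.gt(v, element = "GT")
    out <- vapply(gt[1, ], function(g) {
      if (is.na(g)) return(NA_real_)
      al <- strsplit(g, "[/|]")[[1]]
      if (any(al == ".")) return(NA_real_)
      sum(al != "0")
    }, numeric(1))
  }
  drop <- is.na(out)
  if (any(drop))
    message(sum(drop), " sample(s) with missing genotype excluded")
  out[!drop]
}

#' Read a dosage TSV
#'
#' @param path TSV with header columns `subject_id` and `dosage`.
#' @return named numeric vector keyed by subject id.
#' @export
readDosageTsv <- function(path) {
  df <- readTsv(path, colClasses = c(subject_id = "character"))
  if (!all(c("subject_id", "dosage") %in% names(df)))
    stop("dosage TSV needs columns subject_id, dosage")
  setNames(as.numeric(df$dosage), df$subject_id)
}

#' Read a sparse code count matrix
#'
#' Accepts either the MatrixMarket coordinate file written by
#' [writeCohort()] (with its `counts_subjects.txt` / `counts_codes.txt`
#' sidecars next to it) or a triplet TSV with columns `subject_id`,
#' `code`, `count`. For the triplet form, subjects or codes can be
#' supplied to fix the universe (subjects with no codes would otherwise
#' be absent).
#'
#' @param path `.mtx` file or triplet TSV.
#' @param subjects,codes optional universe for the triplet form.
#' @return a [CodeCountMatrix-class].
#' @export
readCodeCounts <- function(path, subjects = NULL, codes = NULL) {
  if (grepl("\\.mtx$", path)) {
    m <- as(Matrix::readMM(path), "CsparseMatrix")
    sid <- readLines(file.path(dirname(path), "counts_subjects.txt"))
    cod <- readLines(file.path(dirname(path), "counts_codes.txt"))
    if (length(sid) != nrow(m) || length(cod) != ncol(m))
      stop("index sidecar files do not match the matrix dimensions")
    dimnames(m) <- list(sid, cod)
    return(CodeCountMatrix(m))
  }
  df <- readTsv(path, colClasses = c(subject_id = "character",
                                     code = "character"))
  if (!all(c("subject_id", "code", "count") %in% names(df)))
    stop("triplet TSV needs columns subject_id, code, count")
  if (is.null(subjects)) subjects <- unique(df$subject_id)
  if (is.null(codes)) codes <- sort(unique(df$code))
  i <- match(df$subject_id, subjects)
  j <- match(df$code, codes)
  if (anyNA(i) || anyNA(j))
    stop("triplet entries outside the declared subject/code universe")
  CodeCountMatrix(sparseMatrix(i = i, j = j, x = as.integer(df$count),
                               dims = c(length(subjects), length(codes)),
                               dimnames = list(subjects, codes)))
}

#' Read the covariates table
#'
#' @param path TSV with `subject_id`, `wave`, PC columns and optionally
#'   `bmi`.
#' @return data.frame keyed by `subject_id`.
#' @export
readCovariates <- function(path) {
  df <- readTsv(path, colClasses = c(subject_id = "character",
                                     wave = "character"))
  if (!all(c("subject_id", "wave") %in% names(df)))
    stop("covariates TSV needs columns subject_id, wave")
  if (anyDuplicated(df$subject_id))
    stop("duplicate subject ids in covariates table")
  df
}
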