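#' @name sumstats-format
#' @title Summary-statistics table format
#'
#' @description
#' All readers and writers in this package use one canonical per-SNP
#' association table: a `data.frame` with columns
#'
#' * `snp_id` - variant identifier (character);
#' * `chrom` - chromosome label (character);
#' * `pos` - 1-based base-pair position (integer);
#' * `effect_allele`, `other_allele` - single bases among A/C/G/T;
#' * `eaf` - effect-allele frequency in \[0, 1\], `NA` allowed;
#' * `beta` - per-allele effect (log-odds or SD units);
#' * `se` - standard error of `beta`, strictly positive;
#' * `pval` - two-sided association p-value in (0, 1\];
#' * `n` - study sample size, positive, `NA` allowed.
#'
#' Files are tab-delimited with a header row and `NA` as the missing-value
#' sentinel. Multi-base (indel) alleles are rejected: the pipeline is
#' SNP-only.
NULL

.sumstat_cols <- c("snp_id", "chrom", "pos", "effect_allele", "other_allele",
                   "eaf", "beta", "se", "pval", "n")
.sumstat_required <- c("snp_id", "chrom", "pos", "effect_allele",
                       "other_allele", "beta", "se", "pval")

#' Validate a summary-statistics table
#'
#' Checks every row of a per-SNP association table against the format
#' invariants (see [sumstats-format]) and fails with 1-based row numbers for
#' each violated rule.
#'
#' @param x `data.frame` in the canonical summary-statistics layout.
#' @return `x` invisibly, with alleles upper-cased, if valid.
#' @export
validate_sumstats <- function(x) {
  if (!is.data.frame(x)) stop("summary statistics must be a data.frame", call. = FALSE)
  missing_cols <- setdiff(.sumstat_required, names(x))
  if (length(missing_cols) > 0) {
    stop("missing required column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  if (!"eaf" %in% names(x)) x$eaf <- NA_real_
  if (!"n" %in% names(x)) x$n <- NA_real_

  x$effect_allele <- toupper(as.character(x$effect_allele))
  x$other_allele <- toupper(as.character(x$other_allele))
  x$snp_id <- as.character(x$snp_id)
  x$chrom <- as.character(x$chrom)

  bad <- function(cond, what) {
    rows <- which(cond)
    if (length(rows) > 0) {
      stop(sprintf("%s (row%s %s)", what, if (length(rows) > 1) "s" else "",
                   paste(head(rows, 5), collapse = ", ")), call. = FALSE)
    }
  }
  bases <- c("A", "C", "G", "T")
  bad(!(x$effect_allele %in% bases) | !(x$other_allele %in% bases),
      "alleles must be single bases A/C/G/T (indels are not supported)")
  bad(x$effect_allele == x$other_allele, "effect_allele must differ from other_allele")
  bad(!is.finite(x$se) | x$se <= 0, "se must be > 0")
  bad(!is.finite(x$beta), "beta must be finite")
  bad(!is.finite(x$pval) | x$pval <= 0 | x$pval > 1, "pval must lie in (0, 1]")
  bad(!is.na(x$eaf) & (x$eaf < 0 | x$eaf > 1), "eaf must lie in [0, 1]")
  bad(!is.finite(x$pos) | x$pos < 1, "pos must be a positive 1-based coordinate")
  bad(!is.na(x$n) & x$n <= 0, "n must be positive")
  dup <- duplicated(x$snp_id)
  if (any(dup)) {
    stop("duplicated snp_id: ", paste(unique(x$snp_id[dup]), collapse = ", "),
         call. = FALSE)
  }
  invisible(x)
}

#' Read a summary-statistics table
#'
#' Reads a delimited text file of per-SNP associations, optionally renaming
#' foreign column headers via `column_map`, and validates every row. Row
#' order is preserved and alleles are upper-cased.
#'
#' @param path Path to a delimited text file with a header row.
#' @param column_map Optional named character vector mapping canonical column
#'   names to the file's column names, e.g.
#'   `c(snp_id = "SNP", beta = "b", se = "se", pval = "p")`. Unmapped
#'   canonical names are looked up verbatim.
#' @param sep Field separator (default tab).
#' @return A validated `data.frame` in the canonical layout (see
#'   [sumstats-format]).
#' @export
#' @examples
#' f <- tempfile(fileext = ".tsv")
#' df <- data.frame(snp_id = "rs1", chrom = "1", pos = 1000L,
#'                  effect_allele = "A", other_allele = "G", eaf = 0.3,
#'                  beta = 0.1, se = 0.02, pval = 1e-7, n = 10000)
#' write_sumstats(df, f)
#' read_sumstats(f)
read_sumstats <- function(path, column_map = NULL, sep = "\t") {
  raw <- read.delim(path, sep = sep, header = TRUE, stringsAsFactors = FALSE,
                    check.names = FALSE, na.strings = c("NA", ""))
  if (!is.null(column_map)) {
    absent <- setdiff(unname(column_map), names(raw))
    if (length(absent) > 0) {
      stop("mapped column(s) not found in file: ",
           paste(absent, collapse = ", "), call. = FALSE)
    }
    for (canonical in names(column_map)) {
      names(raw)[names(raw) == column_map[[canonical]]] <- canonical
    }
  }
  missing_cols <- setdiff(.sumstat_required, names(raw))
  if (length(missing_cols) > 0) {
    stop("file is missing required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (!"eaf" %in% names(raw)) raw$eaf <- NA_real_
  if (!"n" %in% names(raw)) raw$n <- NA_real_
  out <- raw[, .sumstat_cols]
  out$pos <- as.integer(out$pos)
  for (col in c("eaf", "beta", "se", "pval", "n")) out[[col]] <- as.numeric(out[[col]])
  out <- validate_sumstats(out)
  rownames(out) <- NULL
  out
}

#' Write a summary-statistics table
#'
#' Writes a validated table as tab-delimited text with a deterministic column
#' order and `NA` for missing values, so that [read_sumstats()] round-trips
#' it field-for-field.
#'
#' @param records Canonical summary-statistics `data.frame`.
#' @param path Output file path.
#' @return `path` invisibly.
#' @export
write_sumstats <- function(records, path) {
  records <- validate_sumstats(records)
  write.table(records[, .sumstat_cols], file = path, sep = "\t",
              quote = FALSE, row.names = FALSE, na = "NA")
  invisible(path)
}

#' Validate an LD matrix
#'
#' An LD matrix is a square numeric matrix of pairwise squared correlations
#' (r-squared) with SNP identifiers as both dimnames, unit diagonal,
#' symmetry, and all entries in \[0, 1\]. Asymmetries and diagonal deviations
#' up to `tol` are repaired (by averaging and resetting); anything larger is
#' an error.
#'
#' @param m Numeric matrix with matching row/column SNP identifiers.
#' @param tol Numerical tolerance for symmetry/diagonal repair (default 1e-8).
#' @return The repaired matrix.
#' @export
validate_ld_matrix <- function(m, tol = 1e-8) {
  if (!is.matrix(m) || !is.numeric(m)) stop("LD matrix must be numeric", call. = FALSE)
  if (nrow(m) != ncol(m)) stop("LD matrix must be square", call. = FALSE)
  ids <- rownames(m)
  if (is.null(ids) || is.null(colnames(m))) {
    stop("LD matrix must carry SNP identifiers as dimnames", call. = FALSE)
  }
  if (!identical(ids, colnames(m))) {
    stop("LD matrix row and column identifiers disagree", call. = FALSE)
  }
  if (any(!is.finite(m))) stop("LD matrix contains non-finite entries", call. = FALSE)
  asym <- max(abs(m - t(m)))
  if (asym > tol) {
    stop(sprintf("LD matrix asymmetry %.3g exceeds tolerance %.1g", asym, tol),
         call. = FALSE)
  }
  m <- (m + t(m)) / 2
  if (max(abs(diag(m) - 1)) > tol) {
    stop("LD matrix diagonal must equal 1", call. = FALSE)
  }
  diag(m) <- 1
  if (min(m) < -tol || max(m) > 1 + tol) {
    stop("LD matrix entries must lie in [0, 1]", call. = FALSE)
  }
  m[m < 0] <- 0
  m[m > 1] <- 1
  m
}

#' Read an LD (r-squared) matrix
#'
#' Reads a tab-delimited square labelled matrix: the first row and first
#' column hold SNP identifiers, the body the pairwise r-squared values.
#'
#' @param path Path to the matrix file.
#' @param tol Symmetry/diagonal repair tolerance passed to
#'   [validate_ld_matrix()].
#' @return A validated numeric matrix with SNP identifiers as dimnames.
#' @export
read_ld_matrix <- function(path, tol = 1e-8) {
  m <- as.matrix(utils::read.table(path, header = TRUE, sep = "\t",
                                   row.names = 1, check.names = FALSE))
  storage.mode(m) <- "double"
  validate_ld_matrix(m, tol = tol)
}

#' Write an LD matrix
#'
#' @param m Validated LD matrix (see [validate_ld_matrix()]).
#' @param path Output file path.
#' @return `path` invisibly.
#' @export
write_ld_matrix <- function(m, path) {
  m <- validate_ld_matrix(m)
  write.table(m, file = path, sep = "\t", quote = FALSE, col.names = NA)
  invisible(path)
}
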