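.complement <- function(x) chartr("ACGT", "TGCA", x)

.is_palindromic <- function(a1, a2) a1 == .complement(a2)

#' Align outcome associations to the exposure effect allele
#'
#' Matches exposure instruments to outcome records by `snp_id` and aligns
#' each outcome effect to the exposure's effect allele:
#'
#' * same allele pair, same orientation - kept as is;
#' * same pair, swapped orientation - outcome beta sign-flipped and its
#'   frequency reflected (`eaf -> 1 - eaf`);
#' * complementary pair (strand flip) - complemented, then the two rules
#'   above apply;
#' * palindromic pair (A/T or C/G) - allele labels cannot resolve strand, so
#'   alignment is inferred from allele frequency: if both frequencies lie
#'   outside the ambiguity zone `[0.5 - eaf_ambiguity, 0.5 + eaf_ambiguity]`,
#'   agreement in side of 0.5 means kept and disagreement means sign-flipped;
#'   a frequency inside the zone (or missing) drops the SNP as ambiguous;
#' * irreconcilable allele pairs are dropped as mismatches.
#'
#' Unmatched exposure SNPs are dropped with a message. Dropped rows stay in
#' the returned table, flagged in `action_taken`; every estimator in this
#' package uses only the retained rows.
#'
#' @param exposure Exposure instruments (canonical summary-statistics table,
#'   optionally with `f_stat`).
#' @param outcome Outcome summary statistics.
#' @param eaf_ambiguity Half-width of the frequency ambiguity zone around 0.5
#'   for palindromic SNPs. Default `0.08` (zone \[0.42, 0.58\]).
#' @return A `harmonized_table` data.frame with columns `snp_id`, `chrom`,
#'   `pos`, `effect_allele`, `other_allele` (exposure orientation),
#'   `eaf_exp`, `beta_exp`, `se_exp`, `eaf_out`, `beta_out`, `se_out`,
#'   `action_taken`. The number of unmatched exposure SNPs is stored in
#'   `attr(, "n_unmatched")`.
#' @export
harmonize <- function(exposure, outcome, eaf_ambiguity = 0.08) {
  exposure <- validate_sumstats(exposure)
  outcome <- validate_sumstats(outcome)
  stopifnot(eaf_ambiguity >= 0, eaf_ambiguity < 0.5)

  idx <- match(exposure$snp_id, outcome$snp_id)
  n_unmatched <- sum(is.na(idx))
  if (n_unmatched > 0) {
    message(sprintf("harmonize: %d exposure SNP(s) not found in outcome and dropped",
                    n_unmatched))
  }
  keep <- !is.na(idx)
  exp <- exposure[keep, , drop = FALSE]
  out <- outcome[idx[keep], , drop = FALSE]
  J <- nrow(exp)

  action <- character(J)
  beta_out <- out$beta
  eaf_out <- out$eaf
  lo <- 0.5 - eaf_ambiguity
  hi <- 0.5 + eaf_ambiguity

  for (j in seq_len(J)) {
    a1e <- exp$effect_allele[j]; a2e <- exp$other_allele[j]
    a1o <- out$effect_allele[j]; a2o <- out$other_allele[j]
    if (.is_palindromic(a1e, a2e)) {
      if (!setequal(c(a1o, a2o), c(a1e, a2e))) {
        action[j] <- "dropped_allele_mismatch"
        next
      }
      fe <- exp$eaf[j]; fo <- out$eaf[j]
      if (is.na(fe) || is.na(fo)) {
        warning(sprintf("palindromic SNP %s has missing allele frequency; dropped",
                        exp$snp_id[j]), call. = FALSE)
        action[j] <- "dropped_palindromic_ambiguous"
        next
      }
      if ((fe >= lo && fe <= hi) || (fo >= lo && fo <= hi)) {
        action[j] <- "dropped_palindromic_ambiguous"
        next
      }
      if ((fe < 0.5) == (fo < 0.5)) {
        action[j] <- "kept"
      } else {
        action[j] <- "sign_flipped"
        beta_out[j] <- -beta_out[j]
        eaf_out[j] <- 1 - eaf_out[j]
      }
      next
    }
    # non-palindromic: allele labels identify orientation and strand
    if (a1o == a1e && a2o == a2e) {
      action[j] <- "kept"
    } else if (a1o == a2e && a2o == a1e) {
      action[j] <- "sign_flipped"
      beta_out[j] <- -beta_out[j]
      if (!is.na(eaf_out[j])) eaf_out[j] <- 1 - eaf_out[j]
    } else {
      c1 <- .complement(a1o); c2 <- .complement(a2o)
      if (c1 == a1e && c2 == a2e) {
        action[j] <- "strand_complemented"
      } else if (c1 == a2e && c2 == a1e) {
        action[j] <- "sign_flipped_and_complemented"
        beta_out[j] <- -beta_out[j]
        if (!is.na(eaf_out[j])) eaf_out[j] <- 1 - eaf_out[j]
      } else {
        action[j] <- "dropped_allele_mismatch"
      }
    }
  }

  res <- data.frame(
    snp_id = exp$snp_id, chrom = exp$chrom, pos = exp$pos,
    effect_allele = exp$effect_allele, other_allele = exp$other_allele,
    eaf_exp = exp$eaf, beta_exp = exp$beta, se_exp = exp$se,
    eaf_out = eaf_out, beta_out = beta_out, se_out = out$se,
    action_taken = action, stringsAsFactors = FALSE
  )
  if ("f_stat" %in% names(exp)) res$f_stat <- exp$f_stat
  rownames(res) <- NULL
  attr(res, "n_unmatched") <- n_unmatched
  class(res) <- c("harmonized_table", "data.frame")
  res
}

# Retained (non-dropped) rows of a harmonized table; estimators accept either
# a harmonized_table or any data.frame carrying the aligned-effect columns.
.retained <- function(table) {
  needed <- c("beta_exp", "se_exp", "beta_out", "se_out")
  missing_cols <- setdiff(needed, names(table))
  if (length(missing_cols) > 0) {
    stop("harmonized table is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if ("action_taken" %in% names(table)) {
    table <- table[!startsWith(table$action_taken, "dropped"), , drop = FALSE]
  }
  table
}
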