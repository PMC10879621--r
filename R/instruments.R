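#' Instrument-selection configuration
#'
#' Bundles the thresholds used to pick instrumental variables from exposure
#' summary statistics. Defaults follow the microbiome-GWAS convention of a
#' sub-genome-wide candidate threshold with tight LD pruning and the usual
#' weak-instrument cutoff, plus the looser LD cap customary for cis-eQTL
#' instruments.
#'
#' @param p_threshold Candidate significance cutoff; SNPs with `pval <
#'   p_threshold` (strict) enter clumping. Default `1e-5`.
#' @param clump_r2 LD pruning threshold: within the window, SNPs with
#'   r-squared at or above this value to a better index SNP are discarded.
#'   Default `0.01`.
#' @param clump_window_kb Pruning window in kilobases. Default `30`.
#' @param f_min Minimum per-SNP F-statistic; instruments must satisfy
#'   `f_stat > f_min` (strict). Default `10`.
#' @param cis_window_bp Window on either side of the target gene defining
#'   cis-eQTLs, in base pairs. Default `1e6` (1 Mb).
#' @param eqtl_r2 LD cap for eQTL instruments (pruning threshold, no distance
#'   window). Default `0.30`.
#' @return A `selection_config` list.
#' @export
selection_config <- function(p_threshold = 1e-5, clump_r2 = 0.01,
                             clump_window_kb = 30, f_min = 10,
                             cis_window_bp = 1e6, eqtl_r2 = 0.30) {
  stopifnot(p_threshold > 0, clump_window_kb > 0, f_min > 0, cis_window_bp > 0)
  if (clump_r2 <= 0 || clump_r2 >= 1) stop("clump_r2 must lie in (0, 1)", call. = FALSE)
  if (eqtl_r2 <= 0 || eqtl_r2 >= 1) stop("eqtl_r2 must lie in (0, 1)", call. = FALSE)
  structure(list(p_threshold = p_threshold, clump_r2 = clump_r2,
                 clump_window_kb = clump_window_kb, f_min = f_min,
                 cis_window_bp = cis_window_bp, eqtl_r2 = eqtl_r2),
            class = "selection_config")
}

#' Per-SNP instrument-strength F-statistic
#'
#' The default is the summary-data approximation F = (beta/se)^2, the square
#' of the Wald z-statistic. The variance-explained variant computes the
#' per-SNP R-squared for a standardized trait, R2 = 2*eaf*(1-eaf)*beta^2, and
#' F = R2*(n-2)/(1-R2); it requires `eaf` and `n`.
#'
#' @param beta,se Per-SNP effect and standard error (vectorized).
#' @param method `"wald"` (default) or `"variance_explained"`.
#' @param eaf,n Effect-allele frequency and sample size, required for the
#'   variance-explained variant.
#' @return Numeric vector of non-negative F-statistics.
#' @export
#' @examples
#' compute_f_stat(0.1, 0.01)  # 100
compute_f_stat <- function(beta, se, method = c("wald", "variance_explained"),
                           eaf = NULL, n = NULL) {
  method <- match.arg(method)
  if (any(!is.finite(se)) || any(se <= 0)) stop("se must be > 0", call. = FALSE)
  if (method == "wald") {
    return((beta / se)^2)
  }
  if (is.null(eaf) || is.null(n)) {
    stop("the variance-explained F-statistic requires eaf and n", call. = FALSE)
  }
  r2 <- 2 * eaf * (1 - eaf) * beta^2
  if (any(r2 >= 1)) stop("per-SNP variance explained must be < 1", call. = FALSE)
  r2 * (n - 2) / (1 - r2)
}

# Greedy pruning shared by ld_clump and select_cis_eqtls.
# Sort candidates by p ascending (ties: position, then snp_id); repeatedly
# take the best remaining SNP as index and discard remaining SNPs whose
# r-squared with it is >= r2_threshold and (when window_bp is finite) that
# lie on the same chromosome within window_bp. Retained rows are returned in
# the original input order.
.greedy_clump <- function(candidates, ld, r2_threshold, window_bp) {
  n <- nrow(candidates)
  if (n == 0) return(candidates)
  absent <- setdiff(candidates$snp_id, rownames(ld))
  if (length(absent) > 0) {
    stop("SNP(s) absent from the LD matrix: ",
         paste(head(absent, 5), collapse = ", "), call. = FALSE)
  }
  ord <- order(candidates$pval, candidates$pos, candidates$snp_id)
  alive <- rep(TRUE, n)
  retained <- rep(FALSE, n)
  for (i in ord) {
    if (!alive[i]) next
    retained[i] <- TRUE
    alive[i] <- FALSE
    r2 <- ld[candidates$snp_id[i], candidates$snp_id]
    near <- if (is.finite(window_bp)) {
      candidates$chrom == candidates$chrom[i] &
        abs(candidates$pos - candidates$pos[i]) <= window_bp
    } else {
      rep(TRUE, n)
    }
    alive <- alive & !(near & r2 >= r2_threshold)
  }
  candidates[retained, , drop = FALSE]
}

#' Greedy LD clumping
#'
#' Index-SNP pruning: candidates are visited in order of ascending p-value
#' (ties broken by position, then identifier); each index SNP discards all
#' not-yet-retained SNPs on the same chromosome within `clump_window_kb`
#' whose r-squared with it is at or above `clump_r2`. The retained set is
#' returned in the original input order.
#'
#' @param candidates Summary-statistics `data.frame` (any table carrying
#'   `snp_id`, `chrom`, `pos`, `pval`).
#' @param ld LD matrix covering every candidate (see [read_ld_matrix()]).
#' @param config A [selection_config()].
#' @return The retained subset of `candidates`, input order preserved.
#' @export
ld_clump <- function(candidates, ld, config = selection_config()) {
  stopifnot(inherits(config, "selection_config"))
  out <- .greedy_clump(candidates, ld, config$clump_r2,
                       config$clump_window_kb * 1000)
  rownames(out) <- NULL
  out
}

#' Select instrumental variables for a trait exposure
#'
#' Applies the three-stage instrument filter: (1) significance,
#' `pval < p_threshold`; (2) greedy LD clumping ([ld_clump()]); (3)
#' instrument strength, `f_stat > f_min`. Counts surviving each stage are
#' reported via `message()`.
#'
#' @inheritParams ld_clump
#' @param sumstats Validated exposure summary statistics.
#' @param verbose Emit per-stage counts (default `TRUE`).
#' @return The retained rows with an `f_stat` column appended.
#' @export
select_instruments <- function(sumstats, ld, config = selection_config(),
                               verbose = TRUE) {
  sumstats <- validate_sumstats(sumstats)
  cand <- sumstats[sumstats$pval < config$p_threshold, , drop = FALSE]
  if (verbose) {
    message(sprintf("significance filter (p < %g): %d of %d SNPs retained",
                    config$p_threshold, nrow(cand), nrow(sumstats)))
  }
  clumped <- if (nrow(cand) > 0) ld_clump(cand, ld, config) else cand
  if (verbose) {
    message(sprintf("LD clumping (r2 < %g, %g kb): %d SNPs retained",
                    config$clump_r2, config$clump_window_kb, nrow(clumped)))
  }
  clumped$f_stat <- if (nrow(clumped) > 0) {
    compute_f_stat(clumped$beta, clumped$se)
  } else {
    numeric(0)
  }
  out <- clumped[clumped$f_stat > config$f_min, , drop = FALSE]
  if (verbose) {
    message(sprintf("instrument-strength filter (F > %g): %d SNPs retained",
                    config$f_min, nrow(out)))
  }
  if (nrow(out) == 0) {
    stop("no instruments survive selection; estimators require at least one SNP",
         call. = FALSE)
  }
  rownames(out) <- NULL
  out
}

#' Select cis-eQTL instruments for a gene-expression exposure
#'
#' Restricts eQTL summary statistics to the cis window (`cis_window_bp` on
#' either side of the gene), applies the significance filter, prunes by the
#' greedy rule at the eQTL LD cap `eqtl_r2` (no distance window), and applies
#' the F-statistic filter.
#'
#' @inheritParams select_instruments
#' @param eqtl_stats Validated eQTL summary statistics for the gene.
#' @param gene_chrom Chromosome label of the gene.
#' @param gene_start,gene_end 1-based gene interval bounds.
#' @return The retained rows with an `f_stat` column appended.
#' @export
select_cis_eqtls <- function(eqtl_stats, gene_chrom, gene_start, gene_end,
                             ld, config = selection_config(), verbose = TRUE) {
  stopifnot(gene_start <= gene_end)
  eqtl_stats <- validate_sumstats(eqtl_stats)
  lo <- gene_start - config$cis_window_bp
  hi <- gene_end + config$cis_window_bp
  cis <- eqtl_stats[eqtl_stats$chrom == as.character(gene_chrom) &
                      eqtl_stats$pos >= lo & eqtl_stats$pos <= hi, , drop = FALSE]
  if (verbose) {
    message(sprintf("cis window [%d, %d] on chr%s: %d of %d SNPs retained",
                    as.integer(max(lo, 1)), as.integer(hi), gene_chrom,
                    nrow(cis), nrow(eqtl_stats)))
  }
  cand <- cis[cis$pval < config$p_threshold, , drop = FALSE]
  pruned <- if (nrow(cand) > 0) {
    .greedy_clump(cand, ld, config$eqtl_r2, Inf)
  } else {
    cand
  }
  if (verbose) {
    message(sprintf("significance + LD pruning (r2 < %g): %d SNPs retained",
                    config$eqtl_r2, nrow(pruned)))
  }
  pruned$f_stat <- if (nrow(pruned) > 0) {
    compute_f_stat(pruned$beta, pruned$se)
  } else {
    numeric(0)
  }
  out <- pruned[pruned$f_stat > config$f_min, , drop = FALSE]
  if (nrow(out) == 0) {
    stop("no cis-eQTL instruments survive selection", call. = FALSE)
  }
  rownames(out) <- NULL
  out
}
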