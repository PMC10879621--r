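#' Structural truth for a simulated mediation study
#'
#' Holds the generating parameters of the two-step mediation structural
#' model: `a` (exposure on mediator), `b` (mediator on outcome), and the
#' direct effect `c_prime`, from which the total effect
#' `c = c_prime + a * b` and the true proportion mediated `a*b/c` follow.
#' All traits are standardized (unit variance), so effects are in SD units.
#'
#' @param a_true Exposure-mediator structural effect. Default 0.4.
#' @param b_true Mediator-outcome structural effect. Default 0.5.
#' @param c_prime_true Direct exposure-outcome effect. Default 0.3.
#' @param n_exp,n_med,n_out Sample sizes of the exposure, mediator
#'   (expression), and outcome studies. Default 50000 each.
#' @param j_exp,j_med Instrument counts for the exposure and the mediator
#'   (cis-eQTL) loci. Defaults 30 and 10.
#' @param pleiotropy_mean,pleiotropy_sd Mean and SD of the direct
#'   (pleiotropic) effects of exposure SNPs on the outcome; mean 0 gives
#'   balanced pleiotropy. Defaults 0 and 0.02.
#' @param seed Integer seed driving every random draw of the generator.
#' @return A list of class `simulation_truth` including the derived `c_true`
#'   and `proportion_true`.
#' @export
simulation_truth <- function(a_true = 0.4, b_true = 0.5, c_prime_true = 0.3,
                             n_exp = 50000, n_med = 50000, n_out = 50000,
                             j_exp = 30, j_med = 10,
                             pleiotropy_mean = 0, pleiotropy_sd = 0.02,
                             seed = 1) {
  stopifnot(n_exp > 0, n_med > 0, n_out > 0, j_exp >= 1, j_med >= 1,
            pleiotropy_sd >= 0)
  structure(list(a_true = a_true, b_true = b_true,
                 c_prime_true = c_prime_true,
                 c_true = c_prime_true + a_true * b_true,
                 proportion_true = if (c_prime_true + a_true * b_true != 0) {
                   a_true * b_true / (c_prime_true + a_true * b_true)
                 } else {
                   NA_real_
                 },
                 n_exp = n_exp, n_med = n_med, n_out = n_out,
                 j_exp = as.integer(j_exp), j_med = as.integer(j_med),
                 pleiotropy_mean = pleiotropy_mean,
                 pleiotropy_sd = pleiotropy_sd,
                 seed = as.integer(seed)),
            class = "simulation_truth")
}

#' Block-diagonal LD matrix
#'
#' Constant r-squared `within_r2` inside each block, zero across blocks, and
#' a unit diagonal; positive semi-definite by construction for
#' `within_r2 < 1`. The structure is fully determined by its arguments;
#' `seed` is accepted for interface symmetry with the other generators.
#'
#' @param n_snps Total number of SNPs.
#' @param block_sizes Integer vector partitioning `n_snps`.
#' @param within_r2 Off-diagonal r-squared within blocks, in \[0, 1).
#' @param seed Unused; present for a uniform generator interface.
#' @param snp_ids Optional identifiers (default `snp1..snpN`).
#' @return A validated LD matrix.
#' @export
simulate_ld_matrix <- function(n_snps, block_sizes, within_r2, seed = NULL,
                               snp_ids = NULL) {
  if (sum(block_sizes) != n_snps) {
    stop("block_sizes must partition n_snps", call. = FALSE)
  }
  if (within_r2 < 0 || within_r2 >= 1) {
    stop("within_r2 must lie in [0, 1)", call. = FALSE)
  }
  if (is.null(snp_ids)) snp_ids <- paste0("snp", seq_len(n_snps))
  stopifnot(length(snp_ids) == n_snps)
  m <- matrix(0, n_snps, n_snps, dimnames = list(snp_ids, snp_ids))
  start <- 1L
  for (bs in block_sizes) {
    idx <- start:(start + bs - 1L)
    m[idx, idx] <- within_r2
    start <- start + as.integer(bs)
  }
  diag(m) <- 1
  m
}

# Allele pairs: palindromic SNPs get an A/T or C/G pair; others a random
# non-palindromic ordered pair.
.draw_alleles <- function(n, palindromic_fraction) {
  bases <- c("A", "C", "G", "T")
  pal_pairs <- list(c("A", "T"), c("T", "A"), c("C", "G"), c("G", "C"))
  is_pal <- runif(n) < palindromic_fraction
  a1 <- character(n); a2 <- character(n)
  for (i in seq_len(n)) {
    if (is_pal[i]) {
      p <- pal_pairs[[sample.int(4, 1)]]
    } else {
      repeat {
        p <- sample(bases, 2)
        if (p[2] != .complement(p[1])) break
      }
    }
    a1[i] <- p[1]; a2[i] <- p[2]
  }
  data.frame(effect_allele = a1, other_allele = a2, stringsAsFactors = FALSE)
}

.make_records <- function(snp_id, chrom, pos, alleles, eaf, true_beta, maf, n) {
  se <- 1 / sqrt(2 * maf * (1 - maf) * n)
  beta <- rnorm(length(true_beta), true_beta, se)
  data.frame(snp_id = snp_id, chrom = chrom, pos = as.integer(pos),
             effect_allele = alleles$effect_allele,
             other_allele = alleles$other_allele,
             eaf = eaf, beta = beta, se = se,
             pval = pmax(2 * pnorm(-abs(beta / se)), .Machine$double.xmin),
             n = n, stringsAsFactors = FALSE)
}

# Scale raw effect draws so the instruments jointly explain r2_target of a
# standardized trait's variance: sum(2 p (1-p) gamma^2) = r2_target.
.scale_to_r2 <- function(raw, maf, r2_target) {
  if (r2_target <= 0 || r2_target >= 1) {
    stop("instrument variance-explained target must lie in (0, 1)", call. = FALSE)
  }
  raw * sqrt(r2_target / sum(2 * maf * (1 - maf) * raw^2))
}

#' Simulate a summary-level mediation study
#'
#' Generates GWAS/eQTL summary statistics for the full two-step design with
#' known structural truth. Three disjoint SNP sets are created: exposure
#' instruments (true effects `gamma_j` on the exposure, scaled so they
#' jointly explain `r2_exposure` of trait variance), cis-eQTL instruments
#' for the mediator (effects `delta_k`, positions inside the declared gene
#' window), and outcome-specific instruments (effects on the outcome only,
#' enabling reverse-direction MR). Per-SNP standard errors follow the
#' standardized-trait formula `se = (2 p (1-p) n)^(-1/2)` and observed
#' effects are drawn from normals around the structural expectations:
#' exposure SNPs affect the mediator through `a_true * gamma_j` and the
#' outcome through `c_true * gamma_j` plus a per-SNP pleiotropic effect
#' `alpha_j ~ N(pleiotropy_mean, pleiotropy_sd^2)`; eQTL SNPs affect the
#' outcome through `b_true * delta_k`.
#'
#' A configurable fraction of outcome records is perturbed by allele swaps
#' and strand complementation (with the matching sign/frequency changes), and
#' a fraction of SNPs is palindromic, so harmonization has real work to do on
#' every simulated bundle.
#'
#' @param truth A [simulation_truth()].
#' @param j_out Number of outcome-specific instruments (default 10).
#' @param r2_exposure,r2_eqtl,r2_outcome Variance in the respective trait
#'   jointly explained by each instrument set. Defaults 0.10, 0.05, 0.05.
#' @param ld_block_size SNPs per LD block within each set (default 1:
#'   independent instruments).
#' @param within_r2 r-squared inside LD blocks (default 0).
#' @param perturb_fraction Fraction of outcome records with allele
#'   swap/complement perturbations (default 0.2).
#' @param palindromic_fraction Fraction of palindromic SNPs (default 0.1).
#' @param eaf_noise_sd SD of cross-study allele-frequency noise (default
#'   0.005).
#' @param gene Gene locus for the mediator, a list with `chrom`, `start`,
#'   `end`.
#' @return A list of class `mr_sim_study`: `exposure`, `mediator`,
#'   `outcome`, `eqtl` summary-statistics tables, the combined `ld` matrix,
#'   the `gene` locus, and the `truth`.
#' @export
simulate_mediation_study <- function(truth = simulation_truth(),
                                     j_out = 10,
                                     r2_exposure = 0.10, r2_eqtl = 0.05,
                                     r2_outcome = 0.05,
                                     ld_block_size = 1, within_r2 = 0,
                                     perturb_fraction = 0.2,
                                     palindromic_fraction = 0.1,
                                     eaf_noise_sd = 0.005,
                                     gene = list(chrom = "9",
                                                 start = 97500000,
                                                 end = 97600000)) {
  stopifnot(inherits(truth, "simulation_truth"), j_out >= 0)
  with_seed(truth$seed, {
    je <- truth$j_exp; jm <- truth$j_med; jo <- j_out
    ids_e <- sprintf("rs1%05d", seq_len(je))
    ids_g <- sprintf("rs3%05d", seq_len(jm))
    ids_o <- if (jo > 0) sprintf("rs2%05d", seq_len(jo)) else character(0)

    # positions: exposure/outcome SNPs tile autosomes (block members 5 kb
    # apart, blocks far apart); eQTL SNPs sit inside the cis window
    block_of <- function(n) ceiling(seq_len(n) / ld_block_size)
    place <- function(n, chrom_offset) {
      bl <- block_of(n)
      within <- seq_len(n) - (bl - 1L) * ld_block_size
      chrom <- as.character(((bl - 1L + chrom_offset) %% 22L) + 1L)
      pos <- (((bl - 1L) %/% 22L) + 1L) * 50000000L + within * 5000L
      list(chrom = chrom, pos = pos, blocks = tabulate(bl))
    }
    loc_e <- place(je, 0L)
    loc_o <- if (jo > 0) place(jo, 11L) else list(chrom = character(0), pos = integer(0), blocks = integer(0))
    pos_g <- sort(as.integer(round(runif(jm, gene$start - 5e5, gene$end + 5e5))))

    maf_e <- runif(je, 0.05, 0.5)
    maf_g <- runif(jm, 0.05, 0.5)
    maf_o <- if (jo > 0) runif(jo, 0.05, 0.5) else numeric(0)

    gamma <- .scale_to_r2(rnorm(je), maf_e, r2_exposure)
    delta <- .scale_to_r2(rnorm(jm), maf_g, r2_eqtl)
    omega <- if (jo > 0) .scale_to_r2(rnorm(jo), maf_o, r2_outcome) else numeric(0)
    alpha <- rnorm(je, truth$pleiotropy_mean, truth$pleiotropy_sd)

    al_e <- .draw_alleles(je, palindromic_fraction)
    al_g <- .draw_alleles(jm, palindromic_fraction)
    al_o <- .draw_alleles(jo, palindromic_fraction)

    ids <- c(ids_e, ids_g, ids_o)
    chrom <- c(loc_e$chrom, rep(gene$chrom, jm), loc_o$chrom)
    pos <- c(loc_e$pos, pos_g, loc_o$pos)
    alleles <- rbind(al_e, al_g, al_o)
    maf <- c(maf_e, maf_g, maf_o)
    J <- length(ids)

    noisy_eaf <- function() pmin(0.99, pmax(0.01, maf + rnorm(J, 0, eaf_noise_sd)))

    true_on_exposure <- c(gamma, rep(0, jm), rep(0, jo))
    true_on_mediator <- c(truth$a_true * gamma, delta, rep(0, jo))
    true_on_outcome <- c(truth$c_true * gamma + alpha,
                         truth$b_true * delta, omega)

    exposure <- .make_records(ids, chrom, pos, alleles, maf,
                              true_on_exposure, maf, truth$n_exp)
    mediator <- .make_records(ids, chrom, pos, alleles, noisy_eaf(),
                              true_on_mediator, maf, truth$n_med)
    outcome <- .make_records(ids, chrom, pos, alleles, noisy_eaf(),
                             true_on_outcome, maf, truth$n_out)

    # allele-representation perturbations on the outcome study
    perturbed <- which(runif(J) < perturb_fraction)
    for (i in perturbed) {
      kind <- sample(c("swap", "complement", "swap_complement"), 1)
      if (kind %in% c("swap", "swap_complement")) {
        tmp <- outcome$effect_allele[i]
        outcome$effect_allele[i] <- outcome$other_allele[i]
        outcome$other_allele[i] <- tmp
        outcome$beta[i] <- -outcome$beta[i]
        outcome$eaf[i] <- 1 - outcome$eaf[i]
      }
      if (kind %in% c("complement", "swap_complement")) {
        outcome$effect_allele[i] <- .complement(outcome$effect_allele[i])
        outcome$other_allele[i] <- .complement(outcome$other_allele[i])
      }
    }

    eqtl <- mediator[mediator$snp_id %in% ids_g, , drop = FALSE]
    rownames(eqtl) <- NULL

    ld <- simulate_ld_matrix(J, c(loc_e$blocks, tabulate(block_of(jm)),
                                  loc_o$blocks),
                             within_r2, snp_ids = ids)

    structure(list(exposure = exposure, mediator = mediator,
                   outcome = outcome, eqtl = eqtl, ld = ld,
                   gene = gene, truth = truth,
                   params = list(j_out = jo, r2_exposure = r2_exposure,
                                 r2_eqtl = r2_eqtl, r2_outcome = r2_outcome,
                                 ld_block_size = ld_block_size,
                                 within_r2 = within_r2,
                                 perturb_fraction = perturb_fraction,
                                 palindromic_fraction = palindromic_fraction,
                                 eaf_noise_sd = eaf_noise_sd)),
              class = "mr_sim_study")
  })
}

#' Displace one SNP's effect estimate
#'
#' Shifts the chosen SNP's `beta` by `shift_in_ses` multiples of its
#' standard error, leaving every other field unchanged - a planted outlier
#' for pleiotropy-diagnostic tests.
#'
#' @param sumstats Summary-statistics table.
#' @param snp_id Identifier of the SNP to displace.
#' @param shift_in_ses Shift in units of the SNP's standard error.
#' @return The modified table.
#' @export
inject_outlier <- function(sumstats, snp_id, shift_in_ses) {
  i <- match(snp_id, sumstats$snp_id)
  if (is.na(i)) stop("SNP not found: ", snp_id, call. = FALSE)
  sumstats$beta[i] <- sumstats$beta[i] + shift_in_ses * sumstats$se[i]
  sumstats
}
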