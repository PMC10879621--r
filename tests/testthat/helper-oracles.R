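# Independent oracles and table generators used across the suite. These
# deliberately take different computational routes from the package code
# (lm fits, explicit normal equations, naive scans) so agreement is evidence,
# not tautology.

# A harmonized-style table built directly (no harmonization involved).
random_table <- function(J, seed, theta = 0.5, se_exp = 0.02, se_out = 0.05,
                         het_sd = 0) {
  set.seed(seed)
  bexp_true <- runif(J, 0.1, 0.5)
  bexp <- rnorm(J, bexp_true, se_exp)
  bout <- rnorm(J, theta * bexp_true + rnorm(J, 0, het_sd), se_out)
  data.frame(snp_id = paste0("s", seq_len(J)),
             beta_exp = bexp, se_exp = se_exp,
             beta_out = bout, se_out = se_out,
             stringsAsFactors = FALSE)
}

# Homogeneous no-effect table: outcome effects are pure noise around zero,
# exposure effects essentially noise-free, so Q is exactly chi-square and the
# fixed-effect IVW sampling distribution is exactly normal with known se.
null_table <- function(J, theta = 0) {
  bexp <- runif(J, 0.2, 0.6)
  se_out <- runif(J, 0.03, 0.08)
  data.frame(snp_id = paste0("s", seq_len(J)),
             beta_exp = bexp, se_exp = 1e-6,
             beta_out = rnorm(J, theta * bexp, se_out), se_out = se_out,
             stringsAsFactors = FALSE)
}

# Weighted least squares of beta_out on beta_exp through the origin with
# weights se_out^-2, via lm(); the known-variance slope se is the lm se
# divided by the residual scale.
ivw_wls_oracle <- function(table) {
  fit <- lm(beta_out ~ 0 + beta_exp, data = table, weights = table$se_out^-2)
  s <- summary(fit)
  list(beta = unname(coef(fit)[1]),
       se_fixed = unname(s$coefficients[1, 2] / s$sigma))
}

# MR-Egger by explicit weighted normal equations after orienting each SNP to
# a non-negative exposure effect.
egger_normal_eq_oracle <- function(table) {
  s <- ifelse(table$beta_exp < 0, -1, 1)
  bx <- table$beta_exp * s
  by <- table$beta_out * s
  w <- table$se_out^-2
  X <- cbind(1, bx)
  XtWX <- t(X) %*% (w * X)
  coefs <- solve(XtWX, t(X) %*% (w * by))
  resid <- by - X %*% coefs
  J <- nrow(table)
  sigma2 <- sum(w * resid^2) / (J - 2)
  ses <- unname(sqrt(max(1, sigma2) * diag(solve(XtWX))))
  list(intercept = unname(coefs[1]), slope = unname(coefs[2]),
       se_intercept = ses[1], se_slope = ses[2])
}

# Naive restatement of the greedy clumping rule: repeatedly scan the
# p-sorted list, retain the best remaining SNP, and delete conflicting SNPs,
# recomputing everything from the definitions at each step.
clump_bruteforce_oracle <- function(candidates, ld, r2_threshold, window_bp) {
  remaining <- candidates
  retained_ids <- character(0)
  while (nrow(remaining) > 0) {
    ord <- order(remaining$pval, remaining$pos, remaining$snp_id)
    best <- remaining[ord[1], ]
    retained_ids <- c(retained_ids, best$snp_id)
    conflict <- vapply(seq_len(nrow(remaining)), function(i) {
      row <- remaining[i, ]
      if (row$snp_id == best$snp_id) return(TRUE)
      same_chrom <- row$chrom == best$chrom
      close <- abs(row$pos - best$pos) <= window_bp
      linked <- ld[best$snp_id, row$snp_id] >= r2_threshold
      if (is.finite(window_bp)) same_chrom && close && linked else linked
    }, logical(1))
    remaining <- remaining[!conflict, , drop = FALSE]
  }
  candidates[candidates$snp_id %in% retained_ids, , drop = FALSE]
}

# Random clumping instance: positions sometimes inside the window, arbitrary
# symmetric r2, occasional p-value ties to exercise the tie-break.
random_clump_instance <- function(n, tie_prob = 0.2) {
  ids <- paste0("rs", seq_len(n))
  p <- signif(runif(n, 1e-10, 1e-4), 2)
  if (n >= 2 && runif(1) < tie_prob) p[2] <- p[1]
  m <- matrix(runif(n * n), n, n)
  m <- (m + t(m)) / 2
  diag(m) <- 1
  dimnames(m) <- list(ids, ids)
  data.frame(snp_id = ids, chrom = sample(c("1", "2"), n, replace = TRUE),
             pos = sample.int(60000, n), effect_allele = "A",
             other_allele = "G", eaf = 0.3, beta = 0.1, se = 0.01,
             pval = p, n = 10000, stringsAsFactors = FALSE) -> df
  list(candidates = df, ld = m)
}

# A minimal valid sumstats data.frame for io tests.
make_sumstats <- function(n = 3, seed = 1) {
  set.seed(seed)
  data.frame(snp_id = paste0("rs", seq_len(n)),
             chrom = as.character(sample(1:22, n, replace = TRUE)),
             pos = sample.int(1e8, n),
             effect_allele = sample(c("A", "C"), n, replace = TRUE),
             other_allele = sample(c("G", "T"), n, replace = TRUE),
             eaf = round(runif(n, 0.05, 0.95), 4),
             beta = round(rnorm(n, 0, 0.1), 6),
             se = round(runif(n, 0.01, 0.05), 6),
             pval = signif(runif(n, 1e-9, 0.9), 4),
             n = sample.int(1e5, n), stringsAsFactors = FALSE)
}
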