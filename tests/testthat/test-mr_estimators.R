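test_that("Wald ratio arithmetic, both error orders, and zero handling", {
  r <- wald_ratio(0.1, 0.02, 0.2, 0.05)
  expect_equal(r$ratio, 2.0)
  expect_equal(r$se_ratio, 0.5)
  expect_equal(r$weight, 4.0)

  r2 <- wald_ratio(0.1, 0.02, 0.2, 0.05, order = "second")
  expect_equal(r2$se_ratio, sqrt(0.25 + 0.16))

  r0 <- wald_ratio(0.1, 0.02, 0, 0.05)
  expect_equal(r0$ratio, 0)
  expect_equal(r0$se_ratio, 0.5)

  expect_error(wald_ratio(c(0.1, 0), c(0.02, 0.02), c(0.2, 0.1),
                          c(0.05, 0.05), snp_id = c("rsA", "rsB")),
               "rsB")
})

test_that("IVW degenerate cases: single SNP and equal weights", {
  one <- data.frame(beta_exp = 0.1, se_exp = 0.02, beta_out = 0.2,
                    se_out = 0.05)
  fit <- mr_ivw(one)
  expect_equal(fit$beta, 2.0)
  expect_equal(fit$se, 0.5)
  expect_equal(fit$n_snps, 1L)

  eq <- data.frame(beta_exp = 1, se_exp = 0.001,
                   beta_out = c(0.5, 1.0, 1.5), se_out = 0.5)
  fit <- mr_ivw(eq)
  expect_equal(fit$beta, 1.0)                   # equal weights: plain mean
  expect_equal(fit$extra$q, 2.0)
  expect_equal(fit$extra$se_fixed, 1 / sqrt(12))
  expect_equal(fit$se, 1 / sqrt(12))            # Q/(J-1) = 1: no inflation
  expect_equal(mr_ivw(eq, model = "fixed")$se, 1 / sqrt(12))
})

test_that("IVW equals origin-constrained WLS and Egger equals the normal equations", {
  for (seed in 1:30) {
    tab <- random_table(J = sample(3:25, 1), seed = seed,
                        theta = runif(1, -1, 1), het_sd = runif(1, 0, 0.1))
    wls <- ivw_wls_oracle(tab)
    fit <- mr_ivw(tab)
    expect_equal(fit$beta, wls$beta, tolerance = 1e-10)
    expect_equal(fit$extra$se_fixed, wls$se_fixed, tolerance = 1e-10)

    if (nrow(tab) >= 3) {
      ne <- egger_normal_eq_oracle(tab)
      eg <- mr_egger(tab)
      expect_equal(eg$beta, ne$slope, tolerance = 1e-10)
      expect_equal(eg$extra$intercept, ne$intercept, tolerance = 1e-10)
      expect_equal(eg$se, ne$se_slope, tolerance = 1e-10)
      expect_equal(eg$extra$intercept_se, ne$se_intercept, tolerance = 1e-10)
    }
  }
})

test_that("Egger reproduces exact lines", {
  line1 <- data.frame(beta_exp = 1:3, se_exp = 0.01,
                      beta_out = 1:3, se_out = 0.1)
  fit <- mr_egger(line1)
  expect_equal(fit$beta, 1, tolerance = 1e-12)
  expect_equal(fit$extra$intercept, 0, tolerance = 1e-12)

  line2 <- data.frame(beta_exp = 1:3, se_exp = 0.01,
                      beta_out = c(1, 3, 5), se_out = 0.1)
  fit <- mr_egger(line2)
  expect_equal(fit$beta, 2, tolerance = 1e-12)
  expect_equal(fit$extra$intercept, -1, tolerance = 1e-12)
  expect_equal(fit$extra$rss_w, 0, tolerance = 1e-12)
})

test_that("weighted median: exact median, constant case, breakdown robustness", {
  eq <- data.frame(beta_exp = 1, se_exp = 1e-6,
                   beta_out = c(1, 2, 5), se_out = 1)
  fit <- mr_weighted_median(eq, n_boot = 100, seed = 1)
  expect_equal(fit$beta, 2.0)

  const <- data.frame(beta_exp = 1, se_exp = 1e-4,
                      beta_out = 0.7, se_out = 0.01)[rep(1, 4), ]
  fit <- mr_weighted_median(const, n_boot = 100, seed = 1)
  expect_equal(fit$beta, 0.7)
  expect_gt(fit$se, 0)
  expect_lt(fit$se, 0.05)

  # 7 valid SNPs (ratio 0.5) carry 70% of weight, 3 invalid at ratio 3.
  # With ratio noise sigma the estimate targets the valid cluster's 0.5/0.7
  # quantile, an offset of about qnorm(0.5/0.7) * sigma that vanishes as
  # sigma -> 0; the estimate must sit at the valid value, not be dragged
  # toward the invalid one.
  breakdown_mean <- function(sigma, n_rep) {
    mean(replicate(n_rep, {
      tab <- data.frame(beta_exp = 1, se_exp = 0.001,
                        beta_out = rnorm(10, c(rep(0.5, 7), rep(3, 3)), sigma),
                        se_out = sigma)
      mr_weighted_median(tab, n_boot = 2, seed = 1)$beta
    }))
  }
  set.seed(99)
  offset <- qnorm(0.5 / 0.7)
  m_coarse <- breakdown_mean(0.10, 60)
  m_fine <- breakdown_mean(0.02, 60)
  expect_lt(abs(m_coarse - 0.5), offset * 0.10 + 0.03)
  expect_lt(abs(m_fine - 0.5), offset * 0.02 + 0.01)
  expect_lt(abs(m_fine - 0.5), abs(m_coarse - 0.5) + 0.005)
})

test_that("mode estimators: dominant atom, symmetry, planted bimodality", {
  atom <- data.frame(beta_exp = 1, se_exp = 1e-4,
                     beta_out = c(0.5, 0.5, 0.5, 4.0), se_out = 0.1)
  fit <- mr_mode(atom, n_boot = 50, seed = 2)
  expect_lt(abs(fit$beta - 0.5), 0.1)

  sym <- data.frame(beta_exp = 1, se_exp = 1e-4,
                    beta_out = c(-1, 0, 1), se_out = 0.1)
  fit <- mr_mode(sym, n_boot = 50, seed = 2)
  expect_lt(abs(fit$beta), 0.03)   # within a grid step of 0

  # 60% of ratios near 0.4, 40% near 2.0: simple mode finds the major cluster
  set.seed(5)
  tab <- data.frame(beta_exp = 1, se_exp = 0.01,
                    beta_out = c(rnorm(12, 0.4, 0.05), rnorm(8, 2.0, 0.05)),
                    se_out = 0.05)
  fit <- mr_mode(tab, n_boot = 20, seed = 3)
  expect_lt(abs(fit$beta - 0.4), 0.15)
})

test_that("SMR statistic: plug-in value, strong-instrument limit, null case", {
  fit <- mr_smr(list(beta = 0.5, se = 0.05), list(beta = 0.1, se = 0.02))
  expect_equal(fit$beta, 0.2)
  expect_equal(fit$extra$t_smr, 20)
  expect_equal(fit$se, 0.2 / sqrt(20), tolerance = 1e-12)

  # z_eqtl -> infinity: T -> z_gwas^2, se -> first-order Wald ratio se
  lim <- mr_smr(list(beta = 0.5, se = 1e-9), list(beta = 0.1, se = 0.02))
  expect_equal(lim$extra$t_smr, 25, tolerance = 1e-6)
  expect_equal(lim$se, 0.02 / 0.5, tolerance = 1e-6)

  null <- mr_smr(list(beta = 0.5, se = 0.05), list(beta = 0, se = 0.02))
  expect_equal(null$beta, 0)
  expect_equal(null$extra$t_smr, 0)
  expect_equal(null$pval, 1)

  expect_error(mr_smr(list(beta = 0, se = 0.05), list(beta = 0.1, se = 0.02)),
               "zero eQTL effect")
})

test_that("estimators are scale-equivariant in the exposure effects", {
  tab <- random_table(J = 12, seed = 77, theta = 0.4, het_sd = 0.05)
  k <- 2.5
  scaled <- tab
  scaled$beta_exp <- tab$beta_exp * k
  scaled$se_exp <- tab$se_exp * k
  expect_equal(mr_ivw(scaled)$beta, mr_ivw(tab)$beta / k, tolerance = 1e-10)
  expect_equal(mr_weighted_median(scaled, n_boot = 2, seed = 1)$beta,
               mr_weighted_median(tab, n_boot = 2, seed = 1)$beta / k,
               tolerance = 1e-10)
  expect_equal(mr_mode(scaled, n_boot = 2, seed = 1)$beta,
               mr_mode(tab, n_boot = 2, seed = 1)$beta / k, tolerance = 1e-8)
  # Egger: a global negative rescaling flips every SNP's orientation, which
  # mirrors both axes - the slope divides by the signed k, the intercept
  # negates
  neg <- tab
  neg$beta_exp <- tab$beta_exp * (-2)
  neg$se_exp <- tab$se_exp * 2
  expect_equal(mr_egger(neg)$beta, mr_egger(tab)$beta / (-2), tolerance = 1e-10)
  expect_equal(mr_egger(neg)$extra$intercept, -mr_egger(tab)$extra$intercept,
               tolerance = 1e-10)
})

test_that("estimators enforce their minimum instrument counts", {
  two <- random_table(J = 2, seed = 1)
  expect_error(mr_egger(two), "at least 3")
  expect_error(mr_weighted_median(two, seed = 1), "at least 3")
  expect_error(mr_mode(two, seed = 1), "at least 3")
  empty <- random_table(J = 3, seed = 1)[0, ]
  expect_error(mr_ivw(empty), "no instruments")
})

test_that("unbiasedness under a no-pleiotropy simulation with strong instruments", {
  # true effect theta; all five estimators' mean within 3 MC SEs
  theta <- 0.3
  set.seed(314)
  ests <- replicate(120, {
    J <- 15
    gamma <- runif(J, 0.15, 0.4)
    tab <- data.frame(beta_exp = rnorm(J, gamma, 0.01), se_exp = 0.01,
                      beta_out = rnorm(J, theta * gamma, 0.02), se_out = 0.02)
    c(mr_ivw(tab)$beta, mr_egger(tab)$beta,
      mr_weighted_median(tab, n_boot = 2, seed = 1)$beta,
      mr_mode(tab, n_boot = 2, seed = 1)$beta,
      mr_mode(tab, weighted = TRUE, n_boot = 2, seed = 1)$beta)
  })
  for (i in 1:5) {
    mc_se <- sd(ests[i, ]) / sqrt(ncol(ests))
    expect_lt(abs(mean(ests[i, ]) - theta), 3 * mc_se + 0.01)
  }
})
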