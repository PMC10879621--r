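test_that("F-statistic is the squared Wald z and drives the strength filter", {
  expect_equal(compute_f_stat(0.1, 0.01), 100)
  expect_equal(compute_f_stat(0, 0.5), 0)
  f_weak <- compute_f_stat(0.05, 0.016)
  expect_lt(f_weak, 10)
  expect_gt(f_weak, 9.7)

  # the weak SNP is dropped by select_instruments, the strong one retained
  df <- make_sumstats(2, seed = 9)
  df$beta <- c(0.05, 0.1)
  df$se <- c(0.016, 0.01)
  df$pval <- c(1e-8, 1e-8)
  df$chrom <- c("1", "2")
  ld <- diag(2)
  dimnames(ld) <- list(df$snp_id, df$snp_id)
  out <- select_instruments(df, ld, verbose = FALSE)
  expect_identical(out$snp_id, df$snp_id[2])
  expect_equal(out$f_stat, 100)
})

test_that("clumping honours the r2 threshold and the distance window", {
  base <- make_sumstats(2, seed = 4)
  base$chrom <- "1"
  ld <- matrix(c(1, 0.5, 0.5, 1), 2, dimnames = list(base$snp_id, base$snp_id))

  near <- base
  near$pos <- c(100000L, 110000L)  # 10 kb apart
  near$pval <- c(1e-8, 1e-6)
  kept <- ld_clump(near, ld, selection_config())
  expect_identical(kept$snp_id, base$snp_id[1])

  far <- near
  far$pos <- c(100000L, 150000L)  # 50 kb apart, outside the 30 kb window
  expect_identical(ld_clump(far, ld, selection_config())$snp_id, base$snp_id)

  # candidate missing from the LD matrix is a named error
  expect_error(ld_clump(near, ld[1, 1, drop = FALSE], selection_config()),
               near$snp_id[2])
})

test_that("greedy clumping matches a naive restatement of the rule", {
  cfg <- selection_config()
  set.seed(42)
  for (n in 2:8) {
    for (rep in 1:40) {
      inst <- random_clump_instance(n)
      mine <- ld_clump(inst$candidates, inst$ld, cfg)
      oracle <- clump_bruteforce_oracle(inst$candidates, inst$ld,
                                        cfg$clump_r2,
                                        cfg$clump_window_kb * 1000)
      expect_identical(mine$snp_id, oracle$snp_id)
    }
  }
})

test_that("no retained pair is simultaneously within-window and linked", {
  cfg <- selection_config(clump_r2 = 0.3, clump_window_kb = 20)
  set.seed(11)
  for (rep in 1:30) {
    inst <- random_clump_instance(7)
    kept <- ld_clump(inst$candidates, inst$ld, cfg)
    if (nrow(kept) < 2) next
    pairs <- utils::combn(seq_len(nrow(kept)), 2)
    for (k in seq_len(ncol(pairs))) {
      i <- pairs[1, k]; j <- pairs[2, k]
      incompatible <- kept$chrom[i] == kept$chrom[j] &&
        abs(kept$pos[i] - kept$pos[j]) <= 20000 &&
        inst$ld[kept$snp_id[i], kept$snp_id[j]] >= 0.3
      expect_false(incompatible)
    }
  }
})

test_that("selection pipeline: threshold monotonicity and hand-enumerated panel", {
  # nothing significant -> explicit error
  dull <- make_sumstats(10, seed = 5)
  dull$pval <- 0.5
  ld <- diag(10)
  dimnames(ld) <- list(dull$snp_id, dull$snp_id)
  expect_error(select_instruments(dull, ld, verbose = FALSE),
               "[Nn]o instruments")

  # singleton survives
  one <- make_sumstats(1)
  one$pval <- 1e-9
  one$beta <- 0.1
  one$se <- 0.01
  ld1 <- matrix(1, 1, 1, dimnames = list(one$snp_id, one$snp_id))
  expect_identical(select_instruments(one, ld1, verbose = FALSE)$snp_id,
                   one$snp_id)

  # planted panel: strong (keep), weak-F (drop), linked pair (keep best),
  # non-significant (drop), distant linked (keep)
  panel <- data.frame(
    snp_id = paste0("rs", 1:6), chrom = "1",
    pos = c(1e5, 2e6, 2e6 + 1e4, 4e6, 4e6 + 5e4, 8e6),
    effect_allele = "A", other_allele = "G", eaf = 0.3,
    beta = c(0.10, 0.10, 0.10, 0.10, 0.10, 0.03),
    se = c(0.010, 0.010, 0.012, 0.010, 0.011, 0.010),
    pval = c(1e-9, 1e-9, 1e-7, 1e-8, 1e-7, 1e-6),
    n = 50000, stringsAsFactors = FALSE)
  ldp <- diag(6)
  dimnames(ldp) <- list(panel$snp_id, panel$snp_id)
  ldp["rs2", "rs3"] <- ldp["rs3", "rs2"] <- 0.8  # 10 kb apart: clumped
  ldp["rs4", "rs5"] <- ldp["rs5", "rs4"] <- 0.8  # 50 kb apart: both stay
  got <- select_instruments(panel, ldp, verbose = FALSE)
  expect_identical(got$snp_id, c("rs1", "rs2", "rs4", "rs5"))

  # loosening the p threshold never shrinks the candidate set
  loose <- sum(panel$pval < 1e-4)
  tight <- sum(panel$pval < 1e-8)
  expect_gte(loose, tight)
})

test_that("cis-eQTL selection applies the window and the looser LD cap", {
  gene_start <- 5e6
  gene_end <- 5.1e6
  eq <- data.frame(
    snp_id = paste0("rs", 1:4), chrom = "9",
    pos = c(gene_start - 1.5e6,        # 1.5 Mb upstream: excluded
            gene_start - 5e5, gene_start - 4.9e5, gene_end + 5e5),
    effect_allele = "C", other_allele = "T", eaf = 0.4,
    beta = 0.2, se = 0.02, pval = c(1e-10, 1e-10, 1e-8, 1e-9),
    n = 30000, stringsAsFactors = FALSE)
  ld <- diag(4)
  dimnames(ld) <- list(eq$snp_id, eq$snp_id)

  ld29 <- ld
  ld29["rs2", "rs3"] <- ld29["rs3", "rs2"] <- 0.29
  got <- select_cis_eqtls(eq, "9", gene_start, gene_end, ld29,
                          verbose = FALSE)
  expect_identical(got$snp_id, c("rs2", "rs3", "rs4"))

  ld31 <- ld
  ld31["rs2", "rs3"] <- ld31["rs3", "rs2"] <- 0.31
  got <- select_cis_eqtls(eq, "9", gene_start, gene_end, ld31,
                          verbose = FALSE)
  expect_identical(got$snp_id, c("rs2", "rs4"))
})
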