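# Build exposure/outcome record pairs sharing snp ids.
h_pair <- function(a1e, a2e, eaf_e, a1o, a2o, eaf_o, beta_o = 0.05) {
  exposure <- data.frame(snp_id = "rs1", chrom = "1", pos = 1000L,
                         effect_allele = a1e, other_allele = a2e,
                         eaf = eaf_e, beta = 0.1, se = 0.01, pval = 1e-8,
                         n = 10000, stringsAsFactors = FALSE)
  outcome <- data.frame(snp_id = "rs1", chrom = "1", pos = 1000L,
                        effect_allele = a1o, other_allele = a2o,
                        eaf = eaf_o, beta = beta_o, se = 0.02, pval = 0.01,
                        n = 20000, stringsAsFactors = FALSE)
  harmonize(exposure, outcome)
}

test_that("allele orientation cases map to the documented actions", {
  swapped <- h_pair("A", "G", 0.3, "G", "A", 0.7)
  expect_identical(swapped$action_taken, "sign_flipped")
  expect_equal(swapped$beta_out, -0.05)
  expect_equal(swapped$eaf_out, 0.3)

  same <- h_pair("A", "G", 0.3, "A", "G", 0.3)
  expect_identical(same$action_taken, "kept")
  expect_equal(same$beta_out, 0.05)

  comp <- h_pair("A", "G", 0.3, "T", "C", 0.3)
  expect_identical(comp$action_taken, "strand_complemented")
  expect_equal(comp$beta_out, 0.05)

  comp_swap <- h_pair("A", "G", 0.3, "C", "T", 0.7)
  expect_identical(comp_swap$action_taken, "sign_flipped_and_complemented")
  expect_equal(comp_swap$beta_out, -0.05)

  mismatch <- h_pair("A", "G", 0.3, "A", "C", 0.3)
  expect_identical(mismatch$action_taken, "dropped_allele_mismatch")
})

test_that("palindromic SNPs are resolved by frequency or dropped", {
  # maximal ambiguity
  amb <- h_pair("A", "T", 0.50, "A", "T", 0.50)
  expect_identical(amb$action_taken, "dropped_palindromic_ambiguous")
  # zone boundary is inclusive
  edge <- h_pair("C", "G", 0.42, "C", "G", 0.20)
  expect_identical(edge$action_taken, "dropped_palindromic_ambiguous")
  # missing frequency warns and drops
  expect_warning(na_eaf <- h_pair("A", "T", NA, "A", "T", 0.2),
                 "missing allele frequency")
  expect_identical(na_eaf$action_taken, "dropped_palindromic_ambiguous")

  # the four unambiguous frequency quadrants enumerate the inference rule
  quadrants <- list(
    list(fe = 0.20, fo = 0.30, action = "kept", beta = 0.05),
    list(fe = 0.20, fo = 0.78, action = "sign_flipped", beta = -0.05),
    list(fe = 0.80, fo = 0.30, action = "sign_flipped", beta = -0.05),
    list(fe = 0.80, fo = 0.70, action = "kept", beta = 0.05))
  for (q in quadrants) {
    got <- h_pair("C", "G", q$fe, "C", "G", q$fo)
    expect_identical(got$action_taken, q$action)
    expect_equal(got$beta_out, q$beta)
  }
  # palindromic exposure pair against a non-matching outcome pair
  expect_identical(h_pair("A", "T", 0.2, "A", "C", 0.2)$action_taken,
                   "dropped_allele_mismatch")
})

# Reconstruct outcome-study records from a harmonized table (aligned
# orientation), for the involution property.
outcome_from_harmonized <- function(tab, n = 20000) {
  t <- tab[!startsWith(tab$action_taken, "dropped"), ]
  data.frame(snp_id = t$snp_id, chrom = t$chrom, pos = t$pos,
             effect_allele = t$effect_allele, other_allele = t$other_allele,
             eaf = t$eaf_out, beta = t$beta_out, se = t$se_out,
             pval = pmax(2 * pnorm(-abs(t$beta_out / t$se_out)), 1e-300),
             n = n, stringsAsFactors = FALSE)
}

test_that("harmonization is an involution and coherent under allele flips", {
  sim <- simulate_mediation_study(simulation_truth(seed = 21))
  ins <- select_instruments(sim$exposure, sim$ld, verbose = FALSE)
  tab <- harmonize(ins, sim$outcome)
  retained <- tab[!startsWith(tab$action_taken, "dropped"), ]
  expect_gt(nrow(retained), 5)

  # involution: harmonizing the already-aligned table keeps everything
  again <- harmonize(ins[ins$snp_id %in% retained$snp_id, ],
                     outcome_from_harmonized(tab))
  expect_true(all(again$action_taken == "kept"))
  expect_equal(again$beta_out, retained$beta_out)
  expect_equal(again$eaf_out, retained$eaf_out)

  # sign coherence: swapping every outcome record's alleles and negating its
  # beta yields the identical harmonized table
  flipped <- sim$outcome
  tmp <- flipped$effect_allele
  flipped$effect_allele <- flipped$other_allele
  flipped$other_allele <- tmp
  flipped$beta <- -flipped$beta
  flipped$eaf <- 1 - flipped$eaf
  tab2 <- harmonize(ins, flipped)
  expect_identical(startsWith(tab2$action_taken, "dropped"),
                   startsWith(tab$action_taken, "dropped"))
  keep2 <- !startsWith(tab$action_taken, "dropped")
  expect_equal(tab2$beta_out[keep2], tab$beta_out[keep2])
  expect_equal(tab2$eaf_out[keep2], tab$eaf_out[keep2])

  # estimator invariance across the flip
  expect_equal(mr_ivw(tab2)$beta, mr_ivw(tab)$beta)
  expect_equal(mr_egger(tab2)$beta, mr_egger(tab)$beta)
  expect_equal(mr_weighted_median(tab2, n_boot = 50, seed = 3)$beta,
               mr_weighted_median(tab, n_boot = 50, seed = 3)$beta)
  expect_equal(mr_mode(tab2, n_boot = 50, seed = 3)$beta,
               mr_mode(tab, n_boot = 50, seed = 3)$beta)
})

test_that("unmatched exposure SNPs are dropped with a message", {
  exposure <- make_sumstats(3, seed = 2)
  outcome <- make_sumstats(3, seed = 2)
  outcome <- outcome[1:2, ]
  expect_message(tab <- harmonize(exposure, outcome), "not found")
  expect_equal(nrow(tab), 2)
  expect_equal(attr(tab, "n_unmatched"), 1L)
})
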