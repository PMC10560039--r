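test_that("significance thresholding keeps exactly the genome-wide hits", {
  exposure <- manual_gwas(sprintf("s%d", 1:5),
                          pval = c(1e-9, 1e-7, 2e-8, 0.01, 4e-8))
  kept <- select_instruments(exposure, ld = NULL)
  expect_setequal(kept, c("s1", "s3", "s5"))
  log <- attr(kept, "selection_log")
  expect_identical(log$disposition[log$snp_id == "s2"], "dropped")
})

test_that("clumping keeps the index SNP and respects the r2 threshold", {
  exposure <- manual_gwas(c("a", "b"), pval = c(1e-10, 1e-9),
                          pos = c(1e6, 1.1e6))
  ld_hi <- data.frame(snp_a = "a", snp_b = "b", r2 = 0.5)
  expect_identical(as.character(select_instruments(exposure, ld_hi)), "a")
  ld_lo <- data.frame(snp_a = "a", snp_b = "b", r2 = 0.005)
  expect_setequal(select_instruments(exposure, ld_lo), c("a", "b"))
  # outside the clump window the same r2 no longer prunes
  far <- manual_gwas(c("a", "b"), pval = c(1e-10, 1e-9),
                     pos = c(1e6, 1e6 + 5001 * 1000))
  expect_setequal(select_instruments(far, ld_hi), c("a", "b"))
  expect_error(select_instruments(exposure[0, ]), "non-empty")
})

test_that("greedy clumping matches the brute-force enumeration oracle", {
  for (s in 1:40) {
    inst <- random_clump_instance(s)
    got <- select_instruments(inst$exposure, inst$ld, inst$p_threshold,
                              inst$r2_threshold, inst$clump_kb)
    want <- clump_oracle(inst$exposure, inst$ld, inst$p_threshold,
                         inst$r2_threshold, inst$clump_kb)
    expect_identical(sort(as.character(got)), sort(want), label = paste("instance", s))
  }
})

test_that("lowering the significance threshold never adds instruments", {
  exposure <- simulate_summary_stats(sim_config(n_instruments = 40,
                                                n_null_snps = 20,
                                                seed = 11))$exposure
  counts <- vapply(c(1e-5, 1e-6, 5e-8, 1e-9, 1e-11),
                   function(p) length(select_instruments(exposure,
                                                         p_threshold = p)),
                   numeric(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("harmonization copies, flips, and drops as the alleles dictate", {
  exposure <- manual_gwas(c("s1", "s2", "s3"), beta = 0.1, ea = "A", oa = "G")
  outcome <- exposure
  outcome$beta <- c(0.03, 0.03, 0.03)
  # s2 reported on the other allele; s3 irreconcilable
  outcome$effect_allele[2] <- "G"; outcome$other_allele[2] <- "A"
  outcome$effect_allele[3] <- "A"; outcome$other_allele[3] <- "C"
  set <- harmonize(exposure, outcome, c("s1", "s2", "s3"))
  inst <- set$instruments
  expect_identical(inst$snp_id, c("s1", "s2"))
  expect_equal(inst$beta_out, c(0.03, -0.03))
  expect_identical(inst$flipped, c(FALSE, TRUE))
  expect_match(set$selection_log$reason[3], "irreconcilable")
  # strand-complement representation reconciles without a sign flip
  outcome2 <- exposure[1, ]
  outcome2$effect_allele <- "T"; outcome2$other_allele <- "C"
  one <- harmonize(exposure, outcome2, "s1")
  expect_equal(one$instruments$beta_out, 0.1)
  expect_false(one$instruments$flipped)
})

test_that("palindromic policies drop or rescue strand-ambiguous SNPs", {
  exposure <- manual_gwas("p1", ea = "A", oa = "T", eaf = 0.5)
  outcome <- exposure
  ambiguous <- harmonize(exposure, outcome, "p1")
  expect_identical(nrow(ambiguous$instruments), 0L)
  expect_match(ambiguous$selection_log$reason, "ambiguous")

  exposure$eaf <- 0.2; outcome$eaf <- 0.25
  kept <- harmonize(exposure, outcome, "p1")
  expect_identical(nrow(kept$instruments), 1L)
  expect_false(kept$instruments$flipped)
  outcome$eaf <- 0.75  # frequencies disagree in side: strand flip implied
  flipped <- harmonize(exposure, outcome, "p1")
  expect_true(flipped$instruments$flipped)
  expect_equal(flipped$instruments$beta_out, -outcome$beta)

  dropped <- harmonize(exposure, outcome, "p1", palindromic_policy = "drop")
  expect_identical(nrow(dropped$instruments), 0L)
  expect_identical(nrow(harmonize(exposure, outcome, "p1",
                                  palindromic_policy = "keep_all")$instruments),
                   1L)
})

test_that("harmonization is involutive", {
  sim <- simulate_summary_stats(sim_config(n_instruments = 30,
                                           causal_effect = 0.15,
                                           palindromic_rate = 0.2, seed = 21))
  set1 <- harmonize(sim$exposure, sim$outcomes$cohort_1, sim$exposure$snp_id)
  # express the harmonized outcome as a table in the exposure orientation
  # and harmonize again: nothing may change
  ids <- set1$instruments$snp_id
  out2 <- sim$exposure[match(ids, sim$exposure$snp_id), ]
  out2$beta <- set1$instruments$beta_out
  out2$se <- set1$instruments$se_out
  out2$pval <- 2 * pnorm(-abs(out2$beta / out2$se))
  set2 <- harmonize(sim$exposure, out2, ids)
  expect_identical(set2$instruments$snp_id, ids)
  expect_equal(set2$instruments$beta_out, set1$instruments$beta_out,
               tolerance = 1e-15)
  expect_false(any(set2$instruments$flipped))
})

test_that("instrument strength follows F = beta^2/se^2 and R2 = 2p(1-p)b^2", {
  expect_equal(f_statistic(0.1, 0.02), 25)
  expect_equal(f_statistic(0, 0.02), 0)
  expect_equal(f_statistic(-0.1, 0.02), 25)
  expect_equal(variance_explained(0.5, 0.1), 0.005)
  expect_equal(variance_explained(0.5, 0), 0)
  expect_equal(variance_explained(0.2, 0.05), 2 * 0.2 * 0.8 * 0.0025)
  weak <- manual_set(beta_exp = c(0.01, 0.012, 0.011),
                     beta_out = c(0, 0, 0), se_exp = 0.01)
  expect_warning(instrument_diagnostics(weak), "weak")
  strong <- sim_set(n_snp = 10, seed = 2)
  diag <- instrument_diagnostics(strong)
  expect_gt(diag$mean_f, 10)
  expect_equal(diag$total_r2, sum(diag$r2))
})
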