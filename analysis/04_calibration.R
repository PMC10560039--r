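#!/usr/bin/env Rscript

# Desk-scale operating characteristics of the estimators under the
# generator's known truth: type-I error of the heterogeneity and pleiotropy
# tests, IVW confidence-interval coverage, and the bias protection the robust
# methods buy under directional pleiotropy and planted outliers. Replicate
# counts are kept modest here so the script finishes in well under a minute;
# scripts/acceptance.R runs the same experiments at full size.

suppressPackageStartupMessages(library(mrscreen))

hset <- function(sim) harmonize(sim$exposure, sim$outcomes$cohort_1,
                                sim$exposure$snp_id)
sim_one <- function(seed, n_snp, beta, pm = "none", psd = 0, pmean = 0)
  simulate_summary_stats(sim_config(
    n_instruments = n_snp, n_null_snps = 0, causal_effect = beta,
    pleiotropy_mode = pm, pleiotropy_sd = psd, pleiotropy_mean = pmean,
    palindromic_rate = 0, seed = seed))

n_rep <- 400

q_rej <- mean(vapply(seq_len(n_rep), function(i)
  cochran_q(hset(sim_one(i, 15, 0)))$pval < 0.05, logical(1)))

e_rej <- mean(vapply(seq_len(n_rep), function(i)
  egger_intercept_test(hset(sim_one(5000 + i, 25, 0.1, "balanced",
                                    0.005)))$pval < 0.05, logical(1)))

covered <- mean(vapply(seq_len(n_rep), function(i) {
  e <- mr_ivw(hset(sim_one(10000 + i, 50, 0.2)))
  e$ci_low <= 0.2 && 0.2 <= e$ci_high
}, logical(1)))

bias <- vapply(seq_len(n_rep), function(i) {
  set <- hset(sim_one(20000 + i, 100, 0.2, "directional", 0.005, 0.02))
  c(ivw = mr_ivw(set)$beta - 0.2, egger = mr_egger(set)$beta - 0.2)
}, numeric(2))

presso <- vapply(seq_len(n_rep), function(i) {
  d <- hset(sim_one(30000 + i, 30, 0.2))$instruments
  d$beta_out[7] <- d$beta_out[7] + 10 * d$se_out[7]
  # n_sim must exceed L/alpha or the Bonferroni-adjusted empirical p-values
  # can never clear the outlier threshold
  pr <- mr_presso(d, n_sim = 1000, seed = i)
  c(flag = d$snp_id[7] %in% pr$outlier_snps$snp_id,
    closer = !is.null(pr$estimate_corrected) &&
      abs(pr$estimate_corrected$beta - 0.2) < abs(pr$estimate_raw$beta - 0.2))
}, logical(2))

tab <- data.frame(
  quantity = c("cochran_q_type1_rate", "egger_intercept_type1_rate",
               "ivw_ci_coverage", "ivw_abs_bias_directional",
               "egger_abs_bias_directional", "presso_outlier_flag_rate",
               "presso_correction_improves_rate"),
  value = c(q_rej, e_rej, covered, mean(abs(bias["ivw", ])),
            mean(abs(bias["egger", ])), mean(presso["flag", ]),
            mean(presso["closer", ])),
  n_replicates = n_rep)

dir.create("results", showWarnings = FALSE)
data.table::fwrite(tab, "results/calibration.tsv", sep = "\t")
print(tab, row.names = FALSE, digits = 3)
cat("\nNotes: nominal rates are 0.05 for the two tests and 0.95 for",
    "coverage. Under directional pleiotropy IVW is biased by roughly",
    "mean(alpha)/mean(gamma) while MR-Egger absorbs it in its intercept.",
    "A single 10*se outlier among 30 instruments shifts IVW by only ~1.8 of",
    "its own SEs, so removing it improves the point estimate in roughly",
    "Phi(0.9) ~ 80% of replicates, not always.\n")
cat("Table written to results/calibration.tsv\n")
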