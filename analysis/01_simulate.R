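#!/usr/bin/env Rscript

# Build the synthetic study inputs: three exposure GWASs with known causal
# effects on a binary outcome measured in two independent cohorts of
# different precision (a discovery and a replication cohort), plus three
# exposure -> mediator -> outcome chains with generating mediation shares of
# 25%, 10% and 5%. Everything downstream (02_screen.R, 03_mediation.R) reads
# the tables written here, so the whole analysis is reproducible from this
# script's seeds alone.

suppressPackageStartupMessages(library(mrscreen))

out_root <- "results/data"
dir.create(out_root, recursive = TRUE, showWarnings = FALSE)

## -- screening inputs ------------------------------------------------------
# generating causal effects on the log-odds scale; expB is a true null
effects <- c(expA = 0.20, expB = 0.00, expC = -0.15)

for (i in seq_along(effects)) {
  nm <- names(effects)[i]
  sim <- simulate_summary_stats(sim_config(
    n_instruments = 40, n_null_snps = 40, ld_block_size = 5,
    within_block_r2 = 0.5, causal_effect = effects[[i]],
    n_cohorts = 2, n_exposure = 200000, n_outcome = c(300000, 390000),
    seed = 1000 + i))
  # prefix SNP ids per exposure so the per-cohort outcome tables can be
  # stacked into one file each
  sim$exposure$snp_id <- paste0(nm, "_", sim$exposure$snp_id)
  for (k in 1:2)
    sim$outcomes[[k]]$snp_id <- paste0(nm, "_", sim$outcomes[[k]]$snp_id)
  sim$ld$snp_a <- paste0(nm, "_", sim$ld$snp_a)
  sim$ld$snp_b <- paste0(nm, "_", sim$ld$snp_b)
  write_gwas(sim$exposure, file.path(out_root, paste0(nm, "_exposure.tsv")))
  write_gwas(sim$outcomes$cohort_1,
             file.path(out_root, paste0(nm, "_outcome_discovery.tsv")))
  write_gwas(sim$outcomes$cohort_2,
             file.path(out_root, paste0(nm, "_outcome_replication.tsv")))
  write_ld(sim$ld, file.path(out_root, paste0(nm, "_ld.tsv")))
  cat(sprintf("%s: true effect %+0.2f, %d instrument SNPs written\n",
              nm, effects[[i]], 40))
}

## -- mediation inputs ------------------------------------------------------
# three chains sharing the design of the screening data; generating
# mediation proportions b1*b2 / (b1*b2 + b_direct)
chains <- list(
  med25 = list(b1 = -0.5, b2 = 0.2, b_direct = -0.30),
  med10 = list(b1 = -0.4, b2 = 0.1, b_direct = -0.36),
  med05 = list(b1 = -0.2, b2 = 0.1, b_direct = -0.38))

for (i in seq_along(chains)) {
  nm <- names(chains)[i]
  sim <- simulate_summary_stats(sim_config(
    n_instruments = 40, n_mediator_instruments = 40, n_null_snps = 0,
    mediator_spec = chains[[i]], n_exposure = 300000, n_outcome = 500000,
    n_mediator = 300000, seed = 2000 + i))
  dir <- file.path(out_root, nm)
  write_sim(sim, dir)
  cat(sprintf("%s: true mediation share %.1f%% written to %s\n",
              nm, 100 * sim$truth$true_mediation_proportion, dir))
}

cat("done: synthetic study inputs under", out_root, "\n")
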