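#!/usr/bin/env Rscript

# Discovery -> replication -> meta-analysis screen over the three simulated
# exposures written by 01_simulate.R. For each exposure x cohort pair this
# selects instruments (p < 5e-8, LD r2 < 0.01 within 5,000 kb), harmonizes
# alleles, runs IVW / MR-Egger / weighted median / simple and weighted mode,
# and the sensitivity suite (Cochran's Q, Egger intercept, MR-PRESSO,
# leave-one-out, scatter/funnel tables); per-cohort IVW estimates are then
# combined by fixed-effect meta-analysis and flagged at p <= 0.05.

suppressPackageStartupMessages(library(mrscreen))

data_dir <- "results/data"
if (!dir.exists(data_dir))
  stop("run analysis/01_simulate.R first", call. = FALSE)

exposures <- c("expA", "expB", "expC")
cfg <- list(
  exposures = setNames(lapply(exposures, function(nm)
    file.path(data_dir, paste0(nm, "_exposure.tsv"))), exposures),
  outcomes = list(
    discovery = do.call(rbind, lapply(exposures, function(nm)
      read_gwas(file.path(data_dir, paste0(nm, "_outcome_discovery.tsv"))))),
    replication = do.call(rbind, lapply(exposures, function(nm)
      read_gwas(file.path(data_dir,
                          paste0(nm, "_outcome_replication.tsv")))))),
  ld = do.call(rbind, lapply(exposures, function(nm)
    read_ld(file.path(data_dir, paste0(nm, "_ld.tsv"))))),
  thresholds = list(p_threshold = 5e-8, r2_threshold = 0.01, clump_kb = 5000),
  seed = 42, n_boot = 1000, alpha = 0.05)

scr <- run_screen(cfg, out_dir = "results/screen")
print(scr)

cat("\nPer-cohort and meta findings (IVW):\n")
print(scr$findings, row.names = FALSE)
cat("\nInstrument strength:\n")
print(scr$diagnostics, row.names = FALSE)
cat("\nGenerating effects were expA = +0.20, expB = 0, expC = -0.15;",
    "a faithful screen flags expA and expC but not expB.\n")
cat("Full tables (estimates, sensitivity, meta, plot data, manifest)",
    "are under results/screen/.\n")
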