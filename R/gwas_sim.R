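#' Configuration for the synthetic GWAS summary-statistics generator
#'
#' Builds and validates the configuration of [simulate_summary_stats()]. The
#' generator emulates the data regime of a two-sample MR study: an exposure
#' GWAS with genome-wide-significant instruments, one or two independent
#' outcome GWAS cohorts of (possibly) different precision, optional mediator
#' GWAS, correlated null SNPs organised in LD blocks, and per-SNP direct
#' (pleiotropic) effects on the outcome.
#'
#' Per-SNP instrument effects on the exposure are drawn as
#' `sign * Normal(gamma_mean, gamma_sd)` with random sign; with the defaults
#' (`gamma_mean = 0.03`, `gamma_sd = 0.01`, `n_exposure = 200000`) the median
#' per-SNP F statistic is around 50, i.e. comfortably strong instruments.
#' Standard errors follow GWAS sampling theory for a standardized trait,
#' `se = 1 / sqrt(2 * eaf * (1 - eaf) * n)`; binary traits are treated on the
#' log-odds scale with the same formula and `n` read as an effective sample
#' size.
#'
#' @param n_instruments Number of true instrument SNPs.
#' @param n_null_snps Number of non-instrument SNPs (organised in LD blocks).
#' @param ld_block_size SNPs per LD block among the null SNPs.
#' @param within_block_r2 Target pairwise LD r-squared inside a block, in
#'   `[0, 1]`.
#' @param causal_effect True causal effect of exposure on outcome (per-SD or
#'   log-odds scale). Ignored when `mediator_spec` is given, in which case the
#'   total effect is `b1 * b2 + b_direct`.
#' @param pleiotropy_mode One of `"none"`, `"balanced"`, `"directional"`:
#'   per-SNP direct effects on the outcome are exactly zero, zero-mean, or
#'   shifted by `pleiotropy_mean`.
#' @param pleiotropy_sd SD of per-SNP direct effects.
#' @param pleiotropy_mean Mean of per-SNP direct effects (directional mode
#'   only; must be 0 under `"balanced"`).
#' @param mediator_spec Optional list/vector with elements `b1`
#'   (exposure -> mediator), `b2` (mediator -> outcome) and `b_direct`
#'   (exposure -> outcome not through the mediator).
#' @param n_mediator_instruments Number of SNPs acting directly on the
#'   mediator (only used when `mediator_spec` is given).
#' @param n_exposure,n_mediator GWAS sample sizes for the exposure and
#'   mediator studies.
#' @param n_outcome GWAS sample size(s) for the outcome study; a vector of
#'   length `n_cohorts` gives each cohort its own precision.
#' @param n_cohorts 1 or 2 outcome cohorts sharing true effects but with
#'   independent sampling noise.
#' @param gamma_mean,gamma_sd Mean and SD of instrument effect magnitudes.
#' @param palindromic_rate Fraction of SNPs given strand-ambiguous (A/T or
#'   C/G) alleles, to exercise harmonization.
#' @param orientation_flip_rate Fraction of outcome/mediator records reported
#'   on the opposite effect allele (allele columns swapped, `eaf` and `beta`
#'   reflected), to exercise harmonization.
#' @param seed Integer RNG seed; identical configs reproduce identical tables.
#' @return A validated list of class `"sim_config"`.
#' @seealso [simulate_summary_stats()]
#' @export
sim_config <- function(n_instruments = 50,
                       n_null_snps = 100,
                       ld_block_size = 5,
                       within_block_r2 = 0.5,
                       causal_effect = 0,
                       pleiotropy_mode = c("none", "balanced", "directional"),
                       pleiotropy_sd = 0,
                       pleiotropy_mean = 0,
                       mediator_spec = NULL,
                       n_mediator_instruments = 30,
                       n_exposure = 200000,
                       n_outcome = 300000,
                       n_mediator = 200000,
                       n_cohorts = 1,
                       gamma_mean = 0.03,
                       gamma_sd = 0.01,
                       palindromic_rate = 0.1,
                       orientation_flip_rate = 0.3,
                       seed = 1) {
  pleiotropy_mode <- match.arg(pleiotropy_mode)
  cfg <- list(n_instruments = n_instruments, n_null_snps = n_null_snps,
              ld_block_size = ld_block_size, within_block_r2 = within_block_r2,
              causal_effect = causal_effect,
              pleiotropy_mode = pleiotropy_mode,
              pleiotropy_sd = pleiotropy_sd,
              pleiotropy_mean = pleiotropy_mean,
              mediator_spec = mediator_spec,
              n_mediator_instruments = n_mediator_instruments,
              n_exposure = n_exposure, n_outcome = n_outcome,
              n_mediator = n_mediator, n_cohorts = n_cohorts,
              gamma_mean = gamma_mean, gamma_sd = gamma_sd,
              palindromic_rate = palindromic_rate,
              orientation_flip_rate = orientation_flip_rate, seed = seed)
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  chk_count <- function(field, min = 0) {
    v <- cfg[[field]]
    if (!is.numeric(v) || length(v) != 1L || is.na(v) || v < min ||
        v != round(v))
      stopf("invalid config field '%s': must be an integer >= %d", field, min)
  }
  chk_count("n_instruments", 1)
  chk_count("n_null_snps", 0)
  chk_count("ld_block_size", 1)
  chk_count("n_cohorts", 1)
  if (cfg$n_cohorts > 2)
    stopf("invalid config field 'n_cohorts': must be 1 or 2")
  if (!is.numeric(cfg$within_block_r2) || cfg$within_block_r2 < 0 ||
      cfg$within_block_r2 > 1)
    stopf("invalid config field 'within_block_r2': must be in [0,1]")
  for (f in c("n_exposure", "n_mediator")) {
    if (any(cfg[[f]] < 2))
      stopf("invalid config field '%s': sample sizes must be >= 2", f)
  }
  if (any(cfg$n_outcome < 2) ||
      !length(cfg$n_outcome) %in% c(1L, cfg$n_cohorts))
    stopf("invalid config field 'n_outcome': need >= 2, length 1 or n_cohorts")
  if (cfg$pleiotropy_mode == "balanced" && cfg$pleiotropy_mean != 0)
    stopf("invalid config field 'pleiotropy_mean': must be 0 under balanced pleiotropy")
  if (cfg$pleiotropy_sd < 0)
    stopf("invalid config field 'pleiotropy_sd': must be >= 0")
  if (cfg$palindromic_rate < 0 || cfg$palindromic_rate > 1)
    stopf("invalid config field 'palindromic_rate': must be in [0,1]")
  if (cfg$orientation_flip_rate < 0 || cfg$orientation_flip_rate > 1)
    stopf("invalid config field 'orientation_flip_rate': must be in [0,1]")
  if (!is.null(cfg$mediator_spec)) {
    ms <- as.list(cfg$mediator_spec)
    if (!all(c("b1", "b2", "b_direct") %in% names(ms)))
      stopf("invalid config field 'mediator_spec': need named elements b1, b2, b_direct")
    chk_count("n_mediator_instruments", 1)
  }
  invisible(cfg)
}

# GWAS sampling SE for a standardized trait (log-odds analogue for binary).
gwas_se <- function(eaf, n) 1 / sqrt(2 * eaf * (1 - eaf) * n)

# Exchangeable correlated standard-normal noise: SNPs in the same LD block
# get estimate correlation r = sqrt(r2), matching the allelic correlation
# that LD r2 implies for summary statistics.
block_noise <- function(block, rho) {
  n <- length(block)
  if (rho <= 0) return(stats::rnorm(n))
  u <- stats::rnorm(length(unique(block)))[as.integer(factor(block))]
  sqrt(rho) * u + sqrt(1 - rho) * stats::rnorm(n)
}

sample_alleles <- function(n, palindromic_rate) {
  pal <- stats::runif(n) < palindromic_rate
  bases <- c("A", "C", "G", "T")
  ea <- character(n); oa <- character(n)
  pal_pairs <- matrix(c("A", "T", "T", "A", "C", "G", "G", "C"),
                      ncol = 2, byrow = TRUE)
  idx <- sample.int(4, n, replace = TRUE)
  ea[pal] <- pal_pairs[idx[pal], 1]
  oa[pal] <- pal_pairs[idx[pal], 2]
  for (i in which(!pal)) {
    a <- sample(bases, 1)
    b <- sample(setdiff(bases, c(a, DNA_COMPLEMENT[[a]])), 1)
    ea[i] <- a; oa[i] <- b
  }
  list(ea = ea, oa = oa, palindromic = pal)
}

#' Simulate two-sample GWAS summary statistics with known ground truth
#'
#' Generates exposure, outcome (one or two cohorts) and optionally mediator
#' summary-statistics tables in the standard layout (see [read_gwas()]),
#' together with a pairwise LD table for the null-SNP blocks and a `truth`
#' record holding the generating values. Outcome betas for instrument `j` are
#' `causal_effect * gamma_j + alpha_j + noise`; null SNPs have zero mean
#' effects; all standard errors follow the theoretical GWAS sampling SE at
#' the configured sample size. With a `mediator_spec`, the exposure acts on
#' the mediator (`b1`), the mediator on the outcome (`b2`), and the exposure
#' directly on the outcome (`b_direct`); a separate set of SNPs instruments
#' the mediator, and the true mediation proportion
#' `b1*b2 / (b1*b2 + b_direct)` is recorded in the truth.
#'
#' Identical `(config, seed)` reproduce byte-identical tables; the caller's
#' RNG state is left untouched.
#'
#' @param config A [sim_config()].
#' @return A list of class `"mr_sim"` with elements `exposure`, `outcomes`
#'   (named list of cohort tables), `mediator` (or `NULL`), `ld`, `truth`
#'   and `config`.
#' @examples
#' sim <- simulate_summary_stats(sim_config(n_instruments = 20,
#'                                          causal_effect = 0.2, seed = 7))
#' head(sim$exposure)
#' sim$truth$causal_effect
#' @export
simulate_summary_stats <- function(config) {
  if (!inherits(config, "sim_config")) config <- do.call(sim_config, config)
  validate_sim_config(config)
  with_seed(config$seed, simulate_impl(config))
}

simulate_impl <- function(cfg) {
  has_med <- !is.null(cfg$mediator_spec)
  n_inst <- cfg$n_instruments
  n_med <- if (has_med) cfg$n_mediator_instruments else 0L
  n_null <- cfg$n_null_snps
  n_tot <- n_inst + n_med + n_null

  snp_id <- sprintf("rs%06d", seq_len(n_tot))
  role <- rep(c("instrument", "mediator_instrument", "null"),
              c(n_inst, n_med, n_null))

  # Instrument-type SNPs sit far apart on cycling chromosomes; null SNPs sit
  # in tight LD blocks (1 kb spacing) so clumping has something to prune.
  chr <- integer(n_tot); pos <- integer(n_tot)
  k <- n_inst + n_med
  chr[seq_len(k)] <- rep_len(1:22, k)
  pos[seq_len(k)] <- 1e6 + 2e7 * ((seq_len(k) - 1L) %/% 22L)
  block <- integer(n_tot)
  if (n_null > 0) {
    b <- (seq_len(n_null) - 1L) %/% cfg$ld_block_size
    block[k + seq_len(n_null)] <- b + 1L
    chr[k + seq_len(n_null)] <- rep_len(1:22, max(b) + 1L)[b + 1L]
    pos[k + seq_len(n_null)] <- 5e7 + 2e7 * (b %/% 22L) +
      1000L * ((seq_len(n_null) - 1L) %% cfg$ld_block_size)
  }

  eaf <- stats::runif(n_tot, 0.05, 0.95)
  al <- sample_alleles(n_tot, cfg$palindromic_rate)

  # Instrument effects carry a random reported-allele sign; direct
  # (pleiotropic) effects are specified in the exposure-increasing-allele
  # frame and co-flip with it, so "directional" really shifts the outcome in
  # one direction per unit of exposure-raising allele. Without the co-flip a
  # nonzero pleiotropy_mean would wash out to balanced pleiotropy.
  sgn <- sample(c(-1, 1), n_inst, replace = TRUE)
  gamma <- sgn * stats::rnorm(n_inst, cfg$gamma_mean, cfg$gamma_sd)
  alpha <- sgn * switch(cfg$pleiotropy_mode,
    none = rep(0, n_inst),
    balanced = stats::rnorm(n_inst, 0, cfg$pleiotropy_sd),
    directional = stats::rnorm(n_inst, cfg$pleiotropy_mean, cfg$pleiotropy_sd))

  if (has_med) {
    ms <- as.list(cfg$mediator_spec)
    b1 <- ms$b1; b2 <- ms$b2; bd <- ms$b_direct
    delta <- sample(c(-1, 1), n_med, replace = TRUE) *
      stats::rnorm(n_med, cfg$gamma_mean, cfg$gamma_sd)
    total <- b1 * b2 + bd
    true_exp <- c(gamma, rep(0, n_med + n_null))
    true_med <- c(b1 * gamma, delta, rep(0, n_null))
    true_out <- c(total * gamma + alpha, b2 * delta, rep(0, n_null))
    true_prop <- (b1 * b2) / (b1 * b2 + bd)
  } else {
    total <- cfg$causal_effect
    true_exp <- c(gamma, rep(0, n_null))
    true_out <- c(cfg$causal_effect * gamma + alpha, rep(0, n_null))
    true_med <- NULL
    true_prop <- NA_real_
  }

  rho <- sqrt(cfg$within_block_r2)
  noisy_table <- function(true_beta, n_samp, flip_orientation) {
    se <- gwas_se(eaf, n_samp)
    z <- stats::rnorm(n_tot)
    if (n_null > 0 && rho > 0) {
      idx <- block > 0
      z[idx] <- block_noise(block[idx], rho)
    }
    beta <- true_beta + se * z
    tab <- data.frame(snp_id = snp_id, chr = chr, pos = pos,
                      effect_allele = al$ea, other_allele = al$oa,
                      eaf = eaf, beta = beta, se = se,
                      pval = 2 * stats::pnorm(-abs(beta / se)),
                      n = n_samp, stringsAsFactors = FALSE)
    if (flip_orientation && cfg$orientation_flip_rate > 0) {
      fl <- stats::runif(n_tot) < cfg$orientation_flip_rate
      tmp <- tab$effect_allele[fl]
      tab$effect_allele[fl] <- tab$other_allele[fl]
      tab$other_allele[fl] <- tmp
      tab$eaf[fl] <- 1 - tab$eaf[fl]
      tab$beta[fl] <- -tab$beta[fl]
    }
    tab
  }

  exposure <- noisy_table(true_exp, cfg$n_exposure, flip_orientation = FALSE)
  n_out <- rep_len(cfg$n_outcome, cfg$n_cohorts)
  outcomes <- lapply(seq_len(cfg$n_cohorts), function(k2)
    noisy_table(true_out, n_out[k2], flip_orientation = TRUE))
  names(outcomes) <- paste0("cohort_", seq_len(cfg$n_cohorts))
  mediator <- if (has_med)
    noisy_table(true_med, cfg$n_mediator, flip_orientation = TRUE) else NULL

  ld <- if (n_null > 0 && cfg$ld_block_size > 1) {
    pairs <- do.call(rbind, lapply(split(snp_id[block > 0], block[block > 0]),
      function(ids) {
        if (length(ids) < 2) return(NULL)
        cmb <- utils::combn(ids, 2)
        data.frame(snp_a = cmb[1, ], snp_b = cmb[2, ],
                   r2 = cfg$within_block_r2, stringsAsFactors = FALSE)
      }))
    rownames(pairs) <- NULL
    pairs
  } else data.frame(snp_a = character(), snp_b = character(), r2 = numeric())

  truth <- list(causal_effect = total,
                per_snp_gamma = gamma,
                per_snp_alpha = alpha,
                instrument_ids = snp_id[role == "instrument"],
                mediator_instrument_ids = snp_id[role == "mediator_instrument"],
                true_mediation_proportion = true_prop,
                seed = cfg$seed)

  structure(list(exposure = exposure, outcomes = outcomes,
                 mediator = mediator, ld = ld, truth = truth, config = cfg),
            class = "mr_sim")
}

#' @export
print.mr_sim <- function(x, ...) {
  cfg <- x$config
  cat(sprintf(
    "Synthetic two-sample GWAS: %d instruments, %d null SNPs, %d cohort(s)\n",
    cfg$n_instruments, cfg$n_null_snps, cfg$n_cohorts))
  cat(sprintf("  true total effect: %.4g; pleiotropy: %s; seed: %d\n",
              x$truth$causal_effect, cfg$pleiotropy_mode, cfg$seed))
  if (!is.null(x$mediator))
    cat(sprintf("  mediator chain present; true mediation proportion %.3f\n",
                x$truth$true_mediation_proportion))
  invisible(x)
}

#' Write all tables of a simulated dataset to a directory
#'
#' @param sim An `"mr_sim"` object from [simulate_summary_stats()].
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_sim <- function(sim, dir) {
  stopifnot(inherits(sim, "mr_sim"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_gwas(sim$exposure, file.path(dir, "exposure.tsv"))
  for (nm in names(sim$outcomes))
    write_gwas(sim$outcomes[[nm]], file.path(dir, paste0("outcome_", nm, ".tsv")))
  if (!is.null(sim$mediator))
    write_gwas(sim$mediator, file.path(dir, "mediator.tsv"))
  write_ld(sim$ld, file.path(dir, "ld.tsv"))
  jsonlite::write_json(sim$truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
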