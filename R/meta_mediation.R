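# Fixed-effect meta-analysis across cohorts and two-step mediation MR.

#' Fixed-effect inverse-variance meta-analysis
#'
#' Combines per-cohort estimates as
#' `beta_meta = sum(b_i/se_i^2) / sum(1/se_i^2)` with
#' `se_meta = 1/sqrt(sum(1/se_i^2))`, normal-theory CI and p-value, and
#' reports cross-cohort Cochran's Q (df `k - 1`) when two or more inputs are
#' supplied.
#'
#' @param beta Numeric vector of estimates (or a data.frame with columns
#'   `beta`, `se` and optionally `cohort`).
#' @param se Standard errors (all positive).
#' @param labels Optional cohort labels.
#' @return A list of class `"meta_estimate"`: `beta_meta`, `se_meta`,
#'   `ci_low`, `ci_high`, `pval`, `inputs`, `heterogeneity`.
#' @examples
#' meta_fixed(c(0.1, 0.3), c(0.1, 0.2))  # beta 0.14, se 1/sqrt(125)
#' @export
meta_fixed <- function(beta, se = NULL, labels = NULL) {
  if (is.data.frame(beta)) {
    labels <- if ("cohort" %in% names(beta)) beta$cohort else labels
    se <- beta$se
    beta <- beta$beta
  }
  if (length(beta) < 1L) stopf("meta_fixed needs at least one estimate")
  if (length(se) != length(beta) || any(se <= 0))
    stopf("meta_fixed needs one positive se per estimate")
  if (is.null(labels)) labels <- paste0("input_", seq_along(beta))
  w <- 1 / se^2
  bm <- sum(w * beta) / sum(w)
  sm <- sqrt(1 / sum(w))
  het <- if (length(beta) >= 2L) {
    q <- sum(w * (beta - bm)^2)
    df <- length(beta) - 1L
    structure(list(Q = q, df = df,
                   pval = stats::pchisq(q, df, lower.tail = FALSE),
                   about = "meta"),
              class = "heterogeneity_stat")
  } else NULL
  structure(list(beta_meta = bm, se_meta = sm,
                 ci_low = bm - 1.96 * sm, ci_high = bm + 1.96 * sm,
                 pval = z_pval(bm, sm),
                 inputs = data.frame(cohort = labels, beta = beta, se = se,
                                     stringsAsFactors = FALSE),
                 heterogeneity = het),
            class = "meta_estimate")
}

#' @export
print.meta_estimate <- function(x, ...) {
  cat(sprintf("Fixed-effect meta (%d inputs): beta = %.4g (se %.4g), 95%% CI [%.4g, %.4g], p = %.3g\n",
              nrow(x$inputs), x$beta_meta, x$se_meta, x$ci_low, x$ci_high,
              x$pval))
  if (!is.null(x$heterogeneity))
    cat(sprintf("  cross-cohort Q = %.3g on %d df (p = %.3g)\n",
                x$heterogeneity$Q, x$heterogeneity$df, x$heterogeneity$pval))
  invisible(x)
}

# Harmonize exposure/mediator/outcome tables onto the exposure's effect
# alleles for a common SNP list, returning aligned vectors for MVMR.
align_three <- function(exposure, mediator, outcome, snps, palindromic_policy) {
  h_out <- harmonize(exposure, outcome, snps,
                     palindromic_policy = palindromic_policy)
  h_med <- harmonize(exposure, mediator, snps,
                     palindromic_policy = palindromic_policy)
  common <- intersect(h_out$instruments$snp_id, h_med$instruments$snp_id)
  o <- h_out$instruments[match(common, h_out$instruments$snp_id), ]
  m <- h_med$instruments[match(common, h_med$instruments$snp_id), ]
  list(snp_id = common,
       beta_exp = o$beta_exp, se_exp = o$se_exp,
       beta_med = m$beta_out, se_med = m$se_out,
       beta_out = o$beta_out, se_out = o$se_out)
}

#' Two-step mediation MR with mediation proportion
#'
#' Quantifies how much of an exposure's total effect on the outcome runs
#' through a mediator, from summary statistics alone. Step 1 estimates the
#' exposure's effect on the mediator (`beta1`) by univariable IVW over the
#' exposure's instruments. Step 2 estimates the mediator's effect on the
#' outcome *conditional on the exposure* (`beta2`) by multivariable IVW over
#' the union of exposure and mediator instruments. The total effect is the
#' univariable IVW of exposure on outcome. The indirect effect is
#' `beta1 * beta2` and the mediation proportion is `beta1 * beta2 / total`,
#' reported as a percentage truncated to \[0, 100\] (the untruncated value is
#' retained). Its CI comes from the delta method on the ratio, treating the
#' three fits as independent (`ci_method = "delta"`, default) or from a
#' parametric bootstrap over `(beta1, beta2, total)` (`"bootstrap"`).
#'
#' @param exposure_gwas,mediator_gwas,outcome_gwas Summary-statistics tables
#'   (see [read_gwas()]).
#' @param ld Optional LD table used for clumping.
#' @param p_threshold,r2_threshold,clump_kb Instrument-selection thresholds
#'   (see [select_instruments()]).
#' @param palindromic_policy Passed to [harmonize()].
#' @param ci_method `"delta"` or `"bootstrap"` for the proportion CI.
#' @param n_boot Bootstrap replicates when `ci_method = "bootstrap"`.
#' @param seed RNG seed for the bootstrap.
#' @param total_floor Smallest |total effect| for which a proportion is
#'   reported; below it the proportion is flagged undefined rather than
#'   exploding.
#' @param mediator_name,exposure_name,outcome_name Labels for reports.
#' @return A list of class `"mediation_result"`: `beta1`, `se1`, `beta2`,
#'   `se2`, `total`, `se_total`, `indirect`, `proportion` (in %, truncated),
#'   `ci_low`, `ci_high` (in %), `proportion_raw`, `sign_consistent`,
#'   `defined`, `mediator_name`, plus instrument counts.
#' @export
mediate <- function(exposure_gwas, mediator_gwas, outcome_gwas, ld = NULL,
                    p_threshold = 5e-8, r2_threshold = 0.01, clump_kb = 5000,
                    palindromic_policy = "keep_if_eaf_informative",
                    ci_method = c("delta", "bootstrap"), n_boot = 1000,
                    seed = 1, total_floor = 1e-6,
                    mediator_name = "mediator", exposure_name = "exposure",
                    outcome_name = "outcome") {
  ci_method <- match.arg(ci_method)
  exp_snps <- select_instruments(exposure_gwas, ld, p_threshold, r2_threshold,
                                 clump_kb)
  if (length(exp_snps) < 2L)
    stopf("mediation needs >= 2 exposure instruments after selection")

  total_set <- harmonize(exposure_gwas, outcome_gwas, exp_snps,
                         palindromic_policy = palindromic_policy,
                         exposure_name = exposure_name,
                         outcome_name = outcome_name)
  total_est <- mr_ivw(total_set)

  step1_set <- harmonize(exposure_gwas, mediator_gwas, exp_snps,
                         palindromic_policy = palindromic_policy,
                         exposure_name = exposure_name,
                         outcome_name = mediator_name)
  step1 <- mr_ivw(step1_set)

  med_snps <- select_instruments(mediator_gwas, ld, p_threshold, r2_threshold,
                                 clump_kb)
  union_snps <- union(exp_snps, med_snps)
  union_snps <- union_snps[union_snps %in% exposure_gwas$snp_id]
  al <- align_three(exposure_gwas, mediator_gwas, outcome_gwas, union_snps,
                    palindromic_policy)
  if (length(al$snp_id) < 4L)
    stopf("mediation step 2 needs >= 4 SNPs present in all three tables")
  X <- cbind(mediator = al$beta_med, exposure = al$beta_exp)
  mv <- mr_mvmr_ivw(al$beta_out, al$se_out, X)
  step2 <- mv$mediator

  indirect <- step1$beta * step2$beta
  defined <- abs(total_est$beta) >= total_floor
  prop_raw <- if (defined) indirect / total_est$beta else NA_real_

  ci <- c(NA_real_, NA_real_)
  if (defined) {
    if (ci_method == "delta") {
      # gradient of b1*b2/T in (b1, b2, T); cross-fit covariances taken as 0
      g <- c(step2$beta / total_est$beta,
             step1$beta / total_est$beta,
             -indirect / total_est$beta^2)
      v <- g[1]^2 * step1$se^2 + g[2]^2 * step2$se^2 +
        g[3]^2 * total_est$se^2
      ci <- prop_raw + c(-1.96, 1.96) * sqrt(v)
    } else {
      ci <- with_seed(seed, {
        b1s <- stats::rnorm(n_boot, step1$beta, step1$se)
        b2s <- stats::rnorm(n_boot, step2$beta, step2$se)
        ts <- stats::rnorm(n_boot, total_est$beta, total_est$se)
        stats::quantile(b1s * b2s / ts, c(0.025, 0.975), names = FALSE)
      })
    }
  }
  trunc_pct <- function(p) if (is.na(p)) NA_real_ else min(max(100 * p, 0), 100)

  structure(list(beta1 = step1$beta, se1 = step1$se,
                 beta2 = step2$beta, se2 = step2$se,
                 total = total_est$beta, se_total = total_est$se,
                 indirect = indirect,
                 proportion = trunc_pct(prop_raw),
                 ci_low = trunc_pct(ci[1]), ci_high = trunc_pct(ci[2]),
                 proportion_raw = prop_raw,
                 ci_raw = ci,
                 sign_consistent = isTRUE(sign(indirect) ==
                                            sign(total_est$beta)),
                 defined = defined,
                 ci_method = ci_method,
                 n_snp_step1 = step1$n_snp, n_snp_step2 = step2$n_snp,
                 n_snp_total = total_est$n_snp,
                 mediator_name = mediator_name,
                 exposure_name = exposure_name,
                 outcome_name = outcome_name),
            class = "mediation_result")
}

#' @export
print.mediation_result <- function(x, ...) {
  cat(sprintf("Mediation via %s: beta1 = %.4g, beta2 = %.4g, total = %.4g\n",
              x$mediator_name, x$beta1, x$beta2, x$total))
  if (x$defined)
    cat(sprintf("  indirect = %.4g; proportion = %.1f%% (95%% CI %.1f%%, %.1f%%; %s)\n",
                x$indirect, x$proportion, x$ci_low, x$ci_high, x$ci_method))
  else
    cat("  proportion undefined: |total effect| below floor\n")
  if (!x$sign_consistent)
    cat("  note: indirect and total effects have opposite signs\n")
  invisible(x)
}

#' Rank mediators by mediation proportion
#'
#' @param results A list of `"mediation_result"` objects.
#' @return A `data.frame` sorted by descending point-estimate proportion
#'   (ties broken lexicographically by mediator name) with columns
#'   `mediator, beta1, beta2, total, indirect, proportion, ci_low, ci_high,
#'   defined`.
#' @export
rank_mediators <- function(results) {
  if (inherits(results, "mediation_result")) results <- list(results)
  if (!length(results)) stopf("rank_mediators needs at least one result")
  tab <- do.call(rbind, lapply(results, function(r)
    data.frame(mediator = r$mediator_name, beta1 = r$beta1, beta2 = r$beta2,
               total = r$total, indirect = r$indirect,
               proportion = r$proportion, ci_low = r$ci_low,
               ci_high = r$ci_high, defined = r$defined,
               stringsAsFactors = FALSE)))
  tab <- tab[order(-tab$proportion, tab$mediator), ]
  rownames(tab) <- NULL
  tab
}
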