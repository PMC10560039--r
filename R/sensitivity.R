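# Heterogeneity, pleiotropy, outlier and influence diagnostics for a
# harmonized instrument set.

#' Cochran's Q heterogeneity statistic
#'
#' `Q = sum(w_j (b_j - beta_hat)^2)` over per-SNP Wald ratios `b_j` with
#' weights `w_j = 1/se(b_j)^2`, about the IVW estimate (df `L - 1`) or about
#' the MR-Egger fitted values (df `L - 2`); the p-value is the upper tail of
#' the chi-square distribution. Large Q signals that the per-SNP ratios are
#' more dispersed than their sampling errors allow, i.e. heterogeneity /
#' possible pleiotropy.
#'
#' @param set An `"instrument_set"` with at least 2 (IVW) or 3 (Egger)
#'   instruments.
#' @param about `"ivw"` (default) or `"egger"`.
#' @return A list of class `"heterogeneity_stat"`: `Q`, `df`, `pval`,
#'   `about`.
#' @export
cochran_q <- function(set, about = c("ivw", "egger")) {
  about <- match.arg(about)
  d <- as_instrument_df(set)
  L <- nrow(d)
  if (about == "ivw") {
    if (L < 2L) stopf("cochran_q about IVW needs >= 2 instruments")
    est <- mr_ivw(set, effects_model = "fixed")
    q <- est$extra$Q
    df <- L - 1L
  } else {
    if (L < 3L) stopf("cochran_q about Egger needs >= 3 instruments")
    est <- mr_egger(set)
    q <- est$extra$Q
    df <- L - 2L
  }
  structure(list(Q = q, df = df,
                 pval = stats::pchisq(q, df = df, lower.tail = FALSE),
                 about = about),
            class = "heterogeneity_stat")
}

#' @export
print.heterogeneity_stat <- function(x, ...) {
  cat(sprintf("Cochran's Q (%s): Q = %.4g on %d df, p = %.3g\n",
              x$about, x$Q, x$df, x$pval))
  invisible(x)
}

#' MR-Egger intercept test for directional pleiotropy
#'
#' Returns the intercept row of the MR-Egger fit: the intercept estimates
#' the average direct (pleiotropic) effect of the instruments on the
#' outcome; its p-value comes from the t distribution with `L - 2` degrees
#' of freedom. `p < 0.05` is the conventional declaration of horizontal
#' pleiotropy.
#'
#' @param set An `"instrument_set"` with at least 3 instruments.
#' @return A list: `intercept`, `se`, `pval`, and `pleiotropy_detected`
#'   (`pval < 0.05`).
#' @export
egger_intercept_test <- function(set) {
  est <- mr_egger(set)
  list(intercept = est$extra$egger_intercept,
       se = est$extra$egger_intercept_se,
       pval = est$extra$egger_intercept_pval,
       pleiotropy_detected = est$extra$egger_intercept_pval < 0.05)
}

# Leave-one-out IVW slopes in outcome space (weights 1/se_out^2), computed
# from running sums in O(L).
loo_slopes <- function(x, y, w) {
  sxy <- sum(w * x * y); sxx <- sum(w * x^2)
  (sxy - w * x * y) / (sxx - w * x^2)
}

#' MR-PRESSO: global pleiotropy test, outlier detection and correction
#'
#' A simulation-based residual-sum-of-squares framework. The observed global
#' statistic is `RSS = sum(w_j (beta_out_j - bhat(-j) * beta_exp_j)^2)` with
#' `w_j = 1/se_out_j^2` and `bhat(-j)` the leave-one-out IVW slope. Its null
#' distribution is built from `n_sim` parametric draws
#' `beta_out_j* ~ Normal(bhat(-j) * beta_exp_j, se_out_j)` (leave-one-out
#' slopes recomputed per draw); the global p-value is
#' `(1 + #{RSS* >= RSS}) / (n_sim + 1)`, so it is floored at
#' `1/(n_sim + 1)`. Each SNP's observed weighted squared residual is compared
#' with its own simulated distribution and Bonferroni-adjusted across the L
#' instruments; SNPs significant at `outlier_alpha` are removed and IVW
#' re-estimated on the remainder (the automated counterpart of removing
#' detected outliers by hand). A distortion test compares the raw-vs-corrected
#' shift with the shifts produced by removing random SNP subsets of the same
#' size.
#'
#' @param set An `"instrument_set"` with at least 4 instruments (fewer
#'   returns a not-applicable marker rather than an error, so pipelines can
#'   skip gracefully).
#' @param n_sim Parametric simulation draws (default 1000, minimum 100).
#' @param outlier_alpha Familywise outlier significance level after
#'   Bonferroni adjustment.
#' @param seed RNG seed; identical seeds reproduce the global p-value and
#'   outlier set exactly.
#' @return A list of class `"presso_result"`: `global_rss_observed`,
#'   `global_pval`, `outlier_snps` (data.frame snp_id, pval_bonferroni),
#'   `estimate_raw`, `estimate_corrected`, `distortion_pval`, `n_sim`,
#'   `seed`, `applicable`.
#' @export
mr_presso <- function(set, n_sim = 1000, outlier_alpha = 0.05, seed = 1) {
  d <- as_instrument_df(set)
  L <- nrow(d)
  if (n_sim < 100) stopf("n_sim must be >= 100")
  if (L < 4L) {
    return(structure(list(applicable = FALSE,
                          note = "MR-PRESSO needs >= 4 instruments",
                          n_snp = L, n_sim = n_sim, seed = seed),
                     class = "presso_result"))
  }
  if (L / (n_sim + 1) >= outlier_alpha)
    warnf(paste("n_sim = %d cannot resolve Bonferroni outlier p-values below",
                "alpha = %g with %d instruments (empirical floor %g);",
                "increase n_sim"),
          n_sim, outlier_alpha, L, L / (n_sim + 1))
  x <- d$beta_exp; y <- d$beta_out; s <- d$se_out
  w <- 1 / s^2
  bloo <- loo_slopes(x, y, w)
  resid_obs <- w * (y - bloo * x)^2
  rss_obs <- sum(resid_obs)

  with_seed(seed, {
    # L x n_sim matrix of parametric outcome draws under the LOO-fitted model
    ystar <- matrix(stats::rnorm(L * n_sim, mean = bloo * x, sd = s),
                    nrow = L)
    sxx <- sum(w * x^2)
    sxy_star <- colSums(w * x * ystar)                   # length n_sim
    # LOO slopes per draw: (Sxy* - w_j x_j y*_j) / (Sxx - w_j x_j^2)
    num <- sweep(-(w * x) * ystar, 2, sxy_star, "+")
    bloo_star <- num / (sxx - w * x^2)
    resid_star <- w * (ystar - bloo_star * x)^2          # L x n_sim
    rss_star <- colSums(resid_star)
    global_pval <- (1 + sum(rss_star >= rss_obs)) / (n_sim + 1)
    outlier_p <- (1 + rowSums(resid_star >= resid_obs)) / (n_sim + 1)
  })
  p_bonf <- pmin(outlier_p * L, 1)
  is_out <- p_bonf < outlier_alpha
  outliers <- data.frame(snp_id = if ("snp_id" %in% names(d)) d$snp_id[is_out]
                                  else which(is_out),
                         pval_bonferroni = p_bonf[is_out],
                         stringsAsFactors = FALSE)

  raw <- mr_ivw(set)
  corrected <- NULL
  distortion_pval <- NA_real_
  if (any(is_out) && sum(!is_out) >= 2L) {
    keep <- d[!is_out, , drop = FALSE]
    corrected <- mr_ivw(keep)
    d_obs <- corrected$beta - raw$beta
    n_out <- sum(is_out)
    # IVW slope after removing a subset, via running sums
    swy <- w * x * y; swx <- w * x^2
    sxy_all <- sum(swy); sxx_all <- sum(swx)
    distortion_pval <- with_seed(seed + 1L, {
      dstar <- vapply(seq_len(n_sim), function(i) {
        drop_idx <- sample.int(L, n_out)
        (sxy_all - sum(swy[drop_idx])) / (sxx_all - sum(swx[drop_idx])) -
          raw$beta
      }, numeric(1))
      (1 + sum(abs(dstar) >= abs(d_obs))) / (n_sim + 1)
    })
  }

  structure(list(applicable = TRUE,
                 global_rss_observed = rss_obs,
                 global_pval = global_pval,
                 outlier_snps = outliers,
                 outlier_pvals_bonferroni = p_bonf,
                 estimate_raw = raw,
                 estimate_corrected = corrected,
                 distortion_pval = distortion_pval,
                 n_sim = n_sim, outlier_alpha = outlier_alpha, seed = seed),
            class = "presso_result")
}

#' @export
print.presso_result <- function(x, ...) {
  if (!isTRUE(x$applicable)) {
    cat("MR-PRESSO: not applicable -", x$note, "\n")
    return(invisible(x))
  }
  cat(sprintf("MR-PRESSO global test: RSS = %.4g, p = %.4g (%d sims)\n",
              x$global_rss_observed, x$global_pval, x$n_sim))
  if (nrow(x$outlier_snps)) {
    cat(sprintf("  outliers: %s\n",
                paste(x$outlier_snps$snp_id, collapse = ", ")))
    cat(sprintf("  raw beta %.4g -> corrected %.4g (distortion p = %.3g)\n",
                x$estimate_raw$beta, x$estimate_corrected$beta,
                x$distortion_pval))
  } else cat("  no outliers detected\n")
  invisible(x)
}

#' Leave-one-out IVW series
#'
#' Recomputes the IVW estimate omitting each instrument in turn. Omissions
#' that flip the sign of the estimate or move it by more than one full-set
#' standard error are flagged as influential.
#'
#' @param set An `"instrument_set"` with at least 3 instruments.
#' @return A list of class `"loo_series"`: `series` (data.frame with one row
#'   per omitted SNP: snp_id, beta, se, ci_low, ci_high, pval, nsnp,
#'   influential) and `full` (the full-set `"mr_estimate"`).
#' @export
leave_one_out <- function(set) {
  d <- as_instrument_df(set)
  L <- nrow(d)
  if (L < 3L) stopf("leave_one_out needs >= 3 instruments")
  full <- mr_ivw(set)
  rows <- lapply(seq_len(L), function(j) {
    est <- mr_ivw(d[-j, , drop = FALSE])
    data.frame(snp_id = if ("snp_id" %in% names(d)) d$snp_id[j] else j,
               beta = est$beta, se = est$se, ci_low = est$ci_low,
               ci_high = est$ci_high, pval = est$pval, nsnp = est$n_snp,
               stringsAsFactors = FALSE)
  })
  series <- do.call(rbind, rows)
  series$influential <- sign(series$beta) != sign(full$beta) |
    abs(series$beta - full$beta) > full$se
  structure(list(series = series, full = full), class = "loo_series")
}

#' @export
print.loo_series <- function(x, ...) {
  cat(sprintf("Leave-one-out IVW over %d instruments; full-set beta = %.4g\n",
              nrow(x$series), x$full$beta))
  infl <- x$series$snp_id[x$series$influential]
  if (length(infl)) cat("  influential omissions:",
                        paste(infl, collapse = ", "), "\n")
  else cat("  no influential single instrument\n")
  invisible(x)
}

#' Scatter- and funnel-plot data tables
#'
#' Produces the plain tables behind the standard MR visual diagnostics:
#' a scatter table of per-SNP exposure and outcome betas with their standard
#' errors plus one fitted line per supplied estimate (intercept 0 except for
#' MR-Egger), and a funnel table of per-SNP Wald ratios against their
#' precision `1/se(b_j)` with the IVW estimate as the vertical reference.
#' Rendering is left to the caller; writing these tables is enough to
#' reproduce the plots.
#'
#' @param set An `"instrument_set"`.
#' @param results Optional list of `"mr_estimate"` objects (or a single one)
#'   supplying fitted lines and the funnel reference.
#' @return A list: `scatter`, `lines`, `funnel`, `funnel_reference`.
#' @export
plot_data <- function(set, results = NULL) {
  d <- as_instrument_df(set)
  scatter <- data.frame(snp_id = if ("snp_id" %in% names(d)) d$snp_id
                                 else seq_len(nrow(d)),
                        beta_exp = d$beta_exp, se_exp = d$se_exp,
                        beta_out = d$beta_out, se_out = d$se_out,
                        stringsAsFactors = FALSE)
  if (inherits(results, "mr_estimate")) results <- list(results)
  lines <- NULL
  funnel_ref <- NA_real_
  if (length(results)) {
    lines <- do.call(rbind, lapply(results, function(r)
      data.frame(method = r$method,
                 intercept = if (r$method == "egger")
                   r$extra$egger_intercept else 0,
                 slope = r$beta, stringsAsFactors = FALSE)))
    ivw_idx <- which(vapply(results, function(r) r$method, "") == "ivw")
    if (length(ivw_idx)) funnel_ref <- results[[ivw_idx[1]]]$beta
  }
  wr <- wald_ratios(d)
  funnel <- data.frame(snp_id = scatter$snp_id, ratio = wr$b,
                       precision = 1 / wr$se, stringsAsFactors = FALSE)
  list(scatter = scatter, lines = lines, funnel = funnel,
       funnel_reference = funnel_ref)
}
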