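# Causal estimators for two-sample MR: Wald ratio, IVW, MR-Egger, weighted
# median, mode-based estimators, and multivariable IVW. All operate on a
# harmonized instrument set (or a bare data.frame with beta_exp, se_exp,
# beta_out, se_out) and return "mr_estimate" objects.

new_mr_estimate <- function(method, beta, se, n_snp, pval = NULL,
                            extra = list(), df = NULL) {
  if (is.null(pval)) {
    pval <- if (is.null(df)) z_pval(beta, se)
            else 2 * stats::pt(-abs(beta / se), df = df)
  }
  crit <- 1.96
  structure(list(method = method, beta = beta, se = se,
                 ci_low = beta - crit * se, ci_high = beta + crit * se,
                 pval = pval, n_snp = n_snp, extra = extra),
            class = "mr_estimate")
}

#' @export
print.mr_estimate <- function(x, ...) {
  cat(sprintf("%s: beta = %.4g (se %.4g), 95%% CI [%.4g, %.4g], p = %.3g, nSNP = %d\n",
              x$method, x$beta, x$se, x$ci_low, x$ci_high, x$pval, x$n_snp))
  if (x$method == "egger")
    cat(sprintf("  intercept = %.4g (se %.4g), p = %.3g\n",
                x$extra$egger_intercept, x$extra$egger_intercept_se,
                x$extra$egger_intercept_pval))
  invisible(x)
}

#' @export
as.data.frame.mr_estimate <- function(x, ...) {
  data.frame(method = x$method, nsnp = x$n_snp, beta = x$beta, se = x$se,
             ci_low = x$ci_low, ci_high = x$ci_high, pval = x$pval,
             stringsAsFactors = FALSE)
}

# Per-SNP Wald ratios and their first-order delta-method SEs (se_out/|beta_exp|,
# ignoring se_exp so that IVW over ratios matches weighted regression through
# the origin).
wald_ratios <- function(d) {
  if (any(d$beta_exp == 0))
    stopf("undefined Wald ratio: exposure beta is exactly 0 for %s",
          paste(d$snp_id[d$beta_exp == 0], collapse = ", "))
  list(b = d$beta_out / d$beta_exp, se = d$se_out / abs(d$beta_exp))
}

#' Wald-ratio causal estimate from a single instrument
#'
#' `beta_out / beta_exp` with first-order standard error
#' `se_out / |beta_exp|`, normal-theory CI and p-value. The package-wide
#' default ignores the exposure standard error (the approximation under which
#' IVW reduces to a weighted regression through the origin);
#' `second_order = TRUE` adds the exposure-side term
#' `sqrt(se_out^2/beta_exp^2 + beta_out^2 se_exp^2 / beta_exp^4)`.
#'
#' @param set An `"instrument_set"` (or one-row data.frame) holding exactly
#'   one instrument.
#' @param second_order Use the second-order delta SE.
#' @return An `"mr_estimate"` with method `"wald_ratio"`.
#' @export
mr_wald_ratio <- function(set, second_order = FALSE) {
  d <- as_instrument_df(set)
  if (nrow(d) != 1L) stopf("mr_wald_ratio needs exactly one instrument")
  wr <- wald_ratios(d)
  se <- if (second_order)
    sqrt(d$se_out^2 / d$beta_exp^2 +
           d$beta_out^2 * d$se_exp^2 / d$beta_exp^4)
  else wr$se
  new_mr_estimate("wald_ratio", wr$b, se, 1L)
}

#' Inverse-variance-weighted causal estimate
#'
#' Combines per-SNP Wald ratios `b_j` with weights `w_j = 1/se(b_j)^2`:
#' `beta = sum(w_j b_j) / sum(w_j)`, algebraically identical to a weighted
#' regression of outcome betas on exposure betas through the origin with
#' weights `1/se_out^2`. The default multiplicative random-effects model
#' scales the fixed-effect standard error `1/sqrt(sum(w_j))` by
#' `sqrt(max(Q/(L-1), 1))`, so under-dispersion is never rewarded; the
#' fixed-effect variant is available via `effects_model = "fixed"`.
#'
#' @param set An `"instrument_set"` with at least 2 instruments.
#' @param effects_model `"multiplicative_random"` (default) or `"fixed"`.
#' @return An `"mr_estimate"` with method `"ivw"`; `extra$Q` holds Cochran's
#'   Q about the IVW estimate.
#' @export
mr_ivw <- function(set, effects_model = c("multiplicative_random", "fixed")) {
  effects_model <- match.arg(effects_model)
  d <- as_instrument_df(set)
  if (nrow(d) < 2L)
    stopf("mr_ivw needs >= 2 instruments; use mr_wald_ratio for a single SNP")
  wr <- wald_ratios(d)
  w <- 1 / wr$se^2
  beta <- sum(w * wr$b) / sum(w)
  se_fixed <- sqrt(1 / sum(w))
  q <- sum(w * (wr$b - beta)^2)
  L <- nrow(d)
  se <- if (effects_model == "multiplicative_random")
    se_fixed * sqrt(max(q / (L - 1), 1)) else se_fixed
  new_mr_estimate("ivw", beta, se, L,
                  extra = list(Q = q, Q_df = L - 1,
                               effects_model = effects_model))
}

# Closed-form weighted least squares with intercept, used by Egger. Kept as
# explicit sums (not lm) so tests can cross-check against an independent fit.
wls_with_intercept <- function(x, y, w) {
  sw <- sum(w); sx <- sum(w * x); sy <- sum(w * y)
  sxx <- sum(w * x^2); sxy <- sum(w * x * y)
  det <- sw * sxx - sx^2
  if (abs(det) < 1e-14 * sw * sxx || sxx == 0)
    stopf("singular design: no spread in exposure betas")
  slope <- (sw * sxy - sx * sy) / det
  intercept <- (sy - slope * sx) / sw
  rss <- sum(w * (y - intercept - slope * x)^2)
  var_slope <- sw / det
  var_intercept <- sxx / det
  list(slope = slope, intercept = intercept, rss = rss,
       se_slope = sqrt(var_slope), se_intercept = sqrt(var_intercept))
}

#' MR-Egger regression
#'
#' Weighted regression of outcome betas on exposure betas *with* an
#' intercept, weights `1/se_out^2`. The slope estimates the causal effect
#' under the InSIDE assumption; the intercept estimates average directional
#' pleiotropy and carries its own SE and p-value (reported in `extra`).
#' Instruments are first oriented so all exposure betas are positive
#' (SNP-wise sign flips of both axes). Standard errors use multiplicative
#' random-effects scaling `sqrt(max(Q_egger/(L-2), 1))`; inference uses the t
#' distribution with `L - 2` degrees of freedom.
#'
#' @param set An `"instrument_set"` with at least 3 instruments.
#' @return An `"mr_estimate"` with method `"egger"`; `extra` holds
#'   `egger_intercept`, `egger_intercept_se`, `egger_intercept_pval`, `Q`.
#' @export
mr_egger <- function(set) {
  d <- as_instrument_df(set)
  L <- nrow(d)
  if (L < 3L) stopf("mr_egger needs >= 3 instruments")
  flip <- sign(d$beta_exp)
  flip[flip == 0] <- 1
  x <- d$beta_exp * flip
  y <- d$beta_out * flip
  w <- 1 / d$se_out^2
  fit <- wls_with_intercept(x, y, w)
  scale <- sqrt(max(fit$rss / (L - 2), 1))
  se_slope <- fit$se_slope * scale
  se_int <- fit$se_intercept * scale
  new_mr_estimate("egger", fit$slope, se_slope, L, df = L - 2,
                  extra = list(egger_intercept = fit$intercept,
                               egger_intercept_se = se_int,
                               egger_intercept_pval =
                                 2 * stats::pt(-abs(fit$intercept / se_int),
                                               df = L - 2),
                               Q = fit$rss, Q_df = L - 2))
}

# Weighted median of ratios b with normalized weights w (summing to 1):
# cumulative weight s_j = cumsum(w)_j - w_j/2; linear interpolation at 0.5.
weighted_median_point <- function(b, w) {
  o <- order(b)
  b <- b[o]; w <- w[o] / sum(w)
  s <- cumsum(w) - w / 2
  if (s[1] >= 0.5) return(b[1])
  if (s[length(s)] < 0.5) return(b[length(b)])
  j <- max(which(s < 0.5))
  b[j] + (b[j + 1] - b[j]) * (0.5 - s[j]) / (s[j + 1] - s[j])
}

#' Weighted-median causal estimate
#'
#' Orders the Wald ratios and interpolates the inverse-variance-weighted
#' cumulative distribution at 50%; consistent when instruments carrying at
#' least half the weight are valid. The standard error comes from a
#' parametric bootstrap: each ratio is resampled as
#' `Normal(b_j, se(b_j))`, the weighted median recomputed, and the SD over
#' `n_boot` replicates taken.
#'
#' @param set An `"instrument_set"` with at least 3 instruments.
#' @param n_boot Bootstrap replicates (default 1000).
#' @param seed RNG seed for the bootstrap.
#' @return An `"mr_estimate"` with method `"weighted_median"`.
#' @export
mr_weighted_median <- function(set, n_boot = 1000, seed = 1) {
  d <- as_instrument_df(set)
  if (nrow(d) < 3L) stopf("mr_weighted_median needs >= 3 instruments")
  wr <- wald_ratios(d)
  w <- 1 / wr$se^2
  est <- weighted_median_point(wr$b, w)
  se <- with_seed(seed, {
    reps <- vapply(seq_len(n_boot), function(i) {
      bs <- stats::rnorm(length(wr$b), wr$b, wr$se)
      weighted_median_point(bs, w)
    }, numeric(1))
    stats::sd(reps)
  })
  new_mr_estimate("weighted_median", est, se, nrow(d),
                  extra = list(n_boot = n_boot, seed = seed))
}

# Gaussian-kernel weighted KDE mode over a fine grid. Bandwidth:
# bandwidth_factor * 1.06 * min(sd, mad) * L^(-1/5), with mad on the
# normal-consistent scale (MAD/0.6745); falls back to sd when mad is 0.
kde_mode <- function(b, w, bandwidth_factor) {
  if (length(unique(b)) == 1L) return(b[1])
  s <- min(stats::sd(b), stats::mad(b))
  if (s == 0) s <- stats::sd(b)
  h <- bandwidth_factor * 1.06 * s * length(b)^(-1 / 5)
  grid <- seq(min(b) - 3 * h, max(b) + 3 * h, length.out = 512)
  w <- w / sum(w)
  dens <- vapply(grid, function(g) sum(w * stats::dnorm((g - b) / h)),
                 numeric(1))
  grid[which.max(dens)]
}

#' Mode-based causal estimate (simple and weighted mode)
#'
#' The mode of the Gaussian kernel density over the Wald ratios — unweighted
#' for the simple mode, inverse-variance weighted for the weighted mode.
#' Bandwidth is `bandwidth_factor * 1.06 * min(SD, MAD/0.6745) * L^(-1/5)`
#' over the ratio set; the standard error comes from the same parametric
#' bootstrap as [mr_weighted_median()]. When all ratios coincide the common
#' value is returned with a bootstrap SE.
#'
#' @param set An `"instrument_set"` with at least 3 instruments.
#' @param weighted Use inverse-variance weights (`TRUE` = weighted mode).
#' @param bandwidth_factor Multiplier on the default bandwidth rule.
#' @param n_boot Bootstrap replicates (default 1000).
#' @param seed RNG seed for the bootstrap.
#' @return An `"mr_estimate"` with method `"weighted_mode"` or
#'   `"simple_mode"`.
#' @export
mr_mode <- function(set, weighted = TRUE, bandwidth_factor = 1,
                    n_boot = 1000, seed = 1) {
  d <- as_instrument_df(set)
  if (nrow(d) < 3L) stopf("mr_mode needs >= 3 instruments")
  if (bandwidth_factor <= 0) stopf("bandwidth_factor must be positive")
  wr <- wald_ratios(d)
  w <- if (weighted) 1 / wr$se^2 else rep(1, length(wr$b))
  est <- kde_mode(wr$b, w, bandwidth_factor)
  se <- with_seed(seed, {
    reps <- vapply(seq_len(n_boot), function(i) {
      bs <- stats::rnorm(length(wr$b), wr$b, wr$se)
      kde_mode(bs, w, bandwidth_factor)
    }, numeric(1))
    stats::sd(reps)
  })
  new_mr_estimate(if (weighted) "weighted_mode" else "simple_mode",
                  est, se, nrow(d),
                  extra = list(bandwidth_factor = bandwidth_factor,
                               n_boot = n_boot, seed = seed))
}

#' Multivariable IVW (MVMR)
#'
#' Zero-intercept weighted regression of SNP-outcome betas on a matrix of
#' SNP-exposure betas (one column per exposure) with weights `1/se_out^2`,
#' solved from the normal equations. Returns one conditional causal estimate
#' per exposure with multiplicative random-effects scaling
#' `sqrt(max(Q/(L-k), 1))`.
#'
#' @param beta_out,se_out SNP-outcome betas and standard errors.
#' @param beta_exp_matrix Numeric matrix, SNPs in rows, exposures in columns
#'   (column names label the estimates).
#' @return Named list of `"mr_estimate"` objects, one per exposure, method
#'   `"mvmr_ivw"`.
#' @export
mr_mvmr_ivw <- function(beta_out, se_out, beta_exp_matrix) {
  X <- as.matrix(beta_exp_matrix)
  L <- nrow(X); k <- ncol(X)
  if (length(beta_out) != L || length(se_out) != L)
    stopf("beta_out/se_out must have one entry per SNP row")
  if (L < k + 2) stopf("MVMR needs at least #exposures + 2 SNPs")
  if (is.null(colnames(X))) colnames(X) <- paste0("exposure_", seq_len(k))
  zero_cols <- colSums(X != 0) == 0L
  if (any(zero_cols)) {
    # an identically-zero exposure column carries no information: drop it
    # from the fit (reducing to the lower-dimensional model) and report it
    # as not estimable rather than failing the whole solve
    kept <- mr_mvmr_ivw(beta_out, se_out, X[, !zero_cols, drop = FALSE])
    dropped <- lapply(colnames(X)[zero_cols], function(nm)
      new_mr_estimate("mvmr_ivw", NA_real_, NA_real_, L, pval = NA_real_,
                      extra = list(exposure = nm,
                                   note = "all-zero exposure column")))
    names(dropped) <- colnames(X)[zero_cols]
    return(c(kept, dropped)[colnames(X)])
  }
  qr_x <- qr(X)
  if (qr_x$rank < k) {
    bad <- colnames(X)[setdiff(seq_len(k), qr_x$pivot[seq_len(qr_x$rank)])]
    stopf("singular design: collinear exposure column(s): %s",
          paste(if (length(bad)) bad else "unnamed", collapse = ", "))
  }
  w <- 1 / se_out^2
  XtWX <- crossprod(X, w * X)
  XtWy <- crossprod(X, w * beta_out)
  beta <- unname(solve(XtWX, XtWy)[, 1])
  resid <- beta_out - X %*% beta
  q <- sum(w * resid^2)
  scale2 <- max(q / (L - k), 1)
  vcov <- solve(XtWX) * scale2
  nms <- colnames(X)
  res <- lapply(seq_len(k), function(j)
    new_mr_estimate("mvmr_ivw", beta[j], sqrt(vcov[j, j]), L,
                    extra = list(exposure = nms[j], Q = q, Q_df = L - k)))
  names(res) <- nms
  res
}

#' Run every applicable estimator on an instrument set
#'
#' Dispatches by instrument count: 1 SNP gives the Wald ratio only; 2 SNPs
#' add IVW; 3 or more add MR-Egger, weighted median, and the two mode
#' estimators. Methods whose minimum instrument count is not met are marked
#' not-applicable rather than computed.
#'
#' @param set An `"instrument_set"`.
#' @param methods Which estimators to attempt.
#' @param n_boot,seed Bootstrap settings passed to the median/mode methods.
#' @return A tidy `data.frame` (method, nsnp, beta, se, ci_low, ci_high,
#'   pval, note) with one row per requested method; not-applicable methods
#'   have `NA` estimates and an explanatory note.
#' @export
mr_all <- function(set,
                   methods = c("ivw", "egger", "weighted_median",
                               "simple_mode", "weighted_mode"),
                   n_boot = 1000, seed = 1) {
  d <- as_instrument_df(set)
  L <- nrow(d)
  min_snp <- c(wald_ratio = 1, ivw = 2, egger = 3, weighted_median = 3,
               simple_mode = 3, weighted_mode = 3)
  run_one <- function(m) {
    if (m == "ivw" && L == 1L) {
      # single-SNP sets degrade to the Wald ratio (degenerate meta-analysis)
      est <- mr_wald_ratio(set)
      return(cbind(as.data.frame(est),
                   note = "single SNP: Wald-ratio fallback",
                   stringsAsFactors = FALSE))
    }
    if (L < min_snp[[m]]) {
      return(data.frame(method = m, nsnp = L, beta = NA_real_, se = NA_real_,
                        ci_low = NA_real_, ci_high = NA_real_,
                        pval = NA_real_,
                        note = sprintf("not applicable: needs >= %d SNPs",
                                       min_snp[[m]]),
                        stringsAsFactors = FALSE))
    }
    est <- switch(m,
      wald_ratio = mr_wald_ratio(set),
      ivw = if (L == 1L) mr_wald_ratio(set) else mr_ivw(set),
      egger = mr_egger(set),
      weighted_median = mr_weighted_median(set, n_boot = n_boot, seed = seed),
      simple_mode = mr_mode(set, weighted = FALSE, n_boot = n_boot,
                            seed = seed),
      weighted_mode = mr_mode(set, weighted = TRUE, n_boot = n_boot,
                              seed = seed))
    cbind(as.data.frame(est), note = "", stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, lapply(methods, run_one))
  rownames(out) <- NULL
  out
}
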