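#' Select instrumental variables by significance and greedy LD clumping
#'
#' Keeps SNPs reaching the exposure significance threshold and prunes them to
#' approximately independent index variants: significant SNPs are sorted by
#' ascending p-value (ties broken lexicographically by `snp_id`), the most
#' significant remaining SNP is kept, and every remaining SNP on the same
#' chromosome within `clump_kb` kilobases and with LD `r2 >= r2_threshold`
#' against it is discarded; this repeats until no SNP remains. The defaults
#' are the genome-wide conventions `p < 5e-8`, `r2 < 0.01` within a 5,000 kb
#' window.
#'
#' @param exposure Exposure summary-statistics table (see [read_gwas()]).
#' @param ld Optional pairwise LD table with columns `snp_a, snp_b, r2`.
#'   Missing pairs are treated as `r2 = 0` (recorded in the selection log).
#' @param p_threshold Significance threshold on the exposure p-value.
#' @param r2_threshold LD pruning threshold.
#' @param clump_kb Window, in kb, within which LD pruning applies.
#' @return Character vector of kept `snp_id`s, with a per-SNP disposition
#'   `data.frame` attached as attribute `"selection_log"`.
#' @examples
#' exp <- simulate_summary_stats(sim_config(seed = 3))$exposure
#' head(select_instruments(exp))
#' @export
select_instruments <- function(exposure, ld = NULL, p_threshold = 5e-8,
                               r2_threshold = 0.01, clump_kb = 5000) {
  check_gwas_table(exposure, "exposure")
  if (!is.numeric(p_threshold) || p_threshold <= 0 || p_threshold > 1)
    stopf("p_threshold must be in (0, 1]")
  if (!is.numeric(r2_threshold) || r2_threshold < 0 || r2_threshold > 1)
    stopf("r2_threshold must be in [0, 1]")
  if (!is.numeric(clump_kb) || clump_kb < 0)
    stopf("clump_kb must be non-negative")

  log <- data.frame(snp_id = exposure$snp_id, disposition = "dropped",
                    reason = "pval >= threshold", stringsAsFactors = FALSE)
  sig <- exposure[exposure$pval < p_threshold, , drop = FALSE]
  if (nrow(sig) == 0L) {
    res <- character()
    attr(res, "selection_log") <- log
    return(res)
  }
  sig <- sig[order(sig$pval, sig$snp_id), , drop = FALSE]

  r2_lookup <- make_r2_lookup(ld)
  kept <- character()
  remaining <- sig
  while (nrow(remaining) > 0L) {
    idx <- remaining[1L, ]
    kept <- c(kept, idx$snp_id)
    log$disposition[log$snp_id == idx$snp_id] <- "kept"
    log$reason[log$snp_id == idx$snp_id] <- "index SNP"
    remaining <- remaining[-1L, , drop = FALSE]
    if (nrow(remaining) == 0L) break
    near <- remaining$chr == idx$chr &
      abs(remaining$pos - idx$pos) <= clump_kb * 1000
    if (any(near)) {
      r2 <- r2_lookup(idx$snp_id, remaining$snp_id[near])
      clumped <- near
      clumped[near] <- r2 >= r2_threshold
      if (any(clumped)) {
        ids <- remaining$snp_id[clumped]
        log$disposition[log$snp_id %in% ids] <- "dropped"
        log$reason[log$snp_id %in% ids] <-
          sprintf("clumped against %s", idx$snp_id)
        remaining <- remaining[!clumped, , drop = FALSE]
      }
    }
  }
  res <- kept
  attr(res, "selection_log") <- log
  res
}

# Symmetric r2 lookup over unordered pairs; duplicate entries collapse to
# their maximum (the conservative choice for pruning); absent pairs are 0.
make_r2_lookup <- function(ld) {
  if (is.null(ld) || nrow(ld) == 0L) {
    return(function(a, b) rep(0, length(b)))
  }
  key <- paste(pmin(ld$snp_a, ld$snp_b), pmax(ld$snp_a, ld$snp_b),
               sep = "\r")
  val <- tapply(ld$r2, key, max)
  env <- new.env(parent = emptyenv(), size = length(val))
  for (i in seq_along(val)) assign(names(val)[i], val[[i]], envir = env)
  function(a, b) {
    vapply(paste(pmin(a, b), pmax(a, b), sep = "\r"), function(k) {
      if (exists(k, envir = env, inherits = FALSE))
        get(k, envir = env) else 0
    }, numeric(1), USE.NAMES = FALSE)
  }
}

#' Harmonize exposure and outcome associations to a common effect allele
#'
#' For each selected SNP present in both tables, aligns the outcome record to
#' the exposure's effect allele: matching orientations are copied; swapped
#' alleles negate the outcome beta and reflect its allele frequency (flagged
#' `flipped`); strand-complement representations are reconciled the same way.
#' Palindromic (A/T or C/G) SNPs, whose strand cannot be resolved from allele
#' labels, are handled per `palindromic_policy`:
#' `"keep_if_eaf_informative"` (default) drops them when either study's
#' effect-allele frequency lies in the ambiguous band (0.42, 0.58) and
#' otherwise aligns by frequency; `"drop"` removes all of them; `"keep_all"`
#' aligns by allele labels only. SNPs absent from the outcome or with
#' irreconcilable alleles are dropped with a logged reason, never silently
#' kept; there is no proxy-SNP search.
#'
#' @param exposure,outcome Summary-statistics tables (see [read_gwas()]).
#' @param snps Character vector of SNP ids to harmonize (typically from
#'   [select_instruments()]).
#' @param palindromic_policy Handling of strand-ambiguous SNPs (see above).
#' @param exposure_name,outcome_name Labels carried into reports.
#' @param thresholds Optional named list echoing the selection thresholds.
#' @return An object of class `"instrument_set"`: a list with the harmonized
#'   `instruments` data.frame (`snp_id, beta_exp, se_exp, beta_out, se_out,
#'   eaf, flipped, palindromic_kept`), names, `selection_log` and
#'   `thresholds`.
#' @export
harmonize <- function(exposure, outcome, snps,
                      palindromic_policy = c("keep_if_eaf_informative",
                                             "drop", "keep_all"),
                      exposure_name = "exposure", outcome_name = "outcome",
                      thresholds = NULL) {
  palindromic_policy <- match.arg(palindromic_policy)
  check_gwas_table(exposure, "exposure")
  check_gwas_table(outcome, "outcome")
  snps <- as.character(snps)
  if (!all(snps %in% exposure$snp_id))
    stopf("snp(s) not present in the exposure table: %s",
          paste(setdiff(snps, exposure$snp_id), collapse = ", "))

  ex <- exposure[match(snps, exposure$snp_id), ]
  out_idx <- match(snps, outcome$snp_id)
  oc <- outcome[ifelse(is.na(out_idx), 1L, out_idx), ]
  n <- length(snps)

  reason <- character(n)                 # "" = kept
  flipped <- logical(n)
  pal_kept <- logical(n)
  beta_out <- rep(NA_real_, n)

  pal <- is_palindromic(ex$effect_allele, ex$other_allele)
  comp_ea <- unname(DNA_COMPLEMENT[oc$effect_allele])
  comp_oa <- unname(DNA_COMPLEMENT[oc$other_allele])
  same <- oc$effect_allele == ex$effect_allele &
    oc$other_allele == ex$other_allele
  swapped <- oc$effect_allele == ex$other_allele &
    oc$other_allele == ex$effect_allele
  comp_same <- comp_ea == ex$effect_allele & comp_oa == ex$other_allele
  comp_swapped <- comp_ea == ex$other_allele & comp_oa == ex$effect_allele

  reason[is.na(out_idx)] <- "absent from outcome"
  todo <- reason == ""

  # non-palindromic: allele labels decide orientation, complements reconcile
  np <- todo & !pal
  ok_np <- np & (same | swapped | comp_same | comp_swapped)
  flipped[ok_np] <- (swapped | comp_swapped)[ok_np]
  beta_out[ok_np] <- ifelse(flipped[ok_np], -oc$beta[ok_np], oc$beta[ok_np])
  reason[np & !ok_np] <- "irreconcilable alleles"

  # palindromic: strand cannot be resolved from labels
  pp <- todo & pal
  if (any(pp)) {
    if (palindromic_policy == "drop") {
      reason[pp] <- "palindromic"
    } else {
      o_pal <- is_palindromic(oc$effect_allele, oc$other_allele)
      same_pair <- o_pal & (oc$effect_allele == ex$effect_allele |
                              oc$effect_allele == ex$other_allele)
      reason[pp & !same_pair] <- "irreconcilable alleles"
      pp_ok <- pp & same_pair
      if (palindromic_policy == "keep_if_eaf_informative") {
        amb <- (ex$eaf > 0.42 & ex$eaf < 0.58) |
          (oc$eaf > 0.42 & oc$eaf < 0.58)
        reason[pp_ok & amb] <- "palindromic, ambiguous eaf"
        pp_ok <- pp_ok & !amb
        # align by frequency: effect alleles agree iff eafs fall on the same
        # side of 0.5 (allele labels cannot settle strand for these SNPs)
        flipped[pp_ok] <- ((ex$eaf - 0.5) * (oc$eaf - 0.5) < 0)[pp_ok]
      } else { # keep_all: trust the allele labels as printed
        flipped[pp_ok] <- (oc$effect_allele == ex$other_allele)[pp_ok]
      }
      beta_out[pp_ok] <- ifelse(flipped[pp_ok], -oc$beta[pp_ok],
                                oc$beta[pp_ok])
      pal_kept[pp_ok] <- TRUE
    }
  }

  keep <- reason == ""
  log <- data.frame(snp_id = snps,
                    disposition = ifelse(keep, "kept", "dropped"),
                    reason = reason, stringsAsFactors = FALSE)
  inst <- data.frame(snp_id = ex$snp_id[keep], beta_exp = ex$beta[keep],
                     se_exp = ex$se[keep], beta_out = beta_out[keep],
                     se_out = oc$se[keep], eaf = ex$eaf[keep],
                     flipped = flipped[keep], palindromic_kept = pal_kept[keep],
                     stringsAsFactors = FALSE)
  rownames(inst) <- NULL
  new_instrument_set(inst, exposure_name, outcome_name, log, thresholds)
}

new_instrument_set <- function(instruments, exposure_name, outcome_name,
                               selection_log = NULL, thresholds = NULL) {
  structure(list(instruments = instruments,
                 exposure_name = exposure_name, outcome_name = outcome_name,
                 selection_log = selection_log, thresholds = thresholds),
            class = "instrument_set")
}

#' @export
print.instrument_set <- function(x, ...) {
  cat(sprintf("Instrument set: %s -> %s, %d SNP(s)\n",
              x$exposure_name, x$outcome_name, nrow(x$instruments)))
  if (nrow(x$instruments)) {
    f <- f_statistic(x$instruments$beta_exp, x$instruments$se_exp)
    cat(sprintf("  mean F = %.1f; %d flipped; %d palindromic kept\n",
                mean(f), sum(x$instruments$flipped),
                sum(x$instruments$palindromic_kept)))
  }
  invisible(x)
}

# Coerce an instrument_set or bare data.frame to the harmonized layout.
as_instrument_df <- function(set) {
  d <- if (inherits(set, "instrument_set")) set$instruments else set
  need <- c("beta_exp", "se_exp", "beta_out", "se_out")
  if (!is.data.frame(d) || !all(need %in% names(d)))
    stopf("expected an instrument_set or data.frame with columns %s",
          paste(need, collapse = ", "))
  d
}

#' Per-variant instrument strength (F statistic)
#'
#' `F = beta^2 / se^2` for each variant; a set-level mean below 10 is the
#' conventional weak-instrument warning threshold.
#'
#' @param beta_exp Exposure betas (or an `"instrument_set"`, in which case
#'   `se_exp` is ignored).
#' @param se_exp Exposure standard errors.
#' @return Numeric vector of F statistics.
#' @examples
#' f_statistic(0.1, 0.02)  # 25
#' @export
f_statistic <- function(beta_exp, se_exp = NULL) {
  if (inherits(beta_exp, "instrument_set")) {
    d <- beta_exp$instruments
    beta_exp <- d$beta_exp; se_exp <- d$se_exp
  }
  if (any(se_exp <= 0)) stopf("standard errors must be positive")
  beta_exp^2 / se_exp^2
}

#' Per-variant phenotypic variance explained
#'
#' `2 * eaf * (1 - eaf) * beta^2` on the standardized-trait scale; the
#' set-level R-squared is the sum over instruments. Values are clipped to
#' `[0, 1]` with a warning; missing `eaf` yields `NA` (excluded from set
#' sums).
#'
#' @param eaf Effect-allele frequencies (or an `"instrument_set"`).
#' @param beta_exp Exposure betas.
#' @return Numeric vector of per-variant R-squared values.
#' @examples
#' variance_explained(0.5, 0.1)  # 0.005
#' @export
variance_explained <- function(eaf, beta_exp = NULL) {
  if (inherits(eaf, "instrument_set")) {
    d <- eaf$instruments
    beta_exp <- d$beta_exp; eaf <- d$eaf
  }
  r2 <- 2 * eaf * (1 - eaf) * beta_exp^2
  if (any(r2 > 1, na.rm = TRUE)) {
    warnf("variance explained above 1 clipped")
    r2 <- pmin(r2, 1)
  }
  pmax(r2, 0)
}

#' Instrument-strength diagnostics for a harmonized set
#'
#' @param set An `"instrument_set"`.
#' @return A list with per-SNP `F` and `r2`, their set-level summaries
#'   (`mean_f`, `total_r2`), and `weak` (`TRUE` when mean F < 10, with a
#'   warning).
#' @export
instrument_diagnostics <- function(set) {
  d <- as_instrument_df(set)
  f <- f_statistic(d$beta_exp, d$se_exp)
  r2 <- if ("eaf" %in% names(d)) variance_explained(d$eaf, d$beta_exp)
        else rep(NA_real_, nrow(d))
  weak <- mean(f) < 10
  if (weak) warnf("mean instrument F = %.2f < 10: weak-instrument bias likely",
                  mean(f))
  list(F = f, r2 = r2, mean_f = mean(f), total_r2 = sum(r2, na.rm = TRUE),
       weak = weak)
}
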