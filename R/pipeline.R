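# Config-driven orchestration: discovery cohort -> replication cohort ->
# fixed-effect meta-analysis over many exposures, plus the mediation screen.

#' Read a run configuration from YAML or JSON
#'
#' The configuration mirrors the arguments of [run_screen()] /
#' [run_mediation()]: named `exposures` (paths to summary-statistics files),
#' named `outcomes` (one per cohort), optional `ld` path, `thresholds`
#' (`p_threshold`, `r2_threshold`, `clump_kb`), `methods`, `seed`, `alpha`,
#' an optional `mediation` block (`exposure`, `mediators`, `outcome`), and
#' an optional `col_map` for foreign column dialects.
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file.
#' @return A named list.
#' @export
read_run_config <- function(path) {
  if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::read_json(path, simplifyVector = TRUE)
  else yaml::read_yaml(path)
}

resolve_table <- function(x, col_map = NULL) {
  if (is.character(x) && length(x) == 1L) read_gwas(x, col_map = col_map)
  else check_gwas_table(x)
}

default_thresholds <- function(cfg) {
  th <- cfg$thresholds
  list(p_threshold = th$p_threshold %||% 5e-8,
       r2_threshold = th$r2_threshold %||% 0.01,
       clump_kb = th$clump_kb %||% 5000)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Screen many exposures against an outcome across cohorts
#'
#' Runs the full two-sample MR analysis for every exposure x cohort pair:
#' instrument selection with greedy LD clumping, allele harmonization,
#' instrument-strength diagnostics (F, variance explained), every applicable
#' causal estimator ([mr_all()]), and the sensitivity suite (Cochran's Q
#' about IVW and Egger, the Egger intercept test, MR-PRESSO when at least 4
#' instruments survive, leave-one-out, scatter/funnel plot data). Per
#' exposure, the per-cohort IVW estimates are then combined by fixed-effect
#' meta-analysis, and a findings table flags exposures with IVW `p <= alpha`
#' per cohort and in the meta-analysis. Every stochastic step draws its seed
#' deterministically from `config$seed`, so reruns with an identical config
#' are byte-identical; a manifest records thresholds, seeds and versions,
#' and per-SNP dispositions are logged. A failing exposure is logged and
#' skipped, never aborting the screen.
#'
#' @param config Named list (or [read_run_config()] output) with `exposures`
#'   (named list of tables or file paths), `outcomes` (named list, one per
#'   cohort), optional `ld`, `thresholds`, `methods`, `n_boot`,
#'   `presso_n_sim` (default 1000), `seed` (default 1), `alpha` (default
#'   0.05), `palindromic_policy`, `col_map`.
#' @param out_dir Optional directory: tidy TSVs (`estimates.tsv`,
#'   `sensitivity.tsv`, `meta.tsv`, `findings.tsv`, `selection_log.tsv`,
#'   per-pair plot-data TSVs) and `manifest.json` are written there.
#' @return A list of class `"mr_screen"`: `estimates`, `sensitivity`,
#'   `meta`, `findings`, `selection_log`, `diagnostics`, `plot_data`,
#'   `manifest`, `errors`.
#' @export
run_screen <- function(config, out_dir = NULL) {
  th <- default_thresholds(config)
  alpha <- config$alpha %||% 0.05
  seed <- config$seed %||% 1L
  n_boot <- config$n_boot %||% 1000L
  methods <- config$methods %||% c("ivw", "egger", "weighted_median",
                                   "simple_mode", "weighted_mode")
  policy <- config$palindromic_policy %||% "keep_if_eaf_informative"
  ld <- if (!is.null(config$ld)) {
    if (is.character(config$ld)) read_ld(config$ld) else config$ld
  } else NULL
  exposures <- lapply(config$exposures, resolve_table,
                      col_map = config$col_map)
  outcomes <- lapply(config$outcomes, resolve_table)
  if (is.null(names(exposures)) || is.null(names(outcomes)))
    stopf("exposures and outcomes must be named lists")

  estimates <- list(); sens <- list(); sel_logs <- list()
  diagnostics <- list(); plots <- list(); errors <- list()

  for (i in seq_along(exposures)) {
    exp_name <- names(exposures)[i]
    snps <- tryCatch(
      select_instruments(exposures[[i]], ld, th$p_threshold,
                         th$r2_threshold, th$clump_kb),
      error = function(e) e)
    if (inherits(snps, "error")) {
      errors[[exp_name]] <- conditionMessage(snps)
      next
    }
    sel_logs[[exp_name]] <- cbind(exposure = exp_name,
                                  attr(snps, "selection_log"),
                                  stringsAsFactors = FALSE)
    if (length(snps) == 0L) {
      errors[[exp_name]] <- "no instruments passed selection"
      next
    }
    for (j in seq_along(outcomes)) {
      cohort <- names(outcomes)[j]
      pair_seed <- derive_seed(seed, i, j)
      res <- tryCatch({
        set <- harmonize(exposures[[i]], outcomes[[j]], snps,
                         palindromic_policy = policy,
                         exposure_name = exp_name, outcome_name = cohort,
                         thresholds = th)
        L <- nrow(set$instruments)
        if (L == 0L) stopf("no instruments survived harmonization")
        diag <- suppressWarnings(instrument_diagnostics(set))
        est <- mr_all(set, methods = methods, n_boot = n_boot,
                      seed = pair_seed)
        est <- cbind(exposure = exp_name, outcome = config$outcome_name %||%
                       "outcome", cohort = cohort, est,
                     stringsAsFactors = FALSE)
        s_row <- pair_sensitivity(set, exp_name, cohort,
                                  config$presso_n_sim %||% 1000, pair_seed)
        ivw_est <- tryCatch(if (L >= 2) mr_ivw(set) else mr_wald_ratio(set),
                            error = function(e) NULL)
        pd <- plot_data(set, if (!is.null(ivw_est)) list(ivw_est))
        list(est = est, sens = s_row, diag = diag, pd = pd)
      }, error = function(e) e)
      if (inherits(res, "error")) {
        errors[[paste(exp_name, cohort, sep = ".")]] <- conditionMessage(res)
        next
      }
      key <- paste(exp_name, cohort, sep = ".")
      estimates[[key]] <- res$est
      sens[[key]] <- res$sens
      diagnostics[[key]] <- data.frame(exposure = exp_name, cohort = cohort,
                                       nsnp = length(res$diag$F),
                                       mean_f = res$diag$mean_f,
                                       total_r2 = res$diag$total_r2,
                                       weak = res$diag$weak,
                                       stringsAsFactors = FALSE)
      plots[[key]] <- res$pd
    }
  }

  estimates <- if (length(estimates)) do.call(rbind, estimates) else NULL
  sens <- if (length(sens)) do.call(rbind, sens) else NULL
  diagnostics <- if (length(diagnostics)) do.call(rbind, diagnostics) else NULL
  sel_log <- if (length(sel_logs)) do.call(rbind, sel_logs) else NULL
  if (!is.null(estimates)) rownames(estimates) <- NULL
  if (!is.null(sens)) rownames(sens) <- NULL
  if (!is.null(diagnostics)) rownames(diagnostics) <- NULL
  if (!is.null(sel_log)) rownames(sel_log) <- NULL

  meta <- NULL; findings <- NULL
  if (!is.null(estimates)) {
    ivw <- estimates[estimates$method %in% c("ivw", "wald_ratio") &
                       !is.na(estimates$beta), ]
    ivw <- ivw[!duplicated(paste(ivw$exposure, ivw$cohort)), ]
    meta_rows <- list(); find_rows <- list()
    for (exp_name in unique(ivw$exposure)) {
      sub <- ivw[ivw$exposure == exp_name, ]
      m <- meta_fixed(sub$beta, sub$se, labels = sub$cohort)
      meta_rows[[exp_name]] <- data.frame(
        exposure = exp_name, n_cohorts = nrow(sub),
        beta_meta = m$beta_meta, se_meta = m$se_meta,
        ci_low = m$ci_low, ci_high = m$ci_high, pval = m$pval,
        q_cohorts = if (is.null(m$heterogeneity)) NA_real_
                    else m$heterogeneity$Q,
        q_pval = if (is.null(m$heterogeneity)) NA_real_
                 else m$heterogeneity$pval,
        stringsAsFactors = FALSE)
      fr <- data.frame(exposure = exp_name, cohort = sub$cohort,
                       beta = sub$beta, pval = sub$pval,
                       significant = sub$pval <= alpha,
                       stringsAsFactors = FALSE)
      fr <- rbind(fr, data.frame(exposure = exp_name, cohort = "meta",
                                 beta = m$beta_meta, pval = m$pval,
                                 significant = m$pval <= alpha,
                                 stringsAsFactors = FALSE))
      find_rows[[exp_name]] <- fr
    }
    meta <- do.call(rbind, meta_rows); rownames(meta) <- NULL
    findings <- do.call(rbind, find_rows); rownames(findings) <- NULL
  }

  manifest <- list(package = "mrscreen",
                   version = as.character(utils::packageVersion("mrscreen")),
                   thresholds = th, alpha = alpha, seed = seed,
                   n_boot = n_boot, methods = methods,
                   palindromic_policy = policy,
                   exposures = names(exposures), cohorts = names(outcomes),
                   errors = errors)

  out <- structure(list(estimates = estimates, sensitivity = sens,
                        meta = meta, findings = findings,
                        selection_log = sel_log, diagnostics = diagnostics,
                        plot_data = plots, manifest = manifest,
                        errors = errors),
                   class = "mr_screen")
  if (!is.null(out_dir)) write_screen(out, out_dir)
  out
}

# One sensitivity-report row per exposure x cohort pair.
pair_sensitivity <- function(set, exp_name, cohort, presso_n_sim, seed) {
  L <- nrow(set$instruments)
  q_ivw <- if (L >= 2) cochran_q(set, "ivw") else NULL
  q_egger <- if (L >= 3) cochran_q(set, "egger") else NULL
  eg <- if (L >= 3) egger_intercept_test(set) else NULL
  pr <- if (L >= 4) mr_presso(set, n_sim = presso_n_sim, seed = seed)
        else NULL
  loo <- if (L >= 3) leave_one_out(set) else NULL
  data.frame(
    exposure = exp_name, cohort = cohort, nsnp = L,
    q_ivw = q_ivw$Q %||% NA_real_, q_ivw_pval = q_ivw$pval %||% NA_real_,
    q_egger = q_egger$Q %||% NA_real_,
    q_egger_pval = q_egger$pval %||% NA_real_,
    egger_intercept = eg$intercept %||% NA_real_,
    egger_intercept_pval = eg$pval %||% NA_real_,
    presso_global_pval = if (!is.null(pr) && isTRUE(pr$applicable))
      pr$global_pval else NA_real_,
    presso_n_outliers = if (!is.null(pr) && isTRUE(pr$applicable))
      nrow(pr$outlier_snps) else NA_integer_,
    loo_influential = if (!is.null(loo)) sum(loo$series$influential)
                      else NA_integer_,
    stringsAsFactors = FALSE)
}

write_tsv <- function(x, path) {
  if (is.null(x)) return(invisible(NULL))
  data.table::fwrite(x, path, sep = "\t", quote = FALSE)
  invisible(path)
}

write_screen <- function(screen, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  write_tsv(screen$estimates, file.path(out_dir, "estimates.tsv"))
  write_tsv(screen$sensitivity, file.path(out_dir, "sensitivity.tsv"))
  write_tsv(screen$meta, file.path(out_dir, "meta.tsv"))
  write_tsv(screen$findings, file.path(out_dir, "findings.tsv"))
  write_tsv(screen$selection_log, file.path(out_dir, "selection_log.tsv"))
  write_tsv(screen$diagnostics, file.path(out_dir, "diagnostics.tsv"))
  for (key in names(screen$plot_data)) {
    pd <- screen$plot_data[[key]]
    write_tsv(pd$scatter, file.path(out_dir, paste0("scatter_", key, ".tsv")))
    write_tsv(pd$funnel, file.path(out_dir, paste0("funnel_", key, ".tsv")))
  }
  jsonlite::write_json(screen$manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(out_dir)
}

#' @export
print.mr_screen <- function(x, ...) {
  n_pairs <- if (is.null(x$estimates)) 0L
             else length(unique(paste(x$estimates$exposure,
                                      x$estimates$cohort)))
  cat(sprintf("MR screen: %d exposure x cohort pair(s)\n", n_pairs))
  if (!is.null(x$findings)) {
    hits <- x$findings[x$findings$cohort == "meta" & x$findings$significant, ]
    cat(sprintf("  meta-significant exposures: %s\n",
                if (nrow(hits)) paste(hits$exposure, collapse = ", ")
                else "none"))
  }
  if (length(x$errors))
    cat(sprintf("  skipped with errors: %s\n",
                paste(names(x$errors), collapse = ", ")))
  invisible(x)
}

#' Run the mediation screen
#'
#' For every mediator in the config's `mediation` block, runs [mediate()]
#' (exposure -> mediator -> outcome) and returns the ranked mediator table.
#' Mediators that fail (e.g. no instruments after selection) are listed as
#' not-estimable rather than aborting the run.
#'
#' @param config Named list with `exposures`/`mediators`/`outcomes` tables or
#'   paths: the `mediation` block names `exposure` (key into `exposures`),
#'   `mediators` (keys into `mediators` or `exposures`), `outcome` (key into
#'   `outcomes`); plus the shared `thresholds`, `seed`, `ci_method`,
#'   `palindromic_policy`, `ld`.
#' @param out_dir Optional directory for `mediation.tsv`.
#' @return A list of class `"mr_mediation_screen"`: `ranked` (data.frame),
#'   `results` (list of `"mediation_result"`), `errors`.
#' @export
run_mediation <- function(config, out_dir = NULL) {
  med_cfg <- config$mediation
  if (is.null(med_cfg)) stopf("config has no mediation block")
  th <- default_thresholds(config)
  seed <- config$seed %||% 1L
  policy <- config$palindromic_policy %||% "keep_if_eaf_informative"
  ld <- if (!is.null(config$ld)) {
    if (is.character(config$ld)) read_ld(config$ld) else config$ld
  } else NULL

  med_tables <- config$mediators %||% config$exposures
  exposure <- resolve_table(config$exposures[[med_cfg$exposure]])
  outcome <- resolve_table(config$outcomes[[med_cfg$outcome]])
  mediators <- med_cfg$mediators
  if (!length(mediators)) {
    warnf("empty mediator list: nothing to do")
    return(structure(list(ranked = NULL, results = list(), errors = list()),
                     class = "mr_mediation_screen"))
  }

  results <- list(); errors <- list()
  for (i in seq_along(mediators)) {
    m <- mediators[[i]]
    res <- tryCatch(
      mediate(exposure, resolve_table(med_tables[[m]]), outcome, ld = ld,
              p_threshold = th$p_threshold, r2_threshold = th$r2_threshold,
              clump_kb = th$clump_kb, palindromic_policy = policy,
              ci_method = config$ci_method %||% "delta",
              seed = derive_seed(seed, i),
              mediator_name = m, exposure_name = med_cfg$exposure,
              outcome_name = med_cfg$outcome),
      error = function(e) e)
    if (inherits(res, "error")) errors[[m]] <- conditionMessage(res)
    else results[[m]] <- res
  }
  ranked <- if (length(results)) rank_mediators(results) else NULL
  if (length(errors) && !is.null(ranked)) {
    ranked <- rbind(ranked, data.frame(
      mediator = names(errors), beta1 = NA_real_, beta2 = NA_real_,
      total = NA_real_, indirect = NA_real_, proportion = NA_real_,
      ci_low = NA_real_, ci_high = NA_real_, defined = FALSE,
      stringsAsFactors = FALSE))
  }
  out <- structure(list(ranked = ranked, results = results, errors = errors),
                   class = "mr_mediation_screen")
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_tsv(ranked, file.path(out_dir, "mediation.tsv"))
  }
  out
}

#' @export
print.mr_mediation_screen <- function(x, ...) {
  if (is.null(x$ranked)) {
    cat("Mediation screen: no estimable mediators\n")
    return(invisible(x))
  }
  cat("Mediation screen (ranked by proportion):\n")
  print(x$ranked[, c("mediator", "proportion", "ci_low", "ci_high")],
        row.names = FALSE)
  if (length(x$errors))
    cat("  not estimable:", paste(names(x$errors), collapse = ", "), "\n")
  invisible(x)
}
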