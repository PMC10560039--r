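#' Read a GWAS summary-statistics table
#'
#' Reads a tab-separated summary-statistics file with the columns
#' `snp_id, chr, pos, effect_allele, other_allele, eaf, beta, se, pval, n`
#' (positions 1-based). Foreign dialects can be mapped onto this layout with
#' `col_map`, and odds-ratio effect columns are log-transformed on ingestion
#' when `effect_is_or = TRUE`, so downstream code always works on the beta
#' (log-odds) scale.
#'
#' @param path Path to a delimited text file.
#' @param col_map Optional named character vector mapping standard column
#'   names to the file's column names, e.g. `c(snp_id = "rsid", pval = "p")`.
#' @param effect_is_or If `TRUE` the effect column holds odds ratios and is
#'   replaced by its natural log.
#' @param sep Field separator, default tab.
#' @return A `data.frame` in the standard layout.
#' @export
read_gwas <- function(path, col_map = NULL, effect_is_or = FALSE, sep = "\t") {
  x <- data.table::fread(path, sep = sep, data.table = FALSE,
                         showProgress = FALSE)
  if (!is.null(col_map)) {
    for (std in names(col_map)) {
      src <- col_map[[std]]
      if (!src %in% names(x))
        stopf("column '%s' (mapped to '%s') not found in %s", src, std, path)
      names(x)[names(x) == src] <- std
    }
  }
  if (effect_is_or) x$beta <- log(x$beta)
  check_gwas_table(x, basename(path))
  x[required_gwas_cols]
}

#' Write a GWAS summary-statistics table
#'
#' Writes the standard tab-separated layout used throughout the package
#' (see [read_gwas()]).
#'
#' @param x A summary-statistics `data.frame`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gwas <- function(x, path) {
  check_gwas_table(x)
  data.table::fwrite(x[required_gwas_cols], path, sep = "\t", quote = FALSE)
  invisible(path)
}

#' Write a pairwise LD table
#'
#' @param ld A `data.frame` with columns `snp_a, snp_b, r2`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_ld <- function(ld, path) {
  stopifnot(all(c("snp_a", "snp_b", "r2") %in% names(ld)))
  data.table::fwrite(ld[c("snp_a", "snp_b", "r2")], path, sep = "\t",
                     quote = FALSE)
  invisible(path)
}

#' Check that reported p-values are consistent with beta/se
#'
#' Recomputes two-sided normal p-values from `beta/se` and compares them with
#' the reported column, allowing for 10x the rounding error implied by the
#' reported value's printed precision. Inconsistencies warn (they usually
#' indicate a mis-mapped column or a non-normal test) but never stop an
#' analysis.
#'
#' @param x A summary-statistics `data.frame` (see [read_gwas()]).
#' @return Logical vector, `TRUE` where consistent, invisibly.
#' @export
check_pval_consistency <- function(x) {
  check_gwas_table(x)
  expected <- 2 * stats::pnorm(-abs(x$beta / x$se))
  # tolerance: 10x one unit in the last printed significant digit
  mag <- 10^floor(log10(pmax(x$pval, .Machine$double.xmin)))
  ok <- abs(x$pval - expected) <= 10 * mag
  if (any(!ok))
    warnf("%d p-value(s) inconsistent with beta/se under normal theory",
          sum(!ok))
  invisible(ok)
}

#' Read a pairwise LD table
#'
#' @param path Path to a tab-separated file with columns `snp_a, snp_b, r2`.
#' @return A `data.frame`.
#' @export
read_ld <- function(path) {
  x <- data.table::fread(path, sep = "\t", data.table = FALSE,
                         showProgress = FALSE)
  stopifnot(all(c("snp_a", "snp_b", "r2") %in% names(x)))
  x
}
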