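# Internal helpers shared across modules.

# Run `expr` with a private RNG stream seeded at `seed`, restoring the
# caller's .Random.seed afterwards so library code never perturbs user RNG.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  expr
}

# Deterministic per-task seed derived from a base seed; kept inside 32-bit
# integer range.
derive_seed <- function(base, i, j = 0L) {
  as.integer((as.numeric(base) + 7919 * i + 104729 * j) %% 2147483647)
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

# Two-sided normal p-value for z = est/se.
z_pval <- function(est, se) 2 * stats::pnorm(-abs(est / se))

required_gwas_cols <- c("snp_id", "chr", "pos", "effect_allele", "other_allele",
                        "eaf", "beta", "se", "pval", "n")

check_gwas_table <- function(x, name = "table") {
  if (!is.data.frame(x) || nrow(x) == 0L)
    stopf("%s must be a non-empty data.frame of SNP associations", name)
  miss <- setdiff(required_gwas_cols, names(x))
  if (length(miss))
    stopf("%s is missing required column(s): %s", name,
          paste(miss, collapse = ", "))
  if (any(x$se <= 0)) stopf("%s contains non-positive standard errors", name)
  if (any(x$eaf <= 0 | x$eaf >= 1))
    stopf("%s contains effect-allele frequencies outside (0,1)", name)
  if (any(x$effect_allele == x$other_allele))
    stopf("%s contains records with identical effect and other alleles", name)
  invisible(x)
}

DNA_COMPLEMENT <- c(A = "T", T = "A", C = "G", G = "C")

is_palindromic <- function(ea, oa) {
  unname(DNA_COMPLEMENT[ea] == oa)
}
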