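# Shared fixtures and independent oracles, all built in code.

# Harmonized instrument set straight from a simulated two-sample dataset,
# keeping every instrument SNP (no selection filter, no palindromic SNPs) so
# the instrument count and generating truth are exact.
sim_set <- function(n_snp = 30, beta = 0.2, seed = 1,
                    pleiotropy_mode = "none", pleiotropy_sd = 0,
                    pleiotropy_mean = 0, n_exposure = 200000,
                    n_outcome = 300000, cohort = 1, ...) {
  sim <- simulate_summary_stats(sim_config(
    n_instruments = n_snp, n_null_snps = 0, causal_effect = beta,
    pleiotropy_mode = pleiotropy_mode, pleiotropy_sd = pleiotropy_sd,
    pleiotropy_mean = pleiotropy_mean, palindromic_rate = 0,
    n_exposure = n_exposure, n_outcome = n_outcome,
    n_cohorts = cohort, seed = seed, ...))
  harmonize(sim$exposure, sim$outcomes[[cohort]], sim$exposure$snp_id)
}

# Minimal hand-built instrument set from explicit vectors.
manual_set <- function(beta_exp, beta_out, se_exp = 0.01, se_out = 0.01,
                       eaf = 0.5) {
  n <- length(beta_exp)
  data.frame(snp_id = sprintf("s%02d", seq_len(n)),
             beta_exp = beta_exp, se_exp = rep_len(se_exp, n),
             beta_out = beta_out, se_out = rep_len(se_out, n),
             eaf = rep_len(eaf, n), stringsAsFactors = FALSE)
}

# Minimal valid exposure GWAS table from explicit per-SNP fields.
manual_gwas <- function(snp_id, pval = NULL, chr = 1, pos = NULL,
                        beta = 0.1, se = 0.01, eaf = 0.5,
                        ea = "A", oa = "C", n = 100000) {
  k <- length(snp_id)
  if (is.null(pos)) pos <- seq_len(k) * 1e6
  if (is.null(pval)) pval <- 2 * pnorm(-abs(rep_len(beta, k) /
                                              rep_len(se, k)))
  data.frame(snp_id = snp_id, chr = rep_len(chr, k), pos = pos,
             effect_allele = rep_len(ea, k), other_allele = rep_len(oa, k),
             eaf = rep_len(eaf, k), beta = rep_len(beta, k),
             se = rep_len(se, k), pval = pval, n = rep_len(n, k),
             stringsAsFactors = FALSE)
}

# Brute-force clumping oracle: enumerate every conflict-free, maximal subset
# of the significant SNPs and pick the one that is lexicographically best in
# the (ascending pval, snp_id) priority order. Independent of the greedy
# implementation; feasible for <= 12 significant SNPs.
clump_oracle <- function(exposure, ld, p_threshold = 5e-8,
                         r2_threshold = 0.01, clump_kb = 5000) {
  sig <- exposure[exposure$pval < p_threshold, , drop = FALSE]
  sig <- sig[order(sig$pval, sig$snp_id), , drop = FALSE]
  n <- nrow(sig)
  if (n == 0L) return(character())
  stopifnot(n <= 12)
  r2 <- matrix(0, n, n)
  if (!is.null(ld) && nrow(ld)) {
    for (r in seq_len(nrow(ld))) {
      i <- match(ld$snp_a[r], sig$snp_id)
      j <- match(ld$snp_b[r], sig$snp_id)
      if (!is.na(i) && !is.na(j)) {
        v <- max(r2[i, j], ld$r2[r])  # duplicates collapse to the max
        r2[i, j] <- r2[j, i] <- v
      }
    }
  }
  conflict_mask <- integer(n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i != j && sig$chr[i] == sig$chr[j] &&
        abs(sig$pos[i] - sig$pos[j]) <= clump_kb * 1000 &&
        r2[i, j] >= r2_threshold)
      conflict_mask[i] <- bitwOr(conflict_mask[i], bitwShiftL(1L, j - 1L))
  }
  bit <- bitwShiftL(1L, seq_len(n) - 1L)
  best <- NULL
  for (m in seq_len(2^n) - 1L) {
    members <- bitwAnd(m, bit) > 0L
    if (any(bitwAnd(conflict_mask[members], m) > 0L)) next      # not valid
    # a non-member conflicting with nothing kept could be added: not maximal
    if (any(bitwAnd(conflict_mask[!members], m) == 0L)) next
    if (is.null(best) ||
        paste(as.integer(members), collapse = "") >
        paste(as.integer(best), collapse = "")) best <- members
  }
  sig$snp_id[best]
}

# Random clumping instance over a handful of SNPs with random LD pairs.
random_clump_instance <- function(seed) {
  set.seed(seed)
  n <- sample(4:12, 1)
  ids <- sprintf("v%02d", seq_len(n))
  exposure <- manual_gwas(ids,
                          pval = 10^-runif(n, 6, 12),
                          chr = sample(1:2, n, replace = TRUE),
                          pos = sort(sample.int(8e6, n)))
  n_pairs <- sample(0:(n * 2), 1)
  ld <- if (n_pairs > 0) {
    a <- sample(ids, n_pairs, replace = TRUE)
    b <- sample(ids, n_pairs, replace = TRUE)
    keep <- a != b
    data.frame(snp_a = a[keep], snp_b = b[keep],
               r2 = runif(sum(keep)), stringsAsFactors = FALSE)
  } else NULL
  list(exposure = exposure, ld = ld,
       p_threshold = 1e-5, r2_threshold = 0.1,
       clump_kb = sample(c(100, 1000, 5000), 1))
}

# Independent weighted-median oracle: dense scan for the first point where
# the piecewise-linear weighted cumulative curve reaches one half.
weighted_median_oracle <- function(b, w) {
  o <- order(b)
  b <- b[o]; w <- w[o] / sum(w)
  s <- cumsum(w) - w / 2
  grid <- seq(min(b), max(b), length.out = 2000001)
  sv <- approx(b, s, xout = grid, rule = 2)$y
  grid[which(sv >= 0.5)[1]]
}
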