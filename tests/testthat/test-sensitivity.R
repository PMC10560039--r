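test_that("Cochran's Q is zero iff the ratios are identical", {
  d <- manual_set(beta_exp = c(0.1, 0.2, 0.4), beta_out = 0.2 * c(0.1, 0.2, 0.4))
  q <- cochran_q(d)
  expect_lt(q$Q, 1e-12)
  expect_equal(q$pval, 1)
  d$beta_out[1] <- d$beta_out[1] + 0.01
  expect_gt(cochran_q(d)$Q, 1e-6)
})

test_that("Q reproduces the two-ratio hand computation", {
  # ratios 0.1 and 0.3 with se(b) = 0.1 each: IVW 0.2, Q = 0.01/0.01 * 2 = 2
  d <- manual_set(beta_exp = c(1, 1), beta_out = c(0.1, 0.3), se_out = 0.1)
  q <- cochran_q(d, about = "ivw")
  expect_equal(q$Q, 2)
  expect_identical(q$df, 1L)
  expect_equal(q$pval, pchisq(2, 1, lower.tail = FALSE))
  expect_error(cochran_q(manual_set(1, 0.1)), ">= 2")
  eg <- cochran_q(sim_set(10, seed = 3), about = "egger")
  expect_identical(eg$df, 8L)
})

test_that("the Egger intercept test reports the intercept row of the fit", {
  d <- manual_set(beta_exp = c(0.1, 0.2, 0.3), beta_out = c(0.03, 0.05, 0.07))
  it <- egger_intercept_test(d)
  expect_equal(it$intercept, 0.01, tolerance = 1e-12)
  # balanced pleiotropy leaves the intercept centred on zero
  ints <- vapply(1:60, function(s)
    egger_intercept_test(sim_set(25, beta = 0.1, seed = s,
                                 pleiotropy_mode = "balanced",
                                 pleiotropy_sd = 0.005))$intercept,
    numeric(1))
  expect_lt(abs(mean(ints)), 0.002)
})

test_that("MR-PRESSO is seed-reproducible and floors its empirical p", {
  set <- sim_set(12, beta = 0.2, seed = 9)
  a <- mr_presso(set, n_sim = 300, seed = 42)
  b <- mr_presso(set, n_sim = 300, seed = 42)
  expect_identical(a$global_pval, b$global_pval)
  expect_identical(a$outlier_snps, b$outlier_snps)
  expect_gte(a$global_pval, 1 / 301)
  expect_lte(a$global_pval, 1)
  small <- mr_presso(sim_set(3, seed = 1), n_sim = 200)
  expect_false(small$applicable)
  expect_error(mr_presso(set, n_sim = 50), "n_sim")
})

test_that("MR-PRESSO flags a planted outlier and corrects the estimate", {
  set <- sim_set(30, beta = 0.2, seed = 13)
  d <- set$instruments
  d$beta_out[5] <- d$beta_out[5] + 10 * d$se_out[5]
  pr <- mr_presso(d, n_sim = 1000, seed = 7)
  expect_true(d$snp_id[5] %in% pr$outlier_snps$snp_id)
  expect_lt(pr$global_pval, 0.05)
  truth <- 0.2
  expect_lt(abs(pr$estimate_corrected$beta - truth),
            abs(pr$estimate_raw$beta - truth))
  # corrected estimate uses exactly the non-outlier SNPs
  kept <- d[!d$snp_id %in% pr$outlier_snps$snp_id, ]
  expect_equal(pr$estimate_corrected$beta, mr_ivw(kept)$beta)
  expect_false(is.na(pr$distortion_pval))
})

test_that("leave-one-out covers every SNP and satisfies its identity", {
  set <- sim_set(3, beta = 0.1, seed = 5)
  loo <- leave_one_out(set)
  expect_identical(nrow(loo$series), 3L)
  expect_true(all(loo$series$nsnp == 2L))
  # exact identity: LOO slopes averaged with weights Sxx - w_j x_j^2 give
  # back the full fixed-effect slope
  d <- sim_set(20, beta = 0.1, seed = 5)$instruments
  loo20 <- leave_one_out(d)
  w <- 1 / d$se_out^2
  wt <- sum(w * d$beta_exp^2) - w * d$beta_exp^2
  expect_equal(sum(wt * loo20$series$beta) / sum(wt),
               mr_ivw(d, "fixed")$beta, tolerance = 1e-12)
  # homogeneous data: no omission moves the estimate beyond one full-set se
  full <- mr_ivw(d)
  expect_true(all(abs(loo20$series$beta - full$beta) < full$se))
  # a planted outlier produces the largest omission shift at its own SNP
  d$beta_out[3] <- d$beta_out[3] + 8 * d$se_out[3]
  looo <- leave_one_out(d)
  shifts <- abs(looo$series$beta - mr_ivw(d)$beta)
  expect_identical(which.max(shifts), 3L)
  # an omission that flips the estimate's sign is flagged influential
  sgn <- manual_set(beta_exp = c(1, 1, 1), beta_out = c(0.2, 0.2, -1))
  expect_true(leave_one_out(sgn)$series$influential[3])
})

test_that("plot data mirrors the instruments and the fitted estimates", {
  set <- sim_set(8, beta = 0.2, seed = 2)
  ivw <- mr_ivw(set); egger <- mr_egger(set)
  pd <- plot_data(set, list(ivw, egger))
  expect_identical(nrow(pd$scatter), 8L)
  expect_equal(pd$lines$slope, c(ivw$beta, egger$beta))
  expect_equal(pd$lines$intercept, c(0, egger$extra$egger_intercept))
  expect_equal(pd$funnel_reference, ivw$beta)
  expect_equal(pd$funnel$ratio,
               set$instruments$beta_out / set$instruments$beta_exp)
  bare <- plot_data(set)
  expect_null(bare$lines)
  expect_identical(nrow(bare$scatter), 8L)
})
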