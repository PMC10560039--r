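test_that("the Wald ratio follows its closed form, including signs", {
  one <- manual_set(beta_exp = 0.1, beta_out = 0.02, se_out = 0.01)
  est <- mr_wald_ratio(one)
  expect_equal(est$beta, 0.2)
  expect_equal(est$se, 0.1)
  expect_equal(mr_wald_ratio(manual_set(0.1, 0))$beta, 0)
  expect_equal(mr_wald_ratio(manual_set(-0.1, 0.02))$beta, -0.2)
  expect_error(mr_wald_ratio(manual_set(0, 0.02)), "undefined")
})

test_that("IVW equals the weighted-regression-through-origin oracle", {
  set.seed(100)
  for (i in 1:20) {
    d <- manual_set(beta_exp = rnorm(20, 0.05, 0.02),
                    beta_out = rnorm(20, 0.01, 0.01),
                    se_out = runif(20, 0.005, 0.02))
    est <- mr_ivw(d, effects_model = "fixed")
    fit <- lm(beta_out ~ 0 + beta_exp, data = d, weights = 1 / d$se_out^2)
    expect_equal(est$beta, unname(coef(fit)), tolerance = 1e-10)
  }
  two <- manual_set(beta_exp = c(1, 1), beta_out = c(0.1, 0.3))
  expect_equal(mr_ivw(two)$beta, 0.2)
  expect_error(mr_ivw(manual_set(0.1, 0.02)), "wald")
})

test_that("random-effects IVW never reports less variance than fixed", {
  for (s in 1:10) {
    set <- sim_set(n_snp = 15, beta = 0.1, seed = s,
                   pleiotropy_mode = if (s %% 2) "balanced" else "none",
                   pleiotropy_sd = if (s %% 2) 0.01 else 0)
    fe <- mr_ivw(set, "fixed"); re <- mr_ivw(set, "multiplicative_random")
    expect_gte(re$se, fe$se)
    q <- fe$extra$Q
    if (q <= fe$n_snp - 1) expect_equal(re$se, fe$se)
    else expect_gt(re$se, fe$se)
  }
})

test_that("MR-Egger matches the two-parameter WLS oracle and the exact fit", {
  # collinear construction: outcome = 0.01 + 0.2 * exposure, equal weights
  d <- manual_set(beta_exp = c(0.1, 0.2, 0.3),
                  beta_out = c(0.03, 0.05, 0.07))
  est <- mr_egger(d)
  expect_equal(est$beta, 0.2, tolerance = 1e-12)
  expect_equal(est$extra$egger_intercept, 0.01, tolerance = 1e-12)
  set.seed(200)
  for (i in 1:10) {
    d <- manual_set(beta_exp = runif(15, 0.02, 0.1),
                    beta_out = rnorm(15, 0.01, 0.01),
                    se_out = runif(15, 0.005, 0.02))
    est <- mr_egger(d)
    fit <- lm(beta_out ~ beta_exp, data = d, weights = 1 / d$se_out^2)
    expect_equal(est$beta, unname(coef(fit)[2]), tolerance = 1e-10)
    expect_equal(est$extra$egger_intercept, unname(coef(fit)[1]),
                 tolerance = 1e-10)
  }
  expect_error(mr_egger(manual_set(rep(0.1, 4), rnorm(4))), "singular")
})

test_that("Egger orients all exposure betas positive before fitting", {
  d <- manual_set(beta_exp = c(0.1, 0.2, 0.3, 0.15),
                  beta_out = c(0.031, 0.052, 0.068, 0.040))
  flipped <- d
  flipped$beta_exp[2] <- -flipped$beta_exp[2]
  flipped$beta_out[2] <- -flipped$beta_out[2]
  expect_equal(mr_egger(flipped)$beta, mr_egger(d)$beta, tolerance = 1e-12)
  expect_equal(mr_egger(flipped)$extra$egger_intercept,
               mr_egger(d)$extra$egger_intercept, tolerance = 1e-12)
})

test_that("the weighted median interpolates the weighted CDF at one half", {
  eq <- manual_set(beta_exp = rep(1, 3), beta_out = c(0.1, 0.2, 0.9))
  expect_equal(mr_weighted_median(eq, n_boot = 100, seed = 1)$beta, 0.2)
  eq4 <- manual_set(beta_exp = rep(1, 4), beta_out = c(0.4, 0.1, 0.3, 0.2))
  expect_equal(mr_weighted_median(eq4, n_boot = 100, seed = 1)$beta,
               median(c(0.4, 0.1, 0.3, 0.2)))
  # unequal weights (0.5, 0.25, 0.25) on ratios (0.1, 0.2, 0.3): se(b) of
  # (h, 2h, 2h) gives weights proportional to (4,1,1)/... = (0.5,0.25,0.25)
  d <- manual_set(beta_exp = rep(1, 3), beta_out = c(0.1, 0.2, 0.3),
                  se_out = c(0.01, 0.01 * sqrt(2), 0.01 * sqrt(2)))
  est <- mr_weighted_median(d, n_boot = 100, seed = 1)
  w <- 1 / (d$se_out)^2
  expect_equal(est$beta, weighted_median_oracle(d$beta_out, w),
               tolerance = 1e-5)
  expect_equal(est$beta, 0.1 + 0.1 * (0.5 - 0.25) / (0.625 - 0.25))
  expect_error(mr_weighted_median(manual_set(c(1, 1), c(0, 0))), ">= 3")
})

test_that("mode estimators track the dominant cluster of ratios", {
  flat <- manual_set(beta_exp = rep(1, 4), beta_out = rep(0.2, 4))
  expect_equal(mr_mode(flat, n_boot = 100, seed = 1)$beta, 0.2)
  clustered <- manual_set(beta_exp = rep(1, 4),
                          beta_out = c(0.19, 0.20, 0.21, 0.9))
  est <- mr_mode(clustered, weighted = FALSE, n_boot = 100, seed = 1)
  expect_lt(abs(est$beta - 0.20), 0.03)
  # simple and weighted modes coincide under equal weights
  expect_equal(mr_mode(clustered, weighted = TRUE, n_boot = 100,
                       seed = 1)$beta, est$beta)
})

test_that("multivariable IVW solves the weighted normal equations", {
  set.seed(300)
  for (i in 1:10) {
    L <- 12
    X <- cbind(e1 = rnorm(L, 0.05, 0.02), e2 = rnorm(L, 0.03, 0.02))
    y <- X %*% c(0.1, 0.05) + rnorm(L, 0, 0.005)
    se <- runif(L, 0.004, 0.01)
    got <- mr_mvmr_ivw(y, se, X)
    fit <- lm(y ~ 0 + X, weights = 1 / se^2)
    expect_equal(got$e1$beta, unname(coef(fit)[1]), tolerance = 1e-10)
    expect_equal(got$e2$beta, unname(coef(fit)[2]), tolerance = 1e-10)
  }
  # 4-SNP hand-sized system against an explicit normal-equations solve
  X <- cbind(a = c(0.1, 0.2, 0.15, 0.05), b = c(0.02, 0.1, 0.07, 0.12))
  y <- c(0.011, 0.032, 0.024, 0.014)
  se <- c(0.01, 0.02, 0.01, 0.015)
  w <- 1 / se^2
  want <- solve(t(X) %*% (w * X), t(X) %*% (w * y))[, 1]
  got <- mr_mvmr_ivw(y, se, X)
  expect_equal(c(got$a$beta, got$b$beta), unname(want), tolerance = 1e-12)
})

test_that("an all-zero exposure column reduces MVMR to univariable IVW", {
  d <- sim_set(n_snp = 15, beta = 0.2, seed = 4)$instruments
  X <- cbind(main = d$beta_exp, none = 0)
  got <- mr_mvmr_ivw(d$beta_out, d$se_out, X)
  uni <- mr_ivw(d)
  expect_equal(got$main$beta, uni$beta, tolerance = 1e-12)
  expect_true(is.na(got$none$beta))
  # genuinely collinear non-zero columns still fail loudly
  Xc <- cbind(main = d$beta_exp, copy = 2 * d$beta_exp)
  expect_error(mr_mvmr_ivw(d$beta_out, d$se_out, Xc), "collinear")
  expect_error(mr_mvmr_ivw(d$beta_out[1:3], d$se_out[1:3], X[1:3, ]),
               "exposures \\+ 2")
})

test_that("rescaling the exposure rescales every causal estimate inversely", {
  set <- sim_set(n_snp = 20, beta = 0.15, seed = 6)
  d <- set$instruments
  scaled <- d
  c0 <- -2.5
  scaled$beta_exp <- d$beta_exp * c0
  scaled$se_exp <- d$se_exp * abs(c0)
  for (f in list(function(x) mr_ivw(x)$beta,
                 function(x) mr_egger(x)$beta,
                 function(x) mr_weighted_median(x, n_boot = 50, seed = 3)$beta,
                 function(x) mr_mode(x, n_boot = 50, seed = 3)$beta)) {
    expect_equal(f(scaled), f(d) / c0, tolerance = 1e-10)
  }
})

test_that("mr_all applies minimum-instrument rules and the Wald fallback", {
  one <- sim_set(n_snp = 1, seed = 7)
  res1 <- mr_all(one)
  expect_identical(res1$method[1], "wald_ratio")
  expect_match(res1$note[1], "fallback")
  expect_equal(res1$beta[1], mr_wald_ratio(one)$beta)
  two <- sim_set(n_snp = 2, seed = 7)
  res2 <- mr_all(two)
  expect_false(is.na(res2$beta[res2$method == "ivw"]))
  expect_true(all(is.na(res2$beta[res2$method != "ivw"])))
  expect_match(res2$note[res2$method == "egger"], "not applicable")
  many <- sim_set(n_snp = 10, seed = 7)
  res <- mr_all(many, n_boot = 50, seed = 1)
  expect_true(all(!is.na(res$beta)))
  expect_identical(nrow(res), 5L)
})
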