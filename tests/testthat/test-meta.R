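test_that("Cochran's Q matches hand computation and degenerates at zero", {
  het0 <- cochran_q(mk_est(c(1, 1, 1), c(1, 2, 3)))
  expect_equal(het0$Q, 0)
  expect_equal(het0$I2, 0)
  expect_equal(het0$tau2, 0)
  # y=(0,2), v=(1,1): yhat=1, Q = 1*(0-1)^2 + 1*(2-1)^2 = 2 on 1 df
  het <- cochran_q(mk_est(c(0, 2), c(1, 1)))
  expect_equal(het$Q, 2, tolerance = 1e-9)
  expect_equal(het$df, 1L)
  expect_equal(het$p, pchisq(2, 1, lower.tail = FALSE), tolerance = 1e-9)
  expect_error(cochran_q(mk_est(1, 1)), "at least 2")
})

test_that("I-squared follows the printed formula with flooring", {
  expect_equal(i_squared(10, 5), 50.0)
  expect_equal(i_squared(3, 5), 0.0)
  expect_equal(i_squared(0, 5), 0.0)
})

test_that("Q p-values are uniform under homogeneity", {
  set.seed(77)
  v <- rep(0.04, 12)
  p <- replicate(2000, cochran_q(mk_est(rnorm(12, 0.3, sqrt(v)), v))$p)
  expect_gt(suppressWarnings(ks.test(p, "punif"))$p.value, 0.01)
  expect_true(all(p > 0 & p <= 1))
})

test_that("DL tau2 matches hand computation and recovers the truth", {
  # (Q - df) / (sum(w) - sum(w^2)/sum(w)) = (2-1)/(2 - 2/2) = 1
  expect_equal(dl_tau2(mk_est(c(0, 2), c(1, 1))), 1.0, tolerance = 1e-9)
  expect_equal(dl_tau2(mk_est(c(0.7, 0.7, 0.7), c(1, 2, 3))), 0.0)
  # simulation consistency: k=200 precise strata, true tau2 = 0.25
  set.seed(55)
  est <- replicate(200, {
    v <- rep(0.01, 200)
    dl_tau2(mk_est(rnorm(200, 1, sqrt(0.25 + v)), v))
  })
  expect_lt(abs(mean(est) - 0.25) / 0.25, 0.2)
})

test_that("DerSimonian-Laird pooling matches the two-stratum hand example", {
  pr <- pool_random_dl(mk_est(c(0, 2), c(1, 1)))
  # tau2=1 so w*=(0.5,0.5): y_pooled=1, se=1
  expect_equal(pr$y_pooled, 1.0, tolerance = 1e-9)
  expect_equal(pr$se_pooled, 1.0, tolerance = 1e-9)
  expect_equal(pr$or_pooled, exp(1), tolerance = 1e-9)
  expect_equal(pr$ci_low, exp(1 - qnorm(0.975)), tolerance = 1e-9)
  expect_equal(pr$ci_high, exp(1 + qnorm(0.975)), tolerance = 1e-9)
  expect_equal(pr$p, 2 * pnorm(-1), tolerance = 1e-9)
  expect_identical(pr$model, "random_DL")
})

test_that("identical strata collapse pooling to the common value", {
  pr <- pool_random_dl(mk_est(rep(0.5, 4), rep(0.09, 4)))
  expect_equal(pr$y_pooled, 0.5, tolerance = 1e-12)
  expect_equal(pr$het$tau2, 0)
  expect_equal(pr$se_pooled, sqrt(0.09 / 4), tolerance = 1e-12)
})

test_that("with tau2 = 0 random-effects equals inverse-variance pooling", {
  est <- mk_est(c(0.50, 0.52, 0.49), c(1.0, 1.5, 2.0))  # Q < df
  expect_equal(dl_tau2(est), 0)
  pr <- pool_random_dl(est)
  w <- 1 / est$v
  expect_equal(pr$y_pooled, sum(w * est$y) / sum(w), tolerance = 1e-12)
  expect_equal(pr$se_pooled, sqrt(1 / sum(w)), tolerance = 1e-12)
})

test_that("Mantel-Haenszel pooling matches count-scale hand examples", {
  # single stratum: MH OR is the crude OR and RBG variance is Woolf
  pr1 <- pool_fixed_mh(mk_tables(10, 90, 10, 890))
  expect_equal(pr1$or_pooled, 9.888888888889, tolerance = 1e-9)
  expect_equal(pr1$se_pooled^2, 1 / 10 + 1 / 90 + 1 / 10 + 1 / 890,
               tolerance = 1e-9)
  # two strata: (4/6 + 1/4) / (1/6 + 1/4) = 2.2
  pr2 <- pool_fixed_mh(mk_tables(c(2, 1), c(1, 1), c(1, 1), c(2, 1)))
  expect_equal(pr2$or_pooled, 2.2, tolerance = 1e-9)
  expect_identical(pr2$model, "fixed_MH")
  # homogeneity: m identical strata leave the OR unchanged
  m <- 5
  prm <- pool_fixed_mh(mk_tables(rep(10, m), rep(90, m), rep(10, m),
                                 rep(890, m)))
  expect_equal(prm$or_pooled, 9.888888888889, tolerance = 1e-9)
  expect_error(pool_fixed_mh(mk_tables(3, 0, 0, 7)), "undefined")
})

test_that("model selection follows the heterogeneity p-value strictly", {
  het <- function(p) structure(list(p = p), class = "heterogeneity_result")
  expect_identical(select_model(het(0.02)), "random_DL")
  expect_identical(select_model(het(0.5)), "fixed_MH")
  expect_identical(select_model(het(0.05)), "fixed_MH")  # boundary
})

test_that("leave-one-out re-pools under the fixed model family", {
  est <- mk_est(c(0, 2, 1), c(1, 1, 1))
  loo <- leave_one_out(est, "random_DL")
  expect_equal(nrow(loo), 3L)
  # dropping the third stratum reproduces the two-stratum hand example
  expect_equal(loo$or_pooled[loo$left_out == 3], exp(1), tolerance = 1e-9)
  expect_true(all(loo$model == "random_DL"))
  # exchangeability: identical strata leave every reduced estimate equal
  same <- mk_est(rep(0.4, 5), rep(0.04, 5))
  full <- pool_random_dl(same)$or_pooled
  expect_equal(leave_one_out(same, "random_DL")$or_pooled, rep(full, 5),
               tolerance = 1e-12)
  # count-scale family needs the tables and keeps them aligned
  tabs <- mk_tables(c(10, 12, 9), c(90, 88, 91), c(10, 11, 10),
                    c(890, 889, 890))
  est2 <- effect_estimate(continuity_correct(tabs))
  loo2 <- leave_one_out(est2, "fixed_MH", tables = tabs)
  expect_equal(loo2$or_pooled[1],
               pool_fixed_mh(tabs[-1, ])$or_pooled, tolerance = 1e-12)
  expect_error(leave_one_out(mk_est(c(0, 1), c(1, 1)), "random_DL"),
               "at least 3")
  expect_error(leave_one_out(est, "fixed_MH"), "tables")
})

test_that("random-effects pooling recovers known parameters with coverage", {
  # 500 synthetic meta-analyses, k=12 yearly strata, true log OR =
  # log(2.27), tau = 0.2, stratum variances at realistic yearly scale
  set.seed(909)
  mu <- log(2.27); tau <- 0.2
  res <- t(replicate(500, {
    v <- runif(12, 0.02, 0.10)
    y <- rnorm(12, mu, sqrt(tau^2 + v))
    pr <- pool_random_dl(mk_est(y, v))
    c(pr$y_pooled, pr$ci_low < 2.27 & 2.27 < pr$ci_high)
  }))
  mc_se <- sd(res[, 1]) / sqrt(500)
  expect_lt(abs(mean(res[, 1]) - mu), 3 * mc_se)
  expect_gte(mean(res[, 2]), 0.92)
  expect_lte(mean(res[, 2]), 0.98)
})

test_that("MH and DL agree without heterogeneity on large strata", {
  set.seed(414)
  for (i in 1:5) {
    n1 <- 2000; n0 <- 8000; p0 <- 0.08
    p1 <- plogis(qlogis(p0) + log(2))
    a <- rbinom(12, n1, p1); c <- rbinom(12, n0, p0)
    tabs <- mk_tables(a, n1 - a, c, n0 - c, stratum = 1:12)
    or_mh <- pool_fixed_mh(tabs)$or_pooled
    or_dl <- pool_random_dl(effect_estimate(continuity_correct(tabs)))$or_pooled
    expect_lt(abs(or_mh - or_dl) / or_mh, 0.05)
  }
})
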