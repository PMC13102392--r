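test_that("variance F-test is symmetric and centred at equal variances", {
  set.seed(71)
  a <- rnorm(60); b <- rnorm(60)
  v <- variance_f_test(a, b)
  expect_equal(v$variance_ratio, var(b) / var(a), tolerance = 1e-12)
  sw <- variance_f_test(b, a)
  expect_equal(sw$variance_ratio, 1 / v$variance_ratio, tolerance = 1e-12)
  expect_equal(sw$p_value, v$p_value, tolerance = 1e-9)
  expect_error(variance_f_test(rep(1, 5), rnorm(5)), "zero variance")
})

test_that("the F-test detects a doubled standard deviation", {
  set.seed(72)
  rej <- vapply(1:200, function(i) {
    variance_f_test(rnorm(50), rnorm(50, 0, 2))$p_value < 0.05
  }, logical(1))
  expect_gt(mean(rej), 0.8)
})

test_that("moment estimators match their definitions", {
  sym <- c(-2, -1, 0, 1, 2)
  m <- distribution_moments(sym)
  expect_equal(m$skewness, 0)
  # exactly 1 of 50 points beyond 2 SD -> tail percentage 2%
  x <- c(rep(0, 49), 10)
  expect_equal(distribution_moments(x)$tail_pct, 2)
  set.seed(73)
  z <- rnorm(1e5)
  mz <- distribution_moments(z)
  expect_lt(abs(mz$skewness), 3 * sqrt(6 / 1e5))
  expect_lt(abs(mz$excess_kurtosis), 3 * sqrt(24 / 1e5))
  expect_error(distribution_moments(c(1, 2, 3)), "n >= 4")
})

test_that("heteroscedastic LMM recovers genotype-specific residual SDs", {
  set.seed(74)
  est <- vapply(1:40, function(i) {
    heteroscedastic_lmm(make_lmm_fish(sd_mutant = 0.16))$sd_ratio
  }, numeric(1))
  expect_equal(mean(est), 2, tolerance = 0.3 / 2)
  # equal-variance data: ratio near 1 and beta agrees with the
  # homoscedastic fit within one standard error
  d <- make_lmm_fish()
  h <- heteroscedastic_lmm(d)
  li <- fit_lmm_intercept(d)
  expect_equal(h$sd_ratio, 1, tolerance = 0.35)
  expect_lt(abs(h$beta - li$beta), li$se)
  # the heteroscedastic likelihood can only improve on the constrained fit
  expect_gte(h$logLik, h$logLik_homoscedastic - 1e-6)
})

test_that("single-experiment heteroscedastic fit equals the GLS oracle", {
  set.seed(75)
  d <- make_lmm_fish(k = 1, sigma_batch = 0, sd_mutant = 0.16)
  h <- heteroscedastic_lmm(d)
  or <- nlme::gls(log(mean_feret) ~ log(sat_area) + genotype,
                  weights = nlme::varIdent(form = ~ 1 | genotype),
                  data = transform(d, genotype = factor(genotype,
                                                        c("control",
                                                          "mutant"))),
                  method = "ML")
  expect_equal(h$beta, unname(coef(or)["genotypemutant"]),
               tolerance = 1e-6)
})

test_that("permutation p is bounded, seed-reproducible, and 1/(B+1) when
          the observed statistic beats every permutation", {
  set.seed(76)
  d <- make_lmm_fish(beta = log(1.6), sd_control = 0.03,
                     sd_mutant = 0.03, n = 15)
  p1 <- permutation_test(d, B = 59, seed = 99)
  expect_equal(p1$perm_p, 1 / 60)
  expect_equal(p1$raw_proportion, 0)
  p2 <- permutation_test(d, B = 59, seed = 99)
  expect_identical(p1$perm_p, p2$perm_p)
  dn <- make_lmm_fish(n = 15)
  pn <- permutation_test(dn, B = 59, seed = 1)
  expect_gte(pn$perm_p, 1 / 60)
  expect_lte(pn$perm_p, 1)
  expect_error(permutation_test(d, B = 0), "B must be")
})

test_that("the mean-difference permutation statistic is also available", {
  set.seed(77)
  d <- make_lmm_fish(n = 12)
  p <- permutation_test(d, B = 39, seed = 2, statistic = "meandiff")
  expect_gte(p$perm_p, 1 / 40)
  expect_lte(p$perm_p, 1)
})

test_that("Welch test matches the direct formula and its equal-n limit", {
  w0 <- welch_test(c(1, 2, 3), c(1, 2, 3))
  expect_equal(w0$t, 0)
  expect_equal(w0$p_value, 1)
  # equal n, equal sample variances -> Satterthwaite df = n1 + n2 - 2
  we <- welch_test(c(1, 2, 3, 4), c(5, 6, 7, 8))
  expect_equal(we$df, 6, tolerance = 1e-6)
  w <- welch_test(c(1, 2, 3), c(2, 3, 4, 5))
  or <- brute_welch(c(1, 2, 3), c(2, 3, 4, 5))
  expect_equal(w$t, or$t, tolerance = 1e-12)
  expect_equal(w$df, or$df, tolerance = 1e-12)
  expect_equal(w$p_value, or$p, tolerance = 1e-12)
})

test_that("consensus classification follows the three-test rule", {
  expect_equal(consensus_classify(0.01, 0.01, 0.04), "ALL SIG")
  expect_equal(consensus_classify(0.5, 0.9, 0.2), "ALL NS")
  expect_equal(consensus_classify(0.01, 0.2, 0.04), "MIXED")
  expect_error(consensus_classify(0.5, NA, 0.2), "p-values")
})

test_that("strong effects yield ALL SIG consensus in most screens", {
  ge <- data.frame(gene = "g", beta = log(1.2), gamma = 0,
                   var_inflation = 1)
  calls <- vapply(1:10, function(r) {
    scr <- simulate_screen(sim_config(n_control = 40, n_mutant = 40),
                           ge, seed = 700 + r)
    rb <- robustness_suite(scr$fish, B = 99, seed = r)
    rb$consensus
  }, character(1))
  expect_gte(mean(calls == "ALL SIG"), 0.9)
})
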