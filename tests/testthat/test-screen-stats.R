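test_that("KS statistic matches the ECDF-sweep oracle and edge cases", {
  expect_equal(ks_two_sample(c(1, 2, 3), c(1, 2, 3))$statistic, 0)
  expect_equal(ks_two_sample(c(1, 2, 3), c(1, 2, 3))$p_value, 1)
  expect_equal(ks_two_sample(c(1, 2, 3), c(4, 5, 6))$statistic, 1)
  set.seed(51)
  for (r in 1:8) {
    a <- rnorm(sample(10:80, 1)); b <- rnorm(sample(10:80, 1), 0.3)
    expect_equal(ks_two_sample(a, b)$statistic, brute_ks_D(a, b),
                 tolerance = 1e-12)
  }
  expect_error(ks_two_sample(numeric(0), 1), "empty")
})

test_that("Fisher combination follows the chi-squared 2k closed form", {
  expect_equal(fisher_combine(c(1, 1, 1))$chisq, 0)
  expect_equal(fisher_combine(c(1, 1, 1))$p_value, 1)
  fc <- fisher_combine(c(0.05, 0.05))
  expect_equal(fc$chisq, -2 * log(0.05 * 0.05))
  expect_equal(fc$df, 4L)
  # df = 4 upper tail has closed form exp(-x/2) * (1 + x/2)
  expect_equal(fc$p_value, exp(-fc$chisq / 2) * (1 + fc$chisq / 2),
               tolerance = 1e-12)
  expect_equal(fc$p_value, 0.0175, tolerance = 0.002)
  # single p: -2 log p on chi-squared 2 df inverts exactly
  expect_equal(fisher_combine(0.137)$p_value, 0.137, tolerance = 1e-12)
  expect_error(fisher_combine(c(0.5, 0)), "\\(0, 1\\]")
})

test_that("stratified KS with one experiment equals that experiment's p", {
  scr <- simulate_screen(sim_config(n_experiments = 1), seed = 52)
  sk <- stratified_ks_test(scr$fish)
  expect_equal(nrow(sk$per_experiment), 1L)
  expect_equal(sk$p_value, sk$per_experiment$p_value, tolerance = 1e-12)
  expect_equal(sk$effect, sk$per_experiment$effect)
})

test_that("stratified KS weights per-experiment effects by sample size", {
  scr <- simulate_screen(sim_config(n_control = c(40, 10),
                                    n_mutant = c(40, 10)),
                         data.frame(gene = "g", beta = log(1.2),
                                    gamma = 0, var_inflation = 1),
                         seed = 53)
  sk <- stratified_ks_test(scr$fish)
  w <- sk$per_experiment$n_control + sk$per_experiment$n_mutant
  expect_equal(sk$effect,
               sum(sk$per_experiment$effect * w) / sum(w))
})

test_that("LMM percent change is the exact back-transform of beta", {
  set.seed(54)
  d <- make_lmm_fish(beta = log(1.2))
  li <- fit_lmm_intercept(d)
  expect_equal(li$pct_change, (exp(li$beta) - 1) * 100, tolerance = 1e-12)
  expect_equal(li$beta, log(1 + li$pct_change / 100), tolerance = 1e-12)
  expect_equal(li$ci_low, (exp(li$beta - 1.96 * li$se) - 1) * 100)
  expect_equal(li$ci_high, (exp(li$beta + 1.96 * li$se) - 1) * 100)
  expect_true(li$converged)
  # recovered effect is near truth for this well-powered design
  expect_equal(li$pct_change, 20, tolerance = 0.25)
})

test_that("interaction model detects identical scaling as ~0 slope shift", {
  set.seed(55)
  d <- make_lmm_fish(beta = 0)
  ls <- fit_lmm_interaction(d)
  expect_lt(abs(ls$slope_beta), 0.05)
  expect_gt(ls$p_value, 0.05)
})

test_that("LMM preconditions route degenerate designs to errors", {
  set.seed(56)
  d1 <- make_lmm_fish(k = 1)
  expect_error(fit_lmm_intercept(d1), "single_experiment")
  d <- make_lmm_fish()
  expect_error(fit_lmm_intercept(d[d$genotype == "control", ]),
               "both genotypes")
})

test_that("BH adjustment matches the hand step-up and its properties", {
  expect_equal(adjust_fdr(c(0.01, 0.02, 0.03)),
               c(0.03, 0.03, 0.03), ignore_attr = TRUE)
  expect_equal(adjust_fdr(0.2), 0.2, ignore_attr = TRUE)
  set.seed(57)
  p <- runif(25)
  adj <- adjust_fdr(p)
  expect_equal(unname(adj), brute_bh(p), tolerance = 1e-12)
  expect_true(all(adj >= p))
  expect_identical(order(adj[order(p)]), seq_along(p)) # order preserved
  expect_error(adjust_fdr(numeric(0)), "empty")
})

test_that("hit classification implements the dual robustness criterion", {
  res <- data.frame(
    gene = c("a", "b", "c", "d"),
    ks_stratified_adj_p = c(0.01, 0.04, 0.2, 1),
    lmm_adj_p = c(0.02, 0.06, 0.03, 1),
    ks_pooled_p = c(0.001, 0.2, 0.04, 1),
    ks_effect = c(3, -2, 1, 0))
  cl <- classify_hits(res)
  expect_equal(cl$classification,
               c("robust", "distributional_only", "suggestive", "ns"))
  expect_equal(cl$direction,
               c("hypertrophic", "hyperplastic", "hypertrophic",
                 "hypertrophic"))
  allns <- classify_hits(data.frame(ks_stratified_adj_p = rep(1, 3),
                                    lmm_adj_p = rep(1, 3)))
  expect_true(all(allns$classification == "ns"))
})

test_that("Cohen's d uses the (n-1)-weighted pooled SD", {
  expect_equal(cohens_d(c(1, 2, 3), c(1, 2, 3)), 0)
  s <- 1 / sqrt(2)
  expect_equal(cohens_d(c(1 - s, 1 + s), c(-s, s)), 1)
  set.seed(58)
  a <- rnorm(17, 1, 2); b <- rnorm(23, 0, 1.5)
  sp <- sqrt(((17 - 1) * var(a) + (23 - 1) * var(b)) / (17 + 23 - 2))
  expect_equal(cohens_d(a, b), (mean(a) - mean(b)) / sp, tolerance = 1e-12)
  expect_error(cohens_d(1, c(1, 2)), "n >= 2")
})

test_that("t-test power is exact at d = 0 and monotone in n and d", {
  expect_equal(power_two_sample(20, 20, 0), 0.05, tolerance = 1e-10)
  expect_true(power_two_sample(30, 30, 0.8) <
                power_two_sample(40, 30, 0.8))
  expect_true(power_two_sample(30, 30, 0.5) <
                power_two_sample(30, 30, 0.8))
  expect_true(power_two_sample(30, 30, 0.8, two_sided = FALSE) >
                power_two_sample(30, 30, 0.8))
})

test_that("sample size search satisfies the bisection invariant", {
  n <- sample_size_for_power(0.8)
  expect_gte(power_two_sample(n, n, 0.8), 0.8)
  expect_lt(power_two_sample(n - 1, n - 1, 0.8), 0.8)
  # at the two-group minimum n = 2 the t test has only 2 df, so even huge
  # effects need d ~ 8 before the floor is reached (noncentral-t oracle)
  expect_equal(sample_size_for_power(8), 2L)
  expect_equal(sample_size_for_power(3.5), 3L)
  # frozen from the noncentral-t oracle: d = 1.06, control group fixed at 19
  n2 <- sample_size_for_power(1.06, allocation = "fixed_control",
                              n_control = 19)
  expect_equal(n2, 13L)
  expect_gte(power_two_sample(19, n2, 1.06), 0.8)
  expect_lt(power_two_sample(19, n2 - 1, 1.06), 0.8)
})

test_that("trait mixed models back-transform and recover null effects", {
  set.seed(59)
  d <- make_lmm_fish()
  tl <- fit_trait_lmm(d, "standard_length")
  expect_equal(tl$beta, log(1 + tl$pct_change / 100), tolerance = 1e-12)
  # genotypes share the SL distribution -> small percent effect
  expect_lt(abs(tl$pct_change), 5)
  ta <- fit_trait_lmm(d, "total_adiposity")
  expect_true(is.finite(ta$pct_change))
})

test_that("single-experiment OLS equals the zero-batch-variance limit", {
  set.seed(60)
  d <- make_lmm_fish(beta = log(1.1), k = 1, sigma_batch = 0)
  sr <- single_experiment_analysis(d)
  ols <- lm(log(mean_feret) ~ log(sat_area) + genotype,
            data = transform(d, genotype = factor(genotype,
                                                  c("control", "mutant"))))
  expect_equal(sr$beta, unname(coef(ols)["genotypemutant"]),
               tolerance = 1e-12)
  expect_true(sr$preliminary)
  expect_error(single_experiment_analysis(make_lmm_fish(k = 2)),
               "one experiment")
})

test_that("replicate consistency rewards agreement in sign and size", {
  expect_equal(compute_consistency(c(4, 4, 4)), 1)
  expect_equal(compute_consistency(c(5, -5)), 0)
  expect_equal(compute_consistency(c(5, 10)),
               1 / (1 + sd(c(5, 10)) / 7.5), tolerance = 1e-12)
  expect_equal(compute_consistency(c(5, 10)), 0.68, tolerance = 0.005)
  expect_error(compute_consistency(3), ">= 2")
})
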