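make_obs <- function(deltas_by_fish) {
  # build a paired long table from per-fish stratum vectors
  do.call(rbind, lapply(names(deltas_by_fish), function(id) {
    spec <- deltas_by_fish[[id]]
    data.frame(fish_id = id, genotype = spec$genotype, diet = spec$diet,
               timepoint = rep(c("baseline", "post"),
                               each = length(spec$base)),
               stratum = rep(seq_along(spec$base), 2),
               mean_feret = c(spec$base, spec$base + spec$delta))
  }))
}

test_that("paired changes are post minus baseline per fish and stratum", {
  obs <- make_obs(list(
    f1 = list(genotype = "control", diet = "control",
              base = c(50, 45, 40), delta = c(0, 0, 0)),
    f2 = list(genotype = "control", diet = "HFD",
              base = c(52, 46, 41), delta = c(10, 10, 10))))
  d <- paired_changes(obs)
  expect_equal(d$delta[d$fish_id == "f1"], c(0, 0, 0))
  expect_equal(d$delta[d$fish_id == "f2"], c(10, 10, 10))
  expect_equal(nrow(attr(d, "emergent")), 0L)
})

test_that("strata seen at only one timepoint are flagged emergent", {
  obs <- make_obs(list(
    f1 = list(genotype = "control", diet = "HFD",
              base = c(50, 45), delta = c(5, 5))))
  extra <- data.frame(fish_id = "f1", genotype = "control", diet = "HFD",
                      timepoint = "post", stratum = 3, mean_feret = 30)
  d <- paired_changes(rbind(obs, extra))
  expect_equal(nrow(d), 2L)
  em <- attr(d, "emergent")
  expect_equal(em$stratum, 3)
  # a fish lacking a whole timepoint is an error
  bad <- obs[obs$timepoint == "baseline", ]
  expect_error(paired_changes(bad), "missing a timepoint")
})

test_that("stratum diet effects, minimum n, and single-stratum FDR", {
  specs <- list()
  for (i in 1:4) {
    specs[[paste0("c", i)]] <- list(genotype = "control", diet = "control",
                                    base = 50, delta = 1 + 0.1 * i)
    specs[[paste0("h", i)]] <- list(genotype = "control", diet = "HFD",
                                    base = 50, delta = 21 + 0.1 * i)
  }
  d <- paired_changes(make_obs(specs))
  eff <- stratum_diet_effect(d, "control")
  expect_equal(nrow(eff), 1L)
  expect_equal(eff$diet_effect, 20, tolerance = 1e-9)
  expect_equal(eff$adj_p, eff$p_value)  # single stratum: adj = raw
  expect_true(eff$significant)
  # below the per-group minimum: untestable but effect still reported
  eff2 <- stratum_diet_effect(d, "control", min_n = 5)
  expect_false(eff2$testable)
  expect_true(is.na(eff2$p_value))
  expect_equal(eff2$diet_effect, 20, tolerance = 1e-9)
})

test_that("a uniform simulated HFD effect is significant in all strata", {
  ok <- vapply(1:10, function(r) {
    cfg <- sim_config(diet_profile = rep(20, 15), diet_blunting = 1)
    de <- simulate_diet_experiment(cfg, n_per_group = 8, seed = 900 + r)
    d <- paired_changes(de$observations)
    eff <- stratum_diet_effect(d, "control")
    all(eff$significant)
  }, logical(1))
  expect_gte(mean(ok), 0.9)
})

test_that("no simulated diet effect keeps false positives near alpha", {
  sig <- unlist(lapply(1:40, function(r) {
    cfg <- sim_config(diet_profile = rep(0, 15), diet_blunting = 1)
    de <- simulate_diet_experiment(cfg, n_per_group = 8, seed = 1900 + r)
    d <- paired_changes(de$observations)
    # raw p-values across strata (BH would push all to ns anyway)
    stratum_diet_effect(d, "control")$p_value
  }))
  expect_lt(mean(sig < 0.05), 0.10)
})

test_that("baseline genotype contrast recovers the anterior-graded
          hypertrophy of the generator", {
  de <- simulate_diet_experiment(sim_config(), n_per_group = 10,
                                 seed = 91)
  bc <- baseline_genotype_contrast(de$observations, strata = 1:5)
  truth <- de$ground_truth$per_stratum$baseline_shift_mutant[1:5]
  expect_true(all(bc$difference > 0))
  expect_equal(bc$difference, truth, tolerance = 0.35)
  # anterior shift exceeds the posterior one (graded, not uniform)
  expect_gt(bc$difference[1], bc$difference[5])
  expect_true(all(bc$significant))
})

test_that("overall contrast reproduces the difference-in-means arithmetic", {
  oc <- overall_diet_contrast(24.4, 7.7)
  expect_identical(oc$reduction_pct, 68)
  expect_identical(overall_diet_contrast(5, 5)$reduction_pct, 0)
  expect_identical(overall_diet_contrast(5, 0)$reduction_pct, 100)
  # invariant to rescaling all diameters by a common factor
  set.seed(92)
  ew <- runif(10, 10, 30); em <- runif(10, 2, 9)
  expect_identical(overall_diet_contrast(ew, em)$reduction_pct,
                   overall_diet_contrast(3.7 * ew, 3.7 * em)$reduction_pct)
  expect_warning(oc0 <- overall_diet_contrast(0, 1), "undefined")
  expect_true(is.na(oc0$reduction_pct))
})

test_that("per-genotype overall effect equals the mean of stratum effects", {
  de <- simulate_diet_experiment(sim_config(), n_per_group = 8, seed = 93)
  d <- paired_changes(de$observations)
  ew <- stratum_diet_effect(d, "control")
  em <- stratum_diet_effect(d, "mutant")
  oc <- overall_diet_contrast(ew$diet_effect, em$diet_effect)
  expect_equal(oc$effect_wildtype, mean(ew$diet_effect), tolerance = 1e-12)
  expect_equal(oc$effect_mutant, mean(em$diet_effect), tolerance = 1e-12)
})
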