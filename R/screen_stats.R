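# Per-gene screening statistics: pooled and stratified KS tests with Fisher
# combination, random-intercept mixed models with back-transformed percent
# effects, FDR families, hit classification, effect sizes and power.

#' Two-sample Kolmogorov-Smirnov test
#'
#' `D = sup |ECDF_a - ECDF_b|` with a two-sided p-value. The asymptotic
#' distribution is used except when either sample has fewer than
#' `exact_below` observations, where the exact small-sample p is computed.
#' Morphology values are continuous, so ties are measure-zero in practice.
#'
#' @param a,b Numeric samples (non-empty).
#' @param exact_below Use the exact p-value when `min(n_a, n_b)` is below
#'   this (default 10).
#' @return list with `statistic` (D) and `p_value`.
#' @export
ks_two_sample <- function(a, b, exact_below = 10) {
  if (!length(a) || !length(b)) stop("empty sample")
  exact <- min(length(a), length(b)) < exact_below
  kt <- suppressWarnings(stats::ks.test(a, b, exact = exact))
  list(statistic = unname(kt$statistic), p_value = unname(kt$p.value))
}

#' Combine p-values with Fisher's method
#'
#' `chi2 = -2 * sum(log(p_i))` referred to a chi-squared distribution with
#' `2k` degrees of freedom.
#'
#' @param p_values Vector of p-values in (0, 1].
#' @return list with `chisq`, `df` and `p_value`.
#' @export
fisher_combine <- function(p_values) {
  if (!length(p_values)) stop("no p-values to combine")
  if (any(p_values <= 0 | p_values > 1)) stop("p-values must lie in (0, 1]")
  chisq <- -2 * sum(log(p_values))
  df <- 2L * length(p_values)
  list(chisq = chisq, df = df,
       p_value = stats::pchisq(chisq, df, lower.tail = FALSE))
}

#' Pooled KS test of mutant vs control morphology values
#'
#' The smoother is fitted to all controls pooled across experiments; the KS
#' test compares control residuals with mutant deviations from that fit.
#'
#' @param gene_data One gene's fish table (see [morphology_table()]).
#' @param basis_dim Spline basis dimension.
#' @return list with `statistic`, `p_value`, `effect` (mutant minus control
#'   mean morphology value, um), `n_control`, `n_mutant`.
#' @export
pooled_ks_test <- function(gene_data, basis_dim = 10) {
  mt <- morphology_table(gene_data, scope = "pooled", basis_dim = basis_dim)
  cv <- mt$value[mt$genotype == "control"]
  mv <- mt$value[mt$genotype == "mutant"]
  ks <- ks_two_sample(cv, mv)
  list(statistic = ks$statistic, p_value = ks$p_value,
       effect = mean(mv) - mean(cv),
       n_control = length(cv), n_mutant = length(mv))
}

#' Stratified KS test with Fisher combination
#'
#' KS tests are run within each experiment separately, against
#' experiment-specific control smoothers, and combined with
#' [fisher_combine()]; this validates that a distributional shift is
#' reproducible within batches rather than driven by between-batch
#' variability. The effect size is the sample-size-weighted mean of the
#' per-experiment mutant-minus-control morphology-value differences.
#'
#' @param gene_data One gene's fish table.
#' @param min_n Minimum fish per genotype within an experiment for that
#'   experiment to be testable (default 5).
#' @param basis_dim Spline basis dimension.
#' @return list with `per_experiment` (data.frame of experiment, n's, D,
#'   p, effect), `chisq`, `df`, `p_value` (Fisher-combined) and `effect`
#'   (weighted, um).
#' @export
stratified_ks_test <- function(gene_data, min_n = 5, basis_dim = 10) {
  mt <- morphology_table(gene_data, scope = "per_experiment",
                         basis_dim = basis_dim,
                         min_controls_experiment = min_n)
  rows <- lapply(split(mt, mt$experiment), function(sub) {
    cv <- sub$value[sub$genotype == "control"]
    mv <- sub$value[sub$genotype == "mutant"]
    if (length(cv) < min_n || length(mv) < min_n) return(NULL)
    ks <- ks_two_sample(cv, mv)
    data.frame(experiment = sub$experiment[1],
               n_control = length(cv), n_mutant = length(mv),
               statistic = ks$statistic, p_value = ks$p_value,
               effect = mean(mv) - mean(cv))
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (!length(rows)) stop("no experiment meets the per-group minimum n")
  pe <- do.call(rbind, rows)
  rownames(pe) <- NULL
  fc <- fisher_combine(pe$p_value)
  w <- pe$n_control + pe$n_mutant
  list(per_experiment = pe, chisq = fc$chisq, df = fc$df,
       p_value = fc$p_value,
       effect = sum(pe$effect * w) / sum(w))
}

# shared fixed-effect extraction for lme4 fits
.lmer_coef <- function(fit, term, p_method) {
  sm <- summary(fit)$coefficients
  beta <- sm[term, "Estimate"]
  se <- sm[term, "Std. Error"]
  if (p_method == "satterthwaite" &&
      requireNamespace("lmerTest", quietly = TRUE)) {
    p <- sm[term, "Pr(>|t|)"]
  } else {
    p <- 2 * stats::pnorm(-abs(beta / se))
  }
  list(beta = unname(beta), se = unname(se), p_value = unname(p))
}

.lmm_fit <- function(formula, data, p_method) {
  suppressMessages(
    if (p_method == "satterthwaite" &&
        requireNamespace("lmerTest", quietly = TRUE)) {
      lmerTest::lmer(formula, data = data, REML = TRUE)
    } else {
      lme4::lmer(formula, data = data, REML = TRUE)
    })
}

.check_gene_data <- function(gene_data) {
  gene_data <- as.data.frame(gene_data)
  if (length(unique(gene_data$experiment)) < 2L) {
    stop("fewer than 2 experiments; use single_experiment_analysis()")
  }
  if (!all(c("control", "mutant") %in% gene_data$genotype)) {
    stop("both genotypes must be present")
  }
  gene_data$genotype <- factor(gene_data$genotype,
                               levels = c("control", "mutant"))
  gene_data
}

#' Random-intercept mixed model for the genotype effect on droplet size
#'
#' Fits `log(mean_feret) ~ log(sat_area) + genotype + (1 | experiment)` by
#' REML, testing whether mutants have uniformly larger or smaller droplets
#' at any given depot size. The genotype coefficient is back-transformed to
#' a percent change `(exp(beta) - 1) * 100` with a 95% Wald interval
#' `(exp(beta +/- 1.96 se) - 1) * 100`.
#'
#' @param gene_data One gene's fish table (>= 2 experiments, both
#'   genotypes).
#' @param p_method `"wald"` (normal approximation, default) or
#'   `"satterthwaite"` (via lmerTest when available). At screen sample
#'   sizes the two are practically indistinguishable.
#' @return list with `beta`, `se`, `p_value`, `pct_change`, `ci_low`,
#'   `ci_high` (percent), `converged`.
#' @export
fit_lmm_intercept <- function(gene_data,
                              p_method = c("wald", "satterthwaite")) {
  p_method <- match.arg(p_method)
  gene_data <- .check_gene_data(gene_data)
  fit <- tryCatch(
    .lmm_fit(log(mean_feret) ~ log(sat_area) + genotype + (1 | experiment),
             gene_data, p_method),
    error = function(e) e)
  if (inherits(fit, "error")) {
    return(list(beta = NA_real_, se = NA_real_, p_value = NA_real_,
                pct_change = NA_real_, ci_low = NA_real_,
                ci_high = NA_real_, converged = FALSE,
                message = conditionMessage(fit)))
  }
  cf <- .lmer_coef(fit, "genotypemutant", p_method)
  conv <- length(fit@optinfo$conv$lme4$messages) == 0L
  list(beta = cf$beta, se = cf$se, p_value = cf$p_value,
       pct_change = (exp(cf$beta) - 1) * 100,
       ci_low = (exp(cf$beta - 1.96 * cf$se) - 1) * 100,
       ci_high = (exp(cf$beta + 1.96 * cf$se) - 1) * 100,
       converged = conv)
}

#' Mixed model for a genotype-by-depot-size interaction
#'
#' Fits `log(mean_feret) ~ log(sat_area) * genotype + (1 | experiment)`,
#' testing whether the allometric scaling of droplet size with total
#' adiposity differs between genotypes (a size-dependent rather than
#' uniform phenotype).
#'
#' @inheritParams fit_lmm_intercept
#' @return list with `slope_beta` (interaction coefficient), `se`,
#'   `p_value`, `converged`.
#' @export
fit_lmm_interaction <- function(gene_data,
                                p_method = c("wald", "satterthwaite")) {
  p_method <- match.arg(p_method)
  gene_data <- .check_gene_data(gene_data)
  fit <- tryCatch(
    .lmm_fit(log(mean_feret) ~ log(sat_area) * genotype + (1 | experiment),
             gene_data, p_method),
    error = function(e) e)
  if (inherits(fit, "error")) {
    return(list(slope_beta = NA_real_, se = NA_real_, p_value = NA_real_,
                converged = FALSE, message = conditionMessage(fit)))
  }
  cf <- .lmer_coef(fit, "log(sat_area):genotypemutant", p_method)
  list(slope_beta = cf$beta, se = cf$se, p_value = cf$p_value,
       converged = length(fit@optinfo$conv$lme4$messages) == 0L)
}

#' Benjamini-Hochberg adjustment within a test family
#'
#' Applied separately to each of the four screen families (pooled KS,
#' stratified KS, LMM intercept, LMM slope) so that each question carries
#' its own false-discovery budget.
#'
#' @param p_values Raw p-values of one family.
#' @param family Optional family label, carried as an attribute.
#' @return Adjusted p-values (monotone, >= raw).
#' @export
adjust_fdr <- function(p_values, family = NULL) {
  if (!length(p_values)) stop("empty p-value family")
  out <- stats::p.adjust(p_values, method = "BH")
  if (!is.null(family)) attr(out, "family") <- family
  out
}

#' Classify genes by the dual robustness criterion
#'
#' `robust` requires adjusted significance in *both* the stratified KS test
#' and the LMM intercept test: the distributional effect must be
#' reproducible within experiments and the mean shift must survive the
#' random-intercept model. `distributional_only` marks stratified-KS-only
#' signals (altered variance or size-dependent effects); `suggestive` marks
#' genes nominally significant in the pooled KS test only; everything else
#' is `ns`.
#'
#' @param results data.frame with columns `ks_stratified_adj_p`,
#'   `lmm_adj_p`, optionally `ks_pooled_p` (raw) and `ks_effect` for the
#'   direction.
#' @param alpha Significance threshold (default 0.05).
#' @return `results` with added `classification` and (when `ks_effect` is
#'   present) `direction`.
#' @export
classify_hits <- function(results, alpha = 0.05) {
  results <- as.data.frame(results)
  strat <- results$ks_stratified_adj_p < alpha
  lmm <- results$lmm_adj_p < alpha
  pooled <- if ("ks_pooled_p" %in% names(results)) {
    results$ks_pooled_p < alpha
  } else rep(FALSE, nrow(results))
  strat[is.na(strat)] <- FALSE
  lmm[is.na(lmm)] <- FALSE
  pooled[is.na(pooled)] <- FALSE
  results$classification <- ifelse(
    strat & lmm, "robust",
    ifelse(strat, "distributional_only",
           ifelse(pooled, "suggestive", "ns")))
  if ("ks_effect" %in% names(results)) {
    results$direction <- ifelse(results$ks_effect >= 0,
                                "hypertrophic", "hyperplastic")
  }
  results
}

#' Cohen's d standardized mean difference
#'
#' `(mean(a) - mean(b)) / s_pooled` with the pooled variance weighted by
#' `n - 1` in each group.
#'
#' @param a,b Numeric samples with at least 2 observations each.
#' @return Cohen's d.
#' @export
cohens_d <- function(a, b) {
  n1 <- length(a); n2 <- length(b)
  if (n1 < 2L || n2 < 2L) stop("each sample needs n >= 2")
  sp2 <- ((n1 - 1) * stats::var(a) + (n2 - 1) * stats::var(b)) /
    (n1 + n2 - 2)
  if (sp2 <= 0) stop("zero pooled variance")
  (mean(a) - mean(b)) / sqrt(sp2)
}

#' Power of the two-sample t-test at a given effect size
#'
#' Exact power via the noncentral t distribution with
#' `ncp = d * sqrt(n1 n2 / (n1 + n2))` and `df = n1 + n2 - 2`.
#'
#' @param n1,n2 Group sizes (>= 2).
#' @param d Cohen's d effect size (>= 0).
#' @param alpha Significance level (default 0.05).
#' @param two_sided Two-sided test (default TRUE).
#' @return Power in \[0, 1\].
#' @export
power_two_sample <- function(n1, n2, d, alpha = 0.05, two_sided = TRUE) {
  if (any(n1 < 2) || any(n2 < 2)) stop("group sizes must be >= 2")
  if (any(d < 0)) stop("d must be >= 0")
  df <- n1 + n2 - 2
  ncp <- d * sqrt(n1 * n2 / (n1 + n2))
  if (two_sided) {
    tc <- stats::qt(1 - alpha / 2, df)
    stats::pt(-tc, df, ncp) + stats::pt(tc, df, ncp, lower.tail = FALSE)
  } else {
    tc <- stats::qt(1 - alpha, df)
    stats::pt(tc, df, ncp, lower.tail = FALSE)
  }
}

#' Smallest mutant group size reaching a target power
#'
#' Increments `n` until [power_two_sample()] reaches the target, either with
#' equal allocation (`n` controls and `n` mutants) or with the control group
#' fixed at `n_control`.
#'
#' @param d Cohen's d.
#' @param power Target power (default 0.8).
#' @param alpha Significance level.
#' @param allocation `"equal"` or `"fixed_control"`.
#' @param n_control Control group size when `allocation = "fixed_control"`.
#' @param n_max Search ceiling (default 10000).
#' @return Smallest integer mutant n achieving the target.
#' @export
sample_size_for_power <- function(d, power = 0.8, alpha = 0.05,
                                  allocation = c("equal", "fixed_control"),
                                  n_control = NULL, n_max = 10000) {
  allocation <- match.arg(allocation)
  if (power <= 0 || power >= 1) stop("power must be in (0, 1)")
  if (allocation == "fixed_control" &&
      (is.null(n_control) || n_control < 2)) {
    stop("`n_control` >= 2 required for fixed-control allocation")
  }
  pw <- function(n) {
    n1 <- if (allocation == "equal") n else n_control
    power_two_sample(n1, n, d, alpha)
  }
  for (n in 2:n_max) if (pw(n) >= power) return(n)
  stop("requested power not reachable within n_max")
}

#' Mixed-model effect on a whole-animal trait
#'
#' Fits `log(trait) ~ genotype + (1 | experiment)` for standard length or
#' normalized total adiposity (total lipid area divided by
#' `standard_length^sl_exponent`; the default exponent 2 makes the measure
#' scale-free for isometric growth).
#'
#' @param gene_data One gene's fish table with `standard_length` and
#'   `total_lipid_area`.
#' @param trait `"standard_length"` or `"total_adiposity"`.
#' @param sl_exponent Normalization exponent for total adiposity (default 2).
#' @inheritParams fit_lmm_intercept
#' @return list with `trait`, `beta`, `se`, `p_value`, `pct_change`,
#'   `ci_low`, `ci_high`, `converged`.
#' @export
fit_trait_lmm <- function(gene_data,
                          trait = c("standard_length", "total_adiposity"),
                          sl_exponent = 2,
                          p_method = c("wald", "satterthwaite")) {
  trait <- match.arg(trait)
  p_method <- match.arg(p_method)
  gene_data <- .check_gene_data(gene_data)
  gene_data$.y <- if (trait == "standard_length") {
    gene_data$standard_length
  } else {
    gene_data$total_lipid_area / gene_data$standard_length^sl_exponent
  }
  if (any(gene_data$.y <= 0)) stop("trait values must be positive")
  fit <- tryCatch(
    .lmm_fit(log(.y) ~ genotype + (1 | experiment), gene_data, p_method),
    error = function(e) e)
  if (inherits(fit, "error")) {
    return(list(trait = trait, beta = NA_real_, se = NA_real_,
                p_value = NA_real_, pct_change = NA_real_,
                ci_low = NA_real_, ci_high = NA_real_, converged = FALSE))
  }
  cf <- .lmer_coef(fit, "genotypemutant", p_method)
  list(trait = trait, beta = cf$beta, se = cf$se, p_value = cf$p_value,
       pct_change = (exp(cf$beta) - 1) * 100,
       ci_low = (exp(cf$beta - 1.96 * cf$se) - 1) * 100,
       ci_high = (exp(cf$beta + 1.96 * cf$se) - 1) * 100,
       converged = length(fit@optinfo$conv$lme4$messages) == 0L)
}

#' Analysis for genes measured in a single experiment
#'
#' With no replicate experiments, batch correction is impossible: the
#' genotype effect comes from ordinary least squares
#' `log(mean_feret) ~ log(sat_area) + genotype`, alongside a pooled KS test.
#' Results are flagged preliminary and must not enter the FDR families.
#'
#' @param gene_data One gene's fish table from exactly one experiment.
#' @param basis_dim Spline basis dimension for the KS step.
#' @return list with `beta`, `se`, `p_value`, `pct_change`, `ks`
#'   (pooled KS result) and `preliminary = TRUE`.
#' @export
single_experiment_analysis <- function(gene_data, basis_dim = 10) {
  gene_data <- as.data.frame(gene_data)
  if (length(unique(gene_data$experiment)) != 1L) {
    stop("expected exactly one experiment")
  }
  if (!all(c("control", "mutant") %in% gene_data$genotype)) {
    stop("both genotypes must be present")
  }
  gene_data$genotype <- factor(gene_data$genotype,
                               levels = c("control", "mutant"))
  fit <- stats::lm(log(mean_feret) ~ log(sat_area) + genotype,
                   data = gene_data)
  sm <- summary(fit)$coefficients
  ks <- pooled_ks_test(gene_data, basis_dim = basis_dim)
  list(beta = unname(sm["genotypemutant", "Estimate"]),
       se = unname(sm["genotypemutant", "Std. Error"]),
       p_value = unname(sm["genotypemutant", "Pr(>|t|)"]),
       pct_change = (exp(sm["genotypemutant", "Estimate"]) - 1) * 100,
       ks = ks, preliminary = TRUE)
}

#' Replicate consistency score
#'
#' Agreement in direction and magnitude of per-experiment effects:
#' `(fraction of effect pairs agreeing in sign) * 1 / (1 + CV)` where
#' `CV = sd(effects) / |mean(effects)|`. Identical replicate effects score
#' 1; opposite-sign effects score 0. (The published screen reports such a
#' score without a formula; this definition is the package's own and is
#' deterministic.)
#'
#' @param effects Numeric vector of per-experiment effects (length >= 2).
#' @return Score in \[0, 1\].
#' @export
compute_consistency <- function(effects) {
  if (length(effects) < 2L) stop("need >= 2 per-experiment effects")
  pairs <- utils::combn(effects, 2)
  agree <- mean(sign(pairs[1, ]) == sign(pairs[2, ]) & sign(pairs[1, ]) != 0)
  m <- mean(effects)
  if (m == 0) return(0)
  cv <- stats::sd(effects) / abs(m)
  agree / (1 + cv)
}
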