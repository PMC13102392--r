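# Sensitivity suite for the screen's mixed-model estimates: variance
# heterogeneity, distributional moments, a heteroscedastic mixed model, a
# within-experiment permutation test, Welch's t-test, and a consensus call.

#' Variance heterogeneity F-test with distributional moments
#'
#' Tests whether mutants show altered phenotypic *variance* beyond any mean
#' shift: `ratio = var(mutant) / var(control)` referred to an F distribution
#' with `(n_mut - 1, n_ctrl - 1)` degrees of freedom, two-sided
#' (`p = 2 * min(tail, 1 - tail)`). Skewness, excess kurtosis and tail
#' percentage of both groups are attached via [distribution_moments()].
#'
#' @param control_values,mutant_values Morphology values per genotype
#'   (n >= 2 each; n >= 4 for the moment summaries).
#' @return list with `variance_ratio`, `df`, `p_value` and, when group
#'   sizes allow, `moments_control` and `moments_mutant`.
#' @export
variance_f_test <- function(control_values, mutant_values) {
  nc <- length(control_values); nm <- length(mutant_values)
  if (nc < 2L || nm < 2L) stop("each group needs n >= 2")
  vc <- stats::var(control_values); vm <- stats::var(mutant_values)
  if (vc == 0 || vm == 0) stop("zero variance in a group")
  ratio <- vm / vc
  tail <- stats::pf(ratio, nm - 1, nc - 1)
  out <- list(variance_ratio = ratio, df = c(nm - 1L, nc - 1L),
              p_value = min(1, 2 * min(tail, 1 - tail)))
  if (nc >= 4L) out$moments_control <- distribution_moments(control_values)
  if (nm >= 4L) out$moments_mutant <- distribution_moments(mutant_values)
  out
}

#' Skewness, excess kurtosis and tail percentage
#'
#' Moment (method-of-moments, biased) definitions on central moments `m_k`:
#' skewness `g1 = m3 / m2^1.5`, excess kurtosis `g2 = m4 / m2^2 - 3`, and
#' the percentage of observations more than 2 standard deviations
#' (`sqrt(m2)`) from the mean.
#'
#' @param values Numeric vector, n >= 4, non-constant.
#' @return list with `skewness`, `excess_kurtosis`, `tail_pct`.
#' @export
distribution_moments <- function(values) {
  n <- length(values)
  if (n < 4L) stop("need n >= 4")
  mu <- mean(values)
  m2 <- mean((values - mu)^2)
  if (m2 == 0) stop("zero variance")
  m3 <- mean((values - mu)^3)
  m4 <- mean((values - mu)^4)
  list(skewness = m3 / m2^1.5,
       excess_kurtosis = m4 / m2^2 - 3,
       tail_pct = 100 * mean(abs(values - mu) > 2 * sqrt(m2)))
}

#' Mixed model with genotype-specific residual variances
#'
#' Refits the intercept model allowing a different residual standard
#' deviation per genotype (`nlme::lme` with
#' `weights = varIdent(form = ~ 1 | genotype)`, maximum likelihood), so a
#' genotype effect is not an artifact of unequal spread. Constraining the
#' two variances equal recovers the homoscedastic ML log-likelihood.
#'
#' @param gene_data One gene's fish table (>= 2 experiments, both
#'   genotypes).
#' @return list with `beta`, `se`, `p_value`, `residual_sd` (named control /
#'   mutant), `sd_ratio` (mutant / control), `logLik`,
#'   `logLik_homoscedastic` and `converged`.
#' @export
heteroscedastic_lmm <- function(gene_data) {
  gene_data <- as.data.frame(gene_data)
  if (!all(c("control", "mutant") %in% gene_data$genotype)) {
    stop("both genotypes must be present")
  }
  gene_data$genotype <- factor(gene_data$genotype,
                               levels = c("control", "mutant"))
  multi <- length(unique(gene_data$experiment)) >= 2L
  # with a single experiment there is no batch variance to model and the
  # fit reduces to generalized (weighted) least squares
  fit <- tryCatch(
    if (multi) {
      nlme::lme(log(mean_feret) ~ log(sat_area) + genotype,
                random = ~ 1 | experiment,
                weights = nlme::varIdent(form = ~ 1 | genotype),
                data = gene_data, method = "ML")
    } else {
      nlme::gls(log(mean_feret) ~ log(sat_area) + genotype,
                weights = nlme::varIdent(form = ~ 1 | genotype),
                data = gene_data, method = "ML")
    },
    error = function(e) e)
  if (inherits(fit, "error")) {
    return(list(beta = NA_real_, se = NA_real_, p_value = NA_real_,
                residual_sd = c(control = NA_real_, mutant = NA_real_),
                sd_ratio = NA_real_, logLik = NA_real_,
                logLik_homoscedastic = NA_real_, converged = FALSE,
                message = conditionMessage(fit)))
  }
  tt <- summary(fit)$tTable
  sig <- fit$sigma
  # varIdent stores one multiplier per stratum; recover per-genotype SDs
  ratios <- stats::coef(fit$modelStruct$varStruct, unconstrained = FALSE,
                        allCoef = TRUE)
  sds <- sig * ratios[c("control", "mutant")]
  homo <- tryCatch(
    if (multi) {
      nlme::lme(log(mean_feret) ~ log(sat_area) + genotype,
                random = ~ 1 | experiment, data = gene_data, method = "ML")
    } else {
      nlme::gls(log(mean_feret) ~ log(sat_area) + genotype,
                data = gene_data, method = "ML")
    },
    error = function(e) NULL)
  list(beta = unname(tt["genotypemutant", "Value"]),
       se = unname(tt["genotypemutant", "Std.Error"]),
       p_value = unname(tt["genotypemutant", "p-value"]),
       residual_sd = c(control = unname(sds["control"]),
                       mutant = unname(sds["mutant"])),
       sd_ratio = unname(sds["mutant"] / sds["control"]),
       logLik = as.numeric(stats::logLik(fit)),
       logLik_homoscedastic = if (is.null(homo)) NA_real_ else
         as.numeric(stats::logLik(homo)),
       converged = TRUE)
}

#' Within-experiment permutation test of the genotype effect
#'
#' Genotype labels are shuffled independently within each experiment
#' (preserving per-experiment group counts) and the genotype coefficient is
#' refitted each time; the observed absolute effect is referred to this
#' null. The add-one estimator `p = (1 + #(|b*| >= |b|)) / (B + 1)` is
#' reported (it cannot be exactly zero) together with the raw exceedance
#' proportion.
#'
#' @param gene_data One gene's fish table; every experiment must contain
#'   both genotypes.
#' @param B Number of permutations (default 1000).
#' @param seed Optional integer seed; the result is reproducible for a
#'   given seed.
#' @param statistic `"lmm"` (mixed-model genotype coefficient; OLS when only
#'   one experiment) or `"meandiff"` (difference in mean log Feret adjusted
#'   for log depot area via OLS residuals within experiment).
#' @return list with `observed` (|beta|), `perm_p`, `raw_proportion`, `B`,
#'   `seed`.
#' @export
permutation_test <- function(gene_data, B = 1000, seed = NULL,
                             statistic = c("lmm", "meandiff")) {
  statistic <- match.arg(statistic)
  if (B < 1) stop("B must be >= 1")
  gene_data <- as.data.frame(gene_data)
  gene_data$genotype <- factor(gene_data$genotype,
                               levels = c("control", "mutant"))
  by_exp <- split(seq_len(nrow(gene_data)), gene_data$experiment)
  for (i in by_exp) {
    if (length(unique(gene_data$genotype[i])) < 2L) {
      stop("every experiment must contain both genotypes")
    }
  }
  multi <- length(by_exp) >= 2L
  stat_fun <- if (statistic == "lmm" && multi) {
    function(d) {
      fit <- suppressMessages(suppressWarnings(
        lme4::lmer(log(mean_feret) ~ log(sat_area) + genotype +
                     (1 | experiment), data = d, REML = TRUE,
                   control = lme4::lmerControl(calc.derivs = FALSE))))
      abs(unname(lme4::fixef(fit)["genotypemutant"]))
    }
  } else if (statistic == "lmm") {
    function(d) {
      abs(unname(stats::coef(stats::lm(
        log(mean_feret) ~ log(sat_area) + genotype,
        data = d))["genotypemutant"]))
    }
  } else {
    function(d) {
      r <- unlist(lapply(split(d, d$experiment), function(s) {
        stats::residuals(stats::lm(log(mean_feret) ~ log(sat_area),
                                   data = s))
      }), use.names = FALSE)
      g <- unlist(lapply(split(d, d$experiment),
                         function(s) s$genotype), use.names = FALSE)
      abs(mean(r[g == "mutant"]) - mean(r[g == "control"]))
    }
  }
  if (!is.null(seed)) {
    if (exists(".Random.seed", envir = globalenv())) {
      old <- get(".Random.seed", envir = globalenv())
      on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
    }
    set.seed(seed)
  }
  observed <- stat_fun(gene_data)
  perm <- vapply(seq_len(B), function(b) {
    d <- gene_data
    for (i in by_exp) d$genotype[i] <- sample(d$genotype[i])
    stat_fun(d)
  }, numeric(1))
  exceed <- sum(perm >= observed)
  list(observed = observed,
       perm_p = (1 + exceed) / (B + 1),
       raw_proportion = exceed / B,
       B = B, seed = seed)
}

#' Welch's t-test on morphology values
#'
#' Two-sample t-test with the Welch-Satterthwaite degrees-of-freedom
#' correction (no equal-variance assumption).
#'
#' @param control_values,mutant_values Numeric samples (n >= 2 each).
#' @return list with `t`, `df`, `p_value`.
#' @export
welch_test <- function(control_values, mutant_values) {
  if (length(control_values) < 2L || length(mutant_values) < 2L) {
    stop("each group needs n >= 2")
  }
  if (stats::var(control_values) == 0 && stats::var(mutant_values) == 0) {
    stop("zero variance in both groups")
  }
  tt <- stats::t.test(mutant_values, control_values, var.equal = FALSE)
  list(t = unname(tt$statistic), df = unname(tt$parameter),
       p_value = unname(tt$p.value))
}

#' Consensus classification across the three sensitivity tests
#'
#' `"ALL SIG"` when the heteroscedastic LMM, permutation and Welch p-values
#' are all below `alpha`; `"ALL NS"` when none is; `"MIXED"` otherwise.
#' Only genes with consistent significance across all three have robust
#' mixed-model estimates.
#'
#' @param hetero_p,perm_p,welch_p The three p-values.
#' @param alpha Significance threshold (default 0.05).
#' @return `"ALL SIG"`, `"ALL NS"` or `"MIXED"`.
#' @export
consensus_classify <- function(hetero_p, perm_p, welch_p, alpha = 0.05) {
  p <- c(hetero_p, perm_p, welch_p)
  if (any(is.na(p) | p < 0 | p > 1)) stop("p-values must lie in [0, 1]")
  sig <- sum(p < alpha)
  if (sig == 3L) "ALL SIG" else if (sig == 0L) "ALL NS" else "MIXED"
}

#' Run the full robustness suite for one gene
#'
#' @param gene_data One gene's fish table.
#' @param B Number of permutations.
#' @param seed Seed for the permutation test.
#' @param alpha Threshold for the consensus call.
#' @return One-row data.frame: variance ratio and F p, moment summaries,
#'   the three sensitivity p-values, `consensus`, `B`, `seed`.
#' @export
robustness_suite <- function(gene_data, B = 1000, seed = NULL,
                             alpha = 0.05) {
  mt <- morphology_table(gene_data, scope = "pooled")
  cv <- mt$value[mt$genotype == "control"]
  mv <- mt$value[mt$genotype == "mutant"]
  vf <- variance_f_test(cv, mv)
  het <- heteroscedastic_lmm(gene_data)
  perm <- permutation_test(gene_data, B = B, seed = seed)
  w <- welch_test(cv, mv)
  data.frame(
    variance_ratio = vf$variance_ratio, f_p = vf$p_value,
    skewness_control = vf$moments_control$skewness,
    skewness_mutant = vf$moments_mutant$skewness,
    excess_kurtosis_control = vf$moments_control$excess_kurtosis,
    excess_kurtosis_mutant = vf$moments_mutant$excess_kurtosis,
    tail_pct_control = vf$moments_control$tail_pct,
    tail_pct_mutant = vf$moments_mutant$tail_pct,
    hetero_lmm_p = het$p_value, sd_ratio = het$sd_ratio,
    perm_p = perm$perm_p, welch_p = w$p_value,
    consensus = consensus_classify(het$p_value, perm$perm_p, w$p_value,
                                   alpha),
    B = B, seed = if (is.null(seed)) NA_integer_ else seed
  )
}
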