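# Paired baseline/post-diet spatial analysis. Each fish is imaged before
# and after a 14-day dietary period (high-fat or control diet), droplets
# are binned into the same 200 um strata at both timepoints, and the diet
# effect per stratum is the difference-in-differences: the high-fat change
# minus the control-diet change.

#' Per-fish per-stratum paired changes
#'
#' `delta = post - baseline` mean Feret diameter for every (fish, stratum)
#' pair observed at both timepoints. Strata present at only one timepoint
#' (typically newly formed posterior strata) are flagged emergent and
#' excluded from the paired contrast; they are returned in the attribute
#' `emergent`.
#'
#' @param observations Long data.frame with columns `fish_id`, `genotype`,
#'   `diet` (`"control"`/`"HFD"`), `timepoint` (`"baseline"`/`"post"`),
#'   `stratum`, `mean_feret`.
#' @return data.frame with `fish_id`, `genotype`, `diet`, `stratum`,
#'   `baseline`, `post`, `delta`; attribute `emergent` holds the excluded
#'   one-timepoint rows.
#' @export
paired_changes <- function(observations) {
  obs <- as.data.frame(observations)
  need <- c("fish_id", "genotype", "diet", "timepoint", "stratum",
            "mean_feret")
  if (!all(need %in% names(obs))) {
    stop("missing columns: ", paste(setdiff(need, names(obs)),
                                    collapse = ", "))
  }
  if (!all(obs$timepoint %in% c("baseline", "post"))) {
    stop("timepoint must be 'baseline' or 'post'")
  }
  tp <- table(unique(obs[c("fish_id", "timepoint")])$fish_id)
  if (any(tp < 2L)) {
    stop("fish missing a timepoint: ",
         paste(names(tp)[tp < 2L], collapse = ", "))
  }
  base <- obs[obs$timepoint == "baseline",
              c("fish_id", "genotype", "diet", "stratum", "mean_feret")]
  post <- obs[obs$timepoint == "post", c("fish_id", "stratum", "mean_feret")]
  names(base)[names(base) == "mean_feret"] <- "baseline"
  names(post)[names(post) == "mean_feret"] <- "post"
  merged <- merge(base, post, by = c("fish_id", "stratum"))
  merged$delta <- merged$post - merged$baseline
  merged <- merged[order(merged$fish_id, merged$stratum), ]
  rownames(merged) <- NULL
  all_keys <- unique(rbind(base[c("fish_id", "stratum")],
                           post[c("fish_id", "stratum")]))
  paired_key <- paste(merged$fish_id, merged$stratum)
  emergent <- all_keys[!paste(all_keys$fish_id, all_keys$stratum) %in%
                         paired_key, , drop = FALSE]
  rownames(emergent) <- NULL
  attr(merged, "emergent") <- emergent
  merged
}

#' Per-stratum diet effect for one genotype
#'
#' For each stratum with at least `min_n` fish in both diet groups, the
#' effect is `mean(delta | HFD) - mean(delta | control diet)` with a Welch
#' t-test p-value (each fish contributes one delta per stratum, so the
#' two-group comparison on per-fish changes is the observational unit).
#' BH adjustment is applied across the testable strata within the genotype.
#'
#' @param deltas Output of [paired_changes()].
#' @param genotype Genotype to analyse (`"control"` or `"mutant"`).
#' @param min_n Minimum fish per diet group per stratum (default 3).
#' @param alpha Significance threshold for the `significant` flag.
#' @return data.frame with `genotype`, `stratum`, `n_control_diet`,
#'   `n_hfd`, `diet_effect`, `p_value`, `adj_p`, `significant`, `testable`.
#' @export
stratum_diet_effect <- function(deltas, genotype, min_n = 3, alpha = 0.05) {
  d <- deltas[deltas$genotype == genotype, , drop = FALSE]
  if (!nrow(d)) stop("no observations for genotype ", genotype)
  rows <- lapply(split(d, d$stratum), function(s) {
    dc <- s$delta[s$diet == "control"]
    dh <- s$delta[s$diet == "HFD"]
    testable <- length(dc) >= min_n && length(dh) >= min_n
    p <- if (testable) welch_test(dc, dh)$p_value else NA_real_
    data.frame(genotype = genotype, stratum = s$stratum[1],
               n_control_diet = length(dc), n_hfd = length(dh),
               diet_effect = if (length(dc) && length(dh))
                 mean(dh) - mean(dc) else NA_real_,
               p_value = p, testable = testable)
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$stratum), ]
  rownames(out) <- NULL
  out$adj_p <- NA_real_
  if (any(out$testable)) {
    out$adj_p[out$testable] <- adjust_fdr(out$p_value[out$testable])
  }
  out$significant <- !is.na(out$adj_p) & out$adj_p < alpha
  out
}

#' Baseline genotype contrast per stratum
#'
#' Compares mutant versus wild-type (control-genotype) mean Feret diameter
#' at the baseline timepoint, stratum by stratum, with BH adjustment across
#' strata. Used to establish developmental (pre-diet) hypertrophy.
#'
#' @param observations As for [paired_changes()].
#' @param strata Optional vector restricting the strata tested.
#' @param min_n Minimum fish per genotype per stratum (default 3).
#' @param alpha Significance threshold.
#' @return data.frame with `stratum`, `n_control`, `n_mutant`,
#'   `difference` (mutant - control, um), `p_value`, `adj_p`,
#'   `significant`, `testable`.
#' @export
baseline_genotype_contrast <- function(observations, strata = NULL,
                                       min_n = 3, alpha = 0.05) {
  obs <- as.data.frame(observations)
  base <- obs[obs$timepoint == "baseline", , drop = FALSE]
  if (!all(c("control", "mutant") %in% base$genotype)) {
    stop("both genotypes required at baseline")
  }
  if (!is.null(strata)) base <- base[base$stratum %in% strata, , drop = FALSE]
  rows <- lapply(split(base, base$stratum), function(s) {
    fc <- s$mean_feret[s$genotype == "control"]
    fm <- s$mean_feret[s$genotype == "mutant"]
    testable <- length(fc) >= min_n && length(fm) >= min_n
    data.frame(stratum = s$stratum[1],
               n_control = length(fc), n_mutant = length(fm),
               difference = if (length(fc) && length(fm))
                 mean(fm) - mean(fc) else NA_real_,
               p_value = if (testable) welch_test(fc, fm)$p_value
               else NA_real_,
               testable = testable)
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$stratum), ]
  rownames(out) <- NULL
  out$adj_p <- NA_real_
  if (any(out$testable)) {
    out$adj_p[out$testable] <- adjust_fdr(out$p_value[out$testable])
  }
  out$significant <- !is.na(out$adj_p) & out$adj_p < alpha
  out
}

#' Overall diet contrast and reduction in hypertrophic capacity
#'
#' Averages per-stratum diet effects (unweighted) within each genotype and
#' expresses the mutant shortfall as a percentage of the wild-type
#' response: `reduction = 100 * (effect_wt - effect_mut) / effect_wt`,
#' rounded to the nearest integer. Scalar inputs (already-averaged effects)
#' are accepted.
#'
#' @param wildtype_effects Per-stratum diet effects (um) of the wild-type
#'   (control-genotype) group, or a single overall mean.
#' @param mutant_effects Likewise for the mutant group.
#' @return list with `effect_wildtype`, `effect_mutant` (um) and
#'   `reduction_pct` (integer %). If the wild-type effect is ~0 the
#'   reduction is `NA` with a warning.
#' @export
overall_diet_contrast <- function(wildtype_effects, mutant_effects) {
  ew <- mean(wildtype_effects)
  em <- mean(mutant_effects)
  if (abs(ew) < 1e-12) {
    warning("wild-type diet effect is ~0; reduction undefined")
    red <- NA_real_
  } else {
    red <- round(100 * (ew - em) / ew)
  }
  list(effect_wildtype = ew, effect_mutant = em, reduction_pct = red)
}
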