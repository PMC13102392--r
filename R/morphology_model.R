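# The morphology value: residual deviation of a fish's mean lipid-droplet
# Feret diameter from a penalized-spline smoother of diameter on log total
# depot area, fitted to control fish. Positive values = hypertrophic (fewer,
# larger droplets than expected for the depot size); negative = hyperplastic.

#' Fit the diameter-vs-depot-size smoother
#'
#' Fits `mean_feret ~ s(log(sat_area))` with a penalized thin-plate
#' regression spline (mgcv), smoothing parameter chosen by generalized
#' cross-validation. Natural logarithms are used throughout, consistent with
#' back-transforming mixed-model coefficients as `(exp(beta) - 1) * 100`.
#'
#' @param fish data.frame with columns `sat_area` (total SAT lipid area,
#'   um^2, > 0) and `mean_feret` (mean droplet Feret diameter, um, > 0).
#' @param basis_dim Spline basis dimension `k` (default 10). Reduced
#'   automatically when fewer fish than basis functions are available.
#' @param min_fish Minimum number of fish required (default 8).
#' @return Object of class `morphology_fit`: the fitted smoother plus
#'   `r_squared`, `n_fit`, `basis_dim`, `smoothing_parameter` and the fitted
#'   range of `log(sat_area)`.
#' @export
fit_morphology_gam <- function(fish, basis_dim = 10, min_fish = 8) {
  fish <- as.data.frame(fish)
  if (!all(c("sat_area", "mean_feret") %in% names(fish))) {
    stop("`fish` needs columns sat_area and mean_feret")
  }
  ok <- is.finite(fish$sat_area) & fish$sat_area > 0 &
    is.finite(fish$mean_feret) & fish$mean_feret > 0
  fish <- fish[ok, , drop = FALSE]
  if (nrow(fish) < min_fish) {
    stop("too few fish for the smoother (need >= ", min_fish, ")")
  }
  la <- log(fish$sat_area)
  if (diff(range(la)) < sqrt(.Machine$double.eps)) {
    stop("degenerate fit: sat_area is constant")
  }
  k <- min(basis_dim, nrow(fish) - 1L)
  dat <- data.frame(log_area = la, feret = fish$mean_feret)
  g <- mgcv::gam(feret ~ s(log_area, bs = "tp", k = k), data = dat,
                 method = "GCV.Cp")
  ssr <- sum(stats::residuals(g)^2)
  sst <- sum((dat$feret - mean(dat$feret))^2)
  structure(list(gam = g,
                 r_squared = 1 - ssr / sst,
                 n_fit = nrow(fish),
                 basis_dim = k,
                 smoothing_parameter = unname(g$sp),
                 log_area_range = range(la)),
            class = "morphology_fit")
}

#' @export
print.morphology_fit <- function(x, ...) {
  cat(sprintf(
    "<morphology_fit> n = %d, k = %d, R^2 = %.3f, sp = %.3g\n",
    x$n_fit, x$basis_dim, x$r_squared, x$smoothing_parameter[1]))
  invisible(x)
}

#' Predict mean Feret diameter at given depot areas
#'
#' @param object A `morphology_fit`.
#' @param sat_area Vector of total SAT areas (um^2, > 0).
#' @param ... Unused.
#' @return Predicted mean Feret diameters (um).
#' @export
predict.morphology_fit <- function(object, sat_area, ...) {
  if (any(sat_area <= 0)) stop("sat_area must be positive")
  as.numeric(mgcv::predict.gam(object$gam,
                               newdata = data.frame(log_area = log(sat_area))))
}

#' Morphology value of individual fish
#'
#' `value = mean_feret - predicted(mean_feret | sat_area)`. Fish whose
#' `log(sat_area)` lies outside the fitted range are still scored (linear
#' spline extrapolation) but flagged `extrapolated`.
#'
#' @param fit A [fit_morphology_gam()] result.
#' @param fish data.frame with columns `fish_id`, `sat_area`, `mean_feret`.
#' @param tol Absolute deviation (um) below which the direction is reported
#'   as `"neutral"` rather than forced to a sign.
#' @return data.frame with columns `fish_id`, `predicted`, `value`,
#'   `direction` (`hypertrophic`/`hyperplastic`/`neutral`), `extrapolated`.
#' @export
morphology_value <- function(fit, fish, tol = 1e-8) {
  stopifnot(inherits(fit, "morphology_fit"))
  pred <- predict(fit, fish$sat_area)
  value <- fish$mean_feret - pred
  la <- log(fish$sat_area)
  data.frame(
    fish_id = fish$fish_id,
    predicted = pred,
    value = value,
    direction = ifelse(abs(value) <= tol, "neutral",
                       ifelse(value > 0, "hypertrophic", "hyperplastic")),
    extrapolated = la < fit$log_area_range[1] | la > fit$log_area_range[2]
  )
}

#' Morphology values for a control/mutant gene dataset
#'
#' The smoother is fitted to *control* fish only; control values are then
#' residuals of their own fit and mutant values are deviations from the
#' control fit. With `scope = "pooled"` one smoother is fitted to all
#' controls pooled across experiments; with `scope = "per_experiment"`
#' experiment-specific smoothers are fitted to each experiment's controls
#' (experiments with fewer controls than `min_controls_experiment` are
#' dropped with a warning).
#'
#' @param fish data.frame with columns `fish_id`, `genotype`
#'   (`"control"`/`"mutant"`), `experiment`, `sat_area`, `mean_feret`.
#' @param scope `"pooled"` or `"per_experiment"`.
#' @param basis_dim Spline basis dimension passed to [fit_morphology_gam()].
#' @param min_controls_pooled Minimum controls for a pooled fit (default 8).
#' @param min_controls_experiment Minimum controls per experiment for the
#'   stratified scope (default 5).
#' @return data.frame: input columns plus `predicted`, `value`, `direction`,
#'   `extrapolated` and `scope`. Attribute `dropped_experiments` lists
#'   experiments excluded at per-experiment scope.
#' @export
morphology_table <- function(fish, scope = c("pooled", "per_experiment"),
                             basis_dim = 10, min_controls_pooled = 8,
                             min_controls_experiment = 5) {
  scope <- match.arg(scope)
  fish <- as.data.frame(fish)
  if (!all(fish$genotype %in% c("control", "mutant"))) {
    stop("genotype must be 'control' or 'mutant'")
  }
  score <- function(sub, min_ctrl) {
    ctrl <- sub[sub$genotype == "control", , drop = FALSE]
    if (nrow(ctrl) < min_ctrl) return(NULL)
    fit <- fit_morphology_gam(ctrl, basis_dim = basis_dim,
                              min_fish = min_ctrl)
    cbind(sub, morphology_value(fit, sub)[, c("predicted", "value",
                                              "direction", "extrapolated")])
  }
  dropped <- character()
  if (scope == "pooled") {
    out <- score(fish, min_controls_pooled)
    if (is.null(out)) stop("fewer than ", min_controls_pooled,
                           " control fish for the pooled fit")
  } else {
    parts <- lapply(split(fish, fish$experiment), score,
                    min_ctrl = min_controls_experiment)
    dropped <- names(parts)[vapply(parts, is.null, logical(1))]
    if (length(dropped)) {
      warning("experiments dropped (too few controls): ",
              paste(dropped, collapse = ", "))
    }
    parts <- parts[!vapply(parts, is.null, logical(1))]
    if (!length(parts)) stop("no experiment has enough control fish")
    out <- do.call(rbind, parts)
  }
  out$scope <- scope
  rownames(out) <- NULL
  attr(out, "dropped_experiments") <- dropped
  out
}
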