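# Synthetic screen- and diet-experiment-shaped data with the statistical
# structure the analysis assumes: a saturating mean-diameter vs log-depot-
# area curve, an inverse droplet count/size relation (count is set by depot
# area divided by droplet footprint), per-experiment random intercepts,
# log-scale genotype effects (shift, slope, variance inflation), an
# anterior-to-posterior size gradient, and per-stratum diet hypertrophy
# with genotype-dependent blunting. All noise is log-normal on diameters so
# log-scale effects are exact in expectation.

#' Simulation configuration
#'
#' Defaults describe a juvenile zebrafish subcutaneous depot: standard
#' length 7-12 mm; depot area log-linear in SL spanning roughly 1e4-1e6
#' um^2; mean droplet diameter following the saturating curve
#' `D(A) = d_max * (1 - exp(-kappa * (log(A) - a0)))` with a ~65 um
#' plateau; droplet count set by `area * packing / droplet footprint`
#' (hypertrophy therefore reduces count at fixed area); droplets laid
#' anterior to posterior over a depot of length `3 * sqrt(area)` with a
#' mild posterior size deficit. Diet defaults encode a wild-type per-
#' stratum high-fat response rising posteriorly and a mutant response
#' scaled by `diet_blunting` (default 0.32, i.e. a 68% reduction), plus a
#' mutant baseline hypertrophy declining from +22.2 um anteriorly.
#'
#' @param n_experiments Experiments (batches) per gene.
#' @param n_control,n_mutant Fish per genotype per experiment.
#' @param sl_range Standard length range, mm.
#' @param area_intercept,area_slope,sigma_area Log depot area model:
#'   `log(A) ~ N(intercept + slope * SL, sigma_area^2)`.
#' @param d_max,kappa,a0 Saturating size-curve parameters (um, -, log um^2).
#' @param sigma_ld Log-scale per-droplet diameter scatter.
#' @param sigma_fish Log-scale fish-level residual SD.
#' @param sigma_batch Log-scale SD of per-experiment random intercepts.
#' @param packing Fraction of depot area occupied by droplets.
#' @param gradient Log-scale diameter deficit per posterior stratum.
#' @param stratum_width Stratum width, um.
#' @param gamma_center Centre of `log(A)` used for slope effects.
#' @param depot_aspect Depot length is `depot_aspect * sqrt(area)`.
#' @param n_strata_diet Strata simulated in the diet experiment.
#' @param diet_profile Wild-type per-stratum HFD effect (um), length
#'   `n_strata_diet`.
#' @param diet_blunting Mutant HFD effect as a fraction of wild-type.
#' @param baseline_shift_anterior,baseline_shift_slope Mutant baseline
#'   hypertrophy: `anterior - slope * (stratum - 1)` um, floored at 0.
#' @param control_growth Control-diet growth between timepoints, um.
#' @param sigma_diet Per-(fish, stratum) observation SD in the diet
#'   experiment, um.
#' @param sigma_fish_diet Fish-level random intercept SD in the diet
#'   experiment, um.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_experiments = 2, n_control = 30, n_mutant = 30,
                       sl_range = c(7, 12),
                       area_intercept = 2.76, area_slope = 0.92,
                       sigma_area = 0.30,
                       d_max = 65, kappa = 0.35, a0 = 8.0,
                       sigma_ld = 0.30, sigma_fish = 0.06,
                       sigma_batch = 0.08,
                       packing = 0.6, gradient = 0.03,
                       stratum_width = 200, gamma_center = 11.5,
                       depot_aspect = 3,
                       n_strata_diet = 15,
                       diet_profile = seq(17.7, 28.1,
                                          length.out = n_strata_diet),
                       diet_blunting = 0.32,
                       baseline_shift_anterior = 22.2,
                       baseline_shift_slope = 1.1,
                       control_growth = 5,
                       sigma_diet = 4, sigma_fish_diet = 3,
                       min_droplets = 5) {
  cfg <- as.list(environment())
  sds <- c(cfg$sigma_area, cfg$sigma_ld, cfg$sigma_fish, cfg$sigma_batch,
           cfg$sigma_diet, cfg$sigma_fish_diet)
  if (any(sds < 0)) stop("all SDs must be >= 0")
  if (cfg$d_max <= 0) stop("d_max must be > 0")
  if (cfg$diet_blunting < 0 || cfg$diet_blunting > 1) {
    stop("diet_blunting must lie in [0, 1]")
  }
  if (length(cfg$diet_profile) != cfg$n_strata_diet) {
    stop("diet_profile must have length n_strata_diet")
  }
  class(cfg) <- "sim_config"
  cfg
}

#' Expected mean droplet diameter at a given depot area
#'
#' The saturating curve `d_max * (1 - exp(-kappa * (log(A) - a0)))`,
#' floored at 5 um.
#'
#' @param config A [sim_config()].
#' @param sat_area Depot area(s), um^2.
#' @return Expected mean Feret diameter(s), um.
#' @export
size_curve <- function(config, sat_area) {
  pmax(5, config$d_max * (1 - exp(-config$kappa *
                                    (log(sat_area) - config$a0))))
}

#' Simulate one fish with its droplets
#'
#' Draws SL and depot area, places the fish on the size curve times
#' `exp(batch + genotype + fish)` log-scale effects, sets the droplet count
#' from the depot area divided by the mean droplet footprint (so larger
#' droplets mean fewer of them), and lays droplets anterior to posterior
#' with the configured gradient. Uses the current RNG stream.
#'
#' @param config A [sim_config()].
#' @param genotype `"control"` or `"mutant"`.
#' @param experiment Experiment label.
#' @param batch_effect Log-scale batch intercept shared by the experiment.
#' @param beta,gamma,var_inflation Genotype effects for this fish's gene:
#'   log-scale diameter shift, slope shift on `log(A)`, and multiplier on
#'   the fish-level SD. All 0/1 for controls.
#' @param fish_id Identifier.
#' @param gene Gene label.
#' @param noise Set `FALSE` for a deterministic fish exactly on the curve.
#' @return list with `fish` (one-row data.frame) and `droplets`
#'   (data.frame with `droplet_id`, `x_um`, `y_um`, `feret_um`,
#'   `stratum_true`).
#' @export
simulate_fish <- function(config, genotype = "control", experiment = "E1",
                          batch_effect = 0, beta = 0, gamma = 0,
                          var_inflation = 1, fish_id = "fish1",
                          gene = "control", noise = TRUE) {
  stopifnot(inherits(config, "sim_config"))
  sl <- stats::runif(1, config$sl_range[1], config$sl_range[2])
  la <- config$area_intercept + config$area_slope * sl +
    if (noise) stats::rnorm(1, 0, config$sigma_area) else 0
  area <- exp(la)
  mu <- size_curve(config, area)
  fish_dev <- if (noise) {
    stats::rnorm(1, 0, config$sigma_fish * var_inflation)
  } else 0
  log_d0 <- log(mu) + batch_effect + beta +
    gamma * (la - config$gamma_center) + fish_dev
  d0 <- exp(log_d0)
  count <- max(config$min_droplets,
               round(area * config$packing / (pi * (d0 / 2)^2)))
  depot_len <- config$depot_aspect * sqrt(area)
  x <- if (noise) sort(stats::runif(count, 0, depot_len)) else
    seq(0, depot_len, length.out = count)
  # strata anchored at the anterior-most droplet, matching assign_strata()
  stratum <- floor((x - min(x)) / config$stratum_width) + 1L
  ld_dev <- if (noise) {
    stats::rnorm(count, 0, config$sigma_ld) - config$sigma_ld^2 / 2
  } else 0
  feret <- d0 * exp(ld_dev - config$gradient * (stratum - 1L))
  droplets <- data.frame(
    droplet_id = seq_len(count),
    x_um = x,
    y_um = stats::runif(count, 0, 400),
    feret_um = feret,
    stratum_true = as.integer(stratum)
  )
  fish <- data.frame(
    fish_id = fish_id, gene = gene, genotype = genotype,
    experiment = experiment, standard_length = sl,
    sat_area = area,
    total_lipid_area = sum(pi * (feret / 2)^2),
    mean_feret = mean(feret), n_droplets = count
  )
  list(fish = fish, droplets = droplets)
}

#' Simulate a multi-gene screen
#'
#' For each gene, `n_experiments` batches of control and mutant fish are
#' generated with a shared per-(gene, experiment) random intercept.
#' Identical seeds give byte-identical output.
#'
#' @param config A [sim_config()].
#' @param gene_effects data.frame with columns `gene`, `beta` (log-scale
#'   shift), `gamma` (slope shift) and `var_inflation`; one row per gene.
#'   `NULL` gives a single null gene.
#' @param seed Integer seed.
#' @param droplets Keep per-droplet tables (default FALSE; fish-level
#'   summaries are what the screen statistics consume).
#' @return list with `fish` (data.frame over all genes),
#'   `ground_truth` (the effect table with batch intercepts), and
#'   optionally `droplets`.
#' @export
simulate_screen <- function(config = sim_config(), gene_effects = NULL,
                            seed = 1, droplets = FALSE) {
  stopifnot(inherits(config, "sim_config"))
  if (is.null(gene_effects)) {
    gene_effects <- data.frame(gene = "gene1", beta = 0, gamma = 0,
                               var_inflation = 1)
  }
  set.seed(seed)
  fish_all <- list()
  drop_all <- list()
  batch_tab <- list()
  for (gi in seq_len(nrow(gene_effects))) {
    ge <- gene_effects[gi, ]
    for (e in seq_len(config$n_experiments)) {
      b <- stats::rnorm(1, 0, config$sigma_batch)
      batch_tab[[length(batch_tab) + 1L]] <-
        data.frame(gene = ge$gene, experiment = paste0("E", e),
                   batch_effect = b)
      for (g in c("control", "mutant")) {
        # n_control / n_mutant may be vectors of length n_experiments
        # (e.g. to study batch-confounded allocation)
        nn <- if (g == "control") config$n_control else config$n_mutant
        n <- if (length(nn) > 1L) nn[e] else nn
        for (i in seq_len(n)) {
          id <- sprintf("%s_E%d_%s%03d", ge$gene, e, substr(g, 1, 1), i)
          sim <- simulate_fish(
            config, genotype = g, experiment = paste0("E", e),
            batch_effect = b,
            beta = if (g == "mutant") ge$beta else 0,
            gamma = if (g == "mutant") ge$gamma else 0,
            var_inflation = if (g == "mutant") ge$var_inflation else 1,
            fish_id = id, gene = ge$gene)
          fish_all[[length(fish_all) + 1L]] <- sim$fish
          if (droplets) {
            d <- sim$droplets
            d$fish_id <- id
            drop_all[[length(drop_all) + 1L]] <- d
          }
        }
      }
    }
  }
  out <- list(fish = do.call(rbind, fish_all),
              ground_truth = list(gene_effects = gene_effects,
                                  batch_effects = do.call(rbind, batch_tab),
                                  seed = seed))
  if (droplets) out$droplets <- do.call(rbind, drop_all)
  out
}

#' Simulate a paired baseline/post-diet experiment
#'
#' Generates per-(fish, stratum) mean Feret observations at baseline and
#' after the dietary period for wild-type (`genotype = "control"`) and
#' mutant fish on control diet or HFD. Wild-type HFD effects follow
#' `config$diet_profile`; mutant effects are the profile scaled by
#' `config$diet_blunting`; the mutant baseline carries the configured
#' anterior-graded hypertrophy. Both diet groups share the control-diet
#' growth increment, and each fish has a random intercept so the paired
#' design is informative.
#'
#' @param config A [sim_config()].
#' @param n_per_group Fish per (genotype, diet) cell (default 8).
#' @param seed Integer seed.
#' @return list with `observations` (long data.frame for
#'   [paired_changes()]) and `ground_truth` (per-stratum true effects and
#'   the true reduction percentage).
#' @export
simulate_diet_experiment <- function(config = sim_config(),
                                     n_per_group = 8, seed = 1) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(seed)
  ns <- config$n_strata_diet
  strata <- seq_len(ns)
  # baseline wild-type stratum profile: anterior large, posterior still
  # growing toward the plateau
  base_wt <- config$d_max * 0.75 - 1.5 * (strata - 1)
  shift_mut <- pmax(0, config$baseline_shift_anterior -
                      config$baseline_shift_slope * (strata - 1))
  rows <- list()
  for (g in c("control", "mutant")) {
    for (diet in c("control", "HFD")) {
      for (i in seq_len(n_per_group)) {
        id <- sprintf("%s_%s_%02d", g, diet, i)
        fish_int <- stats::rnorm(1, 0, config$sigma_fish_diet)
        mu_base <- base_wt + if (g == "mutant") shift_mut else 0
        diet_eff <- if (diet == "HFD") {
          config$diet_profile *
            if (g == "mutant") config$diet_blunting else 1
        } else 0
        mu_post <- mu_base + config$control_growth + diet_eff
        rows[[length(rows) + 1L]] <- data.frame(
          fish_id = id, genotype = g, diet = diet,
          timepoint = rep(c("baseline", "post"), each = ns),
          stratum = rep(strata, 2),
          mean_feret = c(mu_base + fish_int +
                           stats::rnorm(ns, 0, config$sigma_diet),
                         mu_post + fish_int +
                           stats::rnorm(ns, 0, config$sigma_diet))
        )
      }
    }
  }
  truth <- data.frame(
    stratum = strata,
    effect_wildtype = config$diet_profile,
    effect_mutant = config$diet_profile * config$diet_blunting,
    baseline_shift_mutant = shift_mut
  )
  list(observations = do.call(rbind, rows),
       ground_truth = list(per_stratum = truth,
                           reduction_pct = round(100 *
                                                   (1 - config$diet_blunting)),
                           seed = seed))
}

#' Render a fish's droplets as a label mask
#'
#' Draws each droplet as a filled disc of radius `feret / 2` at its
#' centroid on an integer canvas. Discs that would overlap an already
#' placed disc are jittered and retried; if placement keeps failing the
#' canvas is too crowded and an error is raised. The ground-truth table of
#' *placed* centroids and diameters is attached as attribute `truth`.
#'
#' @param droplets data.frame with `droplet_id`, `x_um`, `y_um`,
#'   `feret_um`.
#' @param pixel_size Micrometres per pixel (default 2).
#' @param margin_um Blank margin around the droplet extent (default 50).
#' @param max_retries Placement attempts per droplet (default 25).
#' @param jitter_um Jitter scale for retries (default 30).
#' @return A [label_image()]; `attr(, "truth")` holds the placed geometry.
#' @export
render_masks <- function(droplets, pixel_size = 2, margin_um = 50,
                         max_retries = 25, jitter_um = 30) {
  n <- nrow(droplets)
  r_um <- droplets$feret_um / 2
  if (n == 0L) {
    return(structure(label_image(matrix(0L, 16, 16), pixel_size),
                     truth = droplets))
  }
  placed_x <- numeric(0); placed_y <- numeric(0); placed_r <- numeric(0)
  out_x <- numeric(n); out_y <- numeric(n)
  for (i in seq_len(n)) {
    ok <- FALSE
    x <- droplets$x_um[i]; y <- droplets$y_um[i]
    for (try in seq_len(max_retries)) {
      clear <- !length(placed_r) ||
        all(sqrt((placed_x - x)^2 + (placed_y - y)^2) >
              placed_r + r_um[i] + pixel_size)
      if (clear) { ok <- TRUE; break }
      x <- droplets$x_um[i] + stats::rnorm(1, 0, jitter_um * try)
      y <- droplets$y_um[i] + stats::rnorm(1, 0, jitter_um * try)
    }
    if (!ok) stop("canvas too crowded: droplet ", droplets$droplet_id[i],
                  " could not be placed without overlap")
    placed_x <- c(placed_x, x); placed_y <- c(placed_y, y)
    placed_r <- c(placed_r, r_um[i])
    out_x[i] <- x; out_y[i] <- y
  }
  x0 <- min(out_x - r_um) - margin_um
  y0 <- min(out_y - r_um) - margin_um
  nc <- ceiling((max(out_x + r_um) + margin_um - x0) / pixel_size)
  nr <- ceiling((max(out_y + r_um) + margin_um - y0) / pixel_size)
  m <- matrix(0L, nr, nc)
  for (i in seq_len(n)) {
    cx <- (out_x[i] - x0) / pixel_size
    cy <- (out_y[i] - y0) / pixel_size
    r <- r_um[i] / pixel_size
    cols <- max(1, floor(cx - r)):min(nc, ceiling(cx + r + 1))
    rws <- max(1, floor(cy - r)):min(nr, ceiling(cy + r + 1))
    # pixel centres at (col - 0.5, row - 0.5)
    dc <- outer(rws - 0.5 - cy, cols - 0.5 - cx,
                function(a, b) sqrt(a^2 + b^2))
    sel <- dc <= r
    m[rws, cols][sel] <- as.integer(droplets$droplet_id[i])
  }
  truth <- data.frame(droplet_id = droplets$droplet_id,
                      x_um = out_x - x0, y_um = out_y - y0,
                      feret_um = droplets$feret_um)
  structure(label_image(m, pixel_size), truth = truth)
}
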