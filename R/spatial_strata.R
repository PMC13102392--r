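# Anterior-posterior stratification of the subcutaneous depot.
#
# Droplets are binned into fixed-width strata anchored at the most anterior
# droplet *centroid* (the measured coordinate), using half-open intervals
# [a + (i-1)w, a + i*w) along the posterior direction so boundary behaviour
# is deterministic. The raster does not record which side of the image is
# anterior, so orientation is an explicit argument.

#' Assign droplets to anterior-posterior strata
#'
#' @param droplets data.frame with columns `droplet_id` and `x_um`
#'   (anterior-posterior centroid position, micrometres).
#' @param width Stratum width in micrometres (default 200).
#' @param orientation `"anterior_min_x"` (default; anterior is at the
#'   smallest x) or `"anterior_max_x"`.
#' @return data.frame with columns `droplet_id` and `stratum`
#'   (1 = anterior-most; the anchoring droplet is always in stratum 1).
#' @export
assign_strata <- function(droplets, width = 200,
                          orientation = c("anterior_min_x", "anterior_max_x")) {
  orientation <- match.arg(orientation)
  if (nrow(droplets) == 0L) stop("no droplets to stratify")
  if (!is.numeric(width) || width <= 0) stop("`width` must be > 0")
  x <- droplets$x_um
  offset <- if (orientation == "anterior_min_x") x - min(x) else max(x) - x
  data.frame(droplet_id = droplets$droplet_id,
             stratum = as.integer(floor(offset / width)) + 1L)
}

#' Per-stratum droplet count and size summary
#'
#' Strata containing no droplets are omitted. `sd_feret` is `NA` for strata
#' with a single droplet.
#'
#' @param droplets data.frame with columns `droplet_id`, `x_um`, `feret_um`.
#' @inheritParams assign_strata
#' @return data.frame with columns `stratum`, `n_droplets`, `mean_feret`,
#'   `sd_feret`, ordered by stratum.
#' @export
stratum_summaries <- function(droplets, width = 200,
                              orientation = c("anterior_min_x",
                                              "anterior_max_x")) {
  orientation <- match.arg(orientation)
  sa <- assign_strata(droplets, width, orientation)
  f <- split(droplets$feret_um, sa$stratum)
  out <- data.frame(
    stratum = as.integer(names(f)),
    n_droplets = vapply(f, length, integer(1)),
    mean_feret = vapply(f, mean, numeric(1)),
    sd_feret = vapply(f, stats::sd, numeric(1))
  )
  rownames(out) <- NULL
  out[order(out$stratum), , drop = FALSE]
}
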