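# Per-droplet morphometrics from integer-labelled segmentation masks.
#
# Masks come from an upstream segmenter (e.g. Cellpose/SAMCell); touching
# droplets are assumed to be already separated, no watershed splitting is
# attempted here.

#' Construct a calibrated label image
#'
#' A label image is a 2-D integer raster in which 0 marks background and each
#' positive integer labels the pixels of one segmented lipid droplet, plus a
#' pixel-size calibration in micrometres per pixel edge.
#'
#' @param pixels Integer matrix; 0 = background, positive integers = droplet
#'   labels. Labels need not be consecutive.
#' @param pixel_size Micrometres per pixel edge (scalar > 0).
#' @return An object of class `label_image` with elements `pixels` and
#'   `pixel_size`.
#' @export
label_image <- function(pixels, pixel_size) {
  if (!is.matrix(pixels)) stop("`pixels` must be a matrix")
  if (any(!is.finite(pixels)) || any(pixels < 0) ||
      any(pixels != round(pixels))) {
    stop("label values must be non-negative integers")
  }
  if (!is.numeric(pixel_size) || length(pixel_size) != 1L || pixel_size <= 0) {
    stop("`pixel_size` must be a single positive number (um per pixel)")
  }
  storage.mode(pixels) <- "integer"
  structure(list(pixels = pixels, pixel_size = as.numeric(pixel_size)),
            class = "label_image")
}

#' @export
print.label_image <- function(x, ...) {
  labs <- setdiff(unique(as.vector(x$pixels)), 0L)
  cat(sprintf("<label_image> %d x %d px, %.3g um/px, %d droplet label(s)\n",
              nrow(x$pixels), ncol(x$pixels), x$pixel_size, length(labs)))
  invisible(x)
}

#' Read a label mask from a TIFF or PNG file
#'
#' Reads a single-channel integer raster written by a segmentation tool (or
#' by [write_label_mask()]) and attaches the pixel-size calibration. TIFFs
#' are read at their native integer values; PNG intensities are rescaled to
#' the file's bit depth and rounded.
#'
#' @param path Path to a single-channel TIFF or PNG file.
#' @param pixel_size Micrometres per pixel edge (> 0).
#' @return A [label_image()].
#' @export
read_label_mask <- function(path, pixel_size) {
  if (!file.exists(path)) stop("cannot read mask file: ", path)
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("tif", "tiff")) {
    img <- tiff::readTIFF(path, as.is = TRUE)
  } else if (ext == "png") {
    img <- png::readPNG(path, info = TRUE)
    depth <- attr(img, "info")$bit.depth
    if (is.null(depth)) depth <- 8L
    img <- round(img * (2^depth - 1))
  } else {
    stop("unsupported mask format: .", ext, " (expected TIFF or PNG)")
  }
  if (length(dim(img)) == 3L) {
    if (dim(img)[3] != 1L) stop("mask must be single-channel")
    img <- img[, , 1L]
  }
  label_image(img, pixel_size)
}

#' Write a label mask to a 16-bit TIFF file
#'
#' Inverse of [read_label_mask()] for label values up to 65535; the written
#' file round-trips to an identical pixel array.
#'
#' @param mask A [label_image()].
#' @param path Output path ending in `.tif` or `.tiff`.
#' @return `path`, invisibly.
#' @export
write_label_mask <- function(mask, path) {
  stopifnot(inherits(mask, "label_image"))
  if (max(mask$pixels) > 65535L) stop("labels exceed 16-bit range")
  tiff::writeTIFF(mask$pixels / 65535, path, bits.per.sample = 16L)
  invisible(path)
}

#' Maximum caliper (Feret) diameter of a pixel set
#'
#' The Feret diameter is computed on the convex hull of the pixel *corner*
#' points (each pixel contributes its four corners), so a single pixel has
#' diameter `sqrt(2) * pixel_size`. This matches the convention of mainstream
#' image-analysis tools and gives degenerate one-pixel objects a nonzero
#' caliper width.
#'
#' @param pixel_coords Two-column matrix (or data.frame) of integer pixel
#'   positions, columns `(row, col)`.
#' @param pixel_size Micrometres per pixel edge.
#' @return Feret diameter in micrometres.
#' @export
feret_diameter <- function(pixel_coords, pixel_size = 1) {
  pixel_coords <- as.matrix(pixel_coords)
  if (nrow(pixel_coords) == 0L) stop("empty pixel set")
  corners <- .pixel_corners(pixel_coords)
  hull <- grDevices::chull(corners)
  h <- corners[hull, , drop = FALSE]
  max(stats::dist(h)) * pixel_size
}

# All distinct corner points of a set of unit pixels; pixel (r, c) occupies
# [c-1, c] x [r-1, r] in (x, y).
.pixel_corners <- function(rc) {
  x <- c(rc[, 2] - 1, rc[, 2], rc[, 2] - 1, rc[, 2])
  y <- c(rc[, 1] - 1, rc[, 1] - 1, rc[, 1], rc[, 1])
  pts <- cbind(x = x, y = y)
  pts[!duplicated(pts), , drop = FALSE]
}

#' Measure all droplets in a label image
#'
#' One row per distinct positive label: centroid (mean of pixel centres,
#' scaled), area (pixel count times `pixel_size^2`), Feret diameter
#' ([feret_diameter()], pixel-corner convention) and perimeter (count of
#' exposed pixel edges times `pixel_size`). Droplets smaller than
#' `min_area_px` pixels are discarded; the number removed is attached as
#' attribute `n_filtered`.
#'
#' @param mask A [label_image()].
#' @param min_area_px Minimum droplet size in pixels (default 4). Imaging at
#'   1-2 um/px cannot resolve the small secondary droplets of multilocular
#'   adipocytes, so a small-object filter is applied; the cutoff is
#'   configurable.
#' @return data.frame with columns `droplet_id`, `x_um`, `y_um`, `area_um2`,
#'   `feret_um`, `perimeter_um`, ordered by label.
#' @export
measure_droplets <- function(mask, min_area_px = 4) {
  stopifnot(inherits(mask, "label_image"))
  m <- mask$pixels
  ps <- mask$pixel_size
  idx <- which(m > 0L, arr.ind = TRUE)
  empty <- data.frame(droplet_id = integer(), x_um = numeric(),
                      y_um = numeric(), area_um2 = numeric(),
                      feret_um = numeric(), perimeter_um = numeric())
  if (nrow(idx) == 0L) {
    attr(empty, "n_filtered") <- 0L
    return(empty)
  }
  labs <- m[idx]

  # exposed-edge perimeter, vectorised over the whole raster
  nr <- nrow(m); nc <- ncol(m)
  pad <- matrix(0L, nr + 2L, nc + 2L)
  pad[2:(nr + 1), 2:(nc + 1)] <- m
  exposed <- integer(max(labs))
  for (sh in list(c(1L, 0L), c(-1L, 0L), c(0L, 1L), c(0L, -1L))) {
    nb <- pad[2:(nr + 1) + sh[1], 2:(nc + 1) + sh[2], drop = FALSE]
    d <- m > 0L & nb != m
    exposed <- exposed + tabulate(m[d], nbins = max(labs))
  }

  by_label <- split(seq_len(nrow(idx)), labs)
  rows <- lapply(by_label, function(i) {
    rc <- idx[i, , drop = FALSE]
    lab <- labs[i[1]]
    data.frame(
      droplet_id = as.integer(lab),
      x_um = mean(rc[, 2] - 0.5) * ps,
      y_um = mean(rc[, 1] - 0.5) * ps,
      area_um2 = nrow(rc) * ps^2,
      feret_um = feret_diameter(rc, ps),
      perimeter_um = exposed[lab] * ps
    )
  })
  out <- do.call(rbind, rows)
  keep <- out$area_um2 / ps^2 >= min_area_px
  res <- out[keep, , drop = FALSE]
  rownames(res) <- NULL
  attr(res, "n_filtered") <- sum(!keep)
  res
}
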