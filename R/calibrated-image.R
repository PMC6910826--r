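#' Calibrated fluorescence image
#'
#' The carrier object for all image operations in zdiscquant: a 2-D
#' intensity raster together with its physical calibration. Pixels are
#' stored as a numeric matrix with rows indexing y (top to bottom) and
#' columns indexing x (left to right). All pixel coordinates reported by
#' the package are 0-based, with bounding boxes half-open, and the centre
#' of pixel `(row i, col j)` sits at `(x = j - 1, y = i - 1)` in pixel
#' units.
#'
#' @param pixels Numeric matrix of non-negative intensities (rows = y,
#'   cols = x).
#' @param pixel_size_um Physical pixel size in micrometres per pixel
#'   (square pixels).
#' @param channel Label for the channel, e.g. `"zdisc"` or `"actin"`.
#' @param bit_depth Nominal acquisition bit depth. Histogramming for
#'   auto-thresholding always uses 256 bins; for `bit_depth = 8` the bins
#'   are the integer intensities 0..255 themselves.
#'
#' @return An object of class `calibrated_image`.
#' @export
calibrated_image <- function(pixels, pixel_size_um, channel = "unknown",
                             bit_depth = 16L) {
  if (!is.matrix(pixels) || !is.numeric(pixels) || length(pixels) == 0L)
    stop("`pixels` must be a non-empty numeric matrix")
  if (anyNA(pixels))
    stop("`pixels` must not contain NA")
  if (min(pixels) < 0)
    stop("intensities must be non-negative")
  if (!is.numeric(pixel_size_um) || length(pixel_size_um) != 1L ||
      !is.finite(pixel_size_um) || pixel_size_um <= 0)
    stop("`pixel_size_um` must be a single positive number")
  structure(
    list(pixels = pixels, pixel_size_um = as.numeric(pixel_size_um),
         channel = as.character(channel), bit_depth = as.integer(bit_depth)),
    class = "calibrated_image")
}

#' @export
print.calibrated_image <- function(x, ...) {
  d <- dim(x$pixels)
  cat(sprintf(
    "calibrated_image: %d x %d px (%.2f x %.2f um), channel '%s', %d-bit\n",
    d[2], d[1], d[2] * x$pixel_size_um, d[1] * x$pixel_size_um,
    x$channel, x$bit_depth))
  cat(sprintf("  intensity range [%.3g, %.3g]\n",
              min(x$pixels), max(x$pixels)))
  invisible(x)
}

#' @export
dim.calibrated_image <- function(x) dim(x$pixels)

is_calibrated_image <- function(x) inherits(x, "calibrated_image")

assert_image <- function(x, arg = deparse(substitute(x))) {
  if (!is_calibrated_image(x))
    stop(sprintf("`%s` must be a calibrated_image", arg))
  invisible(x)
}

#' Binary mask over a calibrated image
#'
#' A boolean raster, same shape as its source image, recording which
#' pixels exceeded a threshold. The mask convention is bright objects on
#' a dark background: a pixel is in the mask iff its source intensity is
#' strictly greater than `threshold_value`.
#'
#' @param pixels Logical matrix.
#' @param threshold_value The intensity cut that produced the mask.
#' @param pixel_size_um Micrometres per pixel, inherited from the source.
#'
#' @return An object of class `binary_mask`.
#' @export
binary_mask <- function(pixels, threshold_value, pixel_size_um) {
  if (!is.matrix(pixels) || !is.logical(pixels))
    stop("`pixels` must be a logical matrix")
  structure(
    list(pixels = pixels, threshold_value = as.numeric(threshold_value),
         polarity = "bright-objects",
         pixel_size_um = as.numeric(pixel_size_um)),
    class = "binary_mask")
}

#' @export
print.binary_mask <- function(x, ...) {
  cat(sprintf(
    "binary_mask: %d x %d px, threshold %.4g (%s), %d foreground px\n",
    ncol(x$pixels), nrow(x$pixels), x$threshold_value, x$polarity,
    sum(x$pixels)))
  invisible(x)
}

# Bilinear interpolation of `pixels` at 0-based pixel-centre coordinates
# (x, y). Points outside the raster return NA. Shared by the rotational
# averager and the diameter profiler.
bilinear_sample <- function(pixels, x, y) {
  nr <- nrow(pixels); nc <- ncol(pixels)
  x0 <- floor(x); y0 <- floor(y)
  fx <- x - x0; fy <- y - y0
  # clamp the four corner indices; validity decided separately
  ok <- x >= 0 & x <= nc - 1 & y >= 0 & y <= nr - 1
  x0c <- pmin(pmax(x0, 0), nc - 1); x1c <- pmin(x0c + 1, nc - 1)
  y0c <- pmin(pmax(y0, 0), nr - 1); y1c <- pmin(y0c + 1, nr - 1)
  idx <- function(yy, xx) yy + 1L + nr * xx    # column-major linear index
  c00 <- pixels[idx(y0c, x0c)]; c10 <- pixels[idx(y0c, x1c)]
  c01 <- pixels[idx(y1c, x0c)]; c11 <- pixels[idx(y1c, x1c)]
  w00 <- (1 - fx) * (1 - fy); w10 <- fx * (1 - fy)
  w01 <- (1 - fx) * fy;       w11 <- fx * fy
  if (anyNA(c(c00, c10, c01, c11))) {
    # NA corners (e.g. outside a selection mask) are dropped and the
    # remaining weights renormalised; all-NA support gives NA
    z <- function(w, c) { w[is.na(c)] <- 0; w }
    w00 <- z(w00, c00); w10 <- z(w10, c10)
    w01 <- z(w01, c01); w11 <- z(w11, c11)
    wt <- w00 + w10 + w01 + w11
    r <- function(c) { c[is.na(c)] <- 0; c }
    v <- (w00 * r(c00) + w10 * r(c10) + w01 * r(c01) + w11 * r(c11)) / wt
    v[wt == 0] <- NA_real_
  } else {
    v <- w00 * c00 + w10 * c10 + w01 * c01 + w11 * c11
  }
  v[!ok] <- NA_real_
  v
}

# Restore the caller's RNG state on exit and seed a local stream.
# All stochastic generators in the package route their randomness
# through this, so identical seeds give identical outputs and callers'
# RNG streams are never disturbed.
with_local_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
      get(".Random.seed", globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(as.integer(seed))
  }
  force(code)
}
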