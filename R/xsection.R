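#' Circular selection around one Z-disc
#'
#' @param center_px Length-2 (x, y), 0-based pixel coordinates.
#' @param radius_px Radius in pixels (> 0).
#' @return An object of class `disc_selection`.
#' @export
disc_selection <- function(center_px, radius_px) {
  if (length(center_px) != 2L || !all(is.finite(center_px)))
    stop("`center_px` must be finite (x, y)")
  if (!is.finite(radius_px) || radius_px <= 0)
    stop("`radius_px` must be > 0")
  structure(list(center_px = as.numeric(center_px),
                 radius_px = as.numeric(radius_px)),
            class = "disc_selection")
}

assert_selection_inside <- function(image, sel) {
  d <- dim(image$pixels)
  c_ <- sel$center_px; r <- sel$radius_px
  if (c_[1] - r < 0 || c_[2] - r < 0 ||
      c_[1] + r > d[2] - 1 || c_[2] + r > d[1] - 1)
    stop("selection circle (centre ", paste(round(c_, 1), collapse = ","),
         ", radius ", round(r, 1), " px) lies outside the image")
  invisible(TRUE)
}

#' Rotational-average denoising of a Z-disc cross section
#'
#' Exploits the rotational symmetry of an end-on Z-disc to suppress
#' noise: the image is rotated about the selection centre in `step_deg`
#' increments `n_rotations` times (defaults 2 degrees x 180, a full
#' turn, the last copy being the identity) and the copies are averaged
#' pixelwise. Rotation uses bilinear interpolation; pixels outside the
#' selection circle are masked out (NA) rather than zero-filled, so the
#' rim is not darkened. For a perfectly symmetric disc the operation is
#' an identity up to interpolation error; for uncorrelated noise it
#' attenuates fluctuations at every radius away from the centre.
#'
#' @param image A [calibrated_image()].
#' @param sel A [disc_selection()] lying fully inside the image.
#' @param step_deg Rotation step in degrees.
#' @param n_rotations Number of rotated copies averaged. A warning is
#'   issued when `step_deg * n_rotations != 360`.
#' @return A [calibrated_image()] of the same geometry with pixels
#'   outside the circle set to NA; attributes `n_rotations` and
#'   `step_deg` record the parameters used.
#' @export
rotational_average <- function(image, sel, step_deg = 2,
                               n_rotations = 180) {
  assert_image(image)
  stopifnot(inherits(sel, "disc_selection"))
  assert_selection_inside(image, sel)
  if (!isTRUE(all.equal(step_deg * n_rotations, 360)))
    warning("step_deg * n_rotations != 360: the rotation set does not ",
            "close a full turn")
  d <- dim(image$pixels)
  cx <- sel$center_px[1]; cy <- sel$center_px[2]
  X <- matrix(seq_len(d[2]) - 1, d[1], d[2], byrow = TRUE) - cx
  Y <- matrix(seq_len(d[1]) - 1, d[1], d[2]) - cy
  # half-pixel rim included so every point of the selection circle has
  # full interpolation support in the output
  inside <- X^2 + Y^2 <= (sel$radius_px + 0.5)^2
  xi <- X[inside]; yi <- Y[inside]
  acc <- numeric(length(xi))
  nok <- integer(length(xi))
  for (k in seq_len(n_rotations)) {
    th <- -k * step_deg * pi / 180     # sample source at backward-rotated pos
    xs <- cos(th) * xi - sin(th) * yi + cx
    ys <- sin(th) * xi + cos(th) * yi + cy
    v <- bilinear_sample(image$pixels, xs, ys)
    bad <- is.na(v)                    # rim pixels whose orbit exits the image
    v[bad] <- 0
    acc <- acc + v
    nok <- nok + !bad
  }
  out <- matrix(NA_real_, d[1], d[2])
  out[inside] <- ifelse(nok > 0, acc / nok, NA_real_)
  res <- calibrated_image_allow_na(out, image$pixel_size_um,
                                   channel = image$channel,
                                   bit_depth = image$bit_depth)
  attr(res, "n_rotations") <- n_rotations
  attr(res, "step_deg") <- step_deg
  res
}

# calibrated_image() forbids NA; the rotational averager legitimately
# masks out-of-circle pixels with NA, so it builds its result here.
calibrated_image_allow_na <- function(pixels, pixel_size_um, channel,
                                      bit_depth) {
  structure(list(pixels = pixels, pixel_size_um = pixel_size_um,
                 channel = channel, bit_depth = as.integer(bit_depth)),
            class = "calibrated_image")
}

#' Disc-orientation coverage filter
#'
#' Cross-section discs are retained only when the Z-disc marker covers
#' (nearly) the whole actin-stained sarcomere area — the criterion used
#' to discard obliquely sectioned discs. Implemented as an overlap
#' fraction: keep iff `|zdisc AND actin| / |actin| >= min_fraction`.
#'
#' @param zdisc_mask,actin_mask [binary_mask()] objects of equal shape.
#' @param min_fraction Minimum covered fraction of the actin area
#'   (default 0.9).
#' @return Logical: `TRUE` to keep the disc. An empty actin mask gives
#'   `FALSE` with a warning.
#' @export
coverage_filter <- function(zdisc_mask, actin_mask, min_fraction = 0.9) {
  stopifnot(inherits(zdisc_mask, "binary_mask"),
            inherits(actin_mask, "binary_mask"))
  if (!identical(dim(zdisc_mask$pixels), dim(actin_mask$pixels)))
    stop("masks must have the same shape")
  na <- sum(actin_mask$pixels)
  if (na == 0L) {
    warning("empty actin mask: coverage undefined, returning FALSE")
    return(FALSE)
  }
  sum(zdisc_mask$pixels & actin_mask$pixels) / na >= min_fraction
}

#' Relative-intensity profile along a disc diameter
#'
#' Samples the image by bilinear interpolation along a diameter of the
#' selection circle at the given angle, at an odd number of evenly
#' spaced positions (so the centre is sampled), and normalises
#' intensities to a maximum of 1 — the "relative intensity at the
#' Z-disc diameter" readout used to compare isoform localisation within
#' the disc.
#'
#' @param image A [calibrated_image()] (e.g. the output of
#'   [rotational_average()]).
#' @param sel A [disc_selection()]; radius must be >= 2 px.
#' @param angle_deg Diameter angle in degrees (0 = horizontal).
#' @param n_samples Odd number of samples; default `2*ceil(radius)+1`
#'   (about one per pixel).
#' @return A data.frame of class `diameter_profile` with columns
#'   `position_um` (signed distance from the centre) and
#'   `rel_intensity` (max 1).
#' @export
diameter_profile <- function(image, sel, angle_deg = 0, n_samples = NULL) {
  assert_image(image)
  stopifnot(inherits(sel, "disc_selection"))
  if (sel$radius_px < 2)
    stop("degenerate selection: radius must be >= 2 px")
  assert_selection_inside(image, sel)
  if (is.null(n_samples)) n_samples <- 2L * ceiling(sel$radius_px) + 1L
  if (n_samples %% 2L == 0L) n_samples <- n_samples + 1L
  t <- seq(-sel$radius_px, sel$radius_px, length.out = n_samples)
  th <- angle_deg * pi / 180
  xs <- sel$center_px[1] + t * cos(th)
  ys <- sel$center_px[2] + t * sin(th)
  v <- bilinear_sample(image$pixels, xs, ys)
  if (anyNA(v)) stop("diameter transect leaves the valid image area")
  mx <- max(v)
  if (mx <= 0) stop("profile has no positive intensity to normalise to")
  out <- data.frame(position_um = t * image$pixel_size_um,
                    rel_intensity = v / mx)
  structure(out, class = c("diameter_profile", "data.frame"),
            pixel_size_um = image$pixel_size_um, angle_deg = angle_deg)
}

# Local maxima of y with topographic prominence, computed as in the
# standard definition: for each peak, walk outwards to the nearest
# higher point on each side; the peak's bases are the minima of those
# stretches and prominence = height - max(base_left, base_right).
find_peaks_prominence <- function(y) {
  n <- length(y)
  if (n < 3) return(data.frame(index = integer(), height = numeric(),
                               prominence = numeric()))
  # condense plateaus to single runs, find maxima on the condensed series
  r <- rle(y)
  run_start <- cumsum(c(1L, r$lengths[-length(r$lengths)]))
  v <- r$values
  m <- length(v)
  cand <- if (m >= 3) which(v[2:(m - 1)] > v[1:(m - 2)] &
                              v[2:(m - 1)] > v[3:m]) + 1L else integer()
  is_max <- run_start[cand] + (r$lengths[cand] - 1L) %/% 2L  # plateau middle
  prom <- vapply(is_max, function(i) {
    h <- y[i]
    left <- if (i > 1) y[seq_len(i - 1)] else numeric()
    higher_l <- which(left > h)
    base_l <- if (length(higher_l)) min(left[(max(higher_l) + 1):(i - 1)])
              else if (length(left)) min(left) else h
    right <- if (i < n) y[(i + 1):n] else numeric()
    higher_r <- which(right > h)
    base_r <- if (length(higher_r)) min(right[seq_len(min(higher_r) - 1)])
              else if (length(right)) min(right) else h
    h - max(base_l, base_r)
  }, numeric(1))
  data.frame(index = is_max, height = y[is_max], prominence = prom)
}

#' Classify a diameter profile as centre-peaked or bimodal
#'
#' Smooths the relative-intensity profile with a centred moving average,
#' finds local maxima with topographic prominence at least
#' `prominence_min`, and calls the within-disc localisation pattern:
#' `center_peaked` when a single qualifying peak lies within the central
#' fraction of the diameter (growing-isoform-like), `bimodal` when
#' exactly two qualifying peaks of opposite sign flank a central local
#' minimum (blocking-isoform-like), and `ambiguous` otherwise, with the
#' peak diagnostics attached.
#'
#' @param profile A `diameter_profile` from [diameter_profile()].
#' @param prominence_min Minimum peak prominence, in units of the
#'   normalised profile (default 0.1).
#' @param central_fraction Half-width of the "central" zone as a
#'   fraction of the radius (default 0.25).
#' @param smoothing_window Moving-average window in samples (odd;
#'   default 5).
#' @return An object of class `profile_call`: list with `call`
#'   (`"center_peaked"`, `"bimodal"` or `"ambiguous"`),
#'   `peak_positions_um`, `peak_prominences`.
#' @export
classify_profile <- function(profile, prominence_min = 0.1,
                             central_fraction = 0.25,
                             smoothing_window = 5) {
  stopifnot(inherits(profile, "diameter_profile"))
  y <- profile$rel_intensity
  pos <- profile$position_um
  w <- max(1L, as.integer(smoothing_window))
  if (w %% 2L == 0L) w <- w + 1L
  if (w > 1L && length(y) >= w) {
    sm <- stats::filter(y, rep(1 / w, w), sides = 2)
    half <- (w - 1L) %/% 2L
    # shrink the window near the edges instead of dropping samples
    for (i in seq_len(half)) {
      sm[i] <- mean(y[1:(i + half)])
      sm[length(y) - i + 1L] <- mean(y[(length(y) - i + 1L - half):length(y)])
    }
    y <- as.numeric(sm)
  }
  pk <- find_peaks_prominence(y)
  pk <- pk[pk$prominence >= prominence_min, , drop = FALSE]
  r <- max(abs(pos))
  central <- abs(pos) <= central_fraction * r
  call <- "ambiguous"
  if (nrow(pk) == 1L && central[pk$index]) {
    call <- "center_peaked"
  } else if (nrow(pk) == 2L) {
    p1 <- pos[pk$index[1]]; p2 <- pos[pk$index[2]]
    between <- y[seq(pk$index[1], pk$index[2])]
    has_central_min <- min(between) < min(pk$height) - 1e-12
    if (sign(p1) * sign(p2) < 0 && has_central_min) call <- "bimodal"
  }
  structure(list(call = call,
                 peak_positions_um = pos[pk$index],
                 peak_prominences = pk$prominence,
                 n_peaks = nrow(pk)),
            class = "profile_call")
}

#' @export
print.profile_call <- function(x, ...) {
  cat(sprintf("profile_call: %s (%d qualifying peak%s at %s um)\n",
              x$call, x$n_peaks, if (x$n_peaks == 1) "" else "s",
              paste(signif(x$peak_positions_um, 3), collapse = ", ")))
  invisible(x)
}
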