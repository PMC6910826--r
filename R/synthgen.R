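#' Noise model parameters
#'
#' Photon (Poisson) plus read (Gaussian) noise, the standard two-term
#' decomposition for fluorescence detection. Poisson noise is applied as
#' `rpois(signal * gain) / gain` so that `poisson_gain` is the number of
#' detected photons per intensity unit; `gaussian_sd` is the SD of the
#' additive read noise in intensity units. Either term can be disabled
#' with 0, which makes noise-free images exactly reproducible for tests.
#'
#' @param poisson_gain Photons per intensity unit; 0 disables shot noise.
#' @param gaussian_sd Additive read-noise SD in intensity units; 0
#'   disables.
#' @param seed Integer seed controlling every random draw of the
#'   generator that receives these parameters.
#' @return An object of class `noise_params`.
#' @export
noise_params <- function(poisson_gain = 50, gaussian_sd = 2, seed = 1L) {
  if (poisson_gain < 0 || gaussian_sd < 0)
    stop("noise gains/SDs must be >= 0")
  structure(list(poisson_gain = poisson_gain, gaussian_sd = gaussian_sd,
                 seed = as.integer(seed)),
            class = "noise_params")
}

#' Parameters for synthetic longitudinal myofibril fields
#'
#' Describes a field of parallel myofibrils viewed side-on: each
#' myofibril is a continuous actin stripe carrying periodic bright
#' Z-disc bands. A band is a rectangle whose extent perpendicular to the
#' myofibril axis equals the disc diameter and whose extent along the
#' axis is the band thickness; bands repeat every `sarcomere_length_um`.
#' Defaults emulate an indirect-flight-muscle confocal field: a
#' 36 x 36 um field at 0.0703 um/px (512 x 512 px), ~3.4 um sarcomeres
#' and 1.4 um Z-disc diameters.
#'
#' @param field_size_um Numeric length-2, field (width, height) in um.
#' @param pixel_size_um Micrometres per pixel.
#' @param n_myofibrils Number of parallel myofibrils, evenly spaced.
#' @param sarcomere_length_um Spacing between consecutive Z-disc bands.
#' @param disc_diameter_um Band extent perpendicular to the axis
#'   (the disc diameter); a scalar, or one value per band recycled over
#'   all bands in raster order.
#' @param band_thickness_um Band extent along the myofibril axis.
#' @param myofibril_axis Axis angle in degrees; 0 = horizontal
#'   myofibrils. The generator renders 0 or 90 only, so that the
#'   ground-truth band geometry is exact to the pixel.
#' @param psf_sigma_um Gaussian blur sigma in um; 0 disables blur.
#' @param background_level,signal_level Intensities (arbitrary units) of
#'   the background and of the band/stripe signal.
#' @param noise A [noise_params()] object.
#' @return An object of class `longitudinal_params`.
#' @export
longitudinal_params <- function(field_size_um = c(36, 36),
                                pixel_size_um = 0.0703,
                                n_myofibrils = 6,
                                sarcomere_length_um = 3.4,
                                disc_diameter_um = 1.4,
                                band_thickness_um = 0.35,
                                myofibril_axis = 0,
                                psf_sigma_um = 0.0703,
                                background_level = 10,
                                signal_level = 100,
                                noise = noise_params()) {
  if (length(field_size_um) != 2L || any(field_size_um <= 0))
    stop("`field_size_um` must be two positive lengths")
  if (pixel_size_um <= 0) stop("`pixel_size_um` must be > 0")
  if (n_myofibrils < 1) stop("`n_myofibrils` must be >= 1")
  if (sarcomere_length_um <= 0) stop("`sarcomere_length_um` must be > 0")
  if (any(disc_diameter_um <= 0)) stop("`disc_diameter_um` must be > 0")
  if (band_thickness_um <= 0) stop("`band_thickness_um` must be > 0")
  if (psf_sigma_um < 0) stop("`psf_sigma_um` must be >= 0")
  if (!myofibril_axis %in% c(0, 90))
    stop("`myofibril_axis`: only 0 or 90 degrees are rendered ",
         "(exact pixel ground truth); got ", myofibril_axis)
  if (max(disc_diameter_um) > min(field_size_um))
    stop("`disc_diameter_um` exceeds the field size")
  if (!inherits(noise, "noise_params")) stop("`noise` must be noise_params()")
  structure(as.list(environment()), class = "longitudinal_params")
}

#' Parameters for synthetic aggregate blobs
#'
#' Aggregates are rendered as bright filled ellipses (axis ratio 4:3,
#' random orientation) substantially larger than any Z-disc band,
#' emulating the large Zasp-protein accumulations seen in myopathy-like
#' overexpression conditions.
#'
#' @param n_aggregates Number of aggregates to place (>= 0).
#' @param aggregate_diameter_um Major-axis diameter(s) in um, recycled.
#' @param intensity_factor Aggregate intensity as a multiple of the
#'   field's `signal_level`.
#' @return An object of class `aggregate_params`.
#' @export
aggregate_params <- function(n_aggregates = 0,
                             aggregate_diameter_um = 3,
                             intensity_factor = 1.5) {
  if (n_aggregates < 0) stop("`n_aggregates` must be >= 0")
  if (any(aggregate_diameter_um <= 0))
    stop("`aggregate_diameter_um` must be > 0")
  structure(list(n_aggregates = as.integer(n_aggregates),
                 aggregate_diameter_um = aggregate_diameter_um,
                 intensity_factor = intensity_factor),
            class = "aggregate_params")
}

# Apply Poisson + Gaussian noise under the stream's current state.
apply_noise <- function(pixels, noise) {
  if (noise$poisson_gain > 0)
    pixels[] <- stats::rpois(length(pixels), pixels * noise$poisson_gain) /
      noise$poisson_gain
  if (noise$gaussian_sd > 0)
    pixels[] <- pixels + stats::rnorm(length(pixels), 0, noise$gaussian_sd)
  pixels[pixels < 0] <- 0
  pixels
}

blur_if <- function(pixels, sigma_px) {
  if (sigma_px <= 0) return(pixels)
  as.matrix(EBImage::gblur(pixels, sigma = sigma_px))
}

#' Generate a synthetic longitudinal myofibril field with ground truth
#'
#' Renders the Z-disc channel (periodic bright bands, optionally plus
#' aggregate blobs) and a continuous actin counterstain channel, blurs
#' with a Gaussian PSF, adds photon and read noise, and returns the pair
#' of calibrated images together with a ground-truth table listing every
#' band and aggregate: its true diameter, bounding box (0-based,
#' half-open, pixels) and centre. Identical parameters and seed give
#' bit-identical rasters.
#'
#' @param params A [longitudinal_params()] object.
#' @param aggregates An [aggregate_params()] object (default: none).
#' @return A list with elements `zdisc` and `actin` (both
#'   [calibrated_image()]) and `truth` (data.frame with columns
#'   `object_kind`, `id`, `true_diameter_um`, `diameter_px`, `bbox_x0`,
#'   `bbox_y0`, `bbox_w`, `bbox_h`, `centre_x_px`, `centre_y_px`).
#' @export
make_longitudinal_image <- function(params, aggregates = aggregate_params()) {
  stopifnot(inherits(params, "longitudinal_params"),
            inherits(aggregates, "aggregate_params"))
  px <- params$pixel_size_um
  # render in axis-aligned frame (myofibrils horizontal), transpose at the
  # end for axis = 90
  fw <- if (params$myofibril_axis == 0) params$field_size_um[1] else
    params$field_size_um[2]
  fh <- if (params$myofibril_axis == 0) params$field_size_um[2] else
    params$field_size_um[1]
  nx <- max(1L, round(fw / px)); ny <- max(1L, round(fh / px))

  n_bands_per <- floor(fw / params$sarcomere_length_um)
  if (n_bands_per < 1)
    stop("field too small: `sarcomere_length_um` (", params$sarcomere_length_um,
         ") exceeds the field extent along the myofibril axis")
  fib_spacing <- fh / params$n_myofibrils
  if (max(params$disc_diameter_um) > fib_spacing)
    stop("field too small: `disc_diameter_um` (max ",
         max(params$disc_diameter_um), ") exceeds the myofibril spacing ",
         signif(fib_spacing, 3), " um implied by `n_myofibrils`")

  zd <- matrix(0, ny, nx)
  actin <- matrix(0, ny, nx)
  n_bands <- n_bands_per * params$n_myofibrils
  diam <- rep_len(params$disc_diameter_um, n_bands)
  w_px <- max(1L, round(params$band_thickness_um / px))

  truth <- vector("list", n_bands + aggregates$n_aggregates)
  k <- 0L
  for (f in seq_len(params$n_myofibrils)) {
    yc_px <- (f - 0.5) * fib_spacing / px            # fibril centre, px units
    fib_h_px <- max(1L, round(max(diam[(f - 1) * n_bands_per +
                                         seq_len(n_bands_per)]) / px))
    fy0 <- max(0L, round(yc_px - fib_h_px / 2))
    fy1 <- min(ny, fy0 + fib_h_px)
    actin[(fy0 + 1):fy1, ] <- params$signal_level
    for (b in seq_len(n_bands_per)) {
      k <- k + 1L
      h_px <- max(1L, round(diam[k] / px))
      xc_px <- (b - 0.5) * params$sarcomere_length_um / px
      x0 <- max(0L, round(xc_px - w_px / 2)); x1 <- min(nx, x0 + w_px)
      y0 <- max(0L, round(yc_px - h_px / 2)); y1 <- min(ny, y0 + h_px)
      zd[(y0 + 1):y1, (x0 + 1):x1] <- params$signal_level
      truth[[k]] <- data.frame(
        object_kind = "zdisc", id = k, true_diameter_um = diam[k],
        diameter_px = y1 - y0, bbox_x0 = x0, bbox_y0 = y0,
        bbox_w = x1 - x0, bbox_h = y1 - y0,
        centre_x_px = (x0 + x1 - 1) / 2, centre_y_px = (y0 + y1 - 1) / 2)
    }
  }

  out <- with_local_seed(params$noise$seed, {
    if (aggregates$n_aggregates > 0) {
      ad <- rep_len(aggregates$aggregate_diameter_um,
                    aggregates$n_aggregates)
      for (a in seq_len(aggregates$n_aggregates)) {
        r_px <- ad[a] / 2 / px
        xc <- stats::runif(1, r_px, nx - 1 - r_px)
        yc <- stats::runif(1, r_px, ny - 1 - r_px)
        th <- stats::runif(1, 0, pi)
        bsemi <- r_px * 0.75                         # 4:3 axis ratio
        xs <- seq_len(nx) - 1; ys <- seq_len(ny) - 1
        X <- matrix(xs, ny, nx, byrow = TRUE) - xc
        Y <- matrix(ys, ny, nx) - yc
        U <- cos(th) * X + sin(th) * Y
        V <- -sin(th) * X + cos(th) * Y
        inside <- (U / r_px)^2 + (V / bsemi)^2 <= 1
        zd[inside] <- aggregates$intensity_factor * params$signal_level
        rows <- which(inside, arr.ind = TRUE)
        k <- k + 1L
        truth[[k]] <- data.frame(
          object_kind = "aggregate", id = k, true_diameter_um = ad[a],
          diameter_px = max(rows[, 1]) - min(rows[, 1]) + 1L,
          bbox_x0 = min(rows[, 2]) - 1L, bbox_y0 = min(rows[, 1]) - 1L,
          bbox_w = max(rows[, 2]) - min(rows[, 2]) + 1L,
          bbox_h = max(rows[, 1]) - min(rows[, 1]) + 1L,
          centre_x_px = xc, centre_y_px = yc)
      }
    }
    sig_px <- params$psf_sigma_um / px
    zd <- blur_if(zd + params$background_level, sig_px)
    actin <- blur_if(actin + params$background_level, sig_px)
    list(zd = apply_noise(zd, params$noise),
         actin = apply_noise(actin, params$noise))
  })

  truth <- do.call(rbind, truth)
  if (params$myofibril_axis == 90) {
    out$zd <- t(out$zd); out$actin <- t(out$actin)
    truth[, c("bbox_x0", "bbox_y0", "bbox_w", "bbox_h",
              "centre_x_px", "centre_y_px")] <-
      truth[, c("bbox_y0", "bbox_x0", "bbox_h", "bbox_w",
                "centre_y_px", "centre_x_px")]
  }
  list(zdisc = calibrated_image(out$zd, px, channel = "zdisc"),
       actin = calibrated_image(out$actin, px, channel = "actin"),
       truth = truth)
}

#' Parameters for synthetic Z-disc cross-section images
#'
#' A single Z-disc seen end-on: a rotationally symmetric intensity
#' profile about the disc centre. `center_peaked` is a radial Gaussian
#' centred at radius 0 (growing-isoform-like central concentration);
#' `ring` is a radial Gaussian centred at radius `profile_scale_um`
#' (blocking-isoform-like peripheral concentration, bimodal on any
#' diameter transect). The ring's radial width is fixed at
#' `profile_scale_um / 2`, which keeps the sharpest default structure
#' comfortably band-limited at the default pixel size.
#'
#' @param image_size_px Image side length in pixels (square image).
#' @param pixel_size_um Micrometres per pixel; the default 0.05 um/px is
#'   Nyquist-level sampling for a 63x/1.4 confocal, the acquisition
#'   regime of zoomed single-disc cross sections.
#' @param disc_center_px Length-2 (x, y), 0-based pixel coordinates of
#'   the disc centre; default: image centre.
#' @param disc_radius_um Radius of the disc/selection circle.
#' @param profile_kind `"center_peaked"` or `"ring"`.
#' @param profile_scale_um Gaussian width (center_peaked) or ring radius
#'   (ring), in um.
#' @param background_level,signal_level Intensities as in
#'   [longitudinal_params()].
#' @param noise A [noise_params()] object.
#' @return An object of class `crosssection_params`.
#' @export
crosssection_params <- function(image_size_px = 101,
                                pixel_size_um = 0.05,
                                disc_center_px = NULL,
                                disc_radius_um = 1.4,
                                profile_kind = c("center_peaked", "ring"),
                                profile_scale_um = 0.5,
                                background_level = 10,
                                signal_level = 100,
                                noise = noise_params()) {
  profile_kind <- match.arg(profile_kind)
  if (image_size_px < 5) stop("`image_size_px` too small")
  if (pixel_size_um <= 0) stop("`pixel_size_um` must be > 0")
  if (disc_radius_um <= 0) stop("`disc_radius_um` must be > 0")
  if (profile_scale_um <= 0) stop("`profile_scale_um` must be > 0")
  if (is.null(disc_center_px))
    disc_center_px <- rep((image_size_px - 1) / 2, 2)
  r_px <- disc_radius_um / pixel_size_um
  if (any(disc_center_px - r_px < 0) ||
      any(disc_center_px + r_px > image_size_px - 1))
    stop("disc (centre ", paste(disc_center_px, collapse = ","),
         ", radius ", signif(r_px, 4), " px) does not fit inside the image")
  if (profile_kind == "ring" && profile_scale_um >= disc_radius_um)
    stop("`profile_scale_um` (ring radius) must be < `disc_radius_um`")
  structure(list(image_size_px = as.integer(image_size_px),
                 pixel_size_um = pixel_size_um,
                 disc_center_px = disc_center_px,
                 disc_radius_um = disc_radius_um,
                 profile_kind = profile_kind,
                 profile_scale_um = profile_scale_um,
                 background_level = background_level,
                 signal_level = signal_level, noise = noise),
            class = "crosssection_params")
}

#' Generate a synthetic Z-disc cross-section image with ground truth
#'
#' The noise-free image is exactly rotationally symmetric about the disc
#' centre (intensity a function of radius alone), so rotational-average
#' denoising acts as an identity on it; seeded Poisson/Gaussian noise is
#' added on top.
#'
#' @param params A [crosssection_params()] object.
#' @return A list with `image` ([calibrated_image()]) and `truth`
#'   (one-row data.frame: object_kind, profile_kind, centre, radius).
#' @export
make_crosssection_image <- function(params) {
  stopifnot(inherits(params, "crosssection_params"))
  n <- params$image_size_px
  px <- params$pixel_size_um
  cx <- params$disc_center_px[1]; cy <- params$disc_center_px[2]
  X <- matrix(seq_len(n) - 1, n, n, byrow = TRUE) - cx
  Y <- matrix(seq_len(n) - 1, n, n) - cy
  r_um <- sqrt(X^2 + Y^2) * px
  prof <- if (params$profile_kind == "center_peaked") {
    exp(-r_um^2 / (2 * params$profile_scale_um^2))
  } else {
    # radial width profile_scale/2 keeps the ring band-limited at the
    # default pixel size (>= ~3.5 px sigma), so bilinear rotation is an
    # identity on the noise-free image to well under 1% of peak
    exp(-(r_um - params$profile_scale_um)^2 /
          (2 * (params$profile_scale_um / 2)^2))
  }
  img <- params$background_level + params$signal_level * prof
  img <- with_local_seed(params$noise$seed, apply_noise(img, params$noise))
  truth <- data.frame(
    object_kind = "zdisc", profile_kind = params$profile_kind,
    centre_x_px = cx, centre_y_px = cy,
    radius_px = params$disc_radius_um / px,
    profile_scale_um = params$profile_scale_um)
  list(image = calibrated_image(img, px, channel = "zdisc"), truth = truth)
}

#' Parameters for synthetic isoform expression time-courses
#'
#' Each transcript's noise-free mean TPM follows a logistic (sigmoid)
#' onset, `plateau * plogis((t - onset) / sharpness)`, with the onset
#' hour set per class. Defaults encode the developmental pattern of
#' flight-muscle Zasp isoforms: growing-class transcripts (two or more
#' LIM domains) switch on around 24 h APF, blocking-class transcripts
#' (0 or 1 LIM domain) around 60 h APF, over a sampling window from
#' 16 h APF to eclosion.
#'
#' @param n_growing,n_blocking Transcript counts per class.
#' @param onset_h Named numeric `c(growing=, blocking=)`, onset hours
#'   APF.
#' @param plateau_tpm Named numeric, plateau TPM per class.
#' @param onset_sharpness Logistic time scale in hours.
#' @param timepoints_h Strictly increasing sampling times, hours APF.
#' @param lognormal_sd SD of multiplicative log-normal noise (0 =
#'   noise-free). Noise is mean-one so class means are unbiased.
#' @param seed Integer seed.
#' @return An object of class `expression_sim_params`.
#' @export
expression_sim_params <- function(n_growing = 20, n_blocking = 20,
                                  onset_h = c(growing = 24, blocking = 60),
                                  plateau_tpm = c(growing = 100,
                                                  blocking = 100),
                                  onset_sharpness = 4,
                                  timepoints_h = c(16, 24, 32, 40, 48,
                                                   60, 72, 90),
                                  lognormal_sd = 0.2, seed = 1L) {
  if (length(timepoints_h) == 0L)
    stop("`timepoints_h` must be a non-empty increasing list of hours")
  if (any(diff(timepoints_h) <= 0))
    stop("`timepoints_h` must be strictly increasing")
  if (n_growing < 0 || n_blocking < 0) stop("transcript counts must be >= 0")
  if (n_growing + n_blocking == 0L) stop("no transcripts requested")
  if (any(plateau_tpm < 0)) stop("`plateau_tpm` must be >= 0")
  if (onset_sharpness <= 0) stop("`onset_sharpness` must be > 0")
  if (lognormal_sd < 0) stop("`lognormal_sd` must be >= 0")
  stopifnot(all(c("growing", "blocking") %in% names(onset_h)),
            all(c("growing", "blocking") %in% names(plateau_tpm)))
  structure(as.list(environment()), class = "expression_sim_params")
}

#' Generate a synthetic isoform TPM time-course with ground truth
#'
#' Growing-class transcripts get LIM-domain counts cycling over 2..4 and
#' gene `Zasp52`; blocking-class transcripts cycle over architectures
#' with 0 or 1 LIM domain across `Zasp52`/`Zasp66`/`Zasp67`, so that the
#' architecture-based classifier recovers the simulated class exactly.
#'
#' @param params An [expression_sim_params()] object.
#' @return A list with `expr` (an [isoform_expression_set()]) and
#'   `truth` (data.frame: transcript_id, class, true_onset_h).
#' @export
make_expression_timecourse <- function(params) {
  stopifnot(inherits(params, "expression_sim_params"))
  ng <- params$n_growing; nb <- params$n_blocking
  ids <- c(if (ng > 0) sprintf("G%03d", seq_len(ng)),
           if (nb > 0) sprintf("B%03d", seq_len(nb)))
  cls <- c(rep("growing", ng), rep("blocking", nb))
  n_lim <- c(if (ng > 0) rep_len(c(2L, 3L, 4L), ng),
             if (nb > 0) rep_len(c(0L, 1L), nb))
  gene <- ifelse(cls == "growing", "Zasp52",
                 ifelse(n_lim == 1L, "Zasp52",
                        rep_len(c("Zasp66", "Zasp67"), ng + nb)))
  records <- data.frame(transcript_id = ids, gene = gene, n_lim = n_lim,
                        has_zm = TRUE, has_pdz = n_lim > 0 | cls == "growing",
                        stringsAsFactors = FALSE)
  tp <- params$timepoints_h
  mu <- t(vapply(seq_along(ids), function(i) {
    on <- params$onset_h[[cls[i]]]
    pl <- params$plateau_tpm[[cls[i]]]
    pl * stats::plogis((tp - on) / params$onset_sharpness)
  }, numeric(length(tp))))
  tpm <- with_local_seed(params$seed, {
    if (params$lognormal_sd > 0) {
      s <- params$lognormal_sd
      mu * matrix(exp(stats::rnorm(length(mu), -s^2 / 2, s)),
                  nrow(mu), ncol(mu))
    } else mu
  })
  dimnames(tpm) <- list(ids, as.character(tp))
  truth <- data.frame(transcript_id = ids, object_kind = "transcript",
                      class = cls,
                      true_onset_h = unname(params$onset_h[cls]),
                      stringsAsFactors = FALSE)
  list(expr = isoform_expression_set(tpm, tp, records), truth = truth)
}
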