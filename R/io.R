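#' Write calibrated images to a TIFF file
#'
#' Intensities are rounded to the 16-bit grid (0..65535) and stored as
#' an uncompressed 16-bit TIFF, one page per channel; a written file
#' therefore round-trips exactly. Because the TIFF writer available to
#' this package does not expose resolution tags, the physical pixel
#' size is recorded in a plain-text sidecar file
#' (`<path>.pixelsize.txt`) that [read_calibrated_tiff()] consumes.
#'
#' @param images A [calibrated_image()] or list of them (equal shapes);
#'   intensities must lie in [0, 65535].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_calibrated_tiff <- function(images, path) {
  if (is_calibrated_image(images)) images <- list(images)
  stopifnot(length(images) > 0, all(vapply(images, is_calibrated_image,
                                           logical(1))))
  px <- unique(vapply(images, function(i) i$pixel_size_um, numeric(1)))
  if (length(px) != 1L) stop("all channels must share one pixel size")
  pages <- lapply(images, function(im) {
    v <- round(im$pixels)
    if (min(v) < 0 || max(v) > 65535)
      stop("intensities must lie in [0, 65535] for 16-bit storage")
    v / 65535
  })
  tiff::writeTIFF(pages, path, bits.per.sample = 16L, compression = "none")
  writeLines(c(sprintf("pixel_size_um: %.17g", px),
               paste0("channels: ",
                      paste(vapply(images, function(i) i$channel,
                                   character(1)), collapse = ","))),
             paste0(path, ".pixelsize.txt"))
  invisible(path)
}

#' Read calibrated images from a TIFF file
#'
#' Reads every page of a TIFF as a [calibrated_image()], restoring the
#' 16-bit intensities exactly. The pixel size is resolved in priority
#' order: TIFF resolution tags (inch or cm units), the plain-text
#' sidecar written by [write_calibrated_tiff()], then
#' `pixel_size_override`; if none is available the read fails — a
#' missing calibration is never silently defaulted.
#'
#' @param path TIFF file path.
#' @param pixel_size_override Micrometres per pixel to use when the
#'   file carries no calibration (or to override it).
#' @return A list of [calibrated_image()], page order preserved.
#' @export
read_calibrated_tiff <- function(path, pixel_size_override = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  pages <- tiff::readTIFF(path, all = TRUE, info = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  px <- pixel_size_override
  if (is.null(px)) {
    xres <- attr(pages[[1]], "x.resolution")
    unit <- attr(pages[[1]], "resolution.unit")
    if (!is.null(xres) && is.numeric(xres) && xres > 0) {
      per_um <- switch(as.character(unit %||% "inch"),
                       inch = xres / 25400, cm = xres / 1e4, NULL)
      if (!is.null(per_um)) px <- 1 / per_um
    }
  }
  side <- paste0(path, ".pixelsize.txt")
  chans <- NULL
  if (file.exists(side)) {
    ln <- readLines(side)
    if (is.null(px)) {
      m <- grep("^pixel_size_um:", ln, value = TRUE)
      if (length(m)) px <- as.numeric(sub("^pixel_size_um:\\s*", "", m[1]))
    }
    cm <- grep("^channels:", ln, value = TRUE)
    if (length(cm))
      chans <- strsplit(sub("^channels:\\s*", "", cm[1]), ",")[[1]]
  }
  if (is.null(px) || !is.finite(px) || px <= 0)
    stop("no pixel-size calibration in ", path,
         " (no resolution tags, no sidecar) and no `pixel_size_override`")
  lapply(seq_along(pages), function(i) {
    m <- pages[[i]]
    if (length(dim(m)) == 3L) m <- m[, , 1]        # greyscale expected
    m <- matrix(round(as.numeric(m) * 65535), nrow(m), ncol(m))
    calibrated_image(m, px, channel = chans[i] %||% sprintf("page%d", i))
  })
}

#' Write a data frame as CSV with provenance header lines
#'
#' Key-value metadata lines are written first, prefixed `#`, then the
#' table; [read_table_with_meta()] reads the pair back.
#'
#' @param df Data frame to write.
#' @param path Output path.
#' @param meta Named list/vector of metadata values.
#' @return `path`, invisibly.
#' @export
write_table_with_meta <- function(df, path, meta = list()) {
  con <- file(path, "w")
  on.exit(close(con))
  for (k in names(meta))
    writeLines(sprintf("# %s: %s", k, paste(meta[[k]], collapse = ",")),
               con)
  utils::write.csv(df, con, row.names = FALSE)
  invisible(path)
}

#' @rdname write_table_with_meta
#' @export
read_table_with_meta <- function(path) {
  ln <- readLines(path)
  hdr <- grepl("^#", ln)
  meta <- list()
  for (l in ln[hdr]) {
    kv <- sub("^#\\s*", "", l)
    k <- sub(":.*$", "", kv)
    meta[[k]] <- sub("^[^:]*:\\s*", "", kv)
  }
  df <- utils::read.csv(text = paste(ln[!hdr], collapse = "\n"),
                        stringsAsFactors = FALSE)
  attr(df, "meta") <- meta
  df
}

default_pipeline_config <- function() {
  list(
    pixel_size_um = 0.0703,
    min_area_um2 = 0.2,
    exclude_edges = TRUE,
    bin_edges_um = c(0.5, 1, 1.5, 2),
    myofibril_axis_deg = 0,
    agg_rows = 16, agg_cols = 16,
    threshold_mode = "global",
    area_cutoff_um2 = 0.5,
    step_deg = 2, n_rotations = 180,
    min_coverage = 0.9,
    prominence_min = 0.1, central_fraction = 0.25, smoothing_window = 5,
    exact_limit = 200, mc_replicates = 1e5,
    mutant_diameter_factor = 0.7,
    n_discs_per_group = 200,
    seed = 1L,
    out_dir = "results")
}

#' Pipeline configuration
#'
#' Builds the fully resolved configuration for [run_end_to_end()]: every
#' field has a default, unknown keys are rejected, and the resolved
#' configuration is echoed into every output for provenance.
#' `read_pipeline_config()` loads overrides from a plain-text key-value
#' (YAML) file.
#'
#' @param ... Named overrides of the defaults (see
#'   `default_pipeline_config` in the source for the full list: pixel
#'   size, segmentation, aggregate, cross-section, statistics and
#'   simulation parameters, `seed`, `out_dir`).
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(...) {
  cfg <- default_pipeline_config()
  over <- list(...)
  if (length(over) && (is.null(names(over)) || any(names(over) == "")))
    stop("all configuration overrides must be named")
  bad <- setdiff(names(over), names(cfg))
  if (length(bad))
    stop("unknown configuration key(s): ", paste(bad, collapse = ", "))
  cfg[names(over)] <- over
  structure(cfg, class = "pipeline_config")
}

#' @rdname pipeline_config
#' @param path Path to a YAML/key-value configuration file.
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  do.call(pipeline_config, yaml::read_yaml(path))
}
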