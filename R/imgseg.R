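#' Iterative-intermeans ("Default dark") auto-threshold
#'
#' Computes the isodata-variant iterative-intermeans threshold on a
#' 256-bin histogram, the method behind the reference tool's
#' "Default dark" auto-threshold, and returns the bright-object mask.
#' The returned threshold t is the smallest fixed point of
#' `t = floor((mean(bins <= t) + mean(bins > t)) / 2)` on the histogram
#' bins, reached by monotone iteration from the lowest occupied bin; the
#' mask keeps pixels strictly above the threshold (bright objects on a
#' dark background).
#'
#' For 8-bit integer data the bins are the intensities 0..255 themselves,
#' so the threshold is an intensity; otherwise the intensity range is
#' divided into 256 equal bins and the threshold is mapped back to the
#' upper edge of its bin.
#'
#' `ignore_extremes = TRUE` reproduces the reference tool's additional
#' convention of zeroing the two extreme bins (used there to exclude
#' erased/saturated areas) before iterating; it is off by default because
#' it departs from the pure intermeans fixed point on images that contain
#' true black or saturated pixels.
#'
#' @param image A [calibrated_image()] with at least two distinct
#'   intensity values.
#' @param ignore_extremes Zero bins 0 and 255 before iterating.
#' @return A [binary_mask()] with the threshold recorded in
#'   `threshold_value`.
#' @export
auto_threshold_default_dark <- function(image, ignore_extremes = FALSE) {
  assert_image(image)
  v <- image$pixels
  lo <- min(v); hi <- max(v)
  if (lo == hi)
    stop("constant image: no threshold separates foreground from background")
  eightbit <- image$bit_depth <= 8 ||
    (hi <= 255 && lo >= 0 && all(v == round(v)))
  if (eightbit) {
    counts <- tabulate(as.integer(v) + 1L, nbins = 256L)
    levels <- 0:255
    to_intensity <- function(t) t                       # bins are intensities
  } else {
    bw <- (hi - lo) / 256
    b <- pmin(floor((v - lo) / bw), 255)
    counts <- tabulate(as.integer(b) + 1L, nbins = 256L)
    levels <- 0:255
    to_intensity <- function(t) lo + (t + 1) * bw       # upper bin edge
  }
  if (ignore_extremes) {
    counts[c(1L, 256L)] <- 0L
    if (sum(counts) == 0L || sum(counts > 0) < 2L)
      stop("no threshold exists after ignoring the extreme bins")
  }
  t <- intermeans_iterate(counts, levels)
  thr <- to_intensity(t)
  binary_mask(v > thr, thr, image$pixel_size_um)
}

# Monotone iteration to the smallest intermeans fixed point.
# g(t) = floor((mean of bins <= t + mean of bins > t) / 2) is
# non-decreasing in t; starting from the lowest occupied bin (where
# g(t) >= t) the iteration increases to the smallest fixed point.
intermeans_iterate <- function(counts, levels) {
  csum  <- cumsum(counts)
  cwsum <- cumsum(counts * levels)
  n <- csum[length(csum)]
  wtot <- cwsum[length(cwsum)]
  occ <- which(counts > 0) - 1L
  tmin <- occ[1]; tmax <- occ[length(occ)]
  g <- function(t) {
    i <- t + 1L
    mu_lo <- cwsum[i] / csum[i]
    mu_hi <- (wtot - cwsum[i]) / (n - csum[i])
    floor((mu_lo + mu_hi) / 2)
  }
  t <- tmin
  repeat {
    t2 <- min(g(t), tmax - 1L)
    if (t2 == t) break
    t <- t2
  }
  as.integer(t)
}

# 8-connected component labelling. EBImage's bwlabel is 4-connected,
# whereas the reference particle analyzer joins diagonal neighbours, so
# labelling is done on the 8-neighbour pixel graph.
label_components_8 <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  fg <- which(mask)                       # column-major linear indices
  lab <- matrix(0L, nr, nc)
  if (length(fg) == 0L) return(lab)
  inmask <- logical(nr * nc); inmask[fg] <- TRUE
  row <- (fg - 1L) %% nr + 1L
  col <- (fg - 1L) %/% nr + 1L
  edges <- list()
  # neighbour offsets E, SE, S, SW cover all 8-adjacencies once
  for (d in list(c(0L, 1L), c(1L, 1L), c(1L, 0L), c(1L, -1L))) {
    r2 <- row + d[1]; c2 <- col + d[2]
    ok <- r2 >= 1L & r2 <= nr & c2 >= 1L & c2 <= nc
    nb <- (c2[ok] - 1L) * nr + r2[ok]
    hit <- inmask[nb]
    edges[[length(edges) + 1L]] <- cbind(fg[ok][hit], nb[hit])
  }
  edges <- do.call(rbind, edges)
  vid <- integer(nr * nc); vid[fg] <- seq_along(fg)
  g <- igraph::make_empty_graph(n = length(fg), directed = FALSE)
  if (nrow(edges) > 0)
    g <- igraph::add_edges(g, rbind(vid[edges[, 1]], vid[edges[, 2]]))
  comp <- igraph::components(g)$membership
  # relabel in raster order of first occurrence for determinism
  first <- match(seq_len(max(comp)), comp)
  ord <- rank(first)
  lab[fg] <- as.integer(ord[comp])
  lab
}

#' Extract Z-disc particles from a thresholded image
#'
#' Connected-component analysis of a binary mask (8-connectivity, as in
#' the reference analyzer), dropping components smaller than
#' `min_area_um2` and, when `exclude_edges`, components touching any
#' image border — the `size = 0.2 Infinity ... exclude` settings of the
#' side-view morphometry macro. Each retained particle is reported with
#' its area, 0-based half-open bounding box, centroid, mean source
#' intensity and edge flag. Touching discs are deliberately not split:
#' rare merges of close-by Z-discs are kept, as in the original
#' measurement protocol.
#'
#' @param mask A [binary_mask()].
#' @param image The source [calibrated_image()] (same shape).
#' @param min_area_um2 Minimum particle area in um^2 (default 0.2).
#' @param exclude_edges Drop particles touching the image border.
#' @return A data.frame of class `zdisc_particles` with one row per
#'   retained particle (columns `label`, `area_px`, `area_um2`,
#'   `bbox_x0`, `bbox_y0`, `bbox_w`, `bbox_h`, `centroid_x_px`,
#'   `centroid_y_px`, `mean_intensity`, `touches_edge`); the pixel size
#'   and per-particle pixel indices are carried in attributes.
#' @export
find_particles <- function(mask, image, min_area_um2 = 0.2,
                           exclude_edges = TRUE) {
  stopifnot(inherits(mask, "binary_mask"))
  assert_image(image)
  if (!identical(dim(mask$pixels), dim(image$pixels)))
    stop("mask and image must have the same shape")
  px <- image$pixel_size_um
  lab <- label_components_8(mask$pixels)
  n <- max(lab)
  empty <- data.frame(label = integer(), area_px = integer(),
                      area_um2 = numeric(), bbox_x0 = integer(),
                      bbox_y0 = integer(), bbox_w = integer(),
                      bbox_h = integer(), centroid_x_px = numeric(),
                      centroid_y_px = numeric(), mean_intensity = numeric(),
                      touches_edge = logical())
  if (n == 0L)
    return(structure(empty, class = c("zdisc_particles", "data.frame"),
                     pixel_size_um = px, pixels = list()))
  nr <- nrow(lab); nc <- ncol(lab)
  fg <- which(lab > 0L)
  lv <- lab[fg]
  row <- (fg - 1L) %% nr + 1L
  col <- (fg - 1L) %/% nr + 1L
  area_px <- tabulate(lv, nbins = n)
  xmin <- tapply(col, lv, min); xmax <- tapply(col, lv, max)
  ymin <- tapply(row, lv, min); ymax <- tapply(row, lv, max)
  cx <- tapply(col - 1L, lv, mean); cy <- tapply(row - 1L, lv, mean)
  mi <- tapply(image$pixels[fg], lv, mean)
  touches <- as.logical(tapply(row == 1L | row == nr | col == 1L | col == nc,
                               lv, any))
  out <- data.frame(
    label = seq_len(n), area_px = area_px, area_um2 = area_px * px^2,
    bbox_x0 = as.integer(xmin) - 1L, bbox_y0 = as.integer(ymin) - 1L,
    bbox_w = as.integer(xmax - xmin) + 1L,
    bbox_h = as.integer(ymax - ymin) + 1L,
    centroid_x_px = as.numeric(cx), centroid_y_px = as.numeric(cy),
    mean_intensity = as.numeric(mi), touches_edge = touches)
  pix <- split(fg, lv)
  keep <- out$area_um2 >= min_area_um2
  if (exclude_edges) keep <- keep & !out$touches_edge
  out <- out[keep, , drop = FALSE]
  rownames(out) <- NULL
  structure(out, class = c("zdisc_particles", "data.frame"),
            pixel_size_um = px, pixels = pix[keep], image_dim = c(nr, nc))
}

#' Measure Z-disc diameters (heights) of segmented particles
#'
#' The Z-disc "height" — the particle's bounding-box extent along the
#' direction perpendicular to the myofibril axis — is taken as the disc
#' diameter. For horizontal myofibrils (`myofibril_axis_deg = 0`) this
#' is the bounding-box height; for 90 degrees the width. For arbitrary
#' axes the member-pixel centres are projected onto the perpendicular
#' direction and the extent is that projection span plus one pixel
#' footprint.
#'
#' @param particles A `zdisc_particles` table from [find_particles()].
#' @param myofibril_axis_deg Myofibril axis in degrees (0 = horizontal).
#' @return Numeric vector of diameters in um, aligned with the rows of
#'   `particles`.
#' @export
measure_diameter <- function(particles, myofibril_axis_deg = 0) {
  stopifnot(inherits(particles, "zdisc_particles"))
  px <- attr(particles, "pixel_size_um")
  a <- myofibril_axis_deg %% 180
  if (a == 0) return(particles$bbox_h * px)
  if (a == 90) return(particles$bbox_w * px)
  pix <- attr(particles, "pixels")
  nr <- attr(particles, "image_dim")[1]
  th <- myofibril_axis_deg * pi / 180
  perp <- c(-sin(th), cos(th))
  unname(vapply(pix, function(idx) {
    x <- (idx - 1L) %/% nr; y <- (idx - 1L) %% nr
    p <- perp[1] * x + perp[2] * y
    (max(p) - min(p) + 1) * px
  }, numeric(1)))
}

#' Categorise diameters into size classes
#'
#' Right-open binning over strictly increasing edges, with underflow and
#' overflow collected into the first and last category, matching the
#' size-category frequency plots used to compare Z-disc size
#' distributions between genotypes. The default edges (0.5, 1.0, 1.5,
#' 2.0 um) are configuration defaults of this package, not published
#' category bounds.
#'
#' @param diameters Numeric vector of diameters in um, or a named list
#'   of such vectors (one per group).
#' @param bin_edges_um Strictly increasing numeric vector of edges.
#' @return A data.frame of class `size_category_table`: one row per
#'   category, one count column per group, with the category labels in
#'   `category`.
#' @export
categorize_sizes <- function(diameters, bin_edges_um = c(0.5, 1, 1.5, 2)) {
  if (is.null(bin_edges_um) || length(bin_edges_um) < 1 ||
      any(diff(bin_edges_um) <= 0))
    stop("`bin_edges_um` must be strictly increasing")
  if (!is.list(diameters)) diameters <- list(count = diameters)
  e <- bin_edges_um
  labs <- c(sprintf("<%.2g", e[1]),
            if (length(e) > 1)
              sprintf("[%.2g,%.2g)", e[-length(e)], e[-1]),
            sprintf(">=%.2g", e[length(e)]))
  counts <- lapply(diameters, function(d) {
    stopifnot(all(is.finite(d)))
    tabulate(findInterval(d, e) + 1L, nbins = length(e) + 1L)
  })
  out <- data.frame(category = labs, counts, check.names = FALSE)
  structure(out, class = c("size_category_table", "data.frame"),
            bin_edges_um = e)
}

#' Mean source intensity per particle
#'
#' Mean of the source image over each particle's member pixels — the
#' per-Z-disc raw mean fluorescence used for intensity comparisons
#' between genotypes (see [normalize_to_control()]). The source need not
#' be the channel that was segmented: segmenting on one channel and
#' measuring another is how a reporter's level is read out within
#' Z-disc footprints.
#'
#' @param image A [calibrated_image()] with the same geometry as the
#'   mask the particles came from.
#' @param particles A `zdisc_particles` table.
#' @return Numeric vector aligned with the rows of `particles`.
#' @export
mean_intensity_per_particle <- function(image, particles) {
  assert_image(image)
  stopifnot(inherits(particles, "zdisc_particles"))
  dm <- attr(particles, "image_dim")
  if (!is.null(dm) && !identical(dm, dim(image$pixels)))
    stop("image geometry does not match the particles' source geometry")
  unname(vapply(attr(particles, "pixels"),
                function(idx) mean(image$pixels[idx]), numeric(1)))
}
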