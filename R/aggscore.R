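#' Partition an image into a grid of tiles
#'
#' The montage tiling behind the aggregate-density estimate: a 36 x 36
#' um field split with a 16 x 16 grid gives 256 tiles of roughly
#' 2 x 2 um. Tiles are `floor(W/cols) x floor(H/rows)` pixels; any
#' remainder pixels on the right/bottom edges are dropped (and noted in
#' an attribute), so the tiles partition the analysed region exactly.
#'
#' @param image A [calibrated_image()] with at least `cols` x `rows`
#'   pixels.
#' @param rows,cols Grid dimensions (default 16 x 16).
#' @return A data.frame of class `tile_grid` with one row per tile
#'   (`tile`, `row`, `col`, `x0`, `y0`, `w`, `h`; 0-based, half-open),
#'   with tile size, dropped margins and pixel size as attributes.
#' @export
tile_image <- function(image, rows = 16, cols = 16) {
  assert_image(image)
  d <- dim(image$pixels)
  if (d[1] < rows || d[2] < cols)
    stop(sprintf("image (%d x %d px) smaller than the %d x %d grid",
                 d[2], d[1], cols, rows))
  tw <- d[2] %/% cols; th <- d[1] %/% rows
  dropped <- c(right_px = d[2] - tw * cols, bottom_px = d[1] - th * rows)
  if (any(dropped > 0))
    message(sprintf("tile_image: dropping %d right / %d bottom margin px",
                    dropped[1], dropped[2]))
  g <- expand.grid(col = seq_len(cols), row = seq_len(rows))
  out <- data.frame(tile = seq_len(rows * cols), row = g$row, col = g$col,
                    x0 = (g$col - 1L) * tw, y0 = (g$row - 1L) * th,
                    w = tw, h = th)
  structure(out, class = c("tile_grid", "data.frame"),
            tile_size_px = c(w = tw, h = th), dropped_px = dropped,
            source_dim = d, pixel_size_um = image$pixel_size_um)
}

#' Above-threshold area per tile
#'
#' For each tile, the area (um^2) of pixels above an automatic
#' "Default dark" threshold. `global` mode computes one threshold from
#' the full original image and applies it to every tile (the prose
#' description of the protocol); `per_tile` recomputes the threshold
#' within each tile (the behaviour of the macro's per-slice loop). A
#' tile (or image) with constant intensity admits no threshold; its
#' area is reported as 0 with a warning.
#'
#' @param grid A `tile_grid` from [tile_image()].
#' @param source The [calibrated_image()] the grid was derived from.
#' @param threshold_mode `"global"` (default) or `"per_tile"`.
#' @return Numeric vector of per-tile above-threshold areas in um^2,
#'   aligned with the rows of `grid`.
#' @export
tile_above_threshold_area <- function(grid, source,
                                      threshold_mode = c("global",
                                                         "per_tile")) {
  threshold_mode <- match.arg(threshold_mode)
  stopifnot(inherits(grid, "tile_grid"))
  assert_image(source)
  if (!identical(attr(grid, "source_dim"), dim(source$pixels)))
    stop("grid was not derived from this image's geometry")
  px2 <- source$pixel_size_um^2
  thr_global <- NULL
  if (threshold_mode == "global") {
    thr_global <- tryCatch(
      auto_threshold_default_dark(source)$threshold_value,
      error = function(e) {
        warning("constant image: no global threshold; all areas 0")
        NA_real_
      })
    if (is.na(thr_global)) return(rep(0, nrow(grid)))
  }
  vapply(seq_len(nrow(grid)), function(i) {
    t <- grid[i, ]
    sub <- source$pixels[(t$y0 + 1):(t$y0 + t$h),
                         (t$x0 + 1):(t$x0 + t$w), drop = FALSE]
    thr <- if (threshold_mode == "global") thr_global else {
      if (min(sub) == max(sub)) {
        warning(sprintf("tile %d constant: no threshold; area 0", t$tile))
        return(0)
      }
      sim <- calibrated_image(sub, source$pixel_size_um,
                              channel = source$channel,
                              bit_depth = source$bit_depth)
      auto_threshold_default_dark(sim)$threshold_value
    }
    sum(sub > thr) * px2
  }, numeric(1))
}

#' Call aggregate-positive tiles and summarise
#'
#' A tile is called aggregate-positive when its above-threshold area
#' exceeds `area_cutoff_um2`. The published protocol counts "images with
#' aggregates" without printing the positivity rule, so the cutoff is an
#' explicit, tunable parameter here; [calibrate_area_cutoff()] picks it
#' from ground-truthed synthetic fields.
#'
#' @param areas Per-tile areas from [tile_above_threshold_area()].
#' @param area_cutoff_um2 Positivity cutoff in um^2 (>= 0).
#' @return An object of class `aggregate_score`: list with
#'   `per_tile_area_um2`, `positive_tiles`, `n_tiles`, `frequency`,
#'   `area_cutoff_um2`.
#' @export
count_aggregate_tiles <- function(areas, area_cutoff_um2) {
  stopifnot(is.numeric(areas), all(areas >= 0),
            length(area_cutoff_um2) == 1L, area_cutoff_um2 >= 0)
  pos <- sum(areas > area_cutoff_um2)
  structure(list(per_tile_area_um2 = areas, positive_tiles = pos,
                 n_tiles = length(areas), frequency = pos / length(areas),
                 area_cutoff_um2 = area_cutoff_um2),
            class = "aggregate_score")
}

#' @export
print.aggregate_score <- function(x, ...) {
  cat(sprintf(
    "aggregate_score: %d / %d tiles positive (frequency %.3f) at cutoff %.3g um^2\n",
    x$positive_tiles, x$n_tiles, x$frequency, x$area_cutoff_um2))
  invisible(x)
}

#' Calibrate the aggregate-positivity area cutoff on ground truth
#'
#' Scans the midpoints between consecutive distinct per-tile areas and
#' returns the cutoff maximising agreement (accuracy) with a
#' ground-truth positivity labelling, together with the precision and
#' recall it achieves. Ties are broken towards the largest cutoff, the
#' most conservative caller.
#'
#' @param areas Per-tile areas (um^2).
#' @param truth_positive Logical vector: which tiles truly contain an
#'   aggregate.
#' @return List with `area_cutoff_um2`, `accuracy`, `precision`,
#'   `recall`.
#' @export
calibrate_area_cutoff <- function(areas, truth_positive) {
  stopifnot(length(areas) == length(truth_positive),
            is.logical(truth_positive))
  u <- sort(unique(c(0, areas)))
  cand <- if (length(u) > 1) c((u[-length(u)] + u[-1]) / 2, max(u) + 1)
          else u
  stats_at <- function(cut) {
    call <- areas > cut
    tp <- sum(call & truth_positive); fp <- sum(call & !truth_positive)
    fn <- sum(!call & truth_positive)
    c(acc = mean(call == truth_positive),
      prec = if (tp + fp > 0) tp / (tp + fp) else NA_real_,
      rec = if (tp + fn > 0) tp / (tp + fn) else NA_real_)
  }
  s <- vapply(cand, stats_at, numeric(3))
  best <- max(which(s["acc", ] == max(s["acc", ])))
  list(area_cutoff_um2 = unname(cand[best]),
       accuracy = unname(s["acc", best]),
       precision = unname(s["prec", best]),
       recall = unname(s["rec", best]))
}
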