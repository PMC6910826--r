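#!/usr/bin/env Rscript
# Stage 3: aggregate-density scoring (run 01 first). Each 36 x 36 um
# field is split into a 16 x 16 grid (256 tiles), the per-tile area
# above the image's automatic threshold is measured, and tiles whose
# area exceeds a cutoff are called aggregate-positive. The cutoff is
# calibrated on the ground-truthed aggregate field and then applied to
# both fields.

suppressMessages(library(zdiscquant))

data_dir <- "results/data"
out_dir <- "results/aggregates"
dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

score_field <- function(name) {
  img <- read_calibrated_tiff(file.path(data_dir,
                                        paste0(name, ".tif")))[[1]]
  grid <- tile_image(img)
  areas <- tile_above_threshold_area(grid, img)
  list(grid = grid, areas = areas, img = img)
}

agg <- score_field("aggfield")
ctl <- score_field("control")

# ground truth: tiles overlapped by any true aggregate bounding box
truth <- read_table_with_meta(file.path(data_dir, "aggfield_truth.csv"))
ab <- truth[truth$object_kind == "aggregate", ]
tile_hit <- vapply(seq_len(nrow(agg$grid)), function(i) {
  t <- agg$grid[i, ]
  any(ab$bbox_x0 < t$x0 + t$w & ab$bbox_x0 + ab$bbox_w > t$x0 &
        ab$bbox_y0 < t$y0 + t$h & ab$bbox_y0 + ab$bbox_h > t$y0)
}, logical(1))

cal <- calibrate_area_cutoff(agg$areas, tile_hit)
message(sprintf(
  "calibrated cutoff %.3f um^2 (accuracy %.3f, precision %.3f, recall %.3f)",
  cal$area_cutoff_um2, cal$accuracy, cal$precision, cal$recall))

fields <- list(aggfield = agg, control = ctl)
for (nm in names(fields)) {
  sc <- count_aggregate_tiles(fields[[nm]]$areas, cal$area_cutoff_um2)
  message(sprintf("%s: %d / %d tiles aggregate-positive (frequency %.4f)",
                  nm, sc$positive_tiles, sc$n_tiles, sc$frequency))
  write_table_with_meta(
    data.frame(tile = seq_along(sc$per_tile_area_um2),
               area_um2 = sc$per_tile_area_um2,
               positive = sc$per_tile_area_um2 > sc$area_cutoff_um2),
    file.path(out_dir, paste0("tiles_", nm, ".csv")),
    meta = list(field = nm, area_cutoff_um2 = sc$area_cutoff_um2,
                frequency = sc$frequency))
}
message("wrote ", out_dir)
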