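#!/usr/bin/env Rscript
# Stage 2: Z-disc segmentation and morphometry on the simulated
# control and mutant fields (run analysis/01_simulate_fields.R first).
# Auto-threshold ("Default dark"), particle analysis (area >= 0.2 um^2,
# edge particles excluded), disc diameter = bounding-box height, size
# categories, and the two group comparisons: Fisher's exact test on the
# size-category table, Welch's t-test on control-normalised per-disc
# mean intensities.

suppressMessages(library(zdiscquant))

data_dir <- "results/data"
out_dir <- "results/morphometry"
dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

measure_group <- function(name) {
  img <- read_calibrated_tiff(file.path(data_dir,
                                        paste0(name, ".tif")))[[1]]
  mask <- auto_threshold_default_dark(img)
  parts <- find_particles(mask, img)
  d <- measure_diameter(parts)
  tab <- cbind(as.data.frame(parts), diameter_um = d)
  write_table_with_meta(tab,
                        file.path(out_dir, paste0("particles_", name,
                                                  ".csv")),
                        meta = list(group = name,
                                    threshold = mask$threshold_value))
  message(sprintf("%s: %d discs, mean diameter %.3f um (threshold %.1f)",
                  name, nrow(tab), mean(d), mask$threshold_value))
  list(diameters = d, intensities = parts$mean_intensity)
}

ctrl <- measure_group("control")
mut <- measure_group("mutant")

sizes <- categorize_sizes(list(control = ctrl$diameters,
                               mutant = mut$diameters))
write_table_with_meta(as.data.frame(sizes),
                      file.path(out_dir, "size_categories.csv"),
                      meta = list(bin_edges_um = attr(sizes,
                                                      "bin_edges_um")))
print(as.data.frame(sizes))

cnt <- as.matrix(sizes[, c("control", "mutant")])
cnt <- cnt[rowSums(cnt) > 0, , drop = FALSE]
fe <- fisher_exact(cnt)
message(sprintf("size categories, control vs mutant: Fisher p = %.3g",
                fe$p_value))

rel_ctrl <- normalize_to_control(ctrl$intensities, ctrl$intensities)
rel_mut <- normalize_to_control(mut$intensities, ctrl$intensities)
wt <- welch_t_test(rel_ctrl, rel_mut)
message(sprintf(
  "relative intensity: control 1.00, mutant %.3f; Welch t = %.2f, p = %.3g",
  mean(rel_mut), wt$statistic, wt$p_value))

write_table_with_meta(
  data.frame(test = c("size_category_fisher", "intensity_welch"),
             method = c(fe$method, wt$method),
             statistic = c(NA, wt$statistic), df = c(NA, wt$df),
             p_value = c(fe$p_value, wt$p_value)),
  file.path(out_dir, "tests.csv"), meta = list())
message("wrote ", out_dir)
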