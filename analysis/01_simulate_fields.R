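#!/usr/bin/env Rscript
# Stage 1: generate the synthetic study data every later stage consumes.
#
# Emulated conditions:
#   * a control flight-muscle field (1.4 um Z-discs) and a "mutant"
#     field with 0.7x smaller discs — the small-disc phenotype of
#     LIM-domain-truncating Zasp mutants;
#   * an overexpression-like field carrying three large aggregates;
#   * 10 centre-peaked and 10 ring-like Z-disc cross sections
#     (growing- vs blocking-isoform localisation patterns);
#   * a 40-transcript isoform TPM time-course (growing onset 24 h APF,
#     blocking onset 60 h APF, 16-90 h window).
# Everything is seeded; ground truth accompanies every object.

suppressMessages(library(zdiscquant))

seed <- 20260901L
data_dir <- "results/data"
dir.create(data_dir, showWarnings = FALSE, recursive = TRUE)

message("simulating longitudinal fields (36 x 36 um, 0.0703 um/px) ...")
control <- make_longitudinal_image(
  longitudinal_params(noise = noise_params(seed = seed + 1L)))
mutant <- make_longitudinal_image(
  longitudinal_params(disc_diameter_um = 1.4 * 0.7,
                      noise = noise_params(seed = seed + 2L)))
aggfield <- make_longitudinal_image(
  longitudinal_params(noise = noise_params(seed = seed + 3L)),
  aggregate_params(n_aggregates = 3, aggregate_diameter_um = 3,
                   intensity_factor = 1.5))

for (nm in c("control", "mutant", "aggfield")) {
  g <- get(nm)
  write_calibrated_tiff(list(g$zdisc, g$actin),
                        file.path(data_dir, paste0(nm, ".tif")))
  write_table_with_meta(g$truth,
                        file.path(data_dir, paste0(nm, "_truth.csv")),
                        meta = list(seed = seed, object = nm))
}

message("simulating cross-section discs ...")
xsec_truth <- list()
for (kind in c("center_peaked", "ring")) {
  for (i in 1:10) {
    cp <- crosssection_params(profile_kind = kind,
                              noise = noise_params(50, 2,
                                                   seed = seed + 100L + i))
    ci <- make_crosssection_image(cp)
    write_calibrated_tiff(ci$image,
                          file.path(data_dir,
                                    sprintf("xsec_%s_%02d.tif", kind, i)))
    xsec_truth[[length(xsec_truth) + 1L]] <-
      cbind(file = sprintf("xsec_%s_%02d.tif", kind, i), ci$truth)
  }
}
write_table_with_meta(do.call(rbind, xsec_truth),
                      file.path(data_dir, "xsec_truth.csv"),
                      meta = list(seed = seed))

message("simulating isoform expression time-course ...")
sim <- make_expression_timecourse(expression_sim_params(seed = seed))
write_table_with_meta(
  data.frame(transcript_id = rownames(sim$expr$tpm), sim$expr$tpm,
             check.names = FALSE),
  file.path(data_dir, "tpm.csv"), meta = list(seed = seed))
write_table_with_meta(sim$expr$records,
                      file.path(data_dir, "isoform_annotation.csv"),
                      meta = list(seed = seed))
write_table_with_meta(sim$truth, file.path(data_dir, "tpm_truth.csv"),
                      meta = list(seed = seed))

message("done: ", length(list.files(data_dir)), " files under ", data_dir)
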