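#' Run the full Z-disc quantification pipeline
#'
#' Composes the measurement workflow end to end: either segment
#' user-supplied calibrated TIFFs, or (with `inputs = NULL`) simulate a
#' control field and a small-disc "mutant" field (mutant disc diameters
#' scaled by `mutant_diameter_factor`), then for every field
#' auto-threshold, extract particles, measure diameters and mean
#' intensities, categorise sizes, score aggregate tiles, and finally
#' compare the groups: Fisher's exact test on the size-category table
#' and Welch's t-test on control-normalised intensities. All outputs are
#' CSVs with `#`-prefixed provenance headers under `out_dir`, plus a
#' run manifest; two runs with the same configuration and seed produce
#' byte-identical outputs.
#'
#' The single `seed` in the configuration fans out to fixed per-stage
#' substreams (simulation control/mutant, Monte-Carlo statistics), so
#' individual stages can be re-run reproducibly.
#'
#' @param config A [pipeline_config()].
#' @param inputs `NULL` to simulate, or a character vector of TIFF
#'   paths (each segmented as its own group).
#' @return The run manifest (list with the resolved config, input list,
#'   per-stage record counts, test results and warnings), invisibly
#'   written to `manifest.yaml` in `out_dir`.
#' @export
run_end_to_end <- function(config = pipeline_config(), inputs = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  meta <- list(tool = paste0("zdiscquant ",
                             as.character(utils::packageVersion("zdiscquant"))),
               seed = config$seed)
  warnings <- character()
  groups <- list()      # name -> list(zdisc=calibrated_image, truth=?)

  if (is.null(inputs)) {
    base <- longitudinal_params(
      pixel_size_um = config$pixel_size_um,
      noise = noise_params(seed = config$seed * 1000L + 1L))
    n_per_field <- floor(base$field_size_um[1] / base$sarcomere_length_um) *
      base$n_myofibrils
    n_fields <- max(1L, ceiling(config$n_discs_per_group / n_per_field))
    sim_group <- function(name, dfactor, offset) {
      imgs <- lapply(seq_len(n_fields), function(f) {
        p <- longitudinal_params(
          pixel_size_um = config$pixel_size_um,
          disc_diameter_um = base$disc_diameter_um * dfactor,
          noise = noise_params(seed = config$seed * 1000L + offset + f))
        make_longitudinal_image(p)
      })
      list(name = name, fields = imgs)
    }
    groups <- list(sim_group("control", 1, 100L),
                   sim_group("mutant", config$mutant_diameter_factor, 200L))
  } else {
    if (length(inputs) == 0L) {
      manifest <- c(meta, list(config = unclass(config), inputs = list(),
                               counts = list(), warnings = list()))
      yaml::write_yaml(manifest, file.path(config$out_dir, "manifest.yaml"))
      return(manifest)
    }
    groups <- lapply(seq_along(inputs), function(i) {
      imgs <- read_calibrated_tiff(inputs[i],
                                   pixel_size_override =
                                     config$pixel_size_um)
      list(name = tools::file_path_sans_ext(basename(inputs[i])),
           fields = list(list(zdisc = imgs[[1]], truth = NULL)))
    })
  }

  per_group <- lapply(groups, function(g) {
    parts <- list(); diam <- numeric(); inten <- numeric()
    agg <- numeric()
    for (fld in g$fields) {
      img <- fld$zdisc
      mask <- auto_threshold_default_dark(img)
      p <- find_particles(mask, img, min_area_um2 = config$min_area_um2,
                          exclude_edges = config$exclude_edges)
      d <- measure_diameter(p, config$myofibril_axis_deg)
      diam <- c(diam, d)
      inten <- c(inten, p$mean_intensity)
      parts[[length(parts) + 1L]] <- cbind(field = length(parts) + 1L,
                                           as.data.frame(p),
                                           diameter_um = d)
      grid <- tile_image(img, rows = config$agg_rows,
                         cols = config$agg_cols)
      areas <- tile_above_threshold_area(grid, img,
                                         threshold_mode =
                                           config$threshold_mode)
      sc <- count_aggregate_tiles(areas, config$area_cutoff_um2)
      agg <- c(agg, sc$frequency)
    }
    list(name = g$name, particles = do.call(rbind, parts),
         diameters = diam, intensities = inten, agg_freq = agg)
  })

  # out_dir is implicit in the file location; keeping it out of the CSV
  # headers keeps runs byte-comparable across output directories
  cfg_meta <- lapply(unclass(config)[setdiff(names(config), "out_dir")],
                     function(v) paste(format(v, digits = 15),
                                       collapse = ","))
  for (g in per_group) {
    write_table_with_meta(
      g$particles,
      file.path(config$out_dir, sprintf("particles_%s.csv", g$name)),
      meta = c(list(group = g$name), cfg_meta))
  }

  diam_by_group <- lapply(per_group, function(g) g$diameters)
  names(diam_by_group) <- vapply(per_group, function(g) g$name,
                                 character(1))
  sizes <- categorize_sizes(diam_by_group, config$bin_edges_um)
  write_table_with_meta(as.data.frame(sizes),
                        file.path(config$out_dir, "size_categories.csv"),
                        meta = cfg_meta)

  tests <- list()
  if (length(per_group) >= 2) {
    cnt <- as.matrix(sizes[, -1, drop = FALSE])
    cnt <- cnt[rowSums(cnt) > 0, , drop = FALSE]
    fe <- fisher_exact(cnt, exact_limit = config$exact_limit,
                       mc_replicates = config$mc_replicates,
                       seed = config$seed * 1000L + 900L)
    rel <- normalize_to_control(per_group[[2]]$intensities,
                                per_group[[1]]$intensities)
    relc <- normalize_to_control(per_group[[1]]$intensities,
                                 per_group[[1]]$intensities)
    wt <- welch_t_test(relc, rel)
    tests <- list(size_category_fisher = fe,
                  intensity_welch = wt)
    write_table_with_meta(
      data.frame(test = names(tests),
                 method = vapply(tests, function(t) t$method, character(1)),
                 statistic = vapply(tests, function(t) t$statistic,
                                    numeric(1)),
                 df = vapply(tests, function(t) t$df, numeric(1)),
                 p_value = vapply(tests, function(t) t$p_value,
                                  numeric(1))),
      file.path(config$out_dir, "tests.csv"), meta = cfg_meta)
  }

  counts <- lapply(per_group, function(g)
    list(particles = nrow(g$particles),
         mean_aggregate_tile_frequency = mean(g$agg_freq)))
  names(counts) <- names(diam_by_group)
  manifest <- c(meta, list(
    config = lapply(unclass(config), function(v) v),
    inputs = as.list(inputs %||% character()),
    counts = counts,
    tests = lapply(tests, function(t)
      list(method = t$method, p_value = t$p_value)),
    warnings = as.list(warnings)))
  yaml::write_yaml(manifest, file.path(config$out_dir, "manifest.yaml"))
  invisible(manifest)
}
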