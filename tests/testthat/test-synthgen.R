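test_that("band geometry is exact by construction in clean fields", {
  p <- longitudinal_params(
    field_size_um = c(7, 7), pixel_size_um = 0.07, n_myofibrils = 1,
    sarcomere_length_um = 6.9, disc_diameter_um = 1.4,
    psf_sigma_um = 0, noise = noise_params(0, 0, seed = 1))
  g <- make_longitudinal_image(p)
  expect_equal(nrow(g$truth), 1L)
  expect_equal(g$truth$true_diameter_um, 1.4)
  expect_equal(g$truth$diameter_px, 20L)
  # the rendered band is exactly 20 px tall and nothing else is lit
  band_cols <- (g$truth$bbox_x0 + 1):(g$truth$bbox_x0 + g$truth$bbox_w)
  col_profile <- g$zdisc$pixels[, band_cols[1]]
  expect_equal(sum(col_profile > p$background_level), 20L)
  # actin channel covers the myofibril continuously along x
  actin_rows <- which(apply(g$actin$pixels > p$background_level, 1, all))
  expect_gte(length(actin_rows), g$truth$diameter_px)
})

test_that("identical seeds give bit-identical images and tables", {
  p <- longitudinal_params(noise = noise_params(seed = 42L))
  a <- make_longitudinal_image(p, aggregate_params(n_aggregates = 2))
  b <- make_longitudinal_image(p, aggregate_params(n_aggregates = 2))
  expect_identical(a$zdisc$pixels, b$zdisc$pixels)
  expect_identical(a$actin$pixels, b$actin$pixels)
  expect_identical(a$truth, b$truth)
  c <- make_longitudinal_image(
    longitudinal_params(noise = noise_params(seed = 43L)),
    aggregate_params(n_aggregates = 2))
  expect_false(identical(a$zdisc$pixels, c$zdisc$pixels))
})

test_that("every generated object has exactly one truth row", {
  p <- longitudinal_params(noise = noise_params(seed = 7L))
  n_bands <- floor(p$field_size_um[1] / p$sarcomere_length_um) *
    p$n_myofibrils
  g <- make_longitudinal_image(p, aggregate_params(n_aggregates = 3))
  expect_equal(sum(g$truth$object_kind == "zdisc"), n_bands)
  expect_equal(sum(g$truth$object_kind == "aggregate"), 3L)
  expect_equal(nrow(g$truth), n_bands + 3L)
  # coordinates lie inside the image
  d <- dim(g$zdisc$pixels)
  expect_true(all(g$truth$bbox_x0 >= 0 & g$truth$bbox_y0 >= 0))
  expect_true(all(g$truth$bbox_x0 + g$truth$bbox_w <= d[2]))
  expect_true(all(g$truth$bbox_y0 + g$truth$bbox_h <= d[1]))
})

test_that("impossible geometry is rejected naming the offending parameter", {
  expect_error(longitudinal_params(disc_diameter_um = 40),
               "disc_diameter_um")
  expect_error(
    make_longitudinal_image(
      longitudinal_params(field_size_um = c(2, 36),
                          sarcomere_length_um = 3.4)),
    "sarcomere_length_um")
  expect_error(
    make_longitudinal_image(
      longitudinal_params(n_myofibrils = 30, disc_diameter_um = 1.4)),
    "disc_diameter_um")
  expect_error(longitudinal_params(myofibril_axis = 45), "myofibril_axis")
})

test_that("axis 90 transposes the field and its ground truth", {
  p0 <- clean_field_params(myofibril_axis = 0)
  p90 <- clean_field_params(myofibril_axis = 90)
  g0 <- make_longitudinal_image(p0)
  g90 <- make_longitudinal_image(p90)
  expect_identical(g90$zdisc$pixels, t(g0$zdisc$pixels))
  expect_identical(g90$truth$bbox_w, g0$truth$bbox_h)
  expect_identical(g90$truth$bbox_h, g0$truth$bbox_w)
})

test_that("cross-section profiles have the constructed radial shape", {
  cp <- crosssection_params(profile_kind = "center_peaked",
                            noise = noise_params(0, 0, seed = 1))
  ci <- make_crosssection_image(cp)
  ctr <- cp$disc_center_px + 1
  half_r_px <- round(cp$disc_radius_um / 2 / cp$pixel_size_um)
  expect_gt(ci$image$pixels[ctr[2], ctr[1]],
            ci$image$pixels[ctr[2], ctr[1] + half_r_px])
  rp <- crosssection_params(profile_kind = "ring",
                            noise = noise_params(0, 0, seed = 1))
  ri <- make_crosssection_image(rp)
  ring_px <- round(rp$profile_scale_um / rp$pixel_size_um)
  expect_gte(ri$image$pixels[ctr[2], ctr[1] + ring_px],
             ri$image$pixels[ctr[2], ctr[1]])
})

test_that("noise-free cross sections are invariant under 90-degree rotation", {
  for (kind in c("center_peaked", "ring")) {
    cp <- crosssection_params(profile_kind = kind,
                              noise = noise_params(0, 0, seed = 1))
    img <- make_crosssection_image(cp)$image$pixels
    # odd-sized image centred on the disc: 90-degree rotation maps the
    # pixel grid onto itself
    rot90 <- t(img)[, rev(seq_len(ncol(img)))]
    expect_lt(max(abs(img - rot90)), 0.01 * cp$signal_level)
  }
})

test_that("ring larger than the disc is rejected", {
  expect_error(crosssection_params(profile_kind = "ring",
                                   profile_scale_um = 1.5,
                                   disc_radius_um = 1.4),
               "profile_scale_um")
  expect_error(crosssection_params(disc_center_px = c(2, 2)), "fit")
})

test_that("expression onsets order the classes between their onset hours", {
  p <- expression_sim_params(lognormal_sd = 0, onset_h = c(growing = 24,
                                                           blocking = 60))
  e <- make_expression_timecourse(p)
  cls <- e$truth$class
  at40 <- e$expr$tpm[, "40"]
  expect_true(all(outer(at40[cls == "growing"], at40[cls == "blocking"],
                        ">")))
  expect_true(all(e$expr$tpm >= 0))
})

test_that("expression generator respects class counts and seeding", {
  e0 <- make_expression_timecourse(expression_sim_params(n_growing = 0))
  expect_true(all(e0$truth$class == "blocking"))
  a <- make_expression_timecourse(expression_sim_params(seed = 5L))
  b <- make_expression_timecourse(expression_sim_params(seed = 5L))
  expect_identical(a$expr$tpm, b$expr$tpm)
  expect_identical(a$truth, b$truth)
  expect_error(expression_sim_params(timepoints_h = numeric()), "timepoint")
  expect_error(expression_sim_params(timepoints_h = c(24, 24)),
               "increasing")
})
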