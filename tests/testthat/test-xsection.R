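default_sel <- function(cp = crosssection_params()) {
  disc_selection(cp$disc_center_px, cp$disc_radius_um / cp$pixel_size_um)
}

test_that("rotational averaging is an identity on symmetric discs", {
  for (kind in c("center_peaked", "ring")) {
    cp <- crosssection_params(profile_kind = kind,
                              noise = noise_params(0, 0, seed = 1))
    ci <- make_crosssection_image(cp)
    sel <- default_sel(cp)
    ra <- rotational_average(ci$image, sel)
    expect_equal(attr(ra, "n_rotations"), 180)
    expect_equal(attr(ra, "step_deg"), 2)
    dev <- max(abs(ra$pixels - ci$image$pixels), na.rm = TRUE)
    expect_lt(dev, 0.01 * max(ci$image$pixels))
    expect_lt(dev, 0.01 * cp$signal_level)
  }
})

test_that("rotational averaging suppresses uncorrelated noise at every radius", {
  cp <- crosssection_params(image_size_px = 61, disc_radius_um = 1.2,
                            noise = noise_params(0, 0, seed = 1))
  base <- make_crosssection_image(cp)$image
  sel <- disc_selection(cp$disc_center_px, 1.2 / cp$pixel_size_um)
  n <- dim(base)[1]
  X <- matrix(seq_len(n) - 1, n, n, byrow = TRUE) - cp$disc_center_px[1]
  Y <- matrix(seq_len(n) - 1, n, n) - cp$disc_center_px[2]
  r <- sqrt(X^2 + Y^2)
  bands <- cut(r[r <= sel$radius_px & r > 2], breaks = seq(2, 24, by = 4))
  sd_in <- sd_out <- matrix(NA_real_, 30, nlevels(bands))
  set.seed(101)
  for (s in 1:30) {
    noise <- matrix(stats::rnorm(n^2, 0, 5), n, n)
    noisy <- calibrated_image(pmax(base$pixels + noise, 0),
                              cp$pixel_size_um)
    ra <- rotational_average(noisy, sel)
    res_in <- (noisy$pixels - base$pixels)[r <= sel$radius_px & r > 2]
    res_out <- (ra$pixels - base$pixels)[r <= sel$radius_px & r > 2]
    sd_in[s, ] <- tapply(res_in, bands, stats::sd)
    sd_out[s, ] <- tapply(res_out, bands, stats::sd)
  }
  # variance strictly reduced in every radial band, strongly on average
  expect_true(all(colMeans(sd_out) < colMeans(sd_in)))
  expect_lt(mean(sd_out) / mean(sd_in), 0.5)
})

test_that("rotation-set and selection preconditions are enforced", {
  ci <- make_crosssection_image(crosssection_params())
  sel <- default_sel()
  expect_warning(rotational_average(ci$image, sel, step_deg = 2,
                                    n_rotations = 90), "360")
  expect_error(rotational_average(ci$image, disc_selection(c(5, 5), 30)),
               "outside")
  # idempotence within interpolation tolerance
  ra1 <- rotational_average(ci$image, sel)
  ra2 <- rotational_average(ra1, sel)
  expect_lt(max(abs(ra2$pixels - ra1$pixels), na.rm = TRUE), 1)
  # linearity inside the selection
  lin <- rotational_average(
    calibrated_image(2 * ci$image$pixels + 5, ci$image$pixel_size_um), sel)
  expect_lt(max(abs(lin$pixels - (2 * ra1$pixels + 5)), na.rm = TRUE),
            1e-9)
})

test_that("coverage filter keeps only discs whose marker spans the actin area", {
  m <- matrix(FALSE, 10, 10); m[3:8, 3:8] <- TRUE
  full <- binary_mask(m, 0, 0.05)
  expect_true(coverage_filter(full, full, min_fraction = 1))
  disjoint <- binary_mask(!m, 0, 0.05)
  expect_false(coverage_filter(disjoint, full))
  half <- m; half[3:8, 6:8] <- FALSE     # covers 50% of actin
  half_mask <- binary_mask(half, 0, 0.05)
  expect_false(coverage_filter(half_mask, full, min_fraction = 0.9))
  expect_true(coverage_filter(half_mask, full, min_fraction = 0.5))
  none <- binary_mask(matrix(FALSE, 10, 10), 0, 0.05)
  expect_warning(res <- coverage_filter(full, none), "empty")
  expect_false(res)
})

test_that("diameter profiles recover the constructed radial structure", {
  flat <- calibrated_image(matrix(50, 61, 61), 0.05)
  sel <- disc_selection(c(30, 30), 20)
  pr <- diameter_profile(flat, sel)
  expect_true(all(pr$rel_intensity == 1))
  expect_equal(pr$position_um, -rev(pr$position_um))
  expect_equal(nrow(pr) %% 2, 1)

  cp <- crosssection_params(profile_kind = "center_peaked",
                            noise = noise_params(0, 0, seed = 1))
  ci <- make_crosssection_image(cp)
  prc <- diameter_profile(ci$image, default_sel(cp))
  expect_equal(prc$position_um[which.max(prc$rel_intensity)], 0)

  rp <- crosssection_params(profile_kind = "ring",
                            noise = noise_params(0, 0, seed = 1))
  ri <- make_crosssection_image(rp)
  prr <- diameter_profile(ri$image, default_sel(rp))
  spacing <- diff(prr$position_um[1:2])
  top2 <- prr$position_um[order(prr$rel_intensity, decreasing = TRUE)[1:2]]
  expect_equal(sort(abs(top2)), rep(rp$profile_scale_um, 2),
               tolerance = spacing / rp$profile_scale_um)
  expect_lt(abs(sum(top2)), spacing + 1e-9)      # symmetric pair
  # profile symmetry on noise-free symmetric discs
  expect_lt(max(abs(prr$rel_intensity - rev(prr$rel_intensity))), 0.02)
  expect_error(diameter_profile(flat, disc_selection(c(30, 30), 1.5)),
               "radius")
})

test_that("profile classification separates central from peripheral patterns", {
  flat <- calibrated_image(matrix(50, 61, 61), 0.05)
  sel <- disc_selection(c(30, 30), 20)
  expect_equal(classify_profile(diameter_profile(flat, sel))$call,
               "ambiguous")
  cp <- crosssection_params(profile_kind = "center_peaked",
                            noise = noise_params(0, 0, seed = 1))
  cl <- classify_profile(diameter_profile(make_crosssection_image(cp)$image,
                                          default_sel(cp)))
  expect_equal(cl$call, "center_peaked")
  expect_equal(length(cl$peak_positions_um), 1L)
  rp <- crosssection_params(profile_kind = "ring",
                            noise = noise_params(0, 0, seed = 1))
  clr <- classify_profile(diameter_profile(make_crosssection_image(rp)$image,
                                           default_sel(rp)))
  expect_equal(clr$call, "bimodal")
  expect_equal(length(clr$peak_positions_um), 2L)
  expect_lt(prod(sign(clr$peak_positions_um)), 0)
})

test_that("noisy discs are called correctly after rotational averaging", {
  sel <- default_sel()
  correct <- c(center_peaked = 0L, ring = 0L)
  want <- c(center_peaked = "center_peaked", ring = "bimodal")
  for (s in 1:8) {
    for (kind in names(correct)) {
      cp <- crosssection_params(profile_kind = kind,
                                noise = noise_params(50, 2, seed = s))
      im <- make_crosssection_image(cp)$image
      cl <- classify_profile(diameter_profile(rotational_average(im, sel),
                                              sel))
      correct[kind] <- correct[kind] + (cl$call == want[kind])
    }
  }
  expect_gte(correct[["center_peaked"]], 7L)
  expect_gte(correct[["ring"]], 7L)
})
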