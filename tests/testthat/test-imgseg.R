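test_that("intermeans threshold separates a two-population 8-bit image", {
  img <- calibrated_image(matrix(c(rep(10, 95), rep(200, 5)), 10, 10),
                          0.1, bit_depth = 8L)
  m <- auto_threshold_default_dark(img)
  expect_equal(m$threshold_value, 105)
  expect_equal(sum(m$pixels), 5L)
  expect_true(all(img$pixels[m$pixels] == 200))
})

test_that("constant images admit no threshold", {
  img <- calibrated_image(matrix(7, 5, 5), 0.1, bit_depth = 8L)
  expect_error(auto_threshold_default_dark(img), "constant")
})

test_that("two-value histograms threshold at the midpoint within one bin", {
  set.seed(11)
  for (i in 1:25) {
    ab <- sort(sample(0:255, 2))
    n1 <- sample(1:50, 1); n2 <- sample(1:50, 1)
    v <- sample(c(rep(ab[1], n1), rep(ab[2], n2)))
    img <- calibrated_image(matrix(v, 1), 0.1, bit_depth = 8L)
    thr <- auto_threshold_default_dark(img)$threshold_value
    expect_lte(abs(thr - mean(ab)), 1)
  }
})

test_that("threshold equals the exhaustive-scan intermeans fixed point", {
  set.seed(21)
  for (i in 1:200) {
    k <- sample(2:8, 1)                  # few distinct values
    vals <- sort(sample(0:255, k))
    v <- sample(vals, 64, replace = TRUE)
    if (length(unique(v)) < 2) next
    img <- calibrated_image(matrix(v, 8, 8), 0.1, bit_depth = 8L)
    thr <- auto_threshold_default_dark(img)$threshold_value
    expect_equal(thr, oracle_intermeans(tabulate(v + 1L, 256L)))
  }
})

test_that("particle extraction applies area filter and edge exclusion", {
  px <- 0.1
  blank <- matrix(0, 20, 20)
  img <- calibrated_image(blank, px)
  empty <- binary_mask(blank > 0, 0, px)
  expect_equal(nrow(find_particles(empty, img)), 0L)

  sq <- blank; sq[8:12, 8:12] <- 1       # 5x5 centred square
  m <- binary_mask(sq > 0, 0, px)
  p <- find_particles(m, calibrated_image(sq * 100, px),
                      min_area_um2 = 0.2)
  expect_equal(nrow(p), 1L)
  expect_equal(p$area_um2, 0.25)
  expect_equal(c(p$bbox_w, p$bbox_h), c(5L, 5L))
  expect_equal(p$mean_intensity, 100)

  top <- blank; top[1:5, 8:12] <- 1      # touches the top border
  m2 <- binary_mask(top > 0, 0, px)
  expect_equal(nrow(find_particles(m2, img)), 0L)
  p2 <- find_particles(m2, img, exclude_edges = FALSE, min_area_um2 = 0.2)
  expect_equal(nrow(p2), 1L)
  expect_true(p2$touches_edge)

  # area filter: 4 px = 0.04 um^2 < 0.2
  tiny <- blank; tiny[10:11, 10:11] <- 1
  expect_equal(nrow(find_particles(binary_mask(tiny > 0, 0, px), img)), 0L)
})

test_that("labelling is 8-connected, unlike a 4-connected flood fill", {
  m <- matrix(FALSE, 12, 12)
  m[3:4, 3:4] <- TRUE
  m[5:6, 5:6] <- TRUE                    # joined only at a corner
  img <- calibrated_image(matrix(1, 12, 12), 0.1)
  p <- find_particles(binary_mask(m, 0, 0.1), img, min_area_um2 = 0)
  expect_equal(nrow(p), 1L)
  expect_equal(oracle_component_count(m, eight = TRUE), 1L)
  expect_equal(oracle_component_count(m, eight = FALSE), 2L)

  set.seed(33)
  for (i in 1:10) {
    mm <- matrix(stats::runif(100) < 0.35, 10, 10)
    mm[1, ] <- FALSE; mm[10, ] <- FALSE; mm[, 1] <- FALSE; mm[, 10] <- FALSE
    pp <- find_particles(binary_mask(mm, 0, 0.1),
                         calibrated_image(matrix(1, 10, 10), 0.1),
                         min_area_um2 = 0)
    expect_equal(nrow(pp), oracle_component_count(mm, eight = TRUE))
  }
})

test_that("diameter is the bbox extent perpendicular to the myofibril axis", {
  blank <- matrix(0, 40, 40)
  blank[11:30, 18:22] <- 1               # 20 px tall, 5 px wide
  img <- calibrated_image(blank * 100, 0.07)
  p <- find_particles(binary_mask(blank > 0, 0, 0.07), img)
  expect_equal(measure_diameter(p, 0), 1.40)
  expect_equal(measure_diameter(p, 90), 5 * 0.07)
  # oblique axis: projection extent of an axis-aligned 20x5 band
  d45 <- measure_diameter(p, 45)
  expect_equal(d45, ((19 + 4) / sqrt(2) + 1) * 0.07, tolerance = 1e-6)
})

test_that("noise-free synthetic bands are measured exactly", {
  # 0.07 um/px makes the 1.4 um diameter an exact 20 px band
  g <- make_longitudinal_image(clean_field_params(pixel_size_um = 0.07))
  mask <- auto_threshold_default_dark(g$zdisc)
  p <- find_particles(mask, g$zdisc)
  m <- match_truth_particles(g$truth, p)
  d <- measure_diameter(p)[m$particle_idx]
  expect_equal(d, m$truth$diameter_px * g$zdisc$pixel_size_um)
  expect_equal(d, m$truth$true_diameter_um, tolerance = 1e-8)
  # rendered band intensity recovered exactly
  mi <- mean_intensity_per_particle(g$zdisc, p)
  expect_true(all(abs(mi - 110) < 1e-9))
})

test_that("bands closer than the PSF merge into one particle", {
  blank <- matrix(0, 60, 60)
  blank[21:40, 28:30] <- 100             # two bands 2 px apart
  blank[21:40, 33:35] <- 100
  blurred <- as.matrix(EBImage::gblur(blank + 10, sigma = 2))
  img <- calibrated_image(blurred, 0.07)
  mask <- auto_threshold_default_dark(img)
  p <- find_particles(mask, img, min_area_um2 = 0.1)
  expect_equal(nrow(p), 1L)              # the documented failure mode
})

test_that("size categorisation bins right-open with under/overflow bins", {
  tab <- categorize_sizes(c(0.4, 0.9, 1.6), bin_edges_um = c(0.5, 1.0, 1.5))
  expect_equal(tab$count, c(1L, 1L, 0L, 1L))
  expect_equal(tab$category, c("<0.5", "[0.5,1)", "[1,1.5)", ">=1.5"))
  expect_equal(categorize_sizes(numeric())$count, rep(0L, 5))
  set.seed(3)
  d <- stats::rlnorm(1000, log(1.2), 0.4)
  expect_equal(sum(categorize_sizes(d)$count), 1000L)
  # boundary values fall in the right-open upper bin
  expect_equal(categorize_sizes(c(0.5, 1.0), c(0.5, 1.0))$count,
               c(0L, 1L, 1L))
  expect_error(categorize_sizes(1, c(1, 0.5)), "increasing")
})

test_that("per-particle mean intensity averages member pixels only", {
  blank <- matrix(0, 10, 10)
  blank[4:5, 4:7] <- 1
  src <- matrix(0, 10, 10)
  src[4, 4:7] <- 0; src[5, 4:7] <- 200   # half 0, half 200
  p <- find_particles(binary_mask(blank > 0, 0, 0.2),
                      calibrated_image(src, 0.2), min_area_um2 = 0)
  expect_equal(mean_intensity_per_particle(calibrated_image(src, 0.2), p),
               100)
})
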