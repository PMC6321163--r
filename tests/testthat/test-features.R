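test_that("detection thresholding is exact on clean inputs and guards sigma", {
  model <- structure(list(mu = 0, sigma = 0.1), class = "background_model")
  z <- height_map(matrix(0, 16, 16), 10)
  expect_false(any(threshold_features(z, model, 5)))
  m <- matrix(0, 20, 20); m[8:12, 5:15] <- 1   # 10-sigma rod
  mask <- threshold_features(height_map(m, 10), model, 5)
  expect_identical(mask, m > 0)
  model0 <- structure(list(mu = 0, sigma = 0), class = "background_model")
  expect_error(threshold_features(z, model0, 5), "sigma")
})

test_that("false-positive pixels at k = 5 match the normal tail rate", {
  set.seed(10)
  m <- matrix(rnorm(1024 * 1024, 0, 0.2), 1024, 1024)
  model <- structure(list(mu = 0, sigma = 0.2), class = "background_model")
  n_fp <- sum(threshold_features(height_map(m, 10), model, 5))
  # expectation 1024^2 * 2.87e-7 = 0.3 pixels
  expect_lte(n_fp, 4)
})

test_that("labelling is 8-connected and respects separation and min area", {
  m <- matrix(FALSE, 10, 10)
  m[2, 2] <- TRUE; m[3, 3] <- TRUE             # diagonal touch
  expect_equal(label_features(m, 1)$n_features, 1L)
  m2 <- matrix(FALSE, 10, 12)
  m2[2:5, 2:4] <- TRUE; m2[2:5, 6:8] <- TRUE   # one background column apart
  expect_equal(label_features(m2, 1)$n_features, 2L)
  m3 <- matrix(FALSE, 10, 10)
  m3[2:3, 2:3] <- TRUE                          # area 4
  m3[7, 7] <- TRUE                              # area 1: dropped
  lab <- label_features(m3, 4)
  expect_equal(lab$n_features, 1L)
  expect_equal(lab$labels[7, 7], 0L)
  expect_equal(sort(unique(as.integer(lab$labels))), c(0L, 1L))
})

test_that("well-separated painted discs are each counted once", {
  set.seed(11)
  m <- matrix(FALSE, 400, 400)
  centres <- expand.grid(r = seq(20, 380, by = 40), c = seq(20, 380, by = 40))
  centres <- centres[sample.int(nrow(centres), 100), ]
  for (k in seq_len(100)) {
    jit <- runif(2, -5, 5)
    i0 <- round(centres$r[k] + jit[1]); j0 <- round(centres$c[k] + jit[2])
    for (i in (i0 - 3):(i0 + 3)) for (j in (j0 - 3):(j0 + 3))
      if ((i - i0)^2 + (j - j0)^2 <= 9) m[i, j] <- TRUE
  }
  expect_equal(label_features(m, 4)$n_features, 100L)
})

test_that("a 41 x 5 px rod at 10 nm/px measures 400 +/- 20 nm and is a fibril", {
  rec <- measure_mask(rod_mask(), pixel_size = 10)
  expect_gte(rec$length_nm, 380)
  expect_lte(rec$length_nm, 420)
  expect_equal(rec$width_nm, 50, tolerance = 0.1)
  expect_equal(rec$klass, "fibril")
  expect_equal(rec$n_branches, 1L)
})

test_that("a filled disc has length of order width and classifies as oligomer", {
  rec <- measure_mask(disc_mask(r = 4), pixel_size = 10)
  expect_lt(rec$length_nm / rec$width_nm, 2)
  expect_equal(rec$klass, "oligomer")
})

test_that("a Y-shaped object is one feature whose length sums its branches", {
  mask <- y_mask()
  labs <- label_features(mask, 4)
  expect_equal(labs$n_features, 1L)
  rec <- measure_mask(mask, pixel_size = 10)
  expect_equal(rec$n_branches, 3L)
  # arms: 21 + 21 + ~20.5 px (diagonal arm at 0.7 px steps), in nm at 10 nm/px
  arm_sum <- (21 + 21 + 20 * 0.7 * sqrt(2)) * 10
  expect_lt(abs(rec$length_nm - arm_sum) / arm_sum, 0.10)
})

test_that("classification follows the 2:1 length-to-width rule exactly", {
  for (len_px in c(8, 12, 16, 24, 41)) {
    rec <- measure_mask(rod_mask(cols = 10:(9 + len_px)), pixel_size = 10)
    expected <- rec$length_nm >= 2 * rec$width_nm &&
      rec$area_px > 0 && len_px > 3
    expect_identical(rec$klass == "fibril", expected,
                     label = sprintf("rod length %d px", len_px))
  }
})

test_that("surface coverage is exact pixel arithmetic", {
  expect_equal(surface_coverage(matrix(FALSE, 8, 8)), 0)
  expect_equal(surface_coverage(matrix(TRUE, 8, 8)), 100)
  m <- matrix(FALSE, 1024, 1024)
  m[seq_len(10486)] <- TRUE
  expect_equal(surface_coverage(m), 100 * 10486 / 1024^2)
})

test_that("coverage never decreases when a feature is added", {
  set.seed(12)
  m <- matrix(FALSE, 100, 100)
  m[10:20, 10:12] <- TRUE
  c1 <- surface_coverage(label_features(m, 4)$labels)
  m2 <- m; m2[60:70, 60:62] <- TRUE
  c2 <- surface_coverage(label_features(m2, 4)$labels)
  expect_gte(c2, c1)
})

test_that("a blank noise image yields no features and near-zero coverage", {
  set.seed(13)
  hm <- height_map(matrix(rnorm(256 * 256, 0, 0.1), 256, 256), 10)
  m <- analyze_image(hm)
  expect_equal(nrow(m$features), 0L)
  expect_lt(m$coverage_percent, 0.01)
})

test_that("a well-separated synthetic scene recovers its object count", {
  spec <- scene_spec(image_px = 512, scan_size = 5000, n_fibrils = 20,
                     n_oligomers = 30, length_median_nm = 200,
                     length_gsd = 1.2, seed = 14)
  sc <- render_scene(spec)
  m <- analyze_image(sc$map)
  expect_gte(nrow(m$features), 48)
  expect_lte(nrow(m$features), 52)
})

test_that("90-degree rotation preserves counts and aggregate length", {
  spec <- scene_spec(image_px = 256, scan_size = 2500, n_fibrils = 6,
                     n_oligomers = 4, length_median_nm = 150, length_gsd = 1.3,
                     tilt_x_nm = 0, tilt_y_nm = 0, bow_nm = 0,
                     line_jitter_nm = 0, noise_sigma_nm = 0, tip_blur_px = 0.5,
                     seed = 11)
  sc <- render_scene(spec)
  det <- sc$map$heights > 0.4
  measure_all <- function(mask, heights) {
    labs <- label_features(mask, 4)
    do.call(rbind, lapply(seq_len(labs$n_features), measure_feature,
                          labels = labs,
                          map = height_map(heights, sc$map$pixel_size)))
  }
  r1 <- measure_all(det, sc$map$heights)
  r2 <- measure_all(rot90(det), rot90(sc$map$heights))
  expect_equal(nrow(r1), nrow(r2))
  expect_lt(abs(mean(r2$length_nm) / mean(r1$length_nm) - 1), 0.02)
  # axis-aligned rods rotate exactly
  rec_a <- measure_mask(rod_mask(), pixel_size = 10)
  rec_b <- measure_mask(rot90(rod_mask()), pixel_size = 10)
  expect_equal(rec_a$length_nm, rec_b$length_nm)
  expect_equal(rec_a$width_nm, rec_b$width_nm)
})

test_that("edge-touching features are measured but flagged", {
  m <- matrix(FALSE, 30, 30)
  m[1:10, 14:16] <- TRUE                       # touches the top border
  rec <- measure_mask(m, pixel_size = 10)
  expect_true(rec$touches_edge)
  m2 <- matrix(FALSE, 30, 30)
  m2[10:20, 14:16] <- TRUE
  expect_false(measure_mask(m2, pixel_size = 10)$touches_edge)
})

test_that("measure_feature rejects out-of-range ids", {
  labs <- label_features(rod_mask(), 4)
  hm <- height_map(matrix(0, 60, 60), 10)
  expect_error(measure_feature(labs, 2L, hm), "out of range")
  expect_error(measure_feature(labs, 0L, hm), "out of range")
})
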