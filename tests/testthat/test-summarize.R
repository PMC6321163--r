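# fabricate an image_measurement carrying given fibril lengths/heights
fake_measurement <- function(lengths, heights = rep(2, length(lengths)),
                             coverage = 1, cond = condition_label(0, 24, 1),
                             klass = rep("fibril", length(lengths)),
                             edge = rep(FALSE, length(lengths))) {
  feats <- data.frame(
    feature_id = seq_along(lengths), length_nm = lengths,
    width_nm = pmax(lengths / 4, 1), max_height_nm = heights,
    area_px = rep(10L, length(lengths)), n_branches = rep(1L, length(lengths)),
    klass = klass, touches_edge = edge, stringsAsFactors = FALSE)
  structure(list(source_id = "fake", condition = cond, features = feats,
                 coverage_percent = coverage,
                 n_fibrils = sum(klass == "fibril"),
                 n_oligomers = sum(klass == "oligomer")),
            class = "image_measurement")
}

fake_summary <- function(dha, time, mean_length, n = 50) {
  structure(list(dha_concentration = dha, incubation_time = time,
                 n_images = 8, n_fibrils = n, n_oligomers = n,
                 no_fibrils = FALSE, mean_length = mean_length,
                 sem_length = 1, mean_height = 2, sem_height = 0.1,
                 mean_coverage = 1, sem_coverage = 0.1, length_kde = NULL),
            class = "condition_summary")
}

test_that("condition summaries compute pooled means and SEMs by hand arithmetic", {
  s <- summarize_condition(list(fake_measurement(c(100, 100, 100))))
  expect_equal(s$mean_length, 100)
  expect_equal(s$sem_length, 0)

  s2 <- summarize_condition(list(fake_measurement(c(60, 80, 100))))
  expect_equal(s2$mean_length, 80)
  expect_equal(s2$sem_length, 20 / sqrt(3))
})

test_that("edge-touching fibrils and oligomers are excluded from length statistics", {
  m <- fake_measurement(c(100, 200, 300, 400),
                        klass = c("fibril", "fibril", "oligomer", "fibril"),
                        edge = c(FALSE, FALSE, FALSE, TRUE))
  s <- summarize_condition(list(m))
  expect_equal(s$n_fibrils, 2)
  expect_equal(s$mean_length, 150)
})

test_that("a condition with no fibrils is marked, not zeroed", {
  m <- fake_measurement(c(30, 40), klass = c("oligomer", "oligomer"),
                        coverage = 0.5)
  s <- summarize_condition(list(m))
  expect_true(s$no_fibrils)
  expect_true(is.na(s$mean_length))
  expect_equal(s$mean_coverage, 0.5)
})

test_that("coverage uses images as the replication unit", {
  ms <- list(fake_measurement(c(100), coverage = 1),
             fake_measurement(c(120), coverage = 2),
             fake_measurement(c(140), coverage = 3))
  s <- summarize_condition(ms)
  expect_equal(s$mean_coverage, 2)
  expect_equal(s$sem_coverage, sd(1:3) / sqrt(3))
  expect_equal(s$n_images, 3)
})

test_that("KDE matches the standard normal density and integrates to one", {
  set.seed(15)
  x <- rnorm(1e4)
  kd <- kde_density(x)
  at0 <- kd$density[which.min(abs(kd$value))]
  expect_lt(abs(at0 - dnorm(0)), 0.02)
  integral <- sum(diff(kd$value) * (head(kd$density, -1) + tail(kd$density, -1)) / 2)
  expect_lt(abs(integral - 1), 0.01)
  # order invariance
  kd2 <- kde_density(rev(x))
  expect_equal(kd, kd2)
})

test_that("two-point KDE is symmetric and bimodal; degenerate input errors", {
  kd <- kde_density(c(0, 10))
  peak_lo <- max(kd$density[kd$value < 5])
  peak_hi <- max(kd$density[kd$value > 5])
  expect_lt(abs(peak_lo - peak_hi), 1e-9)
  expect_error(kde_density(rep(5, 10)), "distinct")
})

test_that("contrasts reproduce the reported fibril-length ratios", {
  s0 <- fake_summary(0, 24, 250)     # control at 24 h
  s30 <- fake_summary(30, 24, 126)   # 30 uM at 24 h
  s100 <- fake_summary(100, 24, 421) # 100 uM at 24 h

  red <- contrast(s30, s0, "length")
  expect_equal(red$percent_reduction_small_vs_large, 100 * (1 - 126 / 250))
  expect_lt(abs(red$percent_reduction_small_vs_large - 49.6), 0.01)

  tri <- contrast(s100, s30, "length")
  expect_gte(tri$ratio, 3)

  dbl <- contrast(s0, s30, "length")
  expect_lte(dbl$ratio, 2)

  same <- contrast(s0, s0, "length")
  expect_equal(same$ratio, 1)
  expect_equal(same$percent_change, 0)
})

test_that("contrast reciprocals multiply to one and bad denominators error", {
  a <- fake_summary(0, 24, 137.3); b <- fake_summary(30, 24, 89.1)
  expect_lt(abs(contrast(a, b, "length")$ratio *
                contrast(b, a, "length")$ratio - 1), 1e-12)
  bad <- fake_summary(30, 24, 0)
  expect_error(contrast(a, bad, "length"), "> 0")
  na <- fake_summary(30, 24, NA_real_)
  expect_error(contrast(a, na, "length"), "defined mean")
})

test_that("grid report emits one row per condition plus within-time contrasts", {
  sums <- list()
  means <- matrix(c(110, 64, 150, 170, 88, 280, 250, 126, 421), 3, 3)
  for (ti in 1:3) for (ci in 1:3)
    sums[[length(sums) + 1]] <- fake_summary(c(0, 30, 100)[ci],
                                             c(1, 6, 24)[ti], means[ci, ti])
  rep <- grid_report(sums)
  expect_equal(nrow(rep$table), 9)
  expect_equal(nrow(rep$contrasts), 9)         # 3 pairs x 3 times
  expect_equal(rep$orderings$length_ordering,
               rep("30 < 0 < 100", 3))
  one <- grid_report(sums[1])
  expect_equal(nrow(one$table), 1)
  expect_null(one$contrasts)
})

test_that("SEM shrinks as one over root n under resampling", {
  set.seed(16)
  pop <- rlnorm(4000, log(150), log(1.5))
  sems <- vapply(c(50, 200, 800), function(n) {
    s <- summarize_condition(list(fake_measurement(sample(pop, n))))
    s$sem_length
  }, numeric(1))
  # quadrupling n should roughly halve the SEM
  expect_lt(sems[2] / sems[1], 0.75)
  expect_lt(sems[3] / sems[2], 0.75)
})
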