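test_that("coverage_fraction counts mask pixels inside the ROI", {
  # 5 x 4 = 20-pixel head; 3 mask pixels inside -> 0.15
  roi <- rect_roi(2, 6, 3, 6)
  expect_equal(roi$area_px, 20L)
  m <- matrix(0L, 12, 12)
  m[cbind(c(4, 5, 6), c(3, 4, 5))] <- 1L  # (row, col) 1-based = (y+1, x+1)
  expect_equal(coverage_fraction(roi, m), 0.15)
  expect_equal(coverage_fraction(roi, matrix(0L, 12, 12)), 0)
  expect_equal(coverage_fraction(roi, matrix(1L, 12, 12)), 1)
})

test_that("coverage_fraction rejects polygons outside the image", {
  roi <- rect_roi(2, 6, 3, 6)
  expect_error(coverage_fraction(roi, matrix(0L, 5, 5)), "outside")
})

test_that("coverage_fraction matches a brute-force point-in-polygon oracle", {
  skip_if_not_installed("mgcv")
  set.seed(42)
  size <- 40L
  for (i in 1:60) {
    p <- random_star_polygon(size)
    roi <- try(spine_roi("s", "mushroom", p$x, p$y), silent = TRUE)
    if (inherits(roi, "try-error")) next  # degenerate draw with no pixels
    mask <- matrix(rbinom(size * size, 1, 0.4), size, size)
    # oracle: loop every pixel center through an independent
    # point-in-polygon routine and count mask hits
    bnd <- list(x = c(p$x, p$x[1]), y = c(p$y, p$y[1]))
    g <- expand.grid(x = 0:(size - 1), y = 0:(size - 1))
    inside <- mgcv::in.out(cbind(bnd$x, bnd$y), as.matrix(g))
    hits <- sum(mask[cbind(g$y[inside] + 1L, g$x[inside] + 1L)])
    expect_identical(sum(inside), roi$area_px)
    expect_equal(coverage_fraction(roi, mask), hits / sum(inside))
  }
})

test_that("detect_interactions finds maximal runs at the inclusive criterion", {
  # hand enumeration: frames 2-3 form one interaction, 6 min, max 0.07
  d <- detect_interactions(c(0, 0.06, 0.07, 0.02), frame_interval_min = 3)
  expect_equal(nrow(d), 1L)
  expect_equal(d$start_frame, 2L)
  expect_equal(d$end_frame, 3L)
  expect_equal(d$length_min, 6)
  expect_equal(d$max_coverage, 0.07)

  expect_equal(nrow(detect_interactions(rep(0, 5), 3)), 0L)

  # criterion is inclusive: a frame exactly at 0.05 counts
  d2 <- detect_interactions(c(0.05, 0.04), 3)
  expect_equal(nrow(d2), 1L)
  expect_equal(d2$length_min, 3)
  # ... unless strict mode is requested
  expect_equal(nrow(detect_interactions(c(0.05, 0.04), 3, strict = TRUE)), 0L)
})

test_that("invalid frames break runs and all-invalid is an error", {
  d <- detect_interactions(c(0.1, 0.1, 0.1), 3,
                           valid = c(TRUE, FALSE, TRUE))
  expect_equal(nrow(d), 2L)
  expect_equal(d$length_min, c(3, 3))
  expect_error(detect_interactions(c(0.1, 0.2), 3, valid = c(FALSE, FALSE)),
               "invalid")
})

test_that("appending all-zero frames changes interactions only via time normalization", {
  cov <- c(0, 0.2, 0.2, 0, 0.07)
  a <- detect_interactions(cov, 3)
  b <- detect_interactions(c(cov, 0, 0, 0), 3)
  expect_equal(a, b)
  sa <- summarize_dendrite(list(s1 = a), total_valid_minutes = 15)
  sb <- summarize_dendrite(list(s1 = b), total_valid_minutes = 24)
  expect_equal(sa$rate_per_10min * 15, sb$rate_per_10min * 24)
  expect_equal(sa$mean_length_min, sb$mean_length_min)
})

test_that("summarize_dendrite computes rates and conditional summaries", {
  i3 <- detect_interactions(c(0.1, 0, 0.1, 0, 0.1, 0, 0, 0, 0, 0), 3)
  expect_equal(summarize_dendrite(list(a = i3), 30)$rate_per_10min, 1)

  i2 <- detect_interactions(c(0.1, 0, 0.1, rep(0, 13)), 3)
  expect_equal(summarize_dendrite(list(a = i2), 48)$rate_per_10min,
               2 * 10 / 48, tolerance = 1e-12)

  none <- detect_interactions(rep(0, 5), 3)
  s <- summarize_dendrite(list(a = none, b = none), 15)
  expect_equal(s$prop_with_interaction, 0)
  expect_true(is.na(s$mean_length_min))
  expect_true(is.na(s$mean_max_coverage))

  expect_error(summarize_dendrite(list(a = none), 15,
                                  classes = "filopodial",
                                  class_filter = "mushroom"),
               "no spines of class")
})

test_that("generate_offsets reproduces the published grid geometry", {
  g800 <- generate_offsets(800, 32, 10)
  expect_equal(nrow(g800), 231L)
  expect_equal(sum(g800$mode == "horizontal"), 77L)

  g50 <- generate_offsets(50, 32, 10)
  expect_equal(sort(unique(g50$magnitude)), c(32, 42))
  expect_equal(nrow(g50), 6L)

  g100 <- generate_offsets(100, 32, 10)
  expect_equal(range(g100$magnitude), c(32, 92))
  expect_equal(nrow(g100), 21L)

  expect_false(any(g800$dx == 0 & g800$dy == 0))
  expect_false(any(duplicated(g800[, c("dx", "dy")])))
  expect_error(generate_offsets(30, 32, 10), "start_px")
})

test_that("circular shifts wrap and shifting by the image size is the identity", {
  m <- matrix(rbinom(64, 1, 0.3), 8, 8)
  expect_identical(shift_mask(m, 8, 8), m)
  expect_identical(shift_mask(shift_mask(m, 3, 5), -3, -5), m)
  # content moves right by dx: column 1 ends up in column 4
  expect_identical(shift_mask(m, 3, 0)[, 4], m[, 1])
})

test_that("offset_statistics with the identity shift equals the real statistic", {
  set.seed(9)
  size <- 32L
  mask <- array(rbinom(size * size * 4, 1, 0.2), dim = c(size, size, 4))
  rois <- list(rect_roi(5, 9, 5, 9, "a"), rect_roi(20, 24, 20, 24, "b"))
  mv <- toy_movie(mask, rois)
  grid0 <- data.frame(dx = 0L, dy = 0L, mode = "identity", magnitude = 0)
  real <- contact_spine_table(mv)
  v <- offset_statistics(mv, grid0, statistic = "rate_per_10min",
                         class_filter = NULL)
  expect_equal(v, mean(real$rate_per_10min))
})

test_that("offsets matching a periodic mask's symmetry reproduce the real summary", {
  size <- 32L
  frame <- matrix(0L, size, size)
  frame[, seq(1, size, by = 8)] <- 1L  # vertical stripes, period 8
  mask <- array(frame, dim = c(size, size, 2))
  mv <- toy_movie(mask, list(rect_roi(4, 12, 10, 18, "a")))
  grid <- data.frame(dx = c(8L, 16L), dy = 0L, mode = "horizontal",
                     magnitude = c(8, 16))
  v <- offset_statistics(mv, grid, statistic = "mean_coverage",
                         class_filter = NULL)
  real <- mean(sapply(1:2, function(t) {
    coverage_fraction(mv$rois[[1]], mask[, , t])
  }))
  expect_equal(v, rep(real, 2))
})

test_that("empty microglia channel gives an identically zero null", {
  size <- 48L
  mask <- array(0L, dim = c(size, size, 3))
  mv <- toy_movie(mask, list(rect_roi(10, 14, 10, 14, "a")))
  grid <- generate_offsets(size, 16, 8)
  v <- offset_statistics(mv, grid, statistic = "mean_coverage",
                         class_filter = NULL)
  expect_true(all(v == 0))
  tab <- contact_spine_table(mv)
  expect_equal(tab$n_interactions, 0L)
})

test_that("one-tailed permutation p follows the add-one formula", {
  expect_equal(permutation_test_one_tailed(5, rep(1, 231)), 1 / 232)
  expect_equal(permutation_test_one_tailed(0, rep(1, 10)), 1)
  # 10 of 231 null values at or above the observation -> 11/232
  null <- c(rep(6, 10), rep(1, 221))
  expect_equal(permutation_test_one_tailed(5, null), 11 / 232)
  expect_equal(round(11 / 232, 3), 0.047)  # the granularity behind p ~ 0.048
  expect_warning(p <- permutation_test_one_tailed(5, c(NA, rep(1, 9))),
                 "missing")
  expect_equal(p, 1 / 10)
})

test_that("contact movies are deterministic for a fixed seed and config", {
  cfg <- synth_config(seed = 31, image_size_px = 96)
  a <- make_contact_movie(cfg, n_spines = 5, n_frames = 3)
  b <- make_contact_movie(cfg, n_spines = 5, n_frames = 3)
  expect_identical(a$microglia, b$microglia)
  expect_identical(a$dendrite, b$dendrite)
  expect_identical(lapply(a$rois, `[[`, "x"), lapply(b$rois, `[[`, "x"))
  c2 <- make_contact_movie(synth_config(seed = 32, image_size_px = 96),
                           n_spines = 5, n_frames = 3)
  expect_false(identical(a$microglia, c2$microglia))
})

test_that("ground-truth contact frames agree with the pipeline's detection", {
  cfg <- synth_config(seed = 8, image_size_px = 96)
  mv <- make_contact_movie(cfg, n_spines = 6, n_frames = 5)
  for (i in seq_along(mv$rois)) {
    cov <- sapply(1:5, function(t) coverage_fraction(mv$rois[[i]], mv$microglia[, , t]))
    expect_equal(unname(cov), unname(mv$ground_truth$coverage[i, ]))
    expect_equal(which(cov >= 0.05),
                 mv$ground_truth$contact_frames[[i]],
                 ignore_attr = TRUE)
  }
})

test_that("a movie with no motility and no processes gives all-zero coverage", {
  cfg <- synth_config(seed = 4, image_size_px = 96)
  mv <- make_contact_movie(cfg, n_spines = 4, motility = 0, n_frames = 4)
  mv$microglia[] <- 0L  # empty microglia channel
  tab <- contact_spine_table(mv)
  expect_true(all(tab$n_interactions == 0))
})
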