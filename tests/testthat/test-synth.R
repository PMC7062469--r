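test_that("generators are byte-identical for identical seed and config", {
  cfg <- synth_config(seed = 101, image_size_px = 96, n_odors = 3,
                      n_repeats = 2)
  m1 <- make_contact_movie(cfg, 5, n_frames = 3)
  m2 <- make_contact_movie(cfg, 5, n_frames = 3)
  expect_identical(serialize(m1, NULL), serialize(m2, NULL))

  d1 <- make_calcium_dataset(cfg, 1, 2)
  d2 <- make_calcium_dataset(cfg, 1, 2)
  expect_identical(serialize(d1, NULL), serialize(d2, NULL))

  t1 <- make_rc_testpulse(10, 500, 14, 2, seed = 5)
  t2 <- make_rc_testpulse(10, 500, 14, 2, seed = 5)
  expect_identical(t1$i_pa, t2$i_pa)

  e1 <- make_event_train(10, 30, 0.1, seed = 3)
  e2 <- make_event_train(10, 30, 0.1, seed = 3)
  expect_identical(e1$time_ms, e2$time_ms)
})

test_that("generators do not disturb the caller's RNG stream", {
  set.seed(500)
  before <- .Random.seed
  invisible(make_event_train(5, 10, seed = 1))
  invisible(make_rc_testpulse(10, 100, 10, 1, seed = 2))
  expect_identical(.Random.seed, before)
})

test_that("the RC pulse follows the circuit's closed form", {
  rs <- 10; rm_ <- 500; cm <- 14
  tp <- make_rc_testpulse(rs, rm_, cm, noise_pa = 0, seed = 1,
                          n_repetitions = 2)
  i <- colMeans(tp$i_pa)
  tau <- cm * (rs * rm_ / (rs + rm_)) * 1e-3
  expect_equal(tp$truth$tau_ms, tau)
  # instantaneous peak dV/Rs at the step onset sample
  on_idx <- which(tp$t_ms >= tp$pulse_onset_ms - 1e-9)[1]
  expect_equal(i[on_idx], -10 / rs * 1000, tolerance = 1e-6)
  # steady state dV/(Rs+Rm) at the end of the pulse
  end_idx <- max(which(tp$t_ms < tp$pulse_onset_ms + tp$pulse_ms))
  expect_equal(i[end_idx], -10 / (rs + rm_) * 1000, tolerance = 1e-6)
  # baseline is zero-centered
  expect_equal(mean(i[tp$t_ms < tp$pulse_onset_ms]), 0)
})

test_that("calcium traces carry the designed structure", {
  cfg <- synth_config(seed = 55, n_odors = 4, n_repeats = 3)
  ds <- make_calcium_dataset(cfg, n_mice = 2, n_dendrites_per_mouse = 3,
                             p_respond = 0.5)
  tr <- ds$traces
  expect_setequal(unique(tr$odor), c(sprintf("odor%02d", 1:4), "blank"))
  # one blank trial per repeat set
  expect_equal(sum(tr$odor == "blank" & tr$frame == 1), 2 * 3 * 3)
  expect_equal(ds$meta$odor_onset_frame, 41)  # 10 s baseline at 4 Hz
  # blanks carry no transient
  expect_true(all(!ds$ground_truth$responsive[ds$ground_truth$odor == "blank"]))
  expect_error(make_calcium_dataset(cfg, 1, 1, noise_sd = 0), "noise_sd")
  expect_error(make_calcium_dataset(cfg, 1, 1, p_respond = 2), "p_respond")
})

test_that("photobleaching drift is monotone and exponential when requested", {
  cfg <- synth_config(seed = 56, n_odors = 1, n_repeats = 1)
  ds <- make_calcium_dataset(cfg, 1, 1, p_respond = 0, noise_sd = 1e-9,
                             bleach_tau_s = 30, f0 = 100)
  f <- ds$traces$F[ds$traces$odor == "blank"]
  expect_lt(f[length(f)], f[1])
  t <- (seq_along(f) - 1) / 4
  expect_equal(f, 100 * exp(-t / 30), tolerance = 1e-6)
})

test_that("the injected transient amplitude survives the analysis chain", {
  cfg <- synth_config(seed = 57, n_odors = 2, n_repeats = 4)
  amp <- 2; noise <- 10
  ds <- make_calcium_dataset(cfg, 2, 6, p_respond = 1, amp_sd_units = amp,
                             noise_sd = noise)
  rm_ <- response_matrix(ds$traces, ds$meta)
  fr <- ds$meta$frame_rate_hz; onset <- ds$meta$odor_onset_frame
  win_t <- (seq(onset, onset + 5 * fr - 1) - onset) / fr
  kern_avg <- mean(gcamp_kernel(win_t))
  expect_equal(mean(rm_$responses$response), amp * kern_avg, tolerance = 0.15)
})

test_that("biased movies put more microglia on mushroom spines than chance", {
  cfg <- synth_config(seed = 58, image_size_px = 128)
  mv <- make_contact_movie(cfg, n_spines = 12, bias = 5, n_frames = 8)
  cls <- mv$ground_truth$classes$class
  cov_mush <- mean(mv$ground_truth$coverage[cls == "mushroom", ])
  # matched random locations: the same ROIs under many random circular
  # shifts of the microglia channel
  set.seed(1)
  g <- data.frame(dx = sample(32:96, 25), dy = sample(32:96, 25),
                  mode = "random", magnitude = NA)
  null_cov <- offset_statistics(mv, g, statistic = "mean_coverage",
                                class_filter = "mushroom")
  expect_gt(cov_mush, max(null_cov))
})

test_that("spine polygons always rasterize inside the field", {
  for (seed in 1:5) {
    cfg <- synth_config(seed = seed, image_size_px = 80)
    mv <- make_contact_movie(cfg, n_spines = 8, n_frames = 2)
    for (r in mv$rois) {
      expect_true(all(r$x >= 0 & r$x <= 79 & r$y >= 0 & r$y <= 79))
    }
  }
})

test_that("movies, ROIs and traces round-trip through their file formats", {
  skip_if_not_installed("tiff")
  cfg <- synth_config(seed = 70, image_size_px = 64, n_odors = 2,
                      n_repeats = 2)
  mv <- make_contact_movie(cfg, 4, n_frames = 3)
  tmp <- withr::local_tempfile(fileext = ".tif")
  write_contact_movie(mv, tmp)
  back <- read_contact_movie(tmp, n_frames = 3)
  expect_identical(back$microglia, mv$microglia)
  expect_equal(back$dendrite, mv$dendrite, tolerance = 1e-3)

  rj <- withr::local_tempfile(fileext = ".json")
  write_rois_json(mv$rois, rj)
  rois2 <- read_rois_json(rj)
  expect_equal(lapply(rois2, `[[`, "x"), lapply(mv$rois, `[[`, "x"))
  expect_equal(vapply(rois2, `[[`, "", "class"),
               vapply(mv$rois, `[[`, "", "class"))

  ds <- make_calcium_dataset(cfg, 1, 1)
  tc <- withr::local_tempfile(fileext = ".csv")
  write_traces_csv(ds$traces, tc)
  expect_equal(read_traces_csv(tc), `rownames<-`(ds$traces, NULL),
               tolerance = 1e-12)

  gj <- withr::local_tempfile(fileext = ".json")
  write_ground_truth_json(ds$ground_truth, gj)
  gt2 <- jsonlite::read_json(gj, simplifyVector = TRUE)
  expect_equal(gt2$responsive, ds$ground_truth$responsive)
})

test_that("the empirical event rate matches the Poisson intensity", {
  train <- make_event_train(30, 300, seed = 99)
  expect_equal(length(train$time_ms) / 300, 30, tolerance = 0.05)
  empty <- make_event_train(0, 100, seed = 1)
  expect_equal(length(empty$time_ms), 0L)
})
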