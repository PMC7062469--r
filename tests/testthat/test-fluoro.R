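test_that("frame QC applies the state-specific similarity rules", {
  # identity frame is kept
  expect_true(frame_qc(1.0, 1.0, 1.0, "anesthetized")$keep)
  # anesthetized: 30% deviation from the best-trial mean exceeds 25%
  q <- frame_qc(0.70, 1.0, 0.70, "anesthetized")
  expect_false(q$keep)
  expect_equal(q$reason, "cosine_vs_best")
  # awake: 26% deviation is under the 30% limit (and matches its baseline)
  expect_true(frame_qc(0.74, 1.0, 0.74, "awake")$keep)
  # but the same frame fails the anesthetized 25% rule
  expect_false(frame_qc(0.74, 1.0, 0.74, "anesthetized")$keep)
  # baseline rule: 18% deviation passes anesthetized (20%) but not awake (15%)
  expect_true(frame_qc(0.82, 1.0, 1.0, "anesthetized")$keep)
  q2 <- frame_qc(0.82, 1.0, 1.0, "awake")
  expect_false(q2$keep)
  expect_equal(q2$reason, "cosine_vs_baseline")
  expect_error(frame_qc(0.5, 0, 1), "zero reference")
})

test_that("trial QC discards dim, shifted, and under-sampled trials", {
  expect_equal(trial_qc(0.4, 1, 1, ref_brightness = 1, first_trial_sd = 1)$reason,
               "dim")
  expect_equal(trial_qc(1, 10, 14, ref_brightness = 1, first_trial_sd = 1)$reason,
               "brightness_shift")
  q <- trial_qc(1, 1, 1, ref_brightness = 1, first_trial_sd = 1,
                frac_frames_analysis = 14 / 20)
  expect_equal(q$reason, "insufficient_frames")
  expect_true(trial_qc(1, 1, 1, ref_brightness = 1, first_trial_sd = 1)$keep)
  expect_error(trial_qc(1, 1, 1, ref_brightness = NA, first_trial_sd = 1),
               "3 trials")
})

test_that("bleach correction fits only rising baselines and recovers the endpoint", {
  fr <- 4
  flat <- rep(10, 40)
  b <- bleach_correct(flat + rnorm(40, 0, 1e-9), fr)
  expect_equal(b$f0, 10, tolerance = 1e-6)
  expect_false(b$fitted)

  # known rising exponential: F0 should match the generating curve's endpoint
  t <- (0:39) / fr
  curve <- 5 * exp(0.08 * t) + 4
  set.seed(1)
  b2 <- bleach_correct(curve + rnorm(40, 0, 0.05), fr)
  expect_true(b2$fitted)
  expect_equal(b2$f0, 5 * exp(0.08 * t[40]) + 4, tolerance = 0.02)

  # ratio exactly 1.1 does not trigger (strict >)
  k <- round(2.5 * fr)
  v <- c(rep(10, 20), rep(11, 20))  # last 2.5 s mean exactly 1.1 x first
  b3 <- bleach_correct(v, fr)
  expect_false(b3$fitted)
  expect_equal(b3$f0, mean(v))

  # falling direction triggers the fit instead when requested
  fall <- rev(curve)
  expect_true(bleach_correct(fall, fr, direction = "falling")$fitted)
  expect_false(bleach_correct(fall, fr)$fitted)
  expect_error(bleach_correct(rep(10, 10), fr), "5 s")
})

test_that("dF/F-sigma responses average the analysis window", {
  fr <- 4
  f <- c(rep(10, 40), rep(12, 20), rep(10, 12))
  dff <- dff_sigma(f, f0 = 10, f_sigma = 1)
  expect_equal(response_value(dff, onset_frame = 41, frame_rate_hz = fr), 2)
  expect_equal(response_value(rep(0, 72), 41, fr), 0)
  expect_error(dff_sigma(f, 10, 0), "degenerate")
  # dropped frames are excluded from the mean, not interpolated
  keep <- rep(TRUE, 72); keep[41:50] <- FALSE
  expect_equal(response_value(dff, 41, fr, keep = keep), 2)
  keep[41:60] <- FALSE
  expect_true(is.na(response_value(dff, 41, fr, keep = keep)))
})

test_that("responses are invariant to an affine gain on raw fluorescence", {
  set.seed(3)
  f <- 100 + rnorm(80, 0, 5)
  f[41:60] <- f[41:60] + 12
  resp <- function(x) {
    bl <- x[1:40]
    response_value(dff_sigma(x, mean(bl), sd(bl)), 41, 4)
  }
  expect_equal(resp(f * 3.7), resp(f), tolerance = 1e-12)
})

test_that("ROI noise rule keeps F-sigma at or below 30% of baseline mean", {
  expect_true(roi_qc(2.9, 10))
  expect_false(roi_qc(3.5, 10))
  expect_true(roi_qc(3.0, 10))
  expect_error(roi_qc(1, 0), "> 0")
})

test_that("sniff rate counts peaks with a refractory interval", {
  fs <- 100
  t <- seq(0, 10 - 1 / fs, by = 1 / fs)
  expect_equal(sniff_rate(sin(2 * pi * 4 * t), fs), 4, tolerance = 0.03)
  expect_equal(sniff_rate(rep(0, 1000), fs), 0)
  # two candidate peaks 0.05 s apart merge into one
  x <- rep(0, 200)
  x[c(100, 105)] <- 1
  expect_equal(sniff_rate(x, fs) * 2, 1)
  expect_error(sniff_rate(c(0, 1), fs), "shorter")
})

test_that("QC rules are idempotent on already-filtered data", {
  set.seed(11)
  sims <- pmin(1, 0.95 + rnorm(50, 0, 0.05))
  q1 <- frame_qc(sims, mean(sims), mean(sims[1:10]), "anesthetized")
  kept <- sims[q1$keep]
  q2 <- frame_qc(kept, mean(sims), mean(sims[1:10]), "anesthetized")
  expect_true(all(q2$keep))
})

test_that("response_matrix recovers injected transients and flags noisy ROIs", {
  cfg <- synth_config(seed = 21, n_odors = 4, n_repeats = 3)
  ds <- make_calcium_dataset(cfg, n_mice = 1, n_dendrites_per_mouse = 4,
                             p_respond = 0.5, amp_sd_units = 2, noise_sd = 8)
  rm_ <- response_matrix(ds$traces, ds$meta)
  expect_true(all(is.finite(rm_$responses$response)))
  expect_equal(nrow(rm_$responses) + 0L,
               length(unique(paste(rm_$responses$mouse, rm_$responses$dendrite))) * 4L)
  # analytic check: a responsive pair's mean response ~ amplitude x the
  # window-average of the unit-peak kernel
  fr <- ds$meta$frame_rate_hz
  onset <- ds$meta$odor_onset_frame
  win <- onset:(onset + 5 * fr - 1)
  kern_avg <- mean(gcamp_kernel(((win - 1) - (onset - 1)) / fr))
  gt <- ds$ground_truth
  merged <- merge(rm_$responses, gt, by = c("mouse", "dendrite", "odor"))
  resp_on <- merged$response[merged$responsive]
  resp_off <- merged$response[!merged$responsive]
  expect_equal(mean(resp_on), 2 * kern_avg, tolerance = 0.25)
  expect_lt(abs(mean(resp_off)), 0.35)
  # blanks present for every retained dendrite
  expect_setequal(unique(rm_$blanks$dendrite), unique(rm_$responses$dendrite))
})

test_that("flat traces from a single dendrite give an all-zero response row", {
  cfg <- synth_config(seed = 5, n_odors = 3, n_repeats = 2)
  ds <- make_calcium_dataset(cfg, 1, 1, p_respond = 0, noise_sd = 1e-6, f0 = 100)
  # replace noise with tiny fixed jitter so F_sigma > 0 but responses ~ 0
  rm_ <- response_matrix(ds$traces, ds$meta)
  expect_equal(nrow(rm_$responses), 3L)
  expect_true(all(abs(rm_$responses$response) < 1))
})
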