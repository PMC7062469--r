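test_that("passive properties are recovered from noiseless RC pulses", {
  cases <- list(c(10, 500, 14), c(25, 200, 30), c(15, 300, 25))
  for (cs in cases) {
    tp <- make_rc_testpulse(cs[1], cs[2], cs[3], noise_pa = 0, seed = 1,
                            n_repetitions = 1)
    pp <- estimate_passive_properties(tp)
    expect_equal(pp$rs_mohm, cs[1], tolerance = 0.05)
    expect_equal(pp$rm_mohm, cs[2], tolerance = 0.05)
    expect_equal(pp$cm_pf, cs[3], tolerance = 0.05)
    expect_equal(pp$tau_ms, tp$truth$tau_ms, tolerance = 0.05)
  }
})

test_that("passive properties are recovered within 10% at 2 pA noise over 50 reps", {
  tp <- make_rc_testpulse(10, 500, 14, noise_pa = 2, seed = 7,
                          n_repetitions = 50)
  pp <- estimate_passive_properties(tp)
  expect_equal(pp$rs_mohm, 10, tolerance = 0.10)
  expect_equal(pp$rm_mohm, 500, tolerance = 0.10)
  expect_equal(pp$cm_pf, 14, tolerance = 0.10)
})

test_that("the open-circuit and pure-resistor limits behave", {
  # rm -> infinity: steady-state current ~ 0
  tp <- make_rc_testpulse(10, 1e9, 14, noise_pa = 0, seed = 1,
                          n_repetitions = 1)
  in_ss <- tp$t_ms >= tp$pulse_onset_ms + 0.8 * tp$pulse_ms &
    tp$t_ms < tp$pulse_onset_ms + tp$pulse_ms
  expect_lt(max(abs(colMeans(tp$i_pa)[in_ss])), 0.1)

  # no capacitive transient: tau ~ 0, Cm ~ 0, Rm = dV/I - Rs (here 0)
  flat <- make_rc_testpulse(10, 500, 14, noise_pa = 0, seed = 1,
                            n_repetitions = 1)
  i_ss <- -10 / 510 * 1000
  flat$i_pa[, flat$t_ms >= flat$pulse_onset_ms &
                flat$t_ms < flat$pulse_onset_ms + flat$pulse_ms] <- i_ss
  flat$i_pa[, flat$t_ms >= flat$pulse_onset_ms + flat$pulse_ms] <- 0
  pp <- estimate_passive_properties(flat)
  expect_equal(pp$tau_ms, 0)
  expect_equal(pp$cm_pf, 0)
  expect_equal(pp$rm_mohm, abs(-10 / i_ss * 1000) - pp$rs_mohm)
})

test_that("the series-resistance inclusion rule flags high-Rs cells", {
  tp_bad <- make_rc_testpulse(55, 500, 14, noise_pa = 0, seed = 1,
                              n_repetitions = 1)
  expect_false(estimate_passive_properties(tp_bad)$passes_rs_inclusion)
  tp_ok <- make_rc_testpulse(45, 500, 14, noise_pa = 0, seed = 1,
                             n_repetitions = 1)
  expect_true(estimate_passive_properties(tp_ok)$passes_rs_inclusion)
})

test_that("sweep QC drops deviant sweeps and excludes under-sampled cells", {
  sw <- data.frame(sweep_id = 1:4, rs_mohm = c(10, 10, 10, 13),
                   holding_pa = c(-20, -20, -20, -20))
  q <- sweep_qc(sw)
  expect_equal(q$sweeps$keep, c(TRUE, TRUE, TRUE, FALSE))  # 30% > 25%
  expect_equal(q$sweeps$reason[4], "rs_deviation")
  expect_true(q$cell_keep)

  sw$rs_mohm[4] <- 12  # 20% deviation is fine
  expect_true(all(sweep_qc(sw)$sweeps$keep))

  sw$holding_pa[2] <- -120
  q2 <- sweep_qc(sw)
  expect_false(q2$sweeps$keep[2])
  expect_equal(q2$sweeps$reason[2], "holding_current")

  # 14 of 30 kept (47%) -> cell excluded
  sw3 <- data.frame(sweep_id = 1:30, rs_mohm = c(rep(10, 14), rep(14, 16)),
                    holding_pa = 0)
  q3 <- sweep_qc(sw3)
  expect_equal(sum(q3$sweeps$keep), 14L)
  expect_false(q3$cell_keep)
  expect_error(sweep_qc(sw3[1:2, ]), "3 sweeps")
  # QC changes membership only, never values
  expect_identical(q3$sweeps$rs_mohm, sw3$rs_mohm)
})

test_that("band-stop conditioning meets its attenuation contract", {
  fs <- 5000
  t <- seq(0, 2, by = 1 / fs)
  mid <- seq(round(length(t) * 0.25), round(length(t) * 0.75))
  rms <- function(x) sqrt(mean(x^2))
  for (f in c(60, 120, 180, 240, 300)) {
    x <- sin(2 * pi * f * t)
    y <- bandstop_condition(x, fs)
    expect_lt(rms(y[mid]) / rms(x[mid]), 0.10)  # >= 20 dB down
  }
  for (f in c(30, 1000)) {
    x <- sin(2 * pi * f * t)
    y <- bandstop_condition(x, fs)
    expect_lt(abs(20 * log10(rms(y[mid]) / rms(x[mid]))), 1)  # within 1 dB
  }
  dc <- rep(3.5, 1000)
  expect_equal(bandstop_condition(dc, fs), dc, tolerance = 1e-6)
  expect_error(bandstop_condition(rnorm(100), 500), "sample rate")
})

test_that("doublet exclusion keeps the first event of every run", {
  expect_equal(doublet_exclusion(c(0, 10, 20))$keep, rep(TRUE, 3))
  expect_equal(doublet_exclusion(c(0, 2, 10))$keep, c(TRUE, FALSE, TRUE))
  # sequential rule: 4 - 0 >= 3, so the third event survives
  expect_equal(doublet_exclusion(c(0, 2, 4))$keep, c(TRUE, FALSE, TRUE))
  expect_error(doublet_exclusion(c(5, 1)), "sorted")
})

test_that("doublet exclusion leaves no interval below the cutoff (property)", {
  set.seed(8)
  for (i in 1:20) {
    train <- make_event_train(20, 10, doublet_fraction = 0.2, seed = i)
    d <- doublet_exclusion(train$time_ms)
    kept <- d$time_ms[d$keep]
    if (length(kept) > 1) expect_true(all(diff(kept) >= 3))
    expect_equal(nrow(d), length(train$time_ms))  # flagged, never dropped
  }
})

test_that("planted doublets are removed at roughly their planted fraction", {
  train <- make_event_train(2, 500, doublet_fraction = 0.1, seed = 42)
  d <- doublet_exclusion(train$time_ms)
  n_planted <- sum(train$is_doublet)
  expect_equal(sum(!d$keep), n_planted, tolerance = 0.25)
})

test_that("train summaries respect masks and recover Poisson rates", {
  s <- train_summary(seq(0, 9990, by = 33.3), duration_ms = 10000)
  expect_equal(s$frequency_hz, length(seq(0, 9990, by = 33.3)) / 10)

  train <- make_event_train(30, 300, seed = 3)
  s2 <- train_summary(train$time_ms, train$amplitude_pa, train$duration_ms)
  expect_equal(s2$frequency_hz, 30, tolerance = 0.05)

  # mask half the record: rate computed on the remaining half only
  masks <- data.frame(start_ms = 0, end_ms = 150000)
  s3 <- train_summary(train$time_ms, train$amplitude_pa, train$duration_ms,
                      masks = masks)
  expect_equal(s3$unmasked_s, 150)
  expect_equal(s3$frequency_hz, 30, tolerance = 0.10)
  expect_true(all(s3$amplitudes_pa %in% train$amplitude_pa))
  expect_error(train_summary(1:3, duration_ms = 100,
                             masks = data.frame(start_ms = 0, end_ms = 100)),
               "> 0")
})
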