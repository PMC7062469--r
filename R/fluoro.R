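#' Per-frame motion quality control from cosine similarities
#'
#' Frames are scored by the cosine similarity between each motion-corrected
#' frame and a reference projection (the similarities may be supplied
#' directly as a scalar series). A frame is discarded when its similarity
#' deviates from the best-trial mean by more than 25% (30% for awake
#' imaging) or from that trial's baseline-period mean by more than 20%
#' (15% for awake imaging), in relative absolute terms.
#'
#' @param similarities Numeric vector of per-frame cosine similarities in
#'   `[-1, 1]`.
#' @param best_trial_mean Mean similarity of the reference ("best") trial.
#' @param baseline_mean Mean similarity over the trial's baseline period.
#' @param state `"anesthetized"` or `"awake"`; selects the thresholds.
#' @return data.frame: `frame`, `keep`, `reason` (`""`, `"cosine_vs_best"`,
#'   or `"cosine_vs_baseline"`; one primary reason per discarded frame).
#' @export
frame_qc <- function(similarities, best_trial_mean, baseline_mean,
                     state = c("anesthetized", "awake")) {
  state <- match.arg(state)
  if (any(abs(similarities) > 1, na.rm = TRUE)) {
    stop("cosine similarities must lie in [-1, 1]", call. = FALSE)
  }
  if (best_trial_mean == 0 || baseline_mean == 0) {
    stop("zero reference mean: relative deviation undefined", call. = FALSE)
  }
  thr_best <- if (state == "anesthetized") 0.25 else 0.30
  thr_base <- if (state == "anesthetized") 0.20 else 0.15
  dev_best <- abs(similarities - best_trial_mean) / abs(best_trial_mean)
  dev_base <- abs(similarities - baseline_mean) / abs(baseline_mean)
  bad_best <- dev_best > thr_best
  bad_base <- dev_base > thr_base
  reason <- ifelse(bad_best, "cosine_vs_best",
                   ifelse(bad_base, "cosine_vs_baseline", ""))
  data.frame(frame = seq_along(similarities),
             keep = !(bad_best | bad_base), reason = reason)
}

#' Per-trial brightness and frame-count quality control
#'
#' A trial is discarded when (i) its average brightness falls below half
#' the mean brightness of the first three trials, (ii) the difference in
#' brightness between its baseline and odor periods exceeds three times the
#' brightness SD of the first trial, or (iii) fewer than 75% of the
#' original frames survive frame QC in either the baseline or the odor
#' analysis period.
#'
#' @param brightness Trial mean brightness (on kept frames).
#' @param baseline_brightness,odor_brightness Period means for this trial.
#' @param ref_brightness Mean brightness of the first three trials.
#' @param first_trial_sd Brightness SD of the first trial.
#' @param frac_frames_baseline,frac_frames_analysis Surviving-frame
#'   fractions in the two periods.
#' @param min_frac Minimum surviving fraction (default 0.75).
#' @return List: `keep` (logical), `reason` (`""`, `"dim"`,
#'   `"brightness_shift"`, or `"insufficient_frames"`).
#' @export
trial_qc <- function(brightness, baseline_brightness, odor_brightness,
                     ref_brightness, first_trial_sd,
                     frac_frames_baseline = 1, frac_frames_analysis = 1,
                     min_frac = 0.75) {
  if (is.na(ref_brightness)) {
    stop("reference brightness requires at least 3 trials", call. = FALSE)
  }
  if (brightness < 0.5 * ref_brightness) {
    return(list(keep = FALSE, reason = "dim"))
  }
  if (abs(baseline_brightness - odor_brightness) > 3 * first_trial_sd) {
    return(list(keep = FALSE, reason = "brightness_shift"))
  }
  if (frac_frames_baseline < min_frac || frac_frames_analysis < min_frac) {
    return(list(keep = FALSE, reason = "insufficient_frames"))
  }
  list(keep = TRUE, reason = "")
}

#' Baseline estimate with drift correction
#'
#' Returns the baseline fluorescence F0 for a trial. When the mean over the
#' last 2.5 s of the baseline exceeds 1.1 times the mean over the first
#' 2.5 s (`direction = "rising"`, the rule as printed; set
#' `direction = "falling"` to trigger on decaying baselines instead), a
#' single exponential `a * exp(b * t) + c` is fitted to the baseline
#' segment and its value at the end of the baseline is taken as F0;
#' otherwise F0 is the plain baseline mean. A failed fit falls back to the
#' plain mean with a warning.
#'
#' @param baseline_f Baseline-segment fluorescence (>= 5 s of frames).
#' @param frame_rate_hz Frame rate in Hz.
#' @param ratio Trigger ratio (default 1.1; strictly greater-than).
#' @param direction Which drift direction triggers the fit.
#' @return List: `f0`, `fitted` (logical), `f_sigma` (baseline SD).
#' @export
bleach_correct <- function(baseline_f, frame_rate_hz, ratio = 1.1,
                           direction = c("rising", "falling")) {
  direction <- match.arg(direction)
  n <- length(baseline_f)
  k <- round(2.5 * frame_rate_hz)
  if (n < 2 * k) stop("baseline must be at least 5 s long", call. = FALSE)
  first <- mean(baseline_f[seq_len(k)])
  last <- mean(baseline_f[(n - k + 1):n])
  trigger <- if (direction == "rising") last > ratio * first
             else first > ratio * last
  f0 <- mean(baseline_f)
  fitted <- FALSE
  if (trigger) {
    t <- (seq_len(n) - 1) / frame_rate_hz
    t_end <- (n - 1) / frame_rate_hz
    fit <- tryCatch({
      b0 <- if (direction == "rising") 0.1 else -0.1
      m <- minpack.lm::nlsLM(
        y ~ a * exp(b * t) + c,
        data = data.frame(y = baseline_f, t = t),
        start = list(a = (last - first) / 2, b = b0, c = first),
        control = minpack.lm::nls.lm.control(maxiter = 200)
      )
      stats::predict(m, newdata = data.frame(t = t_end))
    }, error = function(e) NULL)
    if (is.null(fit) || !is.finite(fit)) {
      warning("exponential baseline fit failed; using plain baseline mean")
    } else {
      f0 <- as.numeric(fit)
      fitted <- TRUE
    }
  }
  list(f0 = f0, fitted = fitted, f_sigma = stats::sd(baseline_f))
}

#' Normalize a trace to baseline-SD units and extract the odor response
#'
#' `dff_sigma()` converts raw fluorescence to `(F - F0) / F_sigma`;
#' `response_value()` averages the surviving frames of the odor analysis
#' window (5 s following odor onset by default; missing frames are dropped
#' from the mean, not interpolated).
#'
#' @param f Raw fluorescence trace.
#' @param f0 Baseline mean (see [bleach_correct()]).
#' @param f_sigma Baseline SD (> 0).
#' @return Normalized trace.
#' @export
dff_sigma <- function(f, f0, f_sigma) {
  if (!is.finite(f_sigma) || f_sigma <= 0) {
    stop("F_sigma must be > 0 (degenerate baseline)", call. = FALSE)
  }
  (f - f0) / f_sigma
}

#' @rdname dff_sigma
#' @param dff Normalized trace from `dff_sigma()`.
#' @param onset_frame First odor frame (1-based).
#' @param frame_rate_hz Frame rate in Hz.
#' @param analysis_window_s Analysis window length in seconds (default 5).
#' @param keep Logical per-frame keep flags (default all).
#' @return Mean normalized response over the analysis window.
#' @export
response_value <- function(dff, onset_frame, frame_rate_hz,
                           analysis_window_s = 5, keep = NULL) {
  idx <- seq(onset_frame,
             min(length(dff), onset_frame + round(analysis_window_s * frame_rate_hz) - 1L))
  keep <- keep %||% rep(TRUE, length(dff))
  idx <- idx[keep[idx]]
  if (length(idx) == 0L) return(NA_real_)
  mean(dff[idx])
}

#' ROI noise criterion
#'
#' An ROI is kept only if its baseline SD does not exceed 30% of its mean
#' baseline fluorescence; noisier ROIs are removed from the analysis.
#'
#' @param f_sigma Baseline SD.
#' @param baseline_mean Mean baseline fluorescence (> 0).
#' @param max_ratio Maximum allowed `f_sigma / baseline_mean` (default 0.3).
#' @return `TRUE` to keep the ROI.
#' @export
roi_qc <- function(f_sigma, baseline_mean, max_ratio = 0.30) {
  if (baseline_mean <= 0) stop("baseline mean must be > 0", call. = FALSE)
  f_sigma <= max_ratio * baseline_mean
}

#' Respiration rate from a breathing trace
#'
#' Counts local maxima with an enforced minimum inter-peak interval
#' (0.1 s, i.e. a 10 Hz ceiling) and reports peaks per second over the
#' window.
#'
#' @param resp Respiration trace.
#' @param sample_rate_hz Sampling rate.
#' @param min_peak_interval_s Minimum inter-peak interval (default 0.1 s).
#' @return Sniff rate in Hz.
#' @export
sniff_rate <- function(resp, sample_rate_hz, min_peak_interval_s = 0.1) {
  duration_s <- length(resp) / sample_rate_hz
  if (duration_s < min_peak_interval_s) {
    stop("window shorter than the minimum peak interval", call. = FALSE)
  }
  pk <- pracma::findpeaks(as.numeric(resp),
                          minpeakdistance = max(1L, round(min_peak_interval_s * sample_rate_hz)))
  n <- if (is.null(pk)) 0L else nrow(pk)
  n / duration_s
}

#' Trial-averaged response matrix from long-format traces
#'
#' Runs the per-trial pipeline (baseline F0 with drift correction, ROI
#' noise QC, delta-F over F-sigma, analysis-window mean) over a long-format
#' trace table and averages across trials, yielding one mean response per
#' dendrite x odor plus the blank-trial responses. Dendrites failing the
#' ROI noise rule are dropped with their exclusion counted.
#'
#' @param traces Long data.frame: mouse, dendrite, odor, trial, frame, F.
#' @param meta List with `frame_rate_hz`, `n_baseline_frames`,
#'   `odor_onset_frame`, `analysis_window_s` (as in
#'   [make_calcium_dataset()]).
#' @param blank_label Odor id of the no-odor trials (default `"blank"`).
#' @param bleach_direction Passed to [bleach_correct()].
#' @return List of class `response_matrix`: `responses` (data.frame mouse,
#'   dendrite, odor, response, n_trials), `blanks` (same shape, blank
#'   trials; one row per trial), `excluded_rois` (data.frame with reason),
#'   `meta`.
#' @export
response_matrix <- function(traces, meta, blank_label = "blank",
                            bleach_direction = "rising") {
  fr <- meta$frame_rate_hz
  n_bl <- meta$n_baseline_frames
  onset <- meta$odor_onset_frame
  win_s <- meta$analysis_window_s %||% 5

  key <- interaction(traces$mouse, traces$dendrite, drop = TRUE)
  out <- list(); blanks <- list(); excl <- list()
  for (roi in levels(key)) {
    sub <- traces[key == roi, , drop = FALSE]
    # ROI noise rule on the pooled baseline of all trials
    bl_all <- sub$F[sub$frame <= n_bl]
    if (!roi_qc(stats::sd(bl_all), mean(bl_all))) {
      excl[[roi]] <- data.frame(mouse = sub$mouse[1], dendrite = sub$dendrite[1],
                                reason = "noisy")
      next
    }
    tkey <- interaction(sub$odor, sub$trial, drop = TRUE)
    per_trial <- lapply(levels(tkey), function(tk) {
      tt <- sub[tkey == tk, , drop = FALSE]
      tt <- tt[order(tt$frame), , drop = FALSE]
      bc <- bleach_correct(tt$F[seq_len(n_bl)], fr, direction = bleach_direction)
      if (bc$f_sigma <= 0) return(NULL)
      dff <- dff_sigma(tt$F, bc$f0, bc$f_sigma)
      data.frame(mouse = tt$mouse[1], dendrite = tt$dendrite[1],
                 odor = tt$odor[1], trial = tt$trial[1],
                 response = response_value(dff, onset, fr, win_s))
    })
    per_trial <- do.call(rbind, per_trial)
    is_blank <- per_trial$odor == blank_label
    blanks[[roi]] <- per_trial[is_blank, , drop = FALSE]
    agg <- stats::aggregate(response ~ mouse + dendrite + odor,
                            data = per_trial[!is_blank, , drop = FALSE], FUN = mean)
    cnt <- stats::aggregate(response ~ mouse + dendrite + odor,
                            data = per_trial[!is_blank, , drop = FALSE], FUN = length)
    agg$n_trials <- cnt$response
    out[[roi]] <- agg
  }
  structure(
    list(responses = do.call(rbind, out),
         blanks = do.call(rbind, blanks),
         excluded_rois = if (length(excl)) do.call(rbind, excl) else
           data.frame(mouse = character(), dendrite = character(), reason = character()),
         meta = meta),
    class = "response_matrix"
  )
}
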