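#' GCaMP-like calcium transient kernel
#'
#' Difference-of-exponentials kernel (rise 0.2 s, decay 1.5 s by default,
#' plausible for GCaMP6s), normalized to unit peak. The analysis pipeline is
#' insensitive to the exact kernel; tests only rely on its closed form.
#'
#' @param t_s Time since transient onset, seconds (values < 0 give 0).
#' @param rise_s,decay_s Rise and decay time constants in seconds.
#' @return Kernel values, unit peak.
#' @export
gcamp_kernel <- function(t_s, rise_s = 0.2, decay_s = 1.5) {
  raw <- function(t) ifelse(t < 0, 0, exp(-t / decay_s) - exp(-t / rise_s))
  t_pk <- log(decay_s / rise_s) / (1 / rise_s - 1 / decay_s)
  raw(t_s) / raw(t_pk)
}

#' Simulate a trial-structured odor-response calcium dataset
#'
#' Emulates 4 Hz two-photon ROI traces: a baseline segment, a 2 s odor
#' window, and a decay, for every mouse x dendrite x odor x trial, plus one
#' "no odor" (blank) trial per repeat set. Responsive dendrite-odor pairs
#' (drawn with probability `p_respond`) carry a [gcamp_kernel()] transient
#' whose amplitude is `amp_sd_units` baseline standard deviations; optional
#' monotone exponential drift emulates photobleaching.
#'
#' @param cfg A [synth_config()] (frame rate, odor panel, repeats, seed).
#' @param n_mice,n_dendrites_per_mouse Nesting structure.
#' @param p_respond Probability a dendrite-odor pair is responsive.
#' @param amp_sd_units Transient amplitude in units of baseline SD.
#' @param bleach_tau_s Exponential drift time constant in seconds, or `NULL`
#'   for a flat baseline.
#' @param noise_sd Gaussian noise SD in raw fluorescence units (> 0).
#' @param f0 Baseline fluorescence level (a.u.).
#' @param baseline_s,odor_s,analysis_s,post_s Segment durations in seconds.
#' @return List of class `calcium_dataset`: `traces` (long data.frame with
#'   columns mouse, dendrite, odor, trial, frame, F; odor `"blank"` marks
#'   no-odor trials), `meta` (frame rate and window layout, in frames), and
#'   `ground_truth` (per pair: responsive flag and amplitude in SD units).
#' @examples
#' cfg <- synth_config(seed = 3, n_odors = 4, n_repeats = 2)
#' ds <- make_calcium_dataset(cfg, n_mice = 1, n_dendrites_per_mouse = 2)
#' head(ds$traces)
#' @export
make_calcium_dataset <- function(cfg, n_mice, n_dendrites_per_mouse,
                                 p_respond = 0.3, amp_sd_units = 3,
                                 bleach_tau_s = NULL, noise_sd = 10,
                                 f0 = 100, baseline_s = 10, odor_s = 2,
                                 analysis_s = 5, post_s = 3) {
  stopifnot(inherits(cfg, "synth_config"))
  if (p_respond < 0 || p_respond > 1) stop("`p_respond` must be in [0, 1]", call. = FALSE)
  stop_if_not_scalar_number(noise_sd, "noise_sd", positive = TRUE)
  fr <- cfg$frame_rate_hz
  n_bl <- round(baseline_s * fr)
  n_total <- round((baseline_s + analysis_s + post_s) * fr)
  onset <- n_bl + 1L  # first odor frame (windows half-open in frames)
  t_all <- (seq_len(n_total) - 1) / fr

  odors <- c(sprintf("odor%02d", seq_len(cfg$n_odors)), "blank")
  with_seed(child_seed(cfg$seed, "calcium"), {
    gt <- expand.grid(
      mouse = sprintf("m%02d", seq_len(n_mice)),
      dendrite = sprintf("d%02d", seq_len(n_dendrites_per_mouse)),
      odor = odors, stringsAsFactors = FALSE
    )
    gt$responsive <- ifelse(gt$odor == "blank", FALSE,
                            stats::runif(nrow(gt)) < p_respond)
    gt$amplitude_sd <- ifelse(gt$responsive, amp_sd_units, 0)

    drift <- if (is.null(bleach_tau_s)) rep(1, n_total) else exp(-t_all / bleach_tau_s)
    kern <- gcamp_kernel(t_all - (onset - 1) / fr)

    rows <- vector("list", nrow(gt) * cfg$n_repeats)
    k <- 0L
    for (i in seq_len(nrow(gt))) {
      amp_f <- gt$amplitude_sd[i] * noise_sd
      for (tr in seq_len(cfg$n_repeats)) {
        f <- f0 * drift + amp_f * kern + stats::rnorm(n_total, 0, noise_sd)
        k <- k + 1L
        rows[[k]] <- data.frame(
          mouse = gt$mouse[i], dendrite = gt$dendrite[i], odor = gt$odor[i],
          trial = tr, frame = seq_len(n_total), F = f,
          stringsAsFactors = FALSE
        )
      }
    }
    traces <- do.call(rbind, rows)
    rownames(traces) <- NULL
    structure(
      list(traces = traces,
           meta = list(frame_rate_hz = fr, n_baseline_frames = n_bl,
                       odor_onset_frame = onset,
                       odor_duration_s = odor_s, analysis_window_s = analysis_s,
                       n_frames = n_total),
           ground_truth = gt),
      class = "calcium_dataset"
    )
  })
}
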