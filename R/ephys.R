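#' Passive membrane properties from a voltage-clamp test pulse
#'
#' Repetitions are averaged, then: series resistance Rs from the maximum
#' current at the beginning of the pulse (the capacitive peak, obtained by
#' extrapolating the fitted decay back to the step onset so the true
#' instantaneous peak is not missed between samples); membrane resistance
#' Rm from the steady-state current over the last 20% of the pulse
#' (total resistance minus Rs); and capacitance Cm from the time constant
#' of an exponential fit between the 20% and 80% points of the capacitive
#' decay, via the single-compartment relation `Cm = tau / (Rs || Rm)`.
#'
#' When the decay is flat (no capacitive transient above the noise), the
#' pure-resistor limit is returned: `tau = 0`, `Cm = 0`, `Rs` from the
#' total current, `Rm = 0`.
#'
#' @param pulse A `test_pulse` (see [make_rc_testpulse()]) or a list with
#'   `t_ms`, `i_pa` (repetitions x samples), `dv_mv`, `pulse_onset_ms`,
#'   `pulse_ms`.
#' @param rs_inclusion_mohm Cells at or above this initial Rs fail the
#'   standard inclusion rule (default 50 MOhm); reported as a flag only.
#' @return List of class `passive_props`: `rs_mohm`, `rm_mohm`, `cm_pf`,
#'   `tau_ms`, `passes_rs_inclusion`.
#' @examples
#' tp <- make_rc_testpulse(10, 500, 14, seed = 1)
#' estimate_passive_properties(tp)$rs_mohm
#' @export
estimate_passive_properties <- function(pulse, rs_inclusion_mohm = 50) {
  i_mean <- colMeans(pulse$i_pa)
  t <- pulse$t_ms
  onset <- pulse$pulse_onset_ms
  offset <- onset + pulse$pulse_ms
  pre <- t < onset
  in_pulse <- t >= onset & t < offset
  if (!any(pre) || !any(in_pulse)) stop("pulse window not inside trace", call. = FALSE)

  i_base <- mean(i_mean[pre])
  ss_win <- t >= (offset - 0.2 * pulse$pulse_ms) & t < offset
  i_ss <- mean(i_mean[ss_win])
  sgn <- sign(i_ss - i_base)
  if (sgn == 0) sgn <- sign(pulse$dv_mv)

  tp <- t[in_pulse]
  ip <- i_mean[in_pulse]
  decay <- sgn * (ip - i_ss)           # positive, decaying transient
  pk_idx <- which.max(decay)
  pk_samp <- decay[pk_idx]

  noise_est <- stats::sd(i_mean[pre])
  flat <- pk_samp <= max(4 * noise_est, 1e-9 * max(abs(i_ss - i_base), 1))
  if (flat) {
    r_tot <- abs(pulse$dv_mv) / abs(i_ss - i_base) * 1000
    return(structure(list(rs_mohm = r_tot, rm_mohm = 0, cm_pf = 0, tau_ms = 0,
                          passes_rs_inclusion = r_tot < rs_inclusion_mohm),
                     class = "passive_props"))
  }

  # 20-80% band of the capacitive decay, measured from the sampled peak
  lo <- 0.2 * pk_samp; hi <- 0.8 * pk_samp
  band <- which(decay <= hi & decay >= lo & seq_along(decay) >= pk_idx)
  if (length(band) < 3L) stop("too few samples in the 20-80% decay band", call. = FALSE)
  if (any(diff(decay[band]) > 0.5 * pk_samp)) {
    stop("non-monotone decay segment: exponential fit unreliable", call. = FALSE)
  }
  fit <- stats::lm(log(decay[band]) ~ tp[band])
  tau_ms <- -1 / stats::coef(fit)[[2L]]
  if (!is.finite(tau_ms) || tau_ms <= 0) stop("decay fit gave no positive time constant", call. = FALSE)
  # extrapolate the fitted exponential back to the step onset
  pk0 <- exp(stats::coef(fit)[[1L]] + stats::coef(fit)[[2L]] * onset)
  i_peak <- i_ss + sgn * pk0

  rs <- abs(pulse$dv_mv) / abs(i_peak - i_base) * 1000   # mV/pA -> MOhm
  r_tot <- abs(pulse$dv_mv) / abs(i_ss - i_base) * 1000
  rm <- r_tot - rs
  if (rm <= 0) stop("estimated Rm <= 0 (leaky seal)", call. = FALSE)
  cm_pf <- tau_ms / (rs * rm / (rs + rm)) * 1000          # ms/MOhm -> nF -> pF
  structure(list(rs_mohm = rs, rm_mohm = rm, cm_pf = cm_pf, tau_ms = tau_ms,
                 passes_rs_inclusion = rs < rs_inclusion_mohm),
            class = "passive_props")
}

#' Sweep-level quality control for voltage-clamp recordings
#'
#' Drops sweeps whose series resistance deviates from the mean of the first
#' three sweeps by more than 25% or whose holding current exceeds 100 pA in
#' magnitude (at -70 mV); the cell is excluded entirely if fewer than half
#' the sweeps remain.
#'
#' @param sweeps data.frame with columns `sweep_id`, `rs_mohm`,
#'   `holding_pa` (>= 3 rows).
#' @param rs_deviation Maximum relative Rs deviation (default 0.25).
#' @param holding_max_pa Maximum holding-current magnitude (default 100).
#' @param min_kept_fraction Cell-level survival requirement (default 0.5).
#' @return List: `sweeps` (input plus `keep`, `reason`), `cell_keep`,
#'   `ref_rs_mohm`.
#' @export
sweep_qc <- function(sweeps, rs_deviation = 0.25, holding_max_pa = 100,
                     min_kept_fraction = 0.5) {
  if (nrow(sweeps) < 3L) stop("need at least 3 sweeps for the Rs reference", call. = FALSE)
  ref <- mean(sweeps$rs_mohm[1:3])
  bad_rs <- abs(sweeps$rs_mohm - ref) / ref > rs_deviation
  bad_hold <- abs(sweeps$holding_pa) > holding_max_pa
  sweeps$keep <- !(bad_rs | bad_hold)
  sweeps$reason <- ifelse(bad_rs, "rs_deviation",
                          ifelse(bad_hold, "holding_current", ""))
  list(sweeps = sweeps,
       cell_keep = mean(sweeps$keep) >= min_kept_fraction,
       ref_rs_mohm = ref)
}

#' Line-noise band-stop conditioning
#'
#' Removes mains interference by cascading zero-phase Butterworth band-stop
#' filters at the line frequency and its harmonics (60, 120, ..., 300 Hz by
#' default). The contract is attenuation of at least 20 dB at each
#' harmonic while passing 30 Hz and 1 kHz within 1 dB.
#'
#' @param x Current trace.
#' @param sample_rate_hz Sampling rate; must exceed twice the top harmonic.
#' @param line_hz Line frequency (default 60).
#' @param n_harmonics Number of harmonics including the fundamental
#'   (default 5).
#' @param half_width_hz Half-width of each notch in Hz (default 2).
#' @return Conditioned trace.
#' @export
bandstop_condition <- function(x, sample_rate_hz, line_hz = 60,
                               n_harmonics = 5, half_width_hz = 2) {
  top <- line_hz * n_harmonics
  if (sample_rate_hz <= 2 * (top + half_width_hz)) {
    stop("sample rate too low for the requested harmonics", call. = FALSE)
  }
  out <- as.numeric(x)
  for (h in seq_len(n_harmonics)) {
    f <- line_hz * h
    w <- c(f - half_width_hz, f + half_width_hz) / (sample_rate_hz / 2)
    bf <- signal::butter(2, w, type = "stop")
    # filter around the DC level: a notch passes DC, and removing the mean
    # first avoids the zero-initial-condition edge transient on offsets
    mu <- mean(out)
    out <- signal::filtfilt(bf, out - mu) + mu
  }
  out
}

#' Exclude doubly detected events
#'
#' Sequential scan over sorted event times keeping the first event of any
#' run; an event closer than `min_separation_ms` to the last *kept* event
#' is flagged as a doublet and excluded (so of `{0, 2, 4}` ms, 0 and 4 are
#' kept). Excluded events are flagged, never silently dropped.
#'
#' @param time_ms Sorted event times in ms (errors when unsorted).
#' @param min_separation_ms Minimum separation (default 3 ms).
#' @return data.frame: `time_ms`, `keep`.
#' @examples
#' doublet_exclusion(c(0, 2, 10))
#' @export
doublet_exclusion <- function(time_ms, min_separation_ms = 3) {
  if (is.unsorted(time_ms)) stop("event times must be sorted", call. = FALSE)
  keep <- logical(length(time_ms))
  last_kept <- -Inf
  for (i in seq_along(time_ms)) {
    if (time_ms[i] - last_kept >= min_separation_ms) {
      keep[i] <- TRUE
      last_kept <- time_ms[i]
    }
  }
  data.frame(time_ms = time_ms, keep = keep)
}

#' Event-train summary over unmasked recording time
#'
#' Frequency (kept events per unmasked second), amplitude distribution, and
#' inter-event intervals, computed after removing user-noted noisy sections
#' (time masks) and any events falling inside them. Intervals are between
#' consecutive kept events.
#'
#' @param time_ms Sorted kept event times (ms).
#' @param amplitude_pa Event amplitudes (pA), parallel to `time_ms`.
#' @param duration_ms Total recording duration (ms).
#' @param masks Optional data.frame of noisy intervals with columns
#'   `start_ms`, `end_ms`.
#' @return List: `frequency_hz`, `amplitudes_pa`, `iei_ms`, `n_events`,
#'   `unmasked_s`.
#' @export
train_summary <- function(time_ms, amplitude_pa = NULL, duration_ms,
                          masks = NULL) {
  keep <- rep(TRUE, length(time_ms))
  masked_ms <- 0
  if (!is.null(masks) && nrow(masks) > 0) {
    for (i in seq_len(nrow(masks))) {
      keep <- keep & !(time_ms >= masks$start_ms[i] & time_ms < masks$end_ms[i])
      masked_ms <- masked_ms +
        max(0, min(masks$end_ms[i], duration_ms) - max(masks$start_ms[i], 0))
    }
  }
  unmasked_s <- (duration_ms - masked_ms) / 1000
  if (unmasked_s <= 0) stop("unmasked duration must be > 0", call. = FALSE)
  tk <- time_ms[keep]
  list(frequency_hz = length(tk) / unmasked_s,
       amplitudes_pa = if (is.null(amplitude_pa)) NULL else amplitude_pa[keep],
       iei_ms = if (length(tk) > 1L) diff(tk) else numeric(0),
       n_events = length(tk), unmasked_s = unmasked_s)
}
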