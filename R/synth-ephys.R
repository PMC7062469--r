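#' Simulate a voltage-clamp test pulse from a single-compartment RC cell
#'
#' Current response of the standard series-resistance/membrane RC circuit to
#' a voltage step: instantaneous peak `dV / Rs`, steady state
#' `dV / (Rs + Rm)`, and exponential relaxation with
#' `tau = Cm * Rs * Rm / (Rs + Rm)`; the step offset relaxes symmetrically.
#' White noise of SD `noise_pa` is added independently to each repetition.
#'
#' @param rs_mohm,rm_mohm Series and membrane resistance, MOhm (> 0).
#' @param cm_pf Membrane capacitance, pF (> 0).
#' @param noise_pa Gaussian noise SD in pA (>= 0).
#' @param seed Integer seed or `NULL`.
#' @param dv_mv Step amplitude in mV (default -10).
#' @param pulse_ms Step duration in ms (default 20).
#' @param n_repetitions Number of repeats (default 50).
#' @param sample_rate_hz Sampling rate (default 20 kHz).
#' @param baseline_ms,post_ms Pre- and post-step padding in ms.
#' @return List of class `test_pulse`: `t_ms`, `i_pa` (matrix, repetitions x
#'   samples), `dv_mv`, `pulse_onset_ms`, `pulse_ms`, `sample_rate_hz`, and
#'   the generating `truth` (rs, rm, cm, tau_ms).
#' @examples
#' tp <- make_rc_testpulse(10, 500, 14, noise_pa = 0, seed = 1)
#' estimate_passive_properties(tp)
#' @export
make_rc_testpulse <- function(rs_mohm, rm_mohm, cm_pf, noise_pa = 0,
                              seed = NULL, dv_mv = -10, pulse_ms = 20,
                              n_repetitions = 50L, sample_rate_hz = 20000,
                              baseline_ms = 5, post_ms = 5) {
  stop_if_not_scalar_number(rs_mohm, "rs_mohm", positive = TRUE)
  stop_if_not_scalar_number(rm_mohm, "rm_mohm", positive = TRUE)
  stop_if_not_scalar_number(cm_pf, "cm_pf", positive = TRUE)
  if (noise_pa < 0) stop("`noise_pa` must be >= 0", call. = FALSE)

  dt_ms <- 1000 / sample_rate_hz
  t_ms <- seq(0, baseline_ms + pulse_ms + post_ms, by = dt_ms)
  onset <- baseline_ms
  offset <- baseline_ms + pulse_ms

  tau_ms <- cm_pf * (rs_mohm * rm_mohm / (rs_mohm + rm_mohm)) * 1e-3
  i_pk <- dv_mv / rs_mohm * 1000                  # pA
  i_ss <- dv_mv / (rs_mohm + rm_mohm) * 1000      # pA
  step_response <- function(t) {
    ifelse(t < 0, 0, i_ss + (i_pk - i_ss) * exp(-t / tau_ms))
  }
  clean <- step_response(t_ms - onset) - step_response(t_ms - offset)

  i_pa <- with_seed(seed, {
    m <- matrix(rep(clean, each = n_repetitions), nrow = n_repetitions)
    if (noise_pa > 0) m <- m + matrix(stats::rnorm(length(m), 0, noise_pa),
                                      nrow = n_repetitions)
    m
  })
  structure(
    list(t_ms = t_ms, i_pa = i_pa, dv_mv = dv_mv, pulse_onset_ms = onset,
         pulse_ms = pulse_ms, sample_rate_hz = sample_rate_hz,
         truth = list(rs_mohm = rs_mohm, rm_mohm = rm_mohm, cm_pf = cm_pf,
                      tau_ms = tau_ms)),
    class = "test_pulse"
  )
}

#' Simulate a nested (two-level) Gaussian dataset pair
#'
#' Control and treated groups with upper units (mice, dendrites, or cells)
#' whose means are Gaussian around the group mean (`between_sd`) and whose
#' lower-level values are Gaussian around the unit mean (`within_sd`). The
#' treated group mean is shifted by `-effect`.
#'
#' @param n_upper Upper units per group.
#' @param n_lower_per_upper Values per unit (scalar or vector length
#'   `n_upper`, recycled to both groups).
#' @param between_sd,within_sd Between-unit and within-unit SDs (>= 0).
#' @param effect Downward shift of the treated group mean.
#' @param seed Integer seed or `NULL`.
#' @param grand_mean Control group mean.
#' @return List with data.frames `control` and `treated` (columns
#'   `upper_id`, `value`) and `truth`.
#' @export
make_hierarchical_values <- function(n_upper, n_lower_per_upper,
                                     between_sd, within_sd, effect = 0,
                                     seed = NULL, grand_mean = 0) {
  if (between_sd < 0 || within_sd < 0) stop("SDs must be >= 0", call. = FALSE)
  n_lower <- rep_len(as.integer(n_lower_per_upper), n_upper)
  gen <- function(mu, tag) {
    unit_means <- mu + stats::rnorm(n_upper, 0, between_sd)
    data.frame(
      upper_id = rep(sprintf("%s%02d", tag, seq_len(n_upper)), n_lower),
      value = stats::rnorm(sum(n_lower), rep(unit_means, n_lower), within_sd),
      stringsAsFactors = FALSE
    )
  }
  with_seed(seed, {
    list(control = gen(grand_mean, "c"),
         treated = gen(grand_mean - effect, "t"),
         truth = list(effect = effect, grand_mean = grand_mean,
                      between_sd = between_sd, within_sd = within_sd))
  })
}

#' Simulate a Poisson synaptic event train with planted doublets
#'
#' Homogeneous Poisson event times over `duration_s`; a stated fraction of
#' events is duplicated at an offset below 3 ms, flagged in the ground
#' truth, to exercise the doublet-exclusion post-filter.
#'
#' @param rate_hz Event rate (>= 0).
#' @param duration_s Recording duration in seconds.
#' @param doublet_fraction Fraction of events duplicated at < 3 ms offsets.
#' @param seed Integer seed or `NULL`.
#' @param amplitude_mean_pa,amplitude_sd_pa Event amplitude distribution.
#' @return List of class `event_train`: `time_ms` (sorted), `amplitude_pa`,
#'   `is_doublet` (ground truth), `duration_ms`.
#' @export
make_event_train <- function(rate_hz, duration_s, doublet_fraction = 0,
                             seed = NULL, amplitude_mean_pa = 10,
                             amplitude_sd_pa = 3) {
  if (rate_hz < 0) stop("`rate_hz` must be >= 0", call. = FALSE)
  if (doublet_fraction < 0 || doublet_fraction > 1) {
    stop("`doublet_fraction` must be in [0, 1]", call. = FALSE)
  }
  with_seed(seed, {
    n <- stats::rpois(1, rate_hz * duration_s)
    t_ms <- sort(stats::runif(n, 0, duration_s * 1000))
    amp <- abs(stats::rnorm(n, amplitude_mean_pa, amplitude_sd_pa))
    dbl <- rep(FALSE, n)
    if (n > 0 && doublet_fraction > 0) {
      n_dbl <- round(doublet_fraction * n)
      if (n_dbl > 0) {
        src <- sample.int(n, n_dbl)
        t_ms <- c(t_ms, t_ms[src] + stats::runif(n_dbl, 0.3, 2.9))
        amp <- c(amp, amp[src] * stats::runif(n_dbl, 0.7, 1))
        dbl <- c(dbl, rep(TRUE, n_dbl))
      }
    }
    ord <- order(t_ms)
    structure(
      list(time_ms = t_ms[ord], amplitude_pa = amp[ord],
           is_doublet = dbl[ord], duration_ms = duration_s * 1000),
      class = "event_train"
    )
  })
}
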