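#' Configuration for the synthetic-data generators
#'
#' Bundles the acquisition parameters every generator shares: the field of
#' view, the slow frame interval used for microglia/spine time series
#' (z-stacks every 3 minutes), the fast frame rate used for calcium
#' imaging (4 Hz), and the odor-panel geometry (15 odors, a handful of
#' repeats each plus blank trials).
#'
#' @param seed Integer seed; identical `(seed, config)` pairs give
#'   byte-identical outputs.
#' @param image_size_px Side of the (square) imaging field in pixels.
#' @param frame_interval_min Minutes between frames of the microglia/spine
#'   movies.
#' @param frame_rate_hz Frame rate (Hz) of the calcium traces.
#' @param n_odors Number of odors in the stimulus panel.
#' @param n_repeats Trials per odor (and blank trials per repeat set).
#' @return An object of class `synth_config`.
#' @examples
#' cfg <- synth_config(seed = 1)
#' cfg$n_odors
#' @export
synth_config <- function(seed,
                         image_size_px = 800L,
                         frame_interval_min = 3,
                         frame_rate_hz = 4,
                         n_odors = 15L,
                         n_repeats = 4L) {
  stop_if_not_scalar_number(seed, "seed")
  stop_if_not_scalar_number(image_size_px, "image_size_px", positive = TRUE)
  stop_if_not_scalar_number(frame_interval_min, "frame_interval_min", positive = TRUE)
  stop_if_not_scalar_number(frame_rate_hz, "frame_rate_hz", positive = TRUE)
  stop_if_not_scalar_number(n_odors, "n_odors", positive = TRUE)
  stop_if_not_scalar_number(n_repeats, "n_repeats", positive = TRUE)
  structure(
    list(
      seed = as.integer(seed),
      image_size_px = as.integer(image_size_px),
      frame_interval_min = frame_interval_min,
      frame_rate_hz = frame_rate_hz,
      n_odors = as.integer(n_odors),
      n_repeats = as.integer(n_repeats)
    ),
    class = "synth_config"
  )
}

#' @export
print.synth_config <- function(x, ...) {
  cat("synthetic-data configuration\n")
  cat(sprintf("  seed: %d   field: %d x %d px\n", x$seed, x$image_size_px, x$image_size_px))
  cat(sprintf("  microglia movies: 1 frame / %g min   calcium: %g Hz\n",
              x$frame_interval_min, x$frame_rate_hz))
  cat(sprintf("  odor panel: %d odors x %d repeats (+ blanks)\n", x$n_odors, x$n_repeats))
  invisible(x)
}
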