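# Shared fixture builders: everything is generated in code at test time.

# A rectangle ROI whose raster is exactly the pixel block cols x rows
# (0-based, inclusive); fractional margins keep pixel centers off edges.
rect_roi <- function(x0, x1, y0, y1, id = "s1", class = "mushroom") {
  spine_roi(id, class,
            x = c(x0 - 0.4, x1 + 0.4, x1 + 0.4, x0 - 0.4),
            y = c(y0 - 0.4, y0 - 0.4, y1 + 0.4, y1 + 0.4))
}

# Random simple polygon: star-shaped around a center, so never
# self-intersecting; vertices at irrational-ish radii to avoid pixel-center
# boundary cases.
random_star_polygon <- function(size, n_vertices = sample(3:9, 1)) {
  cx <- runif(1, size * 0.25, size * 0.75)
  cy <- runif(1, size * 0.25, size * 0.75)
  th <- sort(runif(n_vertices, 0, 2 * pi))
  r <- runif(n_vertices, 2, size * 0.2) + pi / 17
  list(x = cx + r * cos(th), y = cy + r * sin(th))
}

# Minimal movie-like object for contact pipeline tests.
toy_movie <- function(microglia, rois, frame_interval_min = 3) {
  structure(list(microglia = microglia, rois = rois,
                 frame_interval_min = frame_interval_min),
            class = "contact_movie")
}

# Blank calcium-style noise traces in dF/F-sigma units.
blank_trace_matrix <- function(n_trials, n_frames, sd = 1) {
  matrix(rnorm(n_trials * n_frames, 0, sd), nrow = n_trials)
}
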