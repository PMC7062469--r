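#' Simulate a two-channel microglia/spine time-lapse movie
#'
#' Generates a registered two-channel stack emulating slow (one frame every
#' few minutes) in vivo imaging of a labeled dendrite and a binary
#' microglia-segmentation channel, together with spine-head ROI polygons
#' and ground-truth interaction frames. Microglial processes are modeled as
#' disks whose centers start uniformly over the (toroidal) field and follow
#' a wrapped random walk, so with `bias = 0` the microglia channel is
#' statistically translation-invariant: circular channel offsets are then
#' exchangeable with the real alignment, which is what makes the offset
#' permutation null exact on these movies. With `bias > 0`, a fraction
#' `bias / (bias + 5)` of process positions is re-drawn each frame at a
#' random mushroom spine head (with small jitter), producing preferential
#' targeting of mushroom spines.
#'
#' @param cfg A [synth_config()]; `image_size_px` and `frame_interval_min`
#'   are taken from it.
#' @param n_spines Number of spines placed along the dendrite (>= 1).
#' @param bias Targeting bias (>= 0, dimensionless); 0 = motion independent
#'   of spine positions.
#' @param motility Random-walk step SD in px/frame for process centers.
#' @param n_frames Number of frames in the movie.
#' @param n_processes Number of microglial processes; default scales with
#'   field area (about 15 in a 224 px field).
#' @param prop_mushroom Proportion of spines given a mushroom morphology
#'   (remainder filopodial); at least one of each class is always placed.
#' @param criterion Coverage fraction defining a ground-truth contact frame.
#' @return A list of class `contact_movie` with elements `dendrite`
#'   (numeric array, rows x cols x frames, intensities in `[0, 1]`),
#'   `microglia` (integer 0/1 array of the same shape), `rois` (list of
#'   [spine_roi()]), `frame_interval_min`, and `ground_truth` (true
#'   coverage matrix, contact frames per spine, class table).
#' @examples
#' cfg <- synth_config(seed = 7, image_size_px = 128)
#' mv <- make_contact_movie(cfg, n_spines = 6, n_frames = 8)
#' dim(mv$microglia)
#' @export
make_contact_movie <- function(cfg, n_spines, bias = 0, motility = 4,
                               n_frames = 16L, n_processes = NULL,
                               prop_mushroom = 0.4, criterion = 0.05) {
  stopifnot(inherits(cfg, "synth_config"))
  stop_if_not_scalar_number(n_spines, "n_spines", positive = TRUE)
  stop_if_not_scalar_number(bias, "bias")
  if (bias < 0) stop("`bias` must be >= 0", call. = FALSE)
  stop_if_not_scalar_number(motility, "motility")
  if (motility < 0) stop("`motility` must be >= 0", call. = FALSE)
  s <- cfg$image_size_px
  n_frames <- as.integer(n_frames)
  n_spines <- as.integer(n_spines)
  if (is.null(n_processes)) n_processes <- max(5L, round(7.5e-4 * s^2))

  with_seed(child_seed(cfg$seed, "contact_movie"), {
    rois <- place_spines(n_spines, s, prop_mushroom)
    pix <- lapply(rois, rasterize_spine, nrow = s, ncol = s)

    # process trajectories on the torus
    cx <- matrix(0, n_processes, n_frames)
    cy <- matrix(0, n_processes, n_frames)
    cx[, 1] <- stats::runif(n_processes, 0, s)
    cy[, 1] <- stats::runif(n_processes, 0, s)
    if (n_frames > 1L) {
      for (t in 2:n_frames) {
        cx[, t] <- (cx[, t - 1] + stats::rnorm(n_processes, 0, motility)) %% s
        cy[, t] <- (cy[, t - 1] + stats::rnorm(n_processes, 0, motility)) %% s
      }
    }
    radius <- stats::runif(n_processes, 2, 5)

    mush <- vapply(rois, function(r) r$class == "mushroom", logical(1))
    mush_x <- vapply(rois[mush], function(r) mean(r$x), numeric(1))
    mush_y <- vapply(rois[mush], function(r) mean(r$y), numeric(1))
    p_target <- if (bias > 0) bias / (bias + 5) else 0

    microglia <- array(0L, dim = c(s, s, n_frames))
    for (t in seq_len(n_frames)) {
      frame <- matrix(0L, s, s)
      for (k in seq_len(n_processes)) {
        px <- cx[k, t]; py <- cy[k, t]
        if (p_target > 0 && length(mush_x) > 0 && stats::runif(1) < p_target) {
          j <- sample.int(length(mush_x), 1L)
          px <- (mush_x[j] + stats::rnorm(1, 0, 1.5)) %% s
          py <- (mush_y[j] + stats::rnorm(1, 0, 1.5)) %% s
        }
        frame <- paint_disk(frame, px, py, radius[k])
      }
      microglia[, , t] <- frame
    }

    dendrite <- render_dendrite(rois, s, n_frames)

    cov <- t(vapply(pix, function(idx) {
      vapply(seq_len(n_frames), function(t) mean(microglia[, , t][idx]), numeric(1))
    }, numeric(n_frames)))
    if (n_frames == 1L) cov <- matrix(cov, nrow = length(pix))
    rownames(cov) <- vapply(rois, `[[`, character(1), "spine_id")

    gt <- list(
      coverage = cov,
      contact_frames = apply(cov, 1L, function(z) which(z >= criterion),
                             simplify = FALSE),
      classes = data.frame(
        spine_id = vapply(rois, `[[`, character(1), "spine_id"),
        class = vapply(rois, `[[`, character(1), "class"),
        stringsAsFactors = FALSE
      ),
      bias = bias, criterion = criterion
    )

    structure(
      list(dendrite = dendrite, microglia = microglia, rois = rois,
           frame_interval_min = cfg$frame_interval_min, ground_truth = gt),
      class = "contact_movie"
    )
  })
}

# Place n spines along a randomly oriented dendrite through the field
# center, with margins so every polygon rasterizes inside the field. Class
# counts are fixed (positions shuffled). The random orientation keeps any
# single offset mode from sliding along the dendrite axis.
place_spines <- function(n_spines, s, prop_mushroom) {
  margin <- max(16, 0.08 * s)
  theta <- stats::runif(1, 0, pi)
  ux <- cos(theta); uy <- sin(theta)     # dendrite axis
  px_ <- -uy; py_ <- ux                  # perpendicular
  half <- (s / 2 - margin) / max(abs(ux), abs(uy))
  u <- seq(-half, half, length.out = n_spines) + stats::runif(n_spines, -2, 2)
  cx0 <- s / 2 + u * ux
  cy0 <- s / 2 + u * uy
  side <- rep_len(c(-1, 1), n_spines)
  n_mush <- min(n_spines, max(1L, round(prop_mushroom * n_spines)))
  cls <- sample(c(rep("mushroom", n_mush),
                  rep("filopodial", n_spines - n_mush)))
  if (n_spines >= 2L && !any(cls == "filopodial")) cls[n_spines] <- "filopodial"
  scale <- max(1, s / 224)
  rois <- lapply(seq_len(n_spines), function(i) {
    if (cls[i] == "mushroom") {
      r <- stats::runif(1, 2, 2 + 1.2 * scale)
      off <- 4 + r
      p <- disk_polygon(cx0[i] + side[i] * off * px_,
                        cy0[i] + side[i] * off * py_, r)
    } else {
      len <- stats::runif(1, 5, 7); w <- 1.1
      b <- 3; tp <- b + len
      # quadrilateral protruding perpendicular to the dendrite
      corners <- rbind(
        c(-w, side[i] * b), c(w, side[i] * b),
        c(w * 0.7, side[i] * tp), c(-w * 0.7, side[i] * tp)
      )
      p <- list(
        x = cx0[i] + corners[, 1] * ux + corners[, 2] * px_ + 0.23,
        y = cy0[i] + corners[, 1] * uy + corners[, 2] * py_ + 0.31
      )
    }
    spine_roi(sprintf("s%02d", i), cls[i], p$x, p$y)
  })
  attr(rois, "axis") <- c(ux, uy)
  rois
}

# Paint a filled disk with toroidal wraparound into an integer 0/1 matrix.
paint_disk <- function(frame, cx, cy, r) {
  s <- nrow(frame)
  rr <- ceiling(r)
  off <- expand.grid(dx = -rr:rr, dy = -rr:rr)
  off <- off[off$dx^2 + off$dy^2 <= r^2, , drop = FALSE]
  cols <- ((round(cx) + off$dx) %% s) + 1L
  rows <- ((round(cy) + off$dy) %% s) + 1L
  frame[cbind(rows, cols)] <- 1L
  frame
}

# Structural channel: a dendrite shaft plus bright spine heads and shot-like
# noise; values in [0, 1]. Only used for realism and IO round-trips.
render_dendrite <- function(rois, s, n_frames) {
  base <- matrix(0, s, s)
  ax <- attr(rois, "axis") %||% c(1, 0)
  # shaft: pixels within 1.5 px of the center line along the dendrite axis
  g <- expand.grid(col = seq_len(s), row = seq_len(s))
  dperp <- abs((g$col - s / 2) * (-ax[2]) + (g$row - s / 2) * ax[1])
  base[cbind(g$row, g$col)[dperp <= 1.5, , drop = FALSE]] <- 0.5
  for (r in rois) {
    idx <- rasterize_spine(r, s, s)
    base[idx] <- if (r$class == "mushroom") 0.9 else 0.6
  }
  arr <- array(0, dim = c(s, s, n_frames))
  for (t in seq_len(n_frames)) {
    arr[, , t] <- pmin(1, pmax(0, base + matrix(stats::rnorm(s * s, 0, 0.02), s, s)))
  }
  arr
}

#' Threshold-based microglia segmentation
#'
#' Turns a raw intensity stack into the binary per-frame mask the contact
#' pipeline consumes. This is a deliberately simple global-threshold
#' segmentation for users whose movies are not pre-segmented; any external
#' binary segmentation can be supplied instead.
#'
#' @param intensity Numeric array (rows x cols x frames) or matrix.
#' @param threshold Intensity cutoff; pixels strictly above it are mask.
#' @return Integer 0/1 array of the same shape.
#' @export
segment_microglia <- function(intensity, threshold) {
  stop_if_not_scalar_number(threshold, "threshold")
  out <- array(0L, dim = dim(intensity) %||% length(intensity))
  out[intensity > threshold] <- 1L
  out
}
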