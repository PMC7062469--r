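#' Fractional microglial coverage of a spine-head ROI
#'
#' The fraction of the ROI's pixels (pixel centers inside the polygon,
#' even-odd rule) that are positive in a binary microglia mask. This is the
#' per-frame colocalization value on which the 5% interaction criterion
#' operates.
#'
#' @param spine A [spine_roi()].
#' @param mask Binary matrix (same dimensions as the imaging frame).
#' @return Coverage fraction in `[0, 1]`.
#' @examples
#' roi <- spine_roi("s1", "mushroom", x = c(1.5, 6.5, 6.5, 1.5),
#'                  y = c(1.5, 1.5, 5.5, 5.5))
#' m <- matrix(0L, 20, 20); m[3:4, 3:7] <- 1L
#' coverage_fraction(roi, m)
#' @export
coverage_fraction <- function(spine, mask) {
  stopifnot(inherits(spine, "spine_roi"), is.matrix(mask))
  idx <- rasterize_spine(spine, nrow(mask), ncol(mask))
  sum(mask[idx] > 0) / length(idx)
}

#' Detect microglia-spine interactions in a coverage series
#'
#' An interaction is a maximal run of consecutive valid frames whose
#' coverage meets the criterion (`>= criterion` by default; set
#' `strict = TRUE` for `>`). Invalid frames (e.g., too dim to segment)
#' break runs. Each interaction's length is `run frames x frame_interval`.
#'
#' @param coverage Numeric vector of per-frame coverage fractions.
#' @param frame_interval_min Minutes between frames.
#' @param criterion Coverage criterion in (0, 1); default 0.05.
#' @param valid Logical per-frame validity flags (default all valid).
#' @param strict If `TRUE`, require coverage strictly above the criterion.
#' @return data.frame with one row per interaction: `start_frame`,
#'   `end_frame` (inclusive), `length_min`, `max_coverage`. Zero rows when
#'   no frame meets the criterion.
#' @examples
#' detect_interactions(c(0, 0.06, 0.07, 0.02), frame_interval_min = 3)
#' @export
detect_interactions <- function(coverage, frame_interval_min,
                                criterion = 0.05, valid = NULL,
                                strict = FALSE) {
  if (criterion <= 0 || criterion >= 1) stop("`criterion` must be in (0, 1)", call. = FALSE)
  if (any(coverage < 0 | coverage > 1, na.rm = TRUE)) {
    stop("coverage values must lie in [0, 1]", call. = FALSE)
  }
  n <- length(coverage)
  if (n < 1L) stop("coverage series is empty", call. = FALSE)
  valid <- valid %||% rep(TRUE, n)
  valid <- valid & !is.na(coverage)
  if (!any(valid)) stop("all frames invalid: interaction state unknowable", call. = FALSE)
  hit <- valid & if (strict) coverage > criterion else coverage >= criterion
  r <- rle(hit)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- which(r$values)
  data.frame(
    start_frame = starts[keep],
    end_frame = ends[keep],
    length_min = r$lengths[keep] * frame_interval_min,
    max_coverage = vapply(keep, function(k) {
      max(coverage[starts[k]:ends[k]])
    }, numeric(1))
  )
}

#' Per-dendrite interaction summary
#'
#' Aggregates per-spine interaction tables into the dendrite-level numbers
#' interaction studies report: the proportion of spines with at least
#' one interaction, the mean interaction rate per 10 minutes across spines,
#' the mean interaction length (across all interactions of the selected
#' spines), and the mean of per-spine mean maximum coverage. Length and
#' coverage summaries use only spines with at least one interaction and are
#' `NA` when no spine interacted.
#'
#' @param interactions Named list (by spine_id) of data.frames from
#'   [detect_interactions()].
#' @param total_valid_minutes Minutes of valid observation (> 0).
#' @param classes Character vector of spine classes, parallel to
#'   `interactions`.
#' @param class_filter `"mushroom"`, `"filopodial"`, or `NULL` for all.
#' @param coverage Optional coverage matrix (spines x frames, before class
#'   filtering) from which the continuous `mean_coverage` summary (mean
#'   per-spine coverage over valid frames) is computed; the count-based
#'   summaries are unchanged by it.
#' @return One-row data.frame: `n_spines`, `prop_with_interaction`,
#'   `rate_per_10min`, `mean_length_min`, `mean_max_coverage`,
#'   `mean_coverage` (`NA` unless `coverage` is given).
#' @export
summarize_dendrite <- function(interactions, total_valid_minutes,
                               classes = NULL, class_filter = NULL,
                               coverage = NULL) {
  stop_if_not_scalar_number(total_valid_minutes, "total_valid_minutes", positive = TRUE)
  sel <- rep(TRUE, length(interactions))
  if (!is.null(class_filter)) {
    if (is.null(classes)) stop("`classes` required when filtering by class", call. = FALSE)
    sel <- classes == class_filter
    if (!any(sel)) stop(sprintf("no spines of class '%s'", class_filter), call. = FALSE)
    interactions <- interactions[sel]
  }
  n_int <- vapply(interactions, nrow, integer(1))
  has <- n_int > 0
  lengths_all <- unlist(lapply(interactions[has], `[[`, "length_min"))
  maxcov_spine <- vapply(interactions[has],
                         function(d) mean(d$max_coverage), numeric(1))
  data.frame(
    n_spines = length(interactions),
    prop_with_interaction = mean(has),
    rate_per_10min = mean(n_int * 10 / total_valid_minutes),
    mean_length_min = if (any(has)) mean(lengths_all) else NA_real_,
    mean_max_coverage = if (any(has)) mean(maxcov_spine) else NA_real_,
    mean_coverage = if (is.null(coverage)) NA_real_ else
      mean(rowMeans(coverage[sel, , drop = FALSE]))
  )
}

#' Offset grid for the channel-translation chance null
#'
#' Circular (wrap-around) translations of the microglia channel relative to
#' the dendrite channel: horizontal, vertical, and diagonal (dx = dy)
#' shifts whose magnitudes start at `start_px` (the maximum spine width, so
#' no offset overlaps the real alignment) and advance by `step_px` (the
#' mean spine width, decorrelating successive offsets) up to the largest
#' magnitude below `image_size_px`. For an 800 px field with the default
#' 32/10 spacing this gives 77 magnitudes per mode, 231 offsets in total.
#'
#' @param image_size_px Side of the square field in pixels.
#' @param start_px First offset magnitude (0 < start_px < image_size_px).
#' @param step_px Magnitude increment (> 0).
#' @return data.frame of class `offset_grid` with columns `dx`, `dy`,
#'   `mode`, `magnitude`.
#' @examples
#' nrow(generate_offsets(800))  # 231
#' @export
generate_offsets <- function(image_size_px, start_px = 32, step_px = 10) {
  stop_if_not_scalar_number(image_size_px, "image_size_px", positive = TRUE)
  stop_if_not_scalar_number(step_px, "step_px", positive = TRUE)
  if (start_px <= 0 || start_px >= image_size_px) {
    stop("`start_px` must satisfy 0 < start_px < image_size_px", call. = FALSE)
  }
  mags <- seq(start_px, image_size_px - 1, by = step_px)
  grid <- rbind(
    data.frame(dx = mags, dy = 0, mode = "horizontal"),
    data.frame(dx = 0, dy = mags, mode = "vertical"),
    data.frame(dx = mags, dy = mags, mode = "diagonal")
  )
  grid$magnitude <- rep(mags, 3)
  attr(grid, "image_size_px") <- image_size_px
  class(grid) <- c("offset_grid", class(grid))
  grid
}

#' Circularly shift a binary mask
#'
#' Shifts mask content by `dx` columns (rightward) and `dy` rows
#' (downward) with wraparound; shifting by the image size is the identity.
#'
#' @param mask Matrix.
#' @param dx,dy Integer shifts in pixels.
#' @return Shifted matrix.
#' @export
shift_mask <- function(mask, dx, dy) {
  nr <- nrow(mask); nc <- ncol(mask)
  ri <- ((seq_len(nr) - 1L - dy) %% nr) + 1L
  ci <- ((seq_len(nc) - 1L - dx) %% nc) + 1L
  mask[ri, ci, drop = FALSE]
}

# Coverage of every spine in every frame under a channel offset (dx, dy),
# computed by looking spine pixels up at circularly shifted positions;
# equivalent to shift_mask() on each frame but touches only ROI pixels.
# `pix_rc` is a list of 2-column (row, col) 1-based matrices per spine.
coverage_matrix_offset <- function(mask_stack, pix_rc, dx, dy) {
  s <- dim(mask_stack)[1]
  n_frames <- dim(mask_stack)[3]
  frame_stride <- s * s
  flat <- as.vector(mask_stack)
  t(vapply(pix_rc, function(rc) {
    r <- ((rc[, 1] - 1L - dy) %% s) + 1L
    c <- ((rc[, 2] - 1L - dx) %% s) + 1L
    base <- (c - 1L) * s + r
    idx <- outer(base, (seq_len(n_frames) - 1L) * frame_stride, `+`)
    colSums(matrix(flat[idx] > 0, nrow = length(base))) / length(base)
  }, numeric(n_frames)))
}

# (row, col) pixel matrices for each spine of a movie.
spine_pixel_rc <- function(rois, s) {
  lapply(rois, function(r) {
    idx <- rasterize_spine(r, s, s)
    cbind(row = ((idx - 1L) %% s) + 1L, col = ((idx - 1L) %/% s) + 1L)
  })
}

# Dendrite summary under one channel offset.
offset_summary <- function(mask_stack, pix_rc, classes, dx, dy,
                           frame_interval_min, criterion, strict,
                           class_filter) {
  cov <- coverage_matrix_offset(mask_stack, pix_rc, dx, dy)
  if (is.null(dim(cov))) cov <- matrix(cov, nrow = length(pix_rc))
  ints <- apply(cov, 1L, detect_interactions,
                frame_interval_min = frame_interval_min,
                criterion = criterion, strict = strict, simplify = FALSE)
  total_min <- ncol(cov) * frame_interval_min
  summarize_dendrite(ints, total_min, classes = classes,
                     class_filter = class_filter, coverage = cov)
}

#' Interaction summaries under every channel offset
#'
#' Recomputes coverage, interaction detection, and the dendrite summary
#' with identical parameters after circularly translating the microglia
#' channel by each offset of the grid, yielding the chance null
#' distribution of the selected statistic. Offsets whose computation fails
#' propagate as `NA` entries (with a warning), never silently dropped.
#'
#' @param movie A `contact_movie`, or a list with elements `microglia`
#'   (binary rows x cols x frames array), `rois`, `frame_interval_min`.
#' @param grid An [generate_offsets()] grid.
#' @param statistic One of `"rate_per_10min"`, `"prop_with_interaction"`,
#'   `"mean_length_min"`, `"mean_max_coverage"`, or `"mean_coverage"` (the
#'   continuous per-spine mean coverage, recommended for permutation
#'   calibration at small movie sizes where the count statistics are
#'   heavily tied).
#' @param criterion,strict Interaction criterion (see
#'   [detect_interactions()]).
#' @param class_filter Restrict to one spine class (default `"mushroom"`).
#' @return Numeric vector, one summary value per offset.
#' @export
offset_statistics <- function(movie, grid, statistic = "rate_per_10min",
                              criterion = 0.05, strict = FALSE,
                              class_filter = "mushroom") {
  stopifnot(nrow(grid) > 0)
  statistic <- match.arg(statistic, c("rate_per_10min", "prop_with_interaction",
                                      "mean_length_min", "mean_max_coverage",
                                      "mean_coverage"))
  s <- dim(movie$microglia)[1]
  pix_rc <- spine_pixel_rc(movie$rois, s)
  classes <- vapply(movie$rois, `[[`, character(1), "class")
  vals <- vapply(seq_len(nrow(grid)), function(i) {
    tryCatch(
      offset_summary(movie$microglia, pix_rc, classes, grid$dx[i], grid$dy[i],
                     movie$frame_interval_min, criterion, strict,
                     class_filter)[[statistic]],
      error = function(e) NA_real_
    )
  }, numeric(1))
  if (anyNA(vals)) {
    warning(sprintf("%d of %d offsets failed and propagate as NA",
                    sum(is.na(vals)), length(vals)))
  }
  vals
}

#' One-tailed permutation p-value against an offset null
#'
#' `p = (1 + #\{null >= observed\}) / (N + 1)` with the add-one convention,
#' testing whether the real-alignment statistic is higher than chance.
#' Missing null entries are excluded from `N` with a warning.
#'
#' @param observed Observed summary value.
#' @param null Numeric vector of null summaries (e.g., from
#'   [offset_statistics()]).
#' @return p-value in `(0, 1]`.
#' @examples
#' permutation_test_one_tailed(5, rep(1, 231))  # 1/232
#' @export
permutation_test_one_tailed <- function(observed, null) {
  if (length(null) == 0L) stop("null distribution is empty", call. = FALSE)
  n_miss <- sum(is.na(null))
  if (n_miss > 0) {
    warning(sprintf("excluding %d missing null entries", n_miss))
    null <- null[!is.na(null)]
    if (length(null) == 0L) stop("all null entries missing", call. = FALSE)
  }
  if (is.na(observed)) stop("observed statistic is missing", call. = FALSE)
  (1 + sum(null >= observed)) / (length(null) + 1)
}

#' Full contact test: observed statistic versus the offset null
#'
#' Convenience wrapper running the whole chain on one movie: real-alignment
#' summary, offset null, and the one-tailed permutation p-value.
#'
#' @inheritParams offset_statistics
#' @param start_px,step_px Offset grid spacing (see [generate_offsets()]).
#' @return List: `observed`, `null`, `p`, `grid`, `summary` (the full
#'   real-alignment summary row).
#' @export
contact_chance_test <- function(movie, statistic = "rate_per_10min",
                                criterion = 0.05, strict = FALSE,
                                class_filter = "mushroom",
                                start_px = 32, step_px = 10) {
  s <- dim(movie$microglia)[1]
  grid <- generate_offsets(s, start_px, step_px)
  pix_rc <- spine_pixel_rc(movie$rois, s)
  classes <- vapply(movie$rois, `[[`, character(1), "class")
  real <- offset_summary(movie$microglia, pix_rc, classes, 0L, 0L,
                         movie$frame_interval_min, criterion, strict,
                         class_filter)
  null <- offset_statistics(movie, grid, statistic = statistic,
                            criterion = criterion, strict = strict,
                            class_filter = class_filter)
  list(observed = real[[statistic]], null = null,
       p = permutation_test_one_tailed(real[[statistic]], null),
       grid = grid, summary = real)
}
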