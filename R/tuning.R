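#' ROC threshold from blank-trial responses
#'
#' Selects the lowest candidate threshold whose false-positive rate on the
#' blank ("no odor") response distribution does not exceed the design
#' target (10%). Candidates are the sorted unique values of the pooled
#' signal and noise responses, with responses from all experimental groups
#' combined before selection. A response counts as positive when strictly
#' above the threshold.
#'
#' @param signal Odor-trial responses (pooled across groups).
#' @param noise Blank-trial responses (pooled across groups; nonempty).
#' @param target_fpr Design false-positive rate (default 0.10).
#' @return List of class `roc_threshold`: `threshold`, `achieved_fpr`
#'   (never above `target_fpr`), `target_fpr`, `n_noise`, `n_signal`.
#' @examples
#' roc_threshold(signal = numeric(0), noise = 1:10)$threshold  # 9
#' @export
roc_threshold <- function(signal, noise, target_fpr = 0.10) {
  if (length(noise) == 0L) stop("blank-trial (noise) sample is empty", call. = FALSE)
  cand <- sort(unique(c(signal, noise)))
  fpr <- vapply(cand, function(th) mean(noise > th), numeric(1))
  ok <- which(fpr <= target_fpr)
  th <- cand[ok[1L]]
  structure(
    list(threshold = th, achieved_fpr = fpr[ok[1L]], target_fpr = target_fpr,
         n_noise = length(noise), n_signal = length(signal)),
    class = "roc_threshold"
  )
}

#' Number of effective odors for one dendrite
#'
#' Counts odors whose mean response is strictly above the ROC threshold.
#'
#' @param responses Odor responses of one dendrite.
#' @param threshold ROC threshold (finite scalar).
#' @return Integer count.
#' @export
effective_odors <- function(responses, threshold) {
  stop_if_not_scalar_number(threshold, "threshold")
  sum(responses > threshold)
}

#' Zero sub-threshold responses
#'
#' Prepares a response vector for [lifetime_sparseness()]: entries not
#' strictly above the threshold are set to zero.
#'
#' @param responses Response vector.
#' @param threshold ROC threshold.
#' @return Thresholded vector (>= 0 entries kept as-is, others zeroed).
#' @export
apply_response_threshold <- function(responses, threshold) {
  ifelse(responses > threshold, responses, 0)
}

#' Lifetime sparseness
#'
#' Tuning-breadth statistic over a thresholded response vector:
#' `LS = (sum(r_j) / m)^2 / (sum(r_j^2) / m)` with `m` odors. LS is 1 for a
#' uniform positive vector, `1/m` for a single responsive odor, and is set
#' to 0 when every response is below threshold (the sparsest possible
#' representation).
#'
#' @param r Thresholded responses (all >= 0; sub-threshold entries zeroed).
#' @param m Number of odors (defaults to `length(r)`).
#' @return LS in `[0, 1]`.
#' @examples
#' lifetime_sparseness(c(1, rep(0, 14)))  # 1/15
#' @export
lifetime_sparseness <- function(r, m = length(r)) {
  if (m == 0L) stop("`m` must be >= 1", call. = FALSE)
  if (any(r < 0)) stop("thresholded responses must be >= 0", call. = FALSE)
  if (all(r == 0)) return(0)
  (sum(r) / m)^2 / (sum(r^2) / m)
}

#' Grid search for event-detection parameters
#'
#' Searches combinations of minimum run length (`n_min` consecutive
#' frames) and amplitude threshold (`k` baseline SDs) and picks the pair
#' whose event rate on blank trials is closest to the design
#' false-positive rate; ties break toward larger `n_min`, then larger `k`
#' (the more conservative setting). Warns when no pair lands within 5
#' percentage points of the target.
#'
#' @param blank_traces Matrix of blank-trial traces in delta-F over F-sigma
#'   units (trials x frames).
#' @param response_frames Frame indices forming the response period.
#' @param target_fpr Design blank event rate (default 0.10).
#' @param n_min_grid,k_grid Candidate grids. Run lengths default to 1..5
#'   frames; amplitude thresholds default to 1..5 baseline SDs in 0.25
#'   steps (integer-only thresholds are too coarse to land near a 10%
#'   blank rate on Gaussian noise).
#' @return List of class `event_params`: `n_min`, `k`, `achieved_fpr`,
#'   `grid` (search table).
#' @export
grid_search_event_params <- function(blank_traces, response_frames,
                                     target_fpr = 0.10,
                                     n_min_grid = 1:5,
                                     k_grid = seq(1, 5, by = 0.25)) {
  if (length(n_min_grid) == 0L || length(k_grid) == 0L) {
    stop("parameter grid is empty", call. = FALSE)
  }
  if (is.null(dim(blank_traces))) blank_traces <- matrix(blank_traces, nrow = 1)
  if (nrow(blank_traces) == 0L) stop("no blank trials supplied", call. = FALSE)
  tab <- expand.grid(n_min = n_min_grid, k = k_grid)
  tab$fpr <- vapply(seq_len(nrow(tab)), function(i) {
    mean(apply(blank_traces, 1L, function(tr) {
      nrow(find_event_runs(tr, response_frames, tab$n_min[i], tab$k[i])) > 0
    }))
  }, numeric(1))
  dev <- abs(tab$fpr - target_fpr)
  best <- tab[order(dev, -tab$n_min, -tab$k), ][1L, ]
  if (abs(best$fpr - target_fpr) > 0.05) {
    warning(sprintf("no parameter pair within 5 points of the %g%% target; closest achieves %.1f%%",
                    100 * target_fpr, 100 * best$fpr))
  }
  structure(list(n_min = best$n_min, k = best$k, achieved_fpr = best$fpr,
                 grid = tab),
            class = "event_params")
}

# Maximal runs of >= n_min consecutive response-period frames at or above
# k (delta-F over F-sigma units). Returns onset/offset/peak frame indices.
find_event_runs <- function(trace, response_frames, n_min, k,
                            inclusive = TRUE) {
  response_frames <- as.integer(response_frames)
  v <- trace[response_frames]
  hit <- if (inclusive) v >= k else v > k
  r <- rle(hit)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- which(r$values & r$lengths >= n_min)
  if (length(keep) == 0L) {
    return(data.frame(onset_frame = integer(), offset_frame = integer(),
                      peak_frame = integer()))
  }
  data.frame(
    onset_frame = response_frames[starts[keep]],
    offset_frame = response_frames[ends[keep]],
    peak_frame = vapply(keep, function(j) {
      rel <- starts[j]:ends[j]
      response_frames[rel[which.max(v[rel])]]
    }, integer(1))
  )
}

#' Sliding-window event detection across repeats
#'
#' Detects events (runs of at least `n_min` consecutive frames at or above
#' `k` baseline SDs) in each repeat's trace, unions the event frames across
#' repeats, averages the traces to a mean event trace, and reports the mean
#' value in a 1 s window centered on the peak of that mean trace (clipped
#' at the response-period edges) as the across-repeat response. Latency is
#' the mean onset delay over repeats that had events.
#'
#' @param traces Matrix (repeats x frames) of delta-F over F-sigma traces.
#' @param params An [grid_search_event_params()] result (or list with
#'   `n_min`, `k`).
#' @param response_frames Frame indices of the response period.
#' @param odor_onset_frame First odor frame (for latency).
#' @param frame_rate_hz Frame rate.
#' @return List of class `event_response`: `events` (per repeat),
#'   `event_frames` (union), `response` (`NA` when no repeat had events),
#'   `latency_s`, `mean_trace`.
#' @export
detect_events <- function(traces, params, response_frames,
                          odor_onset_frame, frame_rate_hz) {
  if (is.null(dim(traces))) traces <- matrix(traces, nrow = 1)
  if (nrow(traces) == 0L) stop("no repeats survive QC", call. = FALSE)
  evs <- lapply(seq_len(nrow(traces)), function(i) {
    find_event_runs(traces[i, ], response_frames, params$n_min, params$k)
  })
  ev_frames <- sort(unique(unlist(lapply(evs, function(e) {
    unlist(mapply(seq, e$onset_frame, e$offset_frame, SIMPLIFY = FALSE))
  }))))
  mean_trace <- colMeans(traces)
  if (length(ev_frames) == 0L) {
    return(structure(list(events = evs, event_frames = integer(),
                          response = NA_real_, latency_s = NA_real_,
                          mean_trace = mean_trace),
                     class = "event_response"))
  }
  peak <- ev_frames[which.max(mean_trace[ev_frames])]
  half <- round(frame_rate_hz / 2)
  win <- max(min(response_frames), peak - half):min(max(response_frames), peak + half)
  win <- intersect(win, ev_frames)  # mean event trace is defined on event frames
  onsets <- vapply(evs, function(e) {
    if (nrow(e) == 0L) NA_real_ else (min(e$onset_frame) - odor_onset_frame) / frame_rate_hz
  }, numeric(1))
  structure(
    list(events = evs, event_frames = ev_frames,
         response = mean(mean_trace[win]),
         latency_s = mean(onsets, na.rm = TRUE),
         mean_trace = mean_trace),
    class = "event_response"
  )
}

#' Principal-angle permutation test on response time courses
#'
#' Computes the first three principal axes (by singular value
#' decomposition of the column-centered trace matrices) of each group's
#' responses over the odor analysis period and measures the largest
#' principal angle between the two 3-dimensional subspaces. A permutation
#' null is built by shuffling which group each whole trace belongs to
#' (preserving group sizes); `p = (1 + #\{null >= observed\}) / (n_perm + 1)`.
#' All three principal angles are returned alongside the largest.
#'
#' @param traces_a,traces_b Matrices (traces x timepoints) covering the
#'   same period at the same frame rate.
#' @param n_pc Number of principal components (default 3).
#' @param n_perm Number of label shuffles (default 1000).
#' @param seed Integer seed or `NULL`.
#' @return List of class `subspace_test`: `angle_deg`,
#'   `principal_angles_deg`, `null_angles`, `p`.
#' @export
subspace_permutation_test <- function(traces_a, traces_b, n_pc = 3,
                                      n_perm = 1000, seed = NULL) {
  traces_a <- as.matrix(traces_a); traces_b <- as.matrix(traces_b)
  if (ncol(traces_a) != ncol(traces_b)) {
    stop("groups must cover the same timepoints", call. = FALSE)
  }
  if (nrow(traces_a) == 0L || nrow(traces_b) == 0L) {
    stop("both groups must be nonempty", call. = FALSE)
  }
  if (min(nrow(traces_a), nrow(traces_b), ncol(traces_a)) < n_pc) {
    stop(sprintf("fewer than %d usable dimensions", n_pc), call. = FALSE)
  }
  obs <- principal_angles(pc_axes(traces_a, n_pc), pc_axes(traces_b, n_pc))
  with_seed(seed, {
    pool <- rbind(traces_a, traces_b)
    na <- nrow(traces_a); ntot <- nrow(pool)
    null <- vapply(seq_len(n_perm), function(i) {
      idx <- sample.int(ntot, na)
      max(principal_angles(pc_axes(pool[idx, , drop = FALSE], n_pc),
                           pc_axes(pool[-idx, , drop = FALSE], n_pc)))
    }, numeric(1))
    structure(
      list(angle_deg = max(obs), principal_angles_deg = obs,
           null_angles = null,
           p = (1 + sum(null >= max(obs))) / (n_perm + 1)),
      class = "subspace_test"
    )
  })
}

# Orthonormal basis of the first n_pc principal axes (loadings over time).
pc_axes <- function(x, n_pc) {
  xc <- sweep(x, 2L, colMeans(x))
  svd(xc, nu = 0, nv = n_pc)$v
}

# Principal angles (degrees) between the column spaces of two orthonormal
# bases; singular values of Va' Vb are the cosines.
principal_angles <- function(va, vb) {
  s <- svd(crossprod(va, vb))$d
  acos(pmin(1, pmax(-1, s))) * 180 / pi
}
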