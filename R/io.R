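#' Write and read two-channel movies as multi-page TIFF
#'
#' Pages are channel-major: all dendrite frames first, then all microglia
#' frames, each page one 16-bit grayscale image. Requires the `tiff`
#' package.
#'
#' @param movie A `contact_movie` (see [make_contact_movie()]).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_contact_movie <- function(movie, path) {
  if (!requireNamespace("tiff", quietly = TRUE)) {
    stop("the 'tiff' package is required for TIFF movie IO", call. = FALSE)
  }
  n_frames <- dim(movie$dendrite)[3]
  pages <- c(
    lapply(seq_len(n_frames), function(t) movie$dendrite[, , t]),
    lapply(seq_len(n_frames), function(t) movie$microglia[, , t] * 1.0)
  )
  tiff::writeTIFF(pages, path, bits.per.sample = 16L)
  invisible(path)
}

#' @rdname write_contact_movie
#' @param n_frames Frames per channel in the file.
#' @export
read_contact_movie <- function(path, n_frames) {
  if (!requireNamespace("tiff", quietly = TRUE)) {
    stop("the 'tiff' package is required for TIFF movie IO", call. = FALSE)
  }
  pages <- tiff::readTIFF(path, all = TRUE)
  stopifnot(length(pages) == 2L * n_frames)
  s <- dim(pages[[1]])
  dendrite <- array(0, dim = c(s[1], s[2], n_frames))
  microglia <- array(0L, dim = c(s[1], s[2], n_frames))
  for (t in seq_len(n_frames)) {
    dendrite[, , t] <- pages[[t]]
    microglia[, , t] <- as.integer(pages[[n_frames + t]] > 0.5)
  }
  list(dendrite = dendrite, microglia = microglia)
}

#' Write and read spine ROIs as JSON
#'
#' One record per spine with 0-based pixel vertices, matching how ROI
#' exports from image annotation tools are exchanged.
#'
#' @param rois List of [spine_roi()] objects.
#' @param path JSON file path.
#' @return `path`, invisibly (writer); list of `spine_roi` (reader).
#' @export
write_rois_json <- function(rois, path) {
  recs <- lapply(rois, function(r) {
    list(spine_id = r$spine_id, class = r$class,
         plane_index = r$plane_index, x = r$x, y = r$y)
  })
  jsonlite::write_json(recs, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_rois_json
#' @export
read_rois_json <- function(path) {
  recs <- jsonlite::read_json(path, simplifyVector = TRUE)
  lapply(seq_len(nrow(recs)), function(i) {
    spine_roi(recs$spine_id[i], recs$class[i],
              x = recs$x[[i]], y = recs$y[[i]],
              plane_index = recs$plane_index[i])
  })
}

#' Write and read trial-structured traces as long-format CSV
#'
#' Columns: mouse, dendrite, odor, trial, frame, F.
#'
#' @param traces Long-format data.frame (as in [make_calcium_dataset()]).
#' @param path CSV file path.
#' @return `path`, invisibly (writer); data.frame (reader).
#' @export
write_traces_csv <- function(traces, path) {
  utils::write.csv(traces, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_traces_csv
#' @export
read_traces_csv <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Write a ground-truth sidecar as JSON
#'
#' @param ground_truth Any ground-truth record from a generator.
#' @param path JSON file path.
#' @return `path`, invisibly.
#' @export
write_ground_truth_json <- function(ground_truth, path) {
  jsonlite::write_json(ground_truth, path, auto_unbox = TRUE, digits = NA,
                       force = TRUE)
  invisible(path)
}
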