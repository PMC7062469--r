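#' Read a plain-text run configuration
#'
#' Key-value lines (`key = value`, `#` comments). Values are parsed as
#' numbers where possible; keys use dots to mark arms, e.g.
#' `contact.n_spines = 20`.
#'
#' @param path Config file path.
#' @return Nested list keyed by arm.
#' @export
read_run_config <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(sub("#.*$", "", lines))
  lines <- lines[nzchar(lines)]
  cfg <- list()
  for (ln in lines) {
    kv <- strsplit(ln, "=", fixed = TRUE)[[1]]
    if (length(kv) != 2L) stop(sprintf("bad config line: '%s'", ln), call. = FALSE)
    key <- trimws(kv[1]); val <- trimws(kv[2])
    num <- suppressWarnings(as.numeric(val))
    val <- if (!is.na(num)) num else val
    parts <- strsplit(key, ".", fixed = TRUE)[[1]]
    if (length(parts) == 2L) cfg[[parts[1]]][[parts[2]]] <- val else cfg[[key]] <- val
  }
  cfg
}

#' Run the full synthetic pipeline and write its summary artifacts
#'
#' Orchestrates an end-to-end run on synthetic inputs: microglia-spine
#' contact scoring against the offset null, calcium responses with ROC
#' thresholding, effective-odor counts and lifetime sparseness, spine
#' morphometry, passive-property estimation, event-train post-filters, and
#' hierarchical-bootstrap group comparison. Every stage logs its exclusion
#' counts (rows in = rows out + excluded) and all artifacts reference one
#' JSON manifest; reruns with the same config and seed are bit-identical.
#'
#' @param config Nested list (or path to a [read_run_config()] file). Top
#'   level: `seed`; arms `contact`, `calcium`, `morpho`, `ephys`, `hstats`
#'   (each optional) carry generator settings.
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, a list of the per-arm results plus the manifest.
#' @export
run_pipeline <- function(config, out_dir) {
  if (is.character(config)) config <- read_run_config(config)
  seed <- as.integer(config$seed %||% 1L)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  results <- list()
  counts <- list()

  if (!is.null(config$contact)) {
    a <- config$contact
    cfg <- synth_config(seed = seed, image_size_px = a$image_size_px %||% 224)
    mv <- tryCatch(
      make_contact_movie(cfg, n_spines = a$n_spines %||% 20,
                         bias = a$bias %||% 0, n_frames = a$n_frames %||% 16),
      error = function(e) stop("stage contact (simulate): ", conditionMessage(e), call. = FALSE)
    )
    ct <- contact_chance_test(mv, start_px = a$start_px %||% 32,
                              step_px = a$step_px %||% 10)
    per_spine <- contact_spine_table(mv)
    utils::write.csv(per_spine, file.path(out_dir, "contact_spines.csv"), row.names = FALSE)
    utils::write.csv(data.frame(offset = seq_along(ct$null), value = ct$null),
                     file.path(out_dir, "contact_null.csv"), row.names = FALSE)
    results$contact <- list(observed = ct$observed, p = ct$p)
    counts$contact <- list(rows_in = nrow(per_spine), rows_out = nrow(per_spine),
                           excluded = 0L)
  }

  if (!is.null(config$calcium)) {
    a <- config$calcium
    cfg <- synth_config(seed = seed + 1L,
                        n_odors = a$n_odors %||% 15, n_repeats = a$n_repeats %||% 4)
    ds <- make_calcium_dataset(cfg, n_mice = a$n_mice %||% 2,
                               n_dendrites_per_mouse = a$n_dendrites %||% 10,
                               p_respond = a$p_respond %||% 0.3)
    rm_ <- response_matrix(ds$traces, ds$meta)
    n_rois <- length(unique(interaction(ds$traces$mouse, ds$traces$dendrite)))
    roc <- roc_threshold(rm_$responses$response, rm_$blanks$response)
    tun <- tuning_table(rm_, roc$threshold, cfg$n_odors)
    utils::write.csv(rm_$responses, file.path(out_dir, "responses.csv"), row.names = FALSE)
    utils::write.csv(tun, file.path(out_dir, "tuning.csv"), row.names = FALSE)
    utils::write.csv(rm_$excluded_rois, file.path(out_dir, "excluded_rois.csv"),
                     row.names = FALSE)
    results$calcium <- list(threshold = roc$threshold,
                            achieved_fpr = roc$achieved_fpr,
                            median_effective_odors = stats::median(tun$n_effective_odors),
                            median_ls = stats::median(tun$lifetime_sparseness))
    counts$calcium <- list(rows_in = n_rois,
                           rows_out = n_rois - nrow(rm_$excluded_rois),
                           excluded = nrow(rm_$excluded_rois))
  }

  if (!is.null(config$ephys)) {
    a <- config$ephys
    tp <- make_rc_testpulse(a$rs_mohm %||% 10, a$rm_mohm %||% 500,
                            a$cm_pf %||% 14, noise_pa = a$noise_pa %||% 2,
                            seed = seed + 2L)
    pp <- estimate_passive_properties(tp)
    train <- make_event_train(a$rate_hz %||% 10, a$duration_s %||% 60,
                              doublet_fraction = a$doublet_fraction %||% 0.1,
                              seed = seed + 3L)
    dbl <- doublet_exclusion(train$time_ms)
    summ <- train_summary(train$time_ms[dbl$keep],
                          train$amplitude_pa[dbl$keep], train$duration_ms)
    utils::write.csv(data.frame(property = c("rs_mohm", "rm_mohm", "cm_pf", "tau_ms"),
                                value = c(pp$rs_mohm, pp$rm_mohm, pp$cm_pf, pp$tau_ms)),
                     file.path(out_dir, "passive_properties.csv"), row.names = FALSE)
    results$ephys <- list(passive = pp[c("rs_mohm", "rm_mohm", "cm_pf")],
                          frequency_hz = summ$frequency_hz)
    counts$ephys <- list(rows_in = length(dbl$keep), rows_out = sum(dbl$keep),
                         excluded = sum(!dbl$keep))
  }

  if (!is.null(config$hstats)) {
    a <- config$hstats
    hv <- make_hierarchical_values(a$n_upper %||% 5, a$n_lower %||% 20,
                                   between_sd = a$between_sd %||% 1,
                                   within_sd = a$within_sd %||% 1,
                                   effect = a$effect %||% 0, seed = seed + 4L)
    cmp <- hboot_compare(hv$control, hv$treated,
                         n_boot = a$n_boot %||% 1000,
                         n_lower = a$n_lower_draw %||% 100, seed = seed + 5L)
    results$hstats <- list(p_direction = cmp$p_direction,
                           mean_control = cmp$res_a$mean, se_control = cmp$res_a$sd,
                           mean_treated = cmp$res_b$mean, se_treated = cmp$res_b$sd)
    counts$hstats <- list(rows_in = nrow(hv$control) + nrow(hv$treated),
                          rows_out = nrow(hv$control) + nrow(hv$treated),
                          excluded = 0L)
  }

  manifest <- list(
    package_version = as.character(utils::packageVersion("spineglia")),
    seed = seed, config = config, stage_counts = counts,
    results = results
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE, force = TRUE)
  # checksum every artifact against the manifest
  files <- setdiff(list.files(out_dir, full.names = TRUE),
                   file.path(out_dir, c("manifest.json", "checksums.csv")))
  if (length(files)) {
    utils::write.csv(data.frame(file = basename(files),
                                md5 = unname(tools::md5sum(files))),
                     file.path(out_dir, "checksums.csv"), row.names = FALSE)
  }
  invisible(list(results = results, manifest = manifest))
}

#' Per-spine interaction table for one movie
#'
#' @param movie A `contact_movie`.
#' @param criterion,strict Interaction criterion.
#' @return data.frame: spine_id, class, n_interactions, rate_per_10min,
#'   mean_length_min, mean_max_coverage.
#' @export
contact_spine_table <- function(movie, criterion = 0.05, strict = FALSE) {
  s <- dim(movie$microglia)[1]
  n_frames <- dim(movie$microglia)[3]
  total_min <- n_frames * movie$frame_interval_min
  rows <- lapply(movie$rois, function(r) {
    cov <- vapply(seq_len(n_frames), function(t) {
      coverage_fraction(r, movie$microglia[, , t])
    }, numeric(1))
    ints <- detect_interactions(cov, movie$frame_interval_min, criterion,
                                strict = strict)
    data.frame(spine_id = r$spine_id, class = r$class,
               n_interactions = nrow(ints),
               rate_per_10min = nrow(ints) * 10 / total_min,
               mean_length_min = if (nrow(ints)) mean(ints$length_min) else NA_real_,
               mean_max_coverage = if (nrow(ints)) mean(ints$max_coverage) else NA_real_)
  })
  do.call(rbind, rows)
}

#' Per-dendrite tuning table from a response matrix
#'
#' @param rm A [response_matrix()] result.
#' @param threshold ROC threshold.
#' @param n_odors Panel size `m` for lifetime sparseness.
#' @return data.frame: mouse, dendrite, n_effective_odors,
#'   lifetime_sparseness, responded_any.
#' @export
tuning_table <- function(rm, threshold, n_odors) {
  key <- interaction(rm$responses$mouse, rm$responses$dendrite, drop = TRUE)
  rows <- lapply(levels(key), function(kk) {
    sub <- rm$responses[key == kk, , drop = FALSE]
    r_thr <- apply_response_threshold(sub$response, threshold)
    data.frame(mouse = sub$mouse[1], dendrite = sub$dendrite[1],
               n_effective_odors = effective_odors(sub$response, threshold),
               lifetime_sparseness = lifetime_sparseness(r_thr, m = n_odors),
               responded_any = any(sub$response > threshold))
  })
  do.call(rbind, rows)
}
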