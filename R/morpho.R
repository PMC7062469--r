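#' Classify a spine as mushroom or filopodial
#'
#' A spine is filopodial when its maximum head diameter is less than 1.5
#' times its mean neck diameter (a headless protrusion); otherwise it is a
#' mushroom spine. The rule depends only on the head/neck ratio.
#'
#' @param head_max_diameter,neck_mean_diameter Diameters in micrometres
#'   (> 0); vectorized.
#' @param ratio Classification ratio (default 1.5; strict less-than).
#' @return Character vector: `"mushroom"` or `"filopodial"`.
#' @examples
#' classify_spine(c(0.70, 0.80), c(0.50, 0.50))
#' @export
classify_spine <- function(head_max_diameter, neck_mean_diameter, ratio = 1.5) {
  if (any(head_max_diameter <= 0) || any(neck_mean_diameter <= 0)) {
    stop("diameters must be > 0", call. = FALSE)
  }
  ifelse(head_max_diameter < ratio * neck_mean_diameter,
         "filopodial", "mushroom")
}

#' Read an Imaris-style spine morphometry export
#'
#' Accepts the exact exported header strings ("Filament No. Spine Terminal
#' Pts", "Spine Part Volume Head", "HeadMaxDiameter", "NeckMeanDiameter")
#' and returns tidy column names. When a protrusion `Length` column is
#' present, rows of 10 um or longer are dropped (only protrusions shorter
#' than 10 um count as spines), with the number removed recorded in an
#' attribute.
#'
#' @param path CSV file path.
#' @param max_protrusion_um Protrusion length cutoff (default 10).
#' @return data.frame with any of: `terminal_points`, `head_volume`,
#'   `head_max_diameter`, `neck_mean_diameter`, plus id columns unchanged;
#'   attribute `n_excluded_long` counts dropped rows.
#' @export
read_imaris_spines <- function(path, max_protrusion_um = 10) {
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  map <- c("Filament No. Spine Terminal Pts" = "terminal_points",
           "Spine Part Volume Head" = "head_volume",
           "HeadMaxDiameter" = "head_max_diameter",
           "NeckMeanDiameter" = "neck_mean_diameter")
  hit <- names(df) %in% names(map)
  names(df)[hit] <- map[names(df)[hit]]
  n_excl <- 0L
  if ("Length" %in% names(df)) {
    long <- df$Length >= max_protrusion_um
    n_excl <- sum(long)
    df <- df[!long, , drop = FALSE]
  }
  attr(df, "n_excluded_long") <- n_excl
  df
}

#' Spine density per dendrite and per cell
#'
#' Density is spine terminal points divided by dendrite length, so branched
#' spines count once per head. Dendrites shorter than 40 um are flagged
#' ineligible and excluded from the unweighted cell-level mean across a
#' cell's (1-5) apical dendrites.
#'
#' @param terminal_points Terminal-point counts per dendrite.
#' @param length_um Dendrite lengths in micrometres.
#' @param min_length_um Eligibility cutoff (default 40).
#' @return data.frame: `density` (spines/um), `eligible`.
#' @examples
#' spine_density(12, 40)$density  # 0.30
#' @export
spine_density <- function(terminal_points, length_um, min_length_um = 40) {
  if (any(length_um <= 0)) stop("dendrite length must be > 0", call. = FALSE)
  data.frame(density = terminal_points / length_um,
             eligible = length_um >= min_length_um)
}

#' @rdname spine_density
#' @param dendrites data.frame with columns `cell_id`, `terminal_points`,
#'   `length_um`.
#' @return For `cell_spine_density()`: data.frame `cell_id`, `density`
#'   (mean across eligible dendrites), `n_dendrites`.
#' @export
cell_spine_density <- function(dendrites, min_length_um = 40) {
  d <- cbind(dendrites,
             spine_density(dendrites$terminal_points, dendrites$length_um,
                           min_length_um))
  d <- d[d$eligible, , drop = FALSE]
  if (nrow(d) == 0L) stop("no eligible dendrites (all shorter than cutoff)", call. = FALSE)
  agg <- stats::aggregate(density ~ cell_id, data = d, FUN = mean)
  cnt <- stats::aggregate(density ~ cell_id, data = d, FUN = length)
  agg$n_dendrites <- cnt$density
  agg
}

#' Head-volume summary with hierarchical bootstrap
#'
#' Per group: the empirical distribution of spine head volumes and the
#' hierarchical-bootstrap sampling distribution of the mean head volume
#' (upper level = dendrites, lower level = spines, 100 spines drawn per
#' dendrite), plus the directional bootstrap probability between the two
#' groups. Empty classes are omitted with a warning.
#'
#' @param spines data.frame: `group`, `dendrite_id`, `head_volume`, and
#'   optionally `class` (filtered by `class_filter` if present).
#' @param class_filter Restrict to one spine class, or `NULL`.
#' @param n_boot,n_lower Bootstrap settings (see
#'   [hierarchical_bootstrap()]).
#' @param seed Integer seed or `NULL`.
#' @return List: `bootstrap` (named list of [hierarchical_bootstrap()]
#'   results per group), `p_direction` (P(first group mean > second)),
#'   `groups`.
#' @export
volume_summary <- function(spines, class_filter = NULL, n_boot = 1000,
                           n_lower = 100, seed = NULL) {
  if (!is.null(class_filter) && "class" %in% names(spines)) {
    spines <- spines[spines$class == class_filter, , drop = FALSE]
  }
  groups <- unique(spines$group)
  keep <- vapply(groups, function(g) sum(spines$group == g) > 0, logical(1))
  if (any(!keep)) warning("omitting empty groups")
  groups <- groups[keep]
  res <- lapply(seq_along(groups), function(i) {
    g <- groups[i]
    sub <- spines[spines$group == g, , drop = FALSE]
    hierarchical_bootstrap(
      data.frame(upper_id = sub$dendrite_id, value = sub$head_volume),
      statistic = "mean", n_boot = n_boot, n_lower = n_lower,
      seed = if (is.null(seed)) NULL else seed + i
    )
  })
  names(res) <- groups
  pd <- if (length(groups) >= 2L) bootstrap_p(res[[1L]], res[[2L]]) else NA_real_
  list(bootstrap = res, p_direction = pd, groups = groups)
}
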