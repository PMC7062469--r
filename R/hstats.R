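#' Two-level hierarchical bootstrap
#'
#' Resampling that respects nesting: each iteration draws the upper-level
#' units (mice, dendrites, or cells) with replacement (sample size = number
#' of units), then draws `n_lower` values with replacement from each drawn
#' unit, and computes the statistic on the pooled draw. Drawing a fixed
#' `n_lower` per unit represents every unit equally regardless of how many
#' raw observations it contributed; `n_lower` is chosen slightly larger
#' than the largest per-unit sample (100 for dendrites/spines, 5000 for
#' synaptic events in the original design).
#'
#' @param data data.frame with columns `upper_id` and `value`; every unit
#'   must be nonempty (checked at load).
#' @param statistic `"mean"`, `"median"`, or `"proportion"` (values must be
#'   0/1 or logical for proportions).
#' @param n_boot Number of bootstrap iterations (default 1000).
#' @param n_lower Values drawn per sampled unit (default 100).
#' @param seed Integer seed or `NULL`.
#' @return List of class `hboot`: `distribution` (length `n_boot`), `mean`,
#'   `sd` (the sampling-distribution SD reported as the bootstrap standard
#'   error), `statistic`, `n_boot`, `n_lower`, `n_upper`.
#' @examples
#' d <- data.frame(upper_id = rep(c("a", "b"), each = 5), value = rnorm(10))
#' hb <- hierarchical_bootstrap(d, "mean", n_boot = 50, seed = 1)
#' hb$mean
#' @export
hierarchical_bootstrap <- function(data, statistic = c("mean", "median", "proportion"),
                                   n_boot = 1000, n_lower = 100, seed = NULL) {
  statistic <- match.arg(statistic)
  if (n_lower < 1) stop("`n_lower` must be >= 1", call. = FALSE)
  if (!all(c("upper_id", "value") %in% names(data))) {
    stop("`data` needs columns `upper_id` and `value`", call. = FALSE)
  }
  vals <- split(as.numeric(data$value), data$upper_id)
  if (any(vapply(vals, length, integer(1)) == 0L)) {
    stop("every upper unit must contain at least one value", call. = FALSE)
  }
  if (statistic == "proportion" && !all(data$value %in% c(0, 1))) {
    stop("proportion statistic needs 0/1 (or logical) values", call. = FALSE)
  }
  stat_fn <- switch(statistic, mean = mean, median = stats::median,
                    proportion = mean)
  n_up <- length(vals)
  lens <- vapply(vals, length, integer(1))
  dist <- with_seed(seed, {
    vapply(seq_len(n_boot), function(b) {
      us <- sample.int(n_up, n_up, replace = TRUE)
      draw <- unlist(lapply(us, function(u) {
        vals[[u]][sample.int(lens[u], n_lower, replace = TRUE)]
      }), use.names = FALSE)
      stat_fn(draw)
    }, numeric(1))
  })
  structure(list(distribution = dist, mean = mean(dist), sd = stats::sd(dist),
                 statistic = statistic, n_boot = n_boot, n_lower = n_lower,
                 n_upper = n_up),
            class = "hboot")
}

#' Directional bootstrap probability between two groups
#'
#' The probability, over paired bootstrap iterations, that group A's
#' statistic exceeds group B's (ties credited 1/2, so
#' `p(A,B) + p(B,A) = 1` exactly). Callers report `p` or `1 - p` according
#' to which direction is of interest.
#'
#' @param res_a,res_b [hierarchical_bootstrap()] results with the same
#'   `n_boot`, independently seeded.
#' @return `p_direction` in `[0, 1]`.
#' @export
bootstrap_p <- function(res_a, res_b) {
  a <- res_a$distribution; b <- res_b$distribution
  if (length(a) != length(b)) stop("bootstrap distributions differ in length", call. = FALSE)
  mean((a > b) + 0.5 * (a == b))
}

#' Rank-sum and distribution comparisons between two groups
#'
#' Thin delegation to the standard two-sided Wilcoxon rank-sum test (for
#' medians of unpaired non-normal samples) and the two-sample
#' Kolmogorov-Smirnov test (for whole distributions), packaged with the
#' medians and interquartile ranges that accompany them in reporting.
#'
#' @param group_a,group_b Nonempty numeric vectors.
#' @return List: `wilcoxon` (`statistic`, `p`), `ks` (`D`, `p`),
#'   `medians`, `iqrs`.
#' @export
rank_and_distribution_tests <- function(group_a, group_b) {
  if (length(group_a) == 0L || length(group_b) == 0L) {
    stop("both groups must be nonempty", call. = FALSE)
  }
  w <- stats::wilcox.test(group_a, group_b, exact = FALSE)
  k <- suppressWarnings(stats::ks.test(group_a, group_b))
  list(
    wilcoxon = list(statistic = unname(w$statistic), p = w$p.value),
    ks = list(D = unname(k$statistic), p = k$p.value),
    medians = c(a = stats::median(group_a), b = stats::median(group_b)),
    iqrs = c(a = stats::IQR(group_a), b = stats::IQR(group_b))
  )
}

#' Compare two nested datasets with the hierarchical bootstrap
#'
#' Convenience wrapper: bootstraps both groups (independently seeded from
#' `seed`) and returns the directional probability that group A's
#' statistic exceeds group B's, together with both sampling distributions.
#'
#' @param data_a,data_b data.frames with `upper_id`, `value`.
#' @inheritParams hierarchical_bootstrap
#' @return List: `res_a`, `res_b`, `p_direction`.
#' @export
hboot_compare <- function(data_a, data_b, statistic = "mean",
                          n_boot = 1000, n_lower = 100, seed = NULL) {
  res_a <- hierarchical_bootstrap(data_a, statistic, n_boot, n_lower,
                                  seed = if (is.null(seed)) NULL else seed)
  res_b <- hierarchical_bootstrap(data_b, statistic, n_boot, n_lower,
                                  seed = if (is.null(seed)) NULL else seed + 1L)
  list(res_a = res_a, res_b = res_b, p_direction = bootstrap_p(res_a, res_b))
}
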