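#!/usr/bin/env Rscript
# Spine morphometry (classification, density, head-volume bootstrap) and
# electrophysiology (passive properties, doublet filtering, train
# summaries) on the simulated datasets.

suppressPackageStartupMessages(library(spineglia))
out <- "results"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

## ---- morphometry -------------------------------------------------------
sp <- read_imaris_spines("results/data/spine_morphometry.csv")
cat("protrusions >= 10 um excluded:", attr(sp, "n_excluded_long"), "\n")
sp$class <- classify_spine(sp$head_max_diameter, sp$neck_mean_diameter)
print(table(sp$group, sp$class))

dend <- unique(sp[, c("group", "cell_id", "dendrite_id",
                      "terminal_points", "dendrite_length_um")])
dens <- cell_spine_density(data.frame(cell_id = dend$cell_id,
                                      terminal_points = dend$terminal_points,
                                      length_um = dend$dendrite_length_um))
dens$group <- sp$group[match(dens$cell_id, sp$cell_id)]
write.csv(dens, file.path(out, "spine_density_by_cell.csv"), row.names = FALSE)
dtest <- rank_and_distribution_tests(dens$density[dens$group == "control"],
                                     dens$density[dens$group == "treated"])
cat(sprintf("density medians (ctl, trt): %.3f, %.3f spines/um; rank-sum p = %.2g\n",
            dtest$medians[1], dtest$medians[2], dtest$wilcoxon$p))

vs <- volume_summary(data.frame(group = sp$group, dendrite_id = sp$dendrite_id,
                                head_volume = sp$head_volume),
                     n_boot = 1000, n_lower = 100, seed = 20260120)
cat(sprintf("mean head volume: control %.3f +/- %.3f vs treated %.3f +/- %.3f um^3\n",
            vs$bootstrap$control$mean, vs$bootstrap$control$sd,
            vs$bootstrap$treated$mean, vs$bootstrap$treated$sd))
cat(sprintf("P(control > treated) = %.4f (hierarchical bootstrap)\n",
            vs$p_direction))
jsonlite::write_json(list(
  control = vs$bootstrap$control[c("mean", "sd")],
  treated = vs$bootstrap$treated[c("mean", "sd")],
  p_direction = vs$p_direction), file.path(out, "head_volume_bootstrap.json"),
  auto_unbox = TRUE, digits = NA)

## ---- electrophysiology -------------------------------------------------
tp <- make_rc_testpulse(10, 500, 14, noise_pa = 2, seed = 20260101L + 4L)
pp <- estimate_passive_properties(tp)
cat(sprintf("passive properties: Rs %.1f MOhm, Rm %.0f MOhm, Cm %.1f pF (tau %.3f ms)\n",
            pp$rs_mohm, pp$rm_mohm, pp$cm_pf, pp$tau_ms))
cat("passes the < 50 MOhm inclusion rule:", pp$passes_rs_inclusion, "\n")

ev <- read.csv("results/data/event_trains.csv")
summ <- do.call(rbind, lapply(split(ev, ev$cell_id), function(tr) {
  d <- doublet_exclusion(tr$time_ms)
  s <- train_summary(tr$time_ms[d$keep], tr$amplitude_pa[d$keep],
                     duration_ms = 300000)
  data.frame(cell_id = tr$cell_id[1], group = tr$group[1],
             n_raw = nrow(tr), n_kept = s$n_events,
             frequency_hz = s$frequency_hz,
             mean_amplitude_pa = mean(s$amplitudes_pa))
}))
write.csv(summ, file.path(out, "event_train_summaries.csv"), row.names = FALSE)
cat(sprintf("doublets excluded: %d of %d events (%.1f%%)\n",
            sum(summ$n_raw - summ$n_kept), sum(summ$n_raw),
            100 * sum(summ$n_raw - summ$n_kept) / sum(summ$n_raw)))
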