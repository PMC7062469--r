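#!/usr/bin/env Rscript
# Generate every synthetic dataset the downstream analyses consume.
# All randomness flows from one seed; rerunning reproduces the files bit
# for bit. Outputs land under results/data/.

suppressPackageStartupMessages(library(spineglia))
seed <- 20260101L
out <- "results/data"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

## 1. Microglia / spine contact movie: 20 spines, 16 frames (48 min at one
##    frame per 3 min), 224 px field, no targeting bias.
cfg_mov <- synth_config(seed = seed, image_size_px = 224)
movie <- make_contact_movie(cfg_mov, n_spines = 20, bias = 0, n_frames = 16)
if (requireNamespace("tiff", quietly = TRUE)) {
  write_contact_movie(movie, file.path(out, "contact_movie.tif"))
}
write_rois_json(movie$rois, file.path(out, "contact_rois.json"))
write_ground_truth_json(movie$ground_truth[c("contact_frames", "classes", "bias")],
                        file.path(out, "contact_ground_truth.json"))

## 2. Trial-structured calcium traces: control and treated arms with a
##    lower response probability in the treated group (the kind of
##    difference the response pipeline is meant to resolve).
cfg_ca <- synth_config(seed = seed + 1L, n_odors = 15, n_repeats = 4)
ctl <- make_calcium_dataset(cfg_ca, n_mice = 3, n_dendrites_per_mouse = 12,
                            p_respond = 0.25, amp_sd_units = 3)
cfg_ca2 <- synth_config(seed = seed + 2L, n_odors = 15, n_repeats = 4)
plx <- make_calcium_dataset(cfg_ca2, n_mice = 3, n_dendrites_per_mouse = 12,
                            p_respond = 0.12, amp_sd_units = 3)
write_traces_csv(ctl$traces, file.path(out, "calcium_control.csv"))
write_traces_csv(plx$traces, file.path(out, "calcium_treated.csv"))
write_ground_truth_json(list(control = ctl$ground_truth,
                             treated = plx$ground_truth),
                        file.path(out, "calcium_ground_truth.json"))

## 3. Imaris-style morphometry table with a known head-volume shift.
set.seed(seed + 3L)
mk_spines <- function(group, n_cells, mu_vol) {
  do.call(rbind, lapply(seq_len(n_cells), function(ci) {
    n_dend <- sample(1:5, 1)
    do.call(rbind, lapply(seq_len(n_dend), function(di) {
      n_sp <- sample(20:60, 1)
      neck <- runif(n_sp, 0.2, 0.6)
      mush <- runif(n_sp) < 0.37
      data.frame(check.names = FALSE,
        group = group, cell_id = sprintf("%s_c%02d", group, ci),
        dendrite_id = sprintf("%s_c%02d_d%d", group, ci, di),
        `Filament No. Spine Terminal Pts` = n_sp,
        dendrite_length_um = runif(1, 45, 120),
        `Spine Part Volume Head` = pmax(0.01, rnorm(n_sp, mu_vol, 0.08)),
        HeadMaxDiameter = neck * ifelse(mush, runif(n_sp, 1.6, 3), runif(n_sp, 0.8, 1.4)),
        NeckMeanDiameter = neck,
        Length = runif(n_sp, 0.5, 8)
      )
    }))
  }))
}
morpho <- rbind(mk_spines("control", 8, 0.30), mk_spines("treated", 8, 0.24))
write.csv(morpho, file.path(out, "spine_morphometry.csv"), row.names = FALSE)

## 4. RC test pulse (the standard -10 mV / 20 ms / 50 reps / 20 kHz design).
tp <- make_rc_testpulse(10, 500, 14, noise_pa = 2, seed = seed + 4L)
write.csv(data.frame(t_ms = tp$t_ms, i_pa_mean = colMeans(tp$i_pa)),
          file.path(out, "test_pulse_mean.csv"), row.names = FALSE)

## 5. Synaptic event trains with planted doublets, per cell.
set.seed(seed + 5L)
trains <- do.call(rbind, lapply(1:12, function(ci) {
  tr <- make_event_train(rate_hz = runif(1, 5, 25), duration_s = 300,
                         doublet_fraction = 0.08, seed = seed + 100L + ci)
  data.frame(cell_id = sprintf("cell%02d", ci),
             group = if (ci <= 6) "control" else "treated",
             time_ms = tr$time_ms,
             amplitude_pa = tr$amplitude_pa * if (ci <= 6) 1.2 else 1.0)
}))
write.csv(trains, file.path(out, "event_trains.csv"), row.names = FALSE)

cat("simulated inputs written to", out, "\n")
cat("  contact movie:", dim(movie$microglia)[3], "frames,",
    length(movie$rois), "spines\n")
cat("  calcium traces:", nrow(ctl$traces) + nrow(plx$traces), "rows\n")
cat("  morphometry:", nrow(morpho), "spines\n")
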