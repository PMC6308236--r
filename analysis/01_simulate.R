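#!/usr/bin/env Rscript

# Stage 1: the synthetic study design.
#
# Generates the five-condition synthetic chromatin-dynamics study (one
# tagged locus per cell plus bulk-probe tracks, fractional Brownian motion
# inside a drifting, rotating elliptical nucleus) and writes the ground
# truth to results/01_synthetic/. Also records the photoactivation
# dosimetry bookkeeping and verifies the generator's MSD law against the
# closed form before anything downstream consumes it.

suppressMessages(library(chromotrack))

out_dir <- "results/01_synthetic"
dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
seed <- 42L

## Photoactivation dosimetry of the damage conditions: 15 J/m^2/s for 10 min
dose <- compute_fluence(15, 600, target_area = 1e-12)
cat(sprintf("dosimetry: %.0f J/m2 delivered to the dish, %.1f nJ onto a ~1 um2 focus\n",
            dose$fluence, dose$energy * 1e9))

## Generator self-check: ensemble MSD of simulated fBM vs 4 d tau^alpha
p <- motion_params(alpha = 0.8, d_app = 2.5e-3, frame_interval = 3,
                   n_frames = 30)
tracks <- simulate_fbm_track(p, seed = seed, n_tracks = 2000)
curves <- lapply(tracks, track_msd, frame_interval = 3)
ens <- ensemble_msd(curves, seq_along(curves))
theory <- 4 * 2.5e-3 * ens$lags^0.8
cat(sprintf("generator MSD law: max |relative deviation| from 4 d tau^alpha = %.3f%% over %d lags\n",
            100 * max(abs(ens$values / theory - 1)), length(ens$lags)))

## The study itself: track tables + ground truth per condition
rows <- list()
for (cond in condition_labels()) {
  ds <- generate_condition_dataset(cond, n_cells = 10, seed = seed +
                                     match(cond, condition_labels()),
                                   n_frames = 30, render = FALSE)
  per_cell <- lapply(ds$truth, function(cell) {
    mk <- function(trs) lapply(trs, function(m)
      data.frame(frame = seq_len(nrow(m)), x = m[, 1], y = m[, 2]))
    list(locus = mk(cell$fixed$locus), bulk = mk(cell$fixed$bulk))
  })
  ts <- build_track_set(per_cell, cond, pixel_size = ds$scene$pixel_size,
                        frame_interval = ds$frame_interval)
  write_tracks_csv(ts, file.path(out_dir, paste0("truth_tracks_",
                                                 gsub("-", "_", cond), ".csv")))
  write_transforms_csv(ds$truth[[1]]$transforms,
                       file.path(out_dir, paste0("true_transforms_",
                                                 gsub("-", "_", cond),
                                                 "_cell1.csv")))
  rows[[cond]] <- data.frame(
    condition = cond,
    preset_alpha = condition_preset(cond)$alpha,
    preset_d_app = condition_preset(cond)$d_app,
    preset_d_cv = condition_preset(cond)$d_cv,
    n_cells = ds$n_cells,
    n_tracks = nrow(ts[!duplicated(ts$track_id), ]))
}
design <- do.call(rbind, rows)
utils::write.csv(design, file.path(out_dir, "study_design.csv"),
                 row.names = FALSE)
cat("study design:\n")
print(design, row.names = FALSE)

## One rendered example movie for inspection
ds <- generate_condition_dataset("repressed", 2, seed = seed, n_frames = 10)
write_stack_tiff(ds$stacks[[1]], file.path(out_dir, "example_stack"))
cat("wrote example rendered movie to", file.path(out_dir, "example_stack"), "\n")
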