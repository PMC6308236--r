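#' Pipeline configuration
#'
#' Collects every stage parameter of the synthetic study pipeline in one
#' serializable list; a config plus its seed reproduces a run bit-for-bit
#' through generation and deterministically through analysis.
#'
#' @param conditions condition labels to simulate (see [condition_preset()]).
#' @param n_cells cells per condition.
#' @param n_frames frames per movie.
#' @param seed master seed.
#' @param scene a [nucleus_scene()].
#' @param frame_interval minutes between frames.
#' @param threshold_k detection threshold (background-SD units).
#' @param max_link_distance linking gate (px).
#' @param max_lag_fraction largest reported MSD lag as fraction of track
#'   length.
#' @param reference_condition baseline group for comparisons.
#' @param out_dir optional output directory for CSV/YAML artifacts.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(conditions = c("bulk", "repressed",
                                           "damaged-repressed"),
                            n_cells = 10L, n_frames = 30L, seed = 1L,
                            scene = nucleus_scene(), frame_interval = 3,
                            threshold_k = 4, max_link_distance = 5,
                            max_lag_fraction = 1 / 3,
                            reference_condition = "bulk",
                            out_dir = NULL) {
  stopifnot(all(conditions %in% condition_labels()), n_cells >= 2)
  structure(list(conditions = conditions, n_cells = as.integer(n_cells),
                 n_frames = as.integer(n_frames), seed = as.integer(seed),
                 scene = scene, frame_interval = frame_interval,
                 threshold_k = threshold_k,
                 max_link_distance = max_link_distance,
                 max_lag_fraction = max_lag_fraction,
                 reference_condition = reference_condition,
                 out_dir = out_dir),
            class = "pipeline_config")
}

# Process one cell's rendered stack: estimate transforms, detect per frame
# on each probe channel, link, keep persistent tracks, and map them to
# nucleus-fixed coordinates with the estimated transforms.
process_cell_stack <- function(stack, config) {
  transforms <- estimate_transforms(stack)
  psf <- config$scene$psf_sigma
  n_frames <- dim(stack$channels[[1]])[3]
  probes <- setdiff(names(stack$channels), "nucleus")
  detections <- list()
  persistent <- list()
  for (ch in probes) {
    dets <- lapply(seq_len(n_frames), function(t) {
      fr <- stack$channels[[ch]][, , t]
      calib <- calibrate_noise(fr, threshold_k = config$threshold_k)
      detect_particles(fr, calib, psf)
    })
    detections[[ch]] <- dets
    cand <- link_frames(dets, config$max_link_distance)
    pt <- suppressWarnings(filter_persistent(cand, n_frames))
    # coordinate-level rigid correction (no image resampling)
    pt$tracks <- lapply(pt$tracks, function(tr) {
      fixed <- transform_tracks(cbind(tr$x, tr$y), transforms)
      tr$x <- fixed[, 1]; tr$y <- fixed[, 2]
      tr
    })
    persistent[[ch]] <- pt
  }
  list(transforms = transforms, detections = detections,
       persistent = persistent)
}

#' Run the synthetic chromatin-dynamics study end to end
#'
#' For every condition: simulate and render per-cell nucleus movies,
#' estimate and remove rigid nuclear motion, detect and link puncta, keep
#' persistent tracks, compute per-track/cell/ensemble MSDs with outlier
#' exclusion, fit the anomalous-diffusion power law, and compare each
#' condition to the reference per lag with Student's t. Locus probes are
#' analysed for locus conditions; the bulk condition is measured from its
#' bulk-probe tracks.
#'
#' @param config a [pipeline_config()].
#' @return list of class `pipeline_result`: per-condition `analyses`
#'   (tracks, `msd` from [analyze_msd()], `fit`, per-cell intermediates),
#'   `comparisons` (vs the reference), `manifest` (parameters and per-stage
#'   counts), `config`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  set.seed(config$seed)
  cond_seeds <- sample.int(.Machine$integer.max - 1L, length(config$conditions))
  names(cond_seeds) <- config$conditions
  analyses <- list()
  counts <- list()
  for (cond in config$conditions) {
    dataset <- generate_condition_dataset(
      cond, config$n_cells, cond_seeds[[cond]], n_frames = config$n_frames,
      scene = config$scene, render = TRUE,
      frame_interval = config$frame_interval)
    cells <- lapply(dataset$stacks, process_cell_stack, config = config)
    per_cell <- lapply(cells, `[[`, "persistent")
    tracks <- build_track_set(per_cell, cond, config$scene$pixel_size,
                              config$frame_interval)
    if (!nrow(tracks))
      stop("stage 'link': empty result for condition ", cond)
    probe <- if (cond == "bulk") "bulk" else "locus"
    msd <- analyze_msd(tracks, probe = probe,
                       max_lag_fraction = config$max_lag_fraction)
    fit <- fit_power_law(msd$ensemble)
    analyses[[cond]] <- list(dataset = dataset, cells = cells,
                             tracks = tracks, probe = probe,
                             msd = msd, fit = fit)
    counts[[cond]] <- list(
      cells = config$n_cells,
      detections = sum(vapply(cells, function(cl)
        sum(vapply(cl$detections, function(dch)
          sum(vapply(dch, nrow, 0L)), 0L)), 0L)),
      candidate_tracks = sum(vapply(cells, function(cl)
        sum(vapply(cl$persistent, `[[`, 0L, "n_candidates")), 0L)),
      persistent_tracks = sum(vapply(cells, function(cl)
        sum(vapply(cl$persistent, `[[`, 0L, "n_retained")), 0L)),
      analysed_tracks = msd$n_tracks_used,
      outliers_removed = length(msd$outliers$excluded))
  }
  ref <- config$reference_condition
  comparisons <- list()
  for (cond in setdiff(config$conditions, ref)) {
    comparisons[[paste0(cond, "_vs_", ref)]] <-
      compare_msd(analyses[[cond]]$msd$ensemble,
                  analyses[[ref]]$msd$ensemble)
  }
  manifest <- list(
    package_version = as.character(utils::packageVersion("chromotrack")),
    r_version = R.version.string,
    seed = config$seed,
    condition_seeds = as.list(cond_seeds),
    parameters = list(
      n_cells = config$n_cells, n_frames = config$n_frames,
      frame_interval_min = config$frame_interval,
      pixel_size_um = config$scene$pixel_size,
      psf_sigma_px = config$scene$psf_sigma,
      threshold_k = config$threshold_k,
      max_link_distance_px = config$max_link_distance,
      max_lag_fraction = config$max_lag_fraction,
      drift_per_frame_px = config$scene$drift_per_frame,
      rotation_per_frame_deg = config$scene$rotation_per_frame,
      noise_sd = config$scene$noise_sd,
      spot_amplitude = config$scene$spot_amplitude),
    counts = counts)
  result <- structure(list(analyses = analyses, comparisons = comparisons,
                           manifest = manifest, config = config),
                      class = "pipeline_result")
  if (!is.null(config$out_dir)) write_pipeline_outputs(result, config$out_dir)
  result
}

#' Validate pipeline output against synthetic ground truth
#'
#' Computes stage-level recovery metrics for one condition of a pipeline
#' run: detection recall/precision and localization error (2 px match
#' radius against true lab-frame spot positions), per-frame registration
#' residuals, linking accuracy (persistent tracks whose every position stays
#' within the match radius of a single true track), and the error of the
#' recovered anomalous exponent and diffusion coefficient against the
#' dataset's true (realized) motion parameters.
#'
#' @param result a `pipeline_result`.
#' @param condition condition label present in the run.
#' @param match_radius px radius for detection/track matching (default 2).
#' @return list of class `recovery_report`.
#' @export
validate_against_truth <- function(result, condition, match_radius = 2) {
  an <- result$analyses[[condition]]
  if (is.null(an)) stop("condition not present in pipeline result")
  truth <- an$dataset$truth
  if (length(truth) != length(an$cells))
    stop("truth/result cell mismatch")
  n_frames <- an$dataset$n_frames
  tp <- fp <- fn <- 0L
  sq_err <- c()
  reg_dpos <- c(); reg_dang <- c()
  n_tracks_matched <- 0L; n_tracks_true <- 0L; n_tracks_found <- 0L
  for (i in seq_along(an$cells)) {
    cell <- an$cells[[i]]
    tru <- truth[[i]]
    if (!identical(tru$cell_id, i)) stop("truth/result cell mismatch")
    for (ch in names(cell$detections)) {
      true_tracks <- tru$lab[[ch]]
      for (t in seq_len(n_frames)) {
        dets <- cell$detections[[ch]][[t]]
        truth_xy <- t(vapply(true_tracks, function(m) m[t, ], numeric(2)))
        used <- rep(FALSE, nrow(truth_xy))
        for (j in seq_len(nrow(dets))) {
          d2 <- (truth_xy[, 1] - dets$x[j])^2 + (truth_xy[, 2] - dets$y[j])^2
          d2[used] <- Inf
          k <- which.min(d2)
          if (length(k) && d2[k] <= match_radius^2) {
            used[k] <- TRUE; tp <- tp + 1L; sq_err <- c(sq_err, d2[k])
          } else fp <- fp + 1L
        }
        fn <- fn + sum(!used)
      }
    }
    pm_hat <- per_frame_motion(cell$transforms)
    pm_true <- per_frame_motion(tru$transforms)
    reg_dpos <- c(reg_dpos, sqrt((pm_hat$ddx - pm_true$ddx)^2 +
                                   (pm_hat$ddy - pm_true$ddy)^2))
    reg_dang <- c(reg_dang, abs(pm_hat$dtheta_deg - pm_true$dtheta_deg))
    # linking: every persistent track must shadow one true nucleus-fixed track
    for (ch in names(cell$persistent)) {
      n_tracks_true <- n_tracks_true + length(tru$fixed[[ch]])
      for (tr in cell$persistent[[ch]]$tracks) {
        n_tracks_found <- n_tracks_found + 1L
        devs <- vapply(tru$fixed[[ch]], function(m)
          max(sqrt((m[, 1] - tr$x)^2 + (m[, 2] - tr$y)^2)), 0)
        if (min(devs) <= match_radius)
          n_tracks_matched <- n_tracks_matched + 1L
      }
    }
  }
  probe <- an$probe
  true_alpha <- mean(vapply(truth, function(tr)
    tr$params[[paste0(probe, "_alpha")]], 0))
  true_d <- mean(unlist(lapply(truth, function(tr)
    tr$params[[paste0(probe, "_d_app")]])))
  structure(list(
    condition = condition,
    detection = list(recall = tp / (tp + fn), precision = tp / (tp + fp),
                     localization_rmse_px = sqrt(mean(sq_err))),
    registration = list(drift_rmse_px = sqrt(mean(reg_dpos^2)),
                        rotation_rmse_deg = sqrt(mean(reg_dang^2)),
                        drift_max_px = max(reg_dpos),
                        rotation_max_deg = max(reg_dang)),
    linking = list(n_true = n_tracks_true, n_found = n_tracks_found,
                   n_matched = n_tracks_matched,
                   accuracy = n_tracks_matched / max(n_tracks_found, 1L)),
    recovery = list(true_alpha = true_alpha, alpha_hat = an$fit$alpha_hat,
                    alpha_error = an$fit$alpha_hat - true_alpha,
                    true_d_app = true_d, d_hat = an$fit$d_hat,
                    d_rel_error = an$fit$d_hat / true_d - 1)),
    class = "recovery_report")
}
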