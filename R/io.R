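#' Read and write image stacks as multi-page TIFF
#'
#' One 16-bit multi-page TIFF per channel (T pages of ny x nx), counts
#' stored as value/65535 per the TIFF convention.
#'
#' @param stack an `image_stack_set`.
#' @param dir output directory (one `<channel>.tif` per channel plus a
#'   `stack.yaml` with frame interval and pixel size).
#' @export
write_stack_tiff <- function(stack, dir) {
  stopifnot(inherits(stack, "image_stack_set"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (ch in names(stack$channels)) {
    arr <- stack$channels[[ch]]
    pages <- lapply(seq_len(dim(arr)[3]), function(t)
      pmin(pmax(arr[, , t] / 65535, 0), 1))
    tiff::writeTIFF(pages, file.path(dir, paste0(ch, ".tif")),
                    bits.per.sample = 16)
  }
  yaml::write_yaml(list(frame_interval = stack$frame_interval,
                        pixel_size = stack$pixel_size,
                        channels = names(stack$channels)),
                   file.path(dir, "stack.yaml"))
  invisible(dir)
}

#' @rdname write_stack_tiff
#' @param dir directory written by [write_stack_tiff()].
#' @return an `image_stack_set`.
#' @export
read_stack_tiff <- function(dir) {
  meta <- yaml::read_yaml(file.path(dir, "stack.yaml"))
  channels <- lapply(meta$channels, function(ch) {
    pages <- tiff::readTIFF(file.path(dir, paste0(ch, ".tif")), all = TRUE)
    arr <- array(0, c(dim(pages[[1]]), length(pages)))
    for (t in seq_along(pages)) arr[, , t] <- pages[[t]] * 65535
    arr
  })
  names(channels) <- meta$channels
  structure(list(channels = channels, frame_interval = meta$frame_interval,
                 pixel_size = meta$pixel_size, clipped = NULL),
            class = "image_stack_set")
}

#' Write/read a rigid transform series as CSV
#'
#' Columns `frame`, `dx_px`, `dy_px`, `theta_deg`; the rotation centre and
#' reference frame ride along as leading comment lines.
#'
#' @param transforms a [rigid_transform_series()].
#' @param path CSV path.
#' @export
write_transforms_csv <- function(transforms, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# center_x=%.6f center_y=%.6f reference=%d",
                     attr(transforms, "center")[1],
                     attr(transforms, "center")[2],
                     attr(transforms, "reference")), con)
  utils::write.csv(data.frame(frame = transforms$frame,
                              dx_px = transforms$dx, dy_px = transforms$dy,
                              theta_deg = transforms$theta_deg),
                   con, row.names = FALSE)
  invisible(path)
}

#' @rdname write_transforms_csv
#' @export
read_transforms_csv <- function(path) {
  hdr <- readLines(path, n = 1)
  m <- as.numeric(regmatches(hdr, gregexpr("-?[0-9.]+", hdr))[[1]])
  d <- utils::read.csv(path, comment.char = "#")
  rigid_transform_series(d$dx_px, d$dy_px, d$theta_deg,
                         center = m[1:2], reference = as.integer(m[3]))
}

#' Write/read a track table as CSV
#'
#' Long format: `cell_id, track_id, probe, condition, frame, x_px, y_px,
#' x_um, y_um`, with pixel size and frame interval as comment metadata.
#'
#' @param tracks a `track_set`.
#' @param path CSV path.
#' @export
write_tracks_csv <- function(tracks, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# pixel_size=%.6f frame_interval=%.6f",
                     attr(tracks, "pixel_size"),
                     attr(tracks, "frame_interval")), con)
  utils::write.csv(as.data.frame(tracks), con, row.names = FALSE)
  invisible(path)
}

#' @rdname write_tracks_csv
#' @export
read_tracks_csv <- function(path) {
  hdr <- readLines(path, n = 1)
  m <- as.numeric(regmatches(hdr, gregexpr("[0-9.]+", hdr))[[1]])
  d <- utils::read.csv(path, comment.char = "#")
  attr(d, "pixel_size") <- m[1]
  attr(d, "frame_interval") <- m[2]
  class(d) <- c("track_set", "data.frame")
  d
}

# Write the tabular artifacts of a pipeline run: per-condition ensemble MSD
# curves, pairwise comparisons, power-law fits, track tables, manifest.
write_pipeline_outputs <- function(result, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  curves <- do.call(rbind, lapply(names(result$analyses), function(cond) {
    e <- result$analyses[[cond]]$msd$ensemble
    data.frame(condition = cond, lag_min = e$lags, msd_um2 = e$values,
               sem = e$sem, n = e$n_cells)
  }))
  utils::write.csv(curves, file.path(out_dir, "msd_curves.csv"),
                   row.names = FALSE)
  if (length(result$comparisons)) {
    comp <- do.call(rbind, lapply(names(result$comparisons), function(nm)
      cbind(data.frame(comparison = nm),
            as.data.frame(result$comparisons[[nm]]))))
    utils::write.csv(comp, file.path(out_dir, "comparisons.csv"),
                     row.names = FALSE)
  }
  fits <- do.call(rbind, lapply(names(result$analyses), function(cond) {
    f <- result$analyses[[cond]]$fit
    data.frame(condition = cond, alpha_hat = f$alpha_hat, d_hat = f$d_hat,
               r_squared = f$r_squared)
  }))
  utils::write.csv(fits, file.path(out_dir, "power_law_fits.csv"),
                   row.names = FALSE)
  for (cond in names(result$analyses))
    write_tracks_csv(result$analyses[[cond]]$tracks,
                     file.path(out_dir, paste0("tracks_", cond, ".csv")))
  yaml::write_yaml(result$manifest, file.path(out_dir, "manifest.yaml"))
  invisible(out_dir)
}
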