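#' Link per-frame detections into candidate trajectories
#'
#' Frame-to-frame correspondence by greedy ascending-distance one-to-one
#' assignment: all head/detection pairs within `max_link_distance` are sorted
#' by distance (ties broken by track index, then detection index, so the
#' result is independent of detection listing order) and assigned greedily.
#' Unassigned detections start new candidate tracks; there is no gap closing,
#' so a missed detection permanently ends a candidate.
#'
#' @param detections list of per-frame data frames with columns `x`, `y`
#'   (px) and optionally `intensity`, `snr`; element t = frame t.
#' @param max_link_distance maximum frame-to-frame displacement (px).
#' @return list of candidate tracks, each a data frame with columns `frame`,
#'   `x`, `y` (plus carried columns), frames consecutive.
#' @export
link_frames <- function(detections, max_link_distance = 5) {
  n_frames <- length(detections)
  tracks <- list()        # finished candidates
  active <- list()        # open candidates, head at current frame
  new_track <- function(det_row, t) {
    cbind(data.frame(frame = t), det_row)
  }
  d0 <- detections[[1]]
  for (i in seq_len(nrow(d0))) active[[i]] <- new_track(d0[i, , drop = FALSE], 1L)
  for (t in seq_len(n_frames - 1L)) {
    dets <- detections[[t + 1L]]
    n_a <- length(active); n_d <- nrow(dets)
    assigned_a <- rep(FALSE, n_a); assigned_d <- rep(FALSE, max(n_d, 0))
    if (n_a > 0 && n_d > 0) {
      hx <- vapply(active, function(tr) tr$x[nrow(tr)], 0)
      hy <- vapply(active, function(tr) tr$y[nrow(tr)], 0)
      dmat <- sqrt(outer(hx, dets$x, "-")^2 + outer(hy, dets$y, "-")^2)
      cand <- which(dmat <= max_link_distance, arr.ind = TRUE)
      if (nrow(cand)) {
        ord <- order(dmat[cand], cand[, 1], cand[, 2])
        for (k in ord) {
          a <- cand[k, 1]; d <- cand[k, 2]
          if (assigned_a[a] || assigned_d[d]) next
          assigned_a[a] <- TRUE; assigned_d[d] <- TRUE
          active[[a]] <- rbind(active[[a]],
                               new_track(dets[d, , drop = FALSE], t + 1L))
        }
      }
    }
    # close unextended candidates, open new ones for unassigned detections
    tracks <- c(tracks, active[!assigned_a])
    active <- active[assigned_a]
    if (n_d > 0) {
      for (d in which(!assigned_d))
        active[[length(active) + 1L]] <- new_track(dets[d, , drop = FALSE], t + 1L)
    }
  }
  tracks <- c(tracks, active)
  lapply(tracks, function(tr) { rownames(tr) <- NULL; tr })
}

#' Keep only full-duration (persistent) tracks
#'
#' Retains exactly the candidates with one position in every frame of the
#' movie; everything else — late starters, early enders, broken tracks — is
#' discarded. An empty result is flagged so downstream stages can refuse it.
#'
#' @param candidates list of candidate tracks from [link_frames()].
#' @param n_frames total frames in the movie.
#' @return list of class `persistent_tracks`: `tracks` (the retained list),
#'   `n_candidates`, `n_retained`, `empty` (logical).
#' @export
filter_persistent <- function(candidates, n_frames) {
  ok <- vapply(candidates, function(tr) {
    nrow(tr) == n_frames && all(tr$frame == seq_len(n_frames))
  }, TRUE)
  out <- structure(list(tracks = candidates[ok],
                        n_candidates = length(candidates),
                        n_retained = sum(ok),
                        empty = !any(ok)),
                   class = "persistent_tracks")
  if (out$empty)
    warning("no persistent tracks survive the full-duration filter",
            call. = FALSE)
  out
}

#' Assemble a track table from linked per-cell results
#'
#' Collects persistent tracks from one or more cells into the long-format
#' track table used by the MSD stage, converting pixel coordinates to
#' micrometres.
#'
#' @param per_cell named or unnamed list; element i = list of per-probe
#'   persistent track lists for cell i, e.g.
#'   `list(locus = <persistent_tracks>, bulk = <persistent_tracks>)`.
#' @param condition condition label attached to all rows.
#' @param pixel_size um per px.
#' @param frame_interval minutes between frames.
#' @return data frame of class `track_set` with columns `cell_id`,
#'   `track_id`, `probe`, `condition`, `frame`, `x_px`, `y_px`, `x_um`,
#'   `y_um`; attributes `pixel_size`, `frame_interval`.
#' @export
build_track_set <- function(per_cell, condition, pixel_size, frame_interval) {
  rows <- list()
  tid <- 0L
  for (i in seq_along(per_cell)) {
    for (probe in names(per_cell[[i]])) {
      pt <- per_cell[[i]][[probe]]
      trs <- if (inherits(pt, "persistent_tracks")) pt$tracks else pt
      for (tr in trs) {
        tid <- tid + 1L
        rows[[tid]] <- data.frame(
          cell_id = i, track_id = tid, probe = probe, condition = condition,
          frame = tr$frame, x_px = tr$x, y_px = tr$y,
          x_um = tr$x * pixel_size, y_um = tr$y * pixel_size)
      }
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(cell_id = integer(0), track_id = integer(0),
               probe = character(0), condition = character(0),
               frame = integer(0), x_px = numeric(0), y_px = numeric(0),
               x_um = numeric(0), y_um = numeric(0))
  rownames(out) <- NULL
  attr(out, "pixel_size") <- pixel_size
  attr(out, "frame_interval") <- frame_interval
  class(out) <- c("track_set", "data.frame")
  out
}
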