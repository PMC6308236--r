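#' Rigid transform series for nuclear motion
#'
#' A `rigid_transform_series` records, for every frame of a movie, the rigid
#' body motion (translation + rotation about a fixed centre) that maps
#' nucleus-fixed coordinates into the lab frame:
#' \deqn{x_{lab} = R(\theta_t)\,(x_{fix} - c) + c + d_t}
#' where \eqn{R} rotates counter-clockwise in (x, y) pixel coordinates,
#' \eqn{c} is the rotation centre and \eqn{d_t = (dx_t, dy_t)} the cumulative
#' drift. The transform at the reference frame is the identity, so that frame
#' defines the nucleus-fixed coordinate system.
#'
#' @param dx,dy numeric vectors, cumulative drift per frame (px, sub-pixel).
#' @param theta numeric vector, cumulative rotation per frame (degrees,
#'   counter-clockwise about `center`).
#' @param center length-2 numeric, rotation centre (px).
#' @param reference integer, index of the reference frame (its transform must
#'   be the identity; default 1).
#' @return An object of class `rigid_transform_series`: a data frame with
#'   columns `frame`, `dx`, `dy`, `theta_deg`, plus attributes `center` and
#'   `reference`.
#' @export
rigid_transform_series <- function(dx, dy, theta, center, reference = 1L) {
  n <- length(dx)
  stopifnot(length(dy) == n, length(theta) == n, length(center) == 2,
            reference >= 1, reference <= n)
  if (max(abs(c(dx[reference], dy[reference], theta[reference]))) > 1e-9)
    stop("transform at the reference frame must be the identity")
  out <- data.frame(frame = seq_len(n), dx = dx, dy = dy, theta_deg = theta)
  attr(out, "center") <- as.numeric(center)
  attr(out, "reference") <- as.integer(reference)
  class(out) <- c("rigid_transform_series", "data.frame")
  out
}

#' @export
print.rigid_transform_series <- function(x, ...) {
  cat(sprintf("Rigid transform series: %d frames, reference frame %d, centre (%.2f, %.2f)\n",
              nrow(x), attr(x, "reference"),
              attr(x, "center")[1], attr(x, "center")[2]))
  cat(sprintf("  |drift| max %.3f px, |rotation| max %.3f deg\n",
              max(sqrt(x$dx^2 + x$dy^2)), max(abs(x$theta_deg))))
  invisible(x)
}

rot_mat <- function(theta_deg) {
  a <- theta_deg * pi / 180
  matrix(c(cos(a), sin(a), -sin(a), cos(a)), 2, 2)
}

#' Build a cumulative transform series from per-frame increments
#'
#' Per-frame motion (drift and rotation between consecutive frames) composes
#' into the cumulative nucleus-fixed -> lab transform: with increment
#' \eqn{(\delta d_t, \delta\theta_t)} applied between frames t-1 and t,
#' \eqn{\theta_t = \theta_{t-1} + \delta\theta_t} and
#' \eqn{d_t = R(\delta\theta_t) d_{t-1} + \delta d_t}.
#'
#' @param ddx,ddy,dtheta per-frame increments; element 1 corresponds to the
#'   motion between frame 1 and frame 2 (length `n_frames - 1`).
#' @param n_frames number of frames.
#' @param center rotation centre (px).
#' @return A [rigid_transform_series()] with reference frame 1.
#' @export
compose_increments <- function(ddx, ddy, dtheta, n_frames, center) {
  stopifnot(length(ddx) == n_frames - 1, length(ddy) == n_frames - 1,
            length(dtheta) == n_frames - 1)
  dx <- dy <- th <- numeric(n_frames)
  for (t in seq_len(n_frames - 1L)) {
    R <- rot_mat(dtheta[t])
    d <- R %*% c(dx[t], dy[t]) + c(ddx[t], ddy[t])
    dx[t + 1L] <- d[1]; dy[t + 1L] <- d[2]
    th[t + 1L] <- th[t] + dtheta[t]
  }
  rigid_transform_series(dx, dy, th, center)
}

#' Per-frame motion increments of a transform series
#'
#' Decomposes the cumulative series into frame-to-frame rigid increments
#' (the inverse of [compose_increments()]).
#'
#' @param transforms a [rigid_transform_series()].
#' @return data frame with columns `frame` (2..n), `ddx`, `ddy`, `dtheta_deg`.
#' @export
per_frame_motion <- function(transforms) {
  stopifnot(inherits(transforms, "rigid_transform_series"))
  n <- nrow(transforms)
  dth <- diff(transforms$theta_deg)
  ddx <- ddy <- numeric(n - 1L)
  for (t in seq_len(n - 1L)) {
    R <- rot_mat(dth[t])
    d <- c(transforms$dx[t + 1L], transforms$dy[t + 1L]) -
      R %*% c(transforms$dx[t], transforms$dy[t])
    ddx[t] <- d[1]; ddy[t] <- d[2]
  }
  data.frame(frame = 2:n, ddx = ddx, ddy = ddy, dtheta_deg = dth)
}

#' Apply or invert the frame transform on point coordinates
#'
#' `apply_transform_points` maps nucleus-fixed coordinates to the lab frame
#' of frame `frame`; `invert_transform_points` maps lab-frame coordinates of
#' that frame back to nucleus-fixed coordinates.
#'
#' @param xy n x 2 matrix of (x, y) positions (px).
#' @param transforms a [rigid_transform_series()].
#' @param frame frame index.
#' @return n x 2 matrix of transformed positions.
#' @export
apply_transform_points <- function(xy, transforms, frame) {
  xy <- rbind(xy)
  if (frame < 1 || frame > nrow(transforms))
    stop("frame index outside transform series")
  c0 <- attr(transforms, "center")
  R <- rot_mat(transforms$theta_deg[frame])
  d <- c(transforms$dx[frame], transforms$dy[frame])
  sweep(t(R %*% (t(xy) - c0)), 2, c0 + d, "+")
}

#' @rdname apply_transform_points
#' @export
invert_transform_points <- function(xy, transforms, frame) {
  xy <- rbind(xy)
  if (frame < 1 || frame > nrow(transforms))
    stop("frame index outside transform series")
  c0 <- attr(transforms, "center")
  R <- rot_mat(-transforms$theta_deg[frame])
  d <- c(transforms$dx[frame], transforms$dy[frame])
  sweep(t(R %*% (t(xy) - (c0 + d))), 2, c0, "+")
}

#' Identity transform series
#' @param n_frames number of frames.
#' @param center rotation centre (px).
#' @export
identity_transforms <- function(n_frames, center = c(0, 0)) {
  rigid_transform_series(numeric(n_frames), numeric(n_frames),
                         numeric(n_frames), center)
}
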