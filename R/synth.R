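#' Synthetic nucleus scene description
#'
#' Geometry, optics and noise of a simulated field of view containing one
#' nucleus. Loci live in nucleus-fixed coordinates inside an ellipse; the
#' whole nucleus undergoes rigid-body drift and rotation frame to frame
#' (the artifact the registration stage must remove). Spots are rendered as
#' isotropic Gaussians (the point spread function) on a noisy background.
#'
#' @param size image size in pixels, c(ny, nx).
#' @param center nucleus centre (x, y) in px; defaults to the image centre.
#' @param radii ellipse semi-axes (x, y) in px.
#' @param drift_per_frame rigid drift per frame, c(dx, dy) px/frame, or an
#'   (n_frames-1) x 2 matrix for time-varying drift.
#' @param rotation_per_frame rigid rotation per frame (degrees/frame, about
#'   the nucleus centre), scalar or length n_frames-1.
#' @param psf_sigma Gaussian spot SD (px).
#' @param spot_amplitude spot peak amplitude (counts above background).
#' @param background_level background intensity (counts).
#' @param noise_sd Gaussian read noise SD (counts); default spot_amplitude/10.
#' @param poisson_noise add Poisson shot noise on top of the read noise?
#' @param pixel_size physical pixel size (um/px).
#' @param nucleus_level peak intensity of the nucleus counterstain channel.
#' @param n_texture number of fixed chromatin-texture blobs rendered into the
#'   nucleus channel (they move rigidly with the nucleus and give the
#'   rotation estimator its angular signal, as real chromatin texture does).
#' @return list of class `nucleus_scene`.
#' @export
nucleus_scene <- function(size = c(128L, 128L),
                          center = (rev(size) + 1) / 2,
                          radii = c(45, 32),
                          drift_per_frame = c(0.3, -0.2),
                          rotation_per_frame = 0.4,
                          psf_sigma = 1.3,
                          spot_amplitude = 1000,
                          background_level = 100,
                          noise_sd = spot_amplitude / 10,
                          poisson_noise = FALSE,
                          pixel_size = 0.1,
                          nucleus_level = 2000,
                          n_texture = 10L) {
  stopifnot(all(radii > 0), psf_sigma > 0, pixel_size > 0,
            background_level >= 0, noise_sd >= 0)
  structure(list(size = as.integer(size), center = as.numeric(center),
                 radii = as.numeric(radii),
                 drift_per_frame = drift_per_frame,
                 rotation_per_frame = rotation_per_frame,
                 psf_sigma = psf_sigma, spot_amplitude = spot_amplitude,
                 background_level = background_level, noise_sd = noise_sd,
                 poisson_noise = poisson_noise, pixel_size = pixel_size,
                 nucleus_level = nucleus_level,
                 n_texture = as.integer(n_texture)),
            class = "nucleus_scene")
}

# Radial reflection at the ellipse boundary, in normalized coordinates:
# scale to the unit circle, fold radius r > 1 back to 2 - r. Displacements
# per frame are small relative to the nucleus, so a single fold suffices in
# practice; iterate defensively.
reflect_in_ellipse <- function(xy, center, radii) {
  u <- sweep(xy, 2, center) / rep(radii, each = nrow(xy))
  r <- sqrt(rowSums(u^2))
  bad <- which(r > 1)
  it <- 0L
  while (length(bad) && it < 8L) {
    u[bad, ] <- u[bad, , drop = FALSE] * (2 - r[bad]) / r[bad]
    r <- sqrt(rowSums(u^2))
    bad <- which(r > 1)
    it <- it + 1L
  }
  sweep(u * rep(radii, each = nrow(xy)), 2, center, "+")
}

#' Superimpose rigid nuclear motion on nucleus-fixed trajectories
#'
#' Applies per-frame drift and rotation (about the nucleus centre) to
#' trajectories given in nucleus-fixed pixel coordinates, producing lab-frame
#' trajectories plus the transform series that was applied — the ground truth
#' the registration stage must recover. Rigid motion preserves simultaneous
#' pairwise distances exactly; the frame-1 transform is the identity.
#'
#' @param tracks list of n_frames x 2 matrices (nucleus-fixed px).
#' @param scene a [nucleus_scene()].
#' @param n_frames number of frames (defaults to the first track's length).
#' @return list with `tracks` (lab-frame px) and `transforms`
#'   (a [rigid_transform_series()]).
#' @export
apply_rigid_motion <- function(tracks, scene, n_frames = nrow(tracks[[1]])) {
  stopifnot(inherits(scene, "nucleus_scene"))
  drift <- scene$drift_per_frame
  if (is.null(dim(drift)))
    drift <- matrix(drift, n_frames - 1L, 2, byrow = TRUE)
  rot <- rep_len(scene$rotation_per_frame, n_frames - 1L)
  transforms <- compose_increments(drift[, 1], drift[, 2], rot,
                                   n_frames, scene$center)
  lab <- lapply(tracks, function(xy) {
    out <- xy
    for (t in seq_len(n_frames))
      out[t, ] <- apply_transform_points(xy[t, , drop = FALSE], transforms, t)
    out
  })
  list(tracks = lab, transforms = transforms)
}

# Add an isotropic Gaussian spot to an image in place (img[y, x] indexing).
add_gaussian_spot <- function(img, x0, y0, sigma, amplitude) {
  w <- ceiling(5 * sigma)
  ny <- nrow(img); nx <- ncol(img)
  xs <- max(1L, floor(x0 - w)):min(nx, ceiling(x0 + w))
  ys <- max(1L, floor(y0 - w)):min(ny, ceiling(y0 + w))
  if (!length(xs) || !length(ys)) return(img)
  gx <- exp(-(xs - x0)^2 / (2 * sigma^2))
  gy <- exp(-(ys - y0)^2 / (2 * sigma^2))
  img[ys, xs] <- img[ys, xs] + amplitude * outer(gy, gx)
  img
}

# Smooth filled ellipse (soft edge ~1.5 px) evaluated in nucleus-fixed
# coordinates obtained by inverting the frame transform, plus fixed texture
# blobs that ride along rigidly.
render_nucleus_channel <- function(scene, transforms, frame, texture) {
  ny <- scene$size[1]; nx <- scene$size[2]
  grid <- cbind(x = rep(seq_len(nx), each = ny),
                y = rep(seq_len(ny), times = nx))
  fix <- invert_transform_points(grid, transforms, frame)
  u <- sweep(fix, 2, scene$center) / rep(scene$radii, each = nrow(fix))
  q <- sqrt(rowSums(u^2))
  edge <- 1.5 / mean(scene$radii)
  body <- stats::plogis((1 - q) / edge)
  img <- matrix(scene$nucleus_level * body, ny, nx)
  if (nrow(texture)) {
    for (i in seq_len(nrow(texture))) {
      p <- apply_transform_points(texture[i, 1:2, drop = FALSE],
                                  transforms, frame)
      img <- add_gaussian_spot(img, p[1], p[2], texture[i, 3], texture[i, 4])
    }
  }
  img
}

#' Render a multi-channel synthetic time-lapse
#'
#' Draws each spot as an isotropic 2-D Gaussian (SD `psf_sigma`, peak
#' `spot_amplitude`) on `background_level`, adds Gaussian read noise (and
#' optionally Poisson shot noise), and renders the nucleus counterstain
#' channel as a smooth filled ellipse with rigid-body texture following the
#' same transforms. Deterministic given `seed`.
#'
#' @param tracks named list of track lists per channel (e.g. `locus`, `bulk`),
#'   each a list of n_frames x 2 lab-frame pixel trajectories.
#' @param scene a [nucleus_scene()].
#' @param transforms the [rigid_transform_series()] of the nuclear motion
#'   (used for the nucleus channel).
#' @param seed integer seed for the noise (and texture placement).
#' @return list of class `image_stack_set`: `channels` (named list of
#'   ny x nx x n_frames arrays, nucleus channel first), `frame_interval`,
#'   `pixel_size`, `clipped` (logical per channel/track/frame flags for spots
#'   rendered partially out of frame).
#' @export
render_frames <- function(tracks, scene, transforms, seed = NULL,
                          frame_interval = 3) {
  stopifnot(inherits(scene, "nucleus_scene"))
  if (!is.null(seed)) set.seed(seed)
  n_frames <- nrow(transforms)
  ny <- scene$size[1]; nx <- scene$size[2]
  n_tex <- scene$n_texture
  texture <- if (n_tex > 0) {
    ang <- stats::runif(n_tex, 0, 2 * pi)
    rad <- sqrt(stats::runif(n_tex, 0.05, 0.85))
    cbind(x = scene$center[1] + rad * cos(ang) * scene$radii[1],
          y = scene$center[2] + rad * sin(ang) * scene$radii[2],
          sigma = stats::runif(n_tex, 2, 4),
          amp = scene$nucleus_level * stats::runif(n_tex, -0.35, 0.6))
  } else matrix(numeric(0), 0, 4)

  clipped <- list()
  channels <- list(nucleus = array(0, c(ny, nx, n_frames)))
  for (t in seq_len(n_frames))
    channels$nucleus[, , t] <-
      render_nucleus_channel(scene, transforms, t, texture) +
      scene$background_level
  for (ch in names(tracks)) {
    arr <- array(scene$background_level, c(ny, nx, n_frames))
    flags <- matrix(FALSE, length(tracks[[ch]]), n_frames)
    for (t in seq_len(n_frames)) {
      img <- arr[, , t]
      for (i in seq_along(tracks[[ch]])) {
        p <- tracks[[ch]][[i]][t, ]
        m <- 3 * scene$psf_sigma
        if (p[1] < 1 + m || p[1] > nx - m || p[2] < 1 + m || p[2] > ny - m) {
          flags[i, t] <- TRUE
          warning(sprintf("spot (%s track %d, frame %d) near or out of frame; clipped",
                          ch, i, t), call. = FALSE)
        }
        img <- add_gaussian_spot(img, p[1], p[2], scene$psf_sigma,
                                 scene$spot_amplitude)
      }
      arr[, , t] <- img
    }
    channels[[ch]] <- arr
    clipped[[ch]] <- flags
  }
  for (ch in names(channels)) {
    a <- channels[[ch]]
    if (scene$poisson_noise)
      a <- array(stats::rpois(length(a), pmax(a, 0)), dim(a))
    if (scene$noise_sd > 0)
      a <- a + stats::rnorm(length(a), sd = scene$noise_sd)
    channels[[ch]] <- pmax(a, 0)
  }
  structure(list(channels = channels, frame_interval = frame_interval,
                 pixel_size = scene$pixel_size, clipped = clipped),
            class = "image_stack_set")
}

#' Motion presets for the five experimental conditions
#'
#' The simulator encodes the qualitative ordering seen in live-cell TRE-array
#' experiments: transcriptionally repressed loci are less mobile than active
#' loci and bulk chromatin (which are indistinguishable); DNA damage restores
#' repressed-locus mobility to the bulk level; chromatin at damage foci
#' measured two hours later moves more than bulk, with strongly variable
#' per-track mobility (lognormal d_app, CV 0.6) producing the long-lag skew.
#' Magnitudes are simulator inputs, not measurements.
#'
#' @param condition one of "bulk", "active", "repressed", "damaged-repressed",
#'   "damaged-active-late".
#' @return list with `alpha`, `d_app` (um^2/min^alpha), `d_cv`
#'   (lognormal coefficient of variation of per-track d_app; 0 = fixed).
#' @export
condition_preset <- function(condition) {
  presets <- list(
    "bulk"                = list(alpha = 0.8, d_app = 2.5e-3, d_cv = 0),
    "active"              = list(alpha = 0.8, d_app = 2.5e-3, d_cv = 0),
    "repressed"           = list(alpha = 0.8, d_app = 1.0e-3, d_cv = 0),
    "damaged-repressed"   = list(alpha = 0.8, d_app = 2.5e-3, d_cv = 0),
    "damaged-active-late" = list(alpha = 0.8, d_app = 4.0e-3, d_cv = 0.6)
  )
  if (!condition %in% names(presets))
    stop("unknown condition: ", condition)
  presets[[condition]]
}

#' @rdname condition_preset
#' @export
condition_labels <- function() {
  c("bulk", "active", "repressed", "damaged-repressed", "damaged-active-late")
}

# Draw a per-track d_app: fixed, or lognormal with the preset's CV around
# the preset mean.
draw_d_app <- function(preset, n) {
  if (preset$d_cv <= 0) return(rep(preset$d_app, n))
  s2 <- log(1 + preset$d_cv^2)
  stats::rlnorm(n, meanlog = log(preset$d_app) - s2 / 2, sdlog = sqrt(s2))
}

#' Generate a seeded synthetic condition dataset
#'
#' Simulates `n_cells` fields of view, each containing one nucleus with one
#' condition-specific locus track (one tagged array site per cell, as for
#' TetR/TA fusions) and 1-5 bulk-probe tracks (as for fibrillarin), applies
#' rigid nuclear motion, and optionally renders image stacks. The full ground
#' truth (nucleus-fixed and lab-frame positions, transforms, per-track motion
#' parameters) is returned for recovery testing.
#'
#' @param condition condition label, see [condition_preset()].
#' @param n_cells number of cells (>= 2; the across-cell SEM is undefined
#'   otherwise).
#' @param seed master integer seed.
#' @param n_frames frames per movie (default 40).
#' @param scene a [nucleus_scene()] template (per-cell geometry is shared).
#' @param render render image stacks (TRUE) or return track tables only.
#' @param frame_interval minutes between frames.
#' @return list of class `synthetic_dataset` with elements `stacks` (list of
#'   `image_stack_set`, or NULL), `truth` (list per cell: `fixed` and `lab`
#'   track lists by channel, `transforms`, `params`), `condition`, `scene`,
#'   `frame_interval`, `n_cells`, `n_frames`.
#' @export
generate_condition_dataset <- function(condition, n_cells, seed,
                                       n_frames = 40L,
                                       scene = nucleus_scene(),
                                       render = TRUE,
                                       frame_interval = 3) {
  if (n_cells < 2) stop("n_cells must be >= 2 (SEM over cells undefined)")
  preset <- condition_preset(condition)
  bulk <- condition_preset("bulk")
  set.seed(seed)
  cell_seeds <- sample.int(.Machine$integer.max - 1L, n_cells)
  cells <- vector("list", n_cells)
  for (i in seq_len(n_cells)) {
    set.seed(cell_seeds[i])
    n_bulk <- sample(1:5, 1)
    d_locus <- draw_d_app(preset, 1)
    d_bulk <- draw_d_app(bulk, n_bulk)
    sim_one <- function(alpha, d) {
      p <- motion_params(alpha, d, frame_interval, n_frames)
      simulate_fbm_track(p)  # RNG continues from the cell stream
    }
    start_in_ellipse <- function(n) {
      ang <- stats::runif(n, 0, 2 * pi)
      rad <- sqrt(stats::runif(n, 0, 0.55))
      cbind(scene$center[1] + rad * cos(ang) * scene$radii[1],
            scene$center[2] + rad * sin(ang) * scene$radii[2])
    }
    s_locus <- start_in_ellipse(1)
    s_bulk <- start_in_ellipse(n_bulk)
    to_px <- function(um_xy, start) {
      px <- sweep(um_xy / scene$pixel_size, 2, start, "+")
      reflect_in_ellipse(px, scene$center, scene$radii)
    }
    fixed <- list(locus = list(to_px(sim_one(preset$alpha, d_locus), s_locus[1, ])),
                  bulk = lapply(seq_len(n_bulk), function(j)
                    to_px(sim_one(bulk$alpha, d_bulk[j]), s_bulk[j, ])))
    moved <- apply_rigid_motion(c(fixed$locus, fixed$bulk), scene, n_frames)
    lab <- list(locus = moved$tracks[1],
                bulk = moved$tracks[-1])
    stack <- if (render)
      render_frames(lab, scene, moved$transforms, seed = cell_seeds[i] %% 1e6,
                    frame_interval = frame_interval)
    cells[[i]] <- list(
      cell_id = i, fixed = fixed, lab = lab, transforms = moved$transforms,
      stack = stack,
      params = list(locus_alpha = preset$alpha, locus_d_app = d_locus,
                    bulk_alpha = bulk$alpha, bulk_d_app = d_bulk))
  }
  structure(list(
    stacks = if (render) lapply(cells, `[[`, "stack") else NULL,
    truth = lapply(cells, function(c)
      c[c("cell_id", "fixed", "lab", "transforms", "params")]),
    condition = condition, scene = scene, frame_interval = frame_interval,
    n_cells = n_cells, n_frames = as.integer(n_frames), seed = seed),
    class = "synthetic_dataset")
}

#' Light-dose (fluence) bookkeeping for photoactivation
#'
#' Fluence delivered by a constant irradiance over an exposure, and the
#' energy deposited on a target of given area: fluence = irradiance x
#' duration; energy = fluence x area. For example, 15 J/m^2/s for 10 minutes
#' delivers 9000 J/m^2, i.e. ~9 nJ onto a ~1 um^2 chromatin focus.
#'
#' @param irradiance irradiance (J/m^2/s), >= 0.
#' @param duration exposure duration (s), >= 0.
#' @param target_area optional target area (m^2).
#' @return list with `fluence` (J/m^2) and, if `target_area` given,
#'   `energy` (J).
#' @export
compute_fluence <- function(irradiance, duration, target_area = NULL) {
  if (irradiance < 0 || duration < 0)
    stop("irradiance and duration must be >= 0")
  out <- list(fluence = irradiance * duration)
  if (!is.null(target_area)) {
    if (target_area < 0) stop("target_area must be >= 0")
    out$energy <- out$fluence * target_area
  }
  out
}
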