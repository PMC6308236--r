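# Intensity centroid of the bright (above-median + k*MAD) part of an image.
intensity_centroid <- function(img) {
  thr <- stats::median(img) + 2 * stats::mad(img)
  w <- pmax(img - thr, 0)
  s <- sum(w)
  if (s <= 0) return(c((ncol(img) + 1) / 2, (nrow(img) + 1) / 2))
  xs <- seq_len(ncol(img)); ys <- seq_len(nrow(img))
  c(sum(colSums(w) * xs) / s, sum(rowSums(w) * ys) / s)
}

# Cross-power spectrum peak on an upsampled local grid (matrix-multiply DFT):
# evaluates the phase-correlation surface around `shift0` at `step` px
# resolution within +/- `halfwidth` px and returns the argmax.
upsampled_peak <- function(cp, shift0, halfwidth = 1.5, step = 0.05) {
  ny <- nrow(cp); nx <- ncol(cp)
  fy <- c(0:(ny %/% 2), -((ny - ny %/% 2 - 1):1)) / ny
  fx <- c(0:(nx %/% 2), -((nx - nx %/% 2 - 1):1)) / nx
  sy <- seq(shift0[2] - halfwidth, shift0[2] + halfwidth, by = step)
  sx <- seq(shift0[1] - halfwidth, shift0[1] + halfwidth, by = step)
  Ey <- exp(2i * pi * outer(sy, fy))          # |sy| x ny
  Ex <- exp(2i * pi * outer(fx, sx))          # nx x |sx|
  surf <- Re(Ey %*% cp %*% Ex)                # |sy| x |sx|
  k <- arrayInd(which.max(surf), dim(surf))
  c(sx[k[2]], sy[k[1]])
}

#' Estimate rigid translation between two frames
#'
#' Fourier cross-correlation with a Gaussian spectral weight (equivalent to
#' circularly pre-smoothing both frames with SD `smooth_sigma`, which
#' suppresses the noise-dominated high frequencies of smooth nuclear images)
#' and local DFT upsampling of the peak. Returns the sub-pixel shift
#' `(dx, dy)` by which the frame's content has moved relative to the
#' reference (subtracting it aligns the frame onto the reference). Exact for
#' integer circular shifts; accurate to well under 0.1 px for band-limited
#' sub-pixel shifts.
#'
#' @param frame,reference images (matrices, `img[y, x]`), same shape, same
#'   channel (typically the nucleus counterstain).
#' @param upsample upsampling factor for the sub-pixel refinement.
#' @param smooth_sigma SD (px) of the Gaussian spectral weight.
#' @return length-2 numeric `(dx, dy)` in px.
#' @export
estimate_translation <- function(frame, reference, upsample = 20,
                                 smooth_sigma = 2) {
  if (!all(dim(frame) == dim(reference))) stop("frames must have equal shape")
  if (stats::sd(frame) == 0 || stats::sd(reference) == 0)
    stop("blank (zero-variance) frame: registration impossible")
  Fa <- stats::fft(reference - mean(reference))
  Fb <- stats::fft(frame - mean(frame))
  # frame(p) = ref(p - s)  =>  Fb = Fa e^{-2pi i f.s}; the cross spectrum
  # Fb conj(Fa) then peaks at +s under the inverse transform.
  cp <- Fb * Conj(Fa)
  ny <- nrow(cp); nx <- ncol(cp)
  fy <- c(0:(ny %/% 2), -((ny - ny %/% 2 - 1):1)) / ny
  fx <- c(0:(nx %/% 2), -((nx - nx %/% 2 - 1):1)) / nx
  W <- exp(-4 * pi^2 * smooth_sigma^2 *
             (outer(fy^2, rep(1, nx)) + outer(rep(1, ny), fx^2)))
  cp <- cp * W / max(Mod(cp))
  r <- Re(stats::fft(cp, inverse = TRUE))
  k <- arrayInd(which.max(r), dim(r))
  iy <- k[1] - 1L; ix <- k[2] - 1L
  if (iy > ny / 2) iy <- iy - ny
  if (ix > nx / 2) ix <- ix - nx
  upsampled_peak(cp, c(ix, iy), step = 1 / upsample)
}

# Bilinear sampling of img at arbitrary (x, y) positions; outside pixels get
# `fill` (default: border median).
bilinear_sample <- function(img, x, y, fill = stats::median(img[c(1, nrow(img)), ])) {
  ny <- nrow(img); nx <- ncol(img)
  x0 <- floor(x); y0 <- floor(y)
  fx <- x - x0; fy <- y - y0
  ok <- x0 >= 1 & x0 <= nx - 1 & y0 >= 1 & y0 <= ny - 1
  out <- rep(fill, length(x))
  if (any(ok)) {
    x0k <- x0[ok]; y0k <- y0[ok]; fxk <- fx[ok]; fyk <- fy[ok]
    i00 <- (x0k - 1) * ny + y0k
    v <- img[i00] * (1 - fxk) * (1 - fyk) +
      img[i00 + ny] * fxk * (1 - fyk) +
      img[i00 + 1] * (1 - fxk) * fyk +
      img[i00 + ny + 1] * fxk * fyk
    out[ok] <- v
  }
  out
}

# Resample an image on a polar grid about `center`: rows = radii, cols =
# angles (uniform over [0, 2pi)).
polar_sample <- function(img, center, radii, n_angles) {
  ang <- seq(0, 2 * pi, length.out = n_angles + 1L)[seq_len(n_angles)]
  xs <- outer(radii, cos(ang)) + center[1]
  ys <- outer(radii, sin(ang)) + center[2]
  matrix(bilinear_sample(img, as.vector(xs), as.vector(ys)),
         length(radii), n_angles)
}

#' Estimate rigid rotation between two frames about a centre
#'
#' Resamples both images on a polar grid about `center`, cross-correlates
#' along the angular axis (per radius, via FFT) and refines the peak
#' parabolically. Rotationally symmetric content (an almost featureless
#' angular profile) triggers an ambiguity warning and returns 0.
#'
#' @param frame,reference images (`img[y, x]`), translation already removed.
#' @param center rotation centre (x, y) px — the nucleus centroid of the
#'   reference.
#' @param max_angle maximum |rotation| searched (degrees).
#' @param n_angles angular samples (resolution 360/n_angles degrees before
#'   sub-sample refinement).
#' @return rotation angle (degrees, counter-clockwise in (x, y) coordinates)
#'   mapping the reference onto the frame.
#' @export
estimate_rotation <- function(frame, reference, center,
                              max_angle = 45, n_angles = 720L) {
  if (!all(dim(frame) == dim(reference))) stop("frames must have equal shape")
  rmax <- 0.45 * min(dim(frame))
  radii <- seq(2, rmax, by = 1.5)
  pa_raw <- polar_sample(reference, center, radii, n_angles)
  pb_raw <- polar_sample(frame, center, radii, n_angles)
  pa <- pa_raw - rowMeans(pa_raw)
  pb <- pb_raw - rowMeans(pb_raw)
  # anisotropy: angular variation relative to the overall radial profile;
  # nearly zero for a perfect disk, where rotation is undefined
  aniso <- sqrt(mean(pa^2)) /
    (sqrt(mean((pa_raw - mean(pa_raw))^2)) + 1e-300)
  if (!is.finite(aniso) || aniso < 0.02) {
    warning("rotationally symmetric content: rotation ambiguous, returning 0",
            call. = FALSE)
    return(0)
  }
  # circular cross-correlation along the angle axis, summed over radii
  Fa <- t(stats::mvfft(t(pa)))
  Fb <- t(stats::mvfft(t(pb)))
  cc <- colSums(Re(t(stats::mvfft(t(Fb * Conj(Fa)), inverse = TRUE)))) / n_angles
  lagdeg <- (seq_len(n_angles) - 1L) * 360 / n_angles
  lagdeg[lagdeg > 180] <- lagdeg[lagdeg > 180] - 360
  keep <- abs(lagdeg) <= max_angle
  kk <- which(keep)[which.max(cc[keep])]
  # parabolic sub-sample refinement on the circular correlation
  km <- if (kk == 1L) n_angles else kk - 1L
  kp <- if (kk == n_angles) 1L else kk + 1L
  y1 <- cc[km]; y2 <- cc[kk]; y3 <- cc[kp]
  denom <- (y1 - 2 * y2 + y3)
  delta <- if (abs(denom) > 0) 0.5 * (y1 - y3) / denom else 0
  delta <- max(min(delta, 0.5), -0.5)
  (lagdeg[kk] + delta * 360 / n_angles)
}

# Fourier-shift an image by (dx, dy) (content moves by +dx, +dy).
fourier_shift <- function(img, dx, dy) {
  ny <- nrow(img); nx <- ncol(img)
  fy <- c(0:(ny %/% 2), -((ny - ny %/% 2 - 1):1)) / ny
  fx <- c(0:(nx %/% 2), -((nx - nx %/% 2 - 1):1)) / nx
  ph <- exp(-2i * pi * (outer(fy, rep(1, nx)) * dy + outer(rep(1, ny), fx) * dx))
  Re(stats::fft(stats::fft(img) * ph, inverse = TRUE)) / (ny * nx)
}

# Resample `img` so that output(p) = img(R(theta)(p - c) + c + d): pulls the
# frame back into the reference (nucleus-fixed) coordinate system.
rigid_resample <- function(img, dx, dy, theta_deg, center) {
  ny <- nrow(img); nx <- ncol(img)
  grid <- cbind(x = rep(seq_len(nx), each = ny),
                y = rep(seq_len(ny), times = nx))
  R <- rot_mat(theta_deg)
  src <- sweep(t(R %*% (t(grid) - center)), 2, center + c(dx, dy), "+")
  matrix(bilinear_sample(img, src[, 1], src[, 2]), ny, nx)
}

#' Estimate the rigid transform series of a stack
#'
#' Registers every frame of the nucleus channel onto the reference frame
#' (frame 1). The rotation centre is the reference intensity centroid; the
#' initial drift estimate is the frame-to-reference centroid displacement
#' (which is exact, including the apparent shift a rotation about a
#' different centre induces, when the centroid itself is used as the
#' centre). Translation and rotation residuals are then refined jointly:
#' each iteration pulls the frame back with the current estimate, measures
#' the residual rotation on the polar grid and the residual shift by
#' weighted cross-correlation, and composes them into the estimate.
#'
#' @param stack an `image_stack_set` (or a ny x nx x T array).
#' @param channel channel used for registration (default `"nucleus"`, the
#'   most spatially extended one).
#' @param max_angle maximum |cumulative rotation| searched (degrees).
#' @param n_iter refinement iterations (default 3).
#' @return a [rigid_transform_series()] (cumulative, reference = frame 1)
#'   whose centre is the reference nucleus centroid.
#' @export
estimate_transforms <- function(stack, channel = "nucleus", max_angle = 45,
                                n_iter = 3L) {
  arr <- if (inherits(stack, "image_stack_set")) stack$channels[[channel]] else stack
  n <- dim(arr)[3]
  ref <- arr[, , 1]
  center <- intensity_centroid(ref)
  dx <- dy <- th <- numeric(n)
  for (t in 2:n) {
    fr <- arr[, , t]
    d <- intensity_centroid(fr) - center
    a <- 0
    for (it in seq_len(n_iter)) {
      f1 <- rigid_resample(fr, d[1], d[2], a, center)
      a <- a + suppressWarnings(
        estimate_rotation(f1, ref, center, max_angle = max_angle))
      f2 <- rigid_resample(fr, d[1], d[2], a, center)
      s_res <- estimate_translation(f2, ref)
      # residual shift measured in pulled-back coordinates: compose through
      # the current rotation
      d <- d + as.vector(rot_mat(a) %*% s_res)
    }
    dx[t] <- d[1]; dy[t] <- d[2]; th[t] <- a
  }
  rigid_transform_series(dx, dy, th, center)
}

#' Align an image stack with a rigid transform series
#'
#' Applies the inverse transforms with bilinear interpolation so the output
#' stack shows nucleus-fixed content in every frame; all channels of a frame
#' receive the same transform. Re-estimating the transforms on the output
#' yields near-identity residuals.
#'
#' @param stack an `image_stack_set`.
#' @param transforms a [rigid_transform_series()] covering all frames.
#' @return the registered `image_stack_set`.
#' @export
align_stack <- function(stack, transforms) {
  stopifnot(inherits(stack, "image_stack_set"))
  n <- dim(stack$channels[[1]])[3]
  if (nrow(transforms) != n)
    stop("transform series does not cover all frames")
  center <- attr(transforms, "center")
  out <- stack
  for (ch in names(stack$channels)) {
    arr <- stack$channels[[ch]]
    if (dim(arr)[3] != n) stop("channel shape mismatch")
    for (t in seq_len(n)) {
      if (abs(transforms$dx[t]) + abs(transforms$dy[t]) +
          abs(transforms$theta_deg[t]) < 1e-12) next
      arr[, , t] <- rigid_resample(stack$channels[[ch]][, , t],
                                   transforms$dx[t], transforms$dy[t],
                                   transforms$theta_deg[t], center)
    }
    out$channels[[ch]] <- arr
  }
  out
}

#' Map lab-frame trajectories into nucleus-fixed coordinates
#'
#' Coordinate-level correction: applies the inverse frame transforms to
#' tracked positions, removing nuclear drift and rotation without resampling
#' images. With the true transforms this reproduces nucleus-fixed ground
#' truth to numerical precision.
#'
#' @param tracks a list of n_frames x 2 matrices, or a single matrix, of
#'   lab-frame pixel positions (row t = frame t).
#' @param transforms a [rigid_transform_series()].
#' @return same shape as `tracks`, in nucleus-fixed px.
#' @export
transform_tracks <- function(tracks, transforms) {
  one <- function(xy) {
    if (nrow(xy) > nrow(transforms))
      stop("frame index outside transform series")
    out <- xy
    for (t in seq_len(nrow(xy)))
      out[t, ] <- invert_transform_points(xy[t, , drop = FALSE], transforms, t)
    out
  }
  if (is.matrix(tracks)) one(tracks) else lapply(tracks, one)
}
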