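#' Calibrate background noise parameters of a frame
#'
#' Estimates robust background statistics (median and MAD-based SD) over the
#' background region, so that the detection threshold can be expressed in
#' noise units: `threshold = background_mean + threshold_k * background_sd`.
#' By default the foreground is excluded by a robust cut: pixels above
#' whole-frame median + 3 MAD are masked out and the statistics recomputed
#' on the complement. (Median/MAD are insensitive to the small area puncta
#' occupy, unlike a bimodal split, which degenerates on frames whose
#' foreground fraction is negligible.)
#'
#' @param frame image matrix (`img[y, x]`).
#' @param mask optional logical matrix marking background pixels (TRUE);
#'   if NULL, the robust complement described above is used.
#' @param threshold_k detection threshold in background-SD units (default 4).
#' @return list of class `noise_calibration`: `background_mean`,
#'   `background_sd`, `threshold_k`, `threshold`, `background_mask_source`.
#' @export
calibrate_noise <- function(frame, mask = NULL, threshold_k = 4) {
  if (length(frame) == 0) stop("empty frame")
  src <- if (is.null(mask)) "robust-complement" else "user-ROI"
  if (is.null(mask)) {
    m0 <- stats::median(frame)
    s0 <- stats::mad(frame)
    mask <- if (s0 == 0) matrix(TRUE, nrow(frame), ncol(frame)) else
      frame <= m0 + 3 * s0
  }
  if (!any(mask)) stop("empty background mask")
  bg <- frame[mask]
  m <- stats::median(bg)
  s <- stats::mad(bg)
  if (s == 0) s <- stats::sd(bg)
  if (is.na(s) || s == 0)
    stop("degenerate background: zero spread, cannot calibrate noise")
  structure(list(background_mean = m, background_sd = s,
                 threshold_k = threshold_k,
                 threshold = m + threshold_k * s,
                 background_mask_source = src),
            class = "noise_calibration")
}

# Standard deviation gain of the DoG matched filter for white noise: the
# L2 norm of the discrete difference-of-Gaussians impulse response.
dog_noise_factor <- function(psf_sigma) {
  w <- ceiling(9 * psf_sigma) * 2 + 1
  delta <- matrix(0, w, w)
  delta[(w + 1) / 2, (w + 1) / 2] <- 1
  h <- gauss_filter(delta, psf_sigma) - gauss_filter(delta, 3 * psf_sigma)
  sqrt(sum(h^2))
}

# Peak response of the DoG filter to a unit-amplitude Gaussian spot of SD
# psf_sigma: converts filter response to spot amplitude units.
dog_peak_gain <- function(psf_sigma) {
  w <- ceiling(9 * psf_sigma) * 2 + 1
  c0 <- (w + 1) / 2
  spot <- add_gaussian_spot(matrix(0, w, w), c0, c0, psf_sigma, 1)
  dog <- gauss_filter(spot, psf_sigma) - gauss_filter(spot, 3 * psf_sigma)
  max(dog)
}

# Iterative Gaussian-weighted centroid: the weight mask (SD = psf_sigma) is
# recentred on the running estimate; for a Gaussian spot the fixed point is
# the true centre, and the matched weights suppress the noise contribution
# of window pixels far from the spot.
weighted_centroid <- function(win, xs, ys, x0, y0, psf_sigma, n_iter = 3L) {
  cx <- x0; cy <- y0
  for (it in seq_len(n_iter)) {
    wx <- exp(-(xs - cx)^2 / (2 * psf_sigma^2))
    wy <- exp(-(ys - cy)^2 / (2 * psf_sigma^2))
    v <- win * outer(wy, wx)
    s <- sum(v)
    if (s <= 0) break
    cx <- sum(colSums(v) * xs) / s
    cy <- sum(rowSums(v) * ys) / s
  }
  c(cx, cy)
}

# Gaussian smoothing with EBImage (normalized kernel, replicated boundary).
gauss_filter <- function(img, sigma) {
  as.matrix(EBImage::gblur(EBImage::Image(img), sigma = sigma,
                           boundary = "replicate"))
}

#' Detect fluorescent puncta in a frame
#'
#' Band-pass (difference-of-Gaussians) matched filtering at the PSF scale;
#' local maxima are converted to spot-amplitude estimates through the
#' filter's peak gain and kept when the amplitude exceeds `threshold_k`
#' calibrated background-SD units (the reported `snr` is exactly that
#' amplitude-to-noise ratio). Duplicate maxima within one PSF are merged to
#' the brighter; sub-pixel localization is an iterative Gaussian-weighted
#' (matched-mask) centroid within a window of radius `ceil(3 * psf_sigma)`.
#'
#' @param frame image matrix.
#' @param calib a [calibrate_noise()] result.
#' @param psf_sigma expected spot SD (px), > 0.
#' @return data frame with columns `x`, `y` (sub-pixel, px), `intensity`
#'   (background-subtracted integrated counts), `snr` (estimated spot peak
#'   amplitude over calibrated background SD; >= `threshold_k` for every
#'   reported detection). Empty data frame when nothing is found.
#' @export
detect_particles <- function(frame, calib, psf_sigma) {
  stopifnot(inherits(calib, "noise_calibration"), psf_sigma > 0)
  ny <- nrow(frame); nx <- ncol(frame)
  img0 <- frame - calib$background_mean
  dog <- gauss_filter(img0, psf_sigma) - gauss_filter(img0, 3 * psf_sigma)
  gain <- dog_peak_gain(psf_sigma)
  thr <- calib$threshold_k * calib$background_sd * gain
  # 8-neighbour local maxima above threshold
  pad <- matrix(-Inf, ny + 2, nx + 2)
  pad[2:(ny + 1), 2:(nx + 1)] <- dog
  ctr <- pad[2:(ny + 1), 2:(nx + 1)]
  ismax <- ctr >= thr
  for (dyy in -1:1) for (dxx in -1:1) {
    if (dyy == 0 && dxx == 0) next
    nb <- pad[(2 + dyy):(ny + 1 + dyy), (2 + dxx):(nx + 1 + dxx)]
    ismax <- ismax & (ctr >= nb)
  }
  idx <- which(ismax)
  if (!length(idx)) {
    return(data.frame(x = numeric(0), y = numeric(0),
                      intensity = numeric(0), snr = numeric(0)))
  }
  ys <- ((idx - 1) %% ny) + 1
  xs <- ((idx - 1) %/% ny) + 1
  peaks <- data.frame(x = xs, y = ys, resp = dog[idx])
  # plateau/duplicate suppression: merge maxima within one PSF radius,
  # keeping the strongest (ties broken by position order -> deterministic)
  peaks <- peaks[order(-peaks$resp, peaks$y, peaks$x), ]
  keep <- rep(TRUE, nrow(peaks))
  for (i in seq_len(nrow(peaks))) {
    if (!keep[i]) next
    if (i < nrow(peaks)) {
      j <- (i + 1):nrow(peaks)
      d2 <- (peaks$x[j] - peaks$x[i])^2 + (peaks$y[j] - peaks$y[i])^2
      keep[j][d2 <= psf_sigma^2] <- FALSE
    }
  }
  peaks <- peaks[keep, , drop = FALSE]
  # sub-pixel centroid refinement
  w <- ceiling(3 * psf_sigma)
  out <- lapply(seq_len(nrow(peaks)), function(i) {
    x0 <- peaks$x[i]; y0 <- peaks$y[i]
    xr <- max(1, x0 - w):min(nx, x0 + w)
    yr <- max(1, y0 - w):min(ny, y0 + w)
    win <- img0[yr, xr, drop = FALSE]
    if (sum(pmax(win, 0)) <= 0) return(NULL)
    ctr <- weighted_centroid(win, xr, yr, x0, y0, psf_sigma)
    data.frame(x = ctr[1], y = ctr[2], intensity = sum(pmax(win, 0)),
               snr = peaks$resp[i] / (gain * calib$background_sd))
  })
  out <- do.call(rbind, out)
  if (is.null(out))
    out <- data.frame(x = numeric(0), y = numeric(0),
                      intensity = numeric(0), snr = numeric(0))
  rownames(out) <- NULL
  out[order(out$y, out$x), , drop = FALSE]
}

#' Brightest-spot detection within a nucleus mask
#'
#' For single-locus probes (one tagged site per nucleus) thresholding can be
#' bypassed: the strongest matched-filter response inside the nucleus is
#' taken as the one candidate, guaranteeing a detection per cell.
#'
#' @inheritParams detect_particles
#' @param nucleus_mask logical matrix (TRUE inside the nucleus); NULL = whole
#'   frame.
#' @return one-row detection data frame (as [detect_particles()]).
#' @export
detect_brightest <- function(frame, calib, psf_sigma, nucleus_mask = NULL) {
  stopifnot(inherits(calib, "noise_calibration"), psf_sigma > 0)
  ny <- nrow(frame); nx <- ncol(frame)
  img0 <- frame - calib$background_mean
  dog <- gauss_filter(img0, psf_sigma) - gauss_filter(img0, 3 * psf_sigma)
  if (!is.null(nucleus_mask)) dog[!nucleus_mask] <- -Inf
  k <- arrayInd(which.max(dog), dim(dog))
  w <- ceiling(3 * psf_sigma)
  xr <- max(1, k[2] - w):min(nx, k[2] + w)
  yr <- max(1, k[1] - w):min(ny, k[1] + w)
  win <- img0[yr, xr, drop = FALSE]
  ctr <- weighted_centroid(win, xr, yr, k[2], k[1], psf_sigma)
  data.frame(x = ctr[1], y = ctr[2],
             intensity = sum(pmax(win, 0)),
             snr = dog[k] / (dog_peak_gain(psf_sigma) * calib$background_sd))
}
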