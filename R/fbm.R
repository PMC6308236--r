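#' Motion parameters for an anomalously diffusing locus
#'
#' Chromatin loci move subdiffusively: their mean squared displacement grows
#' as a power law, MSD(tau) = 4 * d_app * tau^alpha in 2-D, with anomalous
#' exponent alpha <= 1 for subdiffusion (alpha = 1 is Brownian, alpha = 2
#' ballistic).
#'
#' @param alpha anomalous exponent, in (0, 2].
#' @param d_app generalized diffusion coefficient (um^2 / min^alpha), >= 0.
#' @param frame_interval time between frames (minutes), > 0. Default 3, the
#'   acquisition interval typical of long-timescale chromatin imaging.
#' @param n_frames number of frames, >= 2.
#' @return list of class `motion_params`.
#' @export
motion_params <- function(alpha = 0.8, d_app = 2.5e-3, frame_interval = 3,
                          n_frames = 40L) {
  if (!is.numeric(alpha) || length(alpha) != 1 || alpha <= 0 || alpha > 2)
    stop("alpha must lie in (0, 2]")
  if (!is.numeric(d_app) || d_app < 0) stop("d_app must be >= 0")
  if (frame_interval <= 0) stop("frame_interval must be > 0")
  n_frames <- as.integer(n_frames)
  if (n_frames < 2) stop("n_frames must be >= 2")
  structure(list(alpha = alpha, d_app = d_app,
                 frame_interval = frame_interval, n_frames = n_frames),
            class = "motion_params")
}

# Autocovariance of fractional Gaussian noise at lag k (unit step variance
# sigma2): gamma(k) = sigma2/2 * ((k+1)^{2H} - 2 k^{2H} + |k-1|^{2H}).
fgn_autocov <- function(k, H, sigma2 = 1) {
  sigma2 / 2 * ((k + 1)^(2 * H) - 2 * k^(2 * H) + abs(k - 1)^(2 * H))
}

# Sample fractional Gaussian noise by circulant embedding (exact spectral
# synthesis). Returns an n_steps x n_tracks matrix. Falls back to Cholesky
# factorization of the Toeplitz covariance when the embedding is not
# nonnegative definite (possible for H near 1 at short lengths); the
# fallback is exact too, never silent (message emitted).
fgn_sample <- function(n_steps, H, sigma2, n_tracks = 1L,
                       method = c("auto", "chol")) {
  method <- match.arg(method)
  if (n_steps == 1L)
    return(matrix(stats::rnorm(n_tracks, sd = sqrt(sigma2)), 1L, n_tracks))
  m <- 2^ceiling(log2(2L * (n_steps - 1L)))
  m <- max(m, 4L)
  g <- fgn_autocov(0:(m / 2), H, sigma2)
  circ <- c(g, rev(g[2:(m / 2)]))
  lambda <- Re(stats::fft(circ))
  if (method == "chol" || min(lambda) < -1e-8 * max(lambda)) {
    if (method != "chol")
      message("circulant embedding not nonnegative definite; ",
              "falling back to exact covariance factorization")
    K <- fgn_autocov(abs(outer(seq_len(n_steps), seq_len(n_steps), "-")),
                     H, sigma2)
    L <- chol(K + diag(1e-12 * sigma2, n_steps))
    z <- matrix(stats::rnorm(n_steps * n_tracks), n_steps, n_tracks)
    return(crossprod(L, z))
  }
  lambda <- pmax(lambda, 0)
  half <- m / 2
  # Hermitian-symmetric complex Gaussian spectrum -> real field with the
  # target circulant covariance.
  out <- matrix(0, n_steps, n_tracks)
  for (j in seq_len(n_tracks)) {
    v <- complex(length.out = m)
    v[1] <- stats::rnorm(1)
    v[half + 1] <- stats::rnorm(1)
    re <- stats::rnorm(half - 1) / sqrt(2)
    im <- stats::rnorm(half - 1) / sqrt(2)
    v[2:half] <- complex(real = re, imaginary = im)
    v[(half + 2):m] <- Conj(v[half:2])
    x <- Re(stats::fft(sqrt(lambda) * v)) / sqrt(m)
    out[, j] <- x[seq_len(n_steps)]
  }
  out
}

#' Simulate a fractional Brownian locus trajectory
#'
#' Generates a planar trajectory whose increments are fractional Gaussian
#' noise with Hurst parameter H = alpha/2, independent per axis, scaled so
#' the expected 2-D MSD at lag tau equals 4 * d_app * tau^alpha. Positions
#' are returned in micrometres, starting at the origin. The circulant
#' embedding used is exact, so the sample covariance of large ensembles
#' converges to the fGn covariance.
#'
#' @param params a [motion_params()] object.
#' @param seed integer seed; the trajectory is deterministic given the seed.
#' @param n_tracks number of independent trajectories to draw at once.
#' @return If `n_tracks == 1`, an `n_frames` x 2 matrix of (x, y) positions
#'   (um); otherwise a list of such matrices.
#' @examples
#' p <- motion_params(alpha = 0.8, d_app = 2.5e-3, frame_interval = 3,
#'                    n_frames = 40)
#' xy <- simulate_fbm_track(p, seed = 1)
#' @export
simulate_fbm_track <- function(params, seed = NULL, n_tracks = 1L) {
  stopifnot(inherits(params, "motion_params"))
  if (!is.null(seed)) set.seed(seed)
  n <- params$n_frames
  if (params$d_app == 0) {
    z <- matrix(0, n, 2)
    return(if (n_tracks == 1L) z else replicate(n_tracks, z, simplify = FALSE))
  }
  H <- params$alpha / 2
  sigma2 <- 2 * params$d_app * params$frame_interval^params$alpha  # per axis
  dx <- fgn_sample(n - 1L, H, sigma2, n_tracks)
  dy <- fgn_sample(n - 1L, H, sigma2, n_tracks)
  tracks <- lapply(seq_len(n_tracks), function(j) {
    cbind(x = c(0, cumsum(dx[, j])), y = c(0, cumsum(dy[, j])))
  })
  if (n_tracks == 1L) tracks[[1]] else tracks
}
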