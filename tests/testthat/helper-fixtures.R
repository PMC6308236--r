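# Shared fixture builders for the suite. Everything is generated in code
# under fixed seeds; no stored data.

# A noisy frame with Gaussian spots at given positions and peak SNR
# (amplitude = snr * noise_sd).
make_spot_frame <- function(positions, snr = 10, size = 128, psf = 1.3,
                            background = 100, noise_sd = 100) {
  img <- matrix(background + stats::rnorm(size * size, sd = noise_sd),
                size, size)
  for (j in seq_len(nrow(positions)))
    img <- chromotrack:::add_gaussian_spot(img, positions[j, 1],
                                           positions[j, 2], psf,
                                           snr * noise_sd)
  img
}

# n spot positions with pairwise separation >= minsep, inside a margin.
separated_positions <- function(n, minsep = 6, lo = 15, hi = 113) {
  pos <- matrix(numeric(0), 0, 2)
  while (nrow(pos) < n) {
    p <- stats::runif(2, lo, hi)
    if (!nrow(pos) ||
        min(sqrt((pos[, 1] - p[1])^2 + (pos[, 2] - p[2])^2)) >= minsep)
      pos <- rbind(pos, p)
  }
  pos
}

# Brute-force MSD by explicit enumeration of all ordered (t, t+k) pairs —
# the independent oracle for the time-averaged MSD.
brute_force_msd <- function(xy, k) {
  n <- nrow(xy)
  tot <- 0
  for (t in seq_len(n - k))
    tot <- tot + (xy[t + k, 1] - xy[t, 1])^2 + (xy[t + k, 2] - xy[t, 2])^2
  tot / (n - k)
}

# Synthetic track-level MSD curve with prescribed values at lags 1..K min.
fake_curve <- function(values, frame_interval = 1) {
  structure(list(lags = seq_along(values) * frame_interval,
                 values = values, n_pairs = rev(seq_along(values)),
                 level = "track", frame_interval = frame_interval),
            class = "msd_curve")
}
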