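test_that("track MSD matches the enumerated example and closed forms", {
  xy <- cbind(c(0, 1, 1, 2), c(0, 0, 1, 1))
  cv <- track_msd(xy, frame_interval = 1, max_lag_fraction = 1)
  # all ordered pairs: lag1 {1,1,1}; lag2 {2,2}; lag3 {5}
  expect_equal(cv$lags, 1:3)
  expect_equal(cv$values, c(1, 2, 5))
  # stationary track
  expect_true(all(track_msd(matrix(3, 10, 2), 1)$values == 0))
  # uniform drift v: MSD(tau) = (v tau)^2 in 2-D with vy = 0
  v <- 0.7
  drift <- cbind(v * (0:19), rep(0, 20))
  cv2 <- track_msd(drift, frame_interval = 2, max_lag_fraction = 1)
  expect_equal(cv2$values, (v * cv2$lags / 2)^2, tolerance = 1e-12)
  expect_error(track_msd(matrix(0, 1, 2), 1), "2 frames")
})

test_that("track MSD equals brute-force pair enumeration on random tracks", {
  set.seed(61)
  for (i in 1:200) {
    n <- sample(4:20, 1)
    xy <- matrix(stats::rnorm(2 * n), n, 2)
    cv <- track_msd(xy, frame_interval = 1, max_lag_fraction = 1)
    for (k in seq_along(cv$lags))
      expect_equal(cv$values[k], brute_force_msd(xy, k), tolerance = 1e-12)
  }
})

test_that("MSD obeys the unit-scaling laws", {
  set.seed(62)
  xy <- matrix(cumsum(stats::rnorm(40)), 20, 2)
  base <- track_msd(xy, frame_interval = 3)
  scaled <- track_msd(2.5 * xy, frame_interval = 3)
  expect_equal(scaled$values, 2.5^2 * base$values, tolerance = 1e-12)
  retimed <- track_msd(xy, frame_interval = 6)
  expect_equal(retimed$lags, 2 * base$lags)
  expect_equal(retimed$values, base$values)
})

test_that("3-SD outlier rule removes the constructed outlier and is sample-size sensitive", {
  # 21 curves: twenty at 1.0, one at 100 -> mean 5.71, sd 21.6; |100-5.71| > 3 sd
  curves21 <- c(replicate(20, fake_curve(c(1, 1, 1)), simplify = FALSE),
                list(fake_curve(c(1, 1, 100))))
  out21 <- remove_outliers(curves21)
  expect_equal(out21$excluded, 21L)
  expect_length(out21$included, 20)
  v <- c(rep(1, 20), 100)
  expect_equal(out21$mean, mean(v))
  expect_equal(out21$sd, stats::sd(v))
  # 10 curves: nine at 1.0, one at 100 -> 3 sd band contains 100, none removed
  curves10 <- c(replicate(9, fake_curve(c(1, 1, 1)), simplify = FALSE),
                list(fake_curve(c(1, 1, 100))))
  out10 <- remove_outliers(curves10)
  expect_length(out10$excluded, 0)
  v10 <- c(rep(1, 9), 100)
  expect_true(abs(100 - mean(v10)) <= 3 * stats::sd(v10))
  # equal curves and zero spread: nothing removed
  expect_length(remove_outliers(replicate(5, fake_curve(c(2, 2)),
                                          simplify = FALSE))$excluded, 0)
})

test_that("outlier rule is single-pass and order-invariant", {
  vals <- c(rep(1, 20), 100, 40)
  curves <- lapply(vals, function(v) fake_curve(c(1, v)))
  out_fwd <- remove_outliers(curves)
  perm <- rev(seq_along(curves))
  out_rev <- remove_outliers(curves[perm])
  expect_equal(sort(perm[out_rev$excluded]), sort(out_fwd$excluded))
})

test_that("ensemble averaging goes track -> cell -> ensemble with SEM over cells", {
  c_a <- fake_curve(c(1, 2, 3)); c_b <- fake_curve(c(3, 4, 5))
  # two tracks in cell 1, one in cell 2: cell 1 averages first
  ens <- ensemble_msd(list(c_a, c_b, c_a), cell_ids = c(1, 1, 2))
  cell1 <- (c_a$values + c_b$values) / 2
  expect_equal(ens$values, (cell1 + c_a$values) / 2)
  expect_equal(ens$n_cells, 2L)
  expect_equal(ens$sem,
               apply(rbind(cell1, c_a$values), 2, stats::sd) / sqrt(2))
  # identical cells: SEM = 0 at every lag
  ens0 <- ensemble_msd(list(c_a, c_a), cell_ids = 1:2)
  expect_true(all(ens0$sem == 0))
  # one track per cell (locus probes): ensemble = plain mean over tracks
  ens1 <- ensemble_msd(list(c_a, c_b), cell_ids = 1:2)
  expect_equal(ens1$values, (c_a$values + c_b$values) / 2)
  expect_error(ensemble_msd(list(c_a), cell_ids = 1), "2 cells")
})

test_that("simulated ensemble MSD stays within 3 SEM of the closed form", {
  p <- motion_params(alpha = 0.8, d_app = 2.5e-3, frame_interval = 3,
                     n_frames = 40)
  tracks <- simulate_fbm_track(p, seed = 63, n_tracks = 60)
  curves <- lapply(tracks, track_msd, frame_interval = 3)
  ens <- ensemble_msd(curves, cell_ids = seq_along(curves))
  theory <- 4 * 2.5e-3 * ens$lags^0.8
  expect_true(all(abs(ens$values - theory) <= 3 * ens$sem))
})

test_that("per-lag Student's t matches the textbook pooled formula", {
  a <- c(1.0, 1.1, 0.9, 1.2); b <- c(2.0, 2.1, 1.9, 2.2)
  cmp <- compare_msd(cbind(a), cbind(b), lags = 3)
  # independent oracle: pooled-variance t computed from first principles
  sp2 <- (3 * stats::var(a) + 3 * stats::var(b)) / 6
  t_oracle <- (mean(a) - mean(b)) / sqrt(sp2 * (1 / 4 + 1 / 4))
  p_oracle <- 2 * stats::pt(-abs(t_oracle), df = 6)
  expect_equal(cmp$t, t_oracle, tolerance = 1e-12)
  expect_equal(cmp$p, p_oracle, tolerance = 1e-12)
  expect_lt(cmp$p, 0.001)
  expect_true(cmp$significant)
})

test_that("degenerate and identical comparisons behave as specified", {
  g <- cbind(c(1, 2, 3))
  cmp <- compare_msd(g, g, lags = 1)
  expect_equal(cmp$t, 0); expect_equal(cmp$p, 1)
  const <- cbind(c(5, 5, 5))
  cmp2 <- compare_msd(const, const, lags = 1)
  expect_equal(cmp2$p, 1)
  expect_true(cmp2$degenerate)
  expect_error(compare_msd(cbind(1), cbind(c(1, 2))), "2 cells")
})

test_that("Bonferroni option multiplies p-values across lags", {
  set.seed(64)
  a <- matrix(stats::rnorm(12), 4, 3); b <- matrix(stats::rnorm(12, 1), 4, 3)
  raw <- compare_msd(a, b, lags = 1:3)
  adj <- compare_msd(a, b, lags = 1:3, bonferroni = TRUE)
  expect_equal(adj$p, pmin(raw$p * 3, 1))
})

test_that("power-law fit inverts exact curves and rejects bad input", {
  lags <- c(3, 6, 9, 12, 15)
  cv <- fake_curve(4 * 0.01 * (1:5 * 3)^0.5, frame_interval = 3)
  fit <- fit_power_law(cv)
  expect_equal(fit$alpha_hat, 0.5, tolerance = 1e-10)
  expect_equal(fit$d_hat, 0.01, tolerance = 1e-10)
  expect_equal(fit$r_squared, 1, tolerance = 1e-10)
  ball <- fake_curve((1:5)^2)
  expect_equal(fit_power_law(ball)$alpha_hat, 2, tolerance = 1e-10)
  expect_error(fit_power_law(fake_curve(c(1, 2))), ">= 3")
  expect_error(fit_power_law(fake_curve(c(1, -1, 2))), "nonpositive")
})

test_that("power-law fit recovers alpha from a simulated ensemble", {
  p <- motion_params(alpha = 0.8, d_app = 2.5e-3, frame_interval = 3,
                     n_frames = 40)
  tracks <- simulate_fbm_track(p, seed = 65, n_tracks = 50)
  curves <- lapply(tracks, track_msd, frame_interval = 3)
  out <- remove_outliers(curves)
  ens <- ensemble_msd(curves[out$included],
                      cell_ids = seq_along(curves)[out$included])
  fit <- fit_power_law(ens)
  expect_lt(abs(fit$alpha_hat - 0.8), 0.1)
})

test_that("turning angles: drift, reversal, and skipped zero displacements", {
  drift <- cbind(1:10, rep(0, 10))
  da <- directionality(list(drift))
  expect_true(all(abs(da$angles) < 1e-12))
  expect_gt(da$R, 0.999)
  zig <- cbind(rep(c(0, 1), 6), rep(0, 12))
  dz <- directionality(list(zig))
  expect_true(all(abs(abs(dz$angles) - pi) < 1e-12))
  expect_gt(dz$R, 0.999)
  expect_equal(abs(dz$mean_angle), pi, tolerance = 1e-9)
  paused <- cbind(c(0, 1, 1, 2, 3), c(0, 0, 0, 0, 1))
  dp <- directionality(list(paused))
  expect_equal(dp$n_skipped, 2L)  # angles touching the zero-length step
  expect_equal(dp$n_angles, 1L)
})

test_that("Rayleigh test is calibrated on uniform angles and rejects directed ones", {
  set.seed(66)
  p_unif <- replicate(400, rayleigh_test(stats::runif(30, -pi, pi))$p_value)
  rate <- mean(p_unif < 0.05)
  expect_lt(abs(rate - 0.05), 3 * sqrt(0.05 * 0.95 / 400))
  expect_lt(rayleigh_test(stats::rnorm(50, 0, 0.3))$p_value, 1e-6)
})
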