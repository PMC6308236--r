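scene_stack <- function(drift, rot, n_frames = 8, seed = 11, ...) {
  sc <- nucleus_scene(drift_per_frame = drift, rotation_per_frame = rot, ...)
  generate_condition_dataset("bulk", 2, seed = seed, n_frames = n_frames,
                             scene = sc)
}

test_that("translation estimation: identity, integer circular shift, sub-pixel", {
  ds <- scene_stack(c(0, 0), 0, n_frames = 2)
  ref <- ds$stacks[[1]]$channels$nucleus[, , 1]
  expect_equal(estimate_translation(ref, ref), c(0, 0), tolerance = 1e-6)
  # integer circular shift is recovered exactly: content moved (+3, -2)
  sh <- ref[c(3:128, 1:2), c(126:128, 1:125)]
  expect_equal(estimate_translation(sh, ref), c(3, -2), tolerance = 1e-9)
  # band-limited half-pixel shift recovered within 0.1 px
  sub <- chromotrack:::fourier_shift(ref, 0.5, -0.5)
  expect_equal(estimate_translation(sub, ref), c(0.5, -0.5), tolerance = 0.1)
  expect_error(estimate_translation(matrix(0, 128, 128), ref), "blank")
  expect_error(estimate_translation(ref[1:64, ], ref), "shape")
})

test_that("rotation estimation recovers an injected 5 degree rotation", {
  ds <- scene_stack(c(0, 0), 5, n_frames = 2)
  st <- ds$stacks[[1]]$channels$nucleus
  ctr <- chromotrack:::intensity_centroid(st[, , 1])
  expect_equal(estimate_rotation(st[, , 1], st[, , 1], ctr), 0,
               tolerance = 0.05)
  a <- estimate_rotation(st[, , 2], st[, , 2 - 1], ctr)
  expect_equal(a, 5, tolerance = 0.5)
})

test_that("rotationally symmetric content yields an ambiguity warning and 0", {
  xg <- outer(rep(1, 96), 1:96)
  yg <- outer(1:96, rep(1, 96))
  disk <- 400 * stats::plogis((30 - sqrt((xg - 48)^2 + (yg - 48)^2)) / 2)
  rot <- chromotrack:::rigid_resample(disk, 0, 0, 20, c(48, 48))
  expect_warning(a <- estimate_rotation(rot, disk, c(48, 48)), "ambiguous")
  expect_equal(a, 0)
})

test_that("injected rigid motion is recovered within 0.25 px and 0.5 deg", {
  ds <- scene_stack(c(1.2, -0.8), 1.5, n_frames = 10)
  tf <- estimate_transforms(ds$stacks[[1]])
  pm_h <- per_frame_motion(tf)
  pm_t <- per_frame_motion(ds$truth[[1]]$transforms)
  expect_lt(max(sqrt((pm_h$ddx - pm_t$ddx)^2 + (pm_h$ddy - pm_t$ddy)^2)),
            0.25)
  expect_lt(max(abs(pm_h$dtheta_deg - pm_t$dtheta_deg)), 0.5)
})

test_that("align_stack with identity transforms returns the input; residuals after alignment are tiny", {
  ds <- scene_stack(c(1, -0.6), 1, n_frames = 6)
  st <- ds$stacks[[1]]
  idt <- identity_transforms(6, center = c(64.5, 64.5))
  expect_identical(align_stack(st, idt)$channels, st$channels)
  tf <- estimate_transforms(st)
  reg <- align_stack(st, tf)
  tf2 <- estimate_transforms(reg)
  expect_lt(max(sqrt(tf2$dx^2 + tf2$dy^2)), 0.15)
  expect_lt(max(abs(tf2$theta_deg)), 0.2)
  bad <- tf[1:4, ]
  class(bad) <- class(tf)
  attr(bad, "center") <- attr(tf, "center"); attr(bad, "reference") <- 1L
  expect_error(align_stack(st, bad), "cover")
})

test_that("coordinate-level correction with the true transforms is exact", {
  ds <- scene_stack(c(0.8, 0.5), 2, n_frames = 10)
  tru <- ds$truth[[1]]
  rec <- transform_tracks(tru$lab$locus[[1]], tru$transforms)
  expect_lt(max(abs(rec - tru$fixed$locus[[1]])), 1e-9)
  # identity series leaves tracks unchanged; pure translation subtracts drift
  idt <- identity_transforms(10, c(0, 0))
  expect_equal(transform_tracks(tru$lab$locus[[1]], idt),
               tru$lab$locus[[1]])
  sh <- rigid_transform_series(0:9, rep(0, 10), rep(0, 10), c(0, 0))
  shifted <- transform_tracks(tru$lab$locus[[1]], sh)
  expect_equal(shifted[, 1], tru$lab$locus[[1]][, 1] - 0:9)
})

test_that("image-space and coordinate-space correction give MSDs within 5%", {
  ds <- scene_stack(c(0.6, -0.4), 0.8, n_frames = 12, seed = 23)
  psf <- ds$scene$psf_sigma
  detect_stack <- function(arr) {
    lapply(seq_len(dim(arr)[3]), function(t) {
      fr <- arr[, , t]
      detect_particles(fr, calibrate_noise(fr), psf)
    })
  }
  curves <- list(a = list(), b = list())
  cells <- list(a = c(), b = c())
  for (i in 1:2) {
    st <- ds$stacks[[i]]
    tf <- estimate_transforms(st)
    reg <- align_stack(st, tf)
    for (ch in c("locus", "bulk")) {
      # route A: detect on raw frames, correct coordinates
      for (tr in filter_persistent(link_frames(detect_stack(st$channels[[ch]]), 5),
                                   12)$tracks) {
        xy <- transform_tracks(cbind(tr$x, tr$y), tf) * ds$scene$pixel_size
        curves$a <- c(curves$a, list(track_msd(xy, frame_interval = 3)))
        cells$a <- c(cells$a, i)
      }
      # route B: align images, detect on registered frames
      for (tr in filter_persistent(link_frames(detect_stack(reg$channels[[ch]]), 5),
                                   12)$tracks) {
        xy <- cbind(tr$x, tr$y) * ds$scene$pixel_size
        curves$b <- c(curves$b, list(track_msd(xy, frame_interval = 3)))
        cells$b <- c(cells$b, i)
      }
    }
  }
  ens_a <- ensemble_msd(curves$a, cells$a)
  ens_b <- ensemble_msd(curves$b, cells$b)
  expect_equal(length(curves$a), length(curves$b))
  expect_lt(max(abs(ens_b$values / ens_a$values - 1)), 0.05)
})
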