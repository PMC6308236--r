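test_that("rigid motion: pure translation shifts x by t px per frame", {
  sc <- nucleus_scene(drift_per_frame = c(1, 0), rotation_per_frame = 0)
  tr <- list(matrix(c(60, 60), 6, 2, byrow = TRUE))
  out <- apply_rigid_motion(tr, sc, 6)
  expect_equal(out$tracks[[1]][, 1], 60 + 0:5)
  expect_equal(out$tracks[[1]][, 2], rep(60, 6))
  expect_equal(out$transforms$dx[1], 0)  # frame-1 transform is identity
})

test_that("rigid motion: a locus at the rotation centre is a fixed point", {
  sc <- nucleus_scene(drift_per_frame = c(0, 0), rotation_per_frame = 90)
  ctr <- sc$center
  tr <- list(matrix(ctr, 5, 2, byrow = TRUE))
  out <- apply_rigid_motion(tr, sc, 5)
  expect_equal(out$tracks[[1]], tr[[1]], tolerance = 1e-12)
})

test_that("rigid motion preserves simultaneous pairwise distances", {
  set.seed(31)
  sc <- nucleus_scene(drift_per_frame = c(0.5, -0.3), rotation_per_frame = 2)
  tracks <- lapply(1:3, function(i)
    cbind(60 + cumsum(stats::rnorm(15, 0, 0.6)),
          62 + cumsum(stats::rnorm(15, 0, 0.6))))
  out <- apply_rigid_motion(tracks, sc, 15)
  for (pair in list(c(1, 2), c(1, 3), c(2, 3))) {
    d_pre <- sqrt(rowSums((tracks[[pair[1]]] - tracks[[pair[2]]])^2))
    d_post <- sqrt(rowSums((out$tracks[[pair[1]]] - out$tracks[[pair[2]]])^2))
    expect_equal(d_post, d_pre, tolerance = 1e-10)
  }
})

test_that("rendered spot integrates to amplitude * 2 pi sigma^2 over background", {
  sc <- nucleus_scene(noise_sd = 0, n_texture = 0L, spot_amplitude = 500,
                      psf_sigma = 1.5, background_level = 50)
  tf <- identity_transforms(2, sc$center)
  tracks <- list(locus = list(matrix(c(64, 64), 2, 2, byrow = TRUE)))
  st <- render_frames(tracks, sc, tf, seed = 1)
  integrated <- sum(st$channels$locus[, , 1] - sc$background_level)
  expect_equal(integrated, 500 * 2 * pi * 1.5^2, tolerance = 1e-3)
})

test_that("rendering with zero loci gives background plus noise only", {
  sc <- nucleus_scene(noise_sd = 25, n_texture = 0L)
  tf <- identity_transforms(3, sc$center)
  st <- render_frames(list(bulk = list()), sc, tf, seed = 4)
  px <- as.vector(st$channels$bulk)
  expect_equal(mean(px), sc$background_level, tolerance = 1)
  expect_equal(stats::sd(px), 25, tolerance = 1)
})

test_that("rendering is bit-identical under a fixed seed", {
  sc <- nucleus_scene()
  tf <- identity_transforms(3, sc$center)
  tracks <- list(locus = list(matrix(c(64, 64), 3, 2, byrow = TRUE)))
  a <- render_frames(tracks, sc, tf, seed = 9)
  b <- render_frames(tracks, sc, tf, seed = 9)
  expect_identical(a$channels, b$channels)
})

test_that("out-of-frame spots warn and are flagged", {
  sc <- nucleus_scene(noise_sd = 0)
  tf <- identity_transforms(2, sc$center)
  tracks <- list(locus = list(matrix(c(2, 64), 2, 2, byrow = TRUE)))
  w <- capture_warnings(st <- render_frames(tracks, sc, tf, seed = 1))
  expect_true(all(grepl("clipped", w)))
  expect_true(all(st$clipped$locus[1, ]))
})

test_that("condition presets encode the experimental mobility ordering", {
  expect_lt(condition_preset("repressed")$d_app,
            condition_preset("bulk")$d_app)
  expect_identical(condition_preset("damaged-repressed"),
                   condition_preset("bulk"))
  expect_identical(condition_preset("active"), condition_preset("bulk"))
  expect_gt(condition_preset("damaged-active-late")$d_app,
            condition_preset("bulk")$d_app)
  expect_gt(condition_preset("damaged-active-late")$d_cv, 0)
  expect_error(condition_preset("nonsense"), "unknown")
})

test_that("dataset n-accounting: one locus track per cell, 1-5 bulk tracks", {
  ds <- generate_condition_dataset("repressed", 2, seed = 3, n_frames = 8,
                                   render = FALSE)
  expect_length(ds$truth, 2)
  for (cell in ds$truth) {
    expect_length(cell$fixed$locus, 1)
    expect_gte(length(cell$fixed$bulk), 1)
    expect_lte(length(cell$fixed$bulk), 5)
  }
  expect_error(generate_condition_dataset("bulk", 1, seed = 1), "n_cells")
})

test_that("loci remain inside the nucleus ellipse for the full movie", {
  ds <- generate_condition_dataset("damaged-active-late", 4, seed = 8,
                                   n_frames = 40, render = FALSE)
  sc <- ds$scene
  for (cell in ds$truth) {
    for (m in c(cell$fixed$locus, cell$fixed$bulk)) {
      u <- sweep(m, 2, sc$center) / rep(sc$radii, each = nrow(m))
      expect_lte(max(sqrt(rowSums(u^2))), 1 + 1e-9)
    }
  }
})

test_that("fluence bookkeeping reproduces the photoactivation dosimetry", {
  out <- compute_fluence(15, 600)
  expect_equal(out$fluence, 9000)
  out2 <- compute_fluence(15, 600, target_area = 1e-12)  # 1 um^2 in m^2
  expect_equal(out2$energy, 9e-9)
  expect_equal(compute_fluence(123, 0)$fluence, 0)
  expect_error(compute_fluence(-1, 10), ">= 0")
})
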