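dets_from_tracks <- function(tracks, frames = nrow(tracks[[1]])) {
  lapply(seq_len(frames), function(t)
    do.call(rbind, lapply(tracks, function(m)
      data.frame(x = m[t, 1], y = m[t, 2]))))
}

test_that("a single detection per frame links into one full-length track", {
  m <- cbind(10 + 0.3 * (0:9), 20 - 0.2 * (0:9))
  cand <- link_frames(dets_from_tracks(list(m)), max_link_distance = 5)
  expect_length(cand, 1)
  expect_equal(nrow(cand[[1]]), 10)
  expect_equal(cand[[1]]$frame, 1:10)
  expect_equal(cand[[1]]$x, m[, 1])
})

test_that("well-separated particles are recovered exactly", {
  set.seed(51)
  tracks <- lapply(c(0, 60), function(off)
    cbind(20 + off + cumsum(stats::rnorm(15, 0, 0.5)),
          60 + cumsum(stats::rnorm(15, 0, 0.5))))
  cand <- link_frames(dets_from_tracks(tracks), max_link_distance = 5)
  pt <- filter_persistent(cand, 15)
  expect_equal(pt$n_retained, 2L)
  for (m in tracks)
    expect_true(any(vapply(pt$tracks, function(tr)
      max(abs(tr$x - m[, 1])) < 1e-12, TRUE)))
})

test_that("a missed detection splits a track; no gap closing occurs", {
  m <- cbind(rep(50, 9), 50 + 0.4 * (0:8))
  dets <- dets_from_tracks(list(m))
  dets[[5]] <- dets[[5]][0, ]  # blink in the middle frame
  cand <- link_frames(dets, max_link_distance = 5)
  expect_length(cand, 2)
  lens <- sort(vapply(cand, nrow, 0L))
  expect_equal(lens, c(4L, 4L))
  pt <- suppressWarnings(filter_persistent(cand, 9))
  expect_equal(pt$n_retained, 0L)
  expect_true(pt$empty)
})

test_that("persistence filter keeps exactly the full-duration tracks", {
  full <- data.frame(frame = 1:40, x = rnorm(40), y = rnorm(40))
  short <- data.frame(frame = 1:39, x = rnorm(39), y = rnorm(39))
  pt <- filter_persistent(list(full, full, short), 40)
  expect_equal(pt$n_retained, 2L)
  expect_equal(pt$n_candidates, 3L)
  pt2 <- filter_persistent(list(full, full), 40)
  expect_equal(pt2$n_retained, 2L)  # all full-length: identity
})

test_that("linking is invariant to detection order within frames", {
  set.seed(52)
  tracks <- lapply(c(0, 30, 60), function(off)
    cbind(20 + off + cumsum(stats::rnorm(12, 0, 0.4)),
          50 + cumsum(stats::rnorm(12, 0, 0.4))))
  dets <- dets_from_tracks(tracks)
  dets_shuffled <- lapply(dets, function(d) d[sample(nrow(d)), , drop = FALSE])
  canon <- function(cands) {
    key <- vapply(cands, function(tr) paste(round(tr$x, 9), collapse = ","), "")
    lapply(cands[order(key)], function(tr) {
      rownames(tr) <- NULL
      tr
    })
  }
  a <- canon(link_frames(dets, 5))
  b <- canon(link_frames(dets_shuffled, 5))
  expect_equal(a, b, ignore_attr = TRUE)
})

test_that("output tracks never contain frame gaps", {
  set.seed(53)
  for (rep in 1:5) {
    n_particles <- sample(2:5, 1)
    dets <- lapply(1:10, function(t) {
      keep <- stats::runif(n_particles) > 0.15
      data.frame(x = stats::runif(n_particles, 0, 100)[keep],
                 y = stats::runif(n_particles, 0, 100)[keep])
    })
    for (tr in link_frames(dets, 8))
      expect_equal(tr$frame, seq(min(tr$frame), max(tr$frame)))
  }
})

test_that("track table assembly converts units and labels correctly", {
  pt <- filter_persistent(list(data.frame(frame = 1:5, x = 1:5, y = 6:10)), 5)
  ts <- build_track_set(list(list(locus = pt)), "repressed",
                        pixel_size = 0.1, frame_interval = 3)
  expect_s3_class(ts, "track_set")
  expect_equal(unique(ts$probe), "locus")
  expect_equal(ts$x_um, ts$x_px * 0.1)
  expect_equal(attr(ts, "frame_interval"), 3)
})
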