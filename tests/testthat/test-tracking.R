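test_that("appearance descriptors are unit-norm and contrast-sensitive", {
  fr <- disc_frame(64, centers = rbind(c(20, 20)))
  box <- c(14, 14, 26, 26)
  d1 <- extract_descriptor(fr, box)
  expect_equal(sqrt(sum(d1^2)), 1)
  expect_equal(extract_descriptor(fr, box), d1)

  inverted <- 255 - fr
  d2 <- extract_descriptor(inverted, box)
  expect_gt(cosine_distance(d1, d2), 0)

  expect_error(extract_descriptor(fr, c(100, 100, 120, 120)), "outside")
})

test_that("cosine distance behaves on unit vectors", {
  a <- c(1, 0); b <- c(sqrt(2) / 2, sqrt(2) / 2)
  expect_equal(cosine_distance(a, a), 0)
  expect_equal(cosine_distance(a, c(0, 1)), 1)
  expect_equal(cosine_distance(a, b), 1 - sqrt(2) / 2)
})

test_that("association matches the obvious cost structure and respects the gate", {
  cfg <- tracker_config()
  fx <- linear_motion_dets(starts = rbind(c(20, 20), c(70, 70)),
                           velocities = rbind(c(1, 0), c(0, 1)), n_frames = 4)
  # no tracks: everything unmatched
  d0 <- fx$dets[fx$dets$frame == 0, ]
  res0 <- associate(list(), d0, fx$frames[[1]], cfg)
  expect_equal(nrow(res0$matches), 0)
  expect_equal(res0$unmatched_dets, 1:2)

  # two tracks from frame 0, detections of frame 1: identity assignment
  tracker <- tracker_init(cfg)
  tracker <- tracker_step(tracker, 0, d0, fx$frames[[1]])
  tracks <- lapply(tracker$tracks, function(tr) { tr$state <- kf_predict(tr$state); tr })
  d1 <- fx$dets[fx$dets$frame == 1, ]
  res1 <- associate(tracks, d1, fx$frames[[2]], cfg)
  expect_equal(nrow(res1$matches), 2)
  m <- res1$matches[order(res1$matches[, "track"]), , drop = FALSE]
  ctr <- box_centroid(d1)
  # track near (20,20) must take the detection near (21,20), not (70,71)
  expect_lt(abs(ctr[m[1, "det"], "x"] - 21), 5)
  expect_lt(abs(ctr[m[2, "det"], "y"] - 71), 5)

  # a detection far beyond any gate or recovery radius stays unmatched
  far <- detections(frame = 1, box = c(90, 10, 94, 14), confidence = 0.9)
  res2 <- associate(tracks[1], far, fx$frames[[2]], cfg)
  expect_equal(nrow(res2$matches), 0)
  expect_equal(res2$unmatched_tracks, 1L)
  expect_equal(res2$unmatched_dets, 1L)
})

test_that("a clean single-agent stream yields one confirmed full-length track", {
  fx <- linear_motion_dets(starts = rbind(c(20, 40)),
                           velocities = rbind(c(2, 0.5)), n_frames = 10)
  out <- track_detections(fx$dets, 10, fx$frames)
  expect_equal(length(unique(out$tracks$id)), 1)
  expect_equal(sort(out$tracks$frame), 0:9)
})

test_that("a short dropout keeps the identity; exceeding max age kills the track", {
  # 2-frame dropout (< max_age): same id resumes, no new identity
  fx <- linear_motion_dets(starts = rbind(c(20, 40)),
                           velocities = rbind(c(2, 0.5)), n_frames = 12,
                           drop_frames = list(5:6))
  out <- track_detections(fx$dets, 12, fx$frames,
                          config = tracker_config(max_age = 5))
  expect_equal(length(unique(out$tracks$id)), 1)
  expect_equal(sort(out$tracks$frame), setdiff(0:11, 5:6))

  # absence longer than max_age: track deleted, reappearance gets a new id
  fx2 <- linear_motion_dets(starts = rbind(c(20, 40)),
                            velocities = rbind(c(2, 0.5)), n_frames = 16,
                            drop_frames = list(6:11))
  out2 <- track_detections(fx2$dets, 16, fx2$frames,
                           config = tracker_config(max_age = 3))
  ids <- unique(out2$tracks$id)
  expect_equal(length(ids), 2)
  expect_gt(min(out2$tracks$frame[out2$tracks$id == ids[2]]),
            max(out2$tracks$frame[out2$tracks$id == ids[1]]))
})

test_that("tentative tracks die on a miss and never reach the output", {
  # agent 2 appears for a single frame only: below n_init, excluded
  fx <- linear_motion_dets(starts = rbind(c(20, 20), c(70, 70)),
                           velocities = rbind(c(1, 0), c(0, 0)), n_frames = 8,
                           drop_frames = list(integer(0), 1:7))
  out <- track_detections(fx$dets, 8, fx$frames,
                          config = tracker_config(n_init = 3))
  expect_equal(length(unique(out$tracks$id)), 1)
})

test_that("frames must be presented in increasing order", {
  tracker <- tracker_init()
  d <- detections(frame = 3, box = c(0, 0, 4, 4), confidence = 0.9)
  tracker <- tracker_step(tracker, 3, d)
  expect_error(tracker_step(tracker, 3, d), "out of order")
  expect_error(tracker_step(tracker, 1, d), "out of order")
})

test_that("live ids are unique at every frame and never reused", {
  set.seed(61)
  n_frames <- 40
  # jittery detections around two paths plus occasional clutter
  rows <- list()
  for (f in seq_len(n_frames) - 1) {
    for (a in 1:2) {
      ctr <- c(15 + 1.5 * f + 8 * (a - 1), 20 + 25 * (a - 1)) + rnorm(2, 0, 0.4)
      rows[[length(rows) + 1]] <- data.frame(
        frame = f, x_min = ctr[1] - 3, y_min = ctr[2] - 3,
        x_max = ctr[1] + 3, y_max = ctr[2] + 3, confidence = 0.9)
    }
    if (runif(1) < 0.2) {
      c2 <- runif(2, 60, 90)
      rows[[length(rows) + 1]] <- data.frame(
        frame = f, x_min = c2[1], y_min = c2[2],
        x_max = c2[1] + 5, y_max = c2[2] + 5, confidence = 0.5)
    }
  }
  dets <- do.call(rbind, rows)
  tracker <- tracker_init(tracker_config(max_age = 4))
  seen_ids <- integer(0)
  dead_ids <- integer(0)
  for (f in seq_len(n_frames) - 1) {
    live_before <- vapply(tracker$tracks, `[[`, integer(1) + 0L, "id")
    tracker <- tracker_step(tracker, f, dets[dets$frame == f, ])
    live <- vapply(tracker$tracks, `[[`, integer(1) + 0L, "id")
    expect_equal(anyDuplicated(live), 0)
    dead_ids <- union(dead_ids, setdiff(live_before, live))
    expect_length(intersect(live, dead_ids), 0)  # no id resurrection
  }
})
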