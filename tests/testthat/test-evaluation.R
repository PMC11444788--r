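pts <- function(frames, x, y) data.frame(frame = frames, x = x, y = y)

test_that("MAE matches hand-evaluated cases and brute-force recomputation", {
  gt <- pts(0:1, c(12, 10), c(9, 10))
  expect_equal(traj_mae(gt, gt), 0)
  expect_equal(traj_mae(pts(0, 10, 10), pts(0, 12, 9)), 3.0)
  # per-frame sums 3 and 1 -> mean 2
  expect_equal(traj_mae(pts(0:1, c(10, 10), c(10, 10)),
                        pts(0:1, c(12, 10.5), c(9, 10.5))), 2.0)

  set.seed(71)
  for (trial in 1:100) {
    n <- sample(2:40, 1)
    frames <- sort(sample(0:200, n))
    est <- pts(frames, rnorm(n, 50, 20), rnorm(n, 50, 20))
    gt2 <- pts(sample(frames), rnorm(n, 50, 20), rnorm(n, 50, 20))
    brute <- mean(vapply(frames, function(f) {
      e <- est[est$frame == f, ]; g <- gt2[gt2$frame == f, ]
      abs(e$x - g$x) + abs(e$y - g$y)
    }, numeric(1)))
    expect_equal(traj_mae(est, gt2), brute)
  }
})

test_that("MAE demands identical frame sets and names the missing frames", {
  expect_error(traj_mae(pts(0:2, 1:3, 1:3), pts(0:1, 1:2, 1:2)),
               "missing from ground truth.*2")
  expect_error(traj_mae(pts(0:1, 1:2, 1:2), pts(0:2, 1:3, 1:3)),
               "missing from estimate.*2")
})

test_that("the accuracy criterion is strict on both axes", {
  tol <- 6
  expect_true(frame_is_accurate(list(x = 0, y = 0), list(x = 0, y = 0), tol))
  expect_true(frame_is_accurate(list(x = 5, y = 5), list(x = 0, y = 0), tol))
  expect_false(frame_is_accurate(list(x = 6, y = 0), list(x = 0, y = 0), tol))
  expect_false(frame_is_accurate(list(x = 0, y = 6), list(x = 0, y = 0), tol))
})

test_that("accuracy percentages reproduce the published per-flight arithmetic", {
  # 3 inaccurate of 3241
  n <- 3241
  est <- pts(seq_len(n) - 1, rep(0, n), rep(0, n))
  gt <- est
  gt$x[1:3] <- 10
  expect_equal(round_half_out(accuracy_percentage(est, gt, 6)), 99.91)

  # 1 inaccurate of 7861
  n <- 7861
  est <- pts(seq_len(n) - 1, rep(0, n), rep(0, n))
  gt <- est
  gt$y[100] <- -7
  expect_equal(round_half_out(accuracy_percentage(est, gt, 6)), 99.99)

  expect_equal(accuracy_percentage(est, est, 6), 100)
  expect_error(accuracy_percentage(est[0, ], est[0, ], 6), "empty")
})

test_that("accuracy against brute force, frame reordering and joint translation", {
  set.seed(83)
  for (trial in 1:100) {
    n <- sample(5:60, 1)
    frames <- sort(sample(0:300, n))
    est <- pts(frames, rnorm(n, 0, 4), rnorm(n, 0, 4))
    gt <- pts(frames, rnorm(n, 0, 4), rnorm(n, 0, 4))
    brute <- 100 * sum(vapply(frames, function(f) {
      e <- est[est$frame == f, ]; g <- gt[gt$frame == f, ]
      abs(e$x - g$x) < 6 && abs(e$y - g$y) < 6
    }, logical(1))) / n
    expect_equal(accuracy_percentage(est, gt, 6), brute)
    shuffled <- est[sample(n), ]
    expect_equal(accuracy_percentage(shuffled, gt, 6), brute)
    est2 <- est; gt2 <- gt
    est2$x <- est2$x + 100; gt2$x <- gt2$x + 100
    est2$y <- est2$y - 40; gt2$y <- gt2$y - 40
    expect_equal(accuracy_percentage(est2, gt2, 6), brute)
  }
})

test_that("tolerance derivation halves the mean body length", {
  expect_equal(derive_tolerance(rep(12, 20)), 6)
  expect_equal(derive_tolerance(c(10, 14)), 6)
  expect_equal(derive_tolerance(13), 6.5)
  expect_error(derive_tolerance(numeric(0)), "no body lengths")
  expect_error(derive_tolerance(c(10, -2)), "positive")
})

boxes_at <- function(id, frames, x, y, half = 5) {
  data.frame(frame = frames, id = id, x_min = x - half, y_min = y - half,
             x_max = x + half, y_max = y + half)
}

test_that("occlusion events are maximal runs of IoU strictly above threshold", {
  # two 10x10 boxes; distance controls IoU. Offsets 0 -> IoU 1, 20 -> IoU 0.
  off <- c(20, 4, 3, 20)  # IoU series approx (0, .43, .54, 0)
  b <- rbind(boxes_at(1, 0:3, 50, 50),
             boxes_at(2, 0:3, 50 + off, 50))
  ev <- detect_occlusions(b, 0.25)
  expect_equal(nrow(ev), 1)
  expect_equal(ev$start_frame, 1)
  expect_equal(ev$end_frame, 2)

  none <- detect_occlusions(rbind(boxes_at(1, 0:3, 0, 0),
                                  boxes_at(2, 0:3, 90, 90)), 0.25)
  expect_equal(nrow(none), 0)

  # IoU exactly at the threshold never counts: overlap 6x10 over union
  # 2*100-60 = 140 -> 3/7; use threshold 3/7
  at <- rbind(boxes_at(1, 0:2, 50, 50), boxes_at(2, 0:2, 54, 50))
  expect_equal(nrow(detect_occlusions(at, box_iou(c(45,45,55,55), c(49,45,59,55)))), 0)
})

test_that("occlusion events agree with a brute-force run extraction oracle", {
  set.seed(97)
  for (trial in 1:25) {
    n_frames <- 30
    ids <- 1:3
    boxes <- do.call(rbind, lapply(ids, function(i) {
      x <- cumsum(c(runif(1, 0, 60), rnorm(n_frames - 1, 0, 4)))
      y <- cumsum(c(runif(1, 0, 60), rnorm(n_frames - 1, 0, 4)))
      boxes_at(i, 0:(n_frames - 1), x, y)
    }))
    thr <- 0.25
    ev <- detect_occlusions(boxes, thr)
    # oracle: per pair per frame, IoU; maximal runs by scanning
    expected <- 0
    for (i in 1:2) for (j in (i + 1):3) {
      bi <- boxes[boxes$id == i, ]; bj <- boxes[boxes$id == j, ]
      over <- box_iou(bi, bj) > thr
      runs <- rle(over)
      expected <- expected + sum(runs$values)
      # every event frame range is fully above threshold, and the frames
      # just outside are not
      evp <- ev[ev$id1 == i & ev$id2 == j, ]
      for (k in seq_len(nrow(evp))) {
        fr <- evp$start_frame[k]:evp$end_frame[k]
        expect_true(all(over[fr + 1]))
        if (evp$start_frame[k] > 0) expect_false(over[evp$start_frame[k]])
        if (evp$end_frame[k] < n_frames - 1) expect_false(over[evp$end_frame[k] + 2])
      }
    }
    expect_equal(nrow(ev), expected)
  }
})

test_that("identity preservation scoring distinguishes swaps from clean exits", {
  expect_equal(score_identity_preservation(
    data.frame(id1 = numeric(), id2 = numeric(),
               start_frame = integer(), end_frame = integer()),
    pts(0, 0, 0), pts(0, 0, 0))$total, 0)

  # two agents cross between frames 4 and 6
  gt <- rbind(cbind(agent_id = 1, pts(0:10, seq(0, 100, 10), 50)),
              cbind(agent_id = 2, pts(0:10, seq(100, 0, -10), 52)))
  ev <- data.frame(id1 = 1, id2 = 2, start_frame = 4, end_frame = 6)

  est_ok <- rbind(cbind(id = 1, pts(0:10, seq(0, 100, 10), 50)),
                  cbind(id = 2, pts(0:10, seq(100, 0, -10), 52)))
  s1 <- score_identity_preservation(ev, est_ok, gt)
  expect_equal(c(s1$correct, s1$total), c(1L, 1L))

  # the tracker swaps the two identities at the exit
  est_swap <- est_ok
  sel1 <- est_swap$id == 1 & est_swap$frame > 6
  sel2 <- est_swap$id == 2 & est_swap$frame > 6
  est_swap$id[sel1] <- 2; est_swap$id[sel2] <- 1
  s2 <- score_identity_preservation(ev, est_swap, gt)
  expect_equal(c(s2$correct, s2$total), c(0L, 1L))

  # an event at the very start of the video cannot be scored
  ev0 <- data.frame(id1 = 1, id2 = 2, start_frame = 0, end_frame = 2)
  s3 <- score_identity_preservation(ev0, est_ok, gt)
  expect_equal(s3$total, 0L)
})

test_that("crossing-window scoring mirrors event scoring from the agent side", {
  gt <- rbind(cbind(agent_id = 1, pts(0:10, seq(0, 100, 10), 50)),
              cbind(agent_id = 2, pts(0:10, seq(100, 0, -10), 52)))
  w <- data.frame(agent1 = 1, agent2 = 2, start_frame = 4, end_frame = 6)
  est_ok <- rbind(cbind(id = 3, pts(0:10, seq(0, 100, 10), 50)),
                  cbind(id = 9, pts(0:10, seq(100, 0, -10), 52)))
  expect_equal(score_crossing_windows(w, est_ok, gt)$correct, 1L)

  est_swap <- est_ok
  sel1 <- est_swap$id == 3 & est_swap$frame > 6
  sel2 <- est_swap$id == 9 & est_swap$frame > 6
  est_swap$id[sel1] <- 9; est_swap$id[sel2] <- 3
  expect_equal(score_crossing_windows(w, est_swap, gt)$correct, 0L)

  # both agents captured by one merged identity: not preserved
  est_merged <- est_ok
  est_merged$id <- 3
  expect_equal(score_crossing_windows(w, est_merged, gt)$correct, 0L)
})

test_that("trajectory-to-agent matching minimizes summed centroid distance", {
  gt <- rbind(cbind(agent_id = 1, pts(0:9, 1:10, rep(10, 10))),
              cbind(agent_id = 2, pts(0:9, 1:10, rep(60, 10))))
  est <- rbind(cbind(id = 5, pts(0:9, 1:10, rep(59, 10))),
               cbind(id = 6, pts(0:9, 1:10, rep(12, 10))))
  m <- match_trajectories(est, gt)
  expect_equal(m$agent_id[m$id == 5], 2)
  expect_equal(m$agent_id[m$id == 6], 1)
  expect_equal(m$shared_frames, c(10L, 10L))
})

test_that("ground-truth files read with and without headers", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("frame,agent_id,x,y", "0,1,10.5,20.5", "1,1,11,21"), path)
  g1 <- read_ground_truth(path)
  expect_equal(g1$x, c(10.5, 11))
  writeLines(c("0,1,10.5,20.5", "1,1,11,21"), path)
  g2 <- read_ground_truth(path)
  expect_equal(g2, g1)
})
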