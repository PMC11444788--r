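make_traj <- function(id, frames, x, y, interp = FALSE) {
  data.frame(frame = frames, id = id, x = x, y = y,
             interpolated = rep_len(interp, length(frames)))
}

test_that("filtration removes identities strictly below the presence threshold", {
  short <- make_traj(1, 0:48, 1:49, 1:49)     # 49 of 1000 frames: below 5%
  long <- make_traj(2, 0:49, 1:50, 1:50)      # exactly 50 = 5%: kept
  traj <- rbind(short, long)
  out <- filter_short_tracks(traj, 1000, 5)
  expect_equal(unique(out$id), 2)

  expect_equal(filter_short_tracks(traj, 1000, 0), traj)
  both <- filter_short_tracks(traj, 100, 5)
  expect_equal(sort(unique(both$id)), c(1, 2))
})

test_that("filtration counts observed frames only", {
  tr <- rbind(make_traj(1, 0:29, 1:30, 1:30, interp = FALSE),
              make_traj(1, 30:59, 31:60, 31:60, interp = TRUE))
  # 30 observed of 1000 -> below 5% despite 60 total rows
  expect_equal(nrow(filter_short_tracks(tr, 1000, 5)), 0)
})

test_that("gap interpolation reproduces linear and cubic motion exactly", {
  # linear: x = 2 f
  lin <- make_traj(1, c(0, 1, 3, 4), 2 * c(0, 1, 3, 4), rep(1, 4))
  out <- interpolate_gaps(lin)
  expect_equal(out$x[out$frame == 2], 4)
  expect_true(out$interpolated[out$frame == 2])

  # cubic: x = f^3 with frame 3 missing; a cubic-reproducing spline is exact
  f <- c(0, 1, 2, 4, 5)
  cub <- make_traj(1, f, f^3, f^2)
  out2 <- interpolate_gaps(cub)
  expect_equal(out2$x[out2$frame == 3], 27)
  expect_equal(out2$y[out2$frame == 3], 9)

  # no gaps: unchanged
  dense <- make_traj(1, 0:5, rnorm(6), rnorm(6))
  expect_equal(interpolate_gaps(dense), dense)
})

test_that("interpolation never alters observed points and fills the whole span", {
  set.seed(17)
  for (trial in 1:10) {
    frames <- sort(sample(0:60, 25))
    traj <- make_traj(1, frames, cumsum(rnorm(25)), cumsum(rnorm(25)))
    out <- interpolate_gaps(traj)
    obs <- out[!out$interpolated, ]
    expect_equal(obs$x, traj$x)
    expect_equal(obs$y, traj$y)
    # observed + interpolated = full span, nothing beyond it
    expect_equal(out$frame, seq(min(frames), max(frames)))
    expect_equal(sum(out$interpolated) + nrow(traj), diff(range(frames)) + 1)
  }
})

test_that("the filled series is C2-smooth at interior knots", {
  set.seed(29)
  frames <- sort(sample(0:40, 12))
  traj <- make_traj(1, frames, cumsum(rnorm(12)), cumsum(rnorm(12)))
  out <- interpolate_gaps(traj)
  # evaluate the implied spline densely and check second differences vary
  # smoothly (no jump larger than the local scale of the third derivative)
  sf <- splinefun(traj$frame, traj$x, method = "fmm")
  g <- seq(min(frames), max(frames), by = 0.05)
  d2 <- diff(sf(g), differences = 2) / 0.05^2
  expect_lt(max(abs(diff(d2))), 1)  # second derivative is continuous
  # interpolate_gaps agrees with that spline at the filled frames
  filled <- out[out$interpolated, ]
  expect_equal(filled$x, sf(filled$frame))
})

test_that("leading and trailing gaps are not extrapolated", {
  tr <- make_traj(1, c(5, 6, 9, 10), 1:4, 1:4)
  out <- interpolate_gaps(tr)
  expect_equal(min(out$frame), 5)
  expect_equal(max(out$frame), 10)
})

test_that("a gap cap limits which runs are filled", {
  tr <- make_traj(1, c(0, 1, 2, 10, 11, 13), 1:6, 1:6)
  out <- interpolate_gaps(tr, max_gap = 2)
  expect_false(any(out$frame %in% 3:9))   # 7-frame gap stays open
  expect_true(12 %in% out$frame)          # 1-frame gap filled
})

test_that("postprocessing commutes with relabeling of track ids", {
  set.seed(43)
  t1 <- make_traj(1, sort(sample(0:50, 20)), rnorm(20), rnorm(20))
  t2 <- make_traj(2, sort(sample(0:50, 8)), rnorm(8), rnorm(8))
  traj <- rbind(t1, t2)
  relabeled <- traj
  relabeled$id <- ifelse(relabeled$id == 1, 7, 3)

  run <- function(d) interpolate_gaps(filter_short_tracks(d, 200, 5))
  a <- run(traj)
  b <- run(relabeled)
  b$id <- ifelse(b$id == 7, 1, 2)
  b <- b[order(b$id, b$frame), ]
  rownames(a) <- rownames(b) <- NULL
  expect_equal(a, b)
})

test_that("interpolation percentages match the published per-flight arithmetic", {
  tr <- rbind(make_traj(1, 0:24, 1:25, 1:25, interp = TRUE),
              make_traj(1, 25:100, 1:76, 1:76, interp = FALSE))
  expect_equal(round_half_out(interpolation_percentage(tr, 3721)), 0.67)

  tr2 <- rbind(make_traj(1, 0:2, 1:3, 1:3, interp = TRUE))
  expect_equal(round_half_out(interpolation_percentage(tr2, 4741)), 0.06)

  expect_equal(interpolation_percentage(make_traj(1, 0:9, 1:10, 1:10), 100), 0)
})

test_that("positions tables round-trip through CSV", {
  path <- withr::local_tempfile(fileext = ".csv")
  traj <- rbind(make_traj(1, 0:3, c(1, 2, 3, 4) + 0.25, 4:1),
                make_traj(2, 2:4, 7:9, 9:11, interp = c(FALSE, TRUE, FALSE)))
  write_positions(traj, path)
  back <- read_positions(path)
  rownames(traj) <- NULL
  expect_equal(back, traj)
})
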