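# Post-processing of raw tracks: drop short-lived identities (the
# Filtration parameter) and fill missing frames by cubic-spline
# interpolation, run in that order so that spurious identities (e.g.
# reflections) never get interpolated.

#' Convert tracked boxes to a trajectory table
#'
#' @param tracks A `mos_tracks` object or its `tracks` data frame.
#' @return Trajectory table: `frame`, `id`, `x`, `y` (box centroids) and
#'   `interpolated` (all `FALSE`).
#' @export
tracks_to_trajectories <- function(tracks) {
  t <- if (inherits(tracks, "mos_tracks")) tracks$tracks else tracks
  ctr <- box_centroid(t)
  data.frame(frame = t$frame, id = t$id, x = ctr[, "x"], y = ctr[, "y"],
             interpolated = FALSE)
}

#' Remove short-lived identities
#'
#' Drops every trajectory whose number of *observed* frames is strictly less
#' than `min_presence_pct` percent of the total video frames. With the
#' default of 5% this removes transient identities such as glass
#' reflections while leaving genuine flights untouched.
#'
#' @param traj Trajectory table (see [tracks_to_trajectories()]).
#' @param total_frames Total frames in the video.
#' @param min_presence_pct Presence threshold in percent (default 5).
#' @return The trajectory table without the short-lived ids.
#' @export
filter_short_tracks <- function(traj, total_frames, min_presence_pct = 5) {
  stopifnot(total_frames >= 1, min_presence_pct >= 0, min_presence_pct <= 100)
  if (nrow(traj) == 0) return(traj)
  obs <- tapply(!traj$interpolated, traj$id, sum)
  cutoff <- min_presence_pct / 100 * total_frames
  keep_ids <- as.numeric(names(obs)[obs >= cutoff])
  out <- traj[traj$id %in% keep_ids, , drop = FALSE]
  rownames(out) <- NULL
  out
}

# Interpolate one coordinate series at missing frames. splinefun's "fmm"
# end condition fits an exact cubic through the four points at each end,
# which reproduces cubic polynomials exactly and falls back to quadratic /
# linear interpolation at three / two observed points.
fill_series <- function(frames, values, at) {
  if (length(frames) == 2) {
    stats::approx(frames, values, xout = at)$y
  } else {
    stats::splinefun(frames, values, method = "fmm")(at)
  }
}

#' Fill trajectory gaps by cubic-spline interpolation
#'
#' For every missing frame strictly between a trajectory's first and last
#' observed frames, `x` and `y` are interpolated independently by a cubic
#' spline through the observed `(frame, coordinate)` points. The spline
#' passes through all observations, so observed points are never altered,
#' and nothing is extrapolated beyond the observed range. With only three
#' (two) observations the interpolant degrades to a quadratic (straight
#' line).
#'
#' @param traj Trajectory table.
#' @param max_gap Longest run of consecutive missing frames that will be
#'   filled (default `Inf`, i.e. no cap).
#' @return The trajectory table with interpolated rows added (flagged
#'   `interpolated = TRUE`), sorted by id then frame.
#' @export
interpolate_gaps <- function(traj, max_gap = Inf) {
  if (nrow(traj) == 0) return(traj)
  pieces <- lapply(split(traj, traj$id), function(d) {
    d <- d[order(d$frame), , drop = FALSE]
    obs <- d[!d$interpolated, , drop = FALSE]
    if (nrow(obs) < 2) return(d)
    full <- seq(min(obs$frame), max(obs$frame))
    missing <- setdiff(full, d$frame)
    if (length(missing) == 0) return(d)
    if (is.finite(max_gap)) {
      prev_obs <- vapply(missing, function(f) max(obs$frame[obs$frame < f]), 0)
      next_obs <- vapply(missing, function(f) min(obs$frame[obs$frame > f]), 0)
      missing <- missing[next_obs - prev_obs - 1 <= max_gap]
      if (length(missing) == 0) return(d)
    }
    fill <- data.frame(frame = missing, id = d$id[1],
                       x = fill_series(obs$frame, obs$x, missing),
                       y = fill_series(obs$frame, obs$y, missing),
                       interpolated = TRUE)
    rbind(d, fill)
  })
  out <- do.call(rbind, pieces)
  out <- out[order(out$id, out$frame), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Percentage of interpolated frames
#'
#' @param traj Trajectory table (for one identity or a whole video).
#' @param total_frames Total frames in the video.
#' @return `100 * (interpolated frame count) / total_frames`, unrounded.
#' @export
interpolation_percentage <- function(traj, total_frames) {
  stopifnot(total_frames >= 1)
  100 * sum(traj$interpolated) / total_frames
}

#' Round half away from zero
#'
#' Percentages in reports are conventionally rounded half away from zero
#' (unlike R's banker's rounding).
#'
#' @param x Numeric vector.
#' @param digits Decimal places (default 2).
#' @return Rounded values.
#' @export
round_half_out <- function(x, digits = 2) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Write a positions table
#'
#' One row per (frame, id): `frame, id, x, y, interpolated` (0/1). This CSV
#' is the canonical positions output of the pipeline.
#'
#' @param traj Trajectory table.
#' @param path Output CSV path.
#' @export
write_positions <- function(traj, path) {
  out <- data.frame(frame = traj$frame, id = traj$id,
                    x = traj$x, y = traj$y,
                    interpolated = as.integer(traj$interpolated))
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' Read a positions table written by [write_positions()]
#'
#' @param path CSV path.
#' @return Trajectory table with a logical `interpolated` column.
#' @export
read_positions <- function(path) {
  d <- utils::read.csv(path)
  d$interpolated <- as.logical(d$interpolated)
  d
}
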