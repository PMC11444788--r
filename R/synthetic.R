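# Synthetic flight videos with exact ground truth.
#
# The generator emulates the recording regime the tracker is built for:
# ~1040 x 1024 px grayscale frames at 60 frames/s, up to five small dark
# bodies (ellipses around 12 px long) flying smoothly over a light
# background, with optional forced crossings (occlusions), per-frame
# detection dropouts and short-lived "reflection" blobs.
#
# Kinematics: each agent's velocity follows a mean-reverting
# (Ornstein-Uhlenbeck-style) random walk, weakly tethered to a per-agent
# anchor so agents occupy separate regions of the arena; a soft pairwise
# repulsion keeps non-crossing agents apart. A forced crossing sends one
# agent of a pair on a straight transit through the other's position
# (smooth blend in, inertial straight exit, gentle rejoin to its own
# path), the way two insects on straight flight segments cross: disjoint
# entry and exit paths, momentarily inseparable at closest approach — the
# classic identity-switch hazard.
#
# All randomness flows from the single seed via named sub-streams (motion,
# crossing geometry, rendering noise, dropout, reflections) so each
# component is independently reproducible.

#' Configuration of the synthetic flight-video generator
#'
#' Defaults mirror the laboratory recording regime the tracker targets:
#' 1040 x 1024 frames, 60 frames/s, five agents, 12 px bodies (so the
#' half-body-length tolerance recipe gives 6 px).
#'
#' @param width,height Frame size in pixels (defaults 1040, 1024).
#' @param fps Frames per second (default 60).
#' @param duration Video duration in seconds (default 5).
#' @param n_agents Number of agents (default 5).
#' @param accel_sd Random acceleration std in px/frame^2 (default 0.8;
#'   yields mean speeds of a few px/frame at 60 frames/s).
#' @param damping Velocity mean-reversion per frame (default 0.08).
#' @param tether Pull toward the agent's anchor, px/frame^2 per px of
#'   displacement (default 0.004).
#' @param max_speed Speed cap in px/frame (default 8).
#' @param sep_min Separation below which non-crossing agents repel, px
#'   (default 40).
#' @param body_length,body_width Ellipse axes in px (defaults 12, 5).
#' @param body_intensity Body gray level, 0-255 (default 60).
#' @param background Background gray level (default 220).
#' @param noise_sd Gaussian pixel-noise std in gray levels (default 2).
#' @param dropout_rate Per-agent-per-frame probability that a visible agent
#'   is not rendered (default 0).
#' @param n_crossings Forced pairwise crossing events (default 0).
#' @param n_reflections Short-lived static reflection blobs (default 0).
#' @param reflection_duration Reflection lifetime in frames (default 0 =
#'   3% of the video when reflections are requested).
#' @param seed Integer seed driving all randomness (default 1).
#' @return A list of class `synth_config`.
#' @export
synth_config <- function(width = 1040L, height = 1024L, fps = 60L,
                         duration = 5, n_agents = 5L,
                         accel_sd = 0.8, damping = 0.08, tether = 0.004,
                         max_speed = 8, sep_min = 40,
                         body_length = 12, body_width = 5,
                         body_intensity = 60, background = 220,
                         noise_sd = 2, dropout_rate = 0,
                         n_crossings = 0L, n_reflections = 0L,
                         reflection_duration = 0L, seed = 1L) {
  stopifnot(width >= 32, height >= 32, fps >= 1, duration > 0, n_agents >= 1,
            body_length > 0, body_width > 0, dropout_rate >= 0,
            dropout_rate < 1, n_crossings >= 0, background > body_intensity)
  structure(as.list(environment()), class = "synth_config")
}

# Named RNG sub-streams derived from the master seed.
synth_streams <- function(seed) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  set.seed(seed)
  s <- sample.int(.Machine$integer.max - 1L, 5L)
  if (!is.null(old)) assign(".Random.seed", old, globalenv())
  stats::setNames(as.list(s),
                  c("motion", "crossing", "noise", "dropout", "reflection"))
}

with_stream <- function(stream_seed, expr) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  set.seed(stream_seed)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  expr
}

# Anchor points spread on a circle inside the arena.
synth_anchors <- function(config) {
  cx <- config$width / 2; cy <- config$height / 2
  r <- 0.33 * min(config$width, config$height)
  if (config$n_agents == 1) return(cbind(x = cx, y = cy))
  ang <- 2 * pi * (seq_len(config$n_agents) - 1) / config$n_agents
  cbind(x = cx + r * cos(ang), y = cy + r * sin(ang))
}

simulate_base_paths <- function(config, stream_seed, crossing_pairs, windows) {
  n_frames <- as.integer(config$fps * config$duration)
  n <- config$n_agents
  anchors <- synth_anchors(config)
  margin <- config$body_length
  pos <- array(0, c(n_frames, n, 2))
  with_stream(stream_seed, {
    p <- anchors + matrix(stats::rnorm(2 * n, 0, 10), n, 2)
    v <- matrix(stats::rnorm(2 * n, 0, 1), n, 2)
    for (t in seq_len(n_frames)) {
      acc <- matrix(stats::rnorm(2 * n, 0, config$accel_sd), n, 2)
      v <- (1 - config$damping) * v + config$tether * (anchors - p) + acc
      # soft pairwise repulsion, suspended inside a pair's crossing window
      if (n > 1 && config$sep_min > 0) {
        for (i in seq_len(n - 1)) for (j in seq((i + 1), n)) {
          if (pair_in_window(i, j, t, crossing_pairs, windows)) next
          dv <- p[i, ] - p[j, ]
          d <- sqrt(sum(dv^2))
          if (d < config$sep_min && d > 0) {
            push <- 0.6 * (config$sep_min - d) / config$sep_min * dv / d
            v[i, ] <- v[i, ] + push
            v[j, ] <- v[j, ] - push
          }
        }
      }
      spd <- sqrt(rowSums(v^2))
      fast <- spd > config$max_speed
      v[fast, ] <- v[fast, , drop = FALSE] * config$max_speed / spd[fast]
      p <- p + v
      # reflective boundaries
      for (k in 1:2) {
        lim <- c(config$width, config$height)[k]
        low <- p[, k] < margin
        p[low, k] <- 2 * margin - p[low, k]
        v[low, k] <- -v[low, k]
        high <- p[, k] > lim - margin
        p[high, k] <- 2 * (lim - margin) - p[high, k]
        v[high, k] <- -v[high, k]
        p[, k] <- pmin(pmax(p[, k], 0), lim - 1e-6)
      }
      pos[t, , ] <- p
    }
  })
  pos
}

pair_in_window <- function(i, j, t, pairs, windows) {
  if (is.null(pairs) || nrow(pairs) == 0) return(FALSE)
  hit <- pairs[, 1] == i & pairs[, 2] == j & t >= windows[, 1] & t <= windows[, 2]
  any(hit)
}

# Count maximal runs of pairwise distance < body_length; returns a data
# frame of observed approach events (agents are 1-based indices here).
count_approaches <- function(pos, body_length) {
  n_frames <- dim(pos)[1]; n <- dim(pos)[2]
  out <- list()
  if (n < 2) return(data.frame(agent1 = integer(), agent2 = integer(),
                               start_frame = integer(), end_frame = integer()))
  for (i in seq_len(n - 1)) for (j in seq((i + 1), n)) {
    d <- sqrt((pos[, i, 1] - pos[, j, 1])^2 + (pos[, i, 2] - pos[, j, 2])^2)
    close <- which(d < body_length)
    if (length(close) == 0) next
    runs <- split(close, cumsum(c(1, diff(close) != 1)))
    for (r in runs)
      out[[length(out) + 1]] <- data.frame(agent1 = i, agent2 = j,
                                           start_frame = min(r) - 1L,
                                           end_frame = max(r) - 1L)
  }
  if (length(out) == 0) return(data.frame(agent1 = integer(), agent2 = integer(),
                                          start_frame = integer(), end_frame = integer()))
  do.call(rbind, out)
}

# Phases of a forced crossing, in frames (designed for 60 frames/s).
CROSS_BLEND_IN <- 20L   # smooth departure from the base path
CROSS_APPROACH <- 40L   # straight transit to the closest approach
CROSS_EXIT <- 20L       # straight inertial continuation past it
CROSS_REJOIN <- 40L     # gentle blend back to the base path

cross_span <- function() CROSS_BLEND_IN + CROSS_APPROACH + CROSS_EXIT + CROSS_REJOIN

smoothstep <- function(s) {
  s <- pmin(1, pmax(0, s))
  s * s * (3 - 2 * s)
}

# Straighten agent i's path around frame tc: inside [tc - half, tc + half]
# the agent flies ballistically along its average heading through its
# position at tc, with smooth blends of `blend` frames on both sides.
# Crossing flights are fast, near-straight segments; the wandering
# (mean-reverting) kinematics resume outside the window.
straighten_segment <- function(pos, i, tc, half = 20L, blend = 15L) {
  n_frames <- dim(pos)[1]
  ta <- max(1, tc - half); tb <- min(n_frames, tc + half)
  v <- (pos[tb, i, ] - pos[ta, i, ]) / (tb - ta)
  p_tc <- pos[tc, i, ]
  for (t in seq(max(1, ta - blend), min(n_frames, tb + blend))) {
    s <- if (t < ta) smoothstep((t - (ta - blend)) / blend)
         else if (t <= tb) 1
         else 1 - smoothstep((t - tb) / blend)
    line <- p_tc + v * (t - tc)
    pos[t, i, ] <- (1 - s) * pos[t, i, ] + s * line
  }
  pos
}

# Override agent j's path with a straight transit through `target` at frame
# tc (1-based). Returns the modified position array.
apply_crossing <- function(pos, j, tc, target) {
  n_frames <- dim(pos)[1]
  t0 <- tc - CROSS_APPROACH              # start of the straight segment
  t1 <- tc + CROSS_EXIT                  # end of the straight segment
  p0 <- pos[t0, j, ]
  u <- (target - p0) / CROSS_APPROACH    # transit velocity, px/frame
  line_at <- function(t) p0 + u * (t - t0)
  for (t in seq(t0 - CROSS_BLEND_IN, min(t1 + CROSS_REJOIN, n_frames))) {
    if (t < 1) next
    s <- if (t < t0) smoothstep((t - (t0 - CROSS_BLEND_IN)) / CROSS_BLEND_IN)
         else if (t <= t1) 1
         else 1 - smoothstep((t - t1) / CROSS_REJOIN)
    pos[t, j, ] <- (1 - s) * pos[t, j, ] + s * line_at(t)
  }
  pos
}

#' Simulate ground-truth agent trajectories
#'
#' Generates smooth stochastic flight paths (mean-reverting velocity,
#' reflective arena boundaries) with exactly `n_crossings` forced pairwise
#' approach events in which two agents pass within one body length of each
#' other. Each crossing is a straight transit of one agent through the
#' other's position — both fly on through with their own headings, as real
#' crossing flights do. Fully reproducible from `config$seed`.
#'
#' @param config A [synth_config()].
#' @return Data frame `frame` (0-based), `agent_id`, `x`, `y`,
#'   `orientation` (radians), `x_min, y_min, x_max, y_max` (tight box of
#'   the body ellipse). Attributes: `crossings` (data frame
#'   `agent1, agent2, start_frame, end_frame` of realized approach events),
#'   `config`.
#' @export
simulate_trajectories <- function(config = synth_config()) {
  n_frames <- as.integer(config$fps * config$duration)
  n <- config$n_agents
  ncr <- config$n_crossings
  if (ncr > 0 && n < 2) stop("crossings require at least two agents")
  span <- cross_span()
  usable <- n_frames - CROSS_BLEND_IN - CROSS_APPROACH - CROSS_EXIT - CROSS_REJOIN
  if (ncr > 0 && (usable < 1 || ncr > max(0, floor(usable / span) + 1)))
    stop(sprintf("%d crossings are infeasible in %d frames", ncr, n_frames))
  streams <- synth_streams(config$seed)

  for (attempt in 0:24) {
    motion_seed <- (streams$motion + attempt * 7919L) %% .Machine$integer.max
    cross_seed <- (streams$crossing + attempt * 104729L) %% .Machine$integer.max

    pairs <- windows <- NULL
    centers <- integer(0)
    if (ncr > 0) {
      all_pairs <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
      all_pairs <- all_pairs[order(all_pairs[, 1], all_pairs[, 2]), , drop = FALSE]
      pairs <- all_pairs[rep_len(seq_len(nrow(all_pairs)), ncr), , drop = FALSE]
      lo <- CROSS_BLEND_IN + CROSS_APPROACH + 1
      hi <- n_frames - CROSS_EXIT - CROSS_REJOIN
      centers <- if (ncr == 1) round((lo + hi) / 2)
                 else round(seq(lo, hi, length.out = ncr))
      windows <- cbind(centers - CROSS_APPROACH - CROSS_BLEND_IN,
                       centers + CROSS_EXIT + CROSS_REJOIN)
    }

    pos <- simulate_base_paths(config, motion_seed, pairs, windows)

    if (ncr > 0) {
      pos <- with_stream(cross_seed, {
        for (k in seq_len(ncr)) {
          i <- pairs[k, 1]; j <- pairs[k, 2]; tc <- centers[k]
          pos <- straighten_segment(pos, i, tc)
          ang <- stats::runif(1, 0, 2 * pi)
          target <- pos[tc, i, ] + (config$body_length / 3) * c(cos(ang), sin(ang))
          pos <- apply_crossing(pos, j, tc, target)
        }
        pos
      })
      m <- config$body_length / 2
      pos[, , 1] <- pmin(pmax(pos[, , 1], m), config$width - m)
      pos[, , 2] <- pmin(pmax(pos[, , 2], m), config$height - m)
    }

    realized <- count_approaches(pos, config$body_length)
    if (nrow(realized) == ncr) {
      return(build_trajectory_table(pos, realized, config))
    }
  }
  stop("could not realize the requested number of crossings; ",
       "configuration appears infeasible")
}

build_trajectory_table <- function(pos, crossings, config) {
  n_frames <- dim(pos)[1]; n <- dim(pos)[2]
  rows <- lapply(seq_len(n), function(a) {
    x <- pos[, a, 1]; y <- pos[, a, 2]
    vx <- c(diff(x), utils::tail(diff(x), 1))
    vy <- c(diff(y), utils::tail(diff(y), 1))
    ori <- atan2(vy, vx)
    hl <- config$body_length / 2; hw <- config$body_width / 2
    ex <- sqrt((hl * cos(ori))^2 + (hw * sin(ori))^2)
    ey <- sqrt((hl * sin(ori))^2 + (hw * cos(ori))^2)
    data.frame(frame = seq_len(n_frames) - 1L, agent_id = a, x = x, y = y,
               orientation = ori,
               x_min = x - ex, y_min = y - ey, x_max = x + ex, y_max = y + ey)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "crossings") <- crossings
  attr(out, "config") <- config
  out
}

# Draw one anti-aliased dark ellipse into a frame matrix (in place value).
draw_ellipse <- function(mat, x, y, ori, hl, hw, depth) {
  H <- nrow(mat); W <- ncol(mat)
  pad <- hl + 1.5
  c0 <- max(1L, floor(x - pad)); c1 <- min(W, ceiling(x + pad))
  r0 <- max(1L, floor(y - pad)); r1 <- min(H, ceiling(y + pad))
  if (c0 > c1 || r0 > r1) return(mat)
  cs <- c0:c1; rs <- r0:r1
  px <- matrix(cs - 0.5, length(rs), length(cs), byrow = TRUE) - x
  py <- matrix(rs - 0.5, length(rs), length(cs)) - y
  u <- px * cos(ori) + py * sin(ori)
  v <- -px * sin(ori) + py * cos(ori)
  q <- sqrt((u / hl)^2 + (v / hw)^2)
  alpha <- pmin(1, pmax(0, (1 - q) * hw + 0.5))  # ~1 px anti-aliased edge
  patch <- mat[rs, cs, drop = FALSE]
  mat[rs, cs] <- patch * (1 - alpha) + alpha * pmin(patch, depth)
  mat
}

#' Render synthetic frames
#'
#' Draws each agent as a dark anti-aliased ellipse (oriented along its
#' velocity) on a light background with Gaussian pixel noise. Optional
#' per-agent-per-frame dropouts leave the agent unrendered for that frame,
#' and optional short-lived static "reflection" blobs exercise the
#' filtration stage.
#'
#' @param traj Trajectory table from [simulate_trajectories()].
#' @param config The matching [synth_config()].
#' @return List of frame matrices (gray 0-255), one per frame, with
#'   attributes `dropped` (data frame `frame, agent_id` of unrendered
#'   agent-frames) and `reflections` (data frame of blob positions and
#'   lifetimes).
#' @export
render_frames <- function(traj, config = attr(traj, "config")) {
  stopifnot(!is.null(config))
  n_frames <- as.integer(config$fps * config$duration)
  if (nrow(traj)) n_frames <- max(n_frames, max(traj$frame) + 1L)
  streams <- synth_streams(config$seed)
  dropped <- with_stream(streams$dropout, {
    if (config$dropout_rate > 0) {
      hit <- stats::runif(nrow(traj)) < config$dropout_rate
      traj[hit, c("frame", "agent_id")]
    } else data.frame(frame = integer(), agent_id = integer())
  })
  refl <- with_stream(streams$reflection, {
    if (config$n_reflections > 0) {
      dur <- if (config$reflection_duration > 0) config$reflection_duration
             else max(2L, as.integer(0.03 * n_frames))
      data.frame(x = stats::runif(config$n_reflections, 20, config$width - 20),
                 y = stats::runif(config$n_reflections, 20, config$height - 20),
                 start_frame = sample.int(max(1L, n_frames - dur),
                                          config$n_reflections, replace = TRUE) - 1L,
                 duration = dur)
    } else data.frame(x = numeric(), y = numeric(),
                      start_frame = integer(), duration = integer())
  })
  drop_key <- paste(dropped$frame, dropped$agent_id)
  frames <- vector("list", n_frames)
  with_stream(streams$noise, {
    for (f in seq_len(n_frames) - 1L) {
      mat <- matrix(config$background +
                      stats::rnorm(config$width * config$height, 0, config$noise_sd),
                    config$height, config$width)
      tf <- traj[traj$frame == f, , drop = FALSE]
      for (r in seq_len(nrow(tf))) {
        if (paste(f, tf$agent_id[r]) %in% drop_key) next
        mat <- draw_ellipse(mat, tf$x[r], tf$y[r], tf$orientation[r],
                            config$body_length / 2, config$body_width / 2,
                            config$body_intensity)
      }
      if (nrow(refl)) {
        for (r in seq_len(nrow(refl))) {
          if (f >= refl$start_frame[r] && f < refl$start_frame[r] + refl$duration[r])
            mat <- draw_ellipse(mat, refl$x[r], refl$y[r], 0, 3.5, 3.5,
                                config$body_intensity)
        }
      }
      frames[[f + 1L]] <- pmin(pmax(mat, 0), 255)
    }
  })
  attr(frames, "dropped") <- dropped
  attr(frames, "reflections") <- refl
  frames
}

#' Write a synthetic dataset to disk
#'
#' Creates `frames/NNNNNN.png` (grayscale PNG sequence), `gt.csv` (the
#' ground-truth table) and `manifest.json` (the full configuration,
#' including the seed) under `path`.
#'
#' @param traj Trajectory table from [simulate_trajectories()].
#' @param frames Frame list from [render_frames()].
#' @param path Output directory (created if needed).
#' @param config The matching [synth_config()].
#' @return `path`, invisibly.
#' @export
write_dataset <- function(traj, frames, path, config = attr(traj, "config")) {
  stopifnot(length(frames) >= 1)
  fdir <- file.path(path, "frames")
  dir.create(fdir, recursive = TRUE, showWarnings = FALSE)
  for (f in seq_along(frames)) {
    png::writePNG(frames[[f]] / 255,
                  file.path(fdir, sprintf("%06d.png", f - 1L)))
  }
  gt <- traj[, c("frame", "agent_id", "x", "y",
                 "x_min", "y_min", "x_max", "y_max")]
  utils::write.csv(gt, file.path(path, "gt.csv"), row.names = FALSE)
  manifest <- unclass(config)
  manifest$n_frames <- length(frames)
  jsonlite::write_json(manifest, file.path(path, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Simulate and render a complete synthetic video
#'
#' Convenience wrapper: [simulate_trajectories()] then [render_frames()].
#'
#' @param config A [synth_config()].
#' @return List with `traj` and `frames`.
#' @export
simulate_flight_video <- function(config = synth_config()) {
  traj <- simulate_trajectories(config)
  list(traj = traj, frames = render_frames(traj, config))
}
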