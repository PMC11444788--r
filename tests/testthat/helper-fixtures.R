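# Shared fixture builders for the test suite. Everything is generated in
# code; no binary fixtures on disk.

# Random valid boxes for property-style tests.
random_boxes <- function(n, range = 100) {
  x1 <- runif(n, 0, range); y1 <- runif(n, 0, range)
  bbox(x1, y1, x1 + runif(n, 0.1, range / 2), y1 + runif(n, 0.1, range / 2))
}

# A light frame with dark axis-aligned discs at given centers.
disc_frame <- function(size = 64, centers, radius = 3,
                       bg = 220, body = 60) {
  mat <- matrix(bg, size, size)
  for (k in seq_len(nrow(centers))) {
    cx <- centers[k, 1]; cy <- centers[k, 2]
    for (r in seq_len(size)) for (cc in seq_len(size)) {
      if ((cc - 0.5 - cx)^2 + (r - 0.5 - cy)^2 <= radius^2) mat[r, cc] <- body
    }
  }
  mat
}

# Detection stream for agents moving on exact linear paths, as boxes of
# side `side` centered on the path; returns list(dets, frames_list, paths).
linear_motion_dets <- function(starts, velocities, n_frames, side = 6,
                               frame_size = 96, drop_frames = NULL) {
  n_agents <- nrow(starts)
  rows <- list()
  frames <- vector("list", n_frames)
  for (f in seq_len(n_frames) - 1L) {
    centers <- starts + f * velocities
    frames[[f + 1L]] <- disc_frame(frame_size, centers, radius = side / 2)
    for (a in seq_len(n_agents)) {
      if (!is.null(drop_frames) && f %in% drop_frames[[a]]) next
      rows[[length(rows) + 1L]] <- data.frame(
        frame = f,
        x_min = centers[a, 1] - side / 2, y_min = centers[a, 2] - side / 2,
        x_max = centers[a, 1] + side / 2, y_max = centers[a, 2] + side / 2,
        confidence = 0.9)
    }
  }
  list(dets = do.call(rbind, rows), frames = frames)
}

# Brute-force minimum assignment cost by enumerating permutations
# (square matrices, finite entries).
brute_assignment_cost <- function(cost) {
  n <- nrow(cost)
  perms <- function(v) {
    if (length(v) <= 1) return(list(v))
    do.call(c, lapply(seq_along(v), function(i)
      lapply(perms(v[-i]), function(p) c(v[i], p))))
  }
  min(vapply(perms(seq_len(n)),
             function(p) sum(cost[cbind(seq_len(n), p)]), numeric(1)))
}
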