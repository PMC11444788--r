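# Multi-object tracker: per-identity Kalman prediction, Hungarian
# association of predicted tracks to detections, and a Max-Age lifecycle.
#
# Association cost combines an appearance term (smallest cosine distance
# between the detection's intensity-histogram descriptor and the track's
# recent descriptor gallery) with a small motion term (squared Mahalanobis
# distance normalized by the gate). Pairs whose Mahalanobis distance exceeds
# the chi-square gate (4 d.o.f.) are forbidden outright. The motion term
# matters when targets look alike — intensity histograms cannot tell two
# identical insects apart, so near-ties in appearance are resolved by which
# track's predicted position fits the detection best.

#' Tracker configuration
#'
#' @param max_age Consecutive undetected frames after which a track is
#'   deleted (default 30; half a second at 60 frames/s).
#' @param n_init Consecutive matched frames needed before a new track is
#'   confirmed (default 3). Tentative tracks are deleted on their first
#'   miss and excluded from final output unless confirmed.
#' @param gating_quantile Chi-square quantile (4 d.o.f.) for the Mahalanobis
#'   gate (default 0.95, i.e. a gate of 9.4877).
#' @param descriptor_bins Intensity-histogram bins for appearance
#'   descriptors (default 16).
#' @param gallery_size Descriptors retained per track (default 50).
#' @param motion_weight Weight of the gate-normalized Mahalanobis term in
#'   the association cost (default 0.05); the complement weights the cosine
#'   appearance term.
#' @param std_weight_pos,std_weight_vel Kalman noise scales relative to box
#'   height (defaults 1/20 and 1/160 per frame).
#' @return A list of class `tracker_config`.
#' @export
tracker_config <- function(max_age = 30L, n_init = 3L, gating_quantile = 0.95,
                           descriptor_bins = 16L, gallery_size = 50L,
                           motion_weight = 0.05,
                           std_weight_pos = 1 / 20, std_weight_vel = 1 / 160) {
  stopifnot(max_age >= 1, n_init >= 1, gating_quantile > 0, gating_quantile < 1,
            descriptor_bins >= 1, gallery_size >= 1,
            motion_weight >= 0, motion_weight <= 1)
  structure(list(max_age = as.integer(max_age), n_init = as.integer(n_init),
                 gating_quantile = gating_quantile,
                 gate = stats::qchisq(gating_quantile, df = 4),
                 descriptor_bins = as.integer(descriptor_bins),
                 gallery_size = as.integer(gallery_size),
                 motion_weight = motion_weight,
                 std_weight_pos = std_weight_pos,
                 std_weight_vel = std_weight_vel),
            class = "tracker_config")
}

#' Appearance descriptor of an image patch
#'
#' L2-normalized intensity histogram of the pixels inside a bounding box.
#' A patch with an all-zero histogram maps to the uniform unit vector. The
#' box is clipped to the frame; a box entirely outside the frame is an
#' error.
#'
#' @param pixels Grayscale frame matrix (intensities 0-255).
#' @param box A bounding box.
#' @param bins Number of histogram bins (default 16).
#' @return Unit-norm numeric vector of length `bins`.
#' @export
extract_descriptor <- function(pixels, box, bins = 16L) {
  b <- as_box_matrix(box)
  r0 <- max(1L, floor(b[1, "y_min"]) + 1L); r1 <- min(nrow(pixels), ceiling(b[1, "y_max"]))
  c0 <- max(1L, floor(b[1, "x_min"]) + 1L); c1 <- min(ncol(pixels), ceiling(b[1, "x_max"]))
  if (r0 > r1 || c0 > c1) stop("box lies entirely outside the frame")
  patch <- pixels[r0:r1, c0:c1]
  idx <- pmin(bins, floor(patch / 256 * bins) + 1L)
  counts <- tabulate(idx, nbins = bins)
  nrm <- sqrt(sum(counts^2))
  if (nrm == 0) rep(1 / sqrt(bins), bins) else counts / nrm
}

#' Cosine distance between unit vectors
#'
#' @param a,b Unit-norm numeric vectors.
#' @return `1 - sum(a * b)`, clipped to \[0, 2\].
#' @export
cosine_distance <- function(a, b) {
  min(2, max(0, 1 - sum(a * b)))
}

new_track <- function(id, det_box, confidence, descriptor, frame, config) {
  list(id = id,
       state = kf_init(box_to_xyah(det_box),
                       std_weight_pos = config$std_weight_pos,
                       std_weight_vel = config$std_weight_vel),
       history = data.frame(frame = frame, as_box_matrix(det_box)),
       gallery = matrix(descriptor, nrow = 1),
       hits = 1L, time_since_update = 0L,
       status = if (config$n_init <= 1L) "confirmed" else "tentative")
}

#' Create an empty tracker
#'
#' @param config A [tracker_config()].
#' @return Tracker state to be advanced with [tracker_step()].
#' @export
tracker_init <- function(config = tracker_config()) {
  structure(list(tracks = list(), archive = list(), next_id = 1L,
                 last_frame = -1L, config = config),
            class = "mos_tracker")
}

# Appearance + gated-motion cost matrix and admissibility mask.
association_cost <- function(tracks, det_boxes, descriptors, config) {
  nt <- length(tracks); nd <- nrow(det_boxes)
  cost <- matrix(Inf, nt, nd)
  for (i in seq_len(nt)) {
    tr <- tracks[[i]]
    for (j in seq_len(nd)) {
      m2 <- kf_mahalanobis_sq(tr$state, box_to_xyah(det_boxes[j, , drop = FALSE]))
      if (m2 > config$gate) next
      app <- min(apply(tr$gallery, 1, cosine_distance, b = descriptors[[j]]))
      cost[i, j] <- (1 - config$motion_weight) * app +
        config$motion_weight * m2 / config$gate
    }
  }
  cost
}

#' Associate predicted tracks with detections
#'
#' Builds the association cost matrix (appearance with Mahalanobis gating,
#' see [tracker_config()]) and solves the minimum-cost assignment with the
#' Hungarian algorithm, as a matching cascade: tracks are processed in
#' groups of increasing time-since-update, so recently observed tracks have
#' first claim on the detections. Gated (forbidden) pairs are never matched
#' in this stage. A distance-based recovery stage then lets still-unmatched tracks
#' claim still-unmatched detections within twice their predicted box height
#' (at least 16 px), so that one spurious gate violation does not fragment
#' an established track. Rows are ordered by track position in `tracks`
#' (creation order), which fixes the outcome when several assignments are
#' equally good.
#'
#' @param tracks List of track objects (already predicted to this frame).
#' @param dets Detection table for the current frame.
#' @param pixels Grayscale frame matrix, used for appearance descriptors;
#'   `NULL` when tracking external detections without imagery, in which case
#'   descriptors are uniform and the motion term decides.
#' @param config A [tracker_config()].
#' @return List with `matches` (2-column matrix of track and detection
#'   indices), `unmatched_tracks`, `unmatched_dets`.
#' @export
associate <- function(tracks, dets, pixels = NULL, config = tracker_config()) {
  nt <- length(tracks); nd <- nrow(dets)
  det_boxes <- if (nd) as_box_matrix(dets) else NULL
  descriptors <- lapply(seq_len(nd), function(j) {
    if (is.null(pixels)) rep(1 / sqrt(config$descriptor_bins), config$descriptor_bins)
    else extract_descriptor(pixels, det_boxes[j, , drop = FALSE], config$descriptor_bins)
  })
  if (nt == 0 || nd == 0) {
    return(list(matches = matrix(integer(), 0, 2),
                unmatched_tracks = seq_len(nt), unmatched_dets = seq_len(nd),
                descriptors = descriptors))
  }
  # Matching cascade: tracks that were updated recently associate first, so
  # a long-coasting track (whose motion uncertainty has ballooned) cannot
  # steal a detection from a track that is following its target frame by
  # frame.
  matches <- matrix(integer(), 0, 2, dimnames = list(NULL, c("track", "det")))
  un_de <- seq_len(nd)
  tsu <- vapply(tracks, `[[`, integer(1), "time_since_update")
  for (age in sort(unique(tsu))) {
    group <- which(tsu == age)
    if (length(un_de) == 0) break
    cost <- association_cost(tracks[group], det_boxes[un_de, , drop = FALSE],
                             descriptors[un_de], config)
    assign_col <- solve_assignment(cost)
    got <- which(!is.na(assign_col))
    if (length(got)) {
      matches <- rbind(matches,
                       cbind(track = group[got], det = un_de[assign_col[got]]))
      un_de <- setdiff(un_de, un_de[assign_col[got]])
    }
  }
  un_tr <- setdiff(seq_len(nt), matches[, "track"])

  # Recovery stage: an isolated Mahalanobis-gate blip (e.g. a sharp turn)
  # must not fragment an established track, so leftover tracks may still
  # claim leftover detections by plain predicted-position distance within
  # a generous, height-scaled radius.
  if (length(un_tr) && length(un_de)) {
    cost2 <- matrix(Inf, length(un_tr), length(un_de))
    for (ii in seq_along(un_tr)) {
      pred <- tracks[[un_tr[ii]]]$state$mean
      radius <- max(2 * pred[4], 16)
      for (jj in seq_along(un_de)) {
        ctr <- box_centroid(det_boxes[un_de[jj], , drop = FALSE])
        d <- sqrt((ctr[1] - pred[1])^2 + (ctr[2] - pred[2])^2)
        if (d <= radius) cost2[ii, jj] <- d
      }
    }
    assign2 <- solve_assignment(cost2)
    got <- which(!is.na(assign2))
    if (length(got)) {
      matches <- rbind(matches,
                       cbind(track = un_tr[got], det = un_de[assign2[got]]))
      un_tr <- un_tr[-got]
      un_de <- setdiff(un_de, un_de[assign2[got]])
    }
  }
  list(matches = matches, unmatched_tracks = un_tr, unmatched_dets = un_de,
       descriptors = descriptors)
}

#' Advance the tracker by one frame
#'
#' Predicts every live track, associates predictions with the frame's
#' detections, updates matched tracks (resetting their miss counter,
#' appending the appearance descriptor and recording the observed box),
#' ages unmatched tracks (a confirmed track is deleted once its miss count
#' exceeds `max_age`; a tentative track is deleted on any miss), spawns a
#' tentative track per unmatched detection, and confirms tentative tracks
#' after `n_init` consecutive hits. Track ids are never reused.
#'
#' @param tracker Tracker state from [tracker_init()] or a previous step.
#' @param frame Frame index (0-based); must exceed the previous step's.
#' @param dets Detection table for this frame.
#' @param pixels Grayscale frame matrix or `NULL` (see [associate()]).
#' @return The updated tracker state.
#' @export
tracker_step <- function(tracker, frame, dets, pixels = NULL) {
  frame <- as.integer(frame)
  if (frame <= tracker$last_frame)
    stop(sprintf("frame %d out of order (last processed %d)",
                 frame, tracker$last_frame))
  config <- tracker$config
  tracker$tracks <- lapply(tracker$tracks, function(tr) {
    tr$state <- kf_predict(tr$state); tr
  })
  if (nrow(dets)) dets <- dets[dets$frame == frame, , drop = FALSE]
  res <- associate(tracker$tracks, dets, pixels, config)
  det_boxes <- if (nrow(dets)) as_box_matrix(dets) else NULL

  if (nrow(res$matches)) {
    for (k in seq_len(nrow(res$matches))) {
      i <- res$matches[k, 1]; j <- res$matches[k, 2]
      tr <- tracker$tracks[[i]]
      tr$state <- kf_update(tr$state, box_to_xyah(det_boxes[j, , drop = FALSE]))
      tr$hits <- tr$hits + 1L
      tr$time_since_update <- 0L
      tr$gallery <- rbind(tr$gallery, res$descriptors[[j]])
      if (nrow(tr$gallery) > config$gallery_size)
        tr$gallery <- tr$gallery[seq(nrow(tr$gallery) - config$gallery_size + 1,
                                     nrow(tr$gallery)), , drop = FALSE]
      tr$history <- rbind(tr$history,
                          data.frame(frame = frame, det_boxes[j, , drop = FALSE]))
      if (tr$status == "tentative" && tr$hits >= config$n_init)
        tr$status <- "confirmed"
      tracker$tracks[[i]] <- tr
    }
  }

  drop <- logical(length(tracker$tracks))
  for (i in res$unmatched_tracks) {
    tr <- tracker$tracks[[i]]
    tr$time_since_update <- tr$time_since_update + 1L
    if (tr$status == "tentative" || tr$time_since_update > config$max_age) {
      tr$status <- "deleted"
      drop[i] <- TRUE
      if (tr$hits >= config$n_init)  # confirmed at some point: keep history
        tracker$archive <- c(tracker$archive, list(tr))
    }
    tracker$tracks[[i]] <- tr
  }
  tracker$tracks <- tracker$tracks[!drop]

  for (j in res$unmatched_dets) {
    desc <- res$descriptors[[j]]
    if (is.null(desc))
      desc <- rep(1 / sqrt(config$descriptor_bins), config$descriptor_bins)
    tracker$tracks <- c(tracker$tracks,
                        list(new_track(tracker$next_id,
                                       det_boxes[j, , drop = FALSE],
                                       dets$confidence[j], desc, frame, config)))
    tracker$next_id <- tracker$next_id + 1L
  }

  tracker$last_frame <- frame
  tracker
}

#' Run the tracker over a full detection stream
#'
#' Steps the tracker through frames `0 .. n_frames - 1` and collects the
#' observed boxes of every track that was ever confirmed.
#'
#' @param dets Detection table covering all frames.
#' @param n_frames Total number of frames in the video.
#' @param frames Optional list of grayscale frame matrices (index `f + 1`
#'   holds frame `f`) for appearance descriptors.
#' @param config A [tracker_config()].
#' @return An object of class `mos_tracks`: a list with `tracks` (data frame
#'   `frame, id, x_min, y_min, x_max, y_max` of observed boxes of confirmed
#'   tracks), `n_frames` and `config`.
#' @export
track_detections <- function(dets, n_frames, frames = NULL,
                             config = tracker_config()) {
  tracker <- tracker_init(config)
  for (f in seq_len(n_frames) - 1L) {
    fd <- dets[dets$frame == f, , drop = FALSE]
    px <- if (!is.null(frames)) frames[[f + 1]] else NULL
    tracker <- tracker_step(tracker, f, fd, px)
  }
  finished <- c(tracker$archive,
                Filter(function(tr) tr$status == "confirmed", tracker$tracks))
  tab <- if (length(finished)) {
    out <- do.call(rbind, lapply(finished, function(tr)
      cbind(frame = tr$history$frame, id = tr$id,
            as_box_matrix(tr$history))))
    out <- as.data.frame(out)
    out <- out[order(out$id, out$frame), , drop = FALSE]
    rownames(out) <- NULL
    out
  } else {
    data.frame(frame = integer(), id = integer(), x_min = numeric(),
               y_min = numeric(), x_max = numeric(), y_max = numeric())
  }
  structure(list(tracks = tab, n_frames = as.integer(n_frames), config = config),
            class = "mos_tracks")
}

#' @export
print.mos_tracks <- function(x, ...) {
  ids <- unique(x$tracks$id)
  cat("Multi-object tracking result\n")
  cat(sprintf("  frames: %d, tracks: %d, observations: %d\n",
              x$n_frames, length(ids), nrow(x$tracks)))
  invisible(x)
}

#' @export
summary.mos_tracks <- function(object, ...) {
  t <- object$tracks
  if (nrow(t) == 0) {
    cat("No confirmed tracks.\n")
    return(invisible(object))
  }
  per <- do.call(rbind, lapply(split(t, t$id), function(d)
    data.frame(id = d$id[1], first_frame = min(d$frame), last_frame = max(d$frame),
               observed = nrow(d),
               presence_pct = 100 * nrow(d) / object$n_frames)))
  rownames(per) <- NULL
  print(per, row.names = FALSE)
  invisible(per)
}

#' Write tracks as delimited text
#'
#' One row per observed box: `frame, id, x, y, w, h` with `(x, y)` the
#' top-left corner — the same layout accepted by [read_detections()].
#'
#' @param x A `mos_tracks` object or its `tracks` data frame.
#' @param path Output file path.
#' @export
write_tracks <- function(x, path) {
  t <- if (inherits(x, "mos_tracks")) x$tracks else x
  out <- data.frame(frame = t$frame, id = t$id, x = t$x_min, y = t$y_min,
                    w = t$x_max - t$x_min, h = t$y_max - t$y_min)
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}
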