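# Trajectory evaluation against ground truth: mean absolute error,
# tolerance accuracy, the half-body-length tolerance recipe, occlusion-event
# extraction from bounding-box overlap, and identity preservation across
# occlusions.

align_frames <- function(est, gt, what = "trajectory") {
  miss_est <- setdiff(gt$frame, est$frame)
  miss_gt <- setdiff(est$frame, gt$frame)
  if (length(miss_est) || length(miss_gt)) {
    msg <- c(if (length(miss_est))
      sprintf("frames missing from estimate: %s",
              paste(utils::head(miss_est, 10), collapse = ", ")),
      if (length(miss_gt))
        sprintf("frames missing from ground truth: %s",
                paste(utils::head(miss_gt, 10), collapse = ", ")))
    stop(what, " frame sets differ; ", paste(msg, collapse = "; "))
  }
  est <- est[order(est$frame), , drop = FALSE]
  gt <- gt[order(gt$frame), , drop = FALSE]
  list(est = est, gt = gt)
}

#' Mean absolute error of a trajectory
#'
#' Per-frame sum of the absolute x and y deviations between estimated and
#' ground-truth positions, averaged over frames:
#' `MAE = (1/n) * sum_f (|x_f - xhat_f| + |y_f - yhat_f|)`.
#'
#' @param est Estimated trajectory: data frame with `frame`, `x`, `y`.
#' @param gt Ground-truth trajectory with the same columns. The two frame
#'   sets must be identical (error otherwise, listing missing frames).
#' @return MAE in pixels.
#' @export
traj_mae <- function(est, gt) {
  if (nrow(est) == 0) stop("empty trajectory")
  al <- align_frames(est, gt)
  mean(abs(al$est$x - al$gt$x) + abs(al$est$y - al$gt$y))
}

#' Per-frame tolerance accuracy test
#'
#' A frame is accurate when both axis deviations are *strictly* below the
#' tolerance: `|dx| < tol` and `|dy| < tol`.
#'
#' @param est,gt Positions: data frames / lists with `x` and `y` (vectors
#'   allowed; recycled elementwise).
#' @param tolerance Tolerance in pixels (default 6).
#' @return Logical vector.
#' @export
frame_is_accurate <- function(est, gt, tolerance = 6) {
  abs(est$x - gt$x) < tolerance & abs(est$y - gt$y) < tolerance
}

#' Trajectory accuracy percentage
#'
#' Percentage of frames whose estimated position deviates by strictly less
#' than the tolerance on both axes.
#'
#' @inheritParams traj_mae
#' @param tolerance Tolerance in pixels (default 6).
#' @return Accuracy in percent (0-100), unrounded.
#' @export
accuracy_percentage <- function(est, gt, tolerance = 6) {
  if (nrow(est) == 0) stop("empty trajectory")
  al <- align_frames(est, gt)
  100 * mean(frame_is_accurate(al$est, al$gt, tolerance))
}

#' Derive the accuracy tolerance from body lengths
#'
#' The tolerance is half the average body length measured (in pixels) on a
#' sample of frames — the recipe that yields the 6-pixel default for a
#' 12-pixel insect. Sampling the frames is the caller's responsibility.
#'
#' @param body_lengths Positive body lengths in pixels.
#' @return `mean(body_lengths) / 2`, unrounded.
#' @export
derive_tolerance <- function(body_lengths) {
  if (length(body_lengths) == 0) stop("no body lengths supplied")
  if (any(body_lengths <= 0)) stop("body lengths must be positive")
  mean(body_lengths) / 2
}

#' Extract occlusion events from per-identity boxes
#'
#' For every unordered pair of identities, each maximal run of consecutive
#' frames on which the two boxes overlap with IoU *strictly above* the
#' threshold becomes one occlusion event. An IoU exactly at the threshold
#' does not count.
#'
#' @param boxes Data frame `frame, id, x_min, y_min, x_max, y_max`.
#' @param iou_threshold Overlap threshold (default 0.25).
#' @return Data frame `id1, id2, start_frame, end_frame` (inclusive), one
#'   row per event; zero rows when nothing overlaps.
#' @export
detect_occlusions <- function(boxes, iou_threshold = 0.25) {
  empty <- data.frame(id1 = numeric(), id2 = numeric(),
                      start_frame = integer(), end_frame = integer())
  ids <- sort(unique(boxes$id))
  if (length(ids) < 2) return(empty)
  events <- list()
  for (i in seq_along(ids)[-length(ids)]) {
    bi <- boxes[boxes$id == ids[i], , drop = FALSE]
    for (j in seq((i + 1), length(ids))) {
      bj <- boxes[boxes$id == ids[j], , drop = FALSE]
      shared <- intersect(bi$frame, bj$frame)
      if (length(shared) == 0) next
      shared <- sort(shared)
      a <- bi[match(shared, bi$frame), , drop = FALSE]
      b <- bj[match(shared, bj$frame), , drop = FALSE]
      over <- shared[box_iou(a, b) > iou_threshold]
      if (length(over) == 0) next
      runs <- split(over, cumsum(c(1, diff(over) != 1)))
      for (r in runs) {
        events[[length(events) + 1]] <-
          data.frame(id1 = ids[i], id2 = ids[j],
                     start_frame = min(r), end_frame = max(r))
      }
    }
  }
  if (length(events) == 0) return(empty)
  out <- do.call(rbind, events)
  out <- out[order(out$start_frame, out$id1, out$id2), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# Nearest ground-truth agent to a point at one frame; ties broken by lower
# agent id. Returns NA when the ground truth has no point at that frame.
nearest_agent <- function(x, y, gt_frame) {
  if (nrow(gt_frame) == 0) return(NA_real_)
  d <- sqrt((gt_frame$x - x)^2 + (gt_frame$y - y)^2)
  o <- order(d, gt_frame$id)
  gt_frame$id[o[1]]
}

gt_id_col <- function(gt) {
  if ("agent_id" %in% names(gt)) { gt$id <- gt$agent_id }
  gt
}

#' Score identity preservation across occlusion events
#'
#' For each event, each involved estimated identity is mapped to its
#' nearest-centroid ground-truth agent at the last frame before the event
#' and again at the first frame after it (using, in each direction, the
#' nearest frame at which both that identity and the ground truth are
#' observed). The event counts as correctly resolved when both identities
#' keep their pre-event agent. Events for which a mapping cannot be formed
#' (e.g. the event touches the start or end of the video) are undetermined
#' and excluded from the total.
#'
#' @param events Occlusion events as from [detect_occlusions()], with `id1`
#'   and `id2` referring to estimated track ids.
#' @param est Estimated trajectory table (`frame, id, x, y`).
#' @param gt Ground-truth table (`frame, agent_id` or `id`, `x, y`).
#' @return List with `correct`, `total`, and `events` (the input with a
#'   `resolved_correctly` column: `TRUE`/`FALSE`/`NA`).
#' @export
score_identity_preservation <- function(events, est, gt) {
  gt <- gt_id_col(gt)
  if (nrow(events) == 0)
    return(list(correct = 0L, total = 0L,
                events = cbind(events, resolved_correctly = logical(0))))
  map_at <- function(track_id, side, bound) {
    tf <- est[est$id == track_id, , drop = FALSE]
    cand <- intersect(tf$frame, unique(gt$frame))
    cand <- if (side == "pre") cand[cand < bound] else cand[cand > bound]
    if (length(cand) == 0) return(NA_real_)
    f <- if (side == "pre") max(cand) else min(cand)
    p <- tf[tf$frame == f, , drop = FALSE]
    nearest_agent(p$x[1], p$y[1], gt[gt$frame == f, , drop = FALSE])
  }
  resolved <- rep(NA, nrow(events))
  for (k in seq_len(nrow(events))) {
    ev <- events[k, ]
    pre1 <- map_at(ev$id1, "pre", ev$start_frame)
    pre2 <- map_at(ev$id2, "pre", ev$start_frame)
    post1 <- map_at(ev$id1, "post", ev$end_frame)
    post2 <- map_at(ev$id2, "post", ev$end_frame)
    if (any(is.na(c(pre1, pre2, post1, post2)))) next
    resolved[k] <- (pre1 == post1) && (pre2 == post2)
  }
  events$resolved_correctly <- resolved
  list(correct = sum(resolved %in% TRUE), total = sum(!is.na(resolved)),
       events = events)
}

#' Score identity preservation over known crossing windows
#'
#' The converse view of [score_identity_preservation()], used with a
#' synthetic ground truth whose crossing (occlusion) windows are known: for
#' each window, each involved ground-truth agent is mapped to the nearest
#' estimated identity just before and just after the window; the crossing
#' is preserved when both agents keep their estimated identity and the two
#' identities are distinct.
#'
#' @param windows Data frame `agent1, agent2, start_frame, end_frame`.
#' @param est Estimated trajectory table (`frame, id, x, y`).
#' @param gt Ground-truth table (`frame, agent_id` or `id`, `x, y`).
#' @return List with `correct`, `total`, and `windows` (input plus
#'   `resolved_correctly`).
#' @export
score_crossing_windows <- function(windows, est, gt) {
  gt <- gt_id_col(gt)
  if (nrow(windows) == 0)
    return(list(correct = 0L, total = 0L, windows = windows))
  est_frames <- sort(unique(est$frame))
  map_agent <- function(agent, side, bound) {
    af <- gt[gt$id == agent, , drop = FALSE]
    cand <- intersect(af$frame, est_frames)
    cand <- if (side == "pre") cand[cand < bound] else cand[cand > bound]
    if (length(cand) == 0) return(NA_real_)
    f <- if (side == "pre") max(cand) else min(cand)
    p <- af[af$frame == f, , drop = FALSE]
    ef <- est[est$frame == f, , drop = FALSE]
    d <- sqrt((ef$x - p$x[1])^2 + (ef$y - p$y[1])^2)
    o <- order(d, ef$id)
    ef$id[o[1]]
  }
  resolved <- rep(NA, nrow(windows))
  for (k in seq_len(nrow(windows))) {
    w <- windows[k, ]
    pre1 <- map_agent(w$agent1, "pre", w$start_frame)
    pre2 <- map_agent(w$agent2, "pre", w$start_frame)
    post1 <- map_agent(w$agent1, "post", w$end_frame)
    post2 <- map_agent(w$agent2, "post", w$end_frame)
    if (any(is.na(c(pre1, pre2, post1, post2)))) next
    resolved[k] <- (pre1 == post1) && (pre2 == post2) && (pre1 != pre2)
  }
  windows$resolved_correctly <- resolved
  list(correct = sum(resolved %in% TRUE), total = sum(!is.na(resolved)),
       windows = windows)
}

#' Match estimated trajectories to ground-truth agents
#'
#' Minimum-cost assignment where the cost of pairing an estimated identity
#' with an agent is their mean centroid distance over shared frames (pairs
#' with no shared frame are forbidden).
#'
#' @param est Estimated trajectory table (`frame, id, x, y`).
#' @param gt Ground-truth table (`frame, agent_id` or `id`, `x, y`).
#' @return Data frame `id, agent_id, shared_frames, mean_dist`.
#' @export
match_trajectories <- function(est, gt) {
  gt <- gt_id_col(gt)
  est_ids <- sort(unique(est$id)); agents <- sort(unique(gt$id))
  if (length(est_ids) == 0 || length(agents) == 0)
    return(data.frame(id = numeric(), agent_id = numeric(),
                      shared_frames = integer(), mean_dist = numeric()))
  cost <- matrix(Inf, length(est_ids), length(agents))
  shared_n <- cost
  for (i in seq_along(est_ids)) {
    e <- est[est$id == est_ids[i], , drop = FALSE]
    for (j in seq_along(agents)) {
      a <- gt[gt$id == agents[j], , drop = FALSE]
      shared <- intersect(e$frame, a$frame)
      if (length(shared) == 0) next
      ee <- e[match(shared, e$frame), ]; aa <- a[match(shared, a$frame), ]
      cost[i, j] <- mean(sqrt((ee$x - aa$x)^2 + (ee$y - aa$y)^2))
      shared_n[i, j] <- length(shared)
    }
  }
  assign_col <- solve_assignment(cost)
  keep <- which(!is.na(assign_col))
  data.frame(id = est_ids[keep], agent_id = agents[assign_col[keep]],
             shared_frames = as.integer(shared_n[cbind(keep, assign_col[keep])]),
             mean_dist = cost[cbind(keep, assign_col[keep])])
}

#' Read a ground-truth table
#'
#' Delimited text with columns `frame, agent_id, x, y` and optionally
#' `x_min, y_min, x_max, y_max`; a header is auto-detected.
#'
#' @param path CSV path.
#' @return Data frame with those columns.
#' @export
read_ground_truth <- function(path) {
  first <- strsplit(readLines(path, n = 1), ",")[[1]]
  has_header <- any(is.na(suppressWarnings(as.numeric(first))))
  d <- utils::read.csv(path, header = has_header)
  if (!has_header) {
    nm <- c("frame", "agent_id", "x", "y", "x_min", "y_min", "x_max", "y_max")
    names(d) <- nm[seq_len(ncol(d))]
  }
  d
}
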