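# Batch pipeline: detect -> track -> filter -> interpolate for every video
# in a folder, writing per-video results (positions table, before/after
# interpolation trajectory plots, annotated overlays, run log) under a
# Results directory, plus evaluation against ground truth.

#' Pipeline configuration
#'
#' Bundles the five user-facing tracking parameters (image size,
#' confidence, NMS IoU, max age, filtration) with the detector and
#' occlusion-analysis settings.
#'
#' @param image_size Requested image size in pixels (default 1040); snapped
#'   up to a multiple of 32 at run time.
#' @param confidence Detection confidence threshold (default 0.05).
#' @param nms_iou Non-maximum-suppression IoU threshold (default 0.05).
#' @param max_age Frames a track survives without detections (default 30).
#' @param filtration_pct Minimum identity presence as a percentage of total
#'   frames (default 5); shorter-lived identities are removed.
#' @param detector `"blob"` for the built-in blob detector or `"external"`
#'   for detections supplied via a file (see [read_detections()]).
#' @param occlusion_iou IoU threshold for occlusion events (default 0.25).
#' @param intensity_threshold,min_area,max_area Blob-detector settings, see
#'   [detector_config()].
#' @param motion_weight,n_init Tracker settings, see [tracker_config()].
#' @param max_gap Interpolation gap cap in frames (default `Inf`).
#' @param overlay Write annotated overlay frames (default `TRUE`).
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(image_size = 1040L, confidence = 0.05,
                            nms_iou = 0.05, max_age = 30L,
                            filtration_pct = 5,
                            detector = c("blob", "external"),
                            occlusion_iou = 0.25,
                            intensity_threshold = 140,
                            min_area = 4, max_area = 1000,
                            motion_weight = 0.05, n_init = 3L,
                            max_gap = Inf, overlay = TRUE) {
  detector <- match.arg(detector)
  structure(list(image_size = as.integer(image_size), confidence = confidence,
                 nms_iou = nms_iou, max_age = as.integer(max_age),
                 filtration_pct = filtration_pct, detector = detector,
                 occlusion_iou = occlusion_iou,
                 intensity_threshold = intensity_threshold,
                 min_area = min_area, max_area = max_area,
                 motion_weight = motion_weight, n_init = as.integer(n_init),
                 max_gap = max_gap, overlay = overlay),
            class = "pipeline_config")
}

#' Process one video through the full pipeline
#'
#' Runs image-size adjustment, detection (built-in blob detector or an
#' external detection file), confidence filtering, non-maximum suppression,
#' tracking, short-track filtration and cubic-spline gap interpolation, and
#' writes the results to `<out_root>/<name>/`: `positions.csv`,
#' `boxes.csv` (tracked boxes), `trajectory_before.png`,
#' `trajectory_after.png`, annotated `overlay/` frames and `run.log`. If
#' the run is interrupted partway, whatever positions exist are flushed.
#'
#' @param input Directory of PNG/TIFF frames (see [read_frames()]).
#' @param config A [pipeline_config()].
#' @param out_root Results root directory (default `Results` next to the
#'   input).
#' @param name Video name (default: basename of `input`).
#' @param detections_file Detection file for `detector = "external"`.
#' @return An object of class `mos_run`: list with `name`, `dir`,
#'   `positions` (final trajectory table), `tracks`, `n_frames`,
#'   `interpolation_pct` and `config`.
#' @export
process_video <- function(input, config = pipeline_config(),
                          out_root = file.path(dirname(input), "Results"),
                          name = basename(input), detections_file = NULL) {
  out_dir <- file.path(out_root, name)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  log_path <- file.path(out_dir, "run.log")
  logf <- function(...) cat(sprintf(...), "\n", sep = "", file = log_path,
                            append = TRUE)
  cat("", file = log_path)  # truncate

  eff_size <- adjust_image_size(config$image_size, 32L)
  logf("video=%s", name)
  logf("image_size_requested=%d", config$image_size)
  logf("image_size_effective=%d", eff_size)
  for (p in c("confidence", "nms_iou", "max_age", "filtration_pct",
              "detector", "occlusion_iou"))
    logf("%s=%s", p, format(config[[p]]))

  frames <- read_frames(input)
  n_frames <- length(frames)
  logf("n_frames=%d", n_frames)

  dconf <- detector_config(confidence = config$confidence,
                           nms_iou = config$nms_iou,
                           image_size = config$image_size,
                           intensity_threshold = config$intensity_threshold,
                           min_area = config$min_area,
                           max_area = config$max_area)
  dets <- if (config$detector == "external") {
    if (is.null(detections_file))
      stop("detector = 'external' requires a detections_file")
    read_detections(detections_file)
  } else {
    parts <- lapply(seq_len(n_frames) - 1L, function(f)
      detect_blobs(frames[[f + 1L]], frame = f, config = dconf))
    do.call(rbind, parts)
  }
  dets <- filter_by_confidence(dets, config$confidence)
  if (nrow(dets)) {
    dets <- do.call(rbind, lapply(split(dets, dets$frame), nms,
                                  iou_threshold = config$nms_iou))
    rownames(dets) <- NULL
  }
  logf("n_detections=%d", nrow(dets))
  if (nrow(dets) == 0) warning("no detections in ", name,
                               "; writing empty outputs")

  tconf <- tracker_config(max_age = config$max_age, n_init = config$n_init,
                          motion_weight = config$motion_weight)
  tracks <- track_detections(dets, n_frames, frames = frames, config = tconf)
  write_tracks(tracks, file.path(out_dir, "boxes.csv"))

  raw <- tracks_to_trajectories(tracks)
  kept <- filter_short_tracks(raw, n_frames, config$filtration_pct)

  # flush the pre-interpolation positions first so an interrupted run still
  # leaves usable output behind
  write_positions(kept, file.path(out_dir, "positions.csv"))
  try(plot_trajectories(kept, ncol(frames[[1]]), nrow(frames[[1]]),
                        main = sprintf("%s - before interpolation", name),
                        file = file.path(out_dir, "trajectory_before.png")),
      silent = TRUE)

  final <- interpolate_gaps(kept, max_gap = config$max_gap)
  write_positions(final, file.path(out_dir, "positions.csv"))
  try(plot_trajectories(final, ncol(frames[[1]]), nrow(frames[[1]]),
                        main = sprintf("%s - after interpolation", name),
                        file = file.path(out_dir, "trajectory_after.png")),
      silent = TRUE)
  if (isTRUE(config$overlay))
    try(write_overlays(frames, tracks, file.path(out_dir, "overlay")),
        silent = TRUE)

  ipct <- interpolation_percentage(final, n_frames)
  logf("n_tracks=%d", length(unique(final$id)))
  logf("interpolation_pct=%.4f", ipct)

  structure(list(name = name, dir = out_dir, positions = final,
                 tracks = tracks, n_frames = n_frames,
                 interpolation_pct = ipct, config = config),
            class = "mos_run")
}

#' @export
print.mos_run <- function(x, ...) {
  cat(sprintf("Pipeline run '%s': %d frames, %d identities, %.2f%% interpolated\n",
              x$name, x$n_frames, length(unique(x$positions$id)),
              round_half_out(x$interpolation_pct)))
  cat("  results in ", x$dir, "\n", sep = "")
  invisible(x)
}

#' Process every video in a folder
#'
#' Each subdirectory of `folder` is treated as one video (a directory of
#' frames). Videos are processed independently; a failure in one is
#' recorded in the summary and does not abort the batch. A `summary.csv`
#' is written under the results root.
#'
#' @param folder Input folder.
#' @param config A [pipeline_config()].
#' @param out_root Results root (default `<folder>/Results`).
#' @return Data frame summary (class `mos_batch`): one row per video with
#'   `video`, `status`, `n_tracks`, `interpolation_pct`, `message`.
#' @export
process_folder <- function(folder, config = pipeline_config(),
                           out_root = file.path(folder, "Results")) {
  stopifnot(dir.exists(folder))
  vids <- list.dirs(folder, recursive = FALSE)
  vids <- vids[basename(vids) != "Results"]
  if (length(vids) == 0) {
    warning("no videos found in ", folder)
    return(structure(data.frame(video = character(), status = character(),
                                n_tracks = integer(),
                                interpolation_pct = numeric(),
                                message = character()),
                     class = c("mos_batch", "data.frame")))
  }
  rows <- lapply(vids, function(v) {
    res <- tryCatch(process_video(v, config, out_root = out_root),
                    error = function(e)
                      structure(list(message = conditionMessage(e)),
                                class = "pipeline_failure"))
    if (inherits(res, "pipeline_failure")) {
      data.frame(video = basename(v), status = "failed", n_tracks = NA_integer_,
                 interpolation_pct = NA_real_, message = res$message)
    } else {
      data.frame(video = basename(v), status = "ok",
                 n_tracks = length(unique(res$positions$id)),
                 interpolation_pct = res$interpolation_pct, message = "")
    }
  })
  summary <- do.call(rbind, rows)
  dir.create(out_root, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(summary, file.path(out_root, "summary.csv"),
                   row.names = FALSE)
  structure(summary, class = c("mos_batch", "data.frame"))
}

#' Evaluate a pipeline run against ground truth
#'
#' Matches estimated identities to ground-truth agents (minimal summed
#' centroid distance), computes MAE and tolerance accuracy over the frames
#' the matched pairs share, extracts occlusion events from the tracked
#' boxes and scores identity preservation across them.
#'
#' @param results_dir A results directory written by [process_video()]
#'   (containing `positions.csv` and `boxes.csv`), or a `mos_run` object.
#' @param gt Ground-truth table or path to one (see [read_ground_truth()]).
#' @param tolerance Accuracy tolerance in pixels (default 6).
#' @param occlusion_iou IoU threshold for occlusion events (default 0.25).
#' @return An object of class `mos_eval` with fields `n_frames`, `mae`,
#'   `accuracy_pct`, `n_inaccurate`, `tolerance`, `occlusions_total`,
#'   `occlusions_correct`, `matching` and `per_track`.
#' @export
evaluate_run <- function(results_dir, gt, tolerance = 6,
                         occlusion_iou = 0.25) {
  if (inherits(results_dir, "mos_run")) {
    est <- results_dir$positions
    boxes <- results_dir$tracks$tracks
  } else {
    est <- read_positions(file.path(results_dir, "positions.csv"))
    bx <- utils::read.csv(file.path(results_dir, "boxes.csv"))
    boxes <- data.frame(frame = bx$frame, id = bx$id, x_min = bx$x,
                        y_min = bx$y, x_max = bx$x + bx$w, y_max = bx$y + bx$h)
  }
  if (is.character(gt)) gt <- read_ground_truth(gt)
  gt <- gt_id_col(gt)
  matching <- match_trajectories(est, gt)
  if (nrow(matching) == 0) stop("no estimated identity shares frames with the ground truth")
  per <- lapply(seq_len(nrow(matching)), function(k) {
    e <- est[est$id == matching$id[k], , drop = FALSE]
    a <- gt[gt$id == matching$agent_id[k], , drop = FALSE]
    shared <- intersect(e$frame, a$frame)
    ee <- e[match(shared, e$frame), ]; aa <- a[match(shared, a$frame), ]
    acc <- frame_is_accurate(ee, aa, tolerance)
    data.frame(id = matching$id[k], agent_id = matching$agent_id[k],
               n_frames = length(shared),
               mae = mean(abs(ee$x - aa$x) + abs(ee$y - aa$y)),
               n_inaccurate = sum(!acc))
  })
  per <- do.call(rbind, per)
  n_frames <- sum(per$n_frames)
  n_inacc <- sum(per$n_inaccurate)
  events <- detect_occlusions(boxes, occlusion_iou)
  occ <- score_identity_preservation(events, est, gt)
  structure(list(n_frames = n_frames,
                 mae = sum(per$mae * per$n_frames) / n_frames,
                 accuracy_pct = 100 * (n_frames - n_inacc) / n_frames,
                 n_inaccurate = n_inacc, tolerance = tolerance,
                 occlusions_total = occ$total,
                 occlusions_correct = occ$correct,
                 matching = matching, per_track = per,
                 occlusion_events = occ$events),
            class = "mos_eval")
}

#' @export
print.mos_eval <- function(x, ...) {
  cat("Trajectory evaluation\n")
  cat(sprintf("  frames evaluated: %d\n", x$n_frames))
  cat(sprintf("  MAE: %.3f px\n", x$mae))
  cat(sprintf("  accuracy (tolerance %g px): %.2f%% (%d inaccurate frames)\n",
              x$tolerance, round_half_out(x$accuracy_pct), x$n_inaccurate))
  cat(sprintf("  occlusions: %d/%d identities preserved\n",
              x$occlusions_correct, x$occlusions_total))
  invisible(x)
}
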