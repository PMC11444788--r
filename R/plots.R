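# Trajectory figures and annotated frame overlays (base graphics). Image
# coordinates: y grows downward, so axes are drawn flipped to match the
# footage.

#' Plot trajectories
#'
#' One colored path per identity, in image coordinates (y axis pointing
#' down). Interpolated points are drawn like observed ones — this is the
#' "after interpolation" view when called on an interpolated table.
#'
#' @param traj Trajectory table (`frame, id, x, y`).
#' @param width,height Arena extent in pixels (defaults: data range).
#' @param main Plot title.
#' @param file Optional PNG path; when given the plot is written there
#'   instead of the active device.
#' @return Invisibly, `traj`.
#' @export
plot_trajectories <- function(traj, width = NULL, height = NULL,
                              main = "Trajectories", file = NULL) {
  if (!is.null(file)) {
    grDevices::png(file, width = 900, height = 700)
    on.exit(grDevices::dev.off())
  }
  if (is.null(width)) width <- max(traj$x, 1)
  if (is.null(height)) height <- max(traj$y, 1)
  ids <- sort(unique(traj$id))
  cols <- grDevices::hcl.colors(max(length(ids), 3), "Dark 3")
  graphics::plot(NA, xlim = c(0, width), ylim = c(height, 0),
                 xlab = "x (px)", ylab = "y (px)", main = main, asp = 1)
  for (k in seq_along(ids)) {
    d <- traj[traj$id == ids[k], , drop = FALSE]
    d <- d[order(d$frame), , drop = FALSE]
    graphics::lines(d$x, d$y, col = cols[k], lwd = 1.5)
  }
  if (length(ids))
    graphics::legend("topright", legend = paste("id", ids),
                     col = cols[seq_along(ids)], lwd = 2, cex = 0.8, bg = "white")
  invisible(traj)
}

#' Write annotated frame overlays
#'
#' Writes one PNG per frame with the tracked boxes and identity labels
#' drawn over the grayscale image.
#'
#' @param frames List of frame matrices (gray 0-255).
#' @param tracks A `mos_tracks` object or its `tracks` data frame.
#' @param dir Output directory (created if needed).
#' @param every Write every n-th frame (default 1 = all frames).
#' @return `dir`, invisibly.
#' @export
write_overlays <- function(frames, tracks, dir, every = 1L) {
  t <- if (inherits(tracks, "mos_tracks")) tracks$tracks else tracks
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  ids <- sort(unique(t$id))
  cols <- grDevices::hcl.colors(max(length(ids), 3), "Dark 3")
  for (f in seq_along(frames)) {
    if ((f - 1L) %% every != 0L) next
    mat <- frames[[f]]
    file <- file.path(dir, sprintf("%06d.png", f - 1L))
    grDevices::png(file, width = ncol(mat), height = nrow(mat))
    graphics::par(mar = c(0, 0, 0, 0))
    graphics::plot(NA, xlim = c(0, ncol(mat)), ylim = c(nrow(mat), 0),
                   xaxs = "i", yaxs = "i", axes = FALSE, xlab = "", ylab = "")
    graphics::rasterImage(mat / 255, 0, nrow(mat), ncol(mat), 0)
    tf <- t[t$frame == f - 1L, , drop = FALSE]
    for (r in seq_len(nrow(tf))) {
      col <- cols[match(tf$id[r], ids)]
      graphics::rect(tf$x_min[r], tf$y_max[r], tf$x_max[r], tf$y_min[r],
                     border = col, lwd = 2)
      graphics::text(tf$x_min[r], tf$y_min[r] - 3, labels = tf$id[r],
                     col = col, cex = 0.9, adj = c(0, 1))
    }
    grDevices::dev.off()
  }
  invisible(dir)
}
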