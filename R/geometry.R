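# Box geometry shared by every stage of the pipeline.
#
# Conventions: continuous pixel coordinates, origin at the top-left corner of
# the frame, x increasing rightward and y increasing downward. A bounding box
# is axis-aligned and stored as (x_min, y_min, x_max, y_max); its area is
# (x_max - x_min) * (y_max - y_min) with no one-pixel correction, so IoU is
# scale-free.

#' Construct a bounding box
#'
#' @param x_min,y_min,x_max,y_max Box edges in pixels (continuous, top-left
#'   origin). Vectors are recycled to a common length.
#' @return A numeric matrix with one row per box and columns
#'   `x_min`, `y_min`, `x_max`, `y_max`.
#' @examples
#' bbox(0, 0, 2, 2)
#' @export
bbox <- function(x_min, y_min, x_max, y_max) {
  m <- cbind(x_min = x_min, y_min = y_min, x_max = x_max, y_max = y_max)
  if (!all(is.finite(m))) stop("box coordinates must be finite")
  if (any(m[, "x_max"] < m[, "x_min"]) || any(m[, "y_max"] < m[, "y_min"]))
    stop("box must satisfy x_min <= x_max and y_min <= y_max")
  m
}

# Coerce vectors / data.frames / matrices to an n x 4 box matrix.
as_box_matrix <- function(b) {
  if (is.data.frame(b)) b <- as.matrix(b[, c("x_min", "y_min", "x_max", "y_max")])
  if (is.null(dim(b))) b <- matrix(b, nrow = 1)
  if (ncol(b) < 4) stop("a box needs 4 coordinates")
  cn <- colnames(b)
  if (!is.null(cn) && all(c("x_min", "y_min", "x_max", "y_max") %in% cn))
    b <- b[, c("x_min", "y_min", "x_max", "y_max"), drop = FALSE]
  else
    b <- b[, 1:4, drop = FALSE]
  colnames(b) <- c("x_min", "y_min", "x_max", "y_max")
  b
}

box_area <- function(b) {
  b <- as_box_matrix(b)
  unname((b[, 3] - b[, 1]) * (b[, 4] - b[, 2]))
}

#' Intersection over union of bounding boxes
#'
#' Overlap area divided by union area, in \[0, 1\]. Two boxes whose union has
#' zero area (both degenerate) give 0.
#'
#' @param a,b Boxes: length-4 vectors, n x 4 matrices or data frames with
#'   columns `x_min`, `y_min`, `x_max`, `y_max`. Rows are recycled.
#' @return Numeric vector of IoU values.
#' @examples
#' box_iou(c(0, 0, 2, 2), c(1, 1, 3, 3))  # 1/7
#' @export
box_iou <- function(a, b) {
  a <- as_box_matrix(a); b <- as_box_matrix(b)
  n <- max(nrow(a), nrow(b))
  ia <- rep_len(seq_len(nrow(a)), n); ib <- rep_len(seq_len(nrow(b)), n)
  a <- a[ia, , drop = FALSE]; b <- b[ib, , drop = FALSE]
  iw <- pmax(0, pmin(a[, 3], b[, 3]) - pmax(a[, 1], b[, 1]))
  ih <- pmax(0, pmin(a[, 4], b[, 4]) - pmax(a[, 2], b[, 2]))
  inter <- unname(iw * ih)
  union <- box_area(a) + box_area(b) - inter
  unname(ifelse(union > 0, inter / union, 0))
}

#' Centroid of a bounding box
#'
#' @param box Boxes as for [box_iou()].
#' @return Numeric matrix with columns `x` and `y` (box centers in pixels).
#' @examples
#' box_centroid(c(10, 20, 14, 26))  # (12, 23)
#' @export
box_centroid <- function(box) {
  b <- as_box_matrix(box)
  cbind(x = (b[, 1] + b[, 3]) / 2, y = (b[, 2] + b[, 4]) / 2)
}

# Empty detection table with the canonical columns.
empty_detections <- function() {
  data.frame(frame = integer(), x_min = numeric(), y_min = numeric(),
             x_max = numeric(), y_max = numeric(), confidence = numeric())
}

#' Assemble a detection table
#'
#' @param frame Integer frame indices (0-based).
#' @param box Boxes as for [box_iou()].
#' @param confidence Detection confidences in \[0, 1\].
#' @return A data frame with columns `frame`, `x_min`, `y_min`, `x_max`,
#'   `y_max`, `confidence` — the detection format used throughout.
#' @export
detections <- function(frame, box, confidence) {
  b <- as_box_matrix(box)
  d <- data.frame(frame = as.integer(frame), b, confidence = confidence)
  if (any(d$frame < 0)) stop("frame indices must be >= 0")
  if (any(d$confidence < 0 | d$confidence > 1)) stop("confidence must lie in [0, 1]")
  d
}

#' Non-maximum suppression
#'
#' Greedy suppression of redundant detections within one frame: boxes are
#' visited in order of decreasing confidence (ties broken by smaller `x_min`,
#' then smaller `y_min`); each box is kept unless its IoU with an already-kept
#' box strictly exceeds `iou_threshold`.
#'
#' @param dets Detection table (one frame) as produced by [detections()].
#' @param iou_threshold Overlap above which the lower-confidence box is
#'   suppressed. Default 0.05 — deliberately lenient, suited to small,
#'   closely spaced targets.
#' @return The surviving rows, sorted by decreasing confidence.
#' @export
nms <- function(dets, iou_threshold = 0.05) {
  if (nrow(dets) <= 1) return(dets)
  if (length(unique(dets$frame)) > 1)
    stop("nms() operates on the detections of a single frame")
  o <- order(-dets$confidence, dets$x_min, dets$y_min)
  dets <- dets[o, , drop = FALSE]
  boxes <- as_box_matrix(dets)
  keep <- logical(nrow(dets))
  for (i in seq_len(nrow(dets))) {
    if (!any(keep)) { keep[i] <- TRUE; next }
    ov <- box_iou(boxes[keep, , drop = FALSE], boxes[i, , drop = FALSE])
    if (all(ov <= iou_threshold)) keep[i] <- TRUE
  }
  out <- dets[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}
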