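# Detection stage: the built-in blob detector for infrared-style footage
# (small dark bodies on a light background) and the Confidence / Image Size
# parameters. The detector is deliberately pluggable: externally produced
# detections (e.g. from a trained CNN) can be read from a delimited file and
# fed to the tracker instead — see read_detections().

#' Snap a requested image size to the detector stride
#'
#' Detection backbones require input dimensions that are multiples of their
#' maximum stride. The requested size is rounded *up* to the next multiple,
#' so a 1040-pixel request with the usual stride of 32 becomes 1056.
#'
#' @param requested Requested image size in pixels (>= 1).
#' @param stride Stride in pixels (default 32).
#' @return The smallest multiple of `stride` that is `>= requested`.
#' @examples
#' adjust_image_size(1040, 32)  # 1056
#' @export
adjust_image_size <- function(requested, stride = 32L) {
  if (any(requested < 1) || any(stride < 1))
    stop("requested size and stride must be positive")
  as.integer(ceiling(requested / stride) * stride)
}

#' Blob-detector configuration
#'
#' @param confidence Minimum confidence retained (default 0.05; kept low
#'   because small targets score weak contrast).
#' @param nms_iou IoU threshold for non-maximum suppression (default 0.05).
#' @param image_size Requested image size in pixels (default 1040); snapped
#'   to a multiple of `stride` by [adjust_image_size()].
#' @param stride Backbone stride (default 32).
#' @param intensity_threshold Grayscale level (0-255) below which a pixel
#'   counts as object; dark-on-light imagery assumed. Default 140.
#' @param min_area,max_area Connected-component area bounds in px^2.
#' @return A list of class `detector_config`.
#' @export
detector_config <- function(confidence = 0.05, nms_iou = 0.05,
                            image_size = 1040L, stride = 32L,
                            intensity_threshold = 140,
                            min_area = 4, max_area = 1000) {
  stopifnot(confidence >= 0, confidence <= 1, nms_iou >= 0, nms_iou <= 1,
            min_area <= max_area, intensity_threshold >= 0,
            intensity_threshold <= 255)
  structure(list(confidence = confidence, nms_iou = nms_iou,
                 image_size = as.integer(image_size), stride = as.integer(stride),
                 intensity_threshold = intensity_threshold,
                 min_area = min_area, max_area = max_area),
            class = "detector_config")
}

#' Detect dark blobs in a grayscale frame
#'
#' Binarizes the frame at `intensity_threshold`, labels connected components
#' (8-connectivity via EBImage), drops components outside the configured area
#' range and emits one detection per surviving component with a tight
#' bounding box. Confidence is the component's contrast against the frame
#' background, `(background - mean intensity) / background`, clipped to
#' (0, 1], so stronger (darker) blobs score higher.
#'
#' Pixel `[r, c]` of the matrix covers the square `[c-1, c] x [r-1, r]`, so
#' boxes and centroids are in continuous image coordinates.
#'
#' @param pixels Numeric matrix of grayscale intensities in \[0, 255\];
#'   rows are image rows (y), columns are image columns (x).
#' @param frame Frame index (0-based) stamped on the detections.
#' @param config A [detector_config()].
#' @return Detection table (see [detections()]), sorted by decreasing
#'   confidence; empty for a uniform frame.
#' @export
detect_blobs <- function(pixels, frame = 0L, config = detector_config()) {
  stopifnot(is.matrix(pixels), nrow(pixels) >= 1, ncol(pixels) >= 1)
  mask <- pixels < config$intensity_threshold
  if (!any(mask)) return(empty_detections())
  lab <- EBImage::bwlabel(mask * 1L)
  lab <- as.matrix(EBImage::imageData(lab))
  idx <- which(lab > 0)
  comp <- lab[idx]
  rows <- ((idx - 1L) %% nrow(lab)) + 1L
  cols <- ((idx - 1L) %/% nrow(lab)) + 1L
  area <- tabulate(comp)
  keep <- which(area >= config$min_area & area <= config$max_area)
  if (length(keep) == 0) return(empty_detections())
  bg <- stats::median(pixels)
  out <- lapply(keep, function(k) {
    sel <- comp == k
    r <- rows[sel]; cc <- cols[sel]
    conf <- if (bg > 0) (bg - mean(pixels[idx[sel]])) / bg else 1
    c(x_min = min(cc) - 1, y_min = min(r) - 1, x_max = max(cc), y_max = max(r),
      confidence = min(1, max(conf, 1e-6)))
  })
  m <- do.call(rbind, out)
  d <- detections(frame = rep(frame, nrow(m)), box = m[, 1:4, drop = FALSE],
                  confidence = m[, 5])
  d <- d[order(-d$confidence, d$x_min, d$y_min), , drop = FALSE]
  rownames(d) <- NULL
  d
}

#' Filter detections by confidence
#'
#' Keeps detections whose confidence is greater than *or equal to* the
#' threshold (only scores strictly below it are removed), preserving order.
#'
#' @param dets Detection table.
#' @param threshold Confidence threshold (default 0.05).
#' @return The retained rows.
#' @export
filter_by_confidence <- function(dets, threshold = 0.05) {
  dets[dets$confidence >= threshold, , drop = FALSE]
}

#' Read externally produced detections
#'
#' Parses a comma-delimited detection file, one detection per row in the
#' common tracking-challenge ordering `frame, x, y, w, h, conf` where
#' `(x, y)` is the top-left corner and `w`, `h` the box width and height.
#' Frames are 0-based; a header row is allowed and auto-detected.
#'
#' @param path Path to the file.
#' @return Detection table (see [detections()]) sorted by frame, with boxes
#'   converted to `(x_min, y_min, x_max, y_max)`. An empty file yields an
#'   empty table.
#' @export
read_detections <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines_trim <- trimws(lines)
  rows <- which(nzchar(lines_trim))
  if (length(rows) == 0) return(empty_detections())
  first <- strsplit(lines_trim[rows[1]], ",")[[1]]
  if (any(is.na(suppressWarnings(as.numeric(first))))) rows <- rows[-1]
  if (length(rows) == 0) return(empty_detections())
  parsed <- lapply(rows, function(i) {
    fields <- strsplit(lines_trim[i], ",")[[1]]
    if (length(fields) != 6)
      stop(sprintf("line %d: expected 6 comma-separated fields, got %d",
                   i, length(fields)))
    vals <- suppressWarnings(as.numeric(trimws(fields)))
    if (any(is.na(vals)))
      stop(sprintf("line %d: non-numeric field", i))
    if (vals[4] < 0 || vals[5] < 0)
      stop(sprintf("line %d: negative box width or height", i))
    if (vals[1] < 0)
      stop(sprintf("line %d: negative frame index", i))
    vals
  })
  m <- do.call(rbind, parsed)
  d <- detections(frame = m[, 1],
                  box = cbind(m[, 2], m[, 3], m[, 2] + m[, 4], m[, 3] + m[, 5]),
                  confidence = pmin(1, pmax(0, m[, 6])))
  d <- d[order(d$frame), , drop = FALSE]
  rownames(d) <- NULL
  d
}

#' Read a frame sequence from a directory of images
#'
#' Frames are the lexicographically ordered `.png` / `.tif` / `.tiff` files
#' in `path` (or a single image file). Images are converted to grayscale
#' intensity matrices in \[0, 255\]; multi-channel images are averaged.
#'
#' @param path Directory of image files, or one image file.
#' @return A list of numeric matrices, one per frame, in frame order.
#' @export
read_frames <- function(path) {
  files <- if (dir.exists(path)) {
    f <- list.files(path, pattern = "\\.(png|tif|tiff)$", ignore.case = TRUE,
                    full.names = TRUE)
    sort(f)
  } else path
  if (length(files) == 0) stop("no PNG/TIFF frames found in ", path)
  lapply(files, read_frame_file)
}

read_frame_file <- function(file) {
  ext <- tolower(tools::file_ext(file))
  img <- if (ext == "png") {
    png::readPNG(file)
  } else if (ext %in% c("tif", "tiff")) {
    if (!requireNamespace("tiff", quietly = TRUE))
      stop("reading TIFF frames requires the 'tiff' package")
    tiff::readTIFF(file)
  } else stop("unsupported frame format: ", file)
  if (length(dim(img)) == 3) img <- apply(img[, , 1:min(3, dim(img)[3]), drop = FALSE], c(1, 2), mean)
  img * 255
}
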