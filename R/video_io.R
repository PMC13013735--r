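# Frame input and coordinate calibration.
#
# Input format: a directory of numbered grayscale or RGB image frames
# (PNG, optionally TIFF), plus an optional `frames_meta.yaml` carrying the
# frame rate and metric calibration. This is the format the synthetic
# generator writes and the format the tracker consumes.

#' Construct a FrameSequence
#'
#' An ordered set of grayscale frames with acquisition metadata. Frames are
#' numeric matrices (rows = y, columns = x) with intensities in \[0, 1\].
#'
#' @param frames List of numeric matrices, all the same size; at least two
#'   (optical flow needs frame pairs).
#' @param frame_rate Frames per second (> 0).
#' @param metric_scale Optional meters per pixel (> 0) from camera
#'   calibration; `NULL` if uncalibrated.
#' @return A `FrameSequence` object.
#' @export
frame_sequence <- function(frames, frame_rate = 30, metric_scale = NULL) {
  if (!is.list(frames) || length(frames) < 2)
    stop("a FrameSequence needs at least 2 frames")
  dims <- dim(frames[[1]])
  ok <- vapply(frames, function(f) is.matrix(f) && all(dim(f) == dims), TRUE)
  if (!all(ok)) stop("all frames must be matrices of identical size")
  if (!is.numeric(frame_rate) || frame_rate <= 0)
    stop("frame_rate must be > 0")
  if (!is.null(metric_scale) && metric_scale <= 0)
    stop("metric_scale must be > 0")
  structure(list(frames = frames, frame_rate = frame_rate,
                 width = dims[2], height = dims[1],
                 metric_scale = metric_scale),
            class = "FrameSequence")
}

#' @export
print.FrameSequence <- function(x, ...) {
  cat(sprintf("FrameSequence: %d frames, %d x %d px, %g fps%s\n",
              length(x$frames), x$width, x$height, x$frame_rate,
              if (is.null(x$metric_scale)) ""
              else sprintf(", %g m/px", x$metric_scale)))
  invisible(x)
}

#' @export
length.FrameSequence <- function(x) length(x$frames)

# ITU-R BT.601 luminance; input array is H x W x C in [0, 1]
rgb_to_gray <- function(arr) {
  if (length(dim(arr)) == 2) return(arr)
  if (dim(arr)[3] >= 3)
    return(0.299 * arr[, , 1] + 0.587 * arr[, , 2] + 0.114 * arr[, , 3])
  arr[, , 1]
}

read_one_frame <- function(path) {
  ext <- tolower(tools::file_ext(path))
  arr <- switch(ext,
    png = png::readPNG(path),
    tif = ,
    tiff = tiff::readTIFF(path),
    stop("unsupported frame format: ", ext)
  )
  rgb_to_gray(arr)
}

#' Read a frame sequence from a directory of image files
#'
#' Frames are the PNG (or TIFF) files in `path`, in lexicographic filename
#' order. If the directory contains a `frames_meta.yaml` with `frame_rate`
#' and optionally `metric_scale`, those are used; arguments override it.
#'
#' @param path Directory containing numbered frame images.
#' @param start First frame to read, 0-based (default 0).
#' @param count Number of frames to read; `Inf` reads to the end. If fewer
#'   frames remain than requested the result is truncated with a warning;
#'   fewer than 2 available frames is an error.
#' @param frame_rate,metric_scale Optional overrides of the directory
#'   metadata.
#' @return A [frame_sequence()].
#' @export
read_frames <- function(path, start = 0, count = Inf,
                        frame_rate = NULL, metric_scale = NULL) {
  if (!dir.exists(path)) stop("cannot read frames: no such directory: ", path)
  if (start < 0) stop("start must be >= 0")
  if (count < 2) stop("count must be >= 2")

  files <- list.files(path, pattern = "\\.(png|tif|tiff)$", full.names = TRUE,
                      ignore.case = TRUE)
  files <- sort(files)
  if (length(files) == 0) stop("no decodable frames found in ", path)

  meta_path <- file.path(path, "frames_meta.yaml")
  meta <- if (file.exists(meta_path)) yaml::read_yaml(meta_path) else list()
  if (is.null(frame_rate)) frame_rate <- meta$frame_rate %||% 30
  if (is.null(metric_scale)) metric_scale <- meta$metric_scale

  if (start >= length(files))
    stop("start frame ", start, " beyond end of sequence (",
         length(files), " frames)")
  last <- if (is.finite(count)) start + count - 1 else length(files) - 1
  if (last > length(files) - 1) {
    warning("requested ", count, " frames but only ",
            length(files) - start, " available; truncating")
    last <- length(files) - 1
  }
  sel <- files[(start + 1):(last + 1)]
  if (length(sel) < 2)
    stop("fewer than 2 frames available at start = ", start)

  frame_sequence(lapply(sel, read_one_frame),
                 frame_rate = frame_rate, metric_scale = metric_scale)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Convert pixel coordinates to metric space
#'
#' Component-wise scaling by the meters-per-pixel calibration factor.
#' `metric_to_pixels()` is the exact inverse.
#'
#' @param point Numeric vector `c(x, y)` in pixels, or a two-column matrix.
#' @param metric_scale Meters per pixel (> 0).
#' @return Coordinates in meters, same shape as the input.
#' @examples
#' pixels_to_metric(c(100, 50), 0.001)  # (0.1, 0.05) m
#' @export
pixels_to_metric <- function(point, metric_scale) {
  if (is.null(metric_scale) || !is.numeric(metric_scale))
    stop("metric_scale missing: supply the meters-per-pixel calibration ",
         "of the recording (config key `metric_scale`)")
  if (metric_scale <= 0) stop("metric_scale must be > 0")
  point * metric_scale
}

#' @rdname pixels_to_metric
#' @export
metric_to_pixels <- function(point, metric_scale) {
  if (is.null(metric_scale) || !is.numeric(metric_scale) || metric_scale <= 0)
    stop("metric_scale must be a positive number")
  point / metric_scale
}
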