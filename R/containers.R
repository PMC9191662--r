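#' Calibrated image time series
#'
#' A `frame_stack` holds a T x H x W intensity array together with the
#' acquisition calibration needed to convert pixel displacements into
#' physical velocities: the frame rate in Hz and the lateral pixel size in
#' micrometres per pixel.
#'
#' @param data numeric array with dimensions `c(T, H, W)` (frames, rows,
#'   columns). Rows are the slow galvo axis; columns run along the
#'   line-illumination (fast) axis.
#' @param frame_rate frames per second (Hz), positive.
#' @param pixel_size micrometres per pixel, positive.
#' @param origin free-text acquisition label.
#' @return an object of class `frame_stack`.
#' @export
frame_stack <- function(data, frame_rate, pixel_size, origin = "unknown") {
  data <- as.array(data)
  stopifnot(length(dim(data)) == 3, dim(data)[1] >= 1,
            is.numeric(frame_rate), frame_rate > 0,
            is.numeric(pixel_size), pixel_size > 0)
  structure(list(data = data, frame_rate = frame_rate,
                 pixel_size = pixel_size, origin = origin),
            class = "frame_stack")
}

#' @export
print.frame_stack <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("frame_stack: %d frames of %d x %d px, %.6g Hz, %.4g um/px (%s)\n",
              d[1], d[2], d[3], x$frame_rate, x$pixel_size, x$origin))
  invisible(x)
}

#' @export
dim.frame_stack <- function(x) dim(x$data)

#' Space-time kymograph
#'
#' A kymograph is a 2D image whose rows are successive line samples in time
#' and whose columns are positions along the sampled line. Moving cells
#' appear as slanted streaks; the streak slope in px/line encodes velocity.
#' The row = time, column = space orientation is fixed throughout the
#' package; readers and writers convert explicitly.
#'
#' @param data numeric matrix, rows = time, columns = space.
#' @param line_rate line sampling rate in Hz.
#' @param pixel_size micrometres per column.
#' @return an object of class `kymograph`.
#' @export
kymograph <- function(data, line_rate, pixel_size) {
  data <- as.matrix(data)
  stopifnot(is.numeric(line_rate), line_rate > 0,
            is.numeric(pixel_size), pixel_size > 0)
  structure(list(data = data, line_rate = line_rate, pixel_size = pixel_size),
            class = "kymograph")
}

#' @export
print.kymograph <- function(x, ...) {
  cat(sprintf("kymograph: %d lines x %d px, %.6g Hz, %.4g um/px (%.4g ms)\n",
              nrow(x$data), ncol(x$data), x$line_rate, x$pixel_size,
              1000 * nrow(x$data) / x$line_rate))
  invisible(x)
}

#' @export
dim.kymograph <- function(x) dim(x$data)

#' Cross-sectional space-time image
#'
#' Intensity sampled along a short line placed perpendicular to a vessel
#' axis, one row per frame. Red blood cells crossing the line appear as dark
#' blobs; the space-summed trace feeds flux counting at bifurcations.
#'
#' @param data numeric matrix, rows = time (frames), columns = position.
#' @param frame_rate frames per second (Hz).
#' @param pixel_size micrometres per column.
#' @param geometry optional list describing the sampling line.
#' @export
cross_section_image <- function(data, frame_rate, pixel_size, geometry = NULL) {
  data <- as.matrix(data)
  stopifnot(ncol(data) >= 3, frame_rate > 0, pixel_size > 0)
  structure(list(data = data, frame_rate = frame_rate,
                 pixel_size = pixel_size, geometry = geometry),
            class = "cross_section_image")
}

#' Polyline region of interest
#'
#' Ordered vertices in pixel coordinates (1-based, row 1 / column 1 at the
#' top-left, `x` = column, `y` = row). ROI CSV files on disk use the 0-based
#' convention of common annotation tools; [read_roi_csv()] and
#' [write_roi_csv()] convert.
#'
#' @param x,y vertex coordinates in pixels (equal length, at least 2).
#' @param spacing default resampling spacing in pixels.
#' @export
polyline_roi <- function(x, y, spacing = 1) {
  stopifnot(length(x) == length(y), length(x) >= 2,
            all(is.finite(x)), all(is.finite(y)), spacing > 0)
  structure(list(x = as.numeric(x), y = as.numeric(y), spacing = spacing),
            class = "polyline_roi")
}

#' Resample a polyline at uniform arc-length spacing
#'
#' @param roi a [polyline_roi()].
#' @param spacing sample spacing in pixels (defaults to the ROI's own).
#' @return data.frame with columns `x`, `y`, `s` (arc length, px); adjacent
#'   samples are exactly `spacing` apart.
#' @export
resample_polyline <- function(roi, spacing = roi$spacing) {
  seg <- sqrt(diff(roi$x)^2 + diff(roi$y)^2)
  cum <- c(0, cumsum(seg))
  total <- cum[length(cum)]
  if (total <= 0) stop("polyline has zero length")
  s <- seq(0, total, by = spacing)
  x <- stats::approx(cum, roi$x, xout = s)$y
  y <- stats::approx(cum, roi$y, xout = s)$y
  data.frame(x = x, y = y, s = s)
}

#' Read / write polyline ROI vertices as CSV
#'
#' File format: header `x_px,y_px`, 0-based pixel coordinates with the
#' origin at the top-left. In memory the package uses 1-based coordinates.
#'
#' @param path CSV file path.
#' @param spacing resampling spacing attached to the returned ROI.
#' @return [read_roi_csv()] returns a [polyline_roi()].
#' @export
read_roi_csv <- function(path, spacing = 1) {
  d <- utils::read.csv(path)
  stopifnot(all(c("x_px", "y_px") %in% names(d)))
  polyline_roi(d$x_px + 1, d$y_px + 1, spacing = spacing)
}

#' @rdname read_roi_csv
#' @param roi a [polyline_roi()] to write.
#' @export
write_roi_csv <- function(roi, path) {
  utils::write.csv(data.frame(x_px = roi$x - 1, y_px = roi$y - 1),
                   path, row.names = FALSE)
  invisible(path)
}

#' Signed velocity time series
#'
#' @param time time stamps in seconds, strictly increasing.
#' @param velocity signed velocity in mm/s (`NA` where the estimator flagged
#'   the window as unreliable or out of range).
#' @param quality per-sample quality score (peak correlation for PIV).
#' @param window_ms,stride_ms windowing metadata in milliseconds.
#' @export
velocity_trace <- function(time, velocity, quality = rep(NA_real_, length(time)),
                           window_ms = NA_real_, stride_ms = NA_real_) {
  stopifnot(length(time) == length(velocity), !is.unsorted(time, strictly = TRUE))
  structure(list(time = as.numeric(time), velocity = as.numeric(velocity),
                 quality = as.numeric(quality),
                 window_ms = window_ms, stride_ms = stride_ms),
            class = "velocity_trace")
}

#' @export
print.velocity_trace <- function(x, ...) {
  cat(sprintf("velocity_trace: %d samples over %.4g s, mean %.3g mm/s (%d NA)\n",
              length(x$time), diff(range(x$time)),
              mean(x$velocity, na.rm = TRUE), sum(is.na(x$velocity))))
  invisible(x)
}

#' @rdname velocity_trace
#' @param x a `velocity_trace`.
#' @param path CSV destination (`time_s,velocity_mm_s,quality`).
#' @export
write_velocity_csv <- function(x, path) {
  utils::write.csv(data.frame(time_s = x$time, velocity_mm_s = x$velocity,
                              quality = x$quality),
                   path, row.names = FALSE)
  invisible(path)
}
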