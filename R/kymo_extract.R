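# Kymograph and cross-section extraction from frame stacks along polyline
# regions of interest.

sample_stack_along <- function(s, roi, spacing, band_width) {
  pts <- resample_polyline(roi, spacing = spacing)
  if (nrow(pts) < 3) stop("ROI yields fewer than 3 samples; draw a longer line")
  n_frames <- dim(s$data)[1]
  # optional band averaging: sample parallel offset lines perpendicular to
  # the local tangent and average
  offsets <- if (band_width > 1) {
    seq(-(band_width - 1) / 2, (band_width - 1) / 2)
  } else 0
  tx <- c(diff(pts$x), 0); ty <- c(diff(pts$y), 0)
  tx[length(tx)] <- tx[length(tx) - 1]; ty[length(ty)] <- ty[length(ty) - 1]
  tn <- sqrt(tx^2 + ty^2); tx <- tx / tn; ty <- ty / tn
  out <- matrix(0, n_frames, nrow(pts))
  for (f in seq_len(n_frames)) {
    img <- s$data[f, , ]
    acc <- 0
    for (o in offsets) {
      acc <- acc + bilinear_sample(img, pts$y + o * tx, pts$x - o * ty)
    }
    out[f, ] <- acc / length(offsets)
  }
  list(data = out, pts = pts)
}

#' Extract a kymograph along a vessel-axis polyline
#'
#' The polyline is resampled at uniform arc-length spacing (default 1 px);
#' for every frame the image is sampled by bilinear interpolation at each
#' point, producing one kymograph row per frame. The kymograph inherits
#' `line_rate = frame_rate` and `pixel_size = spacing * stack pixel size`.
#' Reversing the vertex order reverses the space axis and hence flips the
#' sign of every downstream velocity.
#'
#' @param s a [frame_stack()].
#' @param roi a [polyline_roi()] running along the vessel.
#' @param spacing arc-length sample spacing in pixels.
#' @param band_width odd integer; when > 1, intensities are averaged over a
#'   band of this many pixels perpendicular to the line.
#' @return a [kymograph()].
#' @export
extract_kymograph <- function(s, roi, spacing = 1, band_width = 1) {
  stopifnot(inherits(s, "frame_stack"), inherits(roi, "polyline_roi"))
  res <- sample_stack_along(s, roi, spacing, band_width)
  kymograph(res$data, line_rate = s$frame_rate,
            pixel_size = spacing * s$pixel_size)
}

#' Extract a cross-sectional space-time image
#'
#' Samples the stack along a short line placed perpendicular to a
#' capillary, one row per frame; cells crossing the line show as dark
#' blobs. The space-summed trace of the result is the input to
#' bifurcation flux counting.
#'
#' @inheritParams extract_kymograph
#' @param line a [polyline_roi()] crossing the vessel.
#' @return a [cross_section_image()].
#' @export
extract_cross_section <- function(s, line, spacing = 1, band_width = 1) {
  stopifnot(inherits(s, "frame_stack"), inherits(line, "polyline_roi"))
  res <- sample_stack_along(s, line, spacing, band_width)
  cross_section_image(res$data, frame_rate = s$frame_rate,
                      pixel_size = spacing * s$pixel_size,
                      geometry = res$pts)
}
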