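# Reading/writing calibrated TIFF stacks and the preprocessing steps that
# precede any velocimetry: line-illumination gain normalization, temporal
# binning, and rigid motion registration.

stack_sidecar <- function(path) paste0(path, ".yaml")

# tiff stores 32-bit float samples in [0, 1]; scale by an exact power of
# two so the rescaling is lossless in floating point.
tiff_scale <- function(mx) {
  if (!is.finite(mx) || mx <= 1) 1 else 2^ceiling(log2(mx))
}

#' Write / read a frame stack as multi-page 32-bit float TIFF
#'
#' Calibration metadata (frame rate, pixel size, origin) and the intensity
#' scale factor travel in a YAML sidecar next to the TIFF
#' (`<path>.yaml`). On read, explicit `frame_rate` / `pixel_size` arguments
#' override the sidecar; without either source the read fails.
#'
#' @param stack a [frame_stack()].
#' @param path TIFF file path.
#' @export
write_stack <- function(stack, path) {
  stopifnot(inherits(stack, "frame_stack"))
  sc <- tiff_scale(max(stack$data))
  pages <- lapply(seq_len(dim(stack$data)[1]),
                  function(i) stack$data[i, , ] / sc)
  tiff::writeTIFF(pages, path, bits.per.sample = 32L, compression = "none")
  yaml::write_yaml(list(frame_rate_hz = stack$frame_rate,
                        pixel_size_um = stack$pixel_size,
                        origin = stack$origin,
                        intensity_scale = sc,
                        frame_interval_s = 1 / stack$frame_rate),
                   stack_sidecar(path))
  invisible(path)
}

#' @rdname write_stack
#' @param frame_rate,pixel_size metadata overrides (Hz, um/px).
#' @export
read_stack <- function(path, frame_rate = NULL, pixel_size = NULL) {
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  meta <- if (file.exists(stack_sidecar(path))) {
    yaml::read_yaml(stack_sidecar(path))
  } else list()
  frame_rate <- frame_rate %||% meta$frame_rate_hz
  pixel_size <- pixel_size %||% meta$pixel_size_um
  if (is.null(frame_rate) || is.null(pixel_size)) {
    stop("frame rate / pixel size not found in sidecar and not supplied")
  }
  sc <- meta$intensity_scale %||% 1
  arr <- array(0, dim = c(length(pages), nrow(pages[[1]]), ncol(pages[[1]])))
  for (i in seq_along(pages)) arr[i, , ] <- pages[[i]] * sc
  frame_stack(arr, frame_rate, pixel_size, origin = meta$origin %||% path)
}

#' Write / read a kymograph (TIFF or CSV by extension)
#'
#' Rows are time, columns are space, in both formats; the YAML sidecar
#' carries `line_rate_hz` and `pixel_size_um`.
#'
#' @param k a [kymograph()].
#' @param path destination (`.tif`/`.tiff` or `.csv`).
#' @export
write_kymograph <- function(k, path) {
  stopifnot(inherits(k, "kymograph"))
  if (grepl("\\.csv$", path, ignore.case = TRUE)) {
    utils::write.table(k$data, path, sep = ",", row.names = FALSE,
                       col.names = FALSE)
    sc <- 1
  } else {
    sc <- tiff_scale(max(k$data))
    tiff::writeTIFF(k$data / sc, path, bits.per.sample = 32L,
                    compression = "none")
  }
  yaml::write_yaml(list(line_rate_hz = k$line_rate,
                        pixel_size_um = k$pixel_size,
                        intensity_scale = sc),
                   stack_sidecar(path))
  invisible(path)
}

#' @rdname write_kymograph
#' @param line_rate,pixel_size metadata overrides.
#' @export
read_kymograph <- function(path, line_rate = NULL, pixel_size = NULL) {
  meta <- if (file.exists(stack_sidecar(path))) {
    yaml::read_yaml(stack_sidecar(path))
  } else list()
  line_rate <- line_rate %||% meta$line_rate_hz
  pixel_size <- pixel_size %||% meta$pixel_size_um
  if (is.null(line_rate) || is.null(pixel_size)) {
    stop("line rate / pixel size not found in sidecar and not supplied")
  }
  data <- if (grepl("\\.csv$", path, ignore.case = TRUE)) {
    as.matrix(utils::read.table(path, sep = ","))
  } else {
    tiff::readTIFF(path) * (meta$intensity_scale %||% 1)
  }
  dimnames(data) <- NULL
  kymograph(data, line_rate, pixel_size)
}

#' Illumination gain profile
#'
#' @param gain per-position multiplicative factors (unit mean over the
#'   included positions).
#' @param excluded logical mask of positions left unnormalized.
#' @export
gain_profile <- function(gain, excluded) {
  stopifnot(length(gain) == length(excluded), all(gain[!excluded] > 0))
  structure(list(gain = gain, excluded = excluded), class = "gain_profile")
}

#' @rdname gain_profile
#' @param x a `gain_profile`; @param path CSV destination.
#' @export
write_gain_csv <- function(x, path) {
  utils::write.csv(data.frame(position = seq_along(x$gain), gain = x$gain,
                              excluded = x$excluded),
                   path, row.names = FALSE)
  invisible(path)
}

normalize_by_trace <- function(data, trace, boost_cap) {
  included <- trace > 0
  g <- rep(NA_real_, length(trace))
  g[included] <- trace[included] / mean(trace[included])
  # correction beyond the cap (dim columns) stays untouched and is flagged
  boost <- 1 / g
  excl <- !included | (boost > boost_cap)
  g[excl] <- 1
  out <- data
  keep <- which(!excl)
  out[, keep] <- sweep(data[, keep, drop = FALSE], 2, g[keep], `/`)
  list(data = out, gain = gain_profile(g, excl))
}

#' Normalize line-illumination gain of a kymograph
#'
#' The per-column gain is estimated from the kymograph itself by summing
#' along the time dimension; each column is divided by its gain (rescaled
#' to unit mean over the included columns so the overall brightness scale
#' is preserved). Columns that would be boosted by more than `boost_cap`
#' (dim edge pixels) are excluded: they keep their original values and are
#' flagged in the returned profile. A second application is an exact no-op
#' on the included columns.
#'
#' @param k a [kymograph()] with nonnegative intensities.
#' @param boost_cap maximal allowed correction factor (default 5).
#' @return `list(kymograph, gain)` with `gain` a [gain_profile()].
#' @export
normalize_kymograph <- function(k, boost_cap = 5) {
  stopifnot(inherits(k, "kymograph"), all(k$data >= 0))
  res <- normalize_by_trace(k$data, colSums(k$data), boost_cap)
  list(kymograph = kymograph(res$data, k$line_rate, k$pixel_size),
       gain = res$gain)
}

#' Normalize line-illumination gain of a frame stack
#'
#' The gain along the line-illumination axis (frame columns) is estimated
#' from the time-averaged image: rows are ranked by their summed
#' brightness, the `n_lines` brightest rows are summed along the slow axis,
#' and the resulting per-column trace (unit mean over included columns)
#' divides every row of every frame. The `boost_cap` exclusion rule of
#' [normalize_kymograph()] applies.
#'
#' @param s a [frame_stack()] with at least 2 frames.
#' @param n_lines number of brightest rows used for the estimate.
#' @param boost_cap maximal allowed correction factor.
#' @return `list(stack, gain)`.
#' @export
normalize_stack <- function(s, n_lines = 10, boost_cap = 5) {
  stopifnot(inherits(s, "frame_stack"), dim(s$data)[1] >= 2)
  avg <- apply(s$data, c(2, 3), mean)
  if (nrow(avg) < n_lines) {
    warning("fewer rows than n_lines; using all rows")
    n_lines <- nrow(avg)
  }
  top <- order(rowSums(avg), decreasing = TRUE)[seq_len(n_lines)]
  trace <- colSums(avg[top, , drop = FALSE])
  res <- normalize_by_trace(matrix(0, 1, length(trace)), trace, boost_cap)
  g <- res$gain
  out <- s$data
  keep <- which(!g$excluded)
  for (f in seq_len(dim(out)[1])) {
    out[f, , keep] <- sweep(s$data[f, , keep, drop = FALSE][1, , ], 2,
                            g$gain[keep], `/`)
  }
  list(stack = frame_stack(out, s$frame_rate, s$pixel_size, s$origin),
       gain = g)
}

#' Temporal binning
#'
#' Non-overlapping mean of `factor` consecutive frames (or kymograph
#' lines); a trailing remainder shorter than `factor` is dropped and the
#' rate is divided by `factor`.
#'
#' @param x a [frame_stack()] or [kymograph()].
#' @param factor integer >= 1.
#' @export
bin_time <- function(x, factor) UseMethod("bin_time")

#' @export
bin_time.frame_stack <- function(x, factor) {
  factor <- as.integer(factor)
  stopifnot(factor >= 1)
  n <- dim(x$data)[1]
  if (factor > n) stop("binning factor exceeds the number of frames")
  if (factor == 1) return(x)
  n_out <- n %/% factor
  out <- array(0, dim = c(n_out, dim(x$data)[2], dim(x$data)[3]))
  for (i in seq_len(n_out)) {
    idx <- ((i - 1) * factor + 1):(i * factor)
    out[i, , ] <- apply(x$data[idx, , , drop = FALSE], c(2, 3), mean)
  }
  frame_stack(out, x$frame_rate / factor, x$pixel_size, x$origin)
}

#' @export
bin_time.kymograph <- function(x, factor) {
  factor <- as.integer(factor)
  stopifnot(factor >= 1)
  n <- nrow(x$data)
  if (factor > n) stop("binning factor exceeds the number of lines")
  if (factor == 1) return(x)
  n_out <- n %/% factor
  out <- matrix(0, n_out, ncol(x$data))
  for (i in seq_len(n_out)) {
    out[i, ] <- colMeans(x$data[((i - 1) * factor + 1):(i * factor), ,
                                drop = FALSE])
  }
  kymograph(out, x$line_rate / factor, x$pixel_size)
}

# Phase correlation between two images; returns the shift (dx, dy) such
# that img(y, x) ~ ref(y - dy, x - dx), with sub-pixel refinement by a
# matrix-multiply DFT upsampled around the integer peak. A Hann taper
# suppresses the spectral leakage of the non-circular boundary.
phase_correlate <- function(ref, img, upsample = 10, eps = 1e-12) {
  nr <- nrow(ref); nc <- ncol(ref)
  wr <- 0.5 - 0.5 * cos(2 * pi * (seq_len(nr) - 1) / (nr - 1))
  wc <- 0.5 - 0.5 * cos(2 * pi * (seq_len(nc) - 1) / (nc - 1))
  taper <- outer(wr, wc)
  ref <- (ref - mean(ref)) * taper
  img <- (img - mean(img)) * taper
  Fr <- stats::fft(ref); Fi <- stats::fft(img)
  R <- Fr * Conj(Fi)
  R <- R / pmax(Mod(R), eps)
  cc <- Re(stats::fft(R, inverse = TRUE)) / (nr * nc)
  pk <- which(cc == max(cc), arr.ind = TRUE)[1, ]
  peak_val <- max(cc)
  dy <- pk[1] - 1; dx <- pk[2] - 1
  if (dy > nr / 2) dy <- dy - nr
  if (dx > nc / 2) dx <- dx - nc
  # local upsampled DFT of the cross-power spectrum around (dy, dx)
  half <- 1.5
  fy <- seq(dy - half, dy + half, by = 1 / upsample)
  fx <- seq(dx - half, dx + half, by = 1 / upsample)
  ky <- c(0:(ceiling(nr / 2) - 1), -(floor(nr / 2)):-1)
  kx <- c(0:(ceiling(nc / 2) - 1), -(floor(nc / 2)):-1)
  Wy <- exp(2i * pi * outer(fy, ky) / nr)
  Wx <- exp(2i * pi * outer(kx, fx) / nc)
  cc_up <- Re(Wy %*% R %*% Wx)
  pk2 <- which(cc_up == max(cc_up), arr.ind = TRUE)[1, ]
  # the correlation of ref with conj(img) peaks at minus the displacement
  # of img relative to ref, hence the sign flip
  list(dx = -fx[pk2[2]], dy = -fy[pk2[1]], peak = peak_val)
}

#' Rigid motion registration by phase correlation
#'
#' Per-frame translation is estimated against a reference (the time-mean
#' image by default, or a chosen frame) by phase correlation with
#' sub-pixel refinement via an upsampled local discrete Fourier transform
#' (default factor 10). Frames are resampled by bilinear interpolation
#' with replicate padding. Frames whose correlation peak falls below
#' `min_peak` (featureless frames) receive zero shift with a warning.
#'
#' @param s a [frame_stack()] with at least 2 frames.
#' @param reference `"mean"` or an integer frame index.
#' @param upsample sub-pixel refinement factor.
#' @param min_peak phase-correlation peak threshold below which a frame is
#'   declared featureless.
#' @return `list(stack, shifts)` with `shifts` a data.frame
#'   `(frame, dx_px, dy_px, peak)` of the *estimated motion* of each frame
#'   (the correction applied is its negative).
#' @export
register_rigid <- function(s, reference = "mean", upsample = 10,
                           min_peak = 0.03) {
  stopifnot(inherits(s, "frame_stack"), dim(s$data)[1] >= 2)
  n <- dim(s$data)[1]
  ref <- if (identical(reference, "mean")) {
    apply(s$data, c(2, 3), mean)
  } else {
    s$data[as.integer(reference), , ]
  }
  out <- s$data
  dx <- dy <- pk <- numeric(n)
  flat <- FALSE
  for (f in seq_len(n)) {
    frame <- s$data[f, , ]
    if (stats::sd(frame) == 0) {
      flat <- TRUE
      next
    }
    est <- phase_correlate(ref, frame, upsample = upsample)
    if (est$peak < min_peak) {
      flat <- TRUE
      next
    }
    dx[f] <- est$dx; dy[f] <- est$dy; pk[f] <- est$peak
    out[f, , ] <- shift_image(frame, -est$dx, -est$dy)
  }
  if (flat) warning("featureless frame(s): zero shift applied")
  list(stack = frame_stack(out, s$frame_rate, s$pixel_size, s$origin),
       shifts = data.frame(frame = seq_len(n), dx_px = dx, dy_px = dy,
                           peak = pk))
}

#' @rdname register_rigid
#' @param shifts the data.frame returned by `register_rigid`.
#' @param path CSV destination.
#' @export
write_shifts_csv <- function(shifts, path) {
  utils::write.csv(shifts[c("frame", "dx_px", "dy_px")], path,
                   row.names = FALSE)
  invisible(path)
}
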