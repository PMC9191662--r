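# 1D velocimetry on kymographs: windowed cross-correlation PIV (primary)
# and a Radon-style streak-angle estimator (secondary), plus the sampling
# bound on measurable speed.

#' Maximum measurable flow speed
#'
#' A kymograph needs at least two samples of each cell, so the displacement
#' between consecutive lines can be at most half the length of the sampled
#' array: `v_max = f * h / 2`.
#'
#' @param sampling_rate line or frame sampling rate `f`, Hz.
#' @param array_length length `h` of the sampled focal array, micrometres.
#' @return the bound in mm/s.
#' @examples
#' max_measurable_speed(1000, 50)  # 25 mm/s
#' max_measurable_speed(1e6, 50)   # 25000 mm/s = 25 m/s
#' @export
max_measurable_speed <- function(sampling_rate, array_length) {
  stopifnot(sampling_rate > 0, array_length >= 0)
  sampling_rate * array_length / 2 / 1000
}

#' PIV configuration
#'
#' @param window_ms correlation window length, milliseconds.
#' @param stride_ms window advance, milliseconds (must not exceed the
#'   window length). A 2-ms window advanced by 0.2 ms yields 5 velocity
#'   estimates per millisecond.
#' @param line_lag number of lines between the members of each correlated
#'   pair.
#' @param subpixel `"parabolic"` (3-point fit) or `"centroid"`.
#' @param min_quality windows whose mean peak correlation falls below this
#'   are reported as `NA`.
#' @export
piv_config <- function(window_ms = 2, stride_ms = 0.2, line_lag = 1,
                       subpixel = c("parabolic", "centroid"),
                       min_quality = 0.25) {
  subpixel <- match.arg(subpixel)
  stopifnot(window_ms > 0, stride_ms > 0, stride_ms <= window_ms,
            line_lag >= 1)
  structure(list(window_ms = window_ms, stride_ms = stride_ms,
                 line_lag = as.integer(line_lag), subpixel = subpixel,
                 min_quality = min_quality),
            class = "piv_config")
}

# Average normalized cross-correlation over the line pairs of one window.
# A is the earlier lines, B the lines `lag` later; returns the correlation
# curve over integer displacements -dmax..dmax (positive displacement =
# motion toward increasing column index).
window_correlation <- function(A, B, dmax) {
  X <- ncol(A)
  norm_rows <- function(M) {
    mu <- rowMeans(M)
    sd <- sqrt(rowMeans((M - mu)^2))
    keep <- sd > 0
    list(M = (M - mu) / ifelse(sd > 0, sd, 1), keep = keep)
  }
  a <- norm_rows(A); b <- norm_rows(B)
  keep <- a$keep & b$keep
  if (!any(keep)) return(NULL)
  A <- a$M[keep, , drop = FALSE]; B <- b$M[keep, , drop = FALSE]
  ds <- -dmax:dmax
  cc <- vapply(ds, function(d) {
    if (d >= 0) {
      ia <- seq_len(X - d); ib <- ia + d
    } else {
      ib <- seq_len(X + d); ia <- ib - d
    }
    mean(rowSums(A[, ia, drop = FALSE] * B[, ib, drop = FALSE])) / length(ia)
  }, numeric(1))
  list(d = ds, cc = cc)
}

subpixel_peak <- function(d, cc, method) {
  i <- which.max(cc)
  if (i == 1 || i == length(cc)) return(list(d = d[i], edge = TRUE, q = cc[i]))
  if (method == "parabolic") {
    y0 <- cc[i - 1]; y1 <- cc[i]; y2 <- cc[i + 1]
    den <- y0 - 2 * y1 + y2
    frac <- if (den < 0) 0.5 * (y0 - y2) / den else 0
    list(d = d[i] + max(-0.5, min(0.5, frac)), edge = FALSE, q = y1)
  } else {
    w <- cc[(i - 1):(i + 1)] - min(cc[(i - 1):(i + 1)])
    list(d = sum(d[(i - 1):(i + 1)] * w) / sum(w), edge = FALSE, q = cc[i])
  }
}

#' Signed RBC velocity from a kymograph by windowed cross-correlation PIV
#'
#' For every window of `window_ms` lines, each line is cross-correlated
#' (after per-line mean removal and unit-variance normalization) with the
#' line `line_lag` lines later; the correlation curves are averaged over
#' the window and the displacement is the sub-pixel-refined argmax.
#' Velocity is `d * pixel_size * line_rate / line_lag` (converted to
#' mm/s), positive toward increasing column index. Windows whose peak sits
#' at the search boundary are reported as `NA` (out of range, not
#' clipped); featureless windows and windows below `min_quality` are
#' `NA` as well.
#'
#' @param k a [kymograph()].
#' @param cfg a [piv_config()].
#' @param mask optional logical vector flagging columns to exclude from
#'   correlation (e.g. columns excluded by gain normalization).
#' @return a [velocity_trace()]; time stamps are window centres.
#' @export
piv_velocity <- function(k, cfg = piv_config(), mask = NULL) {
  stopifnot(inherits(k, "kymograph"))
  data <- k$data
  if (!is.null(mask)) data <- data[, !mask, drop = FALSE]
  n <- nrow(data); X <- ncol(data)
  lw <- max(round(cfg$window_ms / 1000 * k$line_rate), cfg$line_lag + 1)
  stride <- max(round(cfg$stride_ms / 1000 * k$line_rate), 1)
  if (lw < 2 * cfg$line_lag) stop("window shorter than 2 * line_lag lines")
  if (n < lw + cfg$line_lag) stop("kymograph shorter than one window")
  starts <- seq(1, n - lw - cfg$line_lag + 1, by = stride)
  dmax <- floor(X / 2)
  time <- velocity <- quality <- numeric(length(starts))
  for (w in seq_along(starts)) {
    rows <- starts[w]:(starts[w] + lw - 1)
    A <- data[rows, , drop = FALSE]
    B <- data[rows + cfg$line_lag, , drop = FALSE]
    time[w] <- (starts[w] + (lw - 1) / 2 - 0.5) / k$line_rate
    corr <- window_correlation(A, B, dmax)
    if (is.null(corr)) {
      velocity[w] <- NA; quality[w] <- NA
      next
    }
    pk <- subpixel_peak(corr$d, corr$cc, cfg$subpixel)
    quality[w] <- pk$q
    if (pk$edge || pk$q < cfg$min_quality) {
      velocity[w] <- NA
    } else {
      velocity[w] <- pk$d * k$pixel_size * k$line_rate / cfg$line_lag / 1000
    }
  }
  velocity_trace(time, velocity, quality,
                 window_ms = cfg$window_ms, stride_ms = cfg$stride_ms)
}

#' Streak-angle velocity estimate (Radon-style)
#'
#' Projects the mean-removed window along candidate streak directions and
#' takes the direction whose projection profile has maximal variance —
#' equivalent to maximizing the variance of a Radon sinogram column. The
#' direction is parameterized by the angle from the time axis, so the
#' streak slope is `tan(angle)` px/line and
#' `v = tan(angle) * pixel_size * line_rate`; a coarse angular grid is
#' refined once around the optimum. Windows with no dominant direction
#' (best-to-median variance ratio below `min_anisotropy`) return `NA`.
#'
#' @param k a [kymograph()] (or window thereof) at least 16 x 16 px.
#' @param max_angle largest |angle| from the time axis, degrees (< 90).
#' @param coarse_step coarse angular step, degrees.
#' @param min_anisotropy required ratio of best to median profile variance.
#' @return signed velocity in mm/s, or `NA`.
#' @export
radon_velocity <- function(k, max_angle = 88, coarse_step = 0.5,
                           min_anisotropy = 8) {
  stopifnot(inherits(k, "kymograph"), max_angle < 90)
  img <- k$data
  if (nrow(img) < 16 || ncol(img) < 16) stop("window must be at least 16 x 16")
  img <- img - mean(img)
  n_t <- nrow(img); n_x <- ncol(img)
  jj <- rep(seq_len(n_t), n_x)   # time index of each pixel
  xx <- rep(seq_len(n_x), each = n_t)
  vals <- as.vector(img)
  # support-weighted variance of the projection profile, normalized by the
  # bin count so that featureless noise scores flat across angles:
  # weighting by occupancy stops sparse edge bins from dominating, and for
  # pure noise the weighted variance grows like n_bins / n_pixels, which
  # the normalization removes.
  prof_var <- function(slope) {
    c0 <- xx - slope * jj
    bins <- floor(c0 - min(c0)) + 1L
    s <- rowsum(vals, bins, reorder = FALSE)
    n <- tabulate(bins)
    n <- n[n > 0]
    m <- s / n
    mw <- sum(s) / sum(n)
    (sum(n * (m - mw)^2) / sum(n)) * (sum(n) / length(n))
  }
  eval_grid <- function(angles) {
    vapply(tan(angles * pi / 180), prof_var, numeric(1))
  }
  angles <- seq(-max_angle, max_angle, by = coarse_step)
  v1 <- eval_grid(angles)
  if (max(v1) < min_anisotropy * stats::median(v1)) return(NA_real_)
  best <- angles[which.max(v1)]
  fine <- seq(best - coarse_step, best + coarse_step, length.out = 41)
  fine <- fine[abs(fine) < 90]
  v2 <- eval_grid(fine)
  tan(fine[which.max(v2)] * pi / 180) * k$pixel_size * k$line_rate / 1000
}
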