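# Spectral structure of velocity traces: cardiac fundamental and
# harmonics, the pulsatility index, and correlation of velocity
# fluctuations across vessels.

#' Amplitude spectrum of a velocity trace with harmonic detection
#'
#' The trace is resampled onto a uniform grid (linear interpolation over
#' any gaps; the interpolated fraction is reported), mean-removed,
#' optionally linearly detrended, optionally Hann-windowed, and Fourier
#' transformed. Amplitudes are normalized so that the squared one-sided
#' amplitudes sum to the (window-weighted) signal variance (a Parseval
#' convention). The cardiac fundamental is the largest peak inside
#' `search_band` (default 5-15 Hz, the awake-mouse heart-rate range);
#' harmonic order k is declared detected when the local spectral amplitude
#' around `k * f0` exceeds `floor_factor` times the median amplitude in a
#' surrounding neighbourhood.
#'
#' @param trace a [velocity_trace()].
#' @param detrend subtract a linear trend before transforming.
#' @param window `"hann"` or `"none"`.
#' @param search_band numeric length-2, fundamental search band in Hz.
#' @param max_harmonic highest harmonic order tested.
#' @param floor_factor detection threshold over the local median floor.
#' @return a `spectrum_result` list: `frequency`, `amplitude`, `f0`,
#'   `harmonics` (detected orders), `band_widths_hz` (half-prominence
#'   width per detected order), `interpolated_fraction`.
#' @export
velocity_spectrum <- function(trace, detrend = TRUE,
                              window = c("hann", "none"),
                              search_band = c(5, 15), max_harmonic = 10,
                              floor_factor = 3) {
  window <- match.arg(window)
  stopifnot(inherits(trace, "velocity_trace"))
  t <- trace$time; v <- trace$velocity
  dt <- stats::median(diff(t))
  if (diff(range(t)) < 5 / search_band[1]) {
    stop("record shorter than 5 expected cardiac cycles")
  }
  grid <- seq(t[1], t[length(t)], by = dt)
  ok <- is.finite(v)
  vi <- stats::approx(t[ok], v[ok], xout = grid, rule = 2)$y
  interp_frac <- 1 - sum(ok) / length(grid)
  n <- length(vi)
  x <- vi - mean(vi)
  if (detrend) x <- stats::residuals(stats::lm(x ~ seq_len(n)))
  w <- if (window == "hann") {
    0.5 - 0.5 * cos(2 * pi * seq_len(n) / (n + 1))
  } else rep(1, n)
  X <- stats::fft(x * w)
  # one-sided, energy-preserving: sum(amp^2) == sum((x w)^2) / sum(w^2)
  nf <- floor(n / 2) + 1
  amp2 <- Mod(X[seq_len(nf)])^2 / (n * sum(w^2))
  dbl <- rep(2, nf); dbl[1] <- 1; if (n %% 2 == 0) dbl[nf] <- 1
  amp <- sqrt(amp2 * dbl)
  freq <- (seq_len(nf) - 1) / (n * dt)

  in_band <- freq >= search_band[1] & freq <= search_band[2]
  if (!any(in_band)) stop("no frequency bins inside the search band")
  f0 <- freq[in_band][which.max(amp[in_band])]
  df <- freq[2] - freq[1]

  harmonics <- integer(0); widths <- numeric(0)
  for (k in seq_len(max_harmonic)) {
    fk <- k * f0
    if (fk > max(freq)) break
    band <- which(abs(freq - fk) <= max(2 * df, 0.05 * f0))
    neigh <- which(abs(freq - fk) <= max(20 * df, 0.5 * f0) & freq > 0)
    floor_amp <- stats::median(amp[setdiff(neigh, band)])
    pk <- max(amp[band])
    if (is.finite(floor_amp) && pk > floor_factor * floor_amp) {
      harmonics <- c(harmonics, k)
      half <- floor_amp + (pk - floor_amp) / 2
      above <- band[amp[band] >= half]
      widths <- c(widths, (max(above) - min(above) + 1) * df)
    }
  }
  structure(list(frequency = freq, amplitude = amp, f0 = f0,
                 harmonics = harmonics, band_widths_hz = widths,
                 interpolated_fraction = interp_frac,
                 window = window),
            class = "spectrum_result")
}

#' @export
print.spectrum_result <- function(x, ...) {
  cat(sprintf("spectrum_result: f0 = %.3g Hz, harmonics detected: %s\n",
              x$f0, if (length(x$harmonics))
                paste(x$harmonics, collapse = ", ") else "none"))
  invisible(x)
}

# FFT band-pass (zero phase by construction): keep bins within
# [f0/2, 3 f0/2].
bandpass_fft <- function(x, dt, f0) {
  n <- length(x)
  X <- stats::fft(x - mean(x))
  freq <- (seq_len(n) - 1) / (n * dt)
  freq <- pmin(freq, 1 / dt - freq)  # mirrored positive frequency
  keep <- freq >= f0 / 2 & freq <= 1.5 * f0
  X[!keep] <- 0
  Re(stats::fft(X, inverse = TRUE)) / n
}

#' Pulsatility index of a velocity trace
#'
#' Cardiac cycles are segmented at successive peaks of the trace
#' band-passed around the fundamental `f0`; within each complete cycle the
#' index is `(V_peak_systolic - V_min_diastolic) / V_mean`, and the
#' returned PI is the mean over cycles. For
#' `v(t) = v0 (1 + m sin(2 pi f0 t))` the index is exactly `2 m`; it is
#' invariant to rescaling the trace.
#'
#' @param trace a [velocity_trace()] with uniform sampling.
#' @param f0 cardiac fundamental, Hz (e.g. from [velocity_spectrum()]).
#' @return a `pulsatility_result` list: `pi` (mean index), `cycles`
#'   (per-cycle data.frame with `t_start`, `t_end`, `v_peak`, `v_min`,
#'   `v_mean`, `pi`).
#' @export
pulsatility_index <- function(trace, f0) {
  stopifnot(inherits(trace, "velocity_trace"), f0 > 0)
  v <- trace$velocity; t <- trace$time
  ok <- is.finite(v)
  v <- v[ok]; t <- t[ok]
  dt <- stats::median(diff(t))
  if (stats::sd(v) == 0) {
    return(structure(list(pi = 0, cycles = data.frame()),
                     class = "pulsatility_result"))
  }
  bp <- bandpass_fft(v, dt, f0)
  min_sep <- max(1, floor(0.6 / (f0 * dt)))
  pk <- find_peaks(bp, min_prominence = 0.1 * stats::sd(bp) * 2,
                   min_separation = min_sep)
  if (length(pk) < 4) stop("fewer than 3 complete cardiac cycles")
  cyc <- lapply(seq_len(length(pk) - 1), function(i) {
    idx <- pk[i]:(pk[i + 1] - 1)
    seg <- v[idx]
    data.frame(t_start = t[pk[i]], t_end = t[pk[i + 1]],
               v_peak = max(seg), v_min = min(seg), v_mean = mean(seg),
               pi = (max(seg) - min(seg)) / mean(seg))
  })
  cyc <- do.call(rbind, cyc)
  structure(list(pi = mean(cyc$pi), cycles = cyc),
            class = "pulsatility_result")
}

#' @export
print.pulsatility_result <- function(x, ...) {
  cat(sprintf("pulsatility_result: PI = %.4g over %d cycles\n",
              x$pi, nrow(x$cycles)))
  invisible(x)
}

#' Pairwise Pearson correlation of velocity fluctuations
#'
#' Traces are resampled onto the coarsest common uniform grid and their
#' mean-removed fluctuations correlated pairwise. Zero-variance traces get
#' `NA` rows/columns. The result is symmetric with unit diagonal.
#'
#' @param traces list of [velocity_trace()] objects.
#' @return matrix of Pearson coefficients.
#' @export
correlation_matrix <- function(traces) {
  stopifnot(is.list(traces), length(traces) >= 2)
  t0 <- max(vapply(traces, function(x) min(x$time), numeric(1)))
  t1 <- min(vapply(traces, function(x) max(x$time), numeric(1)))
  dt <- max(vapply(traces, function(x) stats::median(diff(x$time)),
                   numeric(1)))
  grid <- seq(t0, t1, by = dt)
  M <- vapply(traces, function(x) {
    ok <- is.finite(x$velocity)
    stats::approx(x$time[ok], x$velocity[ok], xout = grid, rule = 2)$y
  }, numeric(length(grid)))
  sds <- apply(M, 2, stats::sd)
  cc <- suppressWarnings(stats::cor(M))
  cc[sds == 0, ] <- NA; cc[, sds == 0] <- NA
  diag(cc) <- 1
  cc
}
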