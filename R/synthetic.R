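# Synthetic blood-flow imaging: kymographs, vessel videos and
# penetrating-vessel transit traces with exact ground truth.
#
# The generators emulate two-photon imaging of dextran-labelled plasma:
# unlabelled red blood cells (RBCs) are dark occluders moving through a
# bright background. Cells are rendered with error-function edges so that
# sub-pixel displacement changes the image smoothly, which is what makes
# sub-pixel velocimetry testable. Photon (Poisson) noise is applied per
# pixel on the count scale, with optional additive Gaussian read noise.

#' Specification of a synthetic single-vessel kymograph
#'
#' @param line_rate line sampling rate, Hz.
#' @param pixel_size micrometres per pixel along the line.
#' @param line_length length of the sampled line, micrometres.
#' @param duration record duration, seconds.
#' @param velocity_fn function of time (s) returning signed velocity in
#'   mm/s; evaluated at every line time, must be finite.
#' @param rbc_linear_density mean cell density along the vessel, cells/mm.
#' @param rbc_length cell extent along the flow axis, micrometres.
#' @param contrast fractional intensity drop inside a cell, in (0, 1].
#' @param background_level plasma photon count per pixel.
#' @param edge_softness error-function edge width of the rendered cells,
#'   micrometres.
#' @param noise_model `"none"`, `"poisson"`, or
#'   `list(type = "poisson+gaussian", sd = <counts>)`.
#' @param seed integer RNG seed; identical spec + seed gives bit-identical
#'   output.
#' @param max_pixels guard against accidentally huge renders.
#' @return a `sim_kymograph_spec` list.
#' @export
sim_kymograph_spec <- function(line_rate = 1000, pixel_size = 0.5,
                               line_length = 50, duration = 1,
                               velocity_fn = function(t) rep(2, length(t)),
                               rbc_linear_density = 100, rbc_length = 6,
                               contrast = 0.6, background_level = 100,
                               edge_softness = 0.5,
                               noise_model = "none", seed = 1,
                               max_pixels = 5e7) {
  stopifnot(line_rate > 0, pixel_size > 0, line_length > 0, duration > 0,
            contrast > 0, contrast <= 1, rbc_linear_density >= 0,
            rbc_length > 0, background_level >= 0, edge_softness > 0)
  structure(list(line_rate = line_rate, pixel_size = pixel_size,
                 line_length = line_length, duration = duration,
                 velocity_fn = velocity_fn,
                 rbc_linear_density = rbc_linear_density,
                 rbc_length = rbc_length, contrast = contrast,
                 background_level = background_level,
                 edge_softness = edge_softness, noise_model = noise_model,
                 seed = seed, max_pixels = max_pixels),
            class = "sim_kymograph_spec")
}

apply_noise <- function(img, noise_model) {
  if (identical(noise_model, "none") || is.null(noise_model)) return(img)
  if (identical(noise_model, "poisson")) {
    return(array(stats::rpois(length(img), pmax(img, 0)), dim = dim(img)))
  }
  if (is.list(noise_model) && identical(noise_model$type, "poisson+gaussian")) {
    out <- stats::rpois(length(img), pmax(img, 0)) +
      stats::rnorm(length(img), sd = noise_model$sd)
    return(array(out, dim = dim(img)))
  }
  stop("unknown noise_model")
}

# Occlusion profile of one cell along a periodic axis: an erf-edged boxcar
# of physical length `len` centred at `centre`, evaluated at positions `x`
# (all micrometres), with period `period` so cells wrap smoothly.
cell_occlusion_1d <- function(x, centre, len, soft, period) {
  occ <- 0
  for (shift in c(-period, 0, period)) {
    d <- x - (centre + shift)
    occ <- occ + 0.5 * (erf((d + len / 2) / (sqrt(2) * soft)) -
                          erf((d - len / 2) / (sqrt(2) * soft)))
  }
  occ
}

#' Simulate a single-file-flow kymograph with ground truth
#'
#' Renders dark RBC streaks advected through bright plasma along a periodic
#' vessel segment. The streak slope in px/line equals
#' `v * 1000 / (pixel_size * line_rate)` for `v` in mm/s. Noise, if any, is
#' applied last; the returned ground truth stores exact trajectories, the
#' velocity sampled at line times, and the mean lumen occlusion fraction
#' (so that `mean(image) == background * (1 - contrast * occlusion)` holds
#' exactly on the noiseless path).
#'
#' @param spec a [sim_kymograph_spec()].
#' @return `list(kymograph = <kymograph>, truth = <list>)`.
#' @export
simulate_kymograph <- function(spec) {
  stopifnot(inherits(spec, "sim_kymograph_spec"))
  n_lines <- round(spec$duration * spec$line_rate)
  n_px <- round(spec$line_length / spec$pixel_size)
  if (n_lines * n_px > spec$max_pixels) {
    stop("requested kymograph exceeds max_pixels cap")
  }
  t <- (seq_len(n_lines) - 1) / spec$line_rate
  v <- spec$velocity_fn(t)
  if (length(v) == 1) v <- rep(v, n_lines)
  if (any(!is.finite(v))) stop("velocity_fn returned non-finite values")
  # left-Riemann displacement in micrometres (mm/s * s * 1000)
  disp <- c(0, cumsum(v[-n_lines] / spec$line_rate)) * 1000
  x_px <- (seq_len(n_px) - 0.5) * spec$pixel_size

  with_seed(spec$seed, {
    n_rbc <- max(0L, round(spec$rbc_linear_density * spec$line_length / 1000))
    x0 <- if (n_rbc > 0) stats::runif(n_rbc, 0, spec$line_length) else numeric(0)
    occ <- matrix(0, n_lines, n_px)
    for (i in seq_len(n_rbc)) {
      centres <- (x0[i] + disp) %% spec$line_length
      occ <- occ + t(vapply(centres, function(c0) {
        cell_occlusion_1d(x_px, c0, spec$rbc_length, spec$edge_softness,
                          spec$line_length)
      }, numeric(n_px)))
    }
    occ <- pmin(occ, 1)
    clean <- spec$background_level * (1 - spec$contrast * occ)
    img <- apply_noise(clean, spec$noise_model)
  })

  truth <- list(
    time = t, velocity_mm_s = v,
    trajectories = if (n_rbc > 0) {
      data.frame(cell = rep(seq_len(n_rbc), each = n_lines),
                 time = rep(t, n_rbc),
                 position_um = as.vector(vapply(
                   seq_len(n_rbc),
                   function(i) (x0[i] + disp) %% spec$line_length,
                   numeric(n_lines))))
    } else data.frame(cell = integer(0), time = numeric(0),
                      position_um = numeric(0)),
    occlusion_fraction = mean(occ),
    spec = spec
  )
  list(kymograph = kymograph(img, spec$line_rate, spec$pixel_size),
       truth = truth)
}

#' Specification of a synthetic vessel video
#'
#' Defines a straight (or gently polygonal) vessel segment of radius `R`
#' carrying cells whose axial speed follows the blunted-parabola law
#' `V(r) = v_max * (1 - (1 - beta) * |(r - r0)/R|^B)` modulated in time by a
#' cardiac fundamental plus harmonics,
#' `m(t) = 1 + sum_k depths[k] * sin(2 pi k f0 t)`.
#'
#' @param frame_rate frames per second, Hz.
#' @param pixel_size micrometres per pixel.
#' @param fov `c(H, W)` frame size in pixels.
#' @param vessel_axis [polyline_roi()] of the centreline (defaults to a
#'   horizontal line through the frame centre).
#' @param lumen_radius vessel radius `R`, micrometres.
#' @param profile list with `v_max` (mm/s), `B` (>0), `beta` in `[0,1]`,
#'   `r0` (µm, `|r0| < R`).
#' @param pulsatility list with `f0` (Hz) and `depths` (modulation depth per
#'   harmonic order); `NULL` for steady flow.
#' @param n_rbc number of cells in the segment.
#' @param rbc_radius cell radius, micrometres. When `2 * rbc_radius >=
#'   2 * lumen_radius` the flow is single file and all cells sit on the
#'   centreline offset `r0`.
#' @param duration seconds.
#' @param motion_trace `T x 2` matrix of per-frame rigid shifts `(dx, dy)`
#'   in pixels, or `NULL` for a still preparation.
#' @param faced_gain per-column multiplicative illumination gain (length
#'   `W`, strictly positive), or `NULL` for uniform illumination. The
#'   line-illumination array runs along frame columns.
#' @param background plasma photon count inside the lumen.
#' @param background_out photon count outside the vessel.
#' @param contrast fractional drop inside a cell, in (0, 1].
#' @param edge_softness erf edge width of cells and vessel wall, µm.
#' @param noise_model as in [sim_kymograph_spec()].
#' @param seed integer seed.
#' @export
sim_vessel_spec <- function(frame_rate = 1000, pixel_size = 0.5,
                            fov = c(40, 120), vessel_axis = NULL,
                            lumen_radius = 5,
                            profile = list(v_max = 5, B = 2, beta = 0.1, r0 = 0),
                            pulsatility = NULL,
                            n_rbc = 30, rbc_radius = 2.5, duration = 0.5,
                            motion_trace = NULL, faced_gain = NULL,
                            background = 100, background_out = 5,
                            contrast = 0.7, edge_softness = 0.75,
                            noise_model = "none", seed = 1) {
  stopifnot(frame_rate > 0, pixel_size > 0, length(fov) == 2,
            lumen_radius > 0, profile$B > 0,
            profile$beta >= 0, profile$beta <= 1,
            abs(profile$r0) < lumen_radius,
            n_rbc >= 0, rbc_radius > 0, duration > 0,
            contrast > 0, contrast <= 1)
  if (is.null(vessel_axis)) {
    vessel_axis <- polyline_roi(c(1, fov[2]), rep((fov[1] + 1) / 2, 2))
  }
  if (!is.null(faced_gain)) {
    stopifnot(length(faced_gain) == fov[2], all(faced_gain > 0))
  }
  structure(list(frame_rate = frame_rate, pixel_size = pixel_size,
                 fov = as.integer(fov), vessel_axis = vessel_axis,
                 lumen_radius = lumen_radius, profile = profile,
                 pulsatility = pulsatility, n_rbc = n_rbc,
                 rbc_radius = rbc_radius, duration = duration,
                 motion_trace = motion_trace, faced_gain = faced_gain,
                 background = background, background_out = background_out,
                 contrast = contrast, edge_softness = edge_softness,
                 noise_model = noise_model, seed = seed),
            class = "sim_vessel_spec")
}

#' Blunted-parabola velocity law
#'
#' `V(r) = v_max * (1 - (1 - beta) * |(r - r0) / R|^B)`. `B` is the
#' bluntness exponent (2 = Poiseuille parabola, large B = plug flow), `beta`
#' the extrapolated wall-speed fraction, `r0` the profile asymmetry offset.
#'
#' @param r radial position(s), micrometres.
#' @param v_max centreline velocity, mm/s.
#' @param R lumen radius, micrometres.
#' @param B bluntness exponent, > 0.
#' @param beta wall-speed fraction in `[0, 1]`.
#' @param r0 asymmetry offset, micrometres.
#' @export
blunted_parabola <- function(r, v_max, R, B, beta = 0, r0 = 0) {
  v_max * (1 - (1 - beta) * abs((r - r0) / R)^B)
}

#' Simulate a vessel video with ground truth
#'
#' Cells are seeded uniformly over the lumen (arc position uniform along
#' the rendered segment, radial offset uniform across the open chord) and
#' advected at the blunted-parabola speed of their own radial offset times
#' the shared pulsatile modulation. Cells leaving the downstream end
#' re-enter upstream (periodic segment) so density is stationary. The
#' rendering order is: scene, whole-frame rigid shift, per-column
#' illumination gain, then noise.
#'
#' @param spec a [sim_vessel_spec()].
#' @return `list(stack = <frame_stack>, truth = <list>)`; the truth carries
#'   per-cell trajectories (arc position and radial offset), the per-frame
#'   modulation, the analytic mean velocity map (mm/s) on the pixel grid,
#'   the motion trace, and the gain profile.
#' @export
simulate_vessel_video <- function(spec) {
  stopifnot(inherits(spec, "sim_vessel_spec"))
  H <- spec$fov[1]; W <- spec$fov[2]
  n_frames <- round(spec$duration * spec$frame_rate)
  ax <- resample_polyline(spec$vessel_axis, spacing = 0.5)
  if (any(ax$x < 1 | ax$x > W | ax$y < 1 | ax$y > H)) {
    stop("vessel axis leaves the field of view")
  }
  seg_len_um <- max(ax$s) * spec$pixel_size
  R <- spec$lumen_radius
  prof <- spec$profile
  single_file <- 2 * spec$rbc_radius >= 2 * R

  t <- (seq_len(n_frames) - 1) / spec$frame_rate
  mod <- rep(1, n_frames)
  if (!is.null(spec$pulsatility)) {
    for (k in seq_along(spec$pulsatility$depths)) {
      mod <- mod + spec$pulsatility$depths[k] *
        sin(2 * pi * k * spec$pulsatility$f0 * t)
    }
  }

  # distance-to-axis map (µm) on the pixel grid, and arc position map
  gx <- matrix(rep(seq_len(W), each = H), H, W)
  gy <- matrix(rep(seq_len(H), W), H, W)
  d2 <- matrix(Inf, H, W); arc <- matrix(0, H, W)
  for (i in seq_len(nrow(ax))) {
    di <- (gx - ax$x[i])^2 + (gy - ax$y[i])^2
    upd <- di < d2
    d2[upd] <- di[upd]; arc[upd] <- ax$s[i]
  }
  dist_um <- sqrt(d2) * spec$pixel_size
  lumen_soft <- 0.5 * erfc((dist_um - R) / (sqrt(2) * spec$edge_softness))
  base <- spec$background_out + (spec$background - spec$background_out) * lumen_soft

  # signed radial offset: positive on the left of the axis direction
  dir_end <- nrow(ax)
  ux <- (ax$x[dir_end] - ax$x[1]); uy <- (ax$y[dir_end] - ax$y[1])
  nrm <- sqrt(ux^2 + uy^2); ux <- ux / nrm; uy <- uy / nrm
  nxv <- -uy; nyv <- ux

  with_seed(spec$seed, {
    n <- spec$n_rbc
    s0 <- if (n > 0) stats::runif(n, 0, seg_len_um) else numeric(0)
    half_open <- max(R - spec$rbc_radius, 0.05 * R)
    r_off <- if (single_file) rep(prof$r0, n) else
      stats::runif(n, -half_open, half_open)
    v_r <- blunted_parabola(r_off, prof$v_max, R, prof$B, prof$beta, prof$r0)
    # arc displacement (µm): per-frame cumulated modulation shared by all
    cum_mod <- c(0, cumsum(mod[-n_frames] / spec$frame_rate)) * 1000
    frames <- array(0, dim = c(n_frames, H, W))
    traj_s <- matrix(0, n_frames, max(n, 1))
    soft_px <- spec$edge_softness / spec$pixel_size
    rad_px <- spec$rbc_radius / spec$pixel_size
    win <- ceiling(rad_px + 4 * soft_px)
    for (f in seq_len(n_frames)) {
      occ <- matrix(0, H, W)
      if (n > 0) {
        s_now <- (s0 + v_r * cum_mod[f]) %% seg_len_um
        traj_s[f, seq_len(n)] <- s_now
        # map arc position to xy along the (resampled) axis
        idx <- pmin(pmax(round(s_now / (0.5 * spec$pixel_size)) + 1, 1), nrow(ax))
        cx <- ax$x[idx] + nxv * r_off / spec$pixel_size
        cy <- ax$y[idx] + nyv * r_off / spec$pixel_size
        for (i in seq_len(n)) {
          c0 <- max(1L, floor(cx[i] - win)); c1 <- min(W, ceiling(cx[i] + win))
          r0i <- max(1L, floor(cy[i] - win)); r1 <- min(H, ceiling(cy[i] + win))
          if (c0 > c1 || r0i > r1) next
          px <- seq.int(c0, c1); py <- seq.int(r0i, r1)
          rho <- sqrt(outer((py - cy[i])^2, (px - cx[i])^2, "+")) *
            spec$pixel_size
          occ[py, px] <- occ[py, px] +
            0.5 * erfc((rho - spec$rbc_radius) / (sqrt(2) * spec$edge_softness))
        }
        occ <- pmin(occ, 1)
      }
      img <- base * (1 - spec$contrast * occ * lumen_soft)
      if (!is.null(spec$motion_trace)) {
        img <- shift_image(img, spec$motion_trace[f, 1], spec$motion_trace[f, 2])
      }
      if (!is.null(spec$faced_gain)) {
        img <- sweep(img, 2, spec$faced_gain, `*`)
      }
      frames[f, , ] <- img
    }
    frames <- apply_noise(frames, spec$noise_model)
  })

  vel_map <- blunted_parabola(
    ifelse(dist_um <= R, dist_um, NA), prof$v_max, R, prof$B, prof$beta, prof$r0)
  truth <- list(
    time = t, modulation = mod,
    trajectories = list(arc_um = traj_s, radial_um = r_off,
                        speed_mm_s = if (spec$n_rbc > 0) v_r else numeric(0)),
    mean_velocity_map = vel_map * mean(mod),
    motion_trace = spec$motion_trace,
    gain = spec$faced_gain %||% rep(1, W),
    lumen_radius = R, diameter_um = 2 * R,
    axis = ax, spec = spec
  )
  list(stack = frame_stack(frames, spec$frame_rate, spec$pixel_size,
                           origin = "simulation"),
       truth = truth)
}

#' Specification of a penetrating-vessel fluorescence trace
#'
#' Cross-sections of vessels oriented along the optical axis show
#' transitory fluorescence dips as each unlabeled cell crosses the focal
#' plane. Each dip is rendered as a negative Gaussian of width
#' `transit_sigma` (so both its falling and rising edges are Gaussian
#' edges of that width), arriving as a Poisson process of rate `mean_flux`.
#'
#' @param frame_rate sampling rate, Hz.
#' @param mean_flux Poisson arrival rate, cells/s.
#' @param transit_sigma per-edge Gaussian width, milliseconds.
#' @param dip_depth fractional dip depth in (0, 1].
#' @param baseline plasma fluorescence level, counts.
#' @param duration seconds.
#' @param event_times optional fixed event times (s) overriding the Poisson
#'   draw (used to build coupled bifurcation branches).
#' @param noise_model as in [sim_kymograph_spec()].
#' @param seed integer seed.
#' @export
sim_penetrating_spec <- function(frame_rate = 1000, mean_flux = 20,
                                 transit_sigma = 2, dip_depth = 0.6,
                                 baseline = 100, duration = 10,
                                 event_times = NULL,
                                 noise_model = "none", seed = 1) {
  stopifnot(frame_rate > 0, mean_flux >= 0, transit_sigma > 0,
            dip_depth > 0, dip_depth <= 1, baseline > 0, duration > 0)
  structure(list(frame_rate = frame_rate, mean_flux = mean_flux,
                 transit_sigma = transit_sigma, dip_depth = dip_depth,
                 baseline = baseline, duration = duration,
                 event_times = event_times,
                 noise_model = noise_model, seed = seed),
            class = "sim_penetrating_spec")
}

#' Simulate a penetrating-vessel fluorescence trace
#'
#' @param spec a [sim_penetrating_spec()].
#' @return `list(trace, time, truth)` where `truth$event_times` holds the
#'   exact (strictly increasing) transit times in seconds.
#' @export
simulate_penetrating_trace <- function(spec) {
  stopifnot(inherits(spec, "sim_penetrating_spec"))
  n <- round(spec$duration * spec$frame_rate)
  t <- (seq_len(n) - 0.5) / spec$frame_rate
  sig_s <- spec$transit_sigma / 1000
  if (spec$mean_flux > 0 && 1 / spec$mean_flux < 4 * sig_s) {
    warning("expected inter-event gap below 4 * transit_sigma; ",
            "overlapping transits likely to merge")
  }
  with_seed(spec$seed, {
    ev <- spec$event_times
    if (is.null(ev)) {
      n_ev <- stats::rpois(1, spec$mean_flux * spec$duration)
      ev <- sort(stats::runif(n_ev, 0, spec$duration))
    } else {
      ev <- sort(ev)
    }
    trace <- rep(spec$baseline, n)
    for (e in ev) {
      trace <- trace - spec$baseline * spec$dip_depth *
        exp(-(t - e)^2 / (2 * sig_s^2))
    }
    trace <- pmax(trace, 0)
    trace <- as.numeric(apply_noise(matrix(trace, 1), spec$noise_model))
  })
  list(trace = trace, time = t,
       truth = list(event_times = ev, spec = spec))
}

#' Virtual-source arithmetic of a mirror-pair line-illumination module
#'
#' A beam with input convergence angle `delta_theta` entering a nearly
#' parallel mirror pair with misalignment angle `alpha` and separation `S`
#' is split into `N = delta_theta / alpha` sub-pulses (rounded down) with
#' interpulse delay `2 S / c`.
#'
#' @param delta_theta input convergence angle, degrees.
#' @param alpha mirror misalignment angle, degrees; must satisfy
#'   `0 < alpha < delta_theta`.
#' @param S mirror separation, millimetres.
#' @return list with `n_foci` (integer count) and `delay_ns` (interpulse
#'   delay, nanoseconds, 3 significant figures, using c = 2.998e8 m/s).
#' @export
faced_geometry <- function(delta_theta, alpha, S) {
  stopifnot(alpha > 0, S > 0)
  if (alpha >= delta_theta) stop("alpha must be smaller than delta_theta")
  n_foci <- as.integer(floor(delta_theta / alpha + 1e-9))
  delay_ns <- signif(2 * (S / 1000) / 2.998e8 * 1e9, 3)
  list(n_foci = n_foci, delay_ns = delay_ns)
}
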