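# The simulators are first-class code: every downstream stage is validated
# against their ground truth, so their own contracts get tested hardest.

test_that("kymograph streak slope matches the velocity law", {
  # constant 1 mm/s at 0.5 um/px and 1 kHz advects 2 px per line
  spec <- sim_kymograph_spec(line_rate = 1000, pixel_size = 0.5,
                             line_length = 40, duration = 0.05,
                             velocity_fn = function(t) rep(1, length(t)),
                             rbc_linear_density = 50, seed = 1)
  sim <- simulate_kymograph(spec)
  pos <- sim$truth$trajectories$position_um[sim$truth$trajectories$cell == 1]
  step_px <- diff(pos)[1] / spec$pixel_size
  expect_equal(step_px, 2, tolerance = 1e-12)

  # zero velocity freezes the streaks: every line identical
  spec0 <- sim_kymograph_spec(velocity_fn = function(t) rep(0, length(t)),
                              duration = 0.05, seed = 2)
  sim0 <- simulate_kymograph(spec0)
  expect_equal(max(apply(sim0$kymograph$data, 2, stats::sd)), 0)
})

test_that("identical spec and seed give bit-identical output", {
  spec <- sim_kymograph_spec(duration = 0.05, noise_model = "poisson",
                             seed = 7)
  expect_identical(simulate_kymograph(spec)$kymograph$data,
                   simulate_kymograph(spec)$kymograph$data)
  vspec <- sim_vessel_spec(duration = 0.01, noise_model = "poisson",
                           seed = 7)
  expect_identical(simulate_vessel_video(vspec)$stack$data,
                   simulate_vessel_video(vspec)$stack$data)
  pspec <- sim_penetrating_spec(duration = 1, noise_model = "poisson",
                                seed = 7)
  expect_identical(simulate_penetrating_trace(pspec)$trace,
                   simulate_penetrating_trace(pspec)$trace)
})

test_that("photon conservation holds exactly on the noiseless path", {
  for (seed in 1:3) {
    spec <- sim_kymograph_spec(duration = 0.05, contrast = 0.6,
                               background_level = 120, seed = seed)
    sim <- simulate_kymograph(spec)
    expect_equal(mean(sim$kymograph$data),
                 spec$background_level *
                   (1 - spec$contrast * sim$truth$occlusion_fraction),
                 tolerance = 1e-9)
  }
})

test_that("advection is consistent with the integral of the velocity law", {
  vfun <- function(t) 2 * (1 + 0.5 * sin(2 * pi * 10 * t))
  spec <- sim_kymograph_spec(line_rate = 2000, pixel_size = 0.5,
                             line_length = 60, duration = 0.3,
                             velocity_fn = vfun, seed = 3)
  sim <- simulate_kymograph(spec)
  traj <- sim$truth$trajectories
  p <- traj$position_um[traj$cell == 1]
  t <- traj$time[traj$cell == 1]
  # unwrap periodic jumps before comparing to the integral
  disp <- cumsum(c(0, ifelse(abs(diff(p)) > spec$line_length / 2,
                             diff(p) - sign(diff(p)) * spec$line_length,
                             diff(p))))
  integral <- 1000 * vapply(t, function(ti) {
    stats::integrate(vfun, 0, ti)$value
  }, numeric(1))
  # one sub-pixel rendering step at this line rate
  expect_lt(max(abs(disp - integral)), 1000 * max(vfun(t)) / spec$line_rate)
})

test_that("pulsatile truth shows its spectral peak at the driving frequency", {
  vfun <- function(t) 2 * (1 + 0.5 * sin(2 * pi * 10 * t))
  spec <- sim_kymograph_spec(line_rate = 1000, duration = 2,
                             velocity_fn = vfun, seed = 4)
  sim <- simulate_kymograph(spec)
  v <- sim$truth$velocity_mm_s - mean(sim$truth$velocity_mm_s)
  amp <- Mod(stats::fft(v))[seq_len(length(v) / 2)]
  f <- (seq_along(amp) - 1) / spec$duration
  expect_equal(f[which.max(amp)], 10, tolerance = 1e-9)
})

test_that("simulator rejects invalid inputs", {
  expect_error(sim_kymograph_spec(contrast = 0), "contrast")
  bad <- sim_kymograph_spec(velocity_fn = function(t) rep(NaN, length(t)),
                            duration = 0.01)
  expect_error(simulate_kymograph(bad), "non-finite")
  huge <- sim_kymograph_spec(duration = 1e5)
  expect_error(simulate_kymograph(huge), "max_pixels")
  expect_error(sim_vessel_spec(profile = list(v_max = 5, B = 2, beta = 0,
                                              r0 = 6), lumen_radius = 5))
  expect_error(sim_vessel_spec(faced_gain = rep(-1, 120)))
})

test_that("empty lumen renders gain-shaded background only", {
  gain <- 0.6 + 0.4 * sin(seq(0, pi, length.out = 120))^2
  spec <- sim_vessel_spec(n_rbc = 0, duration = 0.005, faced_gain = gain,
                          seed = 5)
  sim <- simulate_vessel_video(spec)
  # frames identical over time and carrying the per-column gain
  expect_equal(max(apply(sim$stack$data, c(2, 3), stats::sd)), 0)
  f1 <- sim$stack$data[1, , ]
  expect_equal(f1, sweep(f1 / rep(gain, each = nrow(f1)), 2, gain, `*`))
})

test_that("single-file mode puts all cells on the centreline offset", {
  spec <- sim_vessel_spec(lumen_radius = 3, rbc_radius = 3.2,
                          profile = list(v_max = 2, B = 2, beta = 0,
                                         r0 = 0.5),
                          n_rbc = 5, duration = 0.005, seed = 6)
  sim <- simulate_vessel_video(spec)
  expect_true(all(sim$truth$trajectories$radial_um == 0.5))
})

test_that("penetrating trace truth matches its rendering", {
  spec <- sim_penetrating_spec(mean_flux = 0, duration = 1, seed = 1)
  sim <- simulate_penetrating_trace(spec)
  expect_equal(stats::sd(sim$trace), 0)
  expect_length(sim$truth$event_times, 0)

  ev <- separated_events(50, 10, 0.004, seed = 2)
  spec2 <- sim_penetrating_spec(mean_flux = 50, transit_sigma = 2,
                                duration = 10, event_times = ev, seed = 2)
  sim2 <- suppressWarnings(simulate_penetrating_trace(spec2))
  expect_identical(sim2$truth$event_times, sort(ev))
  expect_true(!is.unsorted(sim2$truth$event_times, strictly = TRUE))
  # crowding warning
  expect_warning(simulate_penetrating_trace(
    sim_penetrating_spec(mean_flux = 300, transit_sigma = 2, duration = 1)),
    "4 \\* transit_sigma")
})

test_that("virtual-source arithmetic is exact closed form", {
  g <- faced_geometry(1, 0.0125, 300)
  expect_identical(g$n_foci, 80L)
  expect_equal(g$delay_ns, 2.0)
  expect_equal(faced_geometry(1, 0.0188, 225)$delay_ns, 1.5)
  expect_equal(faced_geometry(1, 0.0125, 150)$delay_ns, 1.0)
  # oracle: direct formula evaluation on a parameter grid
  for (dt in c(0.5, 1, 2)) for (a in c(0.01, 0.0125, 0.05)) {
    expect_identical(faced_geometry(dt, a, 100)$n_foci,
                     as.integer(floor(dt / a + 1e-9)))
  }
  expect_error(faced_geometry(1, 1.5, 300), "smaller")
  expect_error(faced_geometry(1, -0.1, 300))
})
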