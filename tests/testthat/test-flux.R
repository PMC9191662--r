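test_that("well-separated transits are counted exactly", {
  ev <- separated_events(50, 10, 0.004, seed = 61)
  spec <- sim_penetrating_spec(frame_rate = 1000, mean_flux = 50,
                               transit_sigma = 2, duration = 10,
                               event_times = ev, seed = 61)
  sim <- suppressWarnings(simulate_penetrating_trace(spec))
  res <- count_rbc_events(sim$trace, 1000)
  expect_equal(length(res$event_times), length(ev))
  expect_equal(res$flux, 50)
  # detected times within 2 frames of the truth
  expect_lt(max(abs(res$event_times - sim$truth$event_times)), 0.002)
})

test_that("zero flux and flat traces yield zero events", {
  sim <- simulate_penetrating_trace(
    sim_penetrating_spec(mean_flux = 0, duration = 2, seed = 62))
  expect_equal(count_rbc_events(sim$trace, 1000)$flux, 0)
  expect_equal(count_rbc_events(rep(7, 100), 1000)$flux, 0)
})

test_that("event counts are invariant to intensity scaling and offsets", {
  ev <- separated_events(20, 5, 0.01, seed = 63)
  sim <- simulate_penetrating_trace(
    sim_penetrating_spec(mean_flux = 20, duration = 5, event_times = ev,
                         seed = 63))
  n0 <- length(count_rbc_events(sim$trace, 1000)$event_times)
  n1 <- length(count_rbc_events(3.7 * sim$trace + 55, 1000)$event_times)
  expect_equal(n1, n0)
})

test_that("temporal binning undercounts high-flux traces monotonically", {
  spec <- sim_penetrating_spec(frame_rate = 2000, mean_flux = 100,
                               transit_sigma = 0.7, duration = 5,
                               dip_depth = 0.6, seed = 64)
  sim <- suppressWarnings(simulate_penetrating_trace(spec))
  prom <- 0.25 * 100 * 0.6  # fixed depth-based threshold across rates
  counts <- vapply(c(1, 2, 4, 8), function(bf) {
    tb <- hemokymo:::bin_vector(sim$trace, bf)
    length(count_rbc_events(tb, 2000 / bf, min_prominence = prom,
                            min_separation = 2)$event_times)
  }, numeric(1))
  expect_true(all(diff(counts) <= 0))
  expect_lt(counts[4], 0.6 * counts[1])
  expect_lte(counts[1], length(sim$truth$event_times))
})

test_that("Gaussian edges give the 1.687 sigma half-time", {
  spec <- sim_penetrating_spec(frame_rate = 5000, mean_flux = 0,
                               transit_sigma = 2, duration = 1,
                               event_times = 0.5, seed = 65)
  sim <- simulate_penetrating_trace(spec)
  ev <- count_rbc_events(sim$trace, 5000)
  fit <- fit_half_time(sim$trace, ev$event_index[1], 5000)
  expect_rel_error(fit$half_time_ms, 1.687 * 2, 0.02)
  # symmetric dip: rising and falling edges agree
  expect_rel_error(fit$falling_ms, fit$rising_ms, 0.02)
})

test_that("fitted half-time is linear in transit sigma with slope 1.687", {
  sigmas <- c(0.5, 1, 2, 4, 8)
  ht <- vapply(sigmas, function(s) {
    spec <- sim_penetrating_spec(frame_rate = 5000, mean_flux = 0,
                                 transit_sigma = s, duration = 1,
                                 event_times = 0.5, seed = 66)
    sim <- simulate_penetrating_trace(spec)
    ev <- count_rbc_events(sim$trace, 5000)
    fit_half_time(sim$trace, ev$event_index[1], 5000)$half_time_ms
  }, numeric(1))
  slope <- unname(stats::coef(stats::lm(ht ~ sigmas))[2])
  expect_lt(abs(slope - 1.687), 0.05)
})

test_that("half-time inverts to velocity with the cell length scale", {
  expect_equal(velocity_from_half_time(6, 6), 1)
  expect_equal(velocity_from_half_time(15, 6), 0.4)
  expect_equal(velocity_from_half_time(1e9), 6e-9)  # -> 0 in the limit
  expect_error(velocity_from_half_time(-1))
})

test_that("bifurcation flux is conserved and partitioned correctly", {
  set.seed(67)
  parent_ev <- separated_events(20, 20, 0.008, seed = 67)
  to_a <- stats::runif(length(parent_ev)) < 0.6
  mk <- function(ev, seed) {
    spec <- sim_penetrating_spec(frame_rate = 1000, mean_flux = 20,
                                 transit_sigma = 1.5, duration = 20,
                                 event_times = ev, seed = seed)
    sim <- suppressWarnings(simulate_penetrating_trace(spec))
    trace_to_cross_section(sim$trace, 1000)
  }
  res <- bifurcation_flux(list(parent = mk(parent_ev, 1),
                               a = mk(parent_ev[to_a], 2),
                               b = mk(parent_ev[!to_a], 3)))
  expect_lt(res$conservation_error, 0.02)
  expect_equal(unname(res$partition[1]), mean(to_a), tolerance = 0.05)
  # 50/50 split
  to_a2 <- seq_along(parent_ev) %% 2 == 0
  res2 <- bifurcation_flux(list(mk(parent_ev, 1), mk(parent_ev[to_a2], 2),
                                mk(parent_ev[!to_a2], 3)))
  expect_equal(unname(res2$partition[1]), 0.5, tolerance = 0.05)
})

test_that("a plasma channel daughter carries zero flux", {
  parent_ev <- separated_events(15, 10, 0.01, seed = 68)
  mk <- function(ev) {
    spec <- sim_penetrating_spec(frame_rate = 1000, mean_flux = 15,
                                 transit_sigma = 1.5, duration = 10,
                                 event_times = ev, seed = 1)
    trace_to_cross_section(
      suppressWarnings(simulate_penetrating_trace(spec))$trace, 1000)
  }
  res <- bifurcation_flux(list(mk(parent_ev), mk(parent_ev),
                               mk(numeric(0))))
  expect_equal(unname(res$daughter_flux[2]), 0)
  expect_lt(res$conservation_error, 0.02)
})

# multifile line-scan image: each transit is a roughly round dark blob at
# a fixed lateral position, as for flow through the focal plane
multifile_image <- function(n_events, duration, line_rate, width_px,
                            sigma_t_ms, sigma_x_px, seed) {
  set.seed(seed)
  n_lines <- round(duration * line_rate)
  t_ms <- (seq_len(n_lines) - 0.5) / line_rate * 1000
  # jittered lattice keeps events separable (truth stays countable)
  grid_t <- seq(1, duration * 1000 - 1, length.out = ceiling(n_events / 8))
  grid_x <- seq(5, width_px - 4, length.out = 8)
  ev <- expand.grid(t = grid_t, x = grid_x)[seq_len(n_events), ]
  ev$t <- ev$t + stats::runif(n_events, -2, 2)
  ev$x <- ev$x + stats::runif(n_events, -1.5, 1.5)
  img <- matrix(100, n_lines, width_px)
  for (i in seq_len(n_events)) {
    img <- img - 60 * exp(-outer((t_ms - ev$t[i])^2 / (2 * sigma_t_ms^2),
                                 (seq_len(width_px) - ev$x[i])^2 /
                                   (2 * sigma_x_px^2), "+"))
  }
  list(kymo = kymograph(pmax(img, 0), line_rate, 0.5), events = ev)
}

test_that("multifile flux counting finds separable transits within 5 percent", {
  mf <- multifile_image(n_events = 480, duration = 0.5, line_rate = 1e5,
                        width_px = 64, sigma_t_ms = 0.45, sigma_x_px = 1.5,
                        seed = 69)
  res <- multifile_line_flux(mf$kymo, bin_factor = 50, neighborhood = 3)
  expect_lt(abs(nrow(res$events) - 480) / 480, 0.05)
  # fragmentation probe: binning below the roundness point cannot shrink
  # the count
  res_frag <- multifile_line_flux(mf$kymo, bin_factor = 25, neighborhood = 3)
  expect_gte(nrow(res_frag$events), nrow(res$events) * 0.95)
  # empty line scan
  empty <- kymograph(matrix(100, 5000, 64), 1e5, 0.5)
  expect_equal(multifile_line_flux(empty, bin_factor = 50)$flux, 0)
  expect_error(multifile_line_flux(mf$kymo, bin_factor = 50,
                                   neighborhood = 200), "larger")
})
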