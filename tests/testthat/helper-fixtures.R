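# Shared fixtures, all generated in code. Expensive simulations are cached
# so several test files can reuse them.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, force(expr), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

# smooth random texture with enough gradient structure for matching
textured_frame <- function(n = 20, m = n, seed = 1, smooth = 3) {
  set.seed(seed)
  hemokymo:::box_filter(matrix(runif(n * m), n, m), smooth)
}

# well-separated transit times: jittered regular grid, so every event is
# resolvable and detection should be exact
separated_events <- function(rate, duration, jitter, seed = 1) {
  set.seed(seed)
  n <- round(rate * duration)
  seq(duration / (2 * n), duration - duration / (2 * n), length.out = n) +
    stats::runif(n, -jitter, jitter)
}

# cross-section image whose space-summed trace equals `trace`
trace_to_cross_section <- function(trace, frame_rate) {
  w <- c(0.1, 0.2, 0.4, 0.2, 0.1)
  cross_section_image(outer(trace, w), frame_rate, pixel_size = 0.5)
}

# the shared narrow-cell Poiseuille vessel used by profile tests
poiseuille_vessel <- function() {
  cached("poiseuille_vessel", {
    spec <- sim_vessel_spec(
      frame_rate = 1000, pixel_size = 0.5, fov = c(40, 120),
      lumen_radius = 5, profile = list(v_max = 5, B = 2, beta = 0, r0 = 0),
      n_rbc = 120, rbc_radius = 0.4, edge_softness = 0.3,
      duration = 0.5, seed = 21)
    list(spec = spec, sim = simulate_vessel_video(spec))
  })
}

expect_rel_error <- function(actual, expected, tol) {
  expect_lt(max(abs(actual - expected) / abs(expected)), tol)
}
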