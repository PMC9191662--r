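tiny_cfg <- function(bp_iters = 60) {
  sift_flow_config(search_radius = 1, upsample_factor = 1, cell_size = 1,
                   grid = 2, bp_iters = bp_iters)
}

test_that("descriptors ignore additive shifts and normalize away contrast", {
  fr <- textured_frame(16, 16, seed = 51)
  d1 <- compute_descriptors(fr)$desc
  d2 <- compute_descriptors(fr + 7.3)$desc
  expect_identical(d1, d2)
  d3 <- compute_descriptors(1.5 * fr)$desc
  cosim <- rowSums(d1 * d3) /
    (sqrt(rowSums(d1^2)) * sqrt(rowSums(d3^2)) + 1e-12)
  expect_gt(min(cosim), 0.999)
  expect_true(all(d1 >= 0))
  expect_error(compute_descriptors(matrix(1, 4, 4)), "support")
})

test_that("a vertical edge concentrates energy in horizontal-gradient bins", {
  img <- cbind(matrix(0, 16, 8), matrix(1, 16, 8))
  dg <- compute_descriptors(img)
  # bins are at angles k * 45 deg; horizontal gradient = bin 1 (0 deg)
  p <- (8 - 1) * 16 + 8   # pixel at the edge (row 8, col 8), column-major
  per_bin <- rowsum(dg$desc[p, ], rep(1:8, times = 16))
  expect_equal(which.max(per_bin), 1)
})

test_that("identical frames give an exactly zero field", {
  fr <- textured_frame(12, 12, seed = 52)
  fl <- suppressWarnings(sift_flow(fr, fr, tiny_cfg()))
  expect_true(all(fl$u == 0) && all(fl$v == 0))
  # constant frames too (eta tie-break toward zero)
  flat <- suppressWarnings(sift_flow(matrix(1, 12, 12), matrix(1, 12, 12),
                                     tiny_cfg()))
  expect_true(all(flat$u == 0) && all(flat$v == 0))
})

test_that("integer translations are recovered exactly on interior pixels", {
  fr <- textured_frame(16, 16, seed = 53, smooth = 3)
  shifted <- hemokymo:::shift_image(fr, 2, -1)
  cfg <- sift_flow_config(search_radius = 3, upsample_factor = 2,
                          bp_iters = 25)
  fl <- suppressWarnings(sift_flow(fr, shifted, cfg))
  interior <- 6:11
  expect_true(all(fl$u[interior, interior] == 2))
  expect_true(all(fl$v[interior, interior] == -1))
})

test_that("BP energy matches the exhaustive DP oracle within 1 percent", {
  for (seed in 1:5) {
    set.seed(seed)
    a <- matrix(runif(36), 12, 3)
    b <- hemokymo:::shift_image(a, 1, 0) + matrix(rnorm(36, 0, 0.02), 12, 3)
    fl <- suppressWarnings(sift_flow(a, b, tiny_cfg(), return_problem = TRUE))
    exact <- flow_exact_map(fl$problem)
    expect_lte(fl$energy, exact$energy * 1.01)
    expect_gte(fl$energy, exact$energy - 1e-9)  # never below the true min
  }
})

test_that("returned energy never exceeds the zero-field energy", {
  for (seed in 6:9) {
    set.seed(seed)
    a <- matrix(runif(144), 12, 12)
    b <- matrix(runif(144), 12, 12)
    fl <- suppressWarnings(sift_flow(a, b, tiny_cfg(bp_iters = 10)))
    expect_lte(fl$energy, fl$energy_zero)
  }
})

test_that("flow is equivariant under a common shift of both frames", {
  fr <- textured_frame(18, 18, seed = 54, smooth = 3)
  b <- hemokymo:::shift_image(fr, 1, 1)
  cfg <- sift_flow_config(search_radius = 2, upsample_factor = 1,
                          bp_iters = 25)
  f1 <- suppressWarnings(sift_flow(fr, b, cfg))
  a_s <- hemokymo:::shift_image(fr, 3, 2)
  b_s <- hemokymo:::shift_image(b, 3, 2)
  f2 <- suppressWarnings(sift_flow(a_s, b_s, cfg))
  interior <- 8:13
  expect_equal(f1$u[interior, interior], f2$u[interior, interior])
  expect_equal(f1$v[interior, interior], f2$v[interior, interior])
})

# a dense-cell (hematocrit-like) pulsatile arteriole, mapped once and
# reused: dense texture is what anchors the data term against the
# smoothness prior, as in real multifile vessels
sift_vessel_maps <- function() {
  cached("sift_vessel_maps", {
    spec <- sim_vessel_spec(
      frame_rate = 1000, pixel_size = 1, fov = c(20, 48), lumen_radius = 6,
      profile = list(v_max = 3, B = 2, beta = 0.2, r0 = 0),
      pulsatility = list(f0 = 10, depths = 0.4),
      n_rbc = 130, rbc_radius = 1.2, edge_softness = 0.5,
      duration = 0.04, seed = 55)
    sim <- simulate_vessel_video(spec)
    cfg <- sift_flow_config(search_radius = 5, upsample_factor = 1,
                            bp_iters = 25)
    maps <- suppressWarnings(velocity_map_series(sim$stack, NULL, cfg))
    list(sim = sim, maps = maps)
  })
}

test_that("velocity maps resolve the blunted profile and pulsatile drive", {
  vx <- sift_vessel_maps()
  # monotone decrease from centreline to wall along the vertical radius
  prof <- rowMeans(vx$maps$mean_u[, 10:38])
  expect_true(all(diff(prof[10:5]) <= 1e-9))
  expect_true(all(diff(prof[11:16]) <= 1e-9))
  # spatially averaged lumen velocity follows the pulsatile modulation
  lum <- !is.na(vx$sim$truth$mean_velocity_map)
  vbar <- vapply(vx$maps$fields, function(f) mean(f$u[lum]), numeric(1))
  truth <- vx$sim$truth$modulation[seq_along(vbar)]
  expect_gt(stats::cor(vbar, truth), 0.9)
})

test_that("a motionless stack maps to zero inside the ROI", {
  fr <- textured_frame(16, 30, seed = 56)
  arr <- array(0, c(3, 16, 30))
  for (f in 1:3) arr[f, , ] <- fr
  s <- frame_stack(arr, 1000, 1)
  poly <- polyline_roi(c(2, 29, 29, 2), c(2, 2, 15, 15))
  maps <- suppressWarnings(velocity_map_series(
    s, poly, sift_flow_config(search_radius = 2, upsample_factor = 1,
                              bp_iters = 15)))
  expect_equal(max(abs(maps$mean_u)), 0)
  expect_equal(max(abs(maps$mean_v)), 0)
})

test_that("line extraction reports the maximal flow along the line, signed", {
  u <- matrix(3, 10, 20); v <- matrix(0, 10, 20)
  fields <- list(fields = list(list(u = u, v = v), list(u = u, v = v)),
                 time = c(0.001, 0.002))
  line <- polyline_roi(c(2, 18), c(5, 5))
  tr <- line_velocity_from_field(fields, line)
  expect_equal(tr$velocity, c(3, 3))
  # reversing the line flips the sign
  tr_rev <- line_velocity_from_field(fields,
                                     polyline_roi(c(18, 2), c(5, 5)))
  expect_equal(tr_rev$velocity, c(-3, -3))
  # zero field -> zero trace
  z <- matrix(0, 10, 20)
  fields0 <- list(fields = list(list(u = z, v = z)), time = 0.001)
  expect_equal(line_velocity_from_field(fields0, line)$velocity, 0)
  expect_error(line_velocity_from_field(fields, polyline_roi(c(2, 40),
                                                             c(5, 5))),
               "leaves")
})

test_that("line velocities from flow maps track 1D PIV across radii", {
  vx <- sift_vessel_maps()
  offsets <- seq(-4, 4, by = 1)
  v_sift <- v_piv <- numeric(length(offsets))
  for (i in seq_along(offsets)) {
    roi <- polyline_roi(c(4, 45), rep(10.5 + offsets[i], 2))
    tr_s <- line_velocity_from_field(vx$maps, roi)
    v_sift[i] <- mean(abs(tr_s$velocity))
    tr_p <- piv_velocity(extract_kymograph(vx$sim$stack, roi),
                         piv_config(window_ms = 10, stride_ms = 5))
    v_piv[i] <- mean(tr_p$velocity, na.rm = TRUE)
  }
  fit <- stats::lm(v_sift ~ v_piv)
  expect_gt(summary(fit)$r.squared, 0.85)
})
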