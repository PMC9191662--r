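test_that("stack TIFF round trip preserves data and metadata", {
  arr <- array(round(runif(3 * 8 * 10) * 4096) / 16, c(3, 8, 10))
  st <- frame_stack(arr, 500, 0.4, origin = "testcase")
  path <- withr::local_tempfile(fileext = ".tif")
  write_stack(st, path)
  st2 <- read_stack(path)
  # 32-bit TIFF samples: exact up to the writer's 32-bit quantization
  expect_equal(st2$data, arr, tolerance = 1e-8)
  expect_equal(st2$frame_rate, 500)
  expect_equal(st2$pixel_size, 0.4)
  expect_equal(dim(st2$data)[1], 3)
})

test_that("16-bit TIFF reads with supplied calibration", {
  m <- matrix(round(runif(80) * 1000) / 1000, 8, 10)
  path <- withr::local_tempfile(fileext = ".tif")
  tiff::writeTIFF(list(m, m), path, bits.per.sample = 16L)
  st <- read_stack(path, frame_rate = 100, pixel_size = 1)
  expect_equal(dim(st$data), c(2, 8, 10))
  expect_equal(st$data[1, , ], m, tolerance = 1e-4)
  # no sidecar and no overrides -> error
  expect_error(read_stack(path), "not found")
})

test_that("kymograph CSV round trip is exact", {
  k <- kymograph(matrix(round(runif(200) * 1024) / 8, 20, 10), 1e6, 0.3)
  path <- withr::local_tempfile(fileext = ".csv")
  write_kymograph(k, path)
  k2 <- read_kymograph(path)
  expect_identical(k2$data, k$data)
  expect_equal(k2$line_rate, 1e6)
})

test_that("kymograph normalization undoes a synthetic gain profile", {
  sim <- simulate_kymograph(sim_kymograph_spec(duration = 0.5, seed = 8))
  X <- ncol(sim$kymograph$data)
  g <- 0.5 + 0.5 * cos(seq(0, 2 * pi, length.out = X))^2
  shaded <- kymograph(sweep(sim$kymograph$data, 2, g, `*`), 1000, 0.5)
  res <- normalize_kymograph(shaded)
  inc <- !res$gain$excluded
  ratio <- colMeans(res$kymograph$data)[inc] /
    colMeans(sim$kymograph$data)[inc]
  expect_lt(diff(range(ratio)) / mean(ratio), 0.01)
})

test_that("uniform kymograph is left untouched with unit gain", {
  k <- kymograph(matrix(3, 50, 20), 1000, 0.5)
  res <- normalize_kymograph(k)
  expect_equal(res$kymograph$data, k$data)
  expect_equal(res$gain$gain, rep(1, 20))
  expect_false(any(res$gain$excluded))
})

test_that("columns needing more than the boost cap are excluded unchanged", {
  sim <- simulate_kymograph(sim_kymograph_spec(duration = 0.1, seed = 9))
  g <- rep(1, ncol(sim$kymograph$data)); g[3] <- 0.1   # would need 10x boost
  shaded <- kymograph(sweep(sim$kymograph$data, 2, g, `*`), 1000, 0.5)
  res <- normalize_kymograph(shaded)
  expect_true(res$gain$excluded[3])
  expect_identical(res$kymograph$data[, 3], shaded$data[, 3])
  # an all-zero column is excluded, not divided
  z <- shaded$data; z[, 5] <- 0
  res2 <- normalize_kymograph(kymograph(z, 1000, 0.5))
  expect_true(res2$gain$excluded[5])
})

test_that("normalization is idempotent on included columns", {
  sim <- simulate_kymograph(sim_kymograph_spec(duration = 0.2, seed = 10))
  res1 <- normalize_kymograph(sim$kymograph)
  res2 <- normalize_kymograph(res1$kymograph)
  inc <- !res1$gain$excluded & !res2$gain$excluded
  expect_lt(max(abs(res2$kymograph$data[, inc] - res1$kymograph$data[, inc]) /
                  pmax(abs(res1$kymograph$data[, inc]), 1e-12)), 1e-6)
})

test_that("stack normalization flattens a simulated illumination profile", {
  # plasma-only vessel so the time average carries the gain and nothing else
  gain <- 0.55 + 0.45 * sin(seq(0.2, pi - 0.2, length.out = 120))^2
  spec <- sim_vessel_spec(duration = 0.03, faced_gain = gain, n_rbc = 0,
                          seed = 11)
  sim <- simulate_vessel_video(spec)
  res <- normalize_stack(sim$stack)
  inc <- !res$gain$excluded
  avg <- apply(res$stack$data, c(2, 3), mean)
  # background rows (away from the vessel) should be flat after correction
  bg <- colMeans(avg[c(1:5, 36:40), inc])
  expect_lt(diff(range(bg)) / mean(bg), 0.02)
  # unit gain in, identity out
  spec1 <- sim_vessel_spec(duration = 0.03, n_rbc = 0, seed = 11)
  sim1 <- simulate_vessel_video(spec1)
  res1 <- normalize_stack(sim1$stack)
  expect_equal(res1$stack$data, sim1$stack$data, tolerance = 1e-10)
})

test_that("temporal binning follows the floor rule and conserves intensity", {
  k <- kymograph(matrix(runif(200), 10, 20), 1e6, 0.5)
  expect_identical(bin_time(k, 1)$data, k$data)
  kb <- bin_time(k, 3)
  expect_equal(nrow(kb$data), 3)          # line 10 dropped
  expect_equal(kb$line_rate, 1e6 / 3)
  # mean binning conserves summed intensity of retained lines up to factor
  expect_equal(sum(kb$data) * 3, sum(k$data[1:9, ]))
  expect_error(bin_time(k, 11), "exceeds")
  # the 10x binning of megahertz line scans lands at 100 kHz
  expect_equal(bin_time(k, 10)$line_rate, 1e5)
  st <- frame_stack(array(runif(5 * 4 * 4), c(5, 4, 4)), 1000, 0.5)
  expect_equal(dim(bin_time(st, 2)$data)[1], 2)
  expect_equal(bin_time(st, 2)$frame_rate, 500)
})

test_that("rigid registration recovers injected square-wave motion", {
  base <- textured_frame(48, 48, seed = 31, smooth = 5)
  n <- 12
  motion <- cbind(dx = rep(c(3, -3), length.out = n) * rep(c(1, 0), n / 2),
                  dy = rep(c(0, 2), length.out = n))
  arr <- array(0, c(n, 48, 48))
  for (f in seq_len(n)) {
    arr[f, , ] <- hemokymo:::shift_image(base, motion[f, 1], motion[f, 2])
  }
  reg <- register_rigid(frame_stack(arr, 100, 0.5), reference = 1)
  # shifts are relative to the chosen reference frame's own motion
  expected <- sweep(motion, 2, motion[1, ])
  rms <- sqrt(mean((reg$shifts$dx_px - expected[, 1])^2 +
                     (reg$shifts$dy_px - expected[, 2])^2))
  expect_lt(rms, 0.25)
})

test_that("motionless stacks register to near-zero shifts", {
  base <- textured_frame(40, 40, seed = 32)
  arr <- array(rep(base, each = 1), c(4, 40, 40))
  for (f in 1:4) arr[f, , ] <- base
  reg <- register_rigid(frame_stack(arr, 100, 0.5))
  expect_lt(max(abs(c(reg$shifts$dx_px, reg$shifts$dy_px))), 0.1)
  # featureless frames: zero shift and a warning
  flat <- array(1, c(3, 20, 20))
  expect_warning(register_rigid(frame_stack(flat, 10, 1)), "featureless")
})

test_that("registration is inverse-consistent", {
  base <- textured_frame(48, 48, seed = 33, smooth = 5)
  d <- c(2.5, -1.5)
  arr <- array(0, c(2, 48, 48))
  arr[1, , ] <- base
  arr[2, , ] <- hemokymo:::shift_image(base, d[1], d[2])
  reg <- register_rigid(frame_stack(arr, 10, 1), reference = 1)
  # registering the shifted frame back should cancel the injected motion
  expect_lt(abs(reg$shifts$dx_px[2] - d[1]), 0.25)
  expect_lt(abs(reg$shifts$dy_px[2] - d[2]), 0.25)
  rereg <- register_rigid(reg$stack, reference = 1)
  expect_lt(max(abs(c(rereg$shifts$dx_px[2], rereg$shifts$dy_px[2]))), 0.25)
})
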