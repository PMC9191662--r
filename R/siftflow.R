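# Dense 2D velocity mapping by SIFT flow: per-pixel gradient-orientation
# descriptors matched between consecutive frames under the discrete energy
#
#   E(w) = sum_p min(||s1(p) - s2(p + w(p))||_1, t)
#        + sum_p eta * (|u(p)| + |v(p)|)
#        + sum_(p,q) min(alpha |u(p) - u(q)|, d) + min(alpha |v(p) - v(q)|, d)
#
# over integer displacements w(p) = (u, v) within a search radius, with a
# 4-connected neighbourhood. Minimization is min-sum loopy belief
# propagation with separable truncated-L1 distance-transform messages,
# followed by an ICM polish seeded from the better of the BP labelling and
# the zero field, which guarantees E(w) <= E(0).

#' SIFT-flow configuration
#'
#' @param eta small-displacement weight (L1 magnitude penalty per pixel).
#' @param alpha smoothness weight (per neighbour pair, per component).
#' @param d smoothness truncation cap.
#' @param t data-term truncation; `NULL` sets it per frame pair to the
#'   95th percentile of the per-pixel nearest-match descriptor distance.
#' @param search_radius search radius in native pixels.
#' @param upsample_factor integer cubic up-sampling factor applied to the
#'   frames before matching (2 supplies half-pixel flow precision).
#' @param pyramid_levels reserved; only single-scale (1) is implemented.
#' @param bp_iters maximal belief-propagation iterations.
#' @param bp_tol message-change tolerance (in energy units) declaring
#'   convergence.
#' @param damping fraction of the previous message retained at each
#'   update; damping stabilizes min-sum on loopy graphs.
#' @param cell_size,grid descriptor geometry passed to
#'   [compute_descriptors()] (support = `grid * cell_size` px; shrink for
#'   very small frames).
#' @export
sift_flow_config <- function(eta = 0.01, alpha = 50, d = 10020, t = NULL,
                             search_radius = 10, upsample_factor = 2,
                             pyramid_levels = 1, bp_iters = 40,
                             bp_tol = 1, damping = 0.5,
                             cell_size = 2, grid = 4) {
  stopifnot(eta >= 0, alpha >= 0, d >= 0, search_radius >= 1,
            upsample_factor >= 1)
  if (pyramid_levels != 1) {
    stop("only single-scale optimization (pyramid_levels = 1) is implemented")
  }
  structure(list(eta = eta, alpha = alpha, d = d, t = t,
                 search_radius = as.integer(search_radius),
                 upsample_factor = as.integer(upsample_factor),
                 pyramid_levels = 1L,
                 bp_iters = as.integer(bp_iters), bp_tol = bp_tol,
                 damping = damping,
                 cell_size = as.integer(cell_size), grid = as.integer(grid)),
            class = "sift_flow_config")
}

box_filter <- function(m, size) {
  half_lo <- (size - 1L) %/% 2L
  half_hi <- size - 1L - half_lo
  nr <- nrow(m); nc <- ncol(m)
  I <- matrix(0, nr + 1, nc + 1)
  I[-1, -1] <- apply(apply(m, 2, cumsum), 1, cumsum) |> t()
  r0 <- pmax(seq_len(nr) - half_lo, 1); r1 <- pmin(seq_len(nr) + half_hi, nr)
  c0 <- pmax(seq_len(nc) - half_lo, 1); c1 <- pmin(seq_len(nc) + half_hi, nc)
  I[r1 + 1, c1 + 1] - I[r0, c1 + 1] - I[r1 + 1, c0] + I[r0, c0]
}

#' Dense gradient-orientation descriptors
#'
#' Per-pixel SIFT-style descriptor: gradient magnitudes are accumulated
#' into `n_bins` orientation bins over a `grid x grid` arrangement of
#' square cells of `cell_size` pixels centred on the pixel, then
#' L2-normalized with the usual 0.2 clipping. Built from image gradients,
#' the descriptors are exactly invariant to additive brightness shifts and
#' (after normalization) to global contrast scaling.
#'
#' @param frame 2D numeric matrix.
#' @param cell_size cell side, pixels.
#' @param grid cells per side (default 4, giving `4 * 4 * n_bins`
#'   channels).
#' @param n_bins orientation bins.
#' @return a `descriptor_grid` list: `desc` (`npix x n_channels` matrix,
#'   pixels column-major), `dim`, `cell_size`, `grid`, `n_bins`.
#' @export
compute_descriptors <- function(frame, cell_size = 2, grid = 4, n_bins = 8) {
  frame <- as.matrix(frame)
  H <- nrow(frame); W <- ncol(frame)
  support <- grid * cell_size
  if (H < support || W < support) {
    stop("frame smaller than the descriptor support (", support, " px)")
  }
  pad <- function(m) m[c(1, seq_len(nrow(m)), nrow(m)),
                       c(1, seq_len(ncol(m)), ncol(m))]
  fp <- pad(frame)
  gx <- (fp[2:(H + 1), 3:(W + 2)] - fp[2:(H + 1), 1:W]) / 2
  gy <- (fp[3:(H + 2), 2:(W + 1)] - fp[1:H, 2:(W + 1)]) / 2
  mag <- sqrt(gx^2 + gy^2)
  ang <- atan2(gy, gx) %% (2 * pi)
  bin <- pmin(floor(ang / (2 * pi / n_bins)), n_bins - 1) + 1L
  filt <- vector("list", n_bins)
  for (b in seq_len(n_bins)) {
    filt[[b]] <- box_filter(mag * (bin == b), cell_size)
  }
  offs <- (seq_len(grid) - (grid + 1) / 2) * cell_size
  desc <- matrix(0, H * W, grid * grid * n_bins)
  ch <- 0L
  ridx <- rep(seq_len(H), W); cidx <- rep(seq_len(W), each = H)
  for (oy in offs) for (ox in offs) for (b in seq_len(n_bins)) {
    ch <- ch + 1L
    rs <- pmin(pmax(ridx + round(oy), 1), H)
    cs <- pmin(pmax(cidx + round(ox), 1), W)
    desc[, ch] <- filt[[b]][cbind(rs, cs)]
  }
  desc[desc < 0] <- 0  # guard against cumsum cancellation residue
  nrm <- sqrt(rowSums(desc^2)) + 1e-12
  desc <- pmin(desc / nrm, 0.2)
  nrm <- sqrt(rowSums(desc^2)) + 1e-12
  # conventional 0-255 descriptor scale, so the published energy weights
  # (eta = 0.01, alpha = 50, d = 10020) are commensurate with the data term
  desc <- desc / nrm * 255
  structure(list(desc = desc, dim = c(H, W), cell_size = cell_size,
                 grid = grid, n_bins = n_bins),
            class = "descriptor_grid")
}

# Truncated-L1 distance transform over the (u, v) label grid, vectorized
# over pixels: rows of `h` are pixels, columns are labels laid out with u
# fastest. Returns min over (u0, v0) of h + min(a|du|, cap) + min(a|dv|, cap).
dt_truncated <- function(h, nu, nv, a, cap) {
  # pass along u for every v
  for (iv in seq_len(nv)) {
    base <- (iv - 1L) * nu
    for (iu in 2:nu) {
      h[, base + iu] <- pmin(h[, base + iu], h[, base + iu - 1L] + a)
    }
    for (iu in (nu - 1L):1L) {
      h[, base + iu] <- pmin(h[, base + iu], h[, base + iu + 1L] + a)
    }
    mn <- h[, base + 1L]
    for (iu in 2:nu) mn <- pmin(mn, h[, base + iu])
    for (iu in seq_len(nu)) {
      h[, base + iu] <- pmin(h[, base + iu], mn + cap)
    }
  }
  # pass along v for every u
  for (iu in seq_len(nu)) {
    idx <- iu + (seq_len(nv) - 1L) * nu
    for (iv in 2:nv) {
      h[, idx[iv]] <- pmin(h[, idx[iv]], h[, idx[iv - 1L]] + a)
    }
    for (iv in (nv - 1L):1L) {
      h[, idx[iv]] <- pmin(h[, idx[iv]], h[, idx[iv + 1L]] + a)
    }
    mn <- h[, idx[1L]]
    for (iv in 2:nv) mn <- pmin(mn, h[, idx[iv]])
    for (iv in seq_len(nv)) {
      h[, idx[iv]] <- pmin(h[, idx[iv]], mn + cap)
    }
  }
  h
}

pairwise_cost <- function(du_p, dv_p, du_q, dv_q, alpha, d) {
  pmin(alpha * abs(du_p - du_q), d) + pmin(alpha * abs(dv_p - dv_q), d)
}

field_energy <- function(D, lab, dus, dvs, H, W, alpha, d) {
  un <- sum(D[cbind(seq_along(lab), lab)])
  labm <- matrix(lab, H, W)
  um <- matrix(dus[lab], H, W); vm <- matrix(dvs[lab], H, W)
  pw <- 0
  if (H > 1) {
    pw <- pw + sum(pairwise_cost(um[-1, ], vm[-1, ], um[-H, ], vm[-H, ],
                                 alpha, d))
  }
  if (W > 1) {
    pw <- pw + sum(pairwise_cost(um[, -1], vm[, -1], um[, -W], vm[, -W],
                                 alpha, d))
  }
  un + pw
}

icm_polish <- function(D, lab, dus, dvs, H, W, alpha, d, max_pass = 5) {
  npix <- H * W
  K <- length(dus)
  for (pass in seq_len(max_pass)) {
    changed <- FALSE
    for (p in seq_len(npix)) {
      r <- (p - 1L) %% H + 1L; cc <- (p - 1L) %/% H + 1L
      cost <- D[p, ]
      for (q in c(if (r > 1) p - 1L, if (r < H) p + 1L,
                  if (cc > 1) p - H, if (cc < W) p + H)) {
        lq <- lab[q]
        cost <- cost + pairwise_cost(dus, dvs, dus[lq], dvs[lq], alpha, d)
      }
      best <- which.min(cost)
      if (best != lab[p]) {
        lab[p] <- best
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  lab
}

#' SIFT flow between two frames
#'
#' Frames are up-sampled by `cfg$upsample_factor` (cubic), descriptors are
#' computed densely, and the flow minimizing the truncated-L1 energy over
#' integer displacements within the (up-sampled) search radius is
#' estimated by loopy min-sum belief propagation with distance-transform
#' messages, then polished by ICM seeded from the better of the BP result
#' and the zero field (so the returned energy never exceeds the zero-field
#' energy, and on constant frames the flow is exactly zero). The final
#' field is divided by the up-sampling factor, i.e. reported in native
#' px/frame on the native pixel grid.
#'
#' @param frame_a,frame_b 2D matrices of identical shape.
#' @param cfg a [sift_flow_config()].
#' @param return_problem also return the internal discrete problem (data
#'   cost matrix, label displacements, smoothness parameters) for
#'   cross-checking against independent solvers.
#' @return a `flow_field` list: `u`, `v` (native px/frame, H x W),
#'   `energy`, `energy_zero`, `converged`, `cfg`, and optionally
#'   `problem`.
#' @export
sift_flow <- function(frame_a, frame_b, cfg = sift_flow_config(),
                      return_problem = FALSE) {
  stopifnot(all(dim(frame_a) == dim(frame_b)))
  up <- cfg$upsample_factor
  a <- cubic_upsample(as.matrix(frame_a), up)
  b <- cubic_upsample(as.matrix(frame_b), up)
  H <- nrow(a); W <- ncol(a)
  da <- compute_descriptors(a, cell_size = cfg$cell_size, grid = cfg$grid)$desc
  db <- compute_descriptors(b, cell_size = cfg$cell_size, grid = cfg$grid)$desc
  r <- cfg$search_radius * up
  dus <- rep(-r:r, times = 2 * r + 1)
  dvs <- rep(-r:r, each = 2 * r + 1)
  nu <- 2L * r + 1L
  K <- nu * nu
  npix <- H * W
  ridx <- rep(seq_len(H), W); cidx <- rep(seq_len(W), each = H)

  # raw (untruncated) descriptor distances per label
  Draw <- matrix(NA_real_, npix, K)
  for (l in seq_len(K)) {
    rs <- ridx + dvs[l]; cs <- cidx + dus[l]
    valid <- rs >= 1 & rs <= H & cs >= 1 & cs <= W
    if (!any(valid)) next
    q <- (cs[valid] - 1L) * H + rs[valid]
    Draw[valid, l] <- rowSums(abs(da[which(valid), , drop = FALSE] -
                                    db[q, , drop = FALSE]))
  }
  t_cap <- cfg$t
  if (is.null(t_cap)) {
    # outlier cap: leave the bulk of the data term un-truncated
    t_cap <- stats::quantile(Draw, 0.95, na.rm = TRUE, names = FALSE)
    if (!is.finite(t_cap) || t_cap <= 0) t_cap <- 1
  }
  D <- pmin(Draw, t_cap)
  D[is.na(D)] <- t_cap
  D <- D + cfg$eta * (abs(dus) + abs(dvs))[col(D)]

  # min-sum BP; messages indexed by the direction they arrive from
  M <- list(up = matrix(0, npix, K), down = matrix(0, npix, K),
            left = matrix(0, npix, K), right = matrix(0, npix, K))
  has <- list(up = ridx > 1, down = ridx < H, left = cidx > 1, right = cidx < W)
  nb_off <- c(up = -1L, down = 1L, left = -H, right = H)
  opp <- c(up = "down", down = "up", left = "right", right = "left")
  best_lab <- rep(which(dus == 0 & dvs == 0), npix)
  best_E <- field_energy(D, best_lab, dus, dvs, H, W, cfg$alpha, cfg$d)
  converged <- FALSE
  for (iter in seq_len(cfg$bp_iters)) {
    B <- D + M$up + M$down + M$left + M$right
    delta <- 0
    newM <- M
    for (dir in names(nb_off)) {
      # message sent in direction `dir`, arriving at the neighbour from
      # direction opp[dir]
      send <- which(has[[dir]])
      # exclude the message the sender received from the target itself
      h <- B[send, , drop = FALSE] - M[[dir]][send, , drop = FALSE]
      h <- dt_truncated(h, nu, nu, cfg$alpha, cfg$d)
      h <- h - apply(h, 1, min)
      tgt <- send + nb_off[[dir]]
      old <- M[[opp[dir]]][tgt, , drop = FALSE]
      h <- cfg$damping * old + (1 - cfg$damping) * h
      delta <- max(delta, max(abs(h - old)))
      newM[[opp[dir]]][tgt, ] <- h
    }
    M <- newM
    B <- D + M$up + M$down + M$left + M$right
    lab <- max.col(-B, ties.method = "first")
    E <- field_energy(D, lab, dus, dvs, H, W, cfg$alpha, cfg$d)
    if (E < best_E) {
      best_E <- E; best_lab <- lab
    }
    if (delta < cfg$bp_tol) {
      converged <- TRUE
      break
    }
  }
  if (!converged) {
    warning("belief propagation did not converge; returning best labelling found")
  }
  zero_lab <- rep(which(dus == 0 & dvs == 0), npix)
  E_zero <- field_energy(D, zero_lab, dus, dvs, H, W, cfg$alpha, cfg$d)
  seed <- if (best_E <= E_zero) best_lab else zero_lab
  lab <- icm_polish(D, seed, dus, dvs, H, W, cfg$alpha, cfg$d)
  E <- field_energy(D, lab, dus, dvs, H, W, cfg$alpha, cfg$d)

  u_up <- matrix(dus[lab], H, W) / up
  v_up <- matrix(dvs[lab], H, W) / up
  keep_r <- seq(1, H, by = up); keep_c <- seq(1, W, by = up)
  out <- structure(list(u = u_up[keep_r, keep_c],
                        v = v_up[keep_r, keep_c],
                        energy = E, energy_zero = E_zero,
                        converged = converged, t = t_cap, cfg = cfg),
                   class = "flow_field")
  if (return_problem) {
    out$problem <- list(D = D, dus = dus, dvs = dvs, H = H, W = W,
                        alpha = cfg$alpha, d = cfg$d, labels = lab)
  }
  out
}

#' Exact MAP labelling of a narrow flow problem by dynamic programming
#'
#' Junction-tree inference over the pixel grid treating each image row as
#' one clique: exact for any number of rows, exponential in the row width,
#' so only widths up to 4 pixels are accepted. Serves as the independent
#' exhaustive oracle for [sift_flow()]'s belief-propagation optimizer on
#' small instances.
#'
#' @param problem the `problem` element returned by
#'   `sift_flow(..., return_problem = TRUE)` (or any list with the same
#'   fields).
#' @return list with `labels` and `energy` of the exact minimum.
#' @export
flow_exact_map <- function(problem) {
  D <- problem$D; dus <- problem$dus; dvs <- problem$dvs
  H <- problem$H; W <- problem$W
  alpha <- problem$alpha; d <- problem$d
  if (W > 4) stop("exact DP supported only for width <= 4")
  K <- length(dus)
  n_states <- K^W
  # enumerate row states: label of column j in state s
  state_lab <- matrix(0L, n_states, W)
  s <- 0:(n_states - 1)
  for (j in seq_len(W)) {
    state_lab[, j] <- (s %% K) + 1L
    s <- s %/% K
  }
  intra <- numeric(n_states)  # horizontal edges within a row
  if (W > 1) {
    for (j in 2:W) {
      intra <- intra + pairwise_cost(dus[state_lab[, j]], dvs[state_lab[, j]],
                                     dus[state_lab[, j - 1]],
                                     dvs[state_lab[, j - 1]], alpha, d)
    }
  }
  # vertical transition cost between consecutive rows
  trans <- matrix(0, n_states, n_states)
  for (j in seq_len(W)) {
    lu <- dus[state_lab[, j]]; lv <- dvs[state_lab[, j]]
    trans <- trans + pairwise_cost(outer(lu, lu, function(a, b) a),
                                   outer(lv, lv, function(a, b) a),
                                   outer(lu, lu, function(a, b) b),
                                   outer(lv, lv, function(a, b) b), alpha, d)
  }
  row_unary <- function(r) {
    u <- numeric(n_states)
    for (j in seq_len(W)) {
      u <- u + D[(j - 1L) * H + r, state_lab[, j]]
    }
    u + intra
  }
  cost <- row_unary(1)
  back <- matrix(0L, H, n_states)
  for (r in 2:H) {
    tot <- trans + cost  # cost recycles down columns (previous-row state)
    idx <- max.col(-t(tot), ties.method = "first")
    cost <- tot[cbind(idx, seq_len(n_states))] + row_unary(r)
    back[r, ] <- idx
  }
  s_best <- which.min(cost)
  states <- integer(H)
  states[H] <- s_best
  for (r in H:2) states[r - 1] <- back[r, states[r]]
  labels <- integer(H * W)
  for (r in seq_len(H)) {
    labels[(seq_len(W) - 1L) * H + r] <- state_lab[states[r], ]
  }
  list(labels = labels,
       energy = field_energy(D, labels, dus, dvs, H, W, alpha, d))
}

#' Velocity-map series from a registered stack
#'
#' Runs [sift_flow()] on every consecutive frame pair, converts the fields
#' to mm/s via `pixel_size * frame_rate`, and zeroes pixels outside the
#' vessel-footprint polygon for reporting (the polygon plays no part in
#' the optimization). Returns the per-pair fields and the time-mean map.
#'
#' @param s a [frame_stack()] (registered and normalized).
#' @param roi_polygon a [polyline_roi()] whose vertices describe the
#'   vessel footprint polygon, or `NULL` to keep all pixels.
#' @param cfg a [sift_flow_config()].
#' @return list with `fields` (each with `u`, `v` in mm/s), `mean_u`,
#'   `mean_v`, `mean_speed`, `mask`, `time`.
#' @export
velocity_map_series <- function(s, roi_polygon = NULL,
                                cfg = sift_flow_config()) {
  stopifnot(inherits(s, "frame_stack"))
  n <- dim(s$data)[1]
  if (n < 2) stop("need at least 2 frames")
  H <- dim(s$data)[2]; W <- dim(s$data)[3]
  mask <- matrix(TRUE, H, W)
  if (!is.null(roi_polygon)) {
    gx <- rep(seq_len(W), each = H); gy <- rep(seq_len(H), W)
    mask <- matrix(point_in_polygon(gx, gy, roi_polygon$x, roi_polygon$y),
                   H, W)
  }
  scale <- s$pixel_size * s$frame_rate / 1000  # px/frame -> mm/s
  fields <- vector("list", n - 1)
  sum_u <- sum_v <- matrix(0, H, W)
  for (f in seq_len(n - 1)) {
    fl <- sift_flow(s$data[f, , ], s$data[f + 1, , ], cfg)
    u <- fl$u * scale; v <- fl$v * scale
    u[!mask] <- 0; v[!mask] <- 0
    fields[[f]] <- list(u = u, v = v, energy = fl$energy,
                        converged = fl$converged)
    sum_u <- sum_u + u; sum_v <- sum_v + v
  }
  list(fields = fields, mean_u = sum_u / (n - 1), mean_v = sum_v / (n - 1),
       mean_speed = sqrt((sum_u / (n - 1))^2 + (sum_v / (n - 1))^2),
       mask = mask, time = (seq_len(n - 1) - 0.5) / s$frame_rate)
}

#' RBC velocity along a line from a flow-field series
#'
#' For each frame pair the flow vectors are sampled along the line; each
#' sample is signed by the projection of its vector onto the local line
#' tangent, and the sample of maximal magnitude represents the RBC
#' velocity at that time (plasma moves more slowly, so the maximum tracks
#' the cells).
#'
#' @param fields the list returned by [velocity_map_series()].
#' @param line a [polyline_roi()] inside the mapped region.
#' @return a [velocity_trace()] in mm/s.
#' @export
line_velocity_from_field <- function(fields, line) {
  pts <- resample_polyline(line, spacing = 1)
  H <- nrow(fields$fields[[1]]$u); W <- ncol(fields$fields[[1]]$u)
  if (any(pts$x < 1 | pts$x > W | pts$y < 1 | pts$y > H)) {
    stop("line leaves the flow field")
  }
  tx <- c(diff(pts$x), NA); ty <- c(diff(pts$y), NA)
  tx[length(tx)] <- tx[length(tx) - 1]; ty[length(ty)] <- ty[length(ty) - 1]
  tn <- sqrt(tx^2 + ty^2); tx <- tx / tn; ty <- ty / tn
  vel <- vapply(fields$fields, function(fl) {
    us <- bilinear_sample(fl$u, pts$y, pts$x)
    vs <- bilinear_sample(fl$v, pts$y, pts$x)
    mag <- sqrt(us^2 + vs^2)
    i <- which.max(mag)
    sgn <- sign(us[i] * tx[i] + vs[i] * ty[i])
    if (sgn == 0) sgn <- 1
    sgn * mag[i]
  }, numeric(1))
  velocity_trace(fields$time, vel)
}
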