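# Internal numeric helpers shared across modules.

# Error function; base R only ships pnorm.
erf <- function(x) 2 * stats::pnorm(x * sqrt(2)) - 1

erfc <- function(x) 2 * stats::pnorm(-x * sqrt(2))

#' Evaluate code with a fixed RNG seed, restoring the caller's RNG state
#' @noRd
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else {
      NULL
    }
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    }, add = TRUE)
    set.seed(as.integer(seed))
  }
  force(code)
}

#' Gaussian smoothing of a 1D trace.
#'
#' Kernel width is given in samples; the kernel sd is `width / 2` and support
#' extends to 3 sd. Edges are handled by renormalizing the kernel over the
#' in-range samples so no padding bias is introduced.
#' @noRd
gauss_smooth <- function(x, width) {
  if (width <= 1) return(x)
  sd <- width / 2
  half <- max(1L, ceiling(3 * sd))
  k <- exp(-(seq(-half, half))^2 / (2 * sd^2))
  n <- length(x)
  num <- stats::filter(c(rep(0, half), x, rep(0, half)), k, sides = 2)
  den <- stats::filter(c(rep(0, half), rep(1, n), rep(0, half)), k, sides = 2)
  as.numeric(num[(half + 1):(half + n)] / den[(half + 1):(half + n)])
}

#' Local maxima with topographic prominence.
#'
#' A sample is a candidate peak when strictly greater than its immediate
#' neighbours (plateaus take the centre index). Prominence of a peak is its
#' height above the higher of the two key saddles found by walking outward
#' until a taller sample is met. Peaks closer than `min_separation` are
#' resolved greedily in order of decreasing height.
#' @return integer indices of accepted peaks, sorted
#' @noRd
find_peaks <- function(x, min_prominence = 0, min_separation = 1) {
  n <- length(x)
  if (n < 3) return(integer(0))
  d <- diff(x)
  s <- sign(d)
  # collapse zero-runs so plateaus register once
  for (i in seq_len(n - 1)) if (s[i] == 0 && i > 1) s[i] <- s[i - 1]
  cand <- which(diff(s) < 0) + 1L
  cand <- cand[cand > 1 & cand < n]
  if (!length(cand)) return(integer(0))

  prom <- vapply(cand, function(p) {
    h <- x[p]
    left_min <- h
    i <- p - 1L
    while (i >= 1 && x[i] <= h) {
      left_min <- min(left_min, x[i]); i <- i - 1L
    }
    if (i < 1) left_min <- min(x[1:p])
    right_min <- h
    i <- p + 1L
    while (i <= n && x[i] <= h) {
      right_min <- min(right_min, x[i]); i <- i + 1L
    }
    if (i > n) right_min <- min(x[p:n])
    h - max(left_min, right_min)
  }, numeric(1))

  keep <- prom >= min_prominence
  cand <- cand[keep]
  if (!length(cand)) return(integer(0))
  ord <- order(x[cand], decreasing = TRUE)
  accepted <- integer(0)
  for (p in cand[ord]) {
    if (!length(accepted) || all(abs(accepted - p) >= min_separation)) {
      accepted <- c(accepted, p)
    }
  }
  sort(accepted)
}

#' Bilinear sampling of a 2D image at fractional (row, col) coordinates.
#' Out-of-range coordinates are clamped (replicate padding).
#' @noRd
bilinear_sample <- function(img, row, col) {
  nr <- nrow(img); nc <- ncol(img)
  row <- pmin(pmax(row, 1), nr)
  col <- pmin(pmax(col, 1), nc)
  r0 <- pmin(floor(row), nr - 1L); c0 <- pmin(floor(col), nc - 1L)
  fr <- row - r0; fc <- col - c0
  img[cbind(r0, c0)] * (1 - fr) * (1 - fc) +
    img[cbind(r0 + 1, c0)] * fr * (1 - fc) +
    img[cbind(r0, c0 + 1)] * (1 - fr) * fc +
    img[cbind(r0 + 1, c0 + 1)] * fr * fc
}

#' Shift an image by a fractional displacement with replicate padding.
#' Positive dx shifts content toward larger column index.
#' @noRd
shift_image <- function(img, dx, dy) {
  nr <- nrow(img); nc <- ncol(img)
  g <- expand.grid(row = seq_len(nr), col = seq_len(nc))
  out <- bilinear_sample(img, g$row - dy, g$col - dx)
  matrix(out, nr, nc)
}

#' 1D cubic (Catmull-Rom) interpolation at arbitrary positions.
#' @noRd
cubic_interp1 <- function(y, xi) {
  n <- length(y)
  xi <- pmin(pmax(xi, 1), n)
  i1 <- pmin(floor(xi), n - 1L)
  t <- xi - i1
  i0 <- pmax(i1 - 1L, 1L); i2 <- i1 + 1L; i3 <- pmin(i1 + 2L, n)
  p0 <- y[i0]; p1 <- y[i1]; p2 <- y[i2]; p3 <- y[i3]
  0.5 * ((2 * p1) + (-p0 + p2) * t +
           (2 * p0 - 5 * p1 + 4 * p2 - p3) * t^2 +
           (-p0 + 3 * p1 - 3 * p2 + p3) * t^3)
}

#' Separable Catmull-Rom upsampling of a matrix by an integer factor.
#' @noRd
cubic_upsample <- function(img, factor) {
  if (factor == 1) return(img)
  nr <- nrow(img); nc <- ncol(img)
  xi_c <- seq(1, nc, length.out = nc * factor)
  tmp <- t(apply(img, 1, cubic_interp1, xi = xi_c))
  xi_r <- seq(1, nr, length.out = nr * factor)
  apply(tmp, 2, cubic_interp1, xi = xi_r)
}

#' Non-overlapping mean binning of a vector; trailing remainder dropped.
#' @noRd
bin_vector <- function(x, factor) {
  factor <- as.integer(factor)
  if (factor <= 1) return(x)
  n <- (length(x) %/% factor) * factor
  colMeans(matrix(x[seq_len(n)], nrow = factor))
}

#' Ray-casting point-in-polygon test (vectorized over points).
#' @noRd
point_in_polygon <- function(px, py, vx, vy) {
  n <- length(vx)
  inside <- rep(FALSE, length(px))
  j <- n
  for (i in seq_len(n)) {
    crosses <- ((vy[i] > py) != (vy[j] > py)) &
      (px < (vx[j] - vx[i]) * (py - vy[i]) / (vy[j] - vy[i]) + vx[i])
    inside <- xor(inside, crosses & !is.na(crosses))
    j <- i
  }
  inside
}

`%||%` <- function(a, b) if (is.null(a)) b else a
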