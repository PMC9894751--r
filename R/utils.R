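# Internal numeric helpers shared across modules.
#
# Coordinate convention (used everywhere in the package): grids are stored as
# R matrices indexed [row, col]; the physical position of node [i, j] is
# x = (j - 1) * pixel_size, y = (i - 1) * pixel_size (micrometres), with y
# increasing downward as in image indexing. All angles are measured
# counter-clockwise from the +x axis in this (x, y) frame. Director angles are
# line orientations, defined modulo pi; particle headings are full-circle,
# modulo 2*pi.

# wrap an angle into [0, pi)
wrap_pi <- function(a) a %% pi

# wrap an angle into [0, 2*pi)
wrap_2pi <- function(a) a %% (2 * pi)

# smallest signed difference between two director angles, in (-pi/2, pi/2]
nematic_diff <- function(a, b) {
  d <- (a - b) %% pi
  i <- which(d > pi / 2)
  d[i] <- d[i] - pi
  d
}

# smallest signed difference between two headings, in (-pi, pi]
heading_diff <- function(a, b) {
  d <- (a - b) %% (2 * pi)
  i <- which(d > pi)
  d[i] <- d[i] - 2 * pi
  d
}

# 1D Gaussian kernel, truncated at 3 sigma
gauss_kernel <- function(sigma) {
  if (sigma <= 0) return(1)
  r <- max(1L, ceiling(3 * sigma))
  k <- exp(-((-r:r)^2) / (2 * sigma^2))
  k / sum(k)
}

# separable 2D convolution with replicate-padding at the borders
sep_convolve <- function(m, k) {
  r <- (length(k) - 1L) / 2L
  if (r == 0) return(m)
  pad_apply <- function(v) {
    vp <- c(rep(v[1L], r), v, rep(v[length(v)], r))
    as.numeric(stats::filter(vp, k, sides = 2))[(r + 1L):(r + length(v))]
  }
  m2 <- apply(m, 2L, pad_apply)
  t(apply(m2, 1L, pad_apply))
}

gaussian_blur <- function(m, sigma) {
  if (sigma <= 0) return(m)
  sep_convolve(m, gauss_kernel(sigma))
}

# box (moving-average) filter of odd width w, replicate-padded
box_filter <- function(m, w) {
  w <- as.integer(w)
  if (w <= 1L) return(m)
  if (w %% 2L == 0L) w <- w + 1L
  sep_convolve(m, rep(1 / w, w))
}

# 4th-order central differences in the deep interior, 2nd-order central one
# row/column in, one-sided at the borders. h is the grid spacing. Used where
# derivative accuracy matters near steep 1/r distortions (splay/bend maps).
grad_xy4 <- function(m, h = 1) {
  g <- grad_xy(m, h)
  nr <- nrow(m); nc <- ncol(m)
  if (nc >= 5L) {
    j <- 3:(nc - 2L)
    g$x[, j] <- (-m[, j + 2L] + 8 * m[, j + 1L] - 8 * m[, j - 1L] + m[, j - 2L]) / (12 * h)
  }
  if (nr >= 5L) {
    i <- 3:(nr - 2L)
    g$y[i, ] <- (-m[i + 2L, ] + 8 * m[i + 1L, ] - 8 * m[i - 1L, ] + m[i - 2L, ]) / (12 * h)
  }
  g
}

# gradient of a matrix along x (columns) and y (rows): central differences in
# the interior, one-sided at the borders. h is the grid spacing.
grad_xy <- function(m, h = 1) {
  nr <- nrow(m); nc <- ncol(m)
  gx <- matrix(0, nr, nc)
  gy <- matrix(0, nr, nc)
  if (nc >= 3L) gx[, 2:(nc - 1L)] <- (m[, 3:nc] - m[, 1:(nc - 2L)]) / (2 * h)
  if (nc >= 2L) {
    gx[, 1L] <- (m[, 2L] - m[, 1L]) / h
    gx[, nc] <- (m[, nc] - m[, nc - 1L]) / h
  }
  if (nr >= 3L) gy[2:(nr - 1L), ] <- (m[3:nr, ] - m[1:(nr - 2L), ]) / (2 * h)
  if (nr >= 2L) {
    gy[1L, ] <- (m[2L, ] - m[1L, ]) / h
    gy[nr, ] <- (m[nr, ] - m[nr - 1L, ]) / h
  }
  list(x = gx, y = gy)
}

# ray-casting point-in-polygon test; poly is a matrix with columns x, y
point_in_polygon <- function(px, py, poly) {
  n <- nrow(poly)
  xs <- poly[, 1L]; ys <- poly[, 2L]
  inside <- logical(length(px))
  j <- n
  for (i in seq_len(n)) {
    crosses <- ((ys[i] > py) != (ys[j] > py)) &
      (px < (xs[j] - xs[i]) * (py - ys[i]) / (ys[j] - ys[i]) + xs[i])
    inside <- xor(inside, crosses)
    j <- i
  }
  inside
}

# signed area of a polygon (shoelace); positive when vertices turn
# counter-clockwise in the (x, y) frame
polygon_area <- function(poly) {
  x <- poly[, 1L]; y <- poly[, 2L]
  n <- nrow(poly)
  j <- c(n, seq_len(n - 1L))
  sum(x[j] * y - x * y[j]) / 2
}

# derive a reproducible 32-bit sub-seed from a master seed and an index
sub_seed <- function(seed, i) {
  (as.double(seed) * 48271 + i * 7919) %% 2147483647
}
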