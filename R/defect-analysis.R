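#' Winding number of the director along a closed path
#'
#' The topological charge enclosed by a loop is the net rotation of the
#' director along it divided by 2*pi. The path is resampled at half-pixel
#' spacing, the director is interpolated at each sample, and successive
#' angle increments are wrapped into `(-pi/2, pi/2]` (the line field is only
#' defined modulo pi). The result is quantized to the nearest multiple of
#' 1/2.
#'
#' @param field a [director_field()].
#' @param path two-column matrix of (x, y) vertices in micrometres. The path
#'   must be closed (first and last vertex equal, or it is closed
#'   implicitly) and must avoid defect cores and masked nodes.
#' @return the enclosed topological charge (multiple of 1/2); `NA` if any
#'   sample falls outside the valid domain.
#' @export
winding_number <- function(field, path) {
  stopifnot(is.matrix(path), ncol(path) == 2, nrow(path) >= 3)
  if (sqrt(sum((path[1, ] - path[nrow(path), ])^2)) > 1e-9) {
    path <- rbind(path, path[1, ])
  }
  path <- densify_path(path, field$pixel_size / 2)
  ang <- sample_director(field, path[, 1], path[, 2])
  if (anyNA(ang)) return(NA_real_)
  inc <- nematic_diff(ang[-1], ang[-length(ang)])
  # total director rotation divided by 2*pi, quantized to multiples of 1/2
  round(sum(inc) / (2 * pi) * 2) / 2
}

# resample a polyline so consecutive points are at most `step` apart
densify_path <- function(path, step) {
  segs <- sqrt(diff(path[, 1])^2 + diff(path[, 2])^2)
  out <- list(path[1, , drop = FALSE])
  for (i in seq_along(segs)) {
    n <- max(1L, ceiling(segs[i] / step))
    tt <- seq_len(n) / n
    out[[i + 1L]] <- cbind(path[i, 1] + tt * (path[i + 1, 1] - path[i, 1]),
                           path[i, 2] + tt * (path[i + 1, 2] - path[i, 2]))
  }
  do.call(rbind, out)
}

#' Topological charge per grid plaquette
#'
#' Discrete charge density: for every elementary grid square the director
#' winding over its four corners (increments wrapped to `(-pi/2, pi/2]`) is
#' computed and divided by the plaquette area. The discrete winding is
#' exactly quantized, so a defect-free plaquette contributes 0 and a core
#' plaquette +/-1/2; summed over any region (times the area) it equals the
#' winding number of the region boundary.
#'
#' @param field a [director_field()].
#' @return a matrix of size `(rows-1) x (cols-1)` with charge density in
#'   1/um^2; `NA` where a corner is masked. The quantized per-plaquette
#'   charge is attached as attribute `"charge"`.
#' @export
charge_density <- function(field) {
  a <- field$angle
  nr <- nrow(a); nc <- ncol(a)
  a11 <- a[-nr, -nc]; a12 <- a[-nr, -1]
  a22 <- a[-1, -1]; a21 <- a[-1, -nc]
  w <- nematic_diff(a12, a11) + nematic_diff(a22, a12) +
    nematic_diff(a21, a22) + nematic_diff(a11, a21)
  k <- round(w / (2 * pi) * 2) / 2
  bad <- !(field$mask[-nr, -nc] & field$mask[-nr, -1] &
             field$mask[-1, -1] & field$mask[-1, -nc])
  k[bad] <- NA_real_
  dens <- k / field$pixel_size^2
  attr(dens, "charge") <- k
  dens
}

#' Detect half-integer defects in a director field
#'
#' Non-zero plaquettes of the discrete charge density are clustered by
#' single-linkage at `min_separation`; each cluster becomes one defect with
#' charge equal to the cluster's summed plaquette winding and position at
#' the |charge|-weighted centroid of the plaquette centres. For every +1/2
#' defect the comet axis is estimated from the divergence of the Q tensor
#' on a small ring around the core ([defect_axis()]).
#'
#' @param field a [director_field()].
#' @param min_separation merge radius in micrometres.
#' @param ring_radius ring radius for the axis estimate, micrometres
#'   (default 4 px).
#' @return a data.frame with columns `x`, `y` (um), `charge`, `axis_x`,
#'   `axis_y` (unit axis for +1/2 defects, `NA` otherwise); zero rows if the
#'   field is defect-free.
#' @export
detect_defects <- function(field, min_separation = 3 * field$pixel_size,
                           ring_radius = 4 * field$pixel_size) {
  px <- field$pixel_size
  k <- attr(charge_density(field), "charge")
  hit <- which(!is.na(k) & abs(k) >= 0.25, arr.ind = TRUE)
  empty <- data.frame(x = numeric(0), y = numeric(0), charge = numeric(0),
                      axis_x = numeric(0), axis_y = numeric(0))
  if (nrow(hit) == 0) return(empty)
  # plaquette centre positions (half-pixel offset from the corner node)
  xs <- (hit[, 2] - 1) * px + px / 2
  ys <- (hit[, 1] - 1) * px + px / 2
  ch <- k[hit]
  if (nrow(hit) == 1) {
    grp <- 1L
  } else {
    grp <- stats::cutree(
      stats::hclust(stats::dist(cbind(xs, ys)), method = "single"),
      h = min_separation
    )
  }
  q <- director_to_q(field)
  out <- lapply(unique(grp), function(g) {
    i <- grp == g
    w <- abs(ch[i])
    cx <- sum(xs[i] * w) / sum(w)
    cy <- sum(ys[i] * w) / sum(w)
    charge <- round(sum(ch[i]) * 2) / 2
    ax <- c(NA_real_, NA_real_)
    if (abs(charge - 0.5) < 1e-9) {
      ax <- tryCatch(defect_axis(q, cx, cy, ring_radius),
                     error = function(e) c(NA_real_, NA_real_))
    }
    data.frame(x = cx, y = cy, charge = charge, axis_x = ax[1], axis_y = ax[2])
  })
  res <- do.call(rbind, out)
  res[res$charge != 0, , drop = FALSE]
}

# divergence of Q as two component grids (central differences)
q_divergence <- function(q) {
  gxx <- grad_xy(q$qxx, h = q$pixel_size)
  gxy <- grad_xy(q$qxy, h = q$pixel_size)
  list(x = gxx$x + gxy$y, # d_x Qxx + d_y Qxy
       y = gxy$x - gxx$y) # d_x Qxy + d_y Qyy, with Qyy = -Qxx
}

# bilinear sampling of an arbitrary scalar grid at micron positions
sample_grid <- function(m, px, x, y) {
  nr <- nrow(m); nc <- ncol(m)
  cj <- x / px + 1; ri <- y / px + 1
  j0 <- pmin(pmax(floor(cj), 1), nc - 1)
  i0 <- pmin(pmax(floor(ri), 1), nr - 1)
  fx <- pmin(pmax(cj - j0, 0), 1)
  fy <- pmin(pmax(ri - i0, 0), 1)
  idx <- function(i, j) (j - 1) * nr + i
  (1 - fx) * (1 - fy) * m[idx(i0, j0)] + fx * (1 - fy) * m[idx(i0, j0 + 1)] +
    (1 - fx) * fy * m[idx(i0 + 1, j0)] + fx * fy * m[idx(i0 + 1, j0 + 1)]
}

#' Axis of a +1/2 defect from the divergence of Q
#'
#' The comet axis of a +1/2 defect is the normalized average of `div Q`
#' sampled on a ring around the core. With the convention
#' `Q = S (n (x) n - I/2)`, `div Q` of the canonical comet points from the
#' core toward the side on which the director is parallel to the axis (the
#' comet "head"), so the returned unit vector is that average direction.
#'
#' @param q a `q_tensor_field` from [director_to_q()].
#' @param x,y core position, micrometres.
#' @param ring_radius ring radius, micrometres.
#' @param n_ring number of ring samples.
#' @return unit 2-vector `c(axis_x, axis_y)`.
#' @export
defect_axis <- function(q, x, y, ring_radius = 4 * q$pixel_size, n_ring = 36L) {
  dq <- q_divergence(q)
  th <- seq(0, 2 * pi, length.out = n_ring + 1L)[-1L]
  rx <- x + ring_radius * cos(th)
  ry <- y + ring_radius * sin(th)
  w <- field_extent_clip(q, rx, ry)
  if (!any(w)) stop("axis ring lies outside the field")
  vx <- sample_grid(dq$x, q$pixel_size, rx[w], ry[w])
  vy <- sample_grid(dq$y, q$pixel_size, rx[w], ry[w])
  ok <- is.finite(vx) & is.finite(vy)
  mx <- mean(vx[ok]); my <- mean(vy[ok])
  nrm <- sqrt(mx^2 + my^2)
  if (!is.finite(nrm) || nrm < 1e-9) {
    stop("divergence of Q vanishes on the ring; axis undefined")
  }
  c(mx / nrm, my / nrm)
}

# TRUE where (x, y) is inside the grid extent of a q_tensor_field (with a
# one-pixel safety margin for the divergence stencil)
field_extent_clip <- function(q, x, y) {
  px <- q$pixel_size
  w <- (ncol(q$qxx) - 1) * px
  h <- (nrow(q$qxx) - 1) * px
  x >= px & x <= w - px & y >= px & y <= h - px
}

#' Write a defect table to CSV
#'
#' @param defects data.frame from [detect_defects()].
#' @param path output path.
#' @export
write_defects_csv <- function(defects, path) {
  utils::write.csv(
    stats::setNames(defects, c("x_um", "y_um", "charge", "axis_x", "axis_y")),
    path, row.names = FALSE
  )
  invisible(path)
}
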