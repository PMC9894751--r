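#' Velocity-director order parameter
#'
#' `S_v = 2 (n . v / |v|)^2 - 1` measures the alignment of a particle's
#' velocity with the local director: 1 when parallel, -1 when orthogonal, 0
#' at 45 degrees. It is invariant under both `n -> -n` and `v -> -v`, as
#' required for a nematic read-out.
#'
#' @param n_angle director angle(s), radians.
#' @param vx,vy velocity components (any units; only the direction enters).
#' @return `S_v` in `[-1, 1]`; `NA` where `|v| = 0` (signalled with a
#'   warning).
#' @export
order_parameter <- function(n_angle, vx, vy) {
  v <- sqrt(vx^2 + vy^2)
  bad <- v == 0
  if (any(bad, na.rm = TRUE)) warning("zero-velocity samples: S_v undefined there")
  dotp <- (cos(n_angle) * vx + sin(n_angle) * vy) / v
  out <- 2 * dotp^2 - 1
  out[bad] <- NA_real_
  out
}

#' Pearson correlation between two images
#'
#' Both images are lightly smoothed, block-averaged down to a common
#' working size to suppress pixel noise, and compared with the Pearson
#' correlation coefficient
#' `r = sum((I1 - m1)(I2 - m2)) / (sigma1 sigma2 N)`. Used to score
#' simulated occupancy images against reference occupancy/time-projection
#' images.
#'
#' @param img1,img2 numeric matrices covering the same physical extent
#'   (shapes may differ; each is reduced to the working size
#'   independently).
#' @param smooth_sd Gaussian smoothing sigma in pixels (applied before the
#'   reduction).
#' @param downsample_to target side of the working image (default 256; the
#'   image is never upsampled).
#' @return Pearson `r` in `[-1, 1]`.
#' @export
pearson_images <- function(img1, img2, smooth_sd = 1, downsample_to = 256L) {
  a <- reduce_image(img1, smooth_sd, downsample_to)
  b <- reduce_image(img2, smooth_sd, downsample_to)
  stopifnot(all(dim(a) == dim(b)))
  if (stats::sd(a) == 0 || stats::sd(b) == 0) {
    stop("zero-variance image: Pearson correlation undefined")
  }
  stats::cor(as.vector(a), as.vector(b))
}

# smooth then block-average a matrix down to about `target` per side
reduce_image <- function(img, smooth_sd, target) {
  if (smooth_sd > 0) img <- gaussian_blur(img, smooth_sd)
  f <- max(1L, floor(min(dim(img)) / target))
  if (f == 1L) return(img)
  nr <- (nrow(img) %/% f) * f
  nc <- (ncol(img) %/% f) * f
  img <- img[seq_len(nr), seq_len(nc)]
  blocked <- array(img, c(f, nr %/% f, f, nc %/% f))
  apply(blocked, c(2, 4), mean)
}

#' Fraction of particles exiting a defect on the preferred side
#'
#' Given the side counts `n1` and `n2` of particles leaving a +1/2 defect
#' on either side of its axis, the bias is `max(n1, n2) / (n1 + n2)`
#' (in `[0.5, 1]`). Because the counts are small in practice, a two-sided
#' exact binomial p-value against an unbiased 0.5 split is reported with
#' the fraction.
#'
#' @param n1,n2 non-negative integer counts.
#' @return a list with `fraction`, `n1`, `n2` and `p_value`.
#' @export
direction_fraction <- function(n1, n2) {
  stopifnot(n1 >= 0, n2 >= 0)
  if (n1 + n2 < 1) stop("no exits counted: fraction undefined")
  list(fraction = max(n1, n2) / (n1 + n2), n1 = n1, n2 = n2,
       p_value = stats::binom.test(max(n1, n2), n1 + n2, 0.5)$p.value)
}

#' Classify trajectory exits at a +1/2 defect
#'
#' Counts, for every passage of a simulated particle through a defect, the
#' side of the defect axis on which it leaves. A passage qualifies when the
#' particle dwells within `d` of the core (it actually visited the defect);
#' the exit is the first subsequent crossing of the gate radius `2 d`
#' moving outward, and its side is the sign of the velocity component
#' transverse to the defect axis at that crossing. Crossings with a
#' negligible transverse component are discarded as ambiguous.
#'
#' @param sim a `glide_sim` object.
#' @param defect one row of a [detect_defects()] table (+1/2 with axis).
#' @param d gate scale, micrometres (the gate radius is `2 d`).
#' @return a list with counts `n1` (transverse component > 0, i.e. toward
#'   the +90 degree side of the axis), `n2` (other side), and `n_ambiguous`.
#' @export
classify_exits <- function(sim, defect, d = 2) {
  ax <- c(defect$axis_x, defect$axis_y)
  tv <- c(-ax[2], ax[1]) # transverse unit vector (+90 deg from the axis)
  gate <- 2 * d
  n1 <- 0L; n2 <- 0L; amb <- 0L
  for (p in seq_len(ncol(sim$x))) {
    rx <- sim$x[, p] - defect$x
    ry <- sim$y[, p] - defect$y
    rr <- sqrt(rx^2 + ry^2)
    inside <- rr < d
    k <- 1L
    n <- length(rr)
    while (k <= n) {
      if (!inside[k]) { k <- k + 1L; next }
      # dwelled near the core: find the first outward gate crossing
      ex <- k
      while (ex < n && rr[ex] <= gate) ex <- ex + 1L
      if (rr[ex] > gate) {
        ux <- sim$x[ex, p] - sim$x[ex - 1L, p]
        uy <- sim$y[ex, p] - sim$y[ex - 1L, p]
        side <- ux * tv[1] + uy * tv[2]
        nrm <- sqrt(ux^2 + uy^2)
        if (nrm > 0 && abs(side) / nrm > 0.05) {
          if (side > 0) n1 <- n1 + 1L else n2 <- n2 + 1L
        } else {
          amb <- amb + 1L
        }
      }
      # skip until the particle has fully left the gate region
      while (k <= n && rr[k] <= gate) k <- k + 1L
    }
  }
  list(n1 = n1, n2 = n2, n_ambiguous = amb)
}

#' Detect closed loops in trajectories or streamlines
#'
#' A loop is a section of a path that returns within `closure_tol` of an
#' earlier point with direction agreement better than 45 degrees. Each loop
#' is recorded with its chirality (sign of the signed polygon area in the
#' package's x-right / y-down frame), the topological charge enclosed
#' (director winding number along the loop), and, when a ground-truth or
#' detected defect table is supplied, the numbers of +1/2 and -1/2 defects
#' inside the polygon. For polar loops the enclosed charge must be +1 and
#' hence `n_plus - n_minus = 2`.
#'
#' @param paths a list of two-column point matrices (x, y in um), a
#'   `glide_sim` object, or a list of `streamline` objects.
#' @param field a [director_field()] used for the winding number.
#' @param defects optional defect table with columns `x`, `y`, `charge`.
#' @param closure_tol closure distance, micrometres.
#' @param min_perimeter shortest accepted loop perimeter, micrometres
#'   (suppresses jitter-scale self-crossings).
#' @param edge_margin loops coming within this distance (um) of the
#'   rectangular grid border are discarded: circuits closed by reflections
#'   off the finite observation window are artifacts, not polar loops. The
#'   rim of a confining disc is interior to the grid, so genuine edge
#'   currents under confinement are unaffected.
#' @return data.frame with one row per loop: `path_id`, `chirality` (`"CW"`
#'   or `"CCW"`), `signed_area`, `enclosed_charge`, `n_plus`, `n_minus`,
#'   `perimeter`; plus attribute `"polygons"` holding the loop polygons.
#' @export
detect_loops <- function(paths, field, defects = NULL, closure_tol = 1,
                         min_perimeter = 10, edge_margin = 2) {
  pts_list <- as_path_list(paths)
  w <- field_width(field); h <- field_height(field)
  recs <- list()
  polys <- list()
  for (pid in seq_along(pts_list)) {
    pts <- pts_list[[pid]]
    if (is.null(pts) || nrow(pts) < 10) next
    loop <- find_loop(pts, closure_tol, min_perimeter)
    if (is.null(loop)) next
    poly <- pts[loop[1]:loop[2], , drop = FALSE]
    if (edge_margin > 0 &&
        (min(poly[, 1]) < edge_margin || max(poly[, 1]) > w - edge_margin ||
         min(poly[, 2]) < edge_margin || max(poly[, 2]) > h - edge_margin)) {
      next
    }
    area <- polygon_area(poly)
    # enclosed charge and defect counts on the CCW-oriented polygon, so a
    # loop encloses the same charge whichever way it was traversed
    ccw <- if (area > 0) poly else poly[rev(seq_len(nrow(poly))), , drop = FALSE]
    k <- winding_number(field, ccw)
    # loops hugging a confinement rim can sample masked nodes; the winding
    # is homotopy-invariant, so retry on a slightly inward-pulled polygon
    shrink <- 1
    while (is.na(k) && shrink <= 3) {
      k <- winding_number(field, pull_inward(ccw, shrink))
      shrink <- shrink + 1
    }
    npm <- c(NA_integer_, NA_integer_)
    if (!is.null(defects) && nrow(defects) > 0) {
      inside <- point_in_polygon(defects$x, defects$y, poly)
      npm <- c(sum(inside & abs(defects$charge - 0.5) < 1e-9),
               sum(inside & abs(defects$charge + 0.5) < 1e-9))
    }
    recs[[length(recs) + 1L]] <- data.frame(
      path_id = pid,
      chirality = if (area > 0) "CCW" else "CW",
      signed_area = area,
      enclosed_charge = k,
      n_plus = npm[1], n_minus = npm[2],
      perimeter = sum(sqrt(diff(poly[, 1])^2 + diff(poly[, 2])^2))
    )
    polys[[length(polys) + 1L]] <- poly
  }
  out <- if (length(recs)) do.call(rbind, recs) else
    data.frame(path_id = integer(0), chirality = character(0),
               signed_area = numeric(0), enclosed_charge = numeric(0),
               n_plus = integer(0), n_minus = integer(0),
               perimeter = numeric(0))
  attr(out, "polygons") <- polys
  out
}

as_path_list <- function(paths) {
  if (inherits(paths, "glide_sim")) {
    lapply(seq_len(ncol(paths$x)), function(p) cbind(paths$x[, p], paths$y[, p]))
  } else if (is.list(paths) && length(paths) > 0 &&
             inherits(paths[[1]], "streamline")) {
    lapply(paths, function(s) s$points)
  } else if (is.matrix(paths)) {
    list(paths)
  } else {
    paths
  }
}

# first closure (i, j) with j > i, |p_j - p_i| < tol, arc length > min_per,
# direction agreement > cos 45 deg and turning number +/-1 (a polar loop is
# a simple circuit traversed once: the heading makes one full 2*pi
# rotation, which excludes back-and-forth circuits closed by boundary
# reflections). Subsampled scan for speed.
find_loop <- function(pts, tol, min_per) {
  n <- nrow(pts)
  seg <- sqrt(diff(pts[, 1])^2 + diff(pts[, 2])^2)
  arc <- c(0, cumsum(seg))
  step <- max(1L, floor(n / 4000L))
  cand_j <- seq(2L, n, by = step)
  for (j in cand_j) {
    lo <- which(arc <= arc[j] - min_per)
    if (length(lo) == 0) next
    old <- seq_len(max(lo))
    d2 <- (pts[old, 1] - pts[j, 1])^2 + (pts[old, 2] - pts[j, 2])^2
    hit <- which(d2 <= tol^2)
    if (length(hit) == 0) next
    i <- hit[which.min(d2[hit])]
    vi <- pts[min(i + 1L, n), ] - pts[i, ]
    vj <- pts[j, ] - pts[max(j - 1L, 1L), ]
    ni <- sqrt(sum(vi^2)); nj <- sqrt(sum(vj^2))
    if (ni > 1e-12 && nj > 1e-12 &&
        sum(vi * vj) / (ni * nj) > cos(pi / 4) &&
        abs(turning_number(pts[i:j, , drop = FALSE])) == 1L) {
      return(c(i, j))
    }
  }
  NULL
}

# pull every vertex of a polygon a fixed distance toward its centroid
pull_inward <- function(poly, dist) {
  cx <- mean(poly[, 1]); cy <- mean(poly[, 2])
  dx <- cx - poly[, 1]; dy <- cy - poly[, 2]
  nn <- pmax(sqrt(dx^2 + dy^2), 1e-9)
  f <- pmin(dist / nn, 0.5)
  cbind(poly[, 1] + f * dx, poly[, 2] + f * dy)
}

# net rotation of the path tangent around a closed polyline, in turns;
# the polyline is decimated to ~1 um segments so sample noise cancels
turning_number <- function(poly) {
  seg <- sqrt(diff(poly[, 1])^2 + diff(poly[, 2])^2)
  arc <- c(0, cumsum(seg))
  keep <- !duplicated(floor(arc))
  poly <- poly[keep, , drop = FALSE]
  if (nrow(poly) < 4) return(0L)
  hx <- diff(poly[, 1]); hy <- diff(poly[, 2])
  h <- atan2(hy, hx)
  as.integer(round(sum(heading_diff(h[-1], h[-length(h)])) / (2 * pi)))
}

#' Edge-current statistics of a confined simulation
#'
#' Within an annular band at the disc edge, particles are classified per
#' recorded frame as clockwise or counter-clockwise from the sign of the
#' tangential component of their displacement (in the x-right / y-down
#' frame, positive `x vy - y vx` about the centre is CW on screen). Also
#' returns the mean distance from the centre over time, optionally per
#' initial-handedness group.
#'
#' @param sim a `glide_sim` on a confined field.
#' @param band band width as a fraction of the confinement radius.
#' @param groups optional integer vector (one per particle) splitting the
#'   radius statistics by group.
#' @return a list with data.frames `counts` (`t_s`, `n_cw`, `n_ccw`,
#'   `cw_minus_ccw`, `n_band`) and `radius` (`t_s`, `group`, `mean_r`,
#'   `sd_r`).
#' @export
edge_stats <- function(sim, band = 0.15, groups = NULL) {
  if (is.null(sim$confine)) stop("edge statistics require a confined simulation")
  cx <- sim$confine$cx; cy <- sim$confine$cy; R <- sim$confine$R
  nrec <- nrow(sim$x)
  if (is.null(groups)) groups <- rep(1L, ncol(sim$x))
  rx <- sim$x - cx
  ry <- sim$y - cy
  rr <- sqrt(rx^2 + ry^2)
  vx <- rbind(NA, diff(sim$x))
  vy <- rbind(NA, diff(sim$y))
  # tangential sign about the centre: positive = CW in the y-down frame
  tsign <- sign(rx * vy - ry * vx)
  in_band <- rr >= (1 - band) * R
  n_cw <- rowSums(in_band & tsign > 0, na.rm = TRUE)
  n_ccw <- rowSums(in_band & tsign < 0, na.rm = TRUE)
  counts <- data.frame(t_s = sim$t, n_cw = n_cw, n_ccw = n_ccw,
                       cw_minus_ccw = n_cw - n_ccw,
                       n_band = rowSums(in_band))
  radius <- do.call(rbind, lapply(sort(unique(groups)), function(g) {
    sel <- groups == g
    data.frame(t_s = sim$t, group = g,
               mean_r = rowMeans(rr[, sel, drop = FALSE]),
               sd_r = apply(rr[, sel, drop = FALSE], 1, stats::sd))
  }))
  list(counts = counts, radius = radius)
}
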