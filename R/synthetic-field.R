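#' Defect and field specifications for synthetic nematics
#'
#' Ground-truth director fields are built from the standard one-elastic-
#' constant multi-defect ansatz: the director angle is
#' `phi(r) = phi0 + sum_i k_i * atan2(y - y_i, x - x_i)`, where `k_i` are
#' half-integer topological charges. The winding number around any loop is
#' then exactly the sum of the enclosed charges, which makes the generated
#' fields a sharp oracle for the defect-detection and simulation stages.
#'
#' @param x,y defect core position in micrometres.
#' @param charge topological charge; must be an integer multiple of 1/2
#'   (+/-1/2 in the self-assembled nematics emulated here; +/-1 is accepted
#'   for composite tests).
#' @param phase phase offset of the defect's own term, radians.
#' @return `defect_spec`: a one-row data.frame; `field_spec`: a list of class
#'   `field_spec`.
#' @export
defect_spec <- function(x, y, charge, phase = 0) {
  if (abs(charge * 2 - round(charge * 2)) > 1e-9) {
    stop("defect charge must be an integer multiple of 1/2")
  }
  data.frame(x = x, y = y, charge = charge, phase = phase)
}

#' @param shape grid shape `c(rows, cols)` in pixels.
#' @param pixel_size micrometres per pixel.
#' @param phi0 uniform background director angle, radians.
#' @param defects a data.frame of stacked [defect_spec()] rows (possibly
#'   zero rows for a uniform field).
#' @param confine_radius radius of a circular confinement in micrometres, or
#'   `NULL` for an unconfined field. When set, the disc must fit in the grid
#'   and the defect charges must sum to +1.
#' @param min_sep minimum pairwise core separation enforced between defects,
#'   micrometres.
#' @rdname defect_spec
#' @export
field_spec <- function(shape, pixel_size, phi0 = 0, defects = NULL,
                       confine_radius = NULL, min_sep = 2 * pixel_size) {
  if (is.null(defects)) {
    defects <- data.frame(x = numeric(0), y = numeric(0),
                          charge = numeric(0), phase = numeric(0))
  }
  w <- (shape[2] - 1) * pixel_size
  h <- (shape[1] - 1) * pixel_size
  if (nrow(defects) > 0) {
    if (any(defects$x < 0 | defects$x > w | defects$y < 0 | defects$y > h)) {
      stop("defect positions must lie inside the grid")
    }
    if (nrow(defects) > 1) {
      dmin <- min(stats::dist(defects[, c("x", "y")]))
      if (dmin < min_sep) {
        stop(sprintf("defects closer than min_sep (%.3g < %.3g um)", dmin, min_sep))
      }
    }
  }
  if (!is.null(confine_radius)) {
    cx <- w / 2; cy <- h / 2
    if (confine_radius > min(cx, cy)) stop("confinement disc does not fit in the grid")
    if (nrow(defects) == 0 || abs(sum(defects$charge) - 1) > 1e-9) {
      stop("a confined disc requires total defect charge +1 (Poincare-Hopf)")
    }
    rr <- sqrt((defects$x - cx)^2 + (defects$y - cy)^2)
    if (any(rr >= confine_radius)) stop("confined defects must lie strictly inside the disc")
  }
  structure(
    list(shape = as.integer(shape), pixel_size = as.numeric(pixel_size),
         phi0 = as.numeric(phi0), defects = defects,
         confine_radius = confine_radius),
    class = "field_spec"
  )
}

# analytic multi-defect angle at arbitrary positions (micrometres)
ansatz_angle <- function(spec, x, y) {
  phi <- rep(spec$phi0, length(x))
  d <- spec$defects
  for (i in seq_len(nrow(d))) {
    phi <- phi + d$charge[i] * atan2(y - d$y[i], x - d$x[i]) + d$phase[i]
  }
  phi
}

#' Build a director field from a specification
#'
#' Evaluates the multi-defect ansatz on the grid. Defect cores falling
#' exactly on a grid node are shifted by half a pixel so the angle is defined
#' at every node. For confined specs the field is restricted to the disc and
#' a global phase is chosen so the rim director is as tangential as possible
#' (see [make_confined_field()]).
#'
#' @param spec a [field_spec()].
#' @return a [director_field()].
#' @export
make_field <- function(spec) {
  stopifnot(inherits(spec, "field_spec"))
  px <- spec$pixel_size
  nr <- spec$shape[1]; nc <- spec$shape[2]
  d <- spec$defects
  # avoid singular evaluation at a node
  on_node <- (d$x / px) %% 1 < 1e-9 & (d$y / px) %% 1 < 1e-9
  d$x[on_node] <- d$x[on_node] + px / 2
  d$y[on_node] <- d$y[on_node] + px / 2
  spec$defects <- d
  xg <- rep((seq_len(nc) - 1) * px, each = nr)
  yg <- rep((seq_len(nr) - 1) * px, times = nc)
  phi <- matrix(ansatz_angle(spec, xg, yg), nr, nc)
  mask <- NULL
  if (!is.null(spec$confine_radius)) {
    cx <- (nc - 1) * px / 2; cy <- (nr - 1) * px / 2
    rg <- sqrt((matrix(xg, nr, nc) - cx)^2 + (matrix(yg, nr, nc) - cy)^2)
    mask <- rg <= spec$confine_radius
    # rotate the global phase so the rim director is closest to tangential
    rim <- which(mask & rg > 0.92 * spec$confine_radius)
    theta_rim <- atan2(matrix(yg, nr, nc)[rim] - cy, matrix(xg, nr, nc)[rim] - cx)
    dev <- 2 * (phi[rim] - (theta_rim + pi / 2))
    shift <- atan2(mean(sin(dev)), mean(cos(dev))) / 2
    phi <- phi - shift
  }
  fld <- director_field(phi, px, mask)
  attr(fld, "spec") <- spec
  fld
}

#' Random multi-defect field specification
#'
#' Rejection-samples defect cores with a minimum pairwise separation inside a
#' central window of the grid, and assigns half-integer charges in shuffled
#' order so they sum to the requested net charge.
#'
#' @param n_defects number of defects; must have the same parity as
#'   `2 * net_charge`.
#' @param net_charge total topological charge (integer multiple of 1/2).
#' @param shape,pixel_size,phi0 as in [field_spec()].
#' @param min_sep minimum core separation, micrometres (default 10 px).
#' @param margin fraction of the grid kept defect-free at the borders.
#' @param seed RNG seed.
#' @return a [field_spec()].
#' @export
random_field_spec <- function(n_defects, net_charge = 0, shape = c(128L, 128L),
                              pixel_size = 1, phi0 = NULL,
                              min_sep = 10 * pixel_size, margin = 0.15,
                              seed = 1L) {
  n_plus <- n_defects / 2 + net_charge
  n_minus <- n_defects / 2 - net_charge
  if (n_plus %% 1 != 0 || n_plus < 0 || n_minus < 0) {
    stop("n_defects and net_charge are incompatible with +/-1/2 charges")
  }
  set.seed(seed)
  w <- (shape[2] - 1) * pixel_size
  h <- (shape[1] - 1) * pixel_size
  lo_x <- margin * w; hi_x <- (1 - margin) * w
  lo_y <- margin * h; hi_y <- (1 - margin) * h
  pts <- matrix(numeric(0), 0, 2)
  tries <- 0L
  while (nrow(pts) < n_defects) {
    cand <- c(stats::runif(1, lo_x, hi_x), stats::runif(1, lo_y, hi_y))
    if (nrow(pts) == 0 ||
        min(sqrt((pts[, 1] - cand[1])^2 + (pts[, 2] - cand[2])^2)) >= min_sep) {
      pts <- rbind(pts, cand)
    }
    tries <- tries + 1L
    if (tries > 20000L) stop("could not place defects at the requested separation")
  }
  charges <- sample(c(rep(0.5, n_plus), rep(-0.5, n_minus)))
  if (is.null(phi0)) phi0 <- stats::runif(1, 0, pi)
  field_spec(shape, pixel_size, phi0,
             defects = data.frame(x = pts[, 1], y = pts[, 2],
                                  charge = charges, phase = 0),
             min_sep = min_sep)
}

#' Confined disc nematic with total charge +1
#'
#' On a disc with tangential-type boundary the Poincare-Hopf theorem fixes
#' the total enclosed topological charge at +1; with only half-integer
#' defects this requires `n_plus - n_minus = 2`. Cores are rejection-sampled
#' inside 0.55 R_c (negative defects slightly further out than positive
#' ones), the interior ansatz is evaluated, and a global phase is fitted so
#' the rim director is approximately tangential. No elastic relaxation is
#' performed: the construction gives exact defect bookkeeping, not a
#' minimum-energy texture.
#'
#' @param R_c confinement radius, micrometres.
#' @param n_plus,n_minus numbers of +1/2 and -1/2 defects
#'   (`n_plus - n_minus` must equal 2).
#' @param pixel_size micrometres per pixel; the grid is sized to hold the
#'   disc with a small border.
#' @param min_sep minimum core separation, micrometres.
#' @param rim_tilt constant angle (radians) added to the whole texture after
#'   the tangential phase fit, turning the rim anchoring into a spiral.
#'   Self-assembled confined nematics generically carry such a chiral tilt;
#'   it is what makes one edge handedness dynamically stable. 0 gives the
#'   achiral (phase-fitted) texture.
#' @param seed RNG seed.
#' @return a [director_field()] masked to the disc, with the generating
#'   `field_spec` attached as attribute `"spec"`.
#' @export
make_confined_field <- function(R_c, n_plus, n_minus = n_plus - 2L,
                                pixel_size = 1, min_sep = 10 * pixel_size,
                                rim_tilt = 0, seed = 1L) {
  if (n_plus - n_minus != 2) {
    stop("confined disc requires n_plus - n_minus = 2 (total charge +1)")
  }
  if (n_plus < 2) stop("at least two +1/2 defects are required in a disc")
  set.seed(seed)
  n <- n_plus + n_minus
  npx <- 2L * ceiling(R_c / pixel_size) + 9L
  cx <- (npx - 1) * pixel_size / 2
  # positive cores toward the centre, negative ones in an annulus
  r_max <- c(rep(0.45 * R_c, n_plus), rep(0.6 * R_c, n_minus))
  r_min <- c(rep(0, n_plus), rep(0.3 * R_c, n_minus))
  pts <- matrix(numeric(0), 0, 2)
  tries <- 0L
  while (nrow(pts) < n) {
    i <- nrow(pts) + 1L
    rr <- sqrt(stats::runif(1, (r_min[i] / R_c)^2, (r_max[i] / R_c)^2)) * R_c
    th <- stats::runif(1, 0, 2 * pi)
    cand <- c(cx + rr * cos(th), cx + rr * sin(th))
    if (nrow(pts) == 0 ||
        min(sqrt((pts[, 1] - cand[1])^2 + (pts[, 2] - cand[2])^2)) >= min_sep) {
      pts <- rbind(pts, cand)
    }
    tries <- tries + 1L
    if (tries > 20000L) stop("could not place defects at the requested separation")
  }
  charges <- c(rep(0.5, n_plus), rep(-0.5, n_minus))
  spec <- field_spec(c(npx, npx), pixel_size, phi0 = 0,
                     defects = data.frame(x = pts[, 1], y = pts[, 2],
                                          charge = charges, phase = 0),
                     confine_radius = R_c, min_sep = min_sep)
  fld <- make_field(spec)
  if (rim_tilt != 0) {
    fld$angle <- wrap_pi(fld$angle + rim_tilt)
    sp <- attr(fld, "spec")
    sp$rim_tilt <- rim_tilt
    attr(fld, "spec") <- sp
  }
  fld
}

#' Asymmetric +1/2 defect field
#'
#' A canonical +1/2 comet defect (axis along +x) with a smooth, localized
#' director twist just past the core, so that the director sampled at the
#' streamline seed point (2 um along the axis) meets the axis at
#' `skew_angle`. The twist is a Gaussian bump centred at the seed point; it
#' carries no winding, so the defect charge and (for small widths) the axis
#' estimated at the core are unchanged. This emulates the local asymmetries
#' that make real defects eject filaments preferentially to one side.
#'
#' @param skew_angle director-axis mismatch at the seed point, radians;
#'   `|skew_angle| < pi/2`.
#' @param d seed offset along the axis, micrometres.
#' @param shape,pixel_size grid geometry.
#' @param twist_width Gaussian width of the twist bump, micrometres.
#' @return a [director_field()]; the core sits at the grid centre and the
#'   defect axis points along +x.
#' @export
make_asymmetric_plus_half <- function(skew_angle, d = 2, shape = c(81L, 81L),
                                      pixel_size = 0.5,
                                      twist_width = d / 2) {
  if (abs(skew_angle) >= pi / 2) stop("|skew_angle| must be < pi/2")
  px <- pixel_size
  nr <- shape[1]; nc <- shape[2]
  cx <- (nc - 1) * px / 2 + px / 2 # half-pixel shift keeps the core off-node
  cy <- (nr - 1) * px / 2 + px / 2
  xg <- matrix(rep((seq_len(nc) - 1) * px, each = nr), nr, nc)
  yg <- matrix(rep((seq_len(nr) - 1) * px, times = nc), nr, nc)
  phi <- 0.5 * atan2(yg - cy, xg - cx)
  bump <- exp(-((xg - cx - d)^2 + (yg - cy)^2) / (2 * twist_width^2))
  fld <- director_field(phi + skew_angle * bump, px)
  attr(fld, "core") <- c(cx, cy)
  attr(fld, "axis") <- c(1, 0)
  fld
}

#' Render a nematic texture image from a director field
#'
#' Draws short line segments (fluorescent-filament stand-ins) at random
#' positions, each locally aligned with the director, then blurs and adds
#' Gaussian noise. Used as ground-truth input for the structure-tensor
#' extractor.
#'
#' @param field a [director_field()].
#' @param filament_length segment length in micrometres (short actin
#'   filaments are ~0.8 um).
#' @param density filaments per square micrometre.
#' @param noise_sd additive Gaussian noise, as a fraction of the peak
#'   segment intensity.
#' @param blur_sd optical blur sigma in micrometres.
#' @param seed RNG seed.
#' @return an intensity matrix in `[0, 1]`, same shape as the field grid.
#' @export
render_nematic_image <- function(field, filament_length = 0.8, density = 3,
                                 noise_sd = 0.05, blur_sd = 0.1, seed = 1L) {
  stopifnot(density >= 0)
  set.seed(seed)
  px <- field$pixel_size
  nr <- nrow(field$angle); nc <- ncol(field$angle)
  w <- field_width(field); h <- field_height(field)
  n_fil <- stats::rpois(1, density * w * h)
  img <- matrix(0, nr, nc)
  if (n_fil > 0) {
    fx <- stats::runif(n_fil, 0, w)
    fy <- stats::runif(n_fil, 0, h)
    ang <- sample_director(field, fx, fy)
    keep <- !is.na(ang)
    img <- rasterize_segments(fx[keep], fy[keep], ang[keep],
                              filament_length, nr, nc, px)
  }
  if (max(img) > 0) img <- img / max(img)
  img <- gaussian_blur(img, blur_sd / px)
  if (max(img) > 0) img <- img / max(img)
  if (noise_sd > 0) img <- img + stats::rnorm(length(img), 0, noise_sd)
  img[img < 0] <- 0
  img[img > 1] <- 1
  img
}

# accumulate line segments (centres, angles, common length, in um) into a
# count image by dense point sampling along each segment
rasterize_segments <- function(x, y, angle, len, nr, nc, px) {
  n_samp <- max(3L, ceiling(len / (px / 2)))
  tt <- seq(-len / 2, len / 2, length.out = n_samp)
  sx <- rep(x, each = n_samp) + rep(tt, times = length(x)) * cos(rep(angle, each = n_samp))
  sy <- rep(y, each = n_samp) + rep(tt, times = length(x)) * sin(rep(angle, each = n_samp))
  jj <- round(sx / px) + 1
  ii <- round(sy / px) + 1
  ok <- ii >= 1 & ii <= nr & jj >= 1 & jj <= nc
  counts <- tabulate((jj[ok] - 1) * nr + ii[ok], nbins = nr * nc)
  matrix(counts, nr, nc)
}

#' Render frames of moving rods from trajectories
#'
#' Draws one rod sprite per agent per frame, oriented along the agent's
#' heading, for testing the tracker and the optical-flow stage. Microtubule
#' stand-ins are ~2 um rods imaged every few seconds.
#'
#' @param traj a data.frame with columns `frame` (1-based), `x`, `y`
#'   (micrometres) and `theta` (radians).
#' @param shape image shape `c(rows, cols)`.
#' @param pixel_size micrometres per pixel.
#' @param rod_length rod length, micrometres.
#' @param blur_sd optical blur sigma, micrometres.
#' @param noise_sd additive Gaussian noise level.
#' @param seed RNG seed for the noise.
#' @return a 3D array `[row, col, frame]` with intensities in `[0, 1]`.
#' @export
render_mt_frames <- function(traj, shape, pixel_size, rod_length = 2,
                             blur_sd = 0.25, noise_sd = 0.02, seed = 1L) {
  set.seed(seed)
  nr <- shape[1]; nc <- shape[2]
  frames <- sort(unique(traj$frame))
  out <- array(0, c(nr, nc, length(frames)))
  for (k in seq_along(frames)) {
    rows <- traj[traj$frame == frames[k], , drop = FALSE]
    img <- rasterize_segments(rows$x, rows$y, rows$theta, rod_length,
                              nr, nc, pixel_size)
    img <- pmin(img, max(1, stats::quantile(img[img > 0], 0.5, names = FALSE)))
    if (max(img) > 0) img <- img / max(img)
    img <- gaussian_blur(img, blur_sd / pixel_size)
    if (max(img) > 0) img <- img / max(img)
    if (noise_sd > 0) img <- img + stats::rnorm(length(img), 0, noise_sd)
    img[img < 0] <- 0; img[img > 1] <- 1
    out[, , k] <- img
  }
  out
}
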