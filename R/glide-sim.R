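#' Parameters of the gliding-particle simulation
#'
#' The simulator integrates non-interacting, point-like self-propelled
#' particles. Each particle moves persistently along its heading
#' `u = (cos theta, sin theta)` at constant speed `v` (dr/dt = v u) and its
#' heading receives an aligning torque toward the local director plus
#' rotational noise:
#'
#'   d theta / dt = A sin(2 (phi(r) - theta)) + sqrt(2 v / L_p) xi,
#'
#' where `phi(r)` is the director angle at the particle position, `A` is the
#' alignment rate and `xi` is unit-variance Gaussian white noise. The noise
#' prefactor makes the free (A = 0) path persistence length equal `L_p`
#' independently of the speed. The torque is pi-periodic in `phi - theta`,
#' respecting the nematic symmetry of the underlying field.
#'
#' @param speed gliding speed `v`, um/s (default 0.1, the measured mean
#'   microtubule speed).
#' @param align_rate alignment rate `A`, rad/s. The disc-confinement runs in
#'   this package use 0.03 rad/s.
#' @param persistence_length free-path persistence length `L_p`, um
#'   (default 100). `Inf` disables the noise (used for closed-form checks).
#' @param dt integration time step, s. The stability guard `A * dt < 0.2`
#'   keeps the deterministic torque update well inside the linear regime.
#' @param n_steps number of Euler-Maruyama steps.
#' @param seed master RNG seed; each particle derives an independent
#'   reproducible stream from it, so adding particles does not perturb
#'   existing ones.
#' @param boundary `"reflect"` (specular reflection of the heading about the
#'   local wall tangent) or `"slide"` (project the heading onto the
#'   tangent).
#' @return a list of class `sim_params`.
#' @export
sim_params <- function(speed = 0.1, align_rate = 0.03,
                       persistence_length = 100, dt = 0.1,
                       n_steps = 1000L, seed = 1L,
                       boundary = c("reflect", "slide")) {
  boundary <- match.arg(boundary)
  stopifnot(speed > 0, persistence_length > 0, align_rate >= 0, dt > 0,
            n_steps >= 1)
  if (align_rate * dt >= 0.2) stop("A * dt must be < 0.2 for stability")
  structure(
    list(speed = speed, align_rate = align_rate,
         persistence_length = persistence_length, dt = dt,
         n_steps = as.integer(n_steps), seed = seed, boundary = boundary),
    class = "sim_params"
  )
}

# one Euler-Maruyama step, vectorized over particles. The heading is updated
# first, then the position moves with the *new* heading, so every step
# displacement has norm exactly v * dt. `xi` is the pre-drawn standard-normal
# vector for this step.
glide_step <- function(x, y, theta, field, params, xi,
                       confine = NULL) {
  v <- params$speed; dt <- params$dt; A <- params$align_rate
  noise_amp <- if (is.finite(params$persistence_length)) {
    sqrt(2 * v * dt / params$persistence_length)
  } else 0
  if (A > 0) {
    s <- sample_double_angle(field, x, y)
    # sin(2(phi - theta)) from the interpolated double angle, renormalized
    nrm <- sqrt(s$c2^2 + s$s2^2)
    good <- is.finite(nrm) & nrm > 1e-12
    torque <- numeric(length(x))
    torque[good] <- (s$s2[good] * cos(2 * theta[good]) -
                       s$c2[good] * sin(2 * theta[good])) / nrm[good]
    theta <- theta + A * torque * dt + noise_amp * xi
  } else {
    theta <- theta + noise_amp * xi
  }
  theta <- wrap_2pi(theta)
  xn <- x + v * cos(theta) * dt
  yn <- y + v * sin(theta) * dt
  out <- handle_boundary(x, y, xn, yn, theta, field, params, confine)
  out
}

# reflect or slide particles whose proposed position leaves the domain
handle_boundary <- function(x, y, xn, yn, theta, field, params, confine) {
  v <- params$speed; dt <- params$dt
  if (!is.null(confine)) {
    cx <- confine$cx; cy <- confine$cy; R <- confine$R
    rr <- sqrt((xn - cx)^2 + (yn - cy)^2)
    out <- which(rr > R)
    for (i in out) {
      nx <- (x[i] - cx); ny <- (y[i] - cy)
      nn <- sqrt(nx^2 + ny^2); if (nn < 1e-12) next
      nx <- nx / nn; ny <- ny / nn # outward normal at the wall contact
      ux <- cos(theta[i]); uy <- sin(theta[i])
      if (params$boundary == "reflect") {
        dotp <- ux * nx + uy * ny
        ux <- ux - 2 * dotp * nx
        uy <- uy - 2 * dotp * ny
      } else { # slide: project onto the tangent
        dotp <- ux * nx + uy * ny
        ux <- ux - dotp * nx
        uy <- uy - dotp * ny
        nrm <- sqrt(ux^2 + uy^2)
        if (nrm < 1e-9) { ux <- -ny; uy <- nx; nrm <- 1 }
        ux <- ux / nrm; uy <- uy / nrm
      }
      theta[i] <- wrap_2pi(atan2(uy, ux))
      xn[i] <- x[i] + v * cos(theta[i]) * dt
      yn[i] <- y[i] + v * sin(theta[i]) * dt
      rr2 <- sqrt((xn[i] - cx)^2 + (yn[i] - cy)^2)
      if (rr2 > R) { # grazing corner case: hold position, keep new heading
        xn[i] <- x[i]; yn[i] <- y[i]
      }
    }
  } else {
    w <- field_width(field); h <- field_height(field)
    # reflect about the violated wall(s) of the rectangular grid
    lo_x <- xn < 0; hi_x <- xn > w
    lo_y <- yn < 0; hi_y <- yn > h
    flip_x <- lo_x | hi_x
    flip_y <- lo_y | hi_y
    if (any(flip_x | flip_y)) {
      ux <- cos(theta); uy <- sin(theta)
      ux[flip_x] <- -ux[flip_x]
      uy[flip_y] <- -uy[flip_y]
      i <- which(flip_x | flip_y)
      theta[i] <- wrap_2pi(atan2(uy[i], ux[i]))
      xn[i] <- x[i] + v * cos(theta[i]) * dt
      yn[i] <- y[i] + v * sin(theta[i]) * dt
      xn[i] <- pmin(pmax(xn[i], 0), w)
      yn[i] <- pmin(pmax(yn[i], 0), h)
    }
  }
  list(x = xn, y = yn, theta = theta)
}

#' Simulate gliding particles in a static director field
#'
#' Euler-Maruyama integration of the equations of motion (see
#' [sim_params()]); the heading is updated before the position, so in the
#' interior every step displacement is exactly `v * dt`. Particles never
#' interact. If the field carries a circular confinement mask, particles are
#' kept inside the disc by the configured boundary rule; otherwise they
#' reflect off the rectangular grid edges.
#'
#' @param field a [director_field()].
#' @param n_particles number of particles.
#' @param params a [sim_params()].
#' @param init `NULL` for uniform-random initial positions and headings, or
#'   a data.frame with columns `x`, `y`, `theta`.
#' @param record_every store every k-th step (k = 1 keeps all samples).
#' @return an object of class `glide_sim`: matrices `x`, `y`, `theta` of
#'   shape `(n_recorded, n_particles)`, the recorded times `t`, the params
#'   and the confinement geometry (or `NULL`).
#' @export
simulate_gliders <- function(field, n_particles, params, init = NULL,
                             record_every = 1L) {
  stopifnot(inherits(field, "director_field"), n_particles >= 1)
  if (!any(field$mask)) stop("field is fully masked")
  confine <- confinement_of(field)
  set.seed(params$seed)
  if (is.null(init)) {
    init <- random_init(field, n_particles, confine)
  }
  stopifnot(nrow(init) == n_particles)
  x <- init$x; y <- init$y; theta <- wrap_2pi(init$theta)
  n_steps <- params$n_steps
  # independent reproducible noise stream per particle
  xi <- matrix(0, n_particles, n_steps)
  if (is.finite(params$persistence_length)) {
    for (i in seq_len(n_particles)) {
      set.seed(sub_seed(params$seed, i))
      xi[i, ] <- stats::rnorm(n_steps)
    }
  }
  rec <- seq(0L, n_steps, by = record_every)
  nrec <- length(rec)
  X <- matrix(NA_real_, nrec, n_particles)
  Y <- X; TH <- X
  X[1, ] <- x; Y[1, ] <- y; TH[1, ] <- theta
  ri <- 2L
  for (s in seq_len(n_steps)) {
    st <- glide_step(x, y, theta, field, params, xi[, s], confine)
    x <- st$x; y <- st$y; theta <- st$theta
    if (ri <= nrec && s == rec[ri]) {
      X[ri, ] <- x; Y[ri, ] <- y; TH[ri, ] <- theta
      ri <- ri + 1L
    }
  }
  structure(
    list(x = X, y = Y, theta = TH, t = rec * params$dt, params = params,
         confine = confine, field_dim = dim(field$angle),
         pixel_size = field$pixel_size),
    class = "glide_sim"
  )
}

# circular confinement geometry from a field generated with a confine_radius
confinement_of <- function(field) {
  spec <- attr(field, "spec")
  if (!is.null(spec) && !is.null(spec$confine_radius)) {
    return(list(cx = field_width(field) / 2, cy = field_height(field) / 2,
                R = spec$confine_radius))
  }
  NULL
}

random_init <- function(field, n, confine) {
  if (!is.null(confine)) {
    rr <- sqrt(stats::runif(n)) * confine$R * 0.98
    th <- stats::runif(n, 0, 2 * pi)
    data.frame(x = confine$cx + rr * cos(th), y = confine$cy + rr * sin(th),
               theta = stats::runif(n, 0, 2 * pi))
  } else {
    data.frame(x = stats::runif(n, 0, field_width(field)),
               y = stats::runif(n, 0, field_height(field)),
               theta = stats::runif(n, 0, 2 * pi))
  }
}

#' Tidy data.frame of simulated trajectories
#'
#' @param x a `glide_sim` object.
#' @param ... unused.
#' @return data.frame with columns `particle_id`, `t_s`, `x_um`, `y_um`,
#'   `theta_rad`.
#' @export
as.data.frame.glide_sim <- function(x, ...) {
  n <- ncol(x$x)
  data.frame(
    particle_id = rep(seq_len(n), each = nrow(x$x)),
    t_s = rep(x$t, times = n),
    x_um = as.vector(x$x),
    y_um = as.vector(x$y),
    theta_rad = as.vector(x$theta)
  )
}

#' Occupancy image of simulated trajectories
#'
#' Counts, per pixel, how many recorded samples fall in it, emulating the
#' time-projection images used to compare simulations with experiments. The
#' total count equals the number of in-domain samples (conservation).
#'
#' @param sim a `glide_sim` object, or a data.frame with columns `x_um`,
#'   `y_um`.
#' @param shape output grid `c(rows, cols)`; defaults to the simulation
#'   field grid.
#' @param pixel_size micrometres per pixel of the output grid.
#' @return an integer count matrix.
#' @export
occupancy_image <- function(sim, shape = NULL, pixel_size = NULL) {
  if (inherits(sim, "glide_sim")) {
    if (is.null(shape)) shape <- sim$field_dim
    if (is.null(pixel_size)) pixel_size <- sim$pixel_size
    xs <- as.vector(sim$x); ys <- as.vector(sim$y)
  } else {
    stopifnot(!is.null(shape), !is.null(pixel_size))
    xs <- sim$x_um; ys <- sim$y_um
  }
  nr <- shape[1]; nc <- shape[2]
  jj <- round(xs / pixel_size) + 1
  ii <- round(ys / pixel_size) + 1
  ok <- is.finite(ii) & is.finite(jj) & ii >= 1 & ii <= nr & jj >= 1 & jj <= nc
  matrix(tabulate((jj[ok] - 1) * nr + ii[ok], nbins = nr * nc), nr, nc)
}

#' Estimate the path persistence length from free trajectories
#'
#' For particles simulated with the alignment torque off (A = 0) the heading
#' autocorrelation decays as `<u(s) . u(0)> = exp(-s / L_p)` with arc length
#' `s = v t`. The correlation is estimated as `<cos(theta(t + tau) -
#' theta(t))>` over strided time origins, the decay is fitted log-linearly
#' over the range where the correlation is well above its noise floor, and a
#' bootstrap over particles gives a 95% interval.
#'
#' @param sim a `glide_sim` run with `align_rate = 0`.
#' @param max_lag_um largest arc-length lag used in the fit (default: half
#'   the nominal persistence length is a good choice; here half the total
#'   path, capped at `2 L_p`).
#' @param n_lags number of lags.
#' @param n_boot bootstrap replicates.
#' @return a list with `estimate` (um), `ci` (2-vector), `reliable`
#'   (logical; `FALSE` when the paths are too short or noise-free) and the
#'   per-lag correlation table `decay`.
#' @export
estimate_persistence <- function(sim, max_lag_um = NULL, n_lags = 24L,
                                 n_boot = 200L) {
  p <- sim$params
  if (p$align_rate != 0) {
    warning("persistence estimate assumes A = 0; the alignment torque was on")
  }
  dt_rec <- diff(sim$t[1:2])
  ds <- p$speed * dt_rec # arc length per recorded sample
  total_s <- (nrow(sim$theta) - 1) * ds
  if (is.null(max_lag_um)) {
    max_lag_um <- min(total_s / 2, 2 * p$persistence_length)
  }
  lags <- unique(pmax(1L, round(seq(1, max_lag_um / ds, length.out = n_lags))))
  n_part <- ncol(sim$theta)
  origins <- unique(pmax(1L, round(seq(1, nrow(sim$theta) - max(lags),
                                       length.out = 64L))))
  # per-particle, per-lag mean cosine: bootstrap resamples particles
  per_part <- matrix(NA_real_, n_part, length(lags))
  for (li in seq_along(lags)) {
    L <- lags[li]
    dtheta <- sim$theta[origins + L, , drop = FALSE] -
      sim$theta[origins, , drop = FALSE]
    per_part[, li] <- colMeans(cos(dtheta))
  }
  corr <- colMeans(per_part)
  s <- lags * ds
  # fit within about one decay length: lags where the correlation is
  # still above 1/e, so the log-linear fit is not dominated by the noisy,
  # negatively biased tail
  fit_lp <- function(cv) {
    use <- cv > exp(-1)
    if (sum(use) < 3) use <- cv > 0.05
    if (sum(use) < 3) return(NA_real_)
    -1 / stats::coef(stats::lm(log(cv[use]) ~ 0 + s[use]))[[1]]
  }
  est <- fit_lp(corr)
  if (!is.finite(p$persistence_length)) {
    return(list(estimate = Inf, ci = c(NA, NA), reliable = FALSE,
                decay = data.frame(s_um = s, corr = corr)))
  }
  reliable <- is.finite(est) && est > 0 && total_s > est
  boot <- rep(NA_real_, n_boot)
  if (reliable) {
    for (b in seq_len(n_boot)) {
      idx <- sample.int(n_part, replace = TRUE)
      boot[b] <- fit_lp(colMeans(per_part[idx, , drop = FALSE]))
    }
  }
  list(estimate = est,
       ci = stats::quantile(boot, c(0.025, 0.975), na.rm = TRUE, names = FALSE),
       reliable = reliable,
       decay = data.frame(s_um = s, corr = corr))
}
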