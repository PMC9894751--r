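#' Polarity field from the Q tensor
#'
#' The polarity field `p = div Q / |div Q|` encodes the direction along
#' which splay and bend distortions are amplified; at a +1/2 defect it is
#' aligned with the comet axis. Nodes where `|div Q|` falls below the
#' tolerance (e.g. uniform regions) are masked.
#'
#' @param q a `q_tensor_field` from [director_to_q()].
#' @param tol magnitude threshold below which the polarity is undefined,
#'   in units of 1/um.
#' @return a list with unit-vector component matrices `px`, `py` and a
#'   logical `mask`.
#' @export
polarity_field <- function(q, tol = 1e-8) {
  dq <- q_divergence(q)
  nrm <- sqrt(dq$x^2 + dq$y^2)
  mask <- is.finite(nrm) & nrm > tol
  px <- ifelse(mask, dq$x / nrm, NA_real_)
  py <- ifelse(mask, dq$y / nrm, NA_real_)
  list(px = px, py = py, mask = mask)
}

#' Streamline seed at a +1/2 defect
#'
#' Streamlines are seeded a distance `d` past the defect core along the
#' comet axis: `r_seed = r_core + d * axis`. The initial direction is the
#' director at the seed with its sign chosen to minimize the scalar product
#' with the polarity field there, `u0 = n(r_seed) * sign(-n(r_seed) .
#' p(r_seed))`: a self-propelled particle leaving the defect follows the
#' branch that minimizes its reorientation. `d` is the single model
#' parameter of the predictor (~2 um, the distance a filament travels
#' before realigning).
#'
#' @param defect one row of a [detect_defects()] table (charge +1/2 with a
#'   defined axis).
#' @param field a [director_field()].
#' @param q the matching `q_tensor_field`.
#' @param d seed offset, micrometres.
#' @return a list with `r_seed` (2-vector, um), `direction` (unit
#'   2-vector), and `ambiguous` (`TRUE` when `n . p` vanished at the seed
#'   and the `+n` branch was taken by convention).
#' @export
make_seed <- function(defect, field, q, d = 2) {
  if (abs(defect$charge - 0.5) > 1e-9) stop("seeds are defined for +1/2 defects only")
  if (!is.finite(defect$axis_x)) stop("defect carries no axis")
  r_seed <- c(defect$x + d * defect$axis_x, defect$y + d * defect$axis_y)
  ang <- sample_director(field, r_seed[1], r_seed[2])
  if (is.na(ang)) stop("seed point falls outside the valid domain")
  nvec <- c(cos(ang), sin(ang))
  pol <- polarity_field(q)
  pxv <- sample_grid(pol$px, q$pixel_size, r_seed[1], r_seed[2])
  pyv <- sample_grid(pol$py, q$pixel_size, r_seed[1], r_seed[2])
  dp <- nvec[1] * pxv + nvec[2] * pyv
  ambiguous <- !is.finite(dp) || abs(dp) < 1e-12
  sgn <- if (ambiguous) 1 else sign(-dp)
  list(r_seed = r_seed, direction = sgn * nvec, ambiguous = ambiguous)
}

#' Trace one oriented streamline along the director
#'
#' Midpoint (second-order) integration along the line field: at every step
#' the director is sampled and its sign is chosen to maximize the dot
#' product with the previous step direction, giving a polyline that follows
#' `+/- n` continuously. Integration stops when the streamline (a) enters
#' `stop_radius` of a *different* +1/2 defect core, (b) leaves the valid
#' domain ("edge"), (c) returns within `closure_tol` of an earlier point
#' with direction agreement better than 45 degrees ("loop"), or (d) exceeds
#' `max_length`.
#'
#' @param field a [director_field()].
#' @param seed a seed from [make_seed()] (or a list with `r_seed` and
#'   `direction`).
#' @param defects defect table; only +1/2 rows act as terminators. The
#'   defect nearest the seed's origin (within `2 * stop_radius` looking
#'   backwards along the direction) is treated as the parent and ignored.
#' @param step integration step, micrometres (default half a pixel).
#' @param stop_radius termination radius around +1/2 cores, micrometres.
#' @param closure_tol loop-closure distance, micrometres.
#' @param max_length maximum arc length, micrometres (default 10x the grid
#'   perimeter).
#' @param parent index (row of `defects`) of the defect this streamline was
#'   seeded from, or `NA`.
#' @return a list of class `streamline`: `points` (matrix of x, y), `event`
#'   (`"defect"`, `"edge"`, `"loop"` or `"max-length"`), `length_um`, and
#'   for loops the index `loop_start` of the closure point.
#' @export
trace_streamline <- function(field, seed, defects = NULL,
                             step = field$pixel_size / 2, stop_radius = 1,
                             closure_tol = 0.5,
                             max_length = 10 * 2 * (field_width(field) + field_height(field)),
                             parent = NA_integer_) {
  plus_rows <- if (!is.null(defects) && nrow(defects) > 0) {
    which(abs(defects$charge - 0.5) < 1e-9)
  } else integer(0)
  plus <- if (length(plus_rows) > 0) defects[plus_rows, , drop = FALSE] else NULL
  pos <- seed$r_seed
  u <- seed$direction / sqrt(sum(seed$direction^2))
  # identify the parent core so the streamline does not stop where it starts
  # (`parent` indexes the full defect table; map it into the +1/2 subset)
  parent_idx <- if (is.na(parent)) NA_integer_ else match(parent, plus_rows)
  if (is.na(parent_idx) && !is.null(plus)) {
    dists <- sqrt((plus$x - pos[1])^2 + (plus$y - pos[2])^2)
    if (min(dists) <= 4 * stop_radius) parent_idx <- which.min(dists)
  }
  if (!is.null(plus) && !is.na(parent_idx)) {
    keep <- setdiff(seq_len(nrow(plus)), parent_idx)
    plus <- plus[keep, , drop = FALSE]
    if (nrow(plus) == 0) plus <- NULL
  }
  if (!is.null(plus)) {
    d0 <- sqrt((plus$x - pos[1])^2 + (plus$y - pos[2])^2)
    if (any(d0 <= stop_radius)) {
      return(structure(list(points = matrix(pos, 1, 2), event = "defect",
                            length_um = 0, loop_start = NA_integer_),
                       class = "streamline"))
    }
  }
  max_steps <- ceiling(max_length / step)
  pts <- matrix(NA_real_, max_steps + 1L, 2L)
  pts[1, ] <- pos
  event <- "max-length"
  loop_start <- NA_integer_
  n_pts <- 1L
  dir_cos <- cos(pi / 4)
  for (k in seq_len(max_steps)) {
    e1 <- director_unit(field, pos[1], pos[2], u)
    if (is.null(e1)) { event <- "edge"; break }
    mid <- pos + (step / 2) * e1
    e2 <- director_unit(field, mid[1], mid[2], e1)
    if (is.null(e2)) { event <- "edge"; break }
    pos_new <- pos + step * e2
    if (!in_domain(field, pos_new[1], pos_new[2])) { event <- "edge"; break }
    u <- e2
    n_pts <- n_pts + 1L
    pts[n_pts, ] <- pos_new
    pos <- pos_new
    if (!is.null(plus)) {
      dd <- sqrt((plus$x - pos[1])^2 + (plus$y - pos[2])^2)
      if (any(dd <= stop_radius)) { event <- "defect"; break }
    }
    # loop closure: revisit an earlier point with an aligned direction,
    # ignoring the recent past (checked every few steps for speed)
    if (n_pts %% 5L == 0L) {
      guard <- ceiling(4 * closure_tol / step) + 10L
      if (n_pts > guard + 2L) {
        old <- seq_len(n_pts - guard)
        d2 <- (pts[old, 1] - pos[1])^2 + (pts[old, 2] - pos[2])^2
        hit <- which(d2 <= closure_tol^2)
        if (length(hit) > 0) {
          i <- hit[1]
          v_old <- pts[min(i + 1L, n_pts), ] - pts[i, ]
          nv <- sqrt(sum(v_old^2))
          if (nv > 1e-12 && sum(u * v_old) / nv > dir_cos) {
            event <- "loop"
            loop_start <- i
            break
          }
        }
      }
    }
  }
  pts <- pts[seq_len(n_pts), , drop = FALSE]
  structure(
    list(points = pts, event = event,
         length_um = step * (n_pts - 1L), loop_start = loop_start),
    class = "streamline"
  )
}

# director at (x, y) as a unit vector, sign-continuous with `u_prev`;
# NULL when out of domain
director_unit <- function(field, x, y, u_prev) {
  ang <- sample_director(field, x, y)
  if (is.na(ang)) return(NULL)
  e <- c(cos(ang), sin(ang))
  if (sum(e * u_prev) < 0) e <- -e
  e
}

#' Predict the polar streamlines of a director field
#'
#' Runs the full Q-tensor heuristic: detect defects, orient each +1/2
#' defect from the divergence of Q, seed one streamline per oriented defect
#' a distance `d` along its axis, and integrate each streamline along the
#' director with the rotation-minimizing initial direction. Deterministic.
#'
#' @param field a [director_field()].
#' @param d seed offset, micrometres.
#' @param defects optional precomputed defect table.
#' @param min_separation passed to [detect_defects()].
#' @param ... further arguments to [trace_streamline()].
#' @return a list of `streamline` objects (one per +1/2 defect with a
#'   defined axis and an in-domain seed), each carrying `seed` and
#'   `defect_index` fields; empty if no positive defects are present.
#' @export
predict_streamlines <- function(field, d = 2, defects = NULL,
                                min_separation = 3 * field$pixel_size, ...) {
  if (is.null(defects)) defects <- detect_defects(field, min_separation)
  q <- director_to_q(field)
  out <- list()
  for (i in seq_len(nrow(defects))) {
    df <- defects[i, ]
    if (abs(df$charge - 0.5) > 1e-9 || !is.finite(df$axis_x)) next
    sd <- tryCatch(make_seed(df, field, q, d), error = function(e) NULL)
    if (is.null(sd)) next
    sl <- trace_streamline(field, sd, defects, parent = i, ...)
    sl$seed <- sd
    sl$defect_index <- i
    out[[length(out) + 1L]] <- sl
  }
  out
}

#' Streamline list to tidy data.frame
#'
#' @param streamlines list from [predict_streamlines()].
#' @return data.frame with columns `streamline_id`, `order`, `x_um`,
#'   `y_um`, `event`.
#' @export
streamlines_to_df <- function(streamlines) {
  if (length(streamlines) == 0) {
    return(data.frame(streamline_id = integer(0), order = integer(0),
                      x_um = numeric(0), y_um = numeric(0),
                      event = character(0)))
  }
  do.call(rbind, lapply(seq_along(streamlines), function(i) {
    s <- streamlines[[i]]
    data.frame(streamline_id = i, order = seq_len(nrow(s$points)),
               x_um = s$points[, 1], y_um = s$points[, 2], event = s$event)
  }))
}
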