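#' Director field on a regular grid
#'
#' A director field stores the local orientation of a two-dimensional nematic
#' as an angle grid. The director is a line field: `n` and `-n` are the same
#' state, so angles are kept modulo pi. Node `[i, j]` sits at physical
#' position `x = (j - 1) * pixel_size`, `y = (i - 1) * pixel_size`
#' (micrometres, y increasing downward as in image indexing); angles are
#' measured counter-clockwise from the +x axis in this frame.
#'
#' @param angle numeric matrix of director angles (radians); wrapped to
#'   `[0, pi)` on construction.
#' @param pixel_size grid spacing in micrometres per pixel.
#' @param mask optional logical matrix marking valid nodes (e.g. the interior
#'   of a confining disc). Defaults to all-valid.
#' @return an object of class `director_field` with elements `angle`,
#'   `pixel_size` and `mask`.
#' @export
director_field <- function(angle, pixel_size, mask = NULL) {
  stopifnot(is.matrix(angle), is.numeric(angle), pixel_size > 0)
  if (is.null(mask)) {
    mask <- matrix(TRUE, nrow(angle), ncol(angle))
  }
  stopifnot(is.logical(mask), all(dim(mask) == dim(angle)))
  angle <- wrap_pi(angle)
  angle[!mask] <- NA_real_
  structure(
    list(angle = angle, pixel_size = as.numeric(pixel_size), mask = mask),
    class = "director_field"
  )
}

#' @export
print.director_field <- function(x, ...) {
  cat(sprintf(
    "<director_field> %d x %d nodes, %.4g um/px (%.3g x %.3g um), %d%% valid\n",
    nrow(x$angle), ncol(x$angle), x$pixel_size,
    (ncol(x$angle) - 1) * x$pixel_size, (nrow(x$angle) - 1) * x$pixel_size,
    round(100 * mean(x$mask))
  ))
  invisible(x)
}

#' @export
dim.director_field <- function(x) dim(x$angle)

# physical extent helpers (micrometres)
field_width <- function(field) (ncol(field$angle) - 1) * field$pixel_size
field_height <- function(field) (nrow(field$angle) - 1) * field$pixel_size

#' Sample a director field at continuous positions
#'
#' Interpolates the line field at arbitrary (x, y) positions. Because director
#' angles are only defined modulo pi, interpolation is done on the
#' double-angle components `(cos 2 phi, sin 2 phi)` bilinearly, followed by a
#' half-angle reconstruction; raw angles are never averaged across the pi
#' wrap.
#'
#' @param field a [director_field()].
#' @param x,y positions in micrometres (vectorized).
#' @return director angles in `[0, pi)`; `NA` for positions outside the grid
#'   or touching masked nodes.
#' @export
sample_director <- function(field, x, y) {
  s <- sample_double_angle(field, x, y)
  wrap_pi(atan2(s$s2, s$c2) / 2)
}

# bilinear interpolation of (cos 2phi, sin 2phi); shared by sample_director
# and the simulator. Returns NA components out of domain/mask.
sample_double_angle <- function(field, x, y) {
  px <- field$pixel_size
  nr <- nrow(field$angle); nc <- ncol(field$angle)
  cj <- x / px + 1 # fractional column
  ri <- y / px + 1 # fractional row
  j0 <- floor(cj); i0 <- floor(ri)
  # clamp exact upper-edge hits into the last cell
  j0[cj >= nc & cj <= nc + 1e-9] <- nc - 1
  i0[ri >= nr & ri <= nr + 1e-9] <- nr - 1
  ok <- j0 >= 1 & j0 + 1 <= nc & i0 >= 1 & i0 + 1 <= nr & is.finite(x) & is.finite(y)
  fx <- cj - j0
  fy <- ri - i0
  c2 <- rep(NA_real_, length(x)); s2 <- c2
  if (any(ok)) {
    i0k <- i0[ok]; j0k <- j0[ok]; fxk <- fx[ok]; fyk <- fy[ok]
    idx <- function(i, j) (j - 1) * nr + i
    a <- field$angle
    m <- field$mask
    i11 <- idx(i0k, j0k); i12 <- idx(i0k, j0k + 1)
    i21 <- idx(i0k + 1, j0k); i22 <- idx(i0k + 1, j0k + 1)
    valid <- m[i11] & m[i12] & m[i21] & m[i22]
    w11 <- (1 - fxk) * (1 - fyk); w12 <- fxk * (1 - fyk)
    w21 <- (1 - fxk) * fyk; w22 <- fxk * fyk
    cc <- w11 * cos(2 * a[i11]) + w12 * cos(2 * a[i12]) +
      w21 * cos(2 * a[i21]) + w22 * cos(2 * a[i22])
    ss <- w11 * sin(2 * a[i11]) + w12 * sin(2 * a[i12]) +
      w21 * sin(2 * a[i21]) + w22 * sin(2 * a[i22])
    cc[!valid] <- NA_real_; ss[!valid] <- NA_real_
    c2[ok] <- cc; s2[ok] <- ss
  }
  list(c2 = c2, s2 = s2)
}

# TRUE where (x, y) lies inside the grid and all four surrounding nodes are
# valid; used by the simulator's boundary handling
in_domain <- function(field, x, y) {
  s <- sample_double_angle(field, x, y)
  is.finite(s$c2)
}

#' Write / read a director field as CSV with a JSON sidecar
#'
#' The CSV holds one row per node (`x_um`, `y_um`, `angle_rad`, `mask`); the
#' sidecar records the grid shape and pixel size so the field round-trips
#' exactly.
#'
#' @param field a [director_field()].
#' @param path CSV path; the sidecar is written to `<path>.json`.
#' @export
write_field_csv <- function(field, path) {
  nr <- nrow(field$angle); nc <- ncol(field$angle)
  df <- data.frame(
    x_um = rep((seq_len(nc) - 1) * field$pixel_size, each = nr),
    y_um = rep((seq_len(nr) - 1) * field$pixel_size, times = nc),
    angle_rad = as.vector(field$angle),
    mask = as.integer(as.vector(field$mask))
  )
  utils::write.csv(df, path, row.names = FALSE)
  jsonlite::write_json(
    list(nrow = nr, ncol = nc, pixel_size_um = field$pixel_size),
    paste0(path, ".json"),
    auto_unbox = TRUE
  )
  invisible(path)
}

#' @rdname write_field_csv
#' @export
read_field_csv <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".json"))
  df <- utils::read.csv(path)
  angle <- matrix(df$angle_rad, meta$nrow, meta$ncol)
  mask <- matrix(df$mask == 1L, meta$nrow, meta$ncol)
  angle[!mask] <- 0
  director_field(angle, meta$pixel_size_um, mask)
}
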