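#' Extract the director field from a nematic texture image
#'
#' Structure-tensor extraction: in a fluorescence image of aligned filaments
#' the intensity gradient is perpendicular to the filament orientation, so
#' the unit tangent `t = (I_y, -I_x)` follows the local director. The outer
#' product of `t` is averaged in a square box around every pixel (1-px
#' stride) and the principal eigenvector of the averaged tensor gives the
#' director at the box centre. Nodes whose box contains no gradient energy,
#' or where the tensor is isotropic, are masked invalid.
#'
#' Gradients are taken by central differences after a 1-px Gaussian
#' pre-smooth, which stabilizes the tangent normalization against pixel
#' noise.
#'
#' @param image numeric intensity matrix.
#' @param pixel_size micrometres per pixel.
#' @param box averaging box side in micrometres (default 1.3 um).
#' @param smooth_sd pre-smoothing sigma in pixels.
#' @return a [director_field()] with a `"coherence"` attribute (the
#'   normalized eigenvalue gap of the structure tensor, in `[0, 1]`).
#' @export
extract_director <- function(image, pixel_size, box = 1.3, smooth_sd = 1) {
  stopifnot(is.matrix(image))
  box_px <- max(3L, round(box / pixel_size))
  if (min(dim(image)) < box_px) stop("image smaller than the averaging box")
  im <- gaussian_blur(image, smooth_sd)
  g <- grad_xy(im, h = 1)
  tx <- g$y # tangent t = (I_y, -I_x)
  ty <- -g$x
  nrm <- sqrt(tx^2 + ty^2)
  ok <- nrm > 1e-12 * max(1, max(nrm))
  tx <- ifelse(ok, tx / nrm, 0)
  ty <- ifelse(ok, ty / nrm, 0)
  wsum <- box_filter(ok * 1, box_px) # fraction of informative pixels per box
  t11 <- box_filter(tx * tx, box_px)
  t12 <- box_filter(tx * ty, box_px)
  t22 <- box_filter(ty * ty, box_px)
  angle <- 0.5 * atan2(2 * t12, t11 - t22)
  gap <- sqrt((t11 - t22)^2 + 4 * t12^2) # eigenvalue difference
  tr <- t11 + t22
  coherence <- ifelse(tr > 0, gap / tr, 0)
  mask <- wsum > 1e-6 & gap > 1e-9
  # nodes whose averaging box sticks out of the image see a truncated
  # tensor and produce unreliable orientations: mask the border
  half <- (box_px - 1L) %/% 2L + 1L
  mask[c(seq_len(half), nrow(mask) - seq_len(half) + 1L), ] <- FALSE
  mask[, c(seq_len(half), ncol(mask) - seq_len(half) + 1L)] <- FALSE
  if (!any(mask)) {
    warning("no intensity gradients found: returning a fully masked field")
  }
  fld <- director_field(angle, pixel_size, mask)
  attr(fld, "coherence") <- coherence
  fld
}

#' Q-tensor field from a director field
#'
#' Builds the symmetric-traceless nematic order tensor
#' `Q = S (n (x) n - I/2)`, i.e. `Qxx = (S/2) cos 2 phi`,
#' `Qxy = (S/2) sin 2 phi`, `Qyy = -Qxx`. In `"unit"` mode the scalar order
#' `S` is 1 everywhere; in `"coherence"` mode `S` is the structure-tensor
#' coherence attached by [extract_director()]. Since the polarity field
#' `p = div Q / |div Q|` is normalized, the choice of `S` cancels wherever
#' the order is homogeneous.
#'
#' @param field a [director_field()].
#' @param order `"unit"` or `"coherence"`.
#' @return an object of class `q_tensor_field` with matrices `qxx`, `qxy`,
#'   the `pixel_size` and the validity `mask`.
#' @export
director_to_q <- function(field, order = c("unit", "coherence")) {
  order <- match.arg(order)
  s <- if (order == "unit") {
    matrix(1, nrow(field$angle), ncol(field$angle))
  } else {
    co <- attr(field, "coherence")
    if (is.null(co)) stop("field carries no coherence attribute; run extract_director")
    co
  }
  qxx <- (s / 2) * cos(2 * field$angle)
  qxy <- (s / 2) * sin(2 * field$angle)
  qxx[!field$mask] <- NA_real_
  qxy[!field$mask] <- NA_real_
  structure(
    list(qxx = qxx, qxy = qxy, pixel_size = field$pixel_size,
         mask = field$mask),
    class = "q_tensor_field"
  )
}

#' Splay and bend distortion maps
#'
#' Computes the squared splay `(div n)^2` and squared bend `|n x curl n|^2`
#' of a director field. The angle gradient is evaluated through the
#' double-angle representation `(cos 2 phi, sin 2 phi)`, so the result is
#' invariant under the line-field gauge flip `n -> -n` at any subset of
#' nodes and never differentiates across the pi wrap. Border nodes use
#' one-sided differences; masked nodes propagate `NA`.
#'
#' @param field a [director_field()].
#' @return a list with matrices `splay` and `bend` (units 1/um^2).
#' @export
splay_bend <- function(field) {
  px <- field$pixel_size
  a <- field$angle
  c2 <- cos(2 * a); s2 <- sin(2 * a)
  c2[!field$mask] <- NA_real_; s2[!field$mask] <- NA_real_
  gc <- grad_xy4(c2, h = px)
  gs <- grad_xy4(s2, h = px)
  # phi_x = (c2 * d_x s2 - s2 * d_x c2) / 2  (since c2^2 + s2^2 = 1)
  phix <- (c2 * gs$x - s2 * gc$x) / 2
  phiy <- (c2 * gs$y - s2 * gc$y) / 2
  cs <- cos(a); sn <- sin(a)
  splay <- (-sn * phix + cs * phiy)^2 # (div n)^2
  bend <- (cs * phix + sn * phiy)^2 # (n x curl n)^2 in 2D
  splay[!field$mask] <- NA_real_
  bend[!field$mask] <- NA_real_
  list(splay = splay, bend = bend)
}
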