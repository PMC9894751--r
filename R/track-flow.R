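#' Detect rod-like particles in a single frame
#'
#' The frame is binarized (Otsu threshold by default), connected components
#' are labelled, and each component is summarized by its image moments:
#' centroid, orientation of the principal axis, and the ellipse-equivalent
#' major/minor axis lengths. Only elongated contours, with aspect ratio
#' greater than two, are kept, which separates rods from debris and
#' point-like blobs.
#'
#' @param frame numeric intensity matrix.
#' @param pixel_size micrometres per pixel.
#' @param threshold binarization threshold in intensity units, or `NULL`
#'   for Otsu's method.
#' @param min_area minimum component area in pixels.
#' @param min_aspect aspect-ratio cut (kept if strictly greater).
#' @return data.frame with columns `x`, `y` (um), `theta` (radians, mod
#'   pi), `length` (um, major axis), `area` (um^2), `aspect`.
#' @export
detect_rods <- function(frame, pixel_size, threshold = NULL, min_area = 3L,
                        min_aspect = 2) {
  stopifnot(is.matrix(frame))
  if (max(frame) <= min(frame)) return(empty_detections())
  if (is.null(threshold)) {
    rng <- range(frame)
    threshold <- EBImage::otsu(EBImage::Image(t((frame - rng[1]) / diff(rng)))) *
      diff(rng) + rng[1]
  }
  bw <- frame > threshold
  if (!any(bw)) return(empty_detections())
  # EBImage stores images as [x, y]; transpose so labels map back to [row, col]
  lab <- t(EBImage::imageData(EBImage::bwlabel(EBImage::Image(t(bw)))))
  n_lab <- max(lab)
  if (n_lab == 0) return(empty_detections())
  idx <- which(lab > 0)
  lv <- lab[idx]
  ii <- (idx - 1L) %% nrow(lab) + 1L # row -> y
  jj <- (idx - 1L) %/% nrow(lab) + 1L # col -> x
  area_px <- tabulate(lv, n_lab)
  sx <- tapply(jj, lv, sum); sy <- tapply(ii, lv, sum)
  cx <- as.numeric(sx) / area_px
  cy <- as.numeric(sy) / area_px
  # central second moments
  dx <- jj - cx[lv]; dy <- ii - cy[lv]
  mxx <- as.numeric(tapply(dx * dx, lv, sum)) / area_px
  myy <- as.numeric(tapply(dy * dy, lv, sum)) / area_px
  mxy <- as.numeric(tapply(dx * dy, lv, sum)) / area_px
  theta <- wrap_pi(0.5 * atan2(2 * mxy, mxx - myy))
  # eigenvalues -> ellipse-equivalent semi-axes (a = 2 sqrt(lambda))
  tr <- (mxx + myy) / 2
  dd <- sqrt(((mxx - myy) / 2)^2 + mxy^2)
  l1 <- tr + dd; l2 <- pmax(tr - dd, 1e-12)
  len <- 4 * sqrt(l1) * pixel_size
  aspect <- sqrt(l1 / l2)
  out <- data.frame(
    x = (cx - 1) * pixel_size, y = (cy - 1) * pixel_size,
    theta = theta, length = len, area = area_px * pixel_size^2,
    aspect = aspect
  )
  out <- out[area_px >= min_area & out$aspect > min_aspect, , drop = FALSE]
  rownames(out) <- NULL
  out
}

empty_detections <- function() {
  data.frame(x = numeric(0), y = numeric(0), theta = numeric(0),
             length = numeric(0), area = numeric(0), aspect = numeric(0))
}

#' Link detections between two consecutive frames
#'
#' Two detections `i` (frame t) and `j` (frame t+1) are linked if (1) they
#' are closer than `max_dist`; (2) they are mutual nearest neighbours; and
#' (3) the relative change of both area and length (with respect to the
#' earlier contour) is below `max_rel_change`. Candidate pairs are
#' processed greedily in order of increasing distance and matched contours
#' are removed from further matching.
#'
#' @param dets_t,dets_t1 detection tables from [detect_rods()].
#' @param max_dist linking radius, micrometres (default 5).
#' @param max_rel_change maximum relative change of area and length
#'   (default 0.2).
#' @return data.frame with columns `i`, `j` (row indices into the two
#'   tables) and `dist`.
#' @export
link_detections <- function(dets_t, dets_t1, max_dist = 5,
                            max_rel_change = 0.2) {
  n1 <- nrow(dets_t); n2 <- nrow(dets_t1)
  empty <- data.frame(i = integer(0), j = integer(0), dist = numeric(0))
  if (n1 == 0 || n2 == 0) return(empty)
  dmat <- sqrt(outer(dets_t$x, dets_t1$x, "-")^2 +
                 outer(dets_t$y, dets_t1$y, "-")^2)
  links <- empty
  repeat {
    m <- which.min(dmat)
    if (length(m) == 0 || !is.finite(dmat[m]) || dmat[m] > max_dist) break
    i <- (m - 1L) %% n1 + 1L
    j <- (m - 1L) %/% n1 + 1L
    # mutual-nearest is implied by taking the global minimum among the
    # remaining contours; still check the size rules
    da <- abs(dets_t1$area[j] - dets_t$area[i]) / dets_t$area[i]
    dl <- abs(dets_t1$length[j] - dets_t$length[i]) / dets_t$length[i]
    if (da < max_rel_change && dl < max_rel_change) {
      links <- rbind(links, data.frame(i = i, j = j, dist = dmat[m]))
    }
    dmat[i, ] <- Inf
    dmat[, j] <- Inf
    if (all(!is.finite(dmat))) break
  }
  links
}

#' Build tracks from per-frame detections
#'
#' Chains [link_detections()] matches across an ordered list of detection
#' tables. A track ends as soon as its detection is not linked into the
#' next frame (no gap closing).
#'
#' @param det_list list of detection tables, one per frame.
#' @param frame_interval seconds between frames.
#' @param max_dist,max_rel_change linking parameters.
#' @return data.frame with columns `track_id`, `frame`, `x_um`, `y_um`,
#'   `theta_rad`, `length_um`, `speed_um_s` (speed into this frame; `NA`
#'   on the first frame of each track).
#' @export
build_tracks <- function(det_list, frame_interval = 5, max_dist = 5,
                         max_rel_change = 0.2) {
  n_frames <- length(det_list)
  rows <- list()
  next_id <- 1L
  # active[[k]]: track id of detection k in current frame
  active <- rep(NA_integer_, nrow(det_list[[1]]))
  for (k in seq_len(nrow(det_list[[1]]))) {
    active[k] <- next_id; next_id <- next_id + 1L
  }
  push <- function(frame, det_row, id, speed) {
    rows[[length(rows) + 1L]] <<- data.frame(
      track_id = id, frame = frame, x_um = det_row$x, y_um = det_row$y,
      theta_rad = det_row$theta, length_um = det_row$length,
      speed_um_s = speed
    )
  }
  for (k in seq_len(nrow(det_list[[1]]))) {
    push(1L, det_list[[1]][k, ], active[k], NA_real_)
  }
  for (f in seq_len(n_frames - 1L)) {
    links <- link_detections(det_list[[f]], det_list[[f + 1L]],
                             max_dist, max_rel_change)
    nxt <- rep(NA_integer_, nrow(det_list[[f + 1L]]))
    for (r in seq_len(nrow(links))) {
      id <- active[links$i[r]]
      nxt[links$j[r]] <- id
      push(f + 1L, det_list[[f + 1L]][links$j[r], ], id,
           links$dist[r] / frame_interval)
    }
    for (j in which(is.na(nxt))) {
      nxt[j] <- next_id
      push(f + 1L, det_list[[f + 1L]][j, ], next_id, NA_real_)
      next_id <- next_id + 1L
    }
    active <- nxt
  }
  out <- do.call(rbind, rows)
  out[order(out$track_id, out$frame), , drop = FALSE]
}

#' Per-step speeds of one track
#'
#' Speed is the Euclidean distance travelled between consecutive frames
#' divided by the frame interval.
#'
#' @param track data.frame with columns `x_um`, `y_um` ordered by frame.
#' @param frame_interval seconds between frames.
#' @return numeric vector of speeds (um/s); empty for single-frame tracks.
#' @export
track_speed <- function(track, frame_interval) {
  if (nrow(track) < 2) return(numeric(0))
  sqrt(diff(track$x_um)^2 + diff(track$y_um)^2) / frame_interval
}

#' Block-matching optical flow between two frames
#'
#' For every node of a strided grid, the patch around the node in the first
#' frame is compared with patches displaced within a square search box in
#' the second frame by normalized cross-correlation, and the best-matching
#' integer displacement is returned. A mask built from the stack's
#' maximum-intensity projection can restrict the output to regions with
#' enough signal.
#'
#' @param frame_t,frame_t1 intensity matrices of equal shape.
#' @param pixel_size micrometres per pixel.
#' @param box search box side in micrometres (default 3.6): displacements
#'   up to half the box in each direction are scanned.
#' @param patch template patch half-width, pixels.
#' @param stride node spacing in pixels.
#' @param mask optional logical matrix; nodes where it is `FALSE` get `NA`
#'   flow. See [flow_mask()].
#' @return a list with displacement matrices `vx`, `vy` (micrometres, at
#'   the strided nodes), the node coordinate vectors `x_um`, `y_um`, and
#'   the NCC score matrix `score`.
#' @export
block_flow <- function(frame_t, frame_t1, pixel_size, box = 3.6,
                       patch = 3L, stride = 1L, mask = NULL) {
  stopifnot(all(dim(frame_t) == dim(frame_t1)))
  nr <- nrow(frame_t); nc <- ncol(frame_t)
  s <- max(1L, floor(box / pixel_size / 2)) # max displacement, px
  margin <- s + patch + 1L
  if (nr <= 2 * margin || nc <= 2 * margin) stop("frames too small for the search box")
  ri <- seq(margin + 1L, nr - margin, by = stride)
  ci <- seq(margin + 1L, nc - margin, by = stride)
  w <- 2L * patch + 1L
  # precompute box-filtered means/vars of the template frame at the nodes
  mu1 <- box_filter(frame_t, w)
  sq1 <- box_filter(frame_t^2, w)
  sd1 <- sqrt(pmax(sq1 - mu1^2, 0))
  mu2 <- box_filter(frame_t1, w)
  sq2 <- box_filter(frame_t1^2, w)
  sd2 <- sqrt(pmax(sq2 - mu2^2, 0))
  best <- matrix(-Inf, length(ri), length(ci))
  bdx <- matrix(0L, length(ri), length(ci))
  bdy <- matrix(0L, length(ri), length(ci))
  for (dy in -s:s) {
    for (dx in -s:s) {
      # cross term <f1(r) f2(r + d)> over the patch, via a shifted product
      prod_full <- frame_t * shift_matrix(frame_t1, dy, dx)
      cross <- box_filter(prod_full, w)
      ncc <- (cross[ri, ci] - mu1[ri, ci] * mu2[ri + dy, ci + dx]) /
        pmax(sd1[ri, ci] * sd2[ri + dy, ci + dx], 1e-12)
      # bias ties toward the smallest displacement so featureless or
      # periodic patches report zero flow instead of a scan-order artifact
      ncc <- ncc - 1e-4 * (dx^2 + dy^2) / (s^2 + 1)
      upd <- ncc > best
      best[upd] <- ncc[upd]
      bdx[upd] <- dx
      bdy[upd] <- dy
    }
  }
  vx <- bdx * pixel_size
  vy <- bdy * pixel_size
  flat <- sd1[ri, ci] < 1e-9 # featureless template: no flow
  vx[flat] <- 0; vy[flat] <- 0
  if (!is.null(mask)) {
    mm <- mask[ri, ci]
    vx[!mm] <- NA_real_; vy[!mm] <- NA_real_
  }
  list(vx = vx, vy = vy, score = best,
       x_um = (ci - 1) * pixel_size, y_um = (ri - 1) * pixel_size)
}

# shift a matrix by (dy, dx) with zero padding
shift_matrix <- function(m, dy, dx) {
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(0, nr, nc)
  sr <- seq_len(nr); sc <- seq_len(nc)
  tr <- sr + dy; tc <- sc + dx
  okr <- tr >= 1 & tr <= nr; okc <- tc >= 1 & tc <= nc
  out[sr[okr], sc[okc]] <- m[tr[okr], tc[okc]]
  out
}

#' Signal mask from a maximum-intensity projection
#'
#' @param stack 3D array `[row, col, frame]`.
#' @param quantile_cut intensity quantile of the projection below which a
#'   pixel is masked out.
#' @return logical matrix, `TRUE` where enough signal accumulates.
#' @export
flow_mask <- function(stack, quantile_cut = 0.6) {
  proj <- apply(stack, c(1, 2), max)
  proj > stats::quantile(proj, quantile_cut, names = FALSE)
}
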