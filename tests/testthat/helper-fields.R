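# Shared builders for synthetic fixtures. Everything is generated in code at
# test time; seeds are fixed so expectations are reproducible.

# canonical +1/2 comet field (axis +x), core at the grid centre + half pixel
canonical_plus_half <- function(n = 81L, px = 0.5) {
  ctr <- (n - 1) * px / 2
  make_field(field_spec(c(n, n), px, phi0 = 0,
                        defects = defect_spec(ctr, ctr, 0.5)))
}

# circle path around a point, as a two-column matrix
circle_path <- function(cx, cy, r, n = 120L) {
  th <- seq(0, 2 * pi, length.out = n + 1L)
  cbind(cx + r * cos(th), cy + r * sin(th))
}

# true core position after make_field's half-pixel shift
spec_defects <- function(field) attr(field, "spec")$defects

# nematic angular distance (absolute, radians)
ang_err <- function(a, b) {
  d <- (a - b) %% pi
  pmin(d, pi - d)
}

# free arena for persistence runs: a coarse uniform grid much wider than the
# paths so no particle touches the reflecting border
free_arena <- function(width_um = 2000) {
  director_field(matrix(0, 9L, 9L), width_um / 8)
}

# straight-line trajectory data.frame for the rod renderer
line_trajectories <- function(n_agents, n_frames, x0, y0, theta,
                              step_um = 0.5) {
  do.call(rbind, lapply(seq_len(n_frames), function(fr) {
    data.frame(frame = fr, id = seq_len(n_agents),
               x = x0 + step_um * (fr - 1) * cos(theta),
               y = y0 + step_um * (fr - 1) * sin(theta),
               theta = theta %% pi)
  }))
}
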