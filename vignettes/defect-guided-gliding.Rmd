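---
title: "Passive nematic defects steering an active gliding fluid: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Passive nematic defects steering an active gliding fluid}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nemaglide)
```

## The system

Short gliding filaments (microtubules propelled by surface-bound kinesin
motors) moving inside a static, passive two-dimensional nematic made of
short actin filaments form polar streams whose geometry is dictated by the
nematic's half-integer topological defects. `nemaglide` implements the
computational side of that study: synthetic director fields with prescribed
defect content, extraction of director fields from images, defect detection
and orientation, a stochastic simulator of the gliding particles, a
Q-tensor streamline predictor, rod tracking and optical flow, and the
quantitative read-outs (alignment order parameter, exit-direction bias,
chiral loops, edge currents).

The director is a *line* field: `n` and `-n` are the same physical state,
so all director angles live modulo pi and every operation in the package
(interpolation, winding, gradients) works on the double-angle components
`(cos 2 phi, sin 2 phi)` rather than on raw angles. Grids are stored as R
matrices with x along columns, y along rows (increasing downward, as in
image indexing); angles are counter-clockwise from +x in this frame. In
this frame a positive signed polygon area means counter-clockwise in the
mathematical sense, which appears clockwise on screen; the chirality labels
reported by `detect_loops()` and `edge_stats()` follow the sign convention
stated in their documentation, and only relative handedness (which of two
mirror runs is which) is physically meaningful.

## Synthetic director fields

Ground-truth fields come from the standard one-elastic-constant
multi-defect ansatz, `phi(r) = phi0 + sum_i k_i atan2(y - y_i, x - x_i)`
with half-integer charges `k_i`. Its virtue as a test oracle is exactness:
the winding number around any loop equals the sum of enclosed charges with
no approximation, so the defect detector can be validated to machine
precision. It is *not* an elastic-energy minimizer and is not claimed to be
how the experimental textures look in detail; how the original random
textures were produced is not something we infer.

Three generators build on it:

* `make_field()` / `random_field_spec()` — free fields; random cores are
  rejection-sampled with a minimum separation of 10 px and charges are
  shuffled to hit a prescribed net charge.
* `make_confined_field()` — a disc of radius `R_c`. On a disc with
  tangential-type anchoring the Poincare-Hopf theorem fixes the total
  charge at +1, which with half-integer defects means
  `n_plus - n_minus = 2`. The interior ansatz is evaluated and a global
  phase is fitted so the rim director is as tangential as the defect
  configuration allows (typically within 20-35 degrees; full elastic
  relaxation is out of scope — the generator's job is exact topological
  bookkeeping). The optional `rim_tilt` adds a constant angle to the whole
  texture, turning the anchoring into a spiral. Self-assembled confined
  nematics generically carry such a chiral component, and it is what makes
  one edge handedness dynamically stable; with `rim_tilt = 0` the ansatz
  disc is statistically achiral and edge currents of both handedness
  coexist, which is an artifact of the generator's symmetry rather than a
  property of real textures.
* `make_asymmetric_plus_half()` — a canonical +1/2 comet plus a localized
  Gaussian director twist centred at the streamline seed point, so that the
  director 2 um past the core meets the comet axis at a prescribed skew
  angle. The twist carries no winding and emulates the local asymmetry that
  makes real defects eject filaments preferentially to one side.

Rendered images (`render_nematic_image()`, `render_mt_frames()`) place
short line segments (0.8 um filaments, 2 um rods) aligned with the field,
then blur and add Gaussian noise. The default optical blur is 0.1 um; the
filament length-to-width ratio after blurring is what limits how well
orientation can be recovered, and at the 0.065-0.1 um/px pixel sizes used
in the round-trip tests the structure-tensor extractor reaches a median
angular error just under 10 degrees at 5% noise. What the renderer does not
emulate: filament curvature, photobleaching, intensity heterogeneity,
steric layering. Passing round-trip tests therefore demonstrate
self-consistency of the pipeline, not performance on arbitrary microscopy
data.

## Director-field extraction

`extract_director()` follows the classic structure-tensor recipe for dense
filament images: the intensity gradient is perpendicular to the local
filament orientation, so the normalized tangent `t = (I_y, -I_x)` follows
the director; its outer product is box-averaged (1.3 um box, 1 px stride)
and the principal eigenvector gives the angle. Decisions the method
description leaves open, fixed here once: gradients are central differences
after a 1 px Gaussian pre-smooth (stabilizes the normalization against
pixel noise); nodes whose averaging box has no gradient energy, an
isotropic tensor, or sticks out of the image are masked invalid. A
`coherence` attribute (normalized eigenvalue gap) is attached and can serve
as the scalar order parameter `S` in `director_to_q(order = "coherence")`;
the default is `S = 1`, which is inconsequential for the polarity field
`p = div Q / |div Q|` because the normalization cancels any homogeneous
`S` scaling.

Splay `(div n)^2` and bend `|n x curl n|^2` maps are computed from angle
gradients taken in the double-angle representation, which makes them
invariant under arbitrary `n -> -n` gauge flips by construction. Interior
derivatives use a 4th-order stencil: near a defect the distortions grow as
`1/r`, and the 2nd-order truncation error at the validation radius of 5 px
would exceed the 5% accuracy the closed-form tests demand.

## Defect detection and orientation

Topological charge is measured, not modelled: the winding number of a loop
is the sum of director increments wrapped into `(-pi/2, pi/2]`, divided by
2 pi, quantized to multiples of 1/2. The charge density assigns this
discrete winding to every grid plaquette — exactly quantized and
parameter-free, and its sum over a region equals the region-boundary
winding by construction (a discrete Stokes identity the tests exercise).
Defects are clusters of non-zero plaquettes (single-linkage at
`min_separation`), with charge the cluster sum and position the
|charge|-weighted plaquette centroid; no sub-pixel refinement is attempted
beyond that, and the generator/detector round trip is validated to 2 px.

A +1/2 defect's comet axis is the ring-averaged direction of `div Q`
(ring radius 4 px, 36 samples, central differences). For the canonical
comet `phi = theta/2`, `div Q = (1/(2r), 0)` exactly: the axis points from
the core toward the side on which the director is parallel to the axis.
The sign convention is validated functionally — the streamline tests check
that seeds shifted along the axis land on the comet head — rather than
assumed.

## The gliding simulator

Particles are non-interacting points gliding at constant speed `v` along
their heading, with an aligning torque `A sin(2(phi - theta))` toward the
local director and Gaussian rotational noise whose amplitude
`sqrt(2 v / L_p)` fixes the free-path persistence length `L_p` regardless
of speed. Defaults are the study conditions: `v = 0.1` um/s, `L_p = 100`
um, `A = 0.03` rad/s for confined runs, with `A` swept elsewhere.

Numerical choices:

* Euler-Maruyama with the heading updated before the position, so each
  interior step displaces exactly `v dt` — speed conservation is a machine-
  precision invariant, not an approximation. Default `dt = 0.1` s; the
  guard `A dt < 0.2` keeps the torque update stable. Noise-free alignment
  reproduces the closed form `tan(phi - theta)(t) = tan(phi - theta)(0)
  e^{-2At}` to better than 1e-3 relative error at `dt = 0.01` s.
* One reproducible noise stream per particle derived from the master seed,
  so changing the particle count does not perturb existing trajectories.
* Boundaries: the continuous equations say nothing about walls. Discs use
  specular reflection of the heading about the wall tangent by default
  (`"slide"`, projection onto the tangent, is provided and tested);
  unconfined fields reflect off the rectangular grid edge. Free-particle
  estimates (persistence recovery) are run in an arena much wider than the
  paths so the wall rule never enters.
* `L_p = Inf` is an accepted sentinel that disables noise, used by the
  closed-form tests.

`estimate_persistence()` fits `<u(s) . u(0)> = exp(-s/L_p)` log-linearly
over the lags where the measured correlation still exceeds `1/e` — a
self-adaptive window of about one decay length that keeps the fit off the
noisy, negatively biased tail — and bootstraps particles for a 95%
interval. At the study size (200 particles, 500 um of path each) both
`L_p = 25` and `L_p = 100` um are recovered within 10%; the run-to-run
spread of the estimate is about 5%, so occasional excursions near the 10%
edge are expected sampling behaviour, not bias.

## Streamline prediction

The predictor uses only the nematic field near +1/2 defects. Each defect
contributes one seed `r_seed = r_core + d * axis` with `d = 2` um — the
single phenomenological parameter, the distance a filament travels before
realigning — and an initial direction `n(r_seed) * sign(-n(r_seed) .
p(r_seed))`: the branch of the director that minimizes the scalar product
with the polarity field, i.e. the reorientation-minimizing direction for a
self-propelled particle leaving the defect. Integration is midpoint (RK2)
at half-pixel steps along `+/-n` with sign continuity; termination on
reaching another +1/2 core (`stop_radius` 1 um; the parent defect is
excluded — whether streams also stop at -1/2 cores is left open by the
source description, and we do not stop there), leaving the valid domain,
closing into a loop (0.5 um closure, direction agreement better than 45
degrees), or a generous maximum length. A seed with `n . p = 0` is a
measure-zero tie; it takes `+n` and is flagged ambiguous.

One honest limitation, documented rather than hidden: on the idealized
ansatz fields the seed sits on the comet separatrix, and the exact director
line through it hairpins around the core instead of crossing it — the
continuation past the core is a knife-edge that smoothed experimental
fields do not suffer from. Simulated particles cross cores ballistically
(their turning rate is finite), so on generic random ansatz fields the
predicted line downstream of the core and the simulated stream can
diverge. The quantitative prediction/simulation cross-checks are therefore
run where the funnelled stream is axis-organized (the skewed single-defect
texture, where predicted streamlines capture 30-40% of all particle
positions within 3 um against ~0-15% for randomly re-seeded lines, and the
facing-pair texture, where streams connect defect to defect), while
consistency on generic fields is checked at the occupancy level: the
Pearson correlation between occupancy images peaks at the true alignment
rate in the `A` sweep.

## Read-outs

* `order_parameter()` — `S_v = 2 (n . v/|v|)^2 - 1`, gauge- and
  velocity-sign-invariant, 1 for aligned and -1 for orthogonal motion.
* `pearson_images()` — both images smoothed, block-averaged to a common
  working size (256 by default; smaller grids are never upsampled), then
  the Pearson coefficient.
* `classify_exits()` / `direction_fraction()` — passages through a defect
  must dwell within `d` of the core; the exit is the first outward crossing
  of the `2d` gate, classified by the sign of the transverse velocity
  component; near-axial crossings (transverse fraction below 5%) are
  discarded as ambiguous. The bias `max(n1, n2)/(n1 + n2)` is reported with
  a two-sided exact binomial p-value because the counts are small. With the
  gate at the study parameters, a 0.4 rad skew gives a bias around 0.9 and
  the mirrored skew flips the side.
* `detect_loops()` — self-proximity closure (1 um, direction agreement
  above `cos 45deg`) plus a turning-number filter: a polar loop is a simple
  circuit whose tangent completes one full turn, which excludes
  back-and-forth circuits closed by reflections off the observation window;
  loops touching the rectangular window border (within `edge_margin`, 2 um)
  are discarded as finite-window artifacts. Enclosed charge is the director
  winding along the CCW-oriented polygon (retried on a slightly
  inward-pulled polygon when rim-hugging loops touch masked nodes — the
  winding is homotopy-invariant); enclosed defects are counted by
  ray-casting. The bookkeeping identity `charge = (n_plus - n_minus)/2`
  holds for essentially all detected loops; occasional violations occur
  when a defect sits within the closure tolerance of the polygon edge.
* `edge_stats()` — per-frame tangential-sign counts in an edge band
  (0.15 `R_c`) and mean radius per starting-handedness group.

## Problem sizes

The default test and analysis runs use 96-160 px grids, 30-50 particles,
and 6 000-16 000 steps; loop statistics aggregate ten 128 um fields with
50 particles each, and persistence fits use 200 particles with 500 um of
path. These sizes were chosen so each statistic is comfortably resolved
(around a hundred loops, bootstrap intervals a few percent wide) while a
full run of the suite stays in the minutes range on one core.

## Known limitations

* The ansatz generator has no elastic relaxation, defect dynamics or
  annihilation; the passive field is static by assumption.
* The renderer's noise model is additive Gaussian only.
* The tracker does no gap closing or crossing resolution; optical flow
  reports integer-pixel displacements (sub-pixel interpolation is out of
  scope).
* Streamline continuation through idealized cores is ill-conditioned, as
  discussed above.
* Hydrodynamic and particle-particle interactions are deliberately absent:
  the system modelled is dry and dilute.
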