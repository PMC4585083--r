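---
title: "Models and numerics behind ventriflow"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and numerics behind ventriflow}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(ventriflow)
```

ventriflow simulates blood flow in a left ventricle whose endocardial
surface motion is prescribed, and quantifies what that motion does to
intraventricular transport.  This vignette explains the models, the
numerical choices, the tunable parameters, and what the synthetic test
problems do and do not establish about real hearts.

## The one-way coupled picture

The driving idea is a one-way coupling: some upstream source — an
electromechanical model, a registered sequence of segmented images, or the
built-in synthetic generator — supplies the endocardial surface Γ(t) over
one cardiac cycle.  The flow solver treats Γ(t) as a kinematic boundary
condition; no force feedback returns to the wall.  Everything downstream
(particle transport, washout metrics, P–V loops) is a functional of the
resulting velocity and pressure fields.

## Synthetic moving ventricle

The generator stands in for an image-based deformation source so that every
stage of the pipeline is testable without external data.

* **Geometry.** The lumen is the union of a prolate-spheroid LV cavity
  (semi-axes `lv_semi_axes`, long axis vertical, apex down), cut at a basal
  plane, with two vertical tubes standing in for the left atrium (inflow)
  and the aorta (outflow).  Default tube radii (0.85 and 0.8 cm) are chosen
  at the scale of a canine mitral annulus and aortic root, so peak inflow
  and ejection velocities land in the physiological tens-of-cm/s range.
  Creases where the primitives meet are filleted (smooth min/max with a
  0.3 cm radius): concave rings are both unphysiological and the worst case
  for ghost-cell reconstruction.  The surface is extracted by marching
  tetrahedra on a uniform lattice (resolution `mesh_resolution`; the
  default 0.12 cm yields ~43k triangles, inside the 24k–48k band used at
  full scale), then welded.  It is watertight by construction — the tube
  ends are capped above the computational box, so the caps close the
  geometry while the box's top face provides the open cross-sections.
* **Volume waveform.** V(t) is C¹ and periodic with V(0) = ESV (the cycle
  starts at diastole onset): raised-cosine rate bumps give an E wave and an
  A wave over the diastolic fraction (default 0.6 of the period; the
  physiological split is not uniquely determined, so it is exposed as
  configuration), then a single smooth ejection bump.  `ea_peak_ratio`
  (default 2) sets the E:A peak filling-rate ratio.  min V = ESV and
  max V = EDV hold exactly, so SV and EF arithmetic is exact.
* **Deformation.** Each key frame deforms the template by a smooth
  apex-weighted radial scaling about the basal centre; vertices at or above
  the basal plane (the tubes) are fixed, and a C¹ blend reaches full scale
  one blend length below the plane.  The scale factor is found by 1-D root
  finding so the enclosed volume matches V(t) to ~1e-9 relative.  Because
  every frame deforms the *same* template, the sequence is conformal: one
  triangle connectivity for all frames, which is what makes vertex
  velocities well defined.
* **Interpolation.** Positions between key frames come from a periodic
  cubic spline per vertex coordinate; wall velocities are the analytic
  spline derivative.  A kinematic-consistency audit (surface integral of
  wall velocity · normal vs. d/dt of the enclosed volume) holds to better
  than 1%.

## Registration

When the wall motion comes from an external source with varying meshes, a
template is mapped onto each target frame by a greedy kernel flow on the
currents metric: surfaces are compared as area-weighted face normals at
centroids under a Gaussian kernel (width `sigma_w`, default five mean edge
lengths), and the template vertices move down the kernel-smoothed energy
gradient (deformation kernel width `sigma_v`, default 20% of the template's
long axis) with step halving on any energy increase, so the energy trace is
non-increasing by construction.  This deliberately replaces a full
geodesic-shooting formulation: the solver only consumes the mapped frames,
so any smooth, orientation-preserving matcher that meets the conformality
and fidelity contract suffices; orientation is audited by counting normal
flips (zero on all shipped benchmarks).  Rigid pre-alignment is assumed —
template and targets are expected in one coordinate frame.  Quad-faced
surfaces (e.g. hexahedral element faces) are first subdivided n×n with each
sub-quad cut along its shorter diagonal (ties broken deterministically),
giving 2n² triangles per quad with shared edges welded.

## Flow solver

* **Discretisation.** Collocated cell-centered velocities and pressure on a
  uniform Cartesian grid; face-normal fluxes carry the discrete divergence.
  A collocated arrangement was chosen over a staggered one for simpler
  ghost-cell logic; the face-flux machinery is the piece a staggered
  variant would replace.
* **Time stepping.** Second-order projection: explicit Adams–Bashforth for
  advection (Euler on the first step, after a discarded priming step that
  initialises the lagged pressure), implicit Crank–Nicolson for diffusion
  (the Helmholtz solves are diagonally dominant Jacobi iterations), then an
  incremental pressure correction whose Poisson problem is solved by a
  geometric multigrid V-cycle (red–black Gauss–Seidel smoothing,
  mask-aware coarsening, trilinear prolongation).  On smooth problems one
  V-cycle reduces the residual by more than an order of magnitude.
* **Immersed boundary.** Cells are classified against the watertight
  surface by ray parity; the layer of solid cells adjacent to fluid becomes
  ghost cells.  Each ghost cell stores its body intercept (closest surface
  point) and an image point along the wall normal, placed at least one cell
  into the fluid so its trilinear stencil has full fluid support; the ghost
  value is the linear extrapolation through the wall velocity at the
  intercept.  Cells swept from solid to fluid ("fresh" cells) are filled
  with the wall velocity at their nearest surface point.  Wall velocities
  at intercepts are barycentric interpolations of the vertex velocities.
* **Boundary conditions.** The box faces are no-slip walls except the top
  face, which is open (zero-gradient velocity, zero pressure) where the
  tube cross-sections meet it: flow in and out of the lumen is induced
  purely by the wall motion, and mass leaves through the tubes rather than
  through a volumetric compatibility correction.  With no valve leaflets in
  the lumen (deliberately — leaflet kinematics are not modelled), ejection
  would split between both tubes; the far end of the idle tube is therefore
  blocked for each phase (atrial end during ejection, aortic end during
  filling), switching with the sign of dV/dt.  This is a boundary-condition
  stand-in for valves, not a leaflet model.
* **Stabilisation.** Advection is second-order central with an optional
  upwind blend; within three cells of an open face and in the first ring of
  cells against the immersed wall the blend is forced to full upwind — the
  zero-gradient and ghost-extrapolation closures are only stable with
  dissipative transport there.  The moving-geometry loop uses the
  non-incremental correction — the pressure is recomputed from scratch each
  step, so cells swept by the wall never feed a stale lagged pressure back
  into the momentum balance — together with a global blend of 0.2.  The
  fixed-geometry verification path uses the incremental correction with
  pure central advection, where the scheme shows second order in both space
  and time on the decaying Taylor–Green vortex and post-projection
  divergence at the Poisson-solver tolerance; an optional Rhie–Chow face
  correction is available there for long collocated runs (it suppresses
  pressure checkerboarding at the price of a time-step-proportional error
  component).
* **Tolerances.** The pressure solve runs to `rtol` × max|rhs| (1e-4 for
  pipeline runs, machine-level for verification); the CFL guard aborts at
  0.95 by default; the grid may be re-classified every few steps
  (`reclassify_every`, default 3 in the pipeline) because the wall travels
  only a small fraction of a cell per step — ghost wall velocities are
  refreshed every step regardless.

## Lagrangian transport and washout

12,000 point-mass particles (the full-scale reference count; configurable)
are seeded uniformly over the fluid cells, tagged by region (atrial tube,
LV cavity, aortic tract).  Advection is classical RK4 with trilinear
spatial and linear temporal interpolation; ghost-cell values participate so
near-wall particles follow the moving wall, and particles that still end up
beyond the surface are re-projected to the fluid side (counted as a quality
metric; a handful per step at desk scale).  Particles crossing the aortic
plane are removed as ejected with their exit time; inflow particles are
injected on the mitral plane at number density × instantaneous inflow flux
with a fractional accumulator, so the long-run injected count is exact to
±1.  Particles are *not* removed on mitral backflow; they re-enter the
atrial pool.

At each cycle boundary the decomposition counts: inflow particles (atrial
tag, entered the LV this cycle) that were ejected (I) or retained (II), and
cycle-start ventricular particles ejected (III) or remaining (IV), each
class converted to volume by its reference volume — the measured inflow
volume for I/II, the cycle-start cavity volume for III/IV.  The metrics
follow exactly: DR = I/(I+II), WR = III/(III+IV), RR = 1−WR,
EF = (I+III)/(I+II+III+IV), and N₁% = −2/log₁₀RR, reported both real-valued
and rounded to the nearest integer (the rounding convention that reproduces
the reference table: 8.07→8, 10.11→10, 25.37→25, 55.23→55).

## Pressure anchoring and P–V loops

The incompressible solver fixes pressure only up to a constant.  The
absolute level comes from the closed-loop Windkessel model: during filling
the mean pressure in the atrial tube is matched to the lumped-model left
atrial pressure (pre-load); during ejection the aortic-tube mean is matched
to the lumped aortic pressure (after-load).  The lumped network — two RC
compartments per circulation, elastance atria and right ventricle, diode
valves, volume-driven LV integrated inside the same RK4 state so the closed
loop conserves total volume to round-off — has no published parameter set
to reproduce, so its defaults are canine-plausible placeholders (aortic
pressure ≈ 9–11 kPa, LV systolic ≈ 12 kPa, stroke work ≈ 190 mJ for the
normal drive); no quantitative claim depends on them, only conservation,
periodicity and directional responses.  Stroke work is the shoelace area of
the (V, p) loop in mJ.

## Problem sizes and what the tests show

The full-scale configuration of record (128×128×256 grid, Δt = 1e-4 s,
5,000 steps per cycle) is cluster-scale.  The shipped test suite and the
acceptance script instead run: exact arithmetic on the four reference
EDV/ESV and WR rows; analytic verification of every numerical component
(Taylor–Green order, manufactured Poisson solutions, multigrid reduction,
CN amplification, RK4 orbits, RC decay, binomial washout oracles); and a
paired normal (41.2/23.4 mL) versus failing (116.4/100.2 mL) comparison at
32×32×64, Δt = 5e-4 s, two cycles, 12,000 particles — sizes chosen so the
whole suite runs on a single desktop core in well under half an hour.  At
that scale the paired runs reproduce the qualitative physiology robustly —
higher peak mitral velocity, larger swirl-strength vortex volume, higher DR
and WR, and a much smaller washout cycle count for the normal heart — and
land close to the reference transport numbers (normal: WR ≈ 45–50%,
N₁% 7–8; failing: WR ≈ 16.5%, within a point of the reference 16.6%).

What the synthetic generator does *not* emulate: torsion and long-axis
shortening patterns of real ventricles, regional dyssynchrony (the
activation-sequence contrast is represented only through its volumetric
effect), papillary muscles and trabeculae, valve leaflets, and turbulence
at full-scale Reynolds numbers.  Passing the paired comparison shows the
pipeline resolves how *global* volumetric function shapes transport; it
does not validate regional wall-motion effects against measured canine
flows.

## Known limitations

* One-way coupling only; no pressure feedback into the wall motion.
* The valve stand-in switches tube ends with dV/dt; real valve timing and
  regurgitation are outside scope.
* The collocated arrangement relies on an upwind blend and (for long runs)
  a Rhie–Chow correction for robustness; a staggered variant would remove
  both at the cost of heavier ghost-cell logic.
* Desk-scale grids under-resolve the mitral jet; quantitative DR at low
  resolution is biased low relative to the reference values even when WR
  and N₁% agree.
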