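---
title: "Methods: voxel-grid hemodynamics with a sharp-interface immersed boundary"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: voxel-grid hemodynamics with a sharp-interface immersed boundary}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

hemovox turns a voxelized contrast volume (an angiogram-like image in which
the blood-filled lumen is bright against a dark background) directly into a
hemodynamic simulation, without ever building a surface or volume mesh. The
voxel lattice of the image *is* the computational grid. This document
explains the model behind each stage, the choices that were genuinely open,
and what the accompanying tests do and do not demonstrate.

## Pipeline at a glance

1. crop a Cartesian region of interest (ROI) around the target structure;
2. segment the lumen by seeded 3D region growing over voxels with intensity
   `I > I0`, which simultaneously discards any bright structure not
   face-connected to the seed (the "clean-up");
3. build a level-set representation of the wall directly from intensity,
   `phi0 = I - I0`, optionally low-pass filtered; the wall is the `phi = 0`
   iso-surface and `phi > 0` marks the lumen;
4. locate the vessel openings on the ROI faces, extract a local centerline
   frame at the inflow, and impose a steady parabolic and/or oscillatory
   Womersley velocity profile aligned with the centerline tangent;
5. solve the incompressible Navier-Stokes equations on the voxel grid,
   restricted to the masked cells, with a sharp-interface (ghost-fluid) wall
   treatment that uses the sub-voxel wall position from the level set;
6. post-process wall pressure, the near-wall velocity-gradient tensor, wall
   shear stress (WSS), and normalized metrics over a designated aneurysm
   region.

All voxel indices are 1-based, as is natural in R; voxel `(i,j,k)` spans
`[(i-1)dx, i dx)` per axis and its centre is at `(i - 1/2) dx`. Image
geometry is carried in millimetres and converted to SI metres at the solver
boundary; velocities are m/s, pressures Pa.

## Segmentation and its assumptions

Region growing accepts a face-connected neighbor iff `I > I0`, optionally
also requiring the intensity jump from the accepting voxel to stay below
`grad_max`. Six-neighbor connectivity is used deliberately: diagonal
connectivity would let the mask leak through single-voxel wall gaps. The
gradient criterion is defined as `|I_neighbor - I_current| < grad_max`
between the accepting voxel and the candidate; the definition is isolated in
one place because other readings (e.g. a central-difference gradient
magnitude) are plausible and could be swapped.

The threshold is the user's main lever: it fixes both the mask and, through
`phi0 = I - I0`, the wall position. The phantom intensity model is built so
that the half-way level `(I_lumen + I_bg)/2` sits exactly on the analytic
surface, which is what makes threshold selection well-posed in the tests.

## Wall geometry from the level set

The raw level set is smoothed once with a separable 27-point filter with
1D weights `(1/4, 1/2, 1/4)` (centre weight 1/8, weights summing to exactly
one; out-of-range neighbors replaced by the nearest edge value). Smoothing
is always applied before geometric queries in the pipeline — robustness on
noisy data matters more than the tiny bias it introduces on clean data — and
can be disabled in the config.

Per-direction sub-voxel wall distances at wall-adjacent cells are
`d = phi / (dphi/dx)` with central-difference gradients: the linear zero
crossing along `+x` is at offset `-d_x` from the cell centre. A direction is
flagged absent when the gradient is degenerate (below `1e-8 * max|phi| / dx`)
or the implied wall lies beyond 1.5 spacings — such a wall is not that
cell's wall in that direction. Degenerate cells fall back to a wall at half
a spacing. Wall normals are the normalized level-set gradient and point into
the lumen.

## The flow solver

The solver integrates the incompressible Navier-Stokes equations with a
fractional-step (projection) scheme on a staggered MAC grid: face-normal
velocities, cell-centred pressure. Convection uses second-order central
differences advanced explicitly with Adams-Bashforth 2 (forward Euler on the
first step); viscous terms are Crank-Nicolson. A fully implicit treatment of
convection would require a nonlinear solve with no accuracy benefit at the
CFL numbers used here.

### Sharp-interface wall treatment

The wall generally cuts through grid cells. Boundary velocities are imposed
with a ghost-fluid construction that is exact for velocity profiles linear
in the wall-normal coordinate — the property that makes the interface
"sharp" rather than smeared:

* at a point half a spacing from the nearest fluid sample (`u_near`, wall
  distance `d`): linear interpolation through the wall zero when the wall
  lies between sample and point, `U_BC = u_near (1 - dx/(2d))`; otherwise
  the mirrored ghost construction whose closed form is
  `U_BC = (u_near - u_next)(dx/2 - d)/dx`;
* at a full-spacing ghost point (the parallel staggered face): the mirrored
  image value with flipped sign, `u_g = -(u_near + (u_near - u_next)(2d - dx)/dx)`.

Distances come from the level set sampled at face positions (mean of the two
flanking cell values), with the zero crossing found by linear interpolation
between a fluid face and its non-fluid neighbor — a one-sided form of the
`phi/(dphi/dx)` estimate that is identical for locally linear `phi`. `d` is
clamped below at `0.05 dx` (the wall velocity is imposed below the clamp)
and closures with only one usable sample are clamped to `d >= dx/3` to keep
reflection coefficients bounded. When a ghost face borders several fluid
faces (corners), the candidate closures are averaged.

The ghost values are *linear* functions of the interior unknowns, so they
are folded into the implicit Crank-Nicolson operator (`A_eff = A + B C`)
rather than lagged — assembled once, because the geometry is static.

### Projection and outflow

The pressure Poisson equation is solved over masked cells with homogeneous
Neumann conditions at walls and inflow and Dirichlet `P = 0` on outflow
boundary faces (a traction-free outlet together with zero-normal-gradient
velocity). Because the geometry never changes, the Poisson matrix and the
momentum matrices are factorized once (sparse Cholesky / LU) and re-used
every step; the projection is therefore exact to round-off and the reported
post-step divergence is at the 1e-10 1/s level on the benchmarks rather than
at an iterative tolerance. `poisson_tol` remains the documented acceptance
bound for the divergence check. After correction, outflow faces are rescaled
by a single factor so total outflow flux equals total inflow flux; the
divergence reported in the diagnostics is measured on the projected field,
before this rescaling, which is the field the projection controls.

If segmentation yields no outflow patch the pressure system is singular
(all-Neumann) and the solver refuses to run, naming the condition.

### Time step and steadiness

`dt` is fixed per run: either given, or chosen once as
`cfl * min(dx) / max|u_inflow|` with a default CFL target of 0.5. The
measured CFL is recorded each step and a step that exceeds 1.2 aborts with
the measured value. A run is declared steady when the relative L2 velocity
change per flow-through time drops below `steady_tol` (default `1e-3`;
verification runs use `1e-6`).

Like all non-incremental projection methods, the scheme carries an O(dt)
splitting error concentrated at boundaries (the wall closures are imposed on
the intermediate velocity). On the tube benchmark at CFL 0.5 this is below
one percent of the peak velocity and decreases linearly with `dt`; the test
that probes Stokes linearity therefore compares two runs at one fixed `dt`,
so both share the identical discrete operator.

### Periodic axes

Solver axes can be declared periodic. The imaging pipeline never uses this,
but it gives clean verification problems (viscous decay of a sine mode
between two sub-voxel-offset walls; a fully periodic box) that exercise the
same face-classification and ghost machinery as patient-like geometry.

## Inflow model

The inflow profile lives on the patch of masked voxels on the user-named ROI
face. Per-slice mask centroids define centre points; the unit tangent is the
least-squares line direction through the first `centerline_depth` (default
4) centroids, oriented into the domain — with depth 2 this reduces to the
two-point centroid difference. Each patch voxel gets an in-plane radius by
vector rejection, `R' = R - (R.s)s`, and the rim radius `R'_max` is the
patch maximum of `|R'|`, so non-circular openings are handled without
assuming a circular cross-section.

The steady part is the parabola `U0 (1 - (|R'|/R'_max)^2) s`. Pulsatile runs
superpose rigid-tube Womersley modes at harmonics of the heart rate `f0`:
harmonic `h` has Womersley number `Wo sqrt(h)` and a complex centerline
amplitude set by the user's `(amplitude, phase)` pair — amplitudes are
centerline velocities, not flow rates, which is the convention documented
here because either normalization is defensible. The radial shape uses
`J0(i^{3/2} Wo xi)` evaluated by a power series accurate to double precision
for `|z|` up to ~25 (Wo up to ~15 at the rim, ample for cerebral vessels);
the tests compare it against an independently coded quadrature
representation of `J0`.

Default fluid properties are blood-like: density 1060 kg/m^3, dynamic
viscosity 0.0035 Pa s (Newtonian). Verification runs often use a larger
viscosity so that the analytic regime (laminar, fully developed) is reached
in a short simulated time; this is a choice of test fluid, not a change to
the defaults.

## Post-processing

Wall pressure uses the zero-normal-gradient assumption: the wall value
equals the adjacent cell-centre value. The velocity-gradient tensor at
wall-adjacent cells is built from cell-centred velocities and boundary
velocities at the cell faces: one-sided differences over half a spacing
where one neighbor is solid (sign-consistent: fluid-side minus wall-side
over the distance), face-value differences where both are solid, central
differences otherwise, and one-sided fluid differences at ROI edges (which
are openings, not walls). For tangential components the face boundary value
is reconstructed with the two-point ghost extrapolation at every wall
distance: it is as linear-exact as the interpolation branch but its
coefficients stay bounded, so cells whose centre lies almost on the wall do
not amplify discretization noise into the WSS.

WSS is the tangential part of the viscous traction,
`tau_w = mu (grad(u).n - ((grad(u).n).n) n)`, stored on the wall-adjacent
fluid cell; tangentiality holds to round-off by construction and is asserted
on every solver test.

Normalized metrics over an aneurysm region: `tau* = |tau_w| / (rho U0^2)`
summarized by maximum, mean, and variation over the region's wall cells, and
the volume-averaged `|u|/U0` over the region's cells. Dynamic-pressure
scaling is used for `tau*` because it is the normalization that puts
physiological WSS at sub-m/s inflow into the observed sub-0.1 range;
"variation" is the population standard deviation (variance is a one-line
switch). The region itself must be supplied — a phantom truth predicate, a
label array, or a bounding box; automatic ostium detection is out of scope
on purpose, as it is a research problem of its own. The size ratio is the
maximal pairwise extent of region cell centres divided by the parent vessel
diameter; the default diameter estimate is twice the rim radius `R'_max` of
the inflow frame (the mean of `|R'|` over a disc underestimates a diameter
by a factor 3/4, so the rim maximum is the better default), and an explicit
diameter can be passed instead.

## The phantom generator

Phantoms stand in for patient angiograms, which cannot be shipped. They
emulate exactly two features of real data: a bright lumen over a dark
background with a finite-width linear intensity ramp at the wall (half-width
`wall_width`, so the mid-level iso-surface is the analytic wall), and
additive i.i.d. Gaussian noise, seeded and reproducible. They deliberately
do **not** emulate X-ray physics, beam hardening, motion artifacts,
intensity inhomogeneity, or contrast-agent dynamics — so a passing test
suite demonstrates correctness of the geometry/solver chain on idealized
images, not robustness to clinical artifacts.

Four families: straight tube (arbitrary axis), curved tube (torus segment
with straight tangent extensions; `arc_span = 0` reduces voxelwise to the
straight tube), sidewall aneurysm (tube ∪ sphere, with an aneurysm-region
predicate and a closed-form union volume in which the overlap is a spherical
cap cut by the locally planar wall), and two disconnected vessels (for the
clean-up property). Tube centres default to a small off-lattice offset
(`(0.13, 0.37, 0)` voxels) so voxelizations are not artificially symmetric.
Signed distances are exact for the single-surface phantoms; for unions the
pointwise maximum of signed distances has the exact zero set and sign but
understates the interior distance near the weld, which no consumer relies
on.

## Problem sizes and numerical checks used by the tests

The verification suite runs, among smaller cases: a voxelized tube at 10
cells per radius (26 x 26 x 44 grid) for the Poiseuille benchmark (profile,
WSS, axial pressure gradient), the same physical tube at 6 and 12 cells per
radius for the observed convergence order, a 34-cell channel for the viscous
decay rate, and a 30 x 22 x 24 sidewall-aneurysm pipeline run (twice) for
end-to-end determinism. These sizes were chosen as the smallest grids on
which the analytic regimes are cleanly established; all of them complete on
one core in a few minutes total. `scripts/acceptance.R` recomputes the same
quantities from scratch.

## Known limitations

* Rigid walls only: no fluid-structure interaction, and `u_wall = 0` is
  assumed throughout (the closures carry the wall-velocity terms, so moving
  walls are an extension point, but no fresh-cell treatment exists).
* Newtonian rheology; no turbulence model — appropriate for cerebral-artery
  Reynolds numbers, not for stenotic jets.
* Outlets are traction-free; there is no lumped-element (Windkessel)
  downstream model, so absolute pressure levels are only meaningful up to
  the outlet reference.
* One inflow per run; runs with several candidate inflow patches on the
  named face keep the largest and warn.
* The voxel lattice is the grid: resolution is whatever the image provides,
  and no sub-voxel resampling is performed.
* The observed spatial convergence order on the tube benchmark is ~1.4 —
  between first and second order — because wall-cut cells are locally
  first-order even though the interior scheme is second-order.
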