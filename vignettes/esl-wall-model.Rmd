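---
title: "Modeling red blood cell motion near endothelial-surface-layer walls"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling red blood cell motion near endothelial-surface-layer walls}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(rbcflow)
```

## The problem

The inner surface of a capillary is coated by the endothelial surface layer
(ESL), a brush of membrane-bound macromolecules roughly 0.5–2 µm thick. The
layer shapes the effective geometry of the vessel wall: its thickness,
its spatial variation (how bumpy or sparse the brush is), and its
permeability to plasma all change under pathological conditions such as
sepsis or diabetes. Red blood cells (RBCs) flowing near a wall experience a
wall-induced lift — deformation-induced asymmetry in the surrounding shear
generates a lateral force that drives cells away from the wall — and the
collective result is a cell-free layer (CFL) of plasma next to the wall.
`rbcflow` simulates this interaction in two dimensions so the effect of
wall thickness, spatial variation, and permeability on single-cell
migration and CFL formation can be studied systematically.

## The model

Plasma fills a rectangular channel `[0, lx) x [0, ly]`, periodic in the
flow (x) direction with no-slip walls at `y = 0` and `y = ly`. Because
capillary Reynolds numbers are small, the flow obeys the unsteady Stokes
equations

    Re du/dt + grad p = lap u + f,    div u = 0,

with `Re = 0.01`. The driving force `f_body = a (sin(pi y / ly), 0)`
establishes a half-sine velocity profile with closed-form steady state
`u(y) = a (ly/pi)^2 sin(pi y / ly)`; this serves as an exact oracle for the
solver tests.

Cells are closed Lagrangian chains `X(q)` carrying three elastic energies:

* stretching, `ks/2 ∫ (|dX/dq| - 1)^2 dq` — springs with unit rest
  stretch, so the undeformed shape (sampled at its own arclength spacing)
  is the energy minimum;
* bending, `kb/2 ∫ |d²X/dq²|² dq` — no reference curvature is imposed;
* an area penalty, `ka/2 (A - A0)^2`, with `A` the shoelace area and `A0`
  the initial enclosed area, which substitutes for the 3D volume
  constraint and controls the slow area loss the classical immersed
  boundary method otherwise accumulates.

The Lagrangian force density is the exact negative gradient of the summed
discrete energy; every term is verified against central-difference
gradients of the energy in the test suite, and each conserves linear and
angular momentum identically.

Walls are elastic structures tethered to static target points `Z` by stiff
linear springs `F = -k_tether (X - Z)`. Two geometry models are provided:

* **microscopic**: `n_bundles` evenly spaced fans of `fibers_per_bundle`
  open fibers per wall, each fiber tethered at its root on the domain
  boundary, all tips reaching the layer height `h`. The bundle-density
  label is `n_bundles / 2` (10 bundles = healthy density 5; 2 bundles =
  septic density 1).
* **macroscopic**: a continuous sine `y(x) = A sin(a x) + h` with
  `A = 0.336`, integer spatial frequency `a lx / (2 pi)`, every point
  tethered. Thickness is `A + h`. Arbitrary wall shapes (e.g. traced from
  intravital microscopy) enter through the same machinery as two-column
  polylines.

Structure and fluid communicate through the classical 4-point regularized
delta function: forces are spread onto the staggered grid, and structure
points move with the interpolated fluid velocity. Spreading and
interpolation use the same kernel and are exact discrete adjoints. For a
permeable wall a Darcy slip is added: the wall point velocity is

    U = u(X) + kp (F_tether · n) / ||dX/dq|| n,

with `n` the unit normal pointing into the channel, so a force pressing
fluid against the layer produces flux through it. `kp = 0` recovers the
impermeable wall exactly.

## Units and parameter values

The model works in micrometers and seconds with unit fluid viscosity, and
the elastic constants take the tabulated numeric values directly:

| parameter | value | meaning |
|---|---|---|
| `Re` | 0.01 | Reynolds number |
| `ks` | 3 (RBC), 30 (leukocyte) | membrane stretch stiffness |
| `kb` | 0.2 (RBC), 2 (leukocyte) | membrane bending stiffness |
| `ka` | 185 | area penalty |
| `k_tether` | 3200 | wall tether stiffness |
| `ks_esl` | 0.015 | wall fiber stretch stiffness |
| `kb_esl` | 0.001 | wall fiber bending stiffness |
| `kp` | 0–0.01 | wall porosity |
| `h` | 0.8464–1.7696 | ESL thickness |

The printed physical units of these constants are mutually inconsistent
(e.g. a tether constant in N/µm where the 2D energy functional requires
force per length per length), so the package treats them as the model's
nondimensional constants; the bending value corresponds to 2×10⁻¹⁹ N·m in
the bending unit `1 µN/m × µm²`. The wall fiber bending constant is not
tabulated anywhere; the default gives the fibers the same
bending-to-stretching ratio as the membrane (`kb_esl = ks_esl × kb/ks`),
keeping them soft — wall rigidity comes from the tethers, which is also
what keeps the explicit stability bound (and hence the default time step)
set by the tether term rather than by fiber bending.

One free choice remains: the amplitude `a` of the driving force. Taking
the printed `a = 1` literally produces fluid stresses that would stretch a
`ks = 3` membrane by ~50%, contradicting the model's own stated bounds of
<2% area loss and <3% perimeter drift. Simulation presets therefore drive
the channel with `a = 0.02`, placing peak membrane strain inside the <3%
regime — the same calibration logic by which `ka` is chosen to keep area
loss under 2%. Because Stokes flow is linear, lift/drag *fractions* and
all qualitative trends are unaffected by this choice; only absolute force
and velocity scales carry the factor.

A reduced single-cell channel. The printed single-cell domain (4π × 2π)
cannot contain an 8 µm cell between two 1.48 µm layers, so single-cell
experiments use a geometrically scaled biconcave cell (default major
diameter 3 model units, 4:1 aspect preserved) with `kb` scaled by the
square of the linear size, which preserves the bending-to-stretching
length scale and hence the shape dynamics. Multi-cell CFL experiments use
the full 8 × 2 µm cell in the 80 × 40 µm domain (or reductions of it).

## Discretization and numerics

* **Grid**: MAC staggering; `u` on vertical faces, `v` on horizontal
  faces, `p` at centers. Default resolution matches the reference setup:
  256 × 128 on 4π × 2π (h = π/64), and the same spacing on larger
  domains. Lagrangian spacing is half the Eulerian spacing.
* **Fluid solve**: Fourier transform in the periodic direction; for each
  wavenumber the fully coupled implicit (u, v, p) system on the y-line is
  solved directly (θ-scheme viscous terms, θ = 1/2 Crank–Nicolson by
  default; new-time pressure; exact discrete divergence constraint). All
  wavenumber blocks sit in one block-diagonal sparse matrix, LU-factorized
  once per configuration, so a step costs a handful of FFTs and one
  triangular solve. There is no splitting error: the discrete divergence
  is at machine precision every step, and the scheme is second-order in
  space and time (verified by Richardson self-convergence).
* **Coupling**: Heun predictor–corrector. Forces at `X^n` drive a
  provisional solve; structures are advanced with the interpolated
  velocities; forces are recomputed at the predicted positions; the fluid
  is re-solved with the stage-averaged force field; positions are
  corrected with averaged velocities.
* **Time step**: the fluid solve is unconditionally stable, so `dt` is
  limited by the explicit structure forces. `estimate_dt()` bounds the
  relaxation rate of each elastic term through the local mobility of a
  regularized point force (`lambda = mob · k_eff`, with the mobility
  factor calibrated once against an explicit stability bisection) and
  takes half the resulting stability limit. Tethers (`k_tether · dq`) or
  bending (`kb / dq³`) are typically the stiffest.
* **Near-wall truncation**: Lagrangian points within two cells of a
  y-boundary spread only onto interior nodes; lost weight is not
  renormalized. Cells are placed at least four grid cells from the layer,
  so this affects only wall structures rooted on the boundary.
* **Degenerate inputs**: coincident adjacent chain points, clockwise
  polygons, non-monotone wall polylines, and overlapping wall layers are
  rejected with specific errors; velocity blowup beyond a configurable
  bound aborts the run with diagnostics.

## Observables

Lift and drag are computed by summing the Lagrangian forces over the
immersed-boundary points at each saved step and flipping the sign:
`lift = -Σ F_y`, `drag = -Σ F_x`. A closed membrane's elastic force sums
to zero identically (translation invariance of its energy), so the sum is
carried by the wall structures, which transmit the cell's influence
through the fluid; the same identity makes the per-cell force records a
built-in momentum check. Reported magnitudes are absolute time averages,
aggregated over initial conditions that uniformly sample the wall's
spatial period (4 phase offsets in the reference protocol) with
Student-t 95% confidence half-widths.

CFL thickness averages, over evenly spaced vertical slices, the gap
between the outer edge of the cell core and the local wall surface;
empty slices are excluded and counted. Mean cell velocity is the
x-displacement rate of cell centroids (periodic coordinates are advected
continuously, so no unwrapping is needed), converted to mm/s. Density
maps accumulate the scanline-filled cell interiors over snapshots; the
map integrates to the mean total cell area by construction.

## Study conditions and what the tests show

Full-scale runs of the reference protocol (T = 50–200 s on 256 × 128 to
1630 × 815 grids) are overnight-scale computations. The package's test
suite runs the same machinery at reduced problem sizes, chosen as the
package's standard desk-scale conditions:

* membrane-conservation run: 128 × 64, one scaled RBC near the
  macroscopic wall, `t_end = 5` s;
* trend suites: 128 × 64, `t_end` = 3 s, two phase offsets, endpoint
  parameter values (thickness 0.8464/1.7696, frequency 2/8, density 1/5,
  `kp` 0/0.01), with a fixed initial clearance of four grid cells plus
  margin above the layer crest so that thickness changes do not change
  the initial near-wall distance. The center-of-mass migration check
  drives at amplitude 0.2 instead of 0.02: lateral migration develops on
  the shear-scaled horizon `a·t`, and `a·t ≈ 0.6` is the shortest window
  in which the bundle-density ordering of the migration rate is
  established (force fractions, by the linearity of Stokes flow, are
  insensitive to this choice);
* CFL runs: 128 × 64 on a 40 × 20 µm domain with ~10 full-size cells.

These conditions preserve the model structure, the parameter ratios, and
the deterministic protocol, but not the absolute magnitudes of the
full-scale study: trend checks at this scale are qualitative
(orderings and interactions), and quantities such as the steady-state CFL
thickness of a 31 µm channel are not expected to be reproduced
numerically by a 20 µm desk-scale run. Synthetic placements emulate
uniform hematocrit; they do not model aggregation, adhesion, or the
cell-size dispersity of real blood.

## Known limitations

* Two-dimensional: quantitative lift magnitudes and CFL thicknesses
  differ from 3D; trends are expected to transfer.
* No inertia (unsteady Stokes only), no pulsatility, and prescribed
  body-force driving rather than a pressure drop.
* No cell–cell or cell–wall contact potential: separation is maintained
  hydrodynamically and by resolution margins (≥4 grid cells), with no
  lubrication correction below the grid scale.
* Tether targets are static; dynamic ESL shedding or restructuring during
  a run is not modeled.
* The biconcave contour uses the classical Evans–Fung cross-section
  profile scaled to 8 × 2 µm; the original source's exact parametrization
  is not reproduced, and only the stated dimensions and symmetries are
  relied on.
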