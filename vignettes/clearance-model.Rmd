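---
title: "Modelling perivascular solute clearance from brain gray matter"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling perivascular solute clearance from brain gray matter}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The scientific question

Soluble metabolites such as amyloid-beta leave the brain parenchyma in two
stages: they diffuse through the narrow extracellular space (ECS) of gray
matter, and they are taken up into the basement membranes of capillary and
artery walls, along which they drain convectively out of the brain. When a
small tracer (3 kDa dextran) is injected into central gray matter it is
found up to 2.5 mm away within 5 minutes — far beyond what hindered
diffusion can deliver. `periclear` implements a two-compartment transport
model of this process on 2D brain-slice-like domains, so that
diffusion-only, bulk-flow and perivascular-drainage scenarios can be
compared quantitatively.

## The model

Two concentration fields are defined at every interior point of the slice
(the compartments are co-located "layers", not separate regions):

* ECS concentration $c$ (mol m$^{-3}$):
  $$\partial_t c = \nabla\!\cdot\!(D^* \nabla c) - (\mathbf u \cdot \nabla) c - k_b\, c,$$
  with effective (tortuosity-scaled) diffusion $D^*$, an optional
  white-matter bulk-flow velocity $\mathbf u$ along the fiber axis, and
  first-order take-up at rate $k_b$ into the membrane compartment.
* Basement-membrane concentration $c_b$:
  $$\partial_t c_b = -(\mathbf u_b \cdot \nabla) c_b + k_b\, c,$$
  pure advection at the apparent drainage velocity $\mathbf u_b$ plus the
  take-up source. Take-up is an exchange, not a loss: what leaves $c$
  enters $c_b$.

Membrane diffusion is exactly zero. (A finite-element implementation needs
a tiny nonzero value there to keep its system matrix non-singular; an
explicit finite-difference scheme has no such constraint, so the drainage
compartment is advection-only by construction.)

Boundary conditions are zero normal flux on all brain boundaries and along
the needle shaft, for both fields. At the needle tip the ECS field is
prescribed: $c = c_0$ during the injection ($0 \le t \le t_{\rm inject}$)
and $c = 0$ afterwards (the literal reading of the injection schedule,
mode `"dirichlet_zero"`). Whether the original solver treated the
post-injection tip as a localized sink or as a sealed wall is not
documented, so `"no_flux"` is available as an alternative; the two differ
only near the tip (the 5-minute detection distances move by well under a
cell at the default resolution, which is why the literal mode is a safe
default). The membrane field is never prescribed at the tip.

## Parameters

All values are SI; concentrations in mol m$^{-3}$ (numerically equal to
mM, which removes a unit hazard). Defaults in `default_parameters()`:

| parameter | default | meaning |
|---|---|---|
| `D_star` | 8.7e-11 m²/s | effective diffusion of 3 kDa dextran in gray matter at 37 °C |
| `lambda_gray` | 1.60 | gray-matter tortuosity (isotropic) |
| `lambda_white_par`, `lambda_white_perp` | 1.47, 1.68 | white-matter tortuosity along / across fibers |
| `u_white` | 1.75e-7 m/s | bulk flow along white-matter fibers |
| `u_b` | 8.33e-6 m/s | apparent perivascular drainage speed (2.5 mm / 5 min) |
| `k_b` | 2.5e-4 1/s | take-up rate into basement membranes |
| `k_d` | 0 | degradation rate (dextran is not degraded) |
| `c0` | 0.33 mol/m³ | injected concentration (1 µg/µl at 3 kDa) |
| `t_inject`, `t_total` | 120 s, 1920 s | 2 min injection + 30 min observation |
| `detection_fraction` | 1e-3 | detection threshold relative to `c0` |
| `C_max` | 0.5 | Courant-number bound of the explicit step |

`D_star` is treated as the *effective* gray-matter coefficient, since that
is what is measured in tissue. The free-medium coefficient needed for the
white-matter tensor is recovered as $D = D^* \lambda_{\rm gray}^2$ and then
divided by the white-matter $\lambda^2$ per axis, which keeps gray-matter
diffusion exactly at the measured value. The temperature correction
$D_{37} = D_{20} (T_{37}/T_{20})(\mu_{20}/\mu_{37})$ is provided as the
standalone utility `temperature_correct_diffusion()`; the default `D_star`
is already the corrected value, and because the reference temperature of
the underlying measurement is ambiguous in the source literature the
utility takes explicit temperatures and viscosities rather than guessing.

Uptake `k_b` applies in gray *and* white interior cells (the ECS equation
is written domain-wide), and the total first-order rate is `k = k_b`
with `k_d = 0` for dextran; `k_d` exists as a parameter for other solutes.

The ten simulation cases (`build_case()`, `case_ids()`) scale
$(D^*, u, u_b, k_b)$ by fixed multipliers: A1–A3 diffusion only (1, 5,
10×), B1–B3 add bulk flow (1, 5, 10×), C1–C4 add drainage and uptake at
full or reduced strength. `case_peclet()` reports each case's Péclet
number $Pe = L U / D$ with $L$ = 5.5 mm (brain height); the drainage cases
sit at $Pe \sim 10^2$–$10^3$, which is what makes convection decisive.
One published inconsistency is deliberately not reproduced: the printed
Péclet number of case C4 corresponds to the full drainage velocity even
though the case halves it, so C4's Pe is reported as computed from the
case's own multipliers.

## Synthetic geometries

The original study rasterized homogenized atlas slices. Those outlines are
not available as vector data, so `slice_spec()` builds parametric
stand-ins that hard-code the three features the measured quantities
actually depend on:

1. the overall bounding box (coronal 8.0 × 5.5 mm, sagittal 13.7 × 5.5 mm);
2. the needle-tip position (coronal (5.7, 2.8) mm, sagittal (6.1, 3.9) mm
   — the figure-caption coordinates, which are more specific than the
   prose description of the injection site);
3. on the coronal slice, the distance from the tip to the brain boundary
   along the drainage direction: 2.46 mm.

Constraint 3 is implemented by shaping the interior right of the tip as a
half-disc of radius 2.46 mm centred on the tip. This makes the maximum
Euclidean tip-to-boundary distance on that side exactly 2.46 mm at every
height, which is what pins the full-model detection distance at the same
value from 5 min onwards — the behaviour reported for the drainage cases.
The raster domain is padded to 8.2 mm to contain the arc. The rest of the
outline (rounded corners, the white-matter band) is acknowledged
invention: the bulk-flow cases show that white-matter detail does not move
the detection front, and the default band is placed 1.6 mm above the
injection site with its fiber axis along the band, far enough that
detectable tracer reaches it only in the elevated-diffusion cases. The
needle is a 50 µm wide no-flux rectangle from the top boundary down to the
tip; the two cells at its lower end are the inflow cells.

What the stand-ins do *not* emulate: true atlas outlines, the actual
white-matter structures and fiber directions of the homogenized slices,
the vascular tree (drainage is a single constant direction per slice, +x
coronal, +y sagittal), and anything 3D. Passing tests therefore validate
the transport model and its numbers on a faithful *parametric* geometry,
not anatomical detail. On the sagittal stand-in the drainage direction
meets the brain surface 1.6 mm above the tip, so its drainage cases pin at
that shorter distance; the published sagittal drainage distances exceed
the maximum advective reach $u_b t$ and are attributed to an early
transient in the original solver — they are documented here, not modelled.

## Numerics

Uniform Cartesian grid (default `dx` = 25 µm, needle two cells wide),
stair-step boundaries, forward-Euler time stepping:

* **Diffusion** in conservative flux form; face coefficients are harmonic
  means of the adjacent cells' tensor components, zero across needle and
  exterior faces (no-flux walls for free). The white-matter tensor's
  off-diagonal component (rotated fiber axes) is discretized as
  $\partial_x(D_{xy}\partial_y c)+\partial_y(D_{xy}\partial_x c)$ with
  centered cell gradients averaged to faces; a pulse released under a 45°
  tensor reproduces the rotated anisotropic Gaussian to well under 2%
  $L^2$ error (see the test suite).
* **Advection** (both compartments) as first-order upwind in flux form.
  In uniform-velocity interiors this is identical to the non-conservative
  upwind update of the written equations, and at boundaries the advective
  flux vanishes, so tracer accumulates at the downstream wall instead of
  leaking. A consequence worth stating: with the injection off and the
  needle sealed, total moles are conserved to round-off, which the mass
  ledger asserts rather than enforces.
* **Time step**: `stable_dt()` takes the minimum of the Courant bound
  `C_max * dx / max speed` and the diffusive cap
  `0.9 * dx^2 / (4 * max tensor eigenvalue)`; one global `dt` is used per
  output interval (the interval length divided into equal substeps). With
  all transport off the bound is infinite and the output cadence (default
  10 s) caps the step.
* **Initial condition** `c = c_b = 0`; the injection supplies all mass.
* **Divergence guard**: any non-finite value or |value| above ten times
  the injected concentration aborts with the offending time.

Numerical diffusion of the first-order upwind scheme smears the drainage
front over a few cells; since the detection metric thresholds at 0.1% of
`c0`, this moves first-passage times by at most a few output intervals at
the default resolution, which is inside the tolerances used in the tests.

## Detection metric

`detection_distance()` returns the largest Euclidean distance from the
injection site to the center of any cell at or above the threshold.
Choices fixed here, in decreasing order of consequence:

* **Compartment**: the threshold criterion is scanned over the pointwise
  maximum of $c$ and $c_b$ (`"combined"`, the default) — an assay detects
  tracer wherever it sits, and the drainage-case front is carried by the
  membrane compartment, so scanning the ECS alone would miss it.
  Per-compartment distances are always recorded alongside.
* **Connectivity**: none required. The detected region may be
  disconnected (the drainage cases genuinely produce a detached patch at
  the boundary with a below-threshold stream behind it); the maximum is
  taken over all qualifying cells.
* **Resolution**: distances are cell-center values with no sub-cell
  contour interpolation, so they carry a quantization error of at most
  $dx/\sqrt2$.
* **Timing**: summary distances are evaluated 5 and 30 minutes after the
  *end* of the injection, i.e. simulation times 420 s and 1920 s, and
  first-passage times are reported relative to the end of injection.

## Problem sizes and the refinement study

The package replaces adaptive mesh refinement (out of scope along with
FEM) by a uniform-grid refinement study, `convergence_study()`, using the
same probe-point criterion: dimensionless concentration $c/c_0$ at fixed
probes 5 min after the injection, compared across successive grid
halvings. At the default 25 µm the diffusion-only detection distance at
that time changes by under 1% when the grid is halved to 12.5 µm. The
test suite runs the full coronal geometry at 25 µm for the headline
quantities and 50 µm grids for structural properties; the analytic-oracle
tests (heat kernel, two-box exchange, pulse advection) use calibration
rectangles sized so that boundaries stay several standard deviations away
from the released pulse. These sizes are the package's own defaults and
complete in seconds per case on one CPU.

## Known limitations

* 2D only, prescribed velocities (no flow solve), first-order uptake only.
* The drainage pathway is a straight line per slice, not a vascular tree;
  distances beyond the drainage-direction boundary reach are produced by
  diffusion alone.
* Geometry stand-ins are parametric; region shapes beyond the three
  anchored constraints are not anatomical.
* Forward Euler + upwind is first-order accurate in time and in the
  advective terms; the step bound, not accuracy, is what the CFL check
  guarantees. For smooth diffusion-dominated fields the observed accuracy
  is far better (sub-percent against the heat kernel).
* The exploratory injection-driven convective flow is exposed as the
  `injection_velocity` parameter (a radial source flow at the tip during
  the injection) but is off by default and not part of the validated
  behaviour.
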