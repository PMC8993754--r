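---
title: "morphosim: model, numerics and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{morphosim: model, numerics and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The physical model

`morphosim` treats early embryonic tissue as a slow viscous continuum.
On developmental time scales (hours), embryonic tissue creeps: stress is
proportional to strain *rate*, not strain, so the constitutive law is a
viscosity tensor formally identical to a plane-stress Hooke tensor,

$$\sigma = H(E^*, \nu^*)\, \dot\varepsilon, \qquad
  \nabla \cdot \sigma = 0 .$$

Inertia is negligible (the quasi-static approximation): at every instant
the velocity field balances the applied boundary forces exactly. The
deformation history enters only through the evolving geometry, which is
advected with the computed velocity in a Lagrangian fashion. All fields
are two-dimensional: the body is modelled as a flattened lateral
projection of the post-neurulation tube, so out-of-plane invagination
mechanics are outside the model's scope by construction.

The driving forces are line forces along contractile cell lines:

* **Line tension** `T` along a curved contour produces the inward Laplace
  traction $T\kappa$. On a shrinking circular wound the traction grows as
  $1/R$ while the perimeter shrinks as $R$: the total force is constant
  and closure is linear in time.
* **Normal pressure** `P` is curvature-independent; its total force
  decays with the perimeter and closure slows exponentially.
* **Shear pairs** model the tangential line force $F = dT/ds$ of a
  tension gradient along a *straight* segment (where no Laplace term
  exists): constant shear along one half of the segment and the opposite
  value along the other, oriented head-on. The pure shear-pair actuator
  deliberately carries no normal component (which would act to
  straighten the boundary and oppose mouth invagination); a `normal_T`
  flag can add one for exploration.
* **Tension gradients** are uniform tangential tractions signed toward a
  given direction (the dorsal median axis for the ear's dorso-ventral
  patterning bias; the body axis for ventral/dorsal neck pulls).
* **Negative surface tension** models the extensional work of cells
  stacked in a curved ridge: an outward normal growth stress
  $\gamma \kappa^m$. With $m = 1$ the growth stress is proportional to
  curvature; with $m = 2$ the growth response itself scales with the
  bending strain, and since the normal projection carries another factor
  of $\kappa$ the total effect is quadratic — sharper features grow
  faster, producing elongated processes with flatter sides.

Every actuator is re-evaluated on the *deformed* boundary at each step.
This is the model's essential self-consistency: a contraction advects and
shrinks its own source term. For a linear viscous problem driven by a
linear source the flux at the tip of a contracting segment of length $L$
is proportional to $L$, giving $dL/dt \propto -L$ and the exponential
self-arrest $L = L_0 e^{-t/\tau}$ that the `crenel_ear` scenario
verifies.

The quadflow module keeps the closed-form precursor of the shear pair: the
stream function of two head-on pulling source lines,
$$\Psi = \alpha\ln((x-a)^2+(y-b)^2) - \alpha\ln((x-a)^2+(y+b)^2)
       - \beta\ln((x-c)^2+(y-b)^2) + \beta\ln((x-c)^2+(y+b)^2),$$
with $(u,v) = (\partial_y\Psi, -\partial_x\Psi)$ hand-derived (and
unit-tested against central finite differences rather than differentiated
symbolically at run time). This flow advects a passive contour in a
*frozen* field — deliberately not self-consistent — and serves as an
early-time cross-check for the finite-element shear-pair scenarios.

## Parameters and defaults

* `E_star = 2` — stiffness-analog over a body dimension of order 0.4
  model units; with physical scalings (body width ~500 µm, tissue
  stiffness ~1000 Pa, strain rates ~1e-3/s) this puts the model in the
  physiological range. Converters to physical units are deliberately
  absent from the solver: all quantities are dimensionless model units.
* `nu_star = 0.45` — the tissue carries bulk in addition to shear
  viscosity; the exact value is unknown, so the Poisson-analog is
  configurable with a near-incompressible but non-singular default.
  Whether the original material law was a plane-stress or plane-strain
  analog is equally unknown; plane stress is used here.
* Placode softness `f` in `[0, 1]` multiplies `E_star` region-wise;
  `f = 0.01` stands for "very soft" tissue and `f = 0` removes the
  placode from the mesh entirely (an open notch).
* Actuator magnitudes (`T`, `P`, `F`, `strength`, `gamma`) are
  order-unity model values. The original experiments print no magnitudes,
  so the presets are *regimes*, not replications: each default was chosen
  once so that the run lands in the qualitative regime it names
  (closure that completes, an ear that rounds, a bump that nucleates)
  and is recorded in the scenario configuration, never hard-coded.
* Time stepping: explicit forward Euler with `dt = cfl * h_min / v_max`,
  `cfl = 0.2`. A step that would invert an element is rejected and
  retried at half the step, then forces a remesh.
* Solver: direct sparse factorisation (Matrix/CHOLMOD family); the
  algebraic residual on free dofs is checked at about 1e-10 relative.

## Geometry, curvature and remeshing

Domains are generated programmatically: an annulus (wound), a body
rectangle `[0, L] x [0, H]` with the mouth at `x = 0`, the neck at
`x = L`, dorsal at `y = H`, and an optional rounded head (circular arcs
of configurable radius replacing the sharp left corners — curvature is
undefined at a corner, so curvature-driven growth needs the smoothing;
the arcs belong to the `mouth` label so the `dorsal` label stays
straight).

Placodes (the crenel/trapeze territories inherited from the radial
cleavage lines) are *internal hairpin domains* hanging from the dorsal
line into the body: the hairpin contour is the `ear_crenel` chain, its
bottom — the dorso-ventral segment where the antagonistic contraction
acts — is the `ear_base` chain, and the enclosed region carries its own
material tag. This convention was chosen over a protruding notch because
the contraction then winds the territory *into* the body (narrow end
ventral, as an ear primordium should) and because a soft or absent
territory collapses laterally into a slit; with a protruding notch the
stress never reaches the free top of the notch and no slit can form.
With `f = 0` the hairpin becomes an open notch cut into the dorsal
boundary and the slit is the collapse of its walls.

Discrete curvature uses the circumscribed circle through three
consecutive boundary vertices, signed by the cross product of the
adjacent edge vectors. Each closed loop is treated in its own
counter-clockwise frame (normal away from the enclosed region), so a
circle always has $\kappa = +1/R$; label sub-chains borrow stencil
neighbours from their loop, interior chains fall back to one-sided
stencils at their ends (flagged in the output). Growth actuators skip the
terminal vertices of open chains — they sit at label junctions (corners)
where curvature is not defined. Convexity clamping
(no growth where $\kappa \le 0$) is the default, with an unclamped signed
option.

Meshing samples the boundary at the target edge length `h`, seeds the
interior with a deterministic hexagonal lattice kept `0.7 h` away from
every constrained segment (so each constrained segment has an empty
diametral circle and must appear as a Delaunay edge), triangulates with
an unconstrained Delaunay kernel, culls triangles by centroid location
and repairs the kernel's near-degenerate output (flip-based recovery of
missing constrained edges, collinear-sliver removal, a second kernel as
fallback). Remeshing preserves every boundary and feature-chain vertex
exactly — they are material points — and only regenerates free interior
vertices; region tags are re-assigned by point location inside the
(advected) region polygons. A self-intersecting boundary is detected
before triangulation and ends the run as `boundary_contact` with the
trace up to that point.

No randomness is consumed anywhere: boundary sampling, lattice seeding
and the kernel jitter (a fixed sub-tolerance pattern breaking exact
co-circularity) are all deterministic, so identical configurations
reproduce observable CSVs bit-exactly. The `seed` field of a scenario
configuration is recorded for provenance.

## Closure-law fitting

`fit_closure_law` discards a configurable burn-in fraction (default 0.2,
covering the initial-deformation transient), then fits a linear law by
least squares and an exponential law by least squares on $\log L$
(the log-linear plot) refined by nonlinear least squares on the original
scale. Both models are scored by $AIC = n\log(RSS/n) + 2k$ with $k = 2$
each, computed on the original `L` scale so the two are comparable; ties
select linear. The `crenel_ear` preset follows the contraction to 60% of
the initial base length: that is the window over which the decay stays
log-linear ($R^2 \ge 0.99$) before the crenel geometry departs from the
self-similarity that underlies $dL/dt \propto -L$; over much longer runs
the effective rate keeps falling as the territory rounds off.

## Verification

* **Patch test** — consistent tractions of a uniform strain rate are
  reproduced to machine precision on any admissible mesh (constant
  tractions integrate exactly under edge lumping).
* **Manufactured solution** — the harmonic, divergence-free field
  $u = (x^2 - y^2,\, -2xy)$ satisfies the stationary momentum balance
  for any isotropic $H$; nodal errors converge at order ~2 over three
  structured refinements (8, 16, 32 cells per side).
* **Axisymmetric oracle** — the annulus loaded by a uniform inward
  traction on its hole matches the plane-stress thick-cylinder solution
  $u = Ar + B/r$ within 2%, with angular variance below 1%.
* **Mirror symmetry** — symmetric geometry, loads and constraints give a
  mirror-antisymmetric velocity field to 1e-10 on structured meshes.
* **Flow oracles** — $\Psi(x, 0) = 0$ exactly; analytic velocities match
  finite differences to better than 1e-6 relative; the five-point
  Laplacian vanishes at second order on nested grids away from the
  sources; advected closed contours conserve area to 0.1% and markers
  stay on their streamline.

These verifications bound the *numerics*; what passing scenario tests say
about real embryos is weaker. The scenarios establish ordinal, regime
level facts of the model (linear vs exponential closure, slit vs rounded
ear, hindered invagination, faster quadratic growth, nucleated buckling)
— not quantitative shape agreement with any organism, which is out of
scope along with imaging, velocimetry and 3D mechanics.

## Known limitations

* Explicit stepping makes long runs with strong growth feedback
  expensive: the quadratic-growth instability sharpens its own tip,
  curvature and velocity climb, and the CFL step collapses. Presets stop
  on a time horizon before this regime.
* The contact of boundary segments (a closing slit, a deeply folded
  mouth) is a hard stop, not a resolved mechanical contact.
* Remeshing preserves boundary vertices exactly, so a strongly
  contracted boundary keeps its (now short) edges and drags the CFL step
  down with it; boundary coarsening is deliberately not performed because
  boundary vertices carry the labels and chain identities.
* The "surface shear varying with the gradient of curvature" coupling is
  not auto-derived from $\kappa$; in the free-morphology scenario the
  normal and tangential magnitudes are independent free parameters.
* Bulk (volumetric) growth forces are out of scope; growth enters only
  through the boundary stress term.

## Problem sizes

The default presets use `h = 0.05` on the annulus (~2.5k triangles) and
the body (~1.7k), `h = 0.04` for the head-growth scenarios (~1k on the
smaller head domain) and for the ear-contraction mesh-stability
comparison (~2.8k). A full acceptance recomputation
(`scripts/acceptance.R`) is about one minute on one CPU; the test suite
is under a minute.
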