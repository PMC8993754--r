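# morphosim

A 2D quasi-static viscous finite-element simulator for the tensional
mechanics of early vertebrate morphogenesis.

Early embryonic tissue behaves, on developmental time scales, as a slow
viscous material pulled by two orthogonal families of contractile
actin-myosin lines inherited from the first cleavages: circumferential
"purse-string" rings that roll the flat blastodisc into the body tube, and
radial lines whose later contraction positions the mouth and the sensory
organ (ear, eye, nose) primordia along the body. `morphosim` implements
this picture as composable boundary-force *actuators* acting on a
Lagrangian moving triangle mesh, for researchers in tissue biomechanics
who want a small, fully scriptable model of these processes.

## The model

The constitutive law is a Hooke-analog viscosity tensor relating stress to
strain rate,

    sigma = H(E*, nu*) d(eps)/dt,        div sigma = 0,

solved quasi-statically with linear (P1) triangles and a direct sparse
factorisation; the mesh is advected explicitly (forward Euler with a CFL
bound) and re-triangulated when element quality degrades. Boundary forces
are re-evaluated on the deformed boundary at every step, so a contraction
shrinks its own source term — the self-arrest mechanism by which these
morphogenetic movements stop on their own. The available actuators are:

| kind                  | traction                                | role |
|-----------------------|------------------------------------------|------|
| `line_tension`        | `T kappa (-n)` (Laplace purse-string)    | wound/ring closure at constant tension |
| `normal_pressure`     | `P (-n)`                                 | closure at constant pressure |
| `shear_pair`          | `+/- F t`, split at the arclength midpoint | antagonistic D-V contraction (ear, mouth) |
| `tension_gradient`    | tangential, signed toward a direction    | dorsal-ward tension bias, ventral/dorsal pulls |
| `extensional_shear`   | shear pair, outward sense                | neural-tube elongation |
| `neg_surface_tension` | `gamma kappa^m (+n)`, `m` in {1, 2}      | growth of curved ridges (lips, nasal processes, bulges) |

A companion closed-form module (`quad_psi`, `quad_velocity`,
`quad_advect_contour`) implements the quadrupolar potential flow of two
head-on pulling source lines — the non-self-consistent precursor of the
shear-pair actuator — with an analytic stream function that is odd in `y`,
harmonic away from its four logarithmic sources, and exactly
divergence-free.

Fifteen scenario presets (`scenario_names()`) reproduce the model
experiments: wound-ring closure under constant tension vs constant
pressure, crenel-ear contraction (plain, with dorsal tension gradient,
asymmetric, soft/slit), mouth invagination, neck flexure, dorsal
extension, nasal-process growth linear and quadratic in curvature, free
normal+tangential boundary stresses, and a placode-nucleated dorsal
buckling bulge. Analysis utilities fit linear vs exponential closure laws
(AIC-selected) and compute shape metrics (area, perimeter, principal-axis
aspect ratio, isoperimetric ratio, chord deflection).

## Worked example: purse-string wound closure

```r
library(morphosim)

mesh <- build_annulus(outer_radius = 1, hole_radius = 0.3,
                      target_edge_length = 0.05)
print(mesh)
#> trimesh: 1354 vertices, 2544 triangles, 164 boundary edges
#>   labels: outer, hole
#>   area 2.8588, min quality 0.594, h = 0.05

res <- run_preset("wound_ring_tension")
print(res)
#> sim_result: 37 steps, final time 0.3426, stopped by observable
#>   observables: hole_radius, total_force

fit <- fit_closure_law(data.frame(time = res$trace$time,
                                  value = res$trace$hole_radius))
print(fit)
#> closure_trace: 31 points, selected law: linear
#>   linear: slope -0.60717 (AIC -466.1)
#>   exponential: tau 0.28352 (AIC -316.2, log-linear R2 0.9823)

range(res$trace$total_force)
#> [1] 6.2743 6.2822      # constant, = 2*pi*T up to discretisation
```

The hole radius shrinks *linearly* in time: the Laplace traction `T/R`
grows exactly as the perimeter `2 pi R` shrinks, keeping the total inward
force constant (`2 pi T = 6.2832`). Re-running with
`run_preset("wound_ring_pressure")` — the same initial total force applied
as a constant pressure — selects the exponential law instead: the total
force now decays with the perimeter and the closure slows itself down.
The same self-arrest appears in the ear scenario, where the contracting
D-V segment length follows `L = L0 exp(-t / tau)` (`dL/dt` proportional
to `-L`).

A command-line front end is installed with the package
(`system.file("scripts", "morphosim", package = "morphosim")`) with
`run`, `fit-closure`, `flow` and `compare` subcommands; scenario
configurations are declarative YAML files that round-trip bit-exactly
(`write_scenario_config` / `read_scenario_config`).

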