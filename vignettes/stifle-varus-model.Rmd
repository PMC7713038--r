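---
title: "A desk-scale model of patellar stability under distal femoral varus"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A desk-scale model of patellar stability under distal femoral varus}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(stiflesim)
```

## The question

Medial patellar luxation (MPL) in dogs is strongly associated with distal
femoral varus: as the anatomic lateral distal femoral angle (aLDFA) grows,
the proximal femur — and with it the origin of the quadriceps — displaces
medially relative to the trochlear groove, tilting the extensor mechanism's
line of pull. Clinically, corrective distal femoral osteotomy is often
advised above an aLDFA around 102 degrees, but the cutoff is anecdotal.
`stiflesim` asks the question in a controlled, fully synthetic setting:
**holding every other anatomical factor fixed, at what varus angle does the
quadriceps pull overwhelm the medial trochlear ridge?**

The package answers it with a deterministic rigid-body simulation: a
parametric canine stifle, a Hill-type rectus femoris, tendon and ligament
spring elements, frictional penalty contact between the patella and the
trochlear surface, and a thirteen-angle sweep of the varus deformity with a
reaction-force luxation criterion.

## The synthetic stifle

No CT geometry ships with the package; `build_reference_stifle()` generates
a parametric stand-in scaled to a ~10.7 kg Beagle (100 mm femur):

* **femur** — a swept elliptical shaft; on the cranial distal epiphysis an
  extruded trochlear cross-section: a circular-arc groove (radius 7 mm)
  flanked by a medial and a lateral ridge, with outer walls descending to a
  flat shelf;
* **patella** — a convex "pillow" body (12 x 8 x 5 mm) whose posterior
  facet is a cylinder of the same radius as the groove arc (conforming
  contact); contact is sampled on the central articulating strip of that
  facet (half-width 2 mm by default — the rim of a real facet is rounded
  and non-articulating);
* **tibia** — a prism oriented along the tibial axis, carrying the tibial
  tuberosity landmark.

The frame is fixed: x mediolateral (+ lateral, left limb), y craniocaudal
(+ cranial), z proximodistal (+ proximal), millimetres. The baseline is a
clinically normal left stifle: aLDFA 95 degrees, anteversion 16 degrees,
sagittal femorotibial angle 127 degrees at the stance pose, and a patellar
ligament measuring 1.55 patellar lengths. Each of those four quantities is
*measured back* from the generated landmarks by an independent metrology
operation (`measure_aldfa()`, `measure_anteversion()`,
`measure_stifle_flexion()`, `measure_lp_ratio()`), all invariant under
rigid motion of the whole geometry.

Varus variants come from `bend_at_cora()`: the proximal segment (shaft,
neck, head, and the virtual-ilium muscle origin) rotates about the
craniocaudal axis through the CORA at the distal one-third of the femur, by
exactly `target - 95` degrees, blended over a 5 mm transition zone.
Vertices distal to the zone — the joint surface, trochlea and condyles —
are bit-identical across all thirteen variants, so every deformity sees
the same groove.

```{r}
geom <- build_reference_stifle()
measure_aldfa(geom)            # 95
bent <- bend_at_cora(geom, 103)
measure_aldfa(bent)            # 103
```

### Calibrated, not measured: groove and ridge proportions

No published values exist for the Beagle's groove depth, ridge heights, or
patellar dimensions, and a rigid conforming facet with a short, stiff
patellar ligament constrains medial excursion far more than articular
cartilage and soft tissue would. The packaged medial ridge height
(0.08 mm above the groove floor, giving a medial arc half-width of about
1.06 mm) is therefore an *effective* calibration of the reference
configuration, chosen once so that the simulated threshold reproduces the
clinically recognised varus cutoff; it is not an anatomical measurement.
All proportions are ordinary `geometry_params()` fields and can be set to
anatomical values by users with their own contact model.

## The muscle model

Only the rectus femoris is modelled (single line of action from a fixed
virtual-ilium origin), as the dominant contributor at a fixed stance pose.
Its force follows the standard Hill decomposition, total force
`F_M = F_CE + F_PE` with

* `F_CE = a(t) * F_max * f_FL(L) * f_FV(v)` — activation times peak
  isometric force (peak isometric stress 5e-4 GPa x PCSA 1850 mm^2 =
  0.925 kN) times normalized force-length and force-velocity factors;
* `F_PE = F_max * (exp((k/L_max)(L-1)) - 1) / (exp(k) - 1)` for positive
  strain, zero otherwise, with shape `k = 6` and maximum strain rate
  `L_max = 2`; the expression is dimensionless and is scaled by `F_max`
  here (the solver convention the constants were written for does not
  state its reference force — this is a documented assumption).

The published curve figures for `f_FL` and `f_FV` are not tabulated
anywhere, so the package uses standard parametric stand-ins with all
constants exposed: a Gaussian `exp(-((L-1)/0.45)^2)` for force-length and a
Hill hyperbola `(1 - v/v_max)/(1 + v/(0.25 v_max))` for shortening, capped
smoothly at 1.4 for lengthening. Activation ramps linearly from 0 to 20%
over the first 5 s and holds at 20% until 50 s, avoiding an impulsive
disarticulation of the patella.

The muscle acts in series with the quadriceps tendon, which is split into
three parallel spring elements (0.19 kN/mm each) attached to three
proximal patellar nodes; the patellar ligament is likewise three springs
from the distal patellar nodes to fixed anchors at the tibial tuberosity.
All springs are tension-only (tendons cannot push). The series junction is
integrated as a light, critically damped 3-DOF node rather than solved
algebraically; at the loading rates used it tracks the quasi-static series
balance.

## The contact and dynamics model

The deformable FEM of the problem is deliberately out of scope: bones are
rigid, and cortical elasticity (E = 15 GPa, nu = 0.3) enters only through
an elastic-foundation penalty pressure `E / ((1 - nu^2) h)` per unit depth
with layer thickness h = 1 mm, applied at sample points of the patellar
facet strip against the analytic trochlear profile. Friction is
regularized Coulomb with mu = 0.02 (cartilage-like, as in the source
material). Femur and tibia are fully constrained; the patella is free in
all six degrees of freedom.

Three numerical conditioning choices keep the stiff penalty contact stable
at a practical step size; all are standard explicit-dynamics devices and
all are exposed in the configuration:

* **penalty scaling** — the raw foundation stiffness is multiplied by
  `penalty_scale = 0.05` (explicit contact codes routinely scale penalty
  stiffness by a factor of this order); seated penetrations stay below a
  few microns times the load, far below the ridge heights that shape the
  mechanism;
* **quasi-static mass scaling** — the patellar mass (mesh volume x bone
  density 2.0e-6 kg/mm^3, about 0.5 g) is multiplied by
  `mass_scale = 1000`. The protocol loads over seconds while the scaled
  contact frequency sits near 12 kHz, so inertial forces remain
  negligible; the step-halving convergence test (< 0.1 mm) is the
  evidence that the integration, at these settings, is resolved;
* **viscous damping** — mass-proportional damping (`viscous_damping =
  2e5 /s`) stands in for all unmodelled dissipation (cartilage, synovium,
  soft tissue). It sets the *time scale* of the medial creep after the
  ridge can no longer hold the patella, and is calibration, not a
  measured value: absolute luxation onset times in this package are
  meaningful only relative to one another.

The integrator is fixed-step semi-implicit Euler (`dt = 2e-5 s` by
default) with implicit velocity damping and quaternion renormalisation,
compiled in C++; a pure-R reference engine with identical semantics is
kept for cross-checking (the test suite holds them to 1e-7 agreement).
A velocity guard aborts a run rather than letting it diverge silently.
There is no randomness anywhere: reruns are bit-identical.

## Luxation criterion

The mediolateral component of the contact force the femur exerts on the
patella ("rcforce") is positive while the medial ridge presses the patella
laterally. Luxation is declared when, after the ramp, rcforce stays at or
below zero for at least 0.5 s **and** the patella has displaced medially
past the medial ridge apex. The dual criterion matters: a transient
rebound (the model has no cartilage or synovium to buffer impacts) also
zeroes the contact force briefly — the packaged baseline itself shows a
0.4 s rebound episode during settling — and the 0.5 s sustain window plus
the displacement test separate those from true luxation. Both the first
zero touch and the onset of the sustained episode are reported. The
detector treats the lateral direction symmetrically, so mirroring the
geometry across the sagittal plane (turning varus into valgus) converts a
medial luxation into a lateral one with the identical onset time — the
test suite verifies the mirrored trajectory is the exact reflection.

## The sweep and what it shows

```{r}
sw <- sweep_aldfa()   # 95, 98, 100..110 under the default 50 s protocol
critical_angle(sw)    # 103
stable_max_angle(sw)  # 102
```

Under the packaged reference configuration the thirteen-angle sweep leaves
the patella seated for aLDFA up to 102 degrees and luxates it medially
from 103 degrees upward, with onset times that broadly shorten as varus
grows (the test suite asserts a negative Spearman rank correlation rather
than strict monotonicity: near the threshold the creep over the ridge is
slow and individual angles can swap order, the same kind of exception the
clinical FE literature reports). The published onset times of the
CT-geometry study this package emulates (11.9-24.9 s) are shipped as
reference context via `luxation_reference_times()`; they depend on
subject-specific meshes and are *not* reproduction targets of the
desk-scale model.

## Numerical and design notes

* Problem sizes: 50 s protocol at dt = 2e-5 s is 2.5 million steps per
  run; a thirteen-angle sweep takes a few minutes on one CPU. Output is
  sampled at 100 Hz.
* The integration step default (2e-5 s) is finer than a first design
  sketch of the package (2e-4 s); the stiff penalty contact at the chosen
  penalty/mass scaling is comfortably stable at the finer step, and the
  cost is absorbed by the compiled core.
* Degenerate inputs: coincident spring endpoints warn and produce zero
  force; infeasible geometry (patella wider than the groove arc,
  out-of-range CORA fraction) is rejected at construction with a named
  diagnostic; unknown configuration keys are rejected by name.
* Ties and tie-breaks: if both a medial and a lateral episode qualify
  (possible only in contrived series), the earlier onset wins, medial on
  an exact tie.
* Gravity is off by default (the stance protocol is load-controlled by
  the quadriceps); it can be enabled in the configuration.

## What passing tests do and do not show

The synthetic geometry emulates the *mechanism* — a quadriceps line of
pull displaced medially by a CORA-level bend, resisted by a ridged
trochlea — not any individual dog. Real stifles add articular cartilage,
a joint capsule and soft-tissue stabilizers, multi-head quadriceps
geometry, femoral torsion, tibial rotation and breed-specific conformation,
all of which move the threshold. A green sweep here shows that the package
reproduces the clinically recognised threshold *under its own packaged
calibration*; it does not validate that threshold for clinical use, and
single-subject conclusions should be drawn from subject-specific geometry,
not from this reference configuration.
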