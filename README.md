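# stiflesim

Desk-scale biomechanical simulation of **medial patellar luxation (MPL)
under distal femoral varus** in the dog.

Distal femoral varus — quantified by the anatomic lateral distal femoral
angle (aLDFA), the frontal-plane angle between the femoral shaft axis and
the distal joint line measured on the lateral side — displaces the
quadriceps line of pull medially relative to the trochlear groove. Past
some angle the medial trochlear ridge can no longer resist the medial
component of the quadriceps force and the patella luxates. `stiflesim`
reproduces that mechanism with everything else held fixed:

* a **parametric canine stifle** (femur with a circular-arc trochlear
  groove flanked by medial/lateral ridges, patella with a conforming
  cylindrical facet, tibia), generated at a clinically normal baseline —
  aLDFA 95°, anteversion 16°, sagittal femorotibial angle 127°, patellar
  ligament 1.55 patellar lengths — each value measurable back from the
  geometry by an independent metrology operation;
* **virtual osteotomy**: `bend_at_cora()` rotates the proximal femoral
  segment about the craniocaudal axis through the CORA (distal one-third
  of the femur) to any target aLDFA, leaving the distal epiphysis
  bit-identical across variants;
* a **Hill-type rectus femoris** (`F_M = a(t)·F_max·f_FL·f_FV + F_PE`,
  with `F_max` = peak isometric stress × PCSA = 0.925 kN) acting through
  three quadriceps-tendon springs and three patellar-ligament springs
  (0.19 kN/mm each, tension-only), activation ramping 0→20 % over 5 s and
  held to 50 s;
* **6-DOF rigid-body dynamics of the patella** against frictional penalty
  contact (μ = 0.02) with the trochlear surface, femur and tibia fully
  constrained, integrated by a compiled fixed-step semi-implicit Euler
  core (deterministic: reruns are bit-identical);
* a **luxation criterion** on the mediolateral patellofemoral reaction
  force ("rcforce"): sustained loss of medial-ridge support (rcforce ≤ 0
  for ≥ 0.5 s) together with displacement past the ridge apex.

See `vignettes/stifle-varus-model.Rmd` for the model, its assumptions,
the packaged calibration, and what the results do and do not show.

## Worked example

```r
library(stiflesim)

geom <- build_reference_stifle()
measure_aldfa(geom)            # [1] 95
measure_anteversion(geom)      # [1] 16
measure_stifle_flexion(geom)   # [1] 127
measure_lp_ratio(geom)         # [1] 1.55

res <- run_simulation(bend_at_cora(geom, 106))
detect_luxation(res)
#> <luxation_report: aLDFA 106.0 deg -> LUXATED (medial) at 17.01 s>
#>   first rcforce zero touch: 6.43 s
#>   max medial displacement: 2.10 mm

sw <- sweep_aldfa()            # the default 13 angles: 95, 98, 100..110
critical_angle(sw)             # [1] 103
stable_max_angle(sw)           # [1] 102
```

The luxation report reads: at aLDFA 106° the reaction force between the
patella and the medial trochlear ridge first touched zero 6.4 s into the
protocol (a transient), dropped to zero-and-below for good at 17.0 s, and
the patella left the groove medially, travelling 2.1 mm past its stance
position — a medial luxation. Over the full sweep the patella stays seated
through 102° and luxates from 103° upward, matching the clinically
recognised threshold for corrective osteotomy.

Single runs and sweeps can be written to CSV + JSON with
`write_outputs()`, plotted with `plot_rcforce()` / `plot_displacement()`,
and driven from a shell via the thin `exec/stifle` wrapper
(`stifle sweep --angles 95,98,100-110 --out runs/`).

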