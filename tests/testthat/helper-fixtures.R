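# Shared fixtures. Expensive artefacts (the reference geometry, the full
# default sweep) are computed once per test run and cached in this
# environment.

.fixtures <- new.env(parent = emptyenv())

fixture_geometry <- function() {
  if (is.null(.fixtures$geom))
    .fixtures$geom <- build_reference_stifle()
  .fixtures$geom
}

## Full default 13-angle sweep under packaged defaults (the study
## conditions); shared between the acceptance checks.
fixture_default_sweep <- function() {
  if (is.null(.fixtures$sweep))
    .fixtures$sweep <- sweep_aldfa()
  .fixtures$sweep
}

## A short, cheap simulation for interface-level tests.
fixture_short_run <- function(total_time = 6) {
  key <- sprintf("run_%g", total_time)
  if (is.null(.fixtures[[key]]))
    .fixtures[[key]] <- run_simulation(
      fixture_geometry(), simulation_config(total_time = total_time))
  .fixtures[[key]]
}

## Hand-built landmark set with a known frontal-plane aLDFA construction.
analytic_landmarks <- function(aldfa = 100, anteversion = 0) {
  a <- aldfa * pi / 180
  aa <- anteversion * pi / 180
  joint <- c(sin(a), 0, cos(a))
  list(
    knee_center = c(0, 0, 0),
    medial_condyle_distal = -8 * joint,
    lateral_condyle_distal = 8 * joint,
    cora = c(0, 0, 30),
    shaft_axis_distal = c(0, 0, 40),
    shaft_axis_proximal = c(0, 0, 90),
    greater_trochanter = c(0, 0, 100),
    femoral_head_center = c(0, 0, 100) + 12 * c(-cos(aa), sin(aa), 1) /
      sqrt(2),
    tibia_proximal = c(0, 0, 0),
    tibia_distal = c(0, -40, -40) / sqrt(2) * sqrt(2),
    patella_apex = c(0, 10, 8),
    patella_base = c(0, 10, 20),
    tibial_tuberosity = c(0, 10, 8) + c(0, 0, -18.6)
  )
}

## Synthetic simulation_result wrapper for detector tests: build a result
## object directly from a reaction-force and displacement series.
synthetic_result <- function(t, rcx, disp_x, w_neg = 1, w_pos = 4,
                             ramp_end = 5) {
  n <- length(t)
  samples <- data.frame(
    time_s = t,
    pos_x_mm = disp_x, pos_y_mm = 0, pos_z_mm = 0,
    quat_w = 1, quat_x = 0, quat_y = 0, quat_z = 0,
    rcforce_x_kN = rcx, rcforce_y_kN = 0, rcforce_z_kN = 0,
    muscle_force_kN = 0.1, n_contacts = 1L, max_friction_ratio = 0)
  structure(list(
    aldfa_deg = 105,
    side = "left",
    samples = samples,
    displacement_origin = c(0, 0, 0),
    profile = list(w_neg = w_neg, w_pos = w_pos),
    config = list(simulation = list(total_time = max(t),
                                    ramp_end = ramp_end)),
    engine = "synthetic"
  ), class = "simulation_result")
}
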