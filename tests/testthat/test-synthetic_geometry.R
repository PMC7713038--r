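# Synthetic stifle generator: construction, metrology, CORA bending,
# mirroring, mesh integrity.

test_that("reference geometry measures back its configured angles", {
  g <- fixture_geometry()
  expect_equal(measure_aldfa(g), 95, tolerance = 0.5 / 95)
  expect_equal(measure_anteversion(g), 16, tolerance = 0.5 / 16)
  expect_equal(measure_stifle_flexion(g), 127, tolerance = 0.5 / 127)
  expect_equal(measure_lp_ratio(g), 1.55, tolerance = 0.01 / 1.55)
})

test_that("measurements agree with analytic landmark constructions", {
  lm <- analytic_landmarks(aldfa = 100)
  expect_equal(measure_aldfa(lm), 100, tolerance = 1e-9)
  expect_equal(measure_anteversion(analytic_landmarks(anteversion = 0)), 0,
               tolerance = 1e-9)
  expect_equal(measure_anteversion(analytic_landmarks(anteversion = 25)), 25,
               tolerance = 1e-9)
  ## collinear femur and tibia axes read 180 degrees
  lm$tibia_distal <- c(0, 0, -50)
  expect_equal(measure_stifle_flexion(lm), 180)
  expect_error(measure_aldfa(list(knee_center = c(0, 0, 0))),
               "missing landmarks")
})

test_that("all measurements are invariant under rigid motion", {
  g <- fixture_geometry()
  ref <- c(measure_aldfa(g), measure_anteversion(g),
           measure_stifle_flexion(g), measure_lp_ratio(g))
  set.seed(11)
  for (i in 1:5) {
    Rm <- stiflesim:::random_rotation()
    tr <- stats::rnorm(3, sd = 40)
    g2 <- transform_geometry(g, Rm, tr)
    got <- c(measure_aldfa(g2), measure_anteversion(g2),
             measure_stifle_flexion(g2), measure_lp_ratio(g2))
    expect_equal(got, ref, tolerance = 1e-9)
  }
})

test_that("CORA bending round-trips through measure_aldfa", {
  g <- fixture_geometry()
  for (target in c(95, 98, 100, 103, 107, 110)) {
    b <- bend_at_cora(g, target)
    expect_equal(measure_aldfa(b), target, tolerance = 0.5 / target)
  }
  ## bending to the baseline angle leaves the mesh bit-identical
  b0 <- bend_at_cora(g, 95)
  expect_identical(b0$femur_mesh$vertices, g$femur_mesh$vertices)
  expect_error(bend_at_cora(g, 130), "90, 120")
  expect_error(bend_at_cora(bend_at_cora(g, 103), 105), "baseline")
})

test_that("the distal epiphysis is bit-identical across all variants", {
  g <- fixture_geometry()
  base_block <- stiflesim:::distal_epiphysis_vertices(g)
  for (target in default_sweep_angles()) {
    b <- bend_at_cora(g, target)
    expect_identical(stiflesim:::distal_epiphysis_vertices(b), base_block)
    expect_identical(b$patella_mesh, g$patella_mesh)
  }
})

test_that("bend rotation is an affine function of the target angle", {
  g <- fixture_geometry()
  ## proximal shaft axis direction rotates by exactly (target - baseline)
  base_dir <- stiflesim:::vhat(g$landmarks$shaft_axis_proximal -
                                 g$landmarks$shaft_axis_distal)
  rot <- vapply(c(98, 101, 104, 107, 110), function(target) {
    b <- bend_at_cora(g, target)
    d <- stiflesim:::vhat(b$landmarks$shaft_axis_proximal -
                            b$landmarks$shaft_axis_distal)
    stiflesim:::vangle_deg(base_dir, d)
  }, numeric(1))
  expect_equal(rot, c(3, 6, 9, 12, 15), tolerance = 1e-9)
})

test_that("meshes are watertight and mirroring preserves angles", {
  g <- fixture_geometry()
  expect_true(mesh_is_watertight(g$femur_mesh))
  expect_true(mesh_is_watertight(g$patella_mesh))
  expect_true(mesh_is_watertight(g$tibia_mesh))
  m <- mirror_geometry(g)
  expect_equal(measure_aldfa(m), measure_aldfa(g))
  expect_equal(measure_anteversion(m), measure_anteversion(g))
  expect_true(mesh_is_watertight(m$femur_mesh))
  ## mirrored mesh keeps outward orientation (positive signed volume)
  expect_gt(stiflesim:::mesh_signed_volume(m$patella_mesh), 0)
  ## the profile swaps its ridge half-widths
  expect_equal(m$profile$w_neg, g$profile$w_pos)
  expect_equal(m$profile$w_pos, g$profile$w_neg)
})

test_that("infeasible parameter combinations are rejected with diagnostics", {
  expect_error(geometry_params(patella_width = 16), "wider than")
  expect_error(geometry_params(cora_fraction = 1.2), "between 0 and 1")
  expect_error(geometry_params(femur_length = -5), "positive length")
  expect_error(geometry_params(groove_depth = 10, groove_arc_radius = 7,
                               medial_ridge_height = 0.1),
               "groove_depth")
  ## ligament length default reproduces the configured L:P ratio exactly
  p <- geometry_params(patella_length = 9)
  expect_equal(p$ligament_length / p$patella_length, 1.55)
})
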