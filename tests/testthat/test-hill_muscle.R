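# Hill-type muscle model: activation schedule, force-length /
# force-velocity scaling, contractile and parallel elastic elements.

test_that("activation schedule ramps linearly to the plateau and holds", {
  expect_equal(activation_schedule(0), 0)
  expect_equal(activation_schedule(2.5), 0.10)
  expect_equal(activation_schedule(5), 0.20)
  expect_equal(activation_schedule(50), 0.20)
  ## piecewise linear and continuous: fine grid has no jumps larger than
  ## the local slope allows, and never exceeds the plateau
  t <- seq(0, 50, by = 0.01)
  a <- activation_schedule(t)
  expect_true(all(diff(a) >= 0))
  expect_true(all(a <= 0.20 + 1e-15))
  expect_lt(max(abs(diff(a))), 0.2 / 5 * 0.01 + 1e-12)
  expect_error(activation_schedule(-1), "non-negative")
})

test_that("peak isometric force is stress times PCSA in kN", {
  p <- hill_muscle_params()
  expect_equal(peak_isometric_force(p), 0.925)
  expect_equal(peak_isometric_force(hill_muscle_params(pcsa = 0)), 0)
  expect_equal(peak_isometric_force(hill_muscle_params(pcsa = 2 * 1850)),
               2 * 0.925)
})

test_that("force-length curve peaks at the optimum and is symmetric", {
  expect_equal(force_length(1), 1)
  expect_equal(force_length(1.45), exp(-1))
  for (d in c(0.05, 0.2, 0.4))
    expect_equal(force_length(1 + d), force_length(1 - d))
  L <- seq(0.3, 1.9, by = 0.01)
  expect_true(all(force_length(L) >= 0 & force_length(L) <= 1))
})

test_that("force-velocity curve is 1 at rest, bounded, non-increasing", {
  expect_equal(force_velocity(0), 1)
  expect_equal(force_velocity(2.0), 0)       # at v_max
  expect_equal(force_velocity(10), 0)        # beyond v_max
  v <- seq(-3, 3, by = 0.01)
  fv <- force_velocity(v)
  expect_true(all(fv >= 0 & fv <= 1.4 + 1e-12))
  expect_true(all(diff(fv) <= 1e-12))        # non-increasing in shortening
  expect_true(all(force_velocity(seq(-5, -0.01, by = 0.05)) <= 1.4))
})

test_that("contractile force follows a(t) x Fmax x fFL x fFV", {
  p <- hill_muscle_params()
  expect_equal(contractile_force(muscle_state(1, 0, 0), p), 0)
  expect_equal(contractile_force(muscle_state(1, 0, 0.2), p), 0.185)
  ## linear in activation at fixed length and velocity
  st <- function(a) muscle_state(1.1, 0.3, a)
  f1 <- contractile_force(st(0.25), p)
  expect_equal(contractile_force(st(0.5), p), 2 * f1)
  expect_equal(contractile_force(st(1), p), 4 * f1)
})

test_that("parallel elastic force: zero under compression, Fmax at L_max", {
  p <- hill_muscle_params()
  expect_equal(parallel_elastic_force(muscle_state(0.9), p), 0)
  ## continuity at zero strain
  expect_lt(parallel_elastic_force(muscle_state(1 + 1e-9), p), 1e-9)
  ## exact normalization: strain = L_max gives exactly Fmax
  expect_equal(parallel_elastic_force(muscle_state(1 + p$max_strain_rate), p),
               peak_isometric_force(p))
  ## non-decreasing in length
  L <- seq(0.5, 3, by = 0.01)
  f <- vapply(L, function(l) parallel_elastic_force(muscle_state(l), p),
              numeric(1))
  expect_true(all(diff(f) >= 0))
})

test_that("total force is F_CE + F_PE and scales with PCSA", {
  p <- hill_muscle_params()
  expect_equal(total_muscle_force(muscle_state(0.95, 0, 0), p)$magnitude, 0)
  expect_equal(total_muscle_force(muscle_state(1, 0, 0.2), p)$magnitude,
               0.185)
  st <- muscle_state(1.3, -0.2, 0.7)
  expect_equal(total_muscle_force(st, p)$magnitude,
               contractile_force(st, p) + parallel_elastic_force(st, p))
  ## all force terms linear in PCSA (dimensional analysis)
  p2 <- hill_muscle_params(pcsa = 3 * 1850)
  expect_equal(total_muscle_force(st, p2)$magnitude,
               3 * total_muscle_force(st, p)$magnitude)
  ## line of action from origin towards insertion, unit length
  lof <- total_muscle_force(st, p, origin = c(0, 0, 0),
                            insertion = c(0, 3, 4))
  expect_equal(lof$direction, c(0, 0.6, 0.8))
})

test_that("parameter validation rejects non-physical values", {
  expect_error(hill_muscle_params(pcsa = -1), "non-negative")
  expect_error(hill_muscle_params(fv_eccentric_cap = 0.5), ">= 1")
  expect_error(muscle_state(current_length = -1), "positive")
  expect_error(muscle_state(activation = 1.5), "0, 1")
  expect_equal(muscle_state(1.2)$strain, 0.2)
})
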