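# Rigid-body dynamics: springs, contact, integrator, engines.

test_that("spring force follows stiffness x elongation, tension-only", {
  sp <- spring_element(rest_length = 10)
  f <- spring_force(sp, c(0, 0, 0), c(11, 0, 0))
  expect_equal(f, c(-0.19, 0, 0))               # pulls b back towards a
  expect_equal(spring_force(sp, c(0, 0, 0), c(10, 0, 0)), c(0, 0, 0))
  expect_equal(spring_force(sp, c(0, 0, 0), c(4, 0, 0)), c(0, 0, 0))
  ## bilateral spring pushes under compression
  sp2 <- spring_element(rest_length = 10, tension_only = FALSE)
  expect_equal(spring_force(sp2, c(0, 0, 0), c(4, 0, 0)), c(0.19 * 6, 0, 0))
  expect_warning(got <- spring_force(sp, c(1, 2, 3), c(1, 2, 3)),
                 "coincident")
  expect_equal(got, c(0, 0, 0))
})

test_that("contact queries resolve analytic and profile geometry", {
  g <- fixture_geometry()
  prof <- g$profile
  ## patella sample points translated 10 mm cranially: clear of bone
  pts <- g$patella_local$contact_points
  world <- sweep(pts, 2, g$patella_pose$position + c(0, 10, 0), "+")
  expect_equal(nrow(contact_query(world, prof)), 0)
  ## pressed 0.2 mm into the groove floor: contacts with cranial normals
  world2 <- sweep(pts, 2, g$patella_pose$position + c(0, -0.2, 0), "+")
  cq <- contact_query(world2, prof)
  expect_gt(nrow(cq), 0)
  expect_true(all(cq$depth > 0))
  expect_equal(sqrt(cq$nx^2 + cq$ny^2 + cq$nz^2), rep(1, nrow(cq)))
  expect_true(all(cq$ny > 0))
  ## analytic sphere against a plane: single contact of closed-form depth
  sph <- list(type = "sphere", center = c(0, 0, 3), radius = 5)
  pl <- list(type = "plane", point = c(0, 0, 0), normal = c(0, 0, 1))
  cs <- contact_query(sph, pl)
  expect_equal(nrow(cs), 1)
  expect_equal(cs$depth, 2)
  expect_equal(c(cs$nx, cs$ny, cs$nz), c(0, 0, 1))
})

test_that("contact response: penalty normal, Coulomb-bounded friction", {
  cp <- contact_params()
  empty <- contact_query(matrix(c(0, 100, 0), 1), fixture_geometry()$profile)
  w0 <- contact_response(empty, cp)
  expect_equal(w0$force, c(0, 0, 0))
  expect_equal(w0$torque, c(0, 0, 0))
  one <- data.frame(px = 0, py = 0, pz = 0, nx = 0, ny = 1, nz = 0,
                    depth = 0.01)
  wr <- contact_response(one, cp, relative_velocity = c(0, 0, 0),
                         tributary_area = 2)
  expect_equal(wr$force, c(0, cp$penalty_stiffness * 2 * 0.01, 0))
  expect_equal(wr$tangential, 0)
  ## sliding: tangential opposes motion, magnitude <= mu x normal
  ws <- contact_response(one, cp, relative_velocity = c(100, 0, 0),
                         tributary_area = 2)
  expect_lt(ws$force[1], 0)
  expect_lte(abs(ws$tangential), cp$friction_mu * ws$normal + 1e-12)
  expect_equal(abs(ws$tangential), cp$friction_mu * ws$normal,
               tolerance = 1e-2)
  ## a pure couple of contact forces changes torque, not net force
  couple <- data.frame(px = c(1, -1), py = 0, pz = 0,
                       nx = c(0, 0), ny = c(1, -1), nz = 0, depth = 0.01)
  wc <- contact_response(couple, cp)
  expect_equal(wc$force, c(0, 0, 0))
  expect_false(all(wc$torque == 0))
})

test_that("semi-implicit step: rest state, oscillator frequency, energy", {
  mass <- list(mass = 0.2, inertia = c(1, 1, 1))
  st <- body_state(position = c(1, 2, 3))
  st2 <- step(st, list(force = c(0, 0, 0), torque = c(0, 0, 0)), mass, 1e-3)
  expect_equal(st2$position, st$position)
  expect_equal(st2$linear_velocity, c(0, 0, 0))
  expect_equal(st2$time, 1e-3)

  ## harmonic oscillator: point mass on a linear spring, no damping;
  ## frequency within 1% of sqrt(k/m)/2pi over 10 periods
  k <- 0.002                                   # kN/mm
  omega <- sqrt(k * 1e6 / mass$mass)           # rad/s
  dt <- 1e-4
  n <- ceiling(10 * 2 * pi / omega / dt)
  s <- body_state(position = c(5, 0, 0))
  xs <- numeric(n)
  for (i in seq_len(n)) {
    wrench <- list(force = c(-k * s$position[1], 0, 0), torque = c(0, 0, 0))
    s <- step(s, wrench, mass, dt)
    xs[i] <- s$position[1]
  }
  crossings <- which(diff(sign(xs)) != 0)
  f_measured <- (length(crossings) / 2) / (n * dt)
  expect_equal(f_measured, omega / (2 * pi), tolerance = 0.01)

  ## with viscous damping, mechanical energy is non-increasing
  s <- body_state(position = c(5, 0, 0))
  e_prev <- Inf
  for (i in seq_len(2000)) {
    wrench <- list(force = c(-k * s$position[1], 0, 0), torque = c(0, 0, 0))
    s <- step(s, wrench, mass, dt, damping = 50)
    e <- 0.5 * mass$mass * sum((s$linear_velocity * 1e-3)^2) +
      0.5 * k * 1e6 * (s$position[1] * 1e-3)^2
    expect_lte(e, e_prev + 1e-12)
    e_prev <- e
  }
})

test_that("assembled wrench vanishes at the all-rest configuration", {
  g <- fixture_geometry()
  st <- body_state(position = g$patella_pose$position)
  w <- assemble_forces(st, g, t = 0)
  expect_equal(w$force, c(0, 0, 0), tolerance = 1e-12)
  expect_equal(w$torque, c(0, 0, 0), tolerance = 1e-12)
  expect_equal(w$muscle_force, 0)
  expect_equal(w$damping_force, c(0, 0, 0))
  ## static transmission: at 20% activation with everything held, the
  ## muscle tension matches the Hill prediction at the initial state
  w2 <- assemble_forces(st, g, t = 10)
  expect_equal(w2$muscle_force, 0.2 * 0.925, tolerance = 1e-6)
  ## and the junction force balance reflects that tension along the chain
  expect_equal(stiflesim:::vnorm(w2$junction_force), w2$muscle_force,
               tolerance = 1e-6)
})

test_that("compiled and reference engines agree step for step", {
  g <- fixture_geometry()
  sc <- simulation_config(total_time = 0.2, ramp_end = 0.1, output_rate = 50)
  rc <- run_simulation(g, sc, engine = "compiled")
  rr <- run_simulation(g, sc, engine = "reference")
  expect_equal(as.matrix(rr$samples[, 1:12]), as.matrix(rc$samples[, 1:12]),
               tolerance = 1e-7)
})

test_that("runs are deterministic and respect the stability guard", {
  g <- fixture_geometry()
  sc <- simulation_config(total_time = 6)
  r1 <- run_simulation(g, sc)
  r2 <- run_simulation(g, sc)
  expect_identical(r1$samples, r2$samples)
  ## instability guard aborts with the failure time
  expect_error(
    run_simulation(g, simulation_config(total_time = 6,
                                        velocity_guard = 1e-4)),
    "unstable.*t = ")
})

test_that("zero plateau activation leaves the patella seated", {
  g <- fixture_geometry()
  r <- run_simulation(g, simulation_config(plateau_activation = 0))
  s <- r$samples
  disp <- sqrt((s$pos_x_mm - s$pos_x_mm[1])^2 +
               (s$pos_y_mm - s$pos_y_mm[1])^2 +
               (s$pos_z_mm - s$pos_z_mm[1])^2)
  expect_lt(max(disp), 0.5)
})

test_that("simulating a rigidly transformed geometry is refused", {
  g <- transform_geometry(fixture_geometry(), stiflesim:::rot_y(20), c(1, 2, 3))
  expect_error(run_simulation(g), "anatomical frame")
})
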