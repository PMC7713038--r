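# Assembly of the simulation "world": every quantity the integrator needs,
# converted once to SI (m, N, kg, s). The compiled core and the pure-R
# reference engine consume the same structure.

MM <- 1e-3          # mm -> m
KN <- 1e3           # kN -> N
KN_MM <- 1e6        # kN/mm -> N/m

build_sim_world <- function(geometry, sim_config = simulation_config(),
                            muscle_params = hill_muscle_params(),
                            contact = contact_params()) {
  stopifnot(inherits(geometry, "stifle_geometry"))
  if (isFALSE(geometry$world_aligned %||% TRUE))
    stop("geometry has been rigidly transformed out of the anatomical ",
         "frame; rebuild it before simulating")
  lm <- geometry$landmarks
  pl <- geometry$patella_local
  pr <- geometry$profile
  params <- geometry$params

  quad_local <- pl$quad_attach * MM
  lig_local <- pl$lig_attach * MM
  tub <- geometry$tuberosity_anchors * MM
  pts <- pl$contact_points * MM
  a_pt <- attr(pl$contact_points, "tributary_area")   # mm^2

  x0 <- geometry$patella_pose$position * MM
  q0 <- geometry$patella_pose$quaternion
  origin <- lm$rectus_femoris_origin * MM

  ## muscle-tendon junction: on the line from the quadriceps attachment
  ## centroid to the origin, one tendon rest length away from the patella
  centroid <- x0 + colMeans(quad_local)
  u <- vhat(origin - centroid)
  j0 <- centroid + params$tendon_rest_length * MM * u
  quad_world0 <- sweep(quad_local, 2, x0, "+")
  tendon_rest <- sqrt(rowSums(sweep(quad_world0, 2, j0, "-")^2))
  L0 <- vnorm(origin - j0) / muscle_params$initial_relative_length

  lig_world0 <- sweep(lig_local, 2, x0, "+")
  lig_rest <- sqrt(rowSums((tub - lig_world0)^2))

  m_phys <- sim_config$patella_density * mesh_volume(geometry$patella_mesh)
  m <- m_phys * sim_config$mass_scale
  dims <- c(params$patella_width, params$patella_thickness,
            params$patella_length) * MM
  inertia <- m / 12 * c(dims[2]^2 + dims[3]^2,
                        dims[1]^2 + dims[3]^2,
                        dims[1]^2 + dims[2]^2)

  k_pt <- contact$penalty_stiffness * a_pt * KN_MM       # N/m per point
  n_pts <- nrow(pts)
  c_pt <- if (is.null(contact$contact_damping))
    2 * sqrt(k_pt * m / n_pts)                   # near-critical normal damping
  else contact$contact_damping * KN_MM           # kN.s/mm -> N.s/m

  k_spring <- (sim_config$spring_stiffness %||% 0.19) * KN_MM

  ## critical damping rate of the junction node against the tendon bundle
  lam_j <- 2 * sqrt(3 * k_spring / sim_config$junction_mass)

  list(
    origin = origin,
    quad_local = quad_local,
    lig_local = lig_local,
    tub = tub,
    tendon_rest = tendon_rest,
    lig_rest = lig_rest,
    k_spring = k_spring,
    pts = pts,
    k_pt = k_pt,
    c_pt = c_pt,
    mu = contact$friction_mu,
    profile = list(R = pr$R * MM, floor = pr$floor * MM,
                   w_neg = pr$w_neg * MM, w_pos = pr$w_pos * MM,
                   outer_slope = pr$outer_slope, shelf = pr$shelf * MM,
                   shelf_width = pr$shelf_width * MM,
                   z0 = pr$z_range[1] * MM, z1 = pr$z_range[2] * MM),
    m = m, m_phys = m_phys, inertia = inertia,
    m_j = sim_config$junction_mass,
    lam = sim_config$viscous_damping,
    lam_j = lam_j,
    muscle = list(Fmax = peak_isometric_force(muscle_params) * KN,
                  L0 = L0,
                  vmax = muscle_params$max_strain_rate,
                  fl_width = muscle_params$fl_width,
                  fv_shape = muscle_params$fv_shape,
                  fv_cap = muscle_params$fv_eccentric_cap,
                  k_shape = muscle_params$shape_k,
                  Lmax = muscle_params$max_strain_rate),
    x0 = x0, q0 = q0, j0 = j0,
    dt = sim_config$dt,
    n_steps = as.integer(round(sim_config$total_time / sim_config$dt)),
    sample_every = max(1L, as.integer(round(
      1 / (sim_config$dt * sim_config$output_rate)))),
    ramp_end = sim_config$ramp_end,
    plateau = sim_config$plateau_activation,
    gravity = if (sim_config$gravity_enabled) c(0, 0, -9.81) else c(0, 0, 0),
    v_guard = sim_config$velocity_guard * MM,
    w_guard = 500
  )
}

## Profile elevation + slope in SI, scalar x; returns c(e, de) with
## e = -Inf where there is no bone.
profile_eval_si <- function(p, x) {
  if (x >= -p$w_neg && x <= p$w_pos) {
    s <- sqrt(p$R^2 - x^2)
    c(p$floor + p$R - s, x / s)
  } else if (x < -(p$w_neg + p$shelf_width) || x > p$w_pos + p$shelf_width) {
    c(-Inf, 0)
  } else if (x < -p$w_neg) {
    apex <- p$floor + (p$R - sqrt(p$R^2 - p$w_neg^2))
    v <- apex - p$outer_slope * (-x - p$w_neg)
    if (v <= p$shelf) c(p$shelf, 0) else c(v, p$outer_slope)
  } else {
    apex <- p$floor + (p$R - sqrt(p$R^2 - p$w_pos^2))
    v <- apex - p$outer_slope * (x - p$w_pos)
    if (v <= p$shelf) c(p$shelf, 0) else c(v, -p$outer_slope)
  }
}

## One full force evaluation; shared semantics with the compiled core.
## State in SI. Returns forces on the patella (F, tau about its centre),
## the junction force, plus diagnostics.
world_forces <- function(w, x, Rm, v, wb, j, Lnorm_prev, t, dt) {
  ww <- as.numeric(Rm %*% wb)   # world angular velocity
  a <- w$plateau * min(t / w$ramp_end, 1)

  F <- w$m * w$gravity
  tau <- c(0, 0, 0)

  ## quadriceps tendon springs (junction -> patella attachments)
  Fj <- c(0, 0, 0)
  for (s in 1:3) {
    att <- x + as.numeric(Rm %*% w$quad_local[s, ])
    d <- att - j
    len <- vnorm(d)
    el <- len - w$tendon_rest[s]
    if (el > 0) {
      f <- w$k_spring * el * d / len     # pulls attachment towards junction
      F <- F - f
      tau <- tau + vcross(att - x, -f)
      Fj <- Fj + f
    }
  }

  ## Hill muscle element (origin -> junction)
  dm <- w$origin - j
  Lm <- vnorm(dm)
  Lnorm <- Lm / w$muscle$L0
  vshort <- -(Lnorm - Lnorm_prev) / dt
  mm <- w$muscle
  ffl <- exp(-((Lnorm - 1) / mm$fl_width)^2)
  ffv <- if (vshort >= 0) {
    vc <- min(vshort, mm$vmax)
    max(0, (1 - vc / mm$vmax) / (1 + vc / (mm$fv_shape * mm$vmax)))
  } else {
    mm$fv_cap - (mm$fv_cap - 1) * exp(vshort / (mm$fv_shape * mm$vmax))
  }
  fpe <- if (Lnorm > 1)
    (exp((mm$k_shape / mm$Lmax) * (Lnorm - 1)) - 1) / (exp(mm$k_shape) - 1)
  else 0
  Tm <- max(0, a * mm$Fmax * ffl * ffv + mm$Fmax * fpe)
  Fj <- Fj + Tm * dm / Lm

  ## patellar ligament springs (patella attachments -> tuberosity anchors)
  for (s in 1:3) {
    att <- x + as.numeric(Rm %*% w$lig_local[s, ])
    d <- w$tub[s, ] - att
    len <- vnorm(d)
    el <- len - w$lig_rest[s]
    if (el > 0) {
      f <- w$k_spring * el * d / len
      F <- F + f
      tau <- tau + vcross(att - x, f)
    }
  }

  ## penalty contact against the trochlear profile
  rc <- c(0, 0, 0)
  n_contacts <- 0L
  max_fric <- 0
  pr <- w$profile
  for (i in seq_len(nrow(w$pts))) {
    p <- x + as.numeric(Rm %*% w$pts[i, ])
    if (p[3] < pr$z0 || p[3] > pr$z1) next
    ed <- profile_eval_si(pr, p[1])
    if (!is.finite(ed[1])) next
    depth <- ed[1] - p[2]
    if (depth <= 0) next
    nn <- sqrt(1 + ed[2]^2)
    nv <- c(-ed[2] / nn, 1 / nn, 0)
    r <- p - x
    vp <- v + vcross(ww, r)
    vn <- sum(vp * nv)
    fn <- w$k_pt * depth - w$c_pt * vn
    if (fn <= 0) next
    vt <- vp - vn * nv
    st <- vnorm(vt)
    f <- fn * nv
    if (st > 0) {
      ft <- -w$mu * fn / (st + 1e-4) * vt
      f <- f + ft
      frac <- vnorm(ft) / fn
      if (frac > max_fric) max_fric <- frac
    }
    F <- F + f
    tau <- tau + vcross(r, f)
    rc <- rc + f
    n_contacts <- n_contacts + 1L
  }

  list(F = F, tau = tau, Fj = Fj, Tm = Tm, rc = rc,
       n_contacts = n_contacts, max_fric = max_fric, Lnorm = Lnorm)
}
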