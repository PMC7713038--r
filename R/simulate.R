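# Top-level simulation driver.

#' Run the 50-second quadriceps-loading simulation
#'
#' Advances the patella as an unconstrained 6-DOF rigid body under the Hill
#' muscle force (transmitted through the three quadriceps-tendon springs and
#' the muscle-tendon junction node), the three patellar-ligament springs
#' anchored on the fixed tibial tuberosity, frictional penalty contact with
#' the trochlear surface, and mass-proportional viscous damping. Femur and
#' tibia are fully constrained throughout. The pipeline is deterministic:
#' identical inputs give bit-identical sampled output.
#'
#' @param geometry A \code{stifle_geometry} (baseline or bent).
#' @param sim_config A \code{\link{simulation_config}}.
#' @param muscle_params A \code{\link{hill_muscle_params}}.
#' @param contact A \code{\link{contact_params}}.
#' @param engine \code{"compiled"} (default) or \code{"reference"}, the
#'   pure-R engine with identical semantics (slow; intended for
#'   cross-checking short horizons).
#' @return A \code{simulation_result}: list with \code{aldfa_deg},
#'   \code{samples} (data.frame sampled at \code{output_rate}:
#'   time_s, pos_x/y/z_mm, quat_w/x/y/z, rcforce_x/y/z_kN, muscle_force_kN,
#'   n_contacts, max_friction_ratio), \code{displacement_origin} (position
#'   at the first patella-groove contact), and the resolved configuration.
#'   Aborts with the failure time if the instability guard trips.
#' @examples
#' \donttest{
#' geom <- build_reference_stifle()
#' res <- run_simulation(geom, simulation_config(total_time = 6))
#' tail(res$samples$rcforce_x_kN)
#' }
#' @export
run_simulation <- function(geometry,
                           sim_config = simulation_config(),
                           muscle_params = hill_muscle_params(),
                           contact = contact_params(),
                           engine = c("compiled", "reference")) {
  engine <- match.arg(engine)
  world <- build_sim_world(geometry, sim_config, muscle_params, contact)
  raw <- if (engine == "compiled") .cpp_run_simulation(world)
         else r_run_simulation(world)
  if (raw$fail_time >= 0)
    stop(sprintf("simulation unstable: velocity guard tripped at t = %.4f s",
                 raw$fail_time))
  s <- raw$samples[seq_len(raw$rows), , drop = FALSE]
  samples <- data.frame(
    time_s = s[, 1],
    pos_x_mm = s[, 2], pos_y_mm = s[, 3], pos_z_mm = s[, 4],
    quat_w = s[, 5], quat_x = s[, 6], quat_y = s[, 7], quat_z = s[, 8],
    rcforce_x_kN = s[, 9], rcforce_y_kN = s[, 10], rcforce_z_kN = s[, 11],
    muscle_force_kN = s[, 12],
    n_contacts = as.integer(s[, 13]),
    max_friction_ratio = s[, 14])
  first_contact <- which(samples$n_contacts > 0)[1]
  disp_origin <- if (is.na(first_contact)) geometry$displacement_origin
    else as.numeric(s[first_contact, 2:4])
  structure(list(
    aldfa_deg = geometry$aldfa_deg,
    side = geometry$side,
    samples = samples,
    displacement_origin = disp_origin,
    profile = geometry$profile,
    config = list(simulation = unclass(sim_config),
                  muscle = unclass(muscle_params),
                  contact = unclass(contact),
                  geometry = unclass(geometry$params)),
    engine = engine
  ), class = "simulation_result")
}

#' @export
print.simulation_result <- function(x, ...) {
  n <- nrow(x$samples)
  cat(sprintf("<simulation_result: aLDFA %.1f deg, %d samples over %.1f s>\n",
              x$aldfa_deg, n, x$samples$time_s[n]))
  cat(sprintf("  final patella position: (%.2f, %.2f, %.2f) mm\n",
              x$samples$pos_x_mm[n], x$samples$pos_y_mm[n],
              x$samples$pos_z_mm[n]))
  cat(sprintf("  final mediolateral reaction force: %.4f kN\n",
              x$samples$rcforce_x_kN[n]))
  invisible(x)
}

## Pure-R engine with semantics identical to the compiled core.
r_run_simulation <- function(w) {
  x <- w$x0; q <- w$q0; j <- w$j0
  v <- c(0, 0, 0); wb <- c(0, 0, 0); vj <- c(0, 0, 0)
  Lnorm_prev <- vnorm(w$origin - j) / w$muscle$L0
  n_out <- w$n_steps %/% w$sample_every + 1
  out <- matrix(0, n_out, 14)
  row <- 0L
  fail_time <- -1
  max_fric_win <- 0
  dt <- w$dt
  for (stepi in 0:w$n_steps) {
    t <- stepi * dt
    Rm <- quat_to_matrix(q)
    ff <- world_forces(w, x, Rm, v, wb, j, Lnorm_prev, t, dt)
    if (ff$max_fric > max_fric_win) max_fric_win <- ff$max_fric
    if (stepi %% w$sample_every == 0 && row < n_out) {
      row <- row + 1L
      out[row, ] <- c(t, x * 1e3, q, ff$rc * 1e-3, ff$Tm * 1e-3,
                      ff$n_contacts, max_fric_win)
      max_fric_win <- 0
    }
    if (stepi == w$n_steps) break
    vj <- (vj + ff$Fj * (dt / w$m_j)) / (1 + w$lam_j * dt)
    j <- j + vj * dt
    Lnorm_prev <- ff$Lnorm
    v <- (v + ff$F * (dt / w$m)) / (1 + w$lam * dt)
    x <- x + v * dt
    tau_b <- as.numeric(t(Rm) %*% ff$tau)
    alpha <- tau_b / w$inertia
    wb <- (wb + alpha * dt) / (1 + w$lam * dt)
    dq <- quat_multiply(q, c(0, wb))
    q <- quat_normalize(q + 0.5 * dt * dq)
    if (any(!is.finite(c(x, v))) || vnorm(v) > w$v_guard ||
        vnorm(wb) > w$w_guard) {
      fail_time <- t + dt
      break
    }
  }
  list(samples = out, rows = row, fail_time = fail_time)
}

#' Net wrench on the patella for a given state
#'
#' Assembles muscle, tendon-spring, ligament-spring, contact, gravity and
#' damping contributions for an arbitrary patellar state at time \code{t}.
#' With zero activation, no penetration and springs at rest the wrench
#' reduces to the damping term alone.
#'
#' @param state A \code{\link{body_state}} of the patella (mm, mm/s).
#' @param geometry A \code{stifle_geometry}.
#' @param muscle_params,contact,sim_config Model parameters.
#' @param t Time, seconds (activation schedule input).
#' @param junction Optional position of the muscle-tendon junction node,
#'   mm; defaults to its reference location.
#' @return List with \code{force} (kN), \code{torque} (kN.mm about the
#'   patella centre), \code{muscle_force} (kN), \code{damping_force} (kN,
#'   the implicit viscous contribution at the current velocity), and
#'   contact diagnostics.
#' @export
assemble_forces <- function(state, geometry,
                            muscle_params = hill_muscle_params(),
                            contact = contact_params(),
                            sim_config = simulation_config(),
                            t = 0, junction = NULL) {
  w <- build_sim_world(geometry, sim_config, muscle_params, contact)
  x <- state$position * 1e-3
  v <- state$linear_velocity * 1e-3
  j <- if (is.null(junction)) w$j0 else junction * 1e-3
  Rm <- quat_to_matrix(state$orientation)
  ff <- world_forces(w, x, Rm, v, state$angular_velocity, j,
                     vnorm(w$origin - j) / w$muscle$L0, t, w$dt)
  if (any(!is.finite(c(ff$F, ff$tau))))
    stop("non-finite wrench assembled; aborting")
  list(force = ff$F * 1e-3,
       torque = ff$tau * 1e-3 * 1e3,     # N.m -> kN.mm
       muscle_force = ff$Tm * 1e-3,
       damping_force = -w$lam * w$m * v * 1e-3,
       junction_force = ff$Fj * 1e-3,
       n_contacts = ff$n_contacts,
       reaction = ff$rc * 1e-3)
}
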