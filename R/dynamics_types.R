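# Configuration objects of the rigid-body dynamics layer. Public units are
# mm-kN-GPa-s-kg (1 GPa = 1 kN/mm^2); the integrator converts to SI
# internally.

#' Linear spring element (tendon / ligament fibre)
#'
#' @param end_a,end_b Attachment identifiers (informational).
#' @param rest_length Rest length, mm.
#' @param stiffness Elastic stiffness, kN/mm.
#' @param tension_only If TRUE (default) the element produces no force under
#'   compression: tendons and ligaments cannot push.
#' @return A \code{spring_element}.
#' @export
spring_element <- function(end_a = "a", end_b = "b", rest_length = 10,
                           stiffness = 0.19, tension_only = TRUE) {
  if (!is.finite(stiffness) || stiffness <= 0) stop("stiffness must be > 0")
  if (!is.finite(rest_length) || rest_length <= 0)
    stop("rest_length must be > 0")
  structure(list(end_a = end_a, end_b = end_b, rest_length = rest_length,
                 stiffness = stiffness, tension_only = isTRUE(tension_only)),
            class = "spring_element")
}

#' Contact model parameters
#'
#' Penalty contact with Coulomb friction. The bones are rigid; cortical
#' elasticity enters through an elastic-foundation penalty pressure
#' \code{E / ((1 - nu^2) h)} per unit depth and unit contact area, with
#' foundation layer thickness \code{h}. \code{penalty_scale} is the
#' standard explicit-contact stiffness scale factor applied to the raw
#' foundation stiffness for integration conditioning (see the methods
#' vignette); \code{penalty_stiffness} is the resolved product, in kN/mm of
#' depth per mm^2 of tributary contact area.
#'
#' @param friction_mu Coulomb friction coefficient.
#' @param youngs_modulus Cortical Young's modulus, GPa.
#' @param poisson Poisson's ratio.
#' @param foundation_layer Elastic foundation thickness h, mm.
#' @param penalty_scale Dimensionless contact-stiffness scale factor.
#' @param contact_damping Normal contact damping per contact point,
#'   kN.s/mm; NULL (default) derives critical damping from the penalty
#'   stiffness and patellar mass when the simulation world is assembled.
#' @return A \code{contact_params} object with the resolved
#'   \code{penalty_stiffness} field.
#' @export
contact_params <- function(friction_mu = 0.02,
                           youngs_modulus = 15.0,
                           poisson = 0.3,
                           foundation_layer = 1.0,
                           penalty_scale = 0.05,
                           contact_damping = NULL) {
  if (friction_mu < 0) stop("friction_mu must be >= 0")
  if (youngs_modulus <= 0 || foundation_layer <= 0 || penalty_scale <= 0)
    stop("modulus, foundation layer and penalty scale must be > 0")
  if (poisson < 0 || poisson >= 0.5) stop("poisson must lie in [0, 0.5)")
  ps <- penalty_scale * youngs_modulus /
    ((1 - poisson^2) * foundation_layer)
  structure(list(friction_mu = friction_mu,
                 youngs_modulus = youngs_modulus,
                 poisson = poisson,
                 foundation_layer = foundation_layer,
                 penalty_scale = penalty_scale,
                 penalty_stiffness = ps,
                 contact_damping = contact_damping),
            class = "contact_params")
}

#' Simulation configuration
#'
#' Integration settings and the activation protocol. The integrator is a
#' fixed-step semi-implicit Euler scheme; quasi-static mass scaling (the
#' standard explicit-dynamics device for long-duration, slow-loading
#' problems) multiplies the physical patellar mass so that the stiff
#' penalty contact is stable at the default step size. The loading is slow
#' enough that inertial forces are negligible at either mass (see the
#' methods vignette for the convergence evidence).
#'
#' @param dt Integration step, seconds (0 < dt <= 1e-3).
#' @param total_time Protocol duration, seconds.
#' @param ramp_end End of the linear activation ramp, seconds.
#' @param plateau_activation Activation held after the ramp, fraction.
#' @param patella_density Physical bone density used for the patellar mass,
#'   kg/mm^3.
#' @param mass_scale Quasi-static mass scaling factor (dimensionless).
#' @param viscous_damping Mass-proportional viscous damping rate on the
#'   patella (and the tendon junction node), per second.
#' @param output_rate Sampling rate of the recorded time series, Hz.
#' @param gravity_enabled Include gravity (off by default; the stance-phase
#'   protocol is load-controlled by the quadriceps).
#' @param spring_stiffness Elastic stiffness of each quadriceps-tendon and
#'   patellar-ligament spring element, kN/mm.
#' @param junction_mass Numerical mass of the muscle-tendon junction node,
#'   kg (mass-scaled like the patella).
#' @param velocity_guard Instability guard: the run aborts if the patellar
#'   speed exceeds this bound, mm/s.
#' @return A \code{simulation_config}.
#' @export
simulation_config <- function(dt = 2e-5,
                              total_time = 50,
                              ramp_end = 5,
                              plateau_activation = 0.20,
                              patella_density = 2.0e-6,
                              mass_scale = 1000,
                              viscous_damping = 2e5,
                              output_rate = 100,
                              spring_stiffness = 0.19,
                              gravity_enabled = FALSE,
                              junction_mass = 0.02,
                              velocity_guard = 2000) {
  if (!is.finite(dt) || dt <= 0 || dt > 1e-3)
    stop("dt must satisfy 0 < dt <= 1e-3 s")
  if (total_time < ramp_end)
    stop("total_time must be at least ramp_end")
  if (plateau_activation < 0 || plateau_activation > 1)
    stop("plateau_activation must lie in [0, 1]")
  if (output_rate <= 0) stop("output_rate must be positive")
  structure(list(dt = dt, total_time = total_time, ramp_end = ramp_end,
                 plateau_activation = plateau_activation,
                 patella_density = patella_density,
                 mass_scale = mass_scale,
                 viscous_damping = viscous_damping,
                 output_rate = output_rate,
                 spring_stiffness = spring_stiffness,
                 gravity_enabled = isTRUE(gravity_enabled),
                 junction_mass = junction_mass,
                 velocity_guard = velocity_guard),
            class = "simulation_config")
}

#' Rigid-body state of the patella
#'
#' @param position Centre position, mm (3-vector).
#' @param orientation Unit quaternion c(w, x, y, z).
#' @param linear_velocity mm/s (3-vector).
#' @param angular_velocity rad/s (3-vector, body frame).
#' @param time Seconds.
#' @return A \code{body_state}.
#' @export
body_state <- function(position = c(0, 0, 0),
                       orientation = c(1, 0, 0, 0),
                       linear_velocity = c(0, 0, 0),
                       angular_velocity = c(0, 0, 0),
                       time = 0) {
  if (abs(vnorm(orientation) - 1) > 1e-9)
    stop("orientation quaternion must be normalized")
  if (!all(is.finite(c(position, orientation, linear_velocity,
                       angular_velocity, time))))
    stop("body state components must be finite")
  structure(list(position = position, orientation = orientation,
                 linear_velocity = linear_velocity,
                 angular_velocity = angular_velocity, time = time),
            class = "body_state")
}
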