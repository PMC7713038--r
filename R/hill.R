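#' Rectus femoris material parameters for the Hill-type muscle model
#'
#' Constants of the phenomenological Hill model used to drive the patella:
#' a contractile element (CE) scaled by activation, a normalized
#' force-length curve and a force-velocity curve, plus a parallel elastic
#' element (PE) that engages under positive strain. Units follow the
#' mm-kN-GPa-s convention (1 GPa = 1 kN/mm^2), so peak isometric force
#' comes out in kilonewtons.
#'
#' @param density Muscle density, kg/mm^3.
#' @param initial_relative_length Initial muscle length normalized by the
#'   optimal (resting) length; the reference pose is built so that the
#'   muscle starts at its optimum.
#' @param max_strain_rate Maximum strain rate \code{L_max} (dimensionless);
#'   also sets the maximum normalized shortening velocity (per second) of
#'   the force-velocity curve.
#' @param peak_isometric_stress Peak isometric stress, GPa.
#' @param shape_k Dimensionless shape parameter controlling the rate of
#'   rise of the parallel-elastic exponential.
#' @param pcsa Physiological cross-sectional area, mm^2.
#' @param fl_width Width of the Gaussian force-length curve
#'   (dimensionless, in normalized-length units).
#' @param fv_shape Curvature parameter of the concentric Hill hyperbola
#'   (dimensionless).
#' @param fv_eccentric_cap Asymptotic force multiplier for lengthening
#'   contractions (>= 1).
#' @return An object of class \code{hill_muscle_params}.
#' @examples
#' p <- hill_muscle_params()
#' peak_isometric_force(p) # 0.925 kN
#' @export
hill_muscle_params <- function(density = 1e-5,
                               initial_relative_length = 1.0,
                               max_strain_rate = 2.0,
                               peak_isometric_stress = 5e-4,
                               shape_k = 6.0,
                               pcsa = 1850,
                               fl_width = 0.45,
                               fv_shape = 0.25,
                               fv_eccentric_cap = 1.4) {
  p <- list(density = density,
            initial_relative_length = initial_relative_length,
            max_strain_rate = max_strain_rate,
            peak_isometric_stress = peak_isometric_stress,
            shape_k = shape_k,
            pcsa = pcsa,
            fl_width = fl_width,
            fv_shape = fv_shape,
            fv_eccentric_cap = fv_eccentric_cap)
  num <- vapply(p, function(x) is.numeric(x) && length(x) == 1 && is.finite(x),
                logical(1))
  if (!all(num)) stop("all Hill muscle parameters must be finite scalars")
  strict <- c("density", "initial_relative_length", "max_strain_rate",
              "peak_isometric_stress", "fl_width", "fv_shape")
  if (any(unlist(p[strict]) <= 0))
    stop("Hill muscle parameters must be strictly positive")
  if (pcsa < 0) stop("pcsa must be non-negative")
  if (shape_k == 0) stop("shape_k must be non-zero")
  if (fv_eccentric_cap < 1) stop("fv_eccentric_cap must be >= 1")
  structure(p, class = "hill_muscle_params")
}

#' Instantaneous kinematic state of the muscle
#'
#' @param current_length Muscle length normalized by optimal length (> 0).
#' @param shortening_velocity Normalized shortening velocity, optimal
#'   lengths per second; positive when the muscle shortens.
#' @param activation Activation fraction in [0, 1].
#' @return An object of class \code{muscle_state}; the strain field is
#'   derived as \code{current_length - 1}.
#' @export
muscle_state <- function(current_length = 1.0,
                         shortening_velocity = 0.0,
                         activation = 0.0) {
  if (!is.finite(current_length) || current_length <= 0)
    stop("current_length must be a positive finite scalar")
  if (!is.finite(shortening_velocity))
    stop("shortening_velocity must be finite")
  if (!is.finite(activation) || activation < 0 || activation > 1)
    stop("activation must lie in [0, 1]")
  structure(list(current_length = current_length,
                 shortening_velocity = shortening_velocity,
                 strain = current_length - 1,
                 activation = activation),
            class = "muscle_state")
}

#' Quadriceps activation schedule
#'
#' Piecewise-linear loading protocol: activation rises linearly from zero to
#' the plateau over \code{[0, ramp_end]} and is then held constant. The slow
#' ramp avoids the unphysiological impulsive disarticulation that a step in
#' muscle force would cause.
#'
#' @param t Time(s) in seconds, vectorized; must be non-negative.
#' @param ramp_end End of the linear ramp, seconds.
#' @param plateau Activation level held after the ramp, fraction of maximal.
#' @return Activation fraction(s) in \code{[0, plateau]}.
#' @examples
#' activation_schedule(c(0, 2.5, 5, 50)) # 0.00 0.10 0.20 0.20
#' @export
activation_schedule <- function(t, ramp_end = 5, plateau = 0.20) {
  if (any(!is.finite(t)) || any(t < 0)) stop("t must be non-negative")
  if (ramp_end <= 0) stop("ramp_end must be positive")
  plateau * pmin(t / ramp_end, 1)
}

#' Peak isometric force
#'
#' \code{F_max = peak isometric stress x PCSA}; with stress in GPa
#' (= kN/mm^2) and area in mm^2 the product is in kN.
#'
#' @param params A \code{\link{hill_muscle_params}} object.
#' @return Peak isometric force, kN.
#' @export
peak_isometric_force <- function(params) {
  params$peak_isometric_stress * params$pcsa
}

#' Normalized force-length curve
#'
#' Gaussian bell \code{exp(-((L - 1)/w)^2)} centred on the optimal length;
#' the curve shape is a package default (all constants configurable), with
#' value 1 at the optimum by construction.
#'
#' @param L Normalized muscle length(s), > 0.
#' @param fl_width Gaussian width \code{w}.
#' @return Coefficient(s) in [0, 1].
#' @export
force_length <- function(L, fl_width = 0.45) {
  if (any(L <= 0)) stop("normalized length must be positive")
  exp(-((L - 1) / fl_width)^2)
}

#' Normalized force-velocity curve
#'
#' Concentric branch: Hill hyperbola
#' \code{(1 - v/v_max) / (1 + v/(a_f v_max))} for shortening velocities
#' \code{0 <= v <= v_max}, zero beyond. Eccentric branch (lengthening,
#' \code{v < 0}): smooth exponential saturation at \code{fv_eccentric_cap}.
#' Continuous, equals 1 at \code{v = 0}, non-increasing in shortening speed.
#'
#' @param v Normalized shortening velocity(ies), optimal lengths per second;
#'   positive = shortening.
#' @param v_max Maximum shortening velocity (defaults to the maximum strain
#'   rate of the muscle, per second).
#' @param fv_shape Hyperbola curvature \code{a_f}.
#' @param fv_eccentric_cap Eccentric force ceiling.
#' @return Coefficient(s) in \code{[0, fv_eccentric_cap]}.
#' @export
force_velocity <- function(v, v_max = 2.0, fv_shape = 0.25,
                           fv_eccentric_cap = 1.4) {
  if (any(!is.finite(v))) stop("velocity must be finite")
  out <- numeric(length(v))
  conc <- v >= 0
  vc <- pmin(v[conc], v_max)
  out[conc] <- pmax(0, (1 - vc / v_max) / (1 + vc / (fv_shape * v_max)))
  ve <- v[!conc]
  out[!conc] <- fv_eccentric_cap -
    (fv_eccentric_cap - 1) * exp(ve / (fv_shape * v_max))
  out
}

#' Contractile element force
#'
#' \code{F_CE = a(t) x F_max x f_FL(L) x f_FV(v)}.
#'
#' @param state A \code{\link{muscle_state}}.
#' @param params A \code{\link{hill_muscle_params}}.
#' @param t Optional time (seconds); kept in the signature for symmetry with
#'   schedule-driven use, the activation is read from \code{state}.
#' @return Contractile force, kN (>= 0).
#' @export
contractile_force <- function(state, params, t = NULL) {
  state$activation * peak_isometric_force(params) *
    force_length(state$current_length, params$fl_width) *
    force_velocity(state$shortening_velocity,
                   v_max = params$max_strain_rate,
                   fv_shape = params$fv_shape,
                   fv_eccentric_cap = params$fv_eccentric_cap)
}

#' Parallel elastic element force
#'
#' Zero under non-positive strain; for strain > 0 the normalized exponential
#' \deqn{\frac{1}{e^k - 1}\left(e^{(k/L_{max})(L-1)} - 1\right)}
#' multiplied by \code{F_max} (the normalization reference adopted here, see
#' the methods vignette). Continuous at zero strain and exactly \code{F_max}
#' when \code{L - 1 = L_max}.
#'
#' @inheritParams contractile_force
#' @return Parallel elastic force, kN (>= 0).
#' @export
parallel_elastic_force <- function(state, params) {
  eps <- state$strain
  if (eps <= 0) return(0)
  k <- params$shape_k
  lmax <- params$max_strain_rate
  peak_isometric_force(params) *
    (exp((k / lmax) * (state$current_length - 1)) - 1) / (exp(k) - 1)
}

#' Total muscle force and line of action
#'
#' \code{F_M = F_CE + F_PE}, tensile only: the force acts along the muscle
#' path so as to shorten it. When origin and insertion points are supplied
#' the unit line of action (origin towards insertion) is returned as well.
#'
#' @inheritParams contractile_force
#' @param origin,insertion Optional 3D points (mm) defining the muscle path.
#' @return A list with \code{magnitude} (kN) and \code{direction} (unit
#'   3-vector from origin to insertion, or NULL).
#' @export
total_muscle_force <- function(state, params, t = NULL,
                               origin = NULL, insertion = NULL) {
  mag <- max(0, contractile_force(state, params, t) +
                parallel_elastic_force(state, params))
  dir <- NULL
  if (!is.null(origin) && !is.null(insertion)) dir <- vhat(insertion - origin)
  list(magnitude = mag, direction = dir)
}

#' Sample the force-length and force-velocity curves
#'
#' Utility to export the curve shapes (e.g. for plotting or CSV export).
#'
#' @param params A \code{\link{hill_muscle_params}}.
#' @param n Number of samples per curve.
#' @return A data.frame with columns \code{curve}, \code{x}, \code{value}.
#' @export
hill_curve_samples <- function(params = hill_muscle_params(), n = 101) {
  L <- seq(0.4, 1.8, length.out = n)
  v <- seq(-params$max_strain_rate, params$max_strain_rate, length.out = n)
  rbind(
    data.frame(curve = "force_length", x = L,
               value = force_length(L, params$fl_width)),
    data.frame(curve = "force_velocity", x = v,
               value = force_velocity(v, params$max_strain_rate,
                                      params$fv_shape,
                                      params$fv_eccentric_cap))
  )
}
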