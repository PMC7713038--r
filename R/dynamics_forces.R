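# Force primitives: springs, contact queries, contact response, the
# semi-implicit Euler step. Public units mm / kN / s / kg.

#' Force of a linear (tension-only) spring element
#'
#' @param spring A \code{\link{spring_element}}.
#' @param pos_a,pos_b Endpoint positions, mm.
#' @param rel_velocity Optional relative velocity of b with respect to a,
#'   mm/s (unused by the pure elastic element; kept for interface
#'   compatibility).
#' @return Force on endpoint b, kN (3-vector); the force on a is its
#'   negative. Magnitude \code{stiffness * max(0, elongation)} for
#'   tension-only elements, directed along the element.
#' @export
spring_force <- function(spring, pos_a, pos_b, rel_velocity = c(0, 0, 0)) {
  d <- pos_b - pos_a
  len <- vnorm(d)
  if (len < 1e-12) {
    warning("coincident spring endpoints: direction undefined, zero force")
    return(c(0, 0, 0))
  }
  elong <- len - spring$rest_length
  if (spring$tension_only) elong <- max(0, elong)
  -spring$stiffness * elong * d / len
}

#' Query contacts between a body and a surface
#'
#' Supports the reduced contact model of the simulator: a set of sample
#' points (or an analytic sphere) against either the trochlear profile
#' surface or an analytic plane. Normals are unit length and point from the
#' femur (surface) into the patella (body); depths are non-negative.
#'
#' @param body Either a numeric n x 3 matrix of world points, or
#'   \code{list(type = "sphere", center =, radius =)}.
#' @param surface A \code{trochlear_profile} (from a \code{stifle_geometry}
#'   \code{$profile}) or \code{list(type = "plane", point =, normal =)}.
#' @return A data.frame with columns px, py, pz (contact point), nx, ny, nz
#'   (normal), depth (mm); zero rows when there is no contact.
#' @export
contact_query <- function(body, surface) {
  empty <- data.frame(px = numeric(0), py = numeric(0), pz = numeric(0),
                      nx = numeric(0), ny = numeric(0), nz = numeric(0),
                      depth = numeric(0))
  if (is.list(body) && identical(body$type, "sphere")) {
    if (!is.list(surface) || !identical(surface$type, "plane"))
      stop("sphere bodies are supported against plane surfaces")
    n <- vhat(surface$normal)
    dist <- sum((body$center - surface$point) * n)
    depth <- body$radius - dist
    if (depth <= 0) return(empty)
    p <- body$center - n * dist
    return(data.frame(px = p[1], py = p[2], pz = p[3],
                      nx = n[1], ny = n[2], nz = n[3], depth = depth))
  }
  pts <- body
  if (!is.matrix(pts) || ncol(pts) != 3 || any(!is.finite(pts)))
    stop("body must be a finite n x 3 point matrix or a sphere")
  if (inherits(surface, "trochlear_profile")) {
    inz <- pts[, 3] >= surface$z_range[1] & pts[, 3] <= surface$z_range[2]
    pe <- profile_eval(surface, pts[, 1])
    depth <- pe$e - pts[, 2]
    hit <- inz & is.finite(pe$e) & depth > 0
    if (!any(hit)) return(empty)
    de <- pe$de[hit]
    nn <- sqrt(1 + de^2)
    data.frame(px = pts[hit, 1], py = pts[hit, 2], pz = pts[hit, 3],
               nx = -de / nn, ny = 1 / nn, nz = 0, depth = depth[hit])
  } else if (is.list(surface) && identical(surface$type, "plane")) {
    n <- vhat(surface$normal)
    d <- as.numeric(pts %*% n) - sum(surface$point * n)
    hit <- d < 0
    if (!any(hit)) return(empty)
    data.frame(px = pts[hit, 1], py = pts[hit, 2], pz = pts[hit, 3],
               nx = n[1], ny = n[2], nz = n[3], depth = -d[hit])
  } else stop("unsupported surface type")
}

#' Net contact wrench from a contact set
#'
#' Normal force \code{penalty_stiffness x area x depth + damping x approach
#' speed}, clamped non-negative; tangential force opposes sliding with
#' magnitude at most \code{friction_mu x normal} (regularized Coulomb
#' friction).
#'
#' @param contacts Contact set from \code{\link{contact_query}}.
#' @param params A \code{\link{contact_params}}.
#' @param relative_velocity Velocity of the body at each contact point
#'   relative to the (fixed) surface, mm/s: either a single 3-vector or an
#'   n x 3 matrix.
#' @param center Reference point for the torque, mm (default origin).
#' @param tributary_area Contact area represented by each point, mm^2.
#' @param velocity_eps Friction regularization velocity, mm/s.
#' @return List with \code{force} (kN), \code{torque} (kN.mm) about
#'   \code{center}, and the per-contact normal/tangential magnitudes.
#' @export
contact_response <- function(contacts, params,
                             relative_velocity = c(0, 0, 0),
                             center = c(0, 0, 0),
                             tributary_area = 1,
                             velocity_eps = 0.1) {
  n <- nrow(contacts)
  if (n == 0)
    return(list(force = c(0, 0, 0), torque = c(0, 0, 0),
                normal = numeric(0), tangential = numeric(0)))
  vel <- if (is.matrix(relative_velocity)) relative_velocity
         else matrix(relative_velocity, n, 3, byrow = TRUE)
  k <- params$penalty_stiffness * tributary_area
  cd <- params$contact_damping %||% 0
  force <- c(0, 0, 0); torque <- c(0, 0, 0)
  fn_out <- numeric(n); ft_out <- numeric(n)
  for (i in seq_len(n)) {
    nv <- c(contacts$nx[i], contacts$ny[i], contacts$nz[i])
    p <- c(contacts$px[i], contacts$py[i], contacts$pz[i])
    vn <- sum(vel[i, ] * nv)
    fn <- k * contacts$depth[i] - cd * vn
    if (fn <= 0) next
    vt <- vel[i, ] - vn * nv
    st <- vnorm(vt)
    ft <- if (st > 0) -params$friction_mu * fn * vt / (st + velocity_eps)
          else c(0, 0, 0)
    f <- fn * nv + ft
    force <- force + f
    torque <- torque + vcross(p - center, f)
    fn_out[i] <- fn; ft_out[i] <- vnorm(ft)
  }
  list(force = force, torque = torque, normal = fn_out, tangential = ft_out)
}

#' Semi-implicit Euler step of a free rigid body
#'
#' Velocities are updated from the wrench, optionally damped implicitly by a
#' mass-proportional viscous rate, then positions and the orientation
#' quaternion are advanced and the quaternion renormalized. Deterministic:
#' no randomness anywhere in the pipeline.
#'
#' @param state A \code{\link{body_state}}.
#' @param wrench List with \code{force} (kN) and \code{torque} (kN.mm,
#'   about the body centre, world axes).
#' @param mass List with \code{mass} (kg) and \code{inertia} (length-3
#'   diagonal of the body-frame inertia tensor, kg.mm^2).
#' @param dt Step, seconds.
#' @param damping Mass-proportional viscous rate, per second.
#' @return The advanced \code{body_state}.
#' @export
step <- function(state, wrench, mass, dt, damping = 0) {
  if (any(!is.finite(c(wrench$force, wrench$torque))))
    stop("non-finite wrench")
  ## 1 kN = 1e6 kg.mm/s^2
  acc <- wrench$force / mass$mass * 1e6
  v <- (state$linear_velocity + dt * acc) / (1 + damping * dt)
  x <- state$position + dt * v
  Rm <- quat_to_matrix(state$orientation)
  tau_body <- as.numeric(t(Rm) %*% wrench$torque)
  alpha <- tau_body / mass$inertia * 1e6
  w <- (state$angular_velocity + dt * alpha) / (1 + damping * dt)
  dq <- 0.5 * quat_multiply(state$orientation, c(0, w))
  q <- quat_normalize(state$orientation + dt * dq)
  body_state(position = x, orientation = q, linear_velocity = v,
             angular_velocity = w, time = state$time + dt)
}
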