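# Construction of the reference stifle geometry.
#
# Fixed anatomical frame: x = mediolateral (+ lateral for the default left
# limb), y = craniocaudal (+ cranial), z = proximodistal (+ proximal),
# units mm, knee centre at the origin.

## ---- trochlear cross-section profile -------------------------------------

## The contact surface of the trochlea is an extruded profile e(x): bone
## surface elevation (cranial coordinate) as a function of the mediolateral
## coordinate. Within the groove it is a circular arc; beyond each ridge
## apex the outer wall descends at a fixed slope to a flat shelf; beyond the
## shelf edge there is no bone.
trochlear_profile <- function(params, side = "left") {
  R <- params$groove_arc_radius
  h_neg <- if (side == "left") params$medial_ridge_height else
    params$lateral_ridge_height
  h_pos <- if (side == "left") params$lateral_ridge_height else
    params$medial_ridge_height
  floor_y <- epiphysis_cranial_extent(params) - params$groove_depth
  structure(list(
    R = R,
    floor = floor_y,
    h_neg = h_neg,
    h_pos = h_pos,
    w_neg = sqrt(h_neg * (2 * R - h_neg)),
    w_pos = sqrt(h_pos * (2 * R - h_pos)),
    outer_slope = tan(deg2rad(params$outer_wall_angle)),
    shelf = floor_y - params$shelf_drop,
    shelf_width = 8,
    z_range = params$trochlea_z_range,
    side = side
  ), class = "trochlear_profile")
}

## Cranial extent of the distal epiphysis (where the groove is carved).
epiphysis_cranial_extent <- function(params) {
  params$shaft_radius + 3
}

## Evaluate elevation e(x) and slope de/dx for a vector of x. Points beyond
## the bone edge get elevation -Inf (no contact possible).
profile_eval <- function(profile, x) {
  R <- profile$R
  e <- numeric(length(x))
  de <- numeric(length(x))
  x_edge_neg <- -(profile$w_neg + profile$shelf_width)
  x_edge_pos <- profile$w_pos + profile$shelf_width
  for (i in seq_along(x)) {
    xi <- x[i]
    if (xi < x_edge_neg || xi > x_edge_pos) {
      e[i] <- -Inf; de[i] <- 0
    } else if (xi >= -profile$w_neg && xi <= profile$w_pos) {
      s <- sqrt(R * R - xi * xi)
      e[i] <- profile$floor + R - s
      de[i] <- xi / s
    } else if (xi < -profile$w_neg) {
      apex <- profile$floor + profile$h_neg
      v <- apex - profile$outer_slope * (-xi - profile$w_neg)
      if (v <= profile$shelf) { e[i] <- profile$shelf; de[i] <- 0 }
      else { e[i] <- v; de[i] <- profile$outer_slope }
    } else {
      apex <- profile$floor + profile$h_pos
      v <- apex - profile$outer_slope * (xi - profile$w_pos)
      if (v <= profile$shelf) { e[i] <- profile$shelf; de[i] <- 0 }
      else { e[i] <- v; de[i] <- -profile$outer_slope }
    }
  }
  list(e = e, de = de)
}

## ---- femur ----------------------------------------------------------------

femur_mesh <- function(params, profile) {
  L <- params$femur_length
  rs <- params$shaft_radius
  ep_a <- rs + 2.5           # epiphysis mediolateral half width
  ep_b <- epiphysis_cranial_extent(params)
  zc <- L * (1 - params$cora_fraction)
  zt <- params$trochlea_z_range
  stations <- sort(unique(c(
    -10, -6, -2, 0,
    seq(zt[1], zt[2], by = 2),
    zt[2] + 2, 30,
    seq(zc - 4, zc + 6, by = 2),
    seq(42, L - 6, by = 8), L
  )))
  k <- 64
  th <- seq(0, 2 * pi, length.out = k + 1)[-(k + 1)]
  smooth01 <- function(u) { u <- pmin(1, pmax(0, u)); u * u * (3 - 2 * u) }
  rings <- lapply(stations, function(z) {
    w <- smooth01((z - (zt[2] + 2)) / 10)  # epiphysis -> shaft blend
    a <- (1 - w) * ep_a + w * rs
    b <- (1 - w) * ep_b + w * rs
    x <- a * cos(th)
    y <- b * sin(th)
    if (z >= zt[1] && z <= zt[2]) {
      pe <- profile_eval(trochlear_profile_clamped(profile), x)
      cranial <- y > 0
      y[cranial] <- pmin(y[cranial], pe$e[cranial])
    }
    cbind(x, y, z)
  })
  tube_mesh(rings)
}

## For mesh carving only: treat "no bone" regions as the shelf elevation so
## the cut stays bounded (contact still uses the -Inf convention).
trochlear_profile_clamped <- function(profile) {
  profile$shelf_width <- 1e6
  profile
}

## ---- patella ---------------------------------------------------------------

patella_mesh <- function(params) {
  w <- params$patella_width
  l <- params$patella_length
  t <- params$patella_thickness
  R <- params$groove_arc_radius
  xs <- seq(-w / 2, w / 2, length.out = 11)
  zs <- seq(-l / 2, l / 2, length.out = 11)
  ## posterior facet: cylinder of radius R (conforming to the groove arc),
  ## lowest point at -t/2 in local coordinates
  f_low <- function(x, z) (R - t / 2) - sqrt(R * R - x * x)
  f_bulge <- function(x, z) {
    t * pmax(0, (1 - (2 * x / w)^2))^0.7 * pmax(0, (1 - (2 * z / l)^2))^0.7
  }
  pillow_mesh(xs, zs, f_low, f_bulge)
}

## Contact sample points on the articulating strip of the posterior facet,
## patella-local coordinates. The strip is the central band of the facet
## that actually bears on the groove (the rim of a real facet is rounded
## and non-articulating).
patella_contact_points <- function(params, nx = 21, nz = 7) {
  l <- params$patella_length
  t <- params$patella_thickness
  R <- params$groove_arc_radius
  a <- min(params$facet_contact_half_width, 0.95 * params$patella_width / 2)
  xs <- seq(-a, a, length.out = nx)
  zs <- seq(-0.85 * l / 2, 0.85 * l / 2, length.out = nz)
  g <- expand.grid(x = xs, z = zs)
  pts <- cbind(g$x, (R - t / 2) - sqrt(R * R - g$x * g$x), g$z)
  arc_width <- 2 * R * asin(a / R)
  attr(pts, "tributary_area") <- arc_width * (0.85 * l) / nrow(pts)
  pts
}

## ---- tibia -----------------------------------------------------------------

tibia_mesh <- function(params, tibia_dir) {
  zt <- vhat(tibia_dir)
  xt <- c(1, 0, 0)
  yt <- vcross(zt, xt)
  center <- c(0, 0, 0) + zt * 38 + yt * 0  # mid-diaphysis along the axis
  box_mesh(center, cbind(xt, yt, zt), c(9, 8, 34))
}

## ---- assembly --------------------------------------------------------------

#' Build the packaged reference stifle geometry
#'
#' Generates the synthetic left canine stifle at the stance pose: femur with
#' trochlear groove, patella seated in the groove (the first patella-groove
#' contact point defines the displacement origin), tibia, and the full
#' landmark set (femoral head centre, greater trochanter, shaft axis points,
#' distal condylar points, trochlear groove ends, patella apex/base, tibial
#' tuberosity, CORA, and the virtual-ilium rectus femoris origin).
#'
#' @param params A \code{\link{geometry_params}} object.
#' @return A \code{stifle_geometry} object with meshes, landmarks, the
#'   trochlear contact profile, and bookkeeping fields (\code{aldfa_deg},
#'   \code{side}, \code{frame}).
#' @examples
#' geom <- build_reference_stifle()
#' measure_aldfa(geom)    # 95
#' measure_lp_ratio(geom) # 1.55
#' @export
build_reference_stifle <- function(params = geometry_params()) {
  validate_geometry_params(params)
  L <- params$femur_length
  zc <- L * (1 - params$cora_fraction)
  profile <- trochlear_profile(params, side = "left")

  ## distal joint orientation line at the configured baseline aLDFA
  a <- deg2rad(params$baseline_aldfa)
  joint_dir <- c(sin(a), 0, cos(a))            # medial -> lateral
  knee <- c(0, 0, 0)

  ## proximal femur, neck and virtual ilium
  aa <- deg2rad(params$baseline_anteversion)
  el <- deg2rad(params$neck_elevation)
  neck_dir <- c(-cos(aa) * cos(el), sin(aa) * cos(el), sin(el))
  shaft_top <- c(0, 0, L)
  head <- shaft_top + params$neck_length * neck_dir
  hs <- deg2rad(params$hip_sagittal_angle)
  ilium_dir <- c(0, sin(hs), -cos(hs))
  origin <- c(-params$quad_origin_medial_offset, 0, 0) + shaft_top +
    params$ilium_offset * ilium_dir

  ## tibia axis from the stance stifle flexion angle (caudodistal)
  sf <- deg2rad(params$stifle_flexion)
  tibia_dir <- c(0, -sin(sf), cos(sf))

  ## patella at the stance pose, facet touching the groove floor
  pat_center <- c(0, profile$floor + params$patella_thickness / 2,
                  params$patella_center_z)
  apex <- pat_center + c(0, 2, -params$patella_length / 2)
  base <- pat_center + c(0, 2, params$patella_length / 2)

  ## tibial tuberosity along the ligament direction from the apex
  la <- deg2rad(params$ligament_sagittal_angle)
  lig_dir <- c(0, -sin(la), -cos(la))
  tuberosity <- apex + params$ligament_length * lig_dir

  landmarks <- list(
    knee_center = knee,
    medial_condyle_distal = knee - params$condyle_half_span * joint_dir,
    lateral_condyle_distal = knee + params$condyle_half_span * joint_dir,
    cora = c(0, 0, zc),
    shaft_axis_distal = c(0, 0, zc + 0.3 * (L - zc)),
    shaft_axis_proximal = c(0, 0, zc + 0.9 * (L - zc)),
    greater_trochanter = shaft_top + c(0, 0, 2),
    femoral_head_center = head,
    rectus_femoris_origin = origin,
    trochlear_groove_proximal = c(0, profile$floor,
                                  params$trochlea_z_range[2]),
    trochlear_groove_distal = c(0, profile$floor, params$trochlea_z_range[1]),
    patella_apex = apex,
    patella_base = base,
    tibial_tuberosity = tuberosity,
    tibia_proximal = knee,
    tibia_distal = knee + 0.7 * L * tibia_dir
  )

  pat_local <- list(
    contact_points = patella_contact_points(params),
    quad_attach = rbind(c(-2.5, 2, params$patella_length / 2),
                        c(0, 2, params$patella_length / 2),
                        c(2.5, 2, params$patella_length / 2)),
    lig_attach = rbind(c(-2.5, 2, -params$patella_length / 2),
                       c(0, 2, -params$patella_length / 2),
                       c(2.5, 2, -params$patella_length / 2)),
    apex = c(0, 2, -params$patella_length / 2),
    base = c(0, 2, params$patella_length / 2)
  )
  tub_anchors <- rbind(tuberosity + c(-2.5, 0, 0),
                       tuberosity,
                       tuberosity + c(2.5, 0, 0))

  geom <- structure(list(
    femur_mesh = femur_mesh(params, profile),
    patella_mesh = patella_mesh(params),
    tibia_mesh = tibia_mesh(params, tibia_dir),
    landmarks = landmarks,
    profile = profile,
    params = params,
    patella_local = pat_local,
    tuberosity_anchors = tub_anchors,
    patella_pose = list(position = pat_center, quaternion = c(1, 0, 0, 0)),
    displacement_origin = pat_center,
    aldfa_deg = params$baseline_aldfa,
    side = "left",
    bent = FALSE,
    frame = paste("x = mediolateral (+lateral), y = craniocaudal (+cranial),",
                  "z = proximodistal (+proximal), mm")
  ), class = "stifle_geometry")

  ## self-check: the generated geometry must measure back its own inputs
  stopifnot(abs(measure_aldfa(geom) - params$baseline_aldfa) < 0.5,
            abs(measure_anteversion(geom) - params$baseline_anteversion) < 0.5,
            abs(measure_stifle_flexion(geom) - params$stifle_flexion) < 0.5,
            abs(measure_lp_ratio(geom) -
                  params$ligament_length / params$patella_length) < 0.01)
  geom
}

#' @export
print.stifle_geometry <- function(x, ...) {
  cat("<stifle_geometry>\n")
  cat(sprintf("  side: %s, aLDFA %.2f deg%s\n", x$side, x$aldfa_deg,
              if (x$bent) " (bent at CORA)" else " (baseline)"))
  cat(sprintf("  femur: %d verts | patella: %d verts | tibia: %d verts\n",
              nrow(x$femur_mesh$vertices), nrow(x$patella_mesh$vertices),
              nrow(x$tibia_mesh$vertices)))
  cat(sprintf("  frame: %s\n", x$frame))
  invisible(x)
}
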