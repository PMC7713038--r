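# Virtual osteotomy: CORA bending and sagittal mirroring.

## Smoothstep blend weight across the bend transition zone.
bend_weight <- function(z, z_cora, blend_width) {
  u <- (z - (z_cora - blend_width / 2)) / blend_width
  u <- pmin(1, pmax(0, u))
  u * u * (3 - 2 * u)
}

#' Bend the femur at the CORA to a target aLDFA
#'
#' Rotates the proximal femoral segment (shaft, neck, head and the virtual
#' ilium origin of the rectus femoris) about the craniocaudal axis through
#' the CORA, producing a pure frontal-plane varus deformity. The rotation
#' angle is \code{target - baseline} degrees, so the bend is an affine
#' function of the target angle and round-trips exactly through
#' \code{\link{measure_aldfa}}. Vertices strictly distal to the blend zone
#' are untouched, so the distal epiphysis (patella, trochlear groove, joint
#' line) is bit-identical across all variants.
#'
#' @param geom A baseline (unbent) \code{stifle_geometry}.
#' @param target_aldfa Target aLDFA in degrees, within [90, 120].
#' @return A \code{stifle_geometry} with \code{aldfa_deg = target_aldfa}.
#' @examples
#' base <- build_reference_stifle()
#' bent <- bend_at_cora(base, 103)
#' measure_aldfa(bent) # 103
#' @export
bend_at_cora <- function(geom, target_aldfa) {
  stopifnot(inherits(geom, "stifle_geometry"))
  if (isTRUE(geom$bent))
    stop("bend_at_cora requires a baseline (unbent) geometry")
  if (!is.finite(target_aldfa) || target_aldfa < 90 || target_aldfa > 120)
    stop("target aLDFA must lie within [90, 120] degrees")
  delta <- target_aldfa - geom$params$baseline_aldfa
  if (delta == 0) {
    geom$aldfa_deg <- target_aldfa
    return(geom)
  }
  ## varus (larger aLDFA) tips the proximal segment medially: for the left
  ## limb (+x lateral) that is a negative rotation about +y; the mirrored
  ## (valgus-reading) limb uses the opposite sign
  sgn <- if (identical(geom$side, "left")) -1 else 1
  z_cora <- geom$landmarks$cora[3]
  bw <- geom$params$blend_width
  cora <- geom$landmarks$cora

  bend_points <- function(m) {
    w <- bend_weight(m[, 3], z_cora, bw)
    out <- m
    idx <- which(w > 0)
    for (i in idx) {
      Rm <- rot_y(sgn * delta * w[i])
      out[i, ] <- as.numeric(Rm %*% (m[i, ] - cora)) + cora
    }
    out
  }
  geom$femur_mesh <- mesh_transform(geom$femur_mesh, bend_points)
  moving <- c("shaft_axis_distal", "shaft_axis_proximal", "greater_trochanter",
              "femoral_head_center", "rectus_femoris_origin")
  for (nm in moving) {
    p <- geom$landmarks[[nm]]
    w <- bend_weight(p[3], z_cora, bw)
    if (w > 0)
      geom$landmarks[[nm]] <- as.numeric(rot_y(sgn * delta * w) %*%
                                           (p - cora)) + cora
  }
  geom$aldfa_deg <- target_aldfa
  geom$bent <- TRUE
  geom
}

## Vertex block of the distal femoral epiphysis (strictly distal to the
## bend transition zone); bit-identical across all bent variants.
distal_epiphysis_vertices <- function(geom) {
  z_cora <- geom$landmarks$cora[3]
  bw <- geom$params$blend_width
  v <- geom$femur_mesh$vertices
  v[v[, 3] < z_cora - bw / 2, , drop = FALSE]
}

#' Mirror a geometry across the sagittal plane
#'
#' Negates the mediolateral coordinate of every vertex, landmark and anchor
#' while keeping the left-limb labelling convention, which turns a varus
#' deformity into the corresponding valgus one: a medially directed
#' quadriceps pull becomes a laterally directed one over the mirrored
#' trochlear profile. Face windings are flipped to keep outward normals and
#' the ridge heights of the contact profile are exchanged.
#'
#' @param geom A \code{stifle_geometry} (baseline or bent).
#' @return The mirrored geometry.
#' @export
mirror_geometry <- function(geom) {
  negx <- function(m) { m[, 1] <- -m[, 1]; m }
  for (nm in c("femur_mesh", "patella_mesh", "tibia_mesh")) {
    geom[[nm]] <- mesh_transform(geom[[nm]], negx)
    geom[[nm]]$faces <- geom[[nm]]$faces[, c(1, 3, 2), drop = FALSE]
  }
  geom$landmarks <- lapply(geom$landmarks,
                           function(p) c(-p[1], p[2], p[3]))
  geom$tuberosity_anchors <- negx(geom$tuberosity_anchors)
  geom$patella_pose$position[1] <- -geom$patella_pose$position[1]
  geom$displacement_origin[1] <- -geom$displacement_origin[1]
  pl <- geom$patella_local
  a <- attr(pl$contact_points, "tributary_area")
  pl$contact_points <- negx(pl$contact_points)
  attr(pl$contact_points, "tributary_area") <- a
  pl$quad_attach <- negx(pl$quad_attach)
  pl$lig_attach <- negx(pl$lig_attach)
  pl$apex <- c(-pl$apex[1], pl$apex[2], pl$apex[3])
  pl$base <- c(-pl$base[1], pl$base[2], pl$base[3])
  geom$patella_local <- pl
  pr <- geom$profile
  tmp <- pr$h_neg; pr$h_neg <- pr$h_pos; pr$h_pos <- tmp
  tmp <- pr$w_neg; pr$w_neg <- pr$w_pos; pr$w_pos <- tmp
  geom$profile <- pr
  geom$mirrored <- !isTRUE(geom$mirrored)
  geom
}
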