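# Anatomical angle metrology on landmark sets. All measurements are built
# from vectors between landmarks, so they are invariant under rigid motion
# of the whole geometry by construction.

get_landmarks <- function(geom) {
  lm <- if (inherits(geom, "stifle_geometry")) geom$landmarks else geom
  if (!is.list(lm)) stop("expected a stifle_geometry or a landmark list")
  lm
}

require_landmarks <- function(lm, needed) {
  missing <- setdiff(needed, names(lm))
  if (length(missing))
    stop("missing landmarks: ", paste(missing, collapse = ", "))
  lm
}

#' Measure the anatomic lateral distal femoral angle (aLDFA)
#'
#' Frontal-plane angle, measured on the lateral side, between the anatomical
#' proximal femoral shaft axis and the distal joint orientation line (the
#' medial-to-lateral condylar landmark line). The two axes are coplanar in
#' this geometry, so the angle is evaluated in the plane they span; larger
#' values mean more distal varus.
#'
#' @param geom A \code{stifle_geometry} or a named landmark list containing
#'   \code{shaft_axis_distal}, \code{shaft_axis_proximal},
#'   \code{medial_condyle_distal} and \code{lateral_condyle_distal}.
#' @return Angle in degrees, in (0, 180).
#' @export
measure_aldfa <- function(geom) {
  lm <- require_landmarks(get_landmarks(geom),
                          c("shaft_axis_distal", "shaft_axis_proximal",
                            "medial_condyle_distal", "lateral_condyle_distal"))
  shaft <- lm$shaft_axis_proximal - lm$shaft_axis_distal
  joint <- lm$lateral_condyle_distal - lm$medial_condyle_distal
  vangle_deg(joint, shaft)
}

#' Measure the femoral anteversion angle
#'
#' Axial-plane angle between the femoral neck axis (greater trochanter to
#' femoral head centre) and the transcondylar axis, both projected onto the
#' plane perpendicular to the proximal shaft axis, taken as the acute angle
#' between the projected lines.
#'
#' @inheritParams measure_aldfa
#' @return Angle in degrees, in [0, 90].
#' @export
measure_anteversion <- function(geom) {
  lm <- require_landmarks(get_landmarks(geom),
                          c("femoral_head_center", "greater_trochanter",
                            "shaft_axis_distal", "shaft_axis_proximal",
                            "medial_condyle_distal", "lateral_condyle_distal"))
  s <- vhat(lm$shaft_axis_proximal - lm$shaft_axis_distal)
  neck <- lm$femoral_head_center - lm$greater_trochanter
  cond <- lm$lateral_condyle_distal - lm$medial_condyle_distal
  proj <- function(v) v - sum(v * s) * s
  n_p <- proj(neck)
  c_p <- proj(cond)
  if (vnorm(n_p) < 1e-9 || vnorm(c_p) < 1e-9)
    stop("axes degenerate with respect to the shaft axis")
  line_angle_deg(n_p, c_p)
}

#' Measure the sagittal stifle flexion angle
#'
#' Angle between the distal femoral segment axis (knee centre towards the
#' CORA) and the tibial long axis (proximal towards distal), evaluated in
#' the plane the two axes span (the sagittal plane of the stance pose).
#'
#' @inheritParams measure_aldfa
#' @return Angle in degrees; 180 for collinear femur and tibia axes.
#' @export
measure_stifle_flexion <- function(geom) {
  lm <- require_landmarks(get_landmarks(geom),
                          c("knee_center", "cora",
                            "tibia_proximal", "tibia_distal"))
  femur <- lm$cora - lm$knee_center
  tibia <- lm$tibia_distal - lm$tibia_proximal
  vangle_deg(femur, tibia)
}

#' Measure the ligament-to-patella length ratio (L:P)
#'
#' Patellar ligament length (patella apex to tibial tuberosity) divided by
#' patella length (apex to base), at the stance pose.
#'
#' @inheritParams measure_aldfa
#' @return Dimensionless positive scalar.
#' @export
measure_lp_ratio <- function(geom) {
  lm <- require_landmarks(get_landmarks(geom),
                          c("patella_apex", "patella_base",
                            "tibial_tuberosity"))
  vnorm(lm$tibial_tuberosity - lm$patella_apex) /
    vnorm(lm$patella_base - lm$patella_apex)
}

#' Apply a rigid transformation to a whole geometry
#'
#' Rotates and translates meshes, landmarks and anchors together. Angle
#' measurements are invariant under this operation.
#'
#' @param geom A \code{stifle_geometry}.
#' @param rotation 3x3 rotation matrix.
#' @param translation 3-vector, mm.
#' @return The transformed geometry. The contact profile is geometry-local
#'   and is marked stale (the simulator requires an untransformed geometry).
#' @export
transform_geometry <- function(geom, rotation = diag(3),
                               translation = c(0, 0, 0)) {
  tf <- function(m) sweep(m %*% t(rotation), 2, -translation)
  for (nm in c("femur_mesh", "patella_mesh", "tibia_mesh"))
    geom[[nm]] <- mesh_transform(geom[[nm]], tf)
  geom$landmarks <- lapply(geom$landmarks,
                           function(p) as.numeric(rotation %*% p) + translation)
  geom$tuberosity_anchors <- tf(geom$tuberosity_anchors)
  geom$patella_pose$position <-
    as.numeric(rotation %*% geom$patella_pose$position) + translation
  geom$world_aligned <- FALSE
  geom
}
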