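#' Parameters of the synthetic canine stifle geometry
#'
#' Defines the parametric stand-in for a CT-derived Beagle stifle: a swept
#' femoral shaft with an extruded trochlear cross-section (circular-arc
#' groove flanked by a medial and a lateral ridge), a patella with a
#' cylindrical posterior facet conforming to the groove arc, and a prismatic
#' tibia carrying the tibial tuberosity landmark. Dimensions default to a
#' roughly 10.7 kg Beagle scale (100 mm femur). Groove depth, ridge heights
#' and patella dimensions are package calibration (no published values
#' exist for them); the shipped defaults are the package's reference
#' configuration.
#'
#' @param femur_length Femur length, mm.
#' @param shaft_radius Mid-shaft radius, mm.
#' @param groove_depth Depth of the trochlear floor below the surrounding
#'   cranial epiphyseal surface, mm (cosmetic carve depth of the mesh).
#' @param medial_ridge_height Height of the medial trochlear ridge apex
#'   above the groove floor, mm. Together with \code{groove_arc_radius}
#'   this sets the medial half-width of the groove arc and therefore the
#'   maximum wall angle the medial ridge can oppose to a medially directed
#'   patellar load.
#' @param lateral_ridge_height Height of the lateral ridge apex above the
#'   groove floor, mm.
#' @param groove_arc_radius Radius of the circular-arc groove cross-section,
#'   mm; the patellar posterior facet uses the same radius (conforming
#'   contact).
#' @param patella_length Proximodistal patella length (apex to base), mm.
#' @param patella_width Mediolateral patella width, mm.
#' @param patella_thickness Craniocaudal patella thickness, mm.
#' @param ligament_length Patellar ligament length (patella apex to tibial
#'   tuberosity), mm. Defaults to 1.55 x \code{patella_length}, the
#'   patellar-height ratio of a clinically normal stifle.
#' @param baseline_aldfa Baseline anatomic lateral distal femoral angle,
#'   degrees.
#' @param baseline_anteversion Baseline femoral anteversion angle, degrees.
#' @param stifle_flexion Sagittal-plane angle between femur and tibia
#'   segments at the stance pose, degrees.
#' @param hip_sagittal_angle Sagittal-plane hip angle locating the virtual
#'   ilium origin of the rectus femoris, degrees.
#' @param cora_fraction Position of the centre of rotation of angulation
#'   along the femur, as a fraction of femur length from the proximal end
#'   (default 2/3, i.e. the distal one-third point).
#' @param blend_width Axial width of the bend transition zone around the
#'   CORA, mm; vertices strictly distal to the zone are never touched.
#' @param outer_wall_angle Slope of the ridge outer walls, degrees from the
#'   groove floor plane.
#' @param shelf_drop Drop from the groove floor to the flat bone shelf
#'   outside the ridges, mm.
#' @param trochlea_z_range Proximodistal extent of the trochlear surface,
#'   mm (2-vector, distal then proximal, relative to the knee centre).
#' @param patella_center_z Proximodistal position of the patella centre at
#'   the stance pose, mm.
#' @param quad_origin_medial_offset Small medial offset of the rectus
#'   femoris origin relative to the extensor axis, mm; gives the baseline
#'   its slight physiological medial load so the stable models press
#'   against the medial ridge.
#' @param ilium_offset Distance from the hip centre to the virtual ilium
#'   origin along the hip sagittal angle, mm.
#' @param neck_length Femoral neck length, mm.
#' @param neck_elevation Femoral neck elevation out of the axial plane,
#'   degrees.
#' @param ligament_sagittal_angle Caudal inclination of the patellar
#'   ligament from the distal vertical, degrees.
#' @param tendon_rest_length Rest length of the quadriceps tendon springs,
#'   mm.
#' @param condyle_half_span Half-distance between the medial and lateral
#'   distal condylar landmarks, mm.
#' @param facet_contact_half_width Mediolateral half-width of the
#'   articulating strip of the patellar facet that bears on the groove, mm
#'   (the facet rim is rounded and non-articulating).
#' @return An object of class \code{geometry_params}.
#' @examples
#' p <- geometry_params()
#' p$ligament_length / p$patella_length # 1.55
#' @export
geometry_params <- function(femur_length = 100,
                            shaft_radius = 7,
                            groove_depth = 2,
                            medial_ridge_height = 0.08,
                            lateral_ridge_height = 1.2,
                            groove_arc_radius = 7,
                            patella_length = 12,
                            patella_width = 8,
                            patella_thickness = 5,
                            ligament_length = NULL,
                            baseline_aldfa = 95,
                            baseline_anteversion = 16,
                            stifle_flexion = 127,
                            hip_sagittal_angle = 125.2,
                            cora_fraction = 2 / 3,
                            blend_width = 5,
                            outer_wall_angle = 35,
                            shelf_drop = 2,
                            trochlea_z_range = c(2, 26),
                            patella_center_z = 14,
                            quad_origin_medial_offset = 1.5,
                            ilium_offset = 40,
                            neck_length = 12,
                            neck_elevation = 45,
                            ligament_sagittal_angle = 20,
                            tendon_rest_length = 15,
                            condyle_half_span = 8,
                            facet_contact_half_width = 2) {
  if (is.null(ligament_length)) ligament_length <- 1.55 * patella_length
  p <- structure(as.list(environment()), class = "geometry_params")
  validate_geometry_params(p)
  p
}

validate_geometry_params <- function(p) {
  lengths <- c("femur_length", "shaft_radius", "groove_depth",
               "medial_ridge_height", "lateral_ridge_height",
               "groove_arc_radius", "patella_length", "patella_width",
               "patella_thickness", "ligament_length", "blend_width",
               "tendon_rest_length", "condyle_half_span", "ilium_offset",
               "neck_length", "facet_contact_half_width")
  for (nm in lengths) {
    v <- p[[nm]]
    if (!is.numeric(v) || length(v) != 1 || !is.finite(v) || v <= 0)
      stop(sprintf("geometry parameter '%s' must be a positive length", nm))
  }
  if (!(p$groove_depth < p$medial_ridge_height + p$groove_arc_radius))
    stop("infeasible geometry: groove_depth must be smaller than ",
         "medial_ridge_height + groove_arc_radius")
  if (p$cora_fraction <= 0 || p$cora_fraction >= 1)
    stop("cora_fraction must lie strictly between 0 and 1")
  if (p$patella_width / 2 >= p$groove_arc_radius)
    stop("infeasible geometry: patella wider than the trochlear arc ",
         sprintf("(width/2 = %.2f mm >= arc radius %.2f mm)",
                 p$patella_width / 2, p$groove_arc_radius))
  if (p$medial_ridge_height >= p$groove_arc_radius ||
      p$lateral_ridge_height >= p$groove_arc_radius)
    stop("infeasible geometry: ridge height must be below the arc radius")
  ridge_top <- max(p$medial_ridge_height, p$lateral_ridge_height)
  if (p$trochlea_z_range[1] >= p$trochlea_z_range[2])
    stop("trochlea_z_range must be increasing")
  if (p$patella_center_z - p$patella_length / 2 < p$trochlea_z_range[1] ||
      p$patella_center_z + p$patella_length / 2 > p$trochlea_z_range[2])
    stop("infeasible geometry: patella does not fit inside the trochlear ",
         "surface extent")
  invisible(p)
}

#' @export
print.geometry_params <- function(x, ...) {
  cat("<geometry_params>\n")
  cat(sprintf("  femur %g mm, baseline aLDFA %g deg, AA %g deg, ",
              x$femur_length, x$baseline_aldfa, x$baseline_anteversion))
  cat(sprintf("stifle %g deg\n", x$stifle_flexion))
  cat(sprintf("  groove arc R %g mm, ridges medial %g / lateral %g mm\n",
              x$groove_arc_radius, x$medial_ridge_height,
              x$lateral_ridge_height))
  cat(sprintf("  patella %g x %g x %g mm, L:P %.3g\n", x$patella_length,
              x$patella_width, x$patella_thickness,
              x$ligament_length / x$patella_length))
  invisible(x)
}
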