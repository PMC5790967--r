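#' Standard NU2 phantom geometry
#'
#' Collects the dimensions of the phantoms used by the performance tests:
#' the polyethylene scatter cylinder with its off-centre line-source hole,
#' the five-aluminium-sleeve sensitivity phantom, and the IEC body-phantom
#' sphere set. Defaults are the standard NU2-07 values.
#'
#' @param cylinder_outer_diameter_mm outer diameter of the scatter cylinder.
#' @param cylinder_length_mm length of the scatter cylinder.
#' @param cylinder_density_g_cm3 polyethylene density.
#' @param line_offset_mm radial distance of the line-source hole from the
#'   cylinder axis.
#' @param iq_sphere_diameters_mm inner diameters of the six IEC spheres,
#'   strictly increasing.
#' @param lung_insert_diameter_mm diameter of the low-density lung insert.
#' @param sleeve_inner_diameters_mm,sleeve_outer_diameters_mm diameters of
#'   the five nested aluminium sleeves.
#' @param sleeve_wall_thickness_mm wall thickness of each sleeve.
#' @param sleeve_length_mm sleeve length.
#' @return object of class `phantom_geometry` (a validated list).
#' @examples
#' geom <- phantom_geometry()
#' scatter_phantom_volume_mL(geom)
#' @export
phantom_geometry <- function(cylinder_outer_diameter_mm = 203,
                             cylinder_length_mm = 700,
                             cylinder_density_g_cm3 = 0.96,
                             line_offset_mm = 45,
                             iq_sphere_diameters_mm = c(10, 13, 17, 22, 28, 37),
                             lung_insert_diameter_mm = 50,
                             sleeve_inner_diameters_mm = c(3.9, 7.0, 10.2, 13.4, 16.6),
                             sleeve_outer_diameters_mm = c(6.4, 9.5, 12.7, 15.9, 19.1),
                             sleeve_wall_thickness_mm = 1.25,
                             sleeve_length_mm = 700) {
  geom <- list(
    cylinder_outer_diameter_mm = cylinder_outer_diameter_mm,
    cylinder_length_mm = cylinder_length_mm,
    cylinder_density_g_cm3 = cylinder_density_g_cm3,
    line_offset_mm = line_offset_mm,
    iq_sphere_diameters_mm = iq_sphere_diameters_mm,
    lung_insert_diameter_mm = lung_insert_diameter_mm,
    sleeve_inner_diameters_mm = sleeve_inner_diameters_mm,
    sleeve_outer_diameters_mm = sleeve_outer_diameters_mm,
    sleeve_wall_thickness_mm = sleeve_wall_thickness_mm,
    sleeve_length_mm = sleeve_length_mm
  )
  lens <- unlist(geom[c("cylinder_outer_diameter_mm", "cylinder_length_mm",
                        "line_offset_mm", "iq_sphere_diameters_mm",
                        "lung_insert_diameter_mm", "sleeve_inner_diameters_mm",
                        "sleeve_outer_diameters_mm", "sleeve_wall_thickness_mm",
                        "sleeve_length_mm")])
  if (any(!is.finite(lens)) || any(lens <= 0))
    stop("all phantom lengths must be positive and finite")
  if (length(sleeve_inner_diameters_mm) != length(sleeve_outer_diameters_mm))
    stop("sleeve diameter lists must have equal length")
  if (length(sleeve_inner_diameters_mm) != 5L)
    stop("the sensitivity phantom has exactly 5 sleeves")
  if (any(sleeve_outer_diameters_mm <= sleeve_inner_diameters_mm))
    stop("each sleeve's outer diameter must exceed its inner diameter")
  if (any(diff(iq_sphere_diameters_mm) <= 0))
    stop("IQ sphere diameters must be strictly increasing")
  structure(geom, class = "phantom_geometry")
}

#' Total volume of the scatter cylinder, in millilitres
#'
#' The activity-concentration denominator used when converting total phantom
#' activity to kBq/cc. For the default geometry this is
#' pi * (101.5 mm)^2 * 700 mm ~= 22,656 mL. Pass `volume_mL` explicitly to
#' the analysis functions to use the rounded 22,000 mL convention instead.
#'
#' @param geometry a [phantom_geometry()].
#' @return volume in mL.
#' @export
scatter_phantom_volume_mL <- function(geometry = phantom_geometry()) {
  r_cm <- geometry$cylinder_outer_diameter_mm / 2 / 10
  pi * r_cm^2 * (geometry$cylinder_length_mm / 10)
}
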