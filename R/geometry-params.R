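# Parameter objects for the synthetic proximal femur surrogate, the
# cephalomedullary implant, and the wall-defect carving rules.
#
# Coordinate convention (right femur): origin on the femoral shaft axis at
# the level of the lesser trochanter; +z proximal, +x anterior, +y lateral
# (medial is -y). All lengths in mm, angles in degrees.

#' Parametric proximal femur surrogate
#'
#' Defines an analytic stand-in for a segmented proximal femur: a femoral
#' head sphere on a neck, blended through a trochanteric swell into a
#' straight shaft, modelled as a variable-radius tube swept along a bent
#' medial axis plus the head sphere. The surrogate defines exactly the
#' landmarks the fracture and defect rules operate on (shaft axis, lesser
#' trochanter, head apex).
#'
#' @param head_radius Femoral head radius, mm.
#' @param neck_radius Neck tube radius, mm.
#' @param neck_length Distance from the neck-axis origin on the shaft axis to
#'   the head centre, mm.
#' @param neck_shaft_angle Angle between neck axis and the distal shaft axis,
#'   degrees; must lie in (110, 150).
#' @param shaft_radius_outer Outer shaft radius, mm.
#' @param cortical_thickness Cortical shell thickness, mm (must be smaller
#'   than `shaft_radius_outer`; also bounds the medullary canal radius).
#' @param shaft_length Shaft length below the lesser trochanter level, mm.
#' @param greater_trochanter_extent Maximal radial extent of the trochanteric
#'   swell from the shaft axis, mm.
#' @param anteversion Femoral neck anteversion, degrees (rotation of the neck
#'   axis toward +x).
#' @return Object of class `femur_params`.
#' @export
femur_params <- function(head_radius = 24, neck_radius = 15, neck_length = 48,
                         neck_shaft_angle = 125, shaft_radius_outer = 14,
                         cortical_thickness = 4, shaft_length = 180,
                         greater_trochanter_extent = 26, anteversion = 0) {
  lens <- c(head_radius = head_radius, neck_radius = neck_radius,
            neck_length = neck_length, shaft_radius_outer = shaft_radius_outer,
            cortical_thickness = cortical_thickness, shaft_length = shaft_length,
            greater_trochanter_extent = greater_trochanter_extent)
  bad <- names(lens)[!(is.finite(lens) & lens > 0)]
  if (length(bad)) stop_input("femur_params: %s must be > 0", paste(bad, collapse = ", "))
  check_that(cortical_thickness < shaft_radius_outer,
             "femur_params: cortical_thickness must be < shaft_radius_outer")
  check_that(neck_shaft_angle > 110 && neck_shaft_angle < 150,
             "femur_params: neck_shaft_angle must lie in (110, 150) degrees")
  check_that(greater_trochanter_extent >= shaft_radius_outer,
             "femur_params: greater_trochanter_extent must be >= shaft_radius_outer")
  structure(as.list(environment())[names(formals(femur_params))],
            class = "femur_params")
}

#' Cephalomedullary implant specification
#'
#' PFNA-type construct: intramedullary nail along the shaft axis, a helical
#' blade (modelled as an equivalent-radius cylinder) into the femoral head,
#' and a distal locking screw. Defaults follow the manufacturer geometry of
#' a short nail: length 200 mm, blade angle 125 degrees, placed at a
#' tip-apex distance (TAD) of 15 mm.
#'
#' @param nail_length Nail length, mm.
#' @param nail_radius Nail radius, mm.
#' @param blade_radius Blade (cylinder surrogate) radius, mm.
#' @param blade_angle Angle between blade axis and distal nail axis, degrees.
#' @param locking_screw_radius Distal locking screw radius, mm.
#' @param target_tad Target tip-apex distance, mm (> 0).
#' @param include_screw Logical; generate the locking screw part.
#' @return Object of class `implant_spec`.
#' @export
implant_spec <- function(nail_length = 200, nail_radius = 5,
                         blade_radius = 5.25, blade_angle = 125,
                         locking_screw_radius = 2.45, target_tad = 15,
                         include_screw = TRUE) {
  check_that(nail_length > 0, "implant_spec: nail_length must be > 0")
  check_that(nail_radius > 0 && blade_radius > 0 && locking_screw_radius > 0,
             "implant_spec: radii must be > 0")
  check_that(blade_angle >= 90 && blade_angle < 180,
             "implant_spec: blade_angle must lie in [90, 180) degrees")
  check_that(target_tad > 0, "implant_spec: target_tad must be > 0")
  structure(as.list(environment())[names(formals(implant_spec))],
            class = "implant_spec")
}

#' Wall-defect carving rules
#'
#' Geometric rules that carve the seven cortical wall defects out of the
#' basic fracture model. The medial wall is the cortical zone within
#' `medial_zone_halfwidth` above and below the lesser trochanter level; the
#' lateral wall is a band on the lateral cortex spanning the blade-entry
#' region. Both defects remove the outer `defect_depth_fraction` of the
#' cortex-to-shaft-axis distance. Anterior/posterior halves are split by a
#' plane through the femoral shaft axis (the sagittal plane x = 0). The PL
#' variant additionally removes the `pl_upper_height` of lateral band
#' immediately proximal to it; the PML variant removes the PM wall, the PL
#' wall, and all posterior outer-wall bone between them.
#'
#' @param medial_zone_halfwidth Half-height of the medial wall band about the
#'   lesser trochanter level, mm (default 20, i.e. 2 cm above and below).
#' @param defect_depth_fraction Fraction of the cortex-to-shaft-axis distance
#'   removed radially, in (0, 1].
#' @param split_plane_normal Normal of the anterior/posterior split plane;
#'   must be orthogonal to the shaft axis so the plane contains it.
#' @param medial_sector_halfangle,lateral_sector_halfangle Azimuthal
#'   half-extent of the medial and lateral walls about the medial (-y) and
#'   lateral (+y) directions, degrees.
#' @param lateral_band Numeric length-2: z-range of the lateral wall band
#'   relative to the lesser trochanter level, mm.
#' @param pl_upper_height Height of the additional proximal lateral-band
#'   region removed in the PL variant, mm.
#' @return Object of class `defect_rules`.
#' @export
defect_rules <- function(medial_zone_halfwidth = 20, defect_depth_fraction = 0.5,
                         split_plane_normal = c(1, 0, 0),
                         medial_sector_halfangle = 60,
                         lateral_sector_halfangle = 60,
                         lateral_band = c(-10, 20), pl_upper_height = 8) {
  check_that(medial_zone_halfwidth > 0, "defect_rules: medial_zone_halfwidth must be > 0")
  check_that(defect_depth_fraction > 0 && defect_depth_fraction <= 1,
             "defect_rules: defect_depth_fraction must lie in (0, 1]")
  check_that(length(split_plane_normal) == 3 && abs(split_plane_normal[3]) < 1e-9,
             "defect_rules: split_plane_normal must be orthogonal to the shaft axis (z)")
  check_that(length(lateral_band) == 2 && lateral_band[2] > lateral_band[1],
             "defect_rules: lateral_band must be an increasing z-range")
  check_that(pl_upper_height >= 0, "defect_rules: pl_upper_height must be >= 0")
  structure(
    list(medial_zone_halfwidth = medial_zone_halfwidth,
         defect_depth_fraction = defect_depth_fraction,
         split_plane_normal = unit(split_plane_normal),
         medial_sector_halfangle = medial_sector_halfangle,
         lateral_sector_halfangle = lateral_sector_halfangle,
         lateral_band = lateral_band, pl_upper_height = pl_upper_height),
    class = "defect_rules"
  )
}

check_variant <- function(variant) {
  check_that(is.character(variant) && length(variant) == 1 &&
               variant %in% fracture_variants(),
             "unknown fracture variant '%s' (expected one of %s)",
             as.character(variant)[1], paste(fracture_variants(), collapse = ", "))
  variant
}
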