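# Bone material assignment: synthetic Hounsfield-unit field on the volume
# mesh, HU -> apparent density -> elastic modulus calibration, and per-element
# elastic constants with implant parts held at titanium-alloy values.

#' Material calibration constants
#'
#' Affine CT calibration used for bone: density `rho = rho_intercept +
#' rho_slope * HU` (kg/m^3) and modulus `E = e_intercept + e_slope * rho`
#' (MPa), with the modulus floored at `e_floor` so every element keeps a
#' positive-definite stiffness (the affine map goes negative for very low
#' density, e.g. marrow-filled canal elements). Bone Poisson ratio and the
#' titanium-alloy implant constants are carried alongside.
#'
#' @param rho_intercept,rho_slope Density calibration (kg/m^3, kg/m^3 per HU).
#' @param e_intercept,e_slope Modulus calibration (MPa, MPa per kg/m^3).
#' @param nu_bone,nu_implant Poisson ratios (dimensionless, in (0, 0.5)).
#' @param e_implant Implant elastic modulus, MPa.
#' @param e_floor Lower bound applied to bone modulus, MPa (> 0).
#' @return Object of class `material_calibration`.
#' @export
material_calibration <- function(rho_intercept = 131, rho_slope = 1.067,
                                 e_intercept = -331, e_slope = 4.56,
                                 nu_bone = 0.3, e_implant = 105000,
                                 nu_implant = 0.35, e_floor = 1) {
  check_that(e_floor > 0, "e_floor must be > 0")
  check_that(rho_slope > 0 && e_slope > 0, "calibration slopes must be > 0")
  check_that(nu_bone > 0 && nu_bone < 0.5, "nu_bone must lie in (0, 0.5)")
  check_that(nu_implant > 0 && nu_implant < 0.5, "nu_implant must lie in (0, 0.5)")
  structure(
    list(rho_intercept = rho_intercept, rho_slope = rho_slope,
         e_intercept = e_intercept, e_slope = e_slope,
         nu_bone = nu_bone, e_implant = e_implant,
         nu_implant = nu_implant, e_floor = e_floor),
    class = "material_calibration"
  )
}

#' Synthetic Hounsfield-unit field specification
#'
#' Parameters of the two-phase HU field that stands in for a patient CT:
#' elements whose centroid lies within `cortical_shell_thickness` of the
#' outer bone surface take the cortical mean, interior elements the
#' trabecular mean, plus a seeded stationary noise field with standard
#' deviation `noise_sd` (a random-phase cosine field, so the same seed
#' reproduces the same HU at the same location in every model variant).
#'
#' @param cortical_hu_mean,trabecular_hu_mean Mean HU of the two phases
#'   (cortical must exceed trabecular).
#' @param noise_sd Gaussian HU noise standard deviation (>= 0).
#' @param cortical_shell_thickness Shell depth classified as cortical, mm.
#' @param seed Integer RNG seed for the noise.
#' @return Object of class `hu_field_spec`.
#' @export
hu_field_spec <- function(cortical_hu_mean = 1500, trabecular_hu_mean = 300,
                          noise_sd = 50, cortical_shell_thickness = 4,
                          seed = 1L) {
  check_that(cortical_hu_mean > trabecular_hu_mean,
             "cortical_hu_mean must exceed trabecular_hu_mean")
  check_that(noise_sd >= 0, "noise_sd must be >= 0")
  check_that(cortical_shell_thickness > 0, "cortical_shell_thickness must be > 0")
  structure(
    list(cortical_hu_mean = cortical_hu_mean,
         trabecular_hu_mean = trabecular_hu_mean,
         noise_sd = noise_sd,
         cortical_shell_thickness = cortical_shell_thickness,
         seed = as.integer(seed)),
    class = "hu_field_spec"
  )
}

#' Synthesize a per-element Hounsfield-unit field
#'
#' @param mesh A `volume_mesh` (see [tetrahedralize()]); only bone elements
#'   receive HU values (implant elements get `NA`).
#' @param spec An [hu_field_spec()].
#' @param boundary_distance Function mapping an n x 3 matrix of points (mm)
#'   to their (approximate) distance to the outer bone surface; defaults to
#'   the solid attached to the mesh. Used to split cortical shell from
#'   trabecular interior.
#' @return Numeric vector, one HU value per element (NA for implant parts).
#'   Attribute `cortical` holds the logical shell mask.
#' @export
synthesize_hu <- function(mesh, spec = hu_field_spec(),
                          boundary_distance = NULL) {
  check_that(inherits(mesh, "volume_mesh"), "mesh must be a volume_mesh")
  if (is.null(boundary_distance)) {
    solid <- attr(mesh, "solid")
    check_that(!is.null(solid) && !is.null(solid$sdf),
               "mesh carries no solid; supply boundary_distance explicitly")
    boundary_distance <- function(p) solid$sdf(p)
  }
  bone <- mesh$element_part %in% c("head_neck_fragment", "shaft_fragment", "bone")
  hu <- rep(NA_real_, nrow(mesh$tets))
  cort <- rep(NA, nrow(mesh$tets))
  if (any(bone)) {
    cen <- element_centroids(mesh)[bone, , drop = FALSE]
    d <- boundary_distance(cen)
    is_cort <- d <= spec$cortical_shell_thickness
    mu <- ifelse(is_cort, spec$cortical_hu_mean, spec$trabecular_hu_mean)
    hu[bone] <- mu + spec$noise_sd * hu_noise_field(cen, spec$seed)
    cort[bone] <- is_cort
  }
  attr(hu, "cortical") <- cort
  hu
}

# Seeded stationary Gaussian-like random field with unit marginal variance,
# evaluated at points (mm): a sum of random-phase cosines. Being a function
# of position (not of element order), the same seed gives the same HU at the
# same location in every model variant, mirroring a single CT volume shared
# by all fracture models of one femur.
hu_noise_field <- function(points, seed, n_modes = 48L, corr_length = 6) {
  p <- as_points(points)
  par <- with_seed(seed, {
    k <- matrix(stats::rnorm(3L * n_modes), n_modes, 3) / corr_length
    list(k = k, phase = stats::runif(n_modes, 0, 2 * pi))
  })
  acc <- numeric(nrow(p))
  for (m in seq_len(n_modes)) {
    acc <- acc + cos(p %*% par$k[m, ] + par$phase[m])
  }
  as.numeric(acc) * sqrt(2 / n_modes)
}

#' Convert Hounsfield units to apparent density
#'
#' `rho = rho_intercept + rho_slope * HU` (kg/m^3).
#'
#' @param hu Numeric HU values.
#' @param cal A [material_calibration()].
#' @return Density, kg/m^3.
#' @export
hu_to_density <- function(hu, cal = material_calibration()) {
  cal$rho_intercept + cal$rho_slope * hu
}

#' Convert apparent density to elastic modulus
#'
#' `E = max(e_floor, e_intercept + e_slope * rho)` (MPa).
#'
#' @param rho Density, kg/m^3.
#' @param cal A [material_calibration()].
#' @return Elastic modulus, MPa (floored at `cal$e_floor`).
#' @export
density_to_modulus <- function(rho, cal = material_calibration()) {
  pmax(cal$e_floor, cal$e_intercept + cal$e_slope * rho)
}

#' Assign per-element elastic constants
#'
#' Maps the HU field through the density and modulus calibrations for bone
#' elements (with the modulus floor) and sets implant elements to the
#' titanium-alloy constants. Optionally bins the bone moduli into
#' `n_bins` equal-width material groups (each element takes its bin's mean
#' modulus), mirroring discrete CT-based material-mapping workflows.
#'
#' @param mesh A `volume_mesh`.
#' @param hu_field Per-element HU values (from [synthesize_hu()] or imported);
#'   must cover all bone elements.
#' @param cal A [material_calibration()].
#' @param n_bins Integer number of equal-width modulus bins for bone, or
#'   `NULL` for continuous per-element values.
#' @return Object of class `element_materials`: list with per-element `E`
#'   (MPa), `nu`, `rho` (kg/m^3, NA for implant), logical `is_bone`, and
#'   integer `material_bin` (NA when unbinned or implant).
#' @export
assign_materials <- function(mesh, hu_field, cal = material_calibration(),
                             n_bins = NULL) {
  check_that(inherits(mesh, "volume_mesh"), "mesh must be a volume_mesh")
  nel <- nrow(mesh$tets)
  check_that(length(hu_field) == nel,
             "hu_field length (%d) must match element count (%d)", length(hu_field), nel)
  bone <- mesh$element_part %in% c("head_neck_fragment", "shaft_fragment", "bone")
  missing <- bone & !is.finite(hu_field)
  if (any(missing)) {
    stop_input("missing HU for bone element(s): %s",
               paste(utils::head(which(missing), 10L), collapse = ", "))
  }
  E <- rep(cal$e_implant, nel)
  nu <- rep(cal$nu_implant, nel)
  rho <- rep(NA_real_, nel)
  bin <- rep(NA_integer_, nel)
  if (any(bone)) {
    rho[bone] <- hu_to_density(hu_field[bone], cal)
    E[bone] <- density_to_modulus(rho[bone], cal)
    nu[bone] <- cal$nu_bone
    if (!is.null(n_bins)) {
      n_bins <- as.integer(n_bins)
      check_that(n_bins >= 1, "n_bins must be >= 1")
      eb <- E[bone]
      rng <- range(eb)
      if (rng[2] > rng[1]) {
        edges <- seq(rng[1], rng[2], length.out = n_bins + 1L)
        idx <- pmin(pmax(findInterval(eb, edges, rightmost.closed = TRUE), 1L), n_bins)
      } else {
        idx <- rep(1L, length(eb))
      }
      means <- tapply(eb, idx, mean)
      E[bone] <- as.numeric(means[as.character(idx)])
      bin[bone] <- idx
    }
  }
  structure(
    list(E = E, nu = nu, rho = rho, is_bone = bone, material_bin = bin),
    class = "element_materials"
  )
}
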