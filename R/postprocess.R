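# Outcome indicators: implant von Mises stress peaks, bone principal-strain
# peaks, risky tensile/compressive volumes at the +-0.9% strain thresholds,
# femoral-head vertex displacement, and fracture-surface gap.

#' Strain-risk thresholds
#'
#' Bone elements with maximum (tensile) principal strain above
#' `tensile_limit` or minimum (compressive) principal strain below
#' `compressive_limit` are classified as at risk of yielding. Comparisons
#' are strict: boundary-equal elements are not risky.
#'
#' @param tensile_limit Tensile strain threshold (> 0), default 0.009.
#' @param compressive_limit Compressive strain threshold (< 0), default
#'   -0.009.
#' @return Object of class `risk_thresholds`.
#' @export
risk_thresholds <- function(tensile_limit = 0.009, compressive_limit = -0.009) {
  check_that(tensile_limit > 0 && compressive_limit < 0,
             "need tensile_limit > 0 > compressive_limit")
  structure(list(tensile_limit = tensile_limit,
                 compressive_limit = compressive_limit),
            class = "risk_thresholds")
}

#' Von Mises equivalent stress
#'
#' @param stress Either an m x 6 Voigt matrix (xx, yy, zz, xy, yz, zx) or a
#'   single symmetric 3 x 3 stress tensor, MPa.
#' @return Non-negative equivalent stress, MPa (vector of length m, or a
#'   scalar for tensor input).
#' @export
von_mises <- function(stress) {
  s <- voigt_input(stress, "stress")
  sqrt(pmax(0.5 * ((s[, 1] - s[, 2])^2 + (s[, 2] - s[, 3])^2 +
                   (s[, 3] - s[, 1])^2) +
            3 * (s[, 4]^2 + s[, 5]^2 + s[, 6]^2), 0))
}

voigt_input <- function(x, what) {
  if (is.matrix(x) && nrow(x) == 3 && ncol(x) == 3) {
    check_that(max(abs(x - t(x))) <= 1e-8 * max(1, max(abs(x))),
               "%s tensor must be symmetric", what)
    return(matrix(c(x[1, 1], x[2, 2], x[3, 3], x[1, 2], x[2, 3], x[3, 1]), 1))
  }
  x <- if (is.null(dim(x))) matrix(x, 1) else as.matrix(x)
  check_that(ncol(x) == 6, "%s must be m x 6 Voigt or a symmetric 3 x 3 tensor", what)
  x
}

#' Principal strains
#'
#' Sorted eigenvalues (`eps1 >= eps2 >= eps3`) of the strain tensor,
#' computed by the closed-form trigonometric solution for symmetric 3 x 3
#' matrices (rotation-invariant). Voigt input uses engineering shear (the
#' off-diagonal tensor components are half the Voigt shear entries).
#'
#' @param strain m x 6 Voigt matrix (engineering shear) or one symmetric
#'   3 x 3 strain tensor.
#' @return m x 3 matrix with columns `eps1 >= eps2 >= eps3`.
#' @export
principal_strains <- function(strain) {
  if (is.matrix(strain) && nrow(strain) == 3 && ncol(strain) == 3) {
    check_that(max(abs(strain - t(strain))) <= 1e-8 * max(1, max(abs(strain))),
               "strain tensor must be symmetric")
    v <- matrix(c(strain[1, 1], strain[2, 2], strain[3, 3],
                  2 * strain[1, 2], 2 * strain[2, 3], 2 * strain[3, 1]), 1)
    return(principal_strains(v))
  }
  e <- voigt_input(strain, "strain")
  a11 <- e[, 1]; a22 <- e[, 2]; a33 <- e[, 3]
  a12 <- e[, 4] / 2; a23 <- e[, 5] / 2; a13 <- e[, 6] / 2
  q <- (a11 + a22 + a33) / 3
  p2 <- (a11 - q)^2 + (a22 - q)^2 + (a33 - q)^2 +
    2 * (a12^2 + a23^2 + a13^2)
  p <- sqrt(p2 / 6)
  out <- matrix(q, nrow = length(q), ncol = 3)
  nz <- p > 1e-300
  if (any(nz)) {
    b11 <- (a11[nz] - q[nz]) / p[nz]; b22 <- (a22[nz] - q[nz]) / p[nz]
    b33 <- (a33[nz] - q[nz]) / p[nz]
    b12 <- a12[nz] / p[nz]; b23 <- a23[nz] / p[nz]; b13 <- a13[nz] / p[nz]
    detb <- b11 * (b22 * b33 - b23^2) - b12 * (b12 * b33 - b23 * b13) +
      b13 * (b12 * b23 - b22 * b13)
    r <- pmin(pmax(detb / 2, -1), 1)
    phi <- acos(r) / 3
    e1 <- q[nz] + 2 * p[nz] * cos(phi)
    e3 <- q[nz] + 2 * p[nz] * cos(phi + 2 * pi / 3)
    e2 <- 3 * q[nz] - e1 - e3
    out[nz, 1] <- e1; out[nz, 2] <- e2; out[nz, 3] <- e3
  }
  colnames(out) <- c("eps1", "eps2", "eps3")
  out
}

#' Risky tensile and compressive bone volumes
#'
#' Sums element volumes whose maximum principal strain strictly exceeds the
#' tensile limit, or whose minimum principal strain lies strictly below the
#' compressive limit, and the corresponding fractions of the total bone
#' volume.
#'
#' @param volumes Element volumes, mm^3 (bone elements).
#' @param eps1,eps3 Per-element maximum and minimum principal strains.
#' @param thresholds A [risk_thresholds()].
#' @param total_volume Denominator for the ratios; defaults to
#'   `sum(volumes)`.
#' @return List: `tensile_volume`, `tensile_ratio`, `compressive_volume`,
#'   `compressive_ratio`, and logical masks `tensile_mask`,
#'   `compressive_mask`.
#' @export
risky_volumes <- function(volumes, eps1, eps3, thresholds = risk_thresholds(),
                          total_volume = NULL) {
  check_that(length(volumes) == length(eps1) && length(volumes) == length(eps3),
             "volumes and strains must have equal length")
  check_that(all(is.finite(eps1)) && all(is.finite(eps3)),
             "missing principal strain for %d element(s)",
             sum(!is.finite(eps1) | !is.finite(eps3)))
  tv <- total_volume %||% sum(volumes)
  tm <- eps1 > thresholds$tensile_limit
  cm <- eps3 < thresholds$compressive_limit
  list(
    tensile_volume = sum(volumes[tm]),
    tensile_ratio = if (tv > 0) sum(volumes[tm]) / tv else 0,
    compressive_volume = sum(volumes[cm]),
    compressive_ratio = if (tv > 0) sum(volumes[cm]) / tv else 0,
    tensile_mask = tm, compressive_mask = cm
  )
}

#' Head-vertex displacement toward the distal femur
#'
#' Magnitude of the distal (-z) displacement component of the femoral-head
#' vertex (the most proximal head node); the full displacement magnitude is
#' attached as attribute `"magnitude"`.
#'
#' @param result A `solve_result`.
#' @param head_vertex Node id of the head vertex.
#' @return Distal displacement, mm (>= 0).
#' @export
head_displacement <- function(result, head_vertex) {
  u <- result$u[head_vertex, ]
  out <- max(0, -u[3])
  attr(out, "magnitude") <- sqrt(sum(u^2))
  out
}

#' Fracture-surface gap
#'
#' Normal opening across the paired fracture-interface nodes after
#' deformation (initial separation subtracted, compressive closing floored
#' at zero). Returns the maximum opening; the mean is attached as attribute
#' `"mean"`. By default the statistic is evaluated on the portion of the
#' fracture surface that no wall defect can remove, so gap values compare
#' the same surface across all model variants; `region = "all"` uses every
#' surviving pair.
#'
#' @param result A `solve_result`.
#' @param assembly The `model_assembly` holding the interface pairing.
#' @param region `"common"` (default) or `"all"`.
#' @return Maximum gap, mm.
#' @export
fracture_gap <- function(result, assembly, region = c("common", "all")) {
  region <- match.arg(region)
  pairs <- assembly$fracture_pairs
  check_that(nrow(pairs) > 0, "assembly has no fracture interface")
  g <- pair_gaps(assembly, result$u)
  if (region == "common" && !is.null(pairs$common) && any(pairs$common)) {
    g <- g[pairs$common]
  }
  out <- max(g)
  attr(out, "mean") <- mean(g)
  out
}

#' Extract the outcome indicator set of one solved model
#'
#' Computes the indicators from a static `solve_result` or a quasi-static
#' `gait_result` envelope: implant von Mises peaks (nail and blade
#' separately), bone principal-strain peaks, risky tensile/compressive
#' volumes and ratios (denominator: total bone volume of the model), the
#' femoral-head vertex distal displacement, and the fracture-surface gap.
#'
#' Peaks are evaluated where the defect mechanics act, away from boundary
#' artifacts of the surrogate: bone strain indicators over the proximal
#' region (elements with centroid above `proximal_cutoff_z`, i.e. the
#' trochanteric/neck/head zone of the fracture model, matching
#' strain evaluation on the proximal fracture fragment), and the nail peak
#' over the nail-blade junction zone (`junction_halfwidth` about the
#' junction height, where the nail-blade load transfer concentrates).
#' Set `proximal_cutoff_z = -Inf` and `junction_halfwidth = Inf` for
#' whole-domain peaks.
#'
#' @param result A `solve_result` or `gait_result`.
#' @param assembly The `model_assembly` that was solved.
#' @param thresholds A [risk_thresholds()].
#' @param proximal_cutoff_z Lower z bound (mm) of the bone region used for
#'   strain peaks and risky volumes.
#' @param junction_halfwidth Half-height (mm) of the nail evaluation zone
#'   about the nail-blade junction.
#' @return Object of class `indicator_set` (named list of numerics; see
#'   fields in the description). `implant_within_yield` flags peaks below
#'   the 750 MPa titanium yield bound.
#' @export
extract_indicators <- function(result, assembly, thresholds = risk_thresholds(),
                               proximal_cutoff_z = -40,
                               junction_halfwidth = 30) {
  part <- assembly$mesh$element_part
  cen_z <- element_centroids(assembly$mesh)[, 3]
  bone <- part %in% c("head_neck_fragment", "shaft_fragment") &
    cen_z >= proximal_cutoff_z
  jz <- assembly$landmarks$blade_nail_junction_z %||% 0
  nail_region <- part == "nail" & abs(cen_z - jz) <= junction_halfwidth
  if (!any(nail_region)) nail_region <- part == "nail"
  check_that(any(part == "nail") && any(part == "blade"),
             "assembly lacks implant parts")
  vol <- assembly$mesh$element_volume
  if (inherits(result, "gait_result")) {
    vms <- result$envelope$vms
    eps1 <- result$envelope$eps1
    eps3 <- result$envelope$eps3
    head_disp <- result$envelope$head_displacement
    head_disp_mag <- max(result$envelope$disp_mag[assembly$head_vertex], head_disp)
    gap <- result$envelope$gap_max
    gap_mean <- result$envelope$gap_mean
  } else {
    check_that(inherits(result, "solve_result"), "result must be a solve_result or gait_result")
    vms <- von_mises(result$stress)
    pr <- principal_strains(result$strain)
    eps1 <- pr[, 1]
    eps3 <- pr[, 3]
    hd <- head_displacement(result, assembly$head_vertex)
    head_disp <- as.numeric(hd)
    head_disp_mag <- attr(hd, "magnitude")
    if (nrow(assembly$fracture_pairs) > 0) {
      fg <- fracture_gap(result, assembly)
      gap <- as.numeric(fg)
      gap_mean <- attr(fg, "mean")
    } else {
      gap <- 0; gap_mean <- 0
    }
  }
  rv <- risky_volumes(vol[bone], eps1[bone], eps3[bone], thresholds)
  structure(
    list(
      nail_peak_vms = max(vms[nail_region]),
      blade_peak_vms = max(vms[part == "blade"]),
      peak_max_principal_strain = max(eps1[bone]),
      peak_min_principal_strain = min(eps3[bone]),
      risky_tensile_volume = rv$tensile_volume,
      risky_tensile_ratio = rv$tensile_ratio,
      risky_compressive_volume = rv$compressive_volume,
      risky_compressive_ratio = rv$compressive_ratio,
      head_vertex_displacement = head_disp,
      head_vertex_displacement_mag = head_disp_mag,
      fracture_gap = gap,
      fracture_gap_mean = gap_mean,
      implant_within_yield = max(vms[part %in% c("nail", "blade")]) < 750
    ),
    class = "indicator_set"
  )
}

# The six default scoring indicators, as magnitudes. The gap enters the
# score as the area-mean opening: on a voxelized fracture surface the
# single-pair maximum is an order statistic whose inter-variant noise
# exceeds the defect signal among the near-stable models, while the mean
# opening integrates over the shared surface. The maximum remains the
# primary value reported by fracture_gap().
default_indicator_columns <- function() {
  c("nail_peak_vms", "blade_peak_vms", "peak_max_principal_strain",
    "peak_min_principal_strain", "head_vertex_displacement",
    "fracture_gap_mean")
}

indicator_magnitudes <- function(ind) {
  v <- vapply(default_indicator_columns(), function(k) abs(as.numeric(ind[[k]])),
              numeric(1))
  names(v) <- default_indicator_columns()
  v
}
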