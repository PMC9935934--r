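# Fracture/defect construction and the analysis-ready assembly: classify the
# background-grid elements into implant parts, proximal (head-neck) and
# distal (shaft) bone fragments, carve the wall defect of the requested
# variant, and separate the fragments by duplicating the nodes on the
# fracture interface so penalty contact can act across it.

# ---- fracture surface ------------------------------------------------------

# Oblique intertrochanteric fracture surface with a seeded irregular
# (band-limited sinusoidal) perturbation of its trace:
#   g(p) = (z - level) - tan(obliquity) * y - amplitude * w(azimuth)
# g > 0 on the proximal (head-neck) side.
fracture_field <- function(seed = 1L, amplitude = 3, level = 25,
                           obliquity_deg = 25) {
  coefs <- with_seed(seed, stats::rnorm(6))
  th <- seq(0, 2 * pi, length.out = 721L)
  wfun <- function(theta) {
    coefs[1] * sin(theta) + coefs[2] * cos(theta) +
      coefs[3] * sin(2 * theta) + coefs[4] * cos(2 * theta) +
      coefs[5] * sin(3 * theta) + coefs[6] * cos(3 * theta)
  }
  wmax <- max(abs(wfun(th)))
  norm <- if (wmax > 0) 1 / wmax else 0
  slope <- tan(deg2rad(obliquity_deg))
  g <- function(p) {
    p <- as_points(p)
    theta <- atan2(p[, 1], -p[, 2])   # azimuth from the medial direction
    (p[, 3] - level) - slope * p[, 2] - amplitude * norm * wfun(theta)
  }
  list(g = g, amplitude = amplitude, level = level, slope = slope,
       seed = as.integer(seed))
}

# unit normal of the fracture surface at points (gradient of g, normalised)
fracture_normal <- function(frac, p) {
  p <- as_points(p)
  eps <- 1e-4
  gx <- (frac$g(p + rep(c(eps, 0, 0), each = nrow(p))) -
         frac$g(p - rep(c(eps, 0, 0), each = nrow(p)))) / (2 * eps)
  gy <- (frac$g(p + rep(c(0, eps, 0), each = nrow(p))) -
         frac$g(p - rep(c(0, eps, 0), each = nrow(p)))) / (2 * eps)
  gz <- (frac$g(p + rep(c(0, 0, eps), each = nrow(p))) -
         frac$g(p - rep(c(0, 0, eps), each = nrow(p)))) / (2 * eps)
  n <- cbind(gx, gy, gz)
  n / row_norm(n)
}

# sanity check: the fracture trace must stay inside the trochanteric zone
check_fracture_in_zone <- function(frac, geom) {
  lm <- geom$landmarks
  R_med <- boundary_radius(geom$solid, z = 10, dir = c(0, -1, 0))
  z_med_min <- frac$level - frac$slope * R_med - frac$amplitude
  z_lat_max <- frac$level + frac$slope * geom$params$greater_trochanter_extent +
    frac$amplitude
  z_top <- max(lm$head_center[3] + geom$params$head_radius, lm$axis_top)
  if (z_med_min < -10 || z_lat_max > z_top) {
    stop_input(paste0("fracture surface leaves the trochanteric zone ",
                      "(medial trace z=%.1f, lateral trace z=%.1f); ",
                      "reduce the amplitude or obliquity"),
               z_med_min, z_lat_max)
  }
  invisible(TRUE)
}

# ---- defect predicate ------------------------------------------------------

# Logical mask over points: does this centroid belong to the removed wall
# region of `variant`? Operates on the intact bone solid via the scaled-point
# test: a point is in the outer `depth` fraction of the wall when pushing it
# radially out by 1/(1 - depth) leaves the bone.
defect_mask <- function(points, variant, rules, geom) {
  variant <- check_variant(variant)
  p <- as_points(points)
  n <- nrow(p)
  if (variant == "BASIC") return(rep(FALSE, n))
  f <- rules$defect_depth_fraction
  outer_wall <- if (f >= 1) rep(TRUE, n) else {
    k <- 1 / (1 - f)
    !geom$solid$inside(cbind(k * p[, 1], k * p[, 2], p[, 3]))
  }
  r <- sqrt(p[, 1]^2 + p[, 2]^2)
  r[r < 1e-9] <- 1e-9
  cos_med <- -p[, 2] / r                       # cos(angle to medial, -y)
  cos_lat <- p[, 2] / r                        # cos(angle to lateral, +y)
  anterior <- as.vector(p %*% rules$split_plane_normal) > 0
  mzh <- rules$medial_zone_halfwidth
  medial_band <- abs(p[, 3]) <= mzh &
    cos_med >= cos(deg2rad(rules$medial_sector_halfangle)) & outer_wall
  lb <- rules$lateral_band
  lateral_band <- p[, 3] >= lb[1] & p[, 3] <= lb[2] &
    cos_lat >= cos(deg2rad(rules$lateral_sector_halfangle)) & outer_wall
  pl_upper <- p[, 3] > lb[2] & p[, 3] <= lb[2] + rules$pl_upper_height &
    cos_lat >= cos(deg2rad(rules$lateral_sector_halfangle)) & outer_wall & !anterior
  switch(variant,
    M = medial_band,
    AM = medial_band & anterior,
    PM = medial_band & !anterior,
    L = lateral_band,
    AL = lateral_band & anterior,
    PL = (lateral_band & !anterior) | pl_upper,
    PML = (!anterior) & outer_wall &
      p[, 3] >= min(-mzh, lb[1]) &
      p[, 3] <= max(mzh, lb[2] + rules$pl_upper_height)
  )
}

# ---- assembly --------------------------------------------------------------

#' Build a complete fracture-fixation finite-element assembly
#'
#' One-step construction of a fracture-fixation model: generates the femur
#' surrogate and places the implant, applies the irregular intertrochanteric
#' fracture surface, carves the wall defect of the requested variant, and
#' tetrahedralizes everything on one conforming background grid. Bone and
#' implant share grid nodes at their interface (a tied osseointegrated
#' contact); the two bone fragments are separated by duplicating the nodes
#' on the fracture interface, with the pairing recorded for penalty contact
#' and gap measurement.
#'
#' @param femur A [femur_params()].
#' @param implant An [implant_spec()].
#' @param rules A [defect_rules()].
#' @param variant One of [fracture_variants()].
#' @param seed Integer seed for the irregular fracture line.
#' @param fracture_amplitude Perturbation amplitude of the fracture trace, mm.
#' @param target_edge Background grid spacing, mm.
#' @param order Element order: 1 (TET4) or 2 (TET10).
#' @return Object of class `model_assembly`: the `volume_mesh` (`$mesh`,
#'   parts `head_neck_fragment`, `shaft_fragment`, `nail`, `blade`, `screw`),
#'   fracture pair table (`$fracture_pairs`: node ids, normals, tributary
#'   areas), `$head_vertex`, `$distal_fixed_nodes`, `$head_surface_nodes`,
#'   `$landmarks`, removed/total volume bookkeeping, and the generating
#'   parameters.
#' @export
build_assembly <- function(femur = femur_params(), implant = implant_spec(),
                           rules = defect_rules(), variant = "BASIC",
                           seed = 1L, fracture_amplitude = 3,
                           target_edge = 4, order = 1) {
  variant <- check_variant(variant)
  geom <- femur_geometry(femur)
  imp <- implant_geometry(geom, implant)
  frac <- fracture_field(seed = seed, amplitude = fracture_amplitude)
  check_fracture_in_zone(frac, geom)

  # grid over femur + implant extents
  bboxes <- c(list(geom$solid$bbox), lapply(imp$parts, `[[`, "bbox"))
  bbox <- rbind(do.call(pmin, lapply(bboxes, function(b) b[1, ])),
                do.call(pmax, lapply(bboxes, function(b) b[2, ])))
  g <- grid_tets(bbox, target_edge)
  cen <- g$centroids
  lab <- rep(NA_character_, nrow(cen))
  for (nm in names(imp$parts)) {
    idx <- which(is.na(lab))
    hit <- chunked_lgl(cen[idx, , drop = FALSE], imp$parts[[nm]]$inside)
    lab[idx[hit]] <- nm
  }
  idx <- which(is.na(lab))
  in_bone <- chunked_lgl(cen[idx, , drop = FALSE], geom$solid$inside)
  bone_idx <- idx[in_bone]
  basic_bone_volume <- length(bone_idx) * prod(g$h) / 6

  # wall defect carving (element removal, exactly conservative)
  defect <- defect_mask(cen[bone_idx, , drop = FALSE], variant, rules, geom)
  if (variant != "BASIC" && !any(defect)) {
    stop_input("defect region for variant %s is empty at this resolution", variant)
  }
  removed_volume <- sum(defect) * prod(g$h) / 6
  bone_idx <- bone_idx[!defect]

  # fragment split by the fracture field
  gval <- frac$g(cen[bone_idx, , drop = FALSE])
  lab[bone_idx[gval > 0]] <- "head_neck_fragment"
  lab[bone_idx[gval <= 0]] <- "shaft_fragment"

  keep <- which(!is.na(lab))
  # drop voxel-classification islands: keep only elements face-connected to
  # the main body (fracture bone-bone faces count as severed; the fragments
  # stay joined through the implant)
  keep <- keep[main_component(g$tets[keep, , drop = FALSE], lab[keep])]
  mesh <- build_volume_mesh(g, keep, lab[keep], order = 1, solid = geom$solid)

  # split the fragments: duplicate nodes shared between proximal and distal
  # bone faces on the fracture interface
  split <- split_fracture_interface(mesh, frac)
  mesh <- split$mesh
  if (nrow(split$pairs) > 0) {
    # flag the pairs on the fracture-surface portion no wall defect can
    # remove, so gap statistics compare the same surface across variants
    pp <- mesh$nodes[split$pairs$distal, , drop = FALSE]
    in_any_wall <- rep(FALSE, nrow(pp))
    for (v in c("M", "L", "PL", "PML")) {
      in_any_wall <- in_any_wall | defect_mask(pp, v, rules, geom)
    }
    split$pairs$common <- !in_any_wall
  }
  if (order == 2) {
    mesh <- tet4_to_tet10(mesh)
    attr(mesh, "solid") <- geom$solid
  }

  prox_nodes <- unique(as.vector(mesh$tets[mesh$element_part == "head_neck_fragment",
                                           1:4, drop = FALSE]))
  head_vertex <- prox_nodes[which.max(mesh$nodes[prox_nodes, 3])]
  zmin <- min(mesh$nodes[, 3])
  distal_fixed <- which(mesh$nodes[, 3] <= zmin + 1e-8)
  # surface nodes on the femoral head (candidates for the load patch)
  bnd <- boundary_faces(mesh)
  bnd_nodes <- unique(as.vector(bnd))
  C <- geom$landmarks$head_center
  dhead <- row_norm(mesh$nodes[bnd_nodes, , drop = FALSE] -
                    matrix(C, length(bnd_nodes), 3, byrow = TRUE))
  head_surface_nodes <- bnd_nodes[abs(dhead - femur$head_radius) <=
                                    1.2 * max(mesh$h) &
                                  mesh$nodes[bnd_nodes, 3] > C[3]]

  structure(
    list(
      variant = variant, mesh = mesh,
      fracture_pairs = split$pairs,
      head_vertex = head_vertex,
      distal_fixed_nodes = distal_fixed,
      head_surface_nodes = head_surface_nodes,
      landmarks = c(geom$landmarks, imp$placement),
      removed_volume = removed_volume,
      basic_bone_volume = basic_bone_volume,
      bone_volume = sum(mesh$element_volume[mesh$element_part %in%
        c("head_neck_fragment", "shaft_fragment")]),
      params = list(femur = femur, implant = implant, rules = rules,
                    seed = as.integer(seed),
                    fracture_amplitude = fracture_amplitude,
                    target_edge = target_edge, order = order),
      solid = geom$solid
    ),
    class = "model_assembly"
  )
}

# Elements face-connected to the largest structural component, treating
# bone-bone faces across the fracture as severed. Guards the stiffness
# operator against floating element islands and single-node hinges that the
# centroid classification can produce at thin boundary features.
main_component <- function(tets, labels) {
  m <- nrow(tets)
  faces <- rbind(tets[, c(1, 2, 3)], tets[, c(1, 2, 4)],
                 tets[, c(1, 3, 4)], tets[, c(2, 3, 4)])
  el <- rep(seq_len(m), 4L)
  key <- paste(pmin(faces[, 1], pmin(faces[, 2], faces[, 3])),
               faces[, 1] + faces[, 2] + faces[, 3],
               pmax(faces[, 1], pmax(faces[, 2], faces[, 3])))
  o <- order(key)
  key <- key[o]; el <- el[o]
  same <- which(key[-1] == key[-length(key)])
  a <- el[same]; b <- el[same + 1L]
  bone <- c("head_neck_fragment", "shaft_fragment")
  severed <- labels[a] %in% bone & labels[b] %in% bone & labels[a] != labels[b]
  gr <- igraph::graph_from_edgelist(cbind(a[!severed], b[!severed]),
                                    directed = FALSE)
  gr <- igraph::add_vertices(gr, max(0L, m - igraph::vcount(gr)))
  comp <- igraph::components(gr)
  comp$membership == which.max(comp$csize)
}

# duplicate fracture-interface nodes: proximal bone elements receive copies,
# pairing (distal original, proximal copy) with smooth fracture normals and
# tributary areas
split_fracture_interface <- function(mesh, frac) {
  prox <- mesh$element_part == "head_neck_fragment"
  dist <- mesh$element_part == "shaft_fragment"
  t4 <- mesh$tets
  face_of <- function(el) {
    tt <- t4[el, , drop = FALSE]
    rbind(tt[, c(1, 3, 2)], tt[, c(1, 2, 4)], tt[, c(2, 3, 4)], tt[, c(1, 4, 3)])
  }
  fkey <- function(f) paste(pmin(f[, 1], pmin(f[, 2], f[, 3])),
                            f[, 1] + f[, 2] + f[, 3],
                            pmax(f[, 1], pmax(f[, 2], f[, 3])))
  fp <- face_of(which(prox))
  fd <- face_of(which(dist))
  shared <- intersect(fkey(fp), fkey(fd))
  if (length(shared) == 0) {
    return(list(mesh = mesh,
                pairs = data.frame(distal = integer(0), proximal = integer(0))))
  }
  iface <- fd[match(shared, fkey(fd)), , drop = FALSE]  # distal-side faces
  iface_nodes <- sort(unique(as.vector(iface)))
  nn0 <- nrow(mesh$nodes)
  dup_id <- stats::setNames(nn0 + seq_along(iface_nodes), iface_nodes)
  # rewrite every occurrence in proximal elements
  tp <- t4[prox, , drop = FALSE]
  hit <- matrix(tp %in% iface_nodes, nrow = nrow(tp))
  tp[hit] <- dup_id[as.character(tp[hit])]
  t4[prox, ] <- tp
  mesh$tets <- t4
  mesh$nodes <- rbind(mesh$nodes, mesh$nodes[iface_nodes, , drop = FALSE])

  # tributary area: one third of each adjacent interface face
  fa <- triangle_areas(mesh$nodes, iface)
  area <- numeric(length(iface_nodes))
  names(area) <- iface_nodes
  for (c0 in 1:3) {
    t <- tapply(fa / 3, iface[, c0], sum)
    area[names(t)] <- area[names(t)] + t
  }
  nrm <- fracture_normal(frac, mesh$nodes[iface_nodes, , drop = FALSE])
  pairs <- data.frame(
    distal = iface_nodes,
    proximal = unname(dup_id),
    nx = nrm[, 1], ny = nrm[, 2], nz = nrm[, 3],
    area = unname(area),
    g0 = 0
  )
  list(mesh = mesh, pairs = pairs)
}

#' @export
print.model_assembly <- function(x, ...) {
  cat(sprintf("model_assembly '%s': %d nodes, %d elements (%s), %d fracture pairs\n",
              x$variant, nrow(x$mesh$nodes), nrow(x$mesh$tets),
              if (ncol(x$mesh$tets) == 10) "TET10" else "TET4",
              nrow(x$fracture_pairs)))
  cat(sprintf("  bone volume %.0f mm^3 (defect removed %.0f mm^3), TAD %.2f mm\n",
              x$bone_volume, x$removed_volume, compute_tad(x)))
  invisible(x)
}

# ---- spec-level surface operations ----------------------------------------

#' Apply the irregular intertrochanteric fracture to a femur surface
#'
#' Splits the femur into a head-neck and a shaft fragment along an oblique
#' intertrochanteric surface whose trace is a seeded band-limited sinusoidal
#' perturbation of a plane. The split is realised on a background tet grid
#' (element-exact volume bookkeeping); the two fragment boundary surfaces
#' and the interface facet pairing are returned.
#'
#' @param femur A surface from [build_femur()].
#' @param seed Integer seed for the perturbation.
#' @param amplitude Perturbation amplitude, mm (0 gives a planar cut).
#' @param target_edge Grid resolution used for the split, mm.
#' @return List with `proximal`/`distal` (`surface_mesh`), `interface`
#'   (data frame of paired facet centroids and normals), and
#'   `volumes` (named: proximal, distal, whole).
#' @export
apply_fracture <- function(femur, seed = 1L, amplitude = 3, target_edge = 4) {
  geom <- attr(femur, "geometry")
  check_that(!is.null(geom), "femur must come from build_femur()")
  frac <- fracture_field(seed = seed, amplitude = amplitude)
  check_fracture_in_zone(frac, geom)
  mesh <- tetrahedralize(geom$solid, target_edge = target_edge)
  gval <- frac$g(element_centroids(mesh))
  mesh$element_part <- ifelse(gval > 0, "head_neck_fragment", "shaft_fragment")
  split <- split_fracture_interface(mesh, frac)
  vols <- tapply(mesh$element_volume, mesh$element_part, sum)
  out <- list(
    proximal = extract_surface(split$mesh, "head_neck_fragment"),
    distal = extract_surface(split$mesh, "shaft_fragment"),
    interface = split$pairs,
    volumes = c(proximal = unname(vols["head_neck_fragment"]),
                distal = unname(vols["shaft_fragment"]),
                whole = sum(mesh$element_volume))
  )
  attr(out, "mesh") <- split$mesh
  attr(out, "geometry") <- geom
  attr(out, "fracture") <- frac
  out
}

#' Carve a wall defect out of a fractured femur
#'
#' Removes the cortical wall region of the requested variant from the
#' fragment meshes produced by [apply_fracture()], per the carving rules:
#' the medial wall band about the lesser trochanter (or the lateral band),
#' to the configured fraction of the cortex-to-shaft-axis distance, split
#' anterior/posterior by the plane through the shaft axis where applicable.
#'
#' @param fragments Result of [apply_fracture()].
#' @param rules A [defect_rules()].
#' @param variant One of [fracture_variants()].
#' @return List like `fragments` plus `removed_volume` (mm^3); `BASIC`
#'   returns the input with `removed_volume = 0`.
#' @export
carve_defect <- function(fragments, rules = defect_rules(), variant = "BASIC") {
  variant <- check_variant(variant)
  mesh <- attr(fragments, "mesh")
  geom <- attr(fragments, "geometry")
  check_that(!is.null(mesh) && !is.null(geom),
             "fragments must come from apply_fracture()")
  mask <- defect_mask(element_centroids(mesh), variant, rules, geom)
  if (variant != "BASIC" && !any(mask)) {
    stop_input("defect region for variant %s is empty at this resolution", variant)
  }
  removed <- sum(mesh$element_volume[mask])
  keep <- !mask
  mesh2 <- mesh
  mesh2$tets <- mesh$tets[keep, , drop = FALSE]
  mesh2$element_part <- mesh$element_part[keep]
  mesh2$element_volume <- mesh$element_volume[keep]
  out <- list(
    proximal = extract_surface(mesh2, "head_neck_fragment"),
    distal = extract_surface(mesh2, "shaft_fragment"),
    removed_volume = removed,
    volumes = c(
      proximal = sum(mesh2$element_volume[mesh2$element_part == "head_neck_fragment"]),
      distal = sum(mesh2$element_volume[mesh2$element_part == "shaft_fragment"])
    )
  )
  attr(out, "mesh") <- mesh2
  attr(out, "geometry") <- geom
  out
}

#' Place the implant in a femur
#'
#' Computes the implant placement for a femur surrogate — nail seated down
#' the medullary canal from the trochanteric entry, blade axis through the
#' head centre at the blade angle with its tip set back from the head apex
#' to realise the target tip-apex distance — and returns the placed implant
#' surfaces together with the placement landmarks. Placement depends only on
#' the femur parameters, so it is identical (vertex-wise) across all defect
#' variants built from the same femur. In meshed assemblies the bone
#' elements inside the implant envelope are reassigned to the implant parts,
#' which realises the implant channels.
#'
#' @param femur A [build_femur()] surface or [femur_params()].
#' @param spec An [implant_spec()].
#' @return List of placed implant `surface_mesh` objects with attributes
#'   `placement` (landmarks incl. blade tip and head apex) and `tad` (mm).
#' @export
position_implant <- function(femur, spec = implant_spec()) {
  surfs <- build_implant(spec, femur)
  pl <- attr(surfs, "placement")
  attr(surfs, "tad") <- tad_from_points(pl$blade_tip, pl$head_apex_blade)
  surfs
}

# sum of tip-apex distances on the frontal (x-z) and lateral (y-z)
# projections at unit magnification
tad_from_points <- function(tip, apex) {
  d <- apex - tip
  sqrt(d[1]^2 + d[3]^2) + sqrt(d[2]^2 + d[3]^2)
}

#' Tip-apex distance of an assembly
#'
#' Standard radiographic TAD: the blade-tip-to-head-apex distance summed
#' over the frontal and lateral projections at unit magnification, computed
#' from the assembly's geometric landmarks (the head apex taken on the blade
#' axis).
#'
#' @param assembly A `model_assembly`, or the result of [position_implant()].
#' @return TAD in mm.
#' @export
compute_tad <- function(assembly) {
  lm <- if (inherits(assembly, "model_assembly")) assembly$landmarks
        else attr(assembly, "placement")
  check_that(!is.null(lm$blade_tip) && !is.null(lm$head_apex_blade),
             "assembly carries no blade/head landmarks")
  tad_from_points(lm$blade_tip, lm$head_apex_blade)
}
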