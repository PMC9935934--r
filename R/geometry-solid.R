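# Implicit-solid representation of the femur surrogate and implant parts.
#
# The femur is a variable-radius tube swept along a bent medial-axis
# polyline (shaft -> trochanteric arc -> neck) united with the head sphere,
# cut flat at the distal end. Implant parts are capped cylinders. Every
# solid exposes a vectorised membership test `inside(points)` and an
# approximate inside-positive boundary distance `sdf(points)`; tet meshing
# and all carving rules operate on these.

# ---- generic solid helpers -------------------------------------------------

new_solid <- function(inside, sdf, bbox, label = "solid") {
  structure(list(inside = inside, sdf = sdf, bbox = bbox, label = label),
            class = "trochfem_solid")
}

# capped cylinder from a to b with radius r; inside-positive sdf
cylinder_solid <- function(a, b, r, label = "cylinder") {
  a <- as.numeric(a); b <- as.numeric(b)
  ax <- b - a
  L <- sqrt(sum(ax * ax))
  u <- ax / L
  sdf <- function(p) {
    d <- cbind(p[, 1] - a[1], p[, 2] - a[2], p[, 3] - a[3])
    s <- d %*% u
    rad <- sqrt(pmax(rowSums(d * d) - s^2, 0))
    pmin(r - rad, pmin(s, L - s))
  }
  pad <- r
  bbox <- rbind(pmin(a, b) - pad, pmax(a, b) + pad)
  new_solid(function(p) sdf(p) >= 0, sdf, bbox, label)
}

sphere_solid <- function(c0, r, label = "sphere") {
  sdf <- function(p) {
    r - sqrt((p[, 1] - c0[1])^2 + (p[, 2] - c0[2])^2 + (p[, 3] - c0[3])^2)
  }
  bbox <- rbind(c0 - r, c0 + r)
  new_solid(function(p) sdf(p) >= 0, sdf, bbox, label)
}

# distance from points to a polyline, returning also the arclength of the
# closest point; vectorised over points, loops over segments
polyline_closest <- function(p, path, s_cum) {
  n <- nrow(p)
  best_d2 <- rep(Inf, n)
  best_s <- rep(0, n)
  for (i in seq_len(nrow(path) - 1L)) {
    a <- path[i, ]; b <- path[i + 1L, ]
    ab <- b - a
    len2 <- sum(ab * ab)
    dx <- p[, 1] - a[1]; dy <- p[, 2] - a[2]; dz <- p[, 3] - a[3]
    t <- pmin(pmax((dx * ab[1] + dy * ab[2] + dz * ab[3]) / len2, 0), 1)
    qx <- dx - t * ab[1]; qy <- dy - t * ab[2]; qz <- dz - t * ab[3]
    d2 <- qx * qx + qy * qy + qz * qz
    hit <- d2 < best_d2
    if (any(hit)) {
      best_d2[hit] <- d2[hit]
      best_s[hit] <- s_cum[i] + t[hit] * sqrt(len2)
    }
  }
  list(dist = sqrt(best_d2), s = best_s)
}

# ---- femur geometry --------------------------------------------------------

# Full derived geometry of the femur surrogate: medial-axis path, radius
# profile, landmarks, and the implicit solid. Internal workhorse behind
# build_femur() and build_assembly().
femur_geometry <- function(params = femur_params()) {
  check_that(inherits(params, "femur_params"), "params must be femur_params()")
  p <- params
  neck_base_height <- 5                       # neck-axis origin above LT level
  blend_radius <- min(30, p$neck_length * 0.55)
  theta <- deg2rad(180 - p$neck_shaft_angle)  # neck axis angle from +z
  av <- deg2rad(p$anteversion)
  u_neck <- c(sin(av) * sin(theta), -cos(av) * sin(theta), cos(theta))
  B <- c(0, 0, neck_base_height)              # neck base on shaft axis
  C <- B + p$neck_length * u_neck             # head centre
  apex <- C + p$head_radius * u_neck          # head apex along neck axis

  # medial-axis path: straight shaft (extended 20 mm past the distal cut so
  # the tube stays cylindrical through it), circular blend at B, neck to C
  d1 <- c(0, 0, 1)
  half <- theta / 2
  Tlen <- blend_radius * tan(half)
  Q1 <- B - Tlen * d1
  Q2 <- B + Tlen * u_neck
  n1 <- unit(u_neck - sum(u_neck * d1) * d1)
  O <- Q1 + blend_radius * n1                 # arc centre
  arc_t <- seq(0, 1, length.out = 13L)
  v1 <- Q1 - O
  v2 <- Q2 - O
  ang <- acos(sum(v1 * v2) / (blend_radius^2))
  w_perp <- unit(v2 - sum(v2 * unit(v1)) * unit(v1))
  arc_pts <- t(vapply(arc_t, function(t) {
    O + blend_radius * (cos(t * ang) * unit(v1) + sin(t * ang) * w_perp)
  }, numeric(3)))

  z_start <- -p$shaft_length - 20
  shaft_z <- seq(z_start, Q1[3], by = 8)
  if (utils::tail(shaft_z, 1) < Q1[3] - 1e-9) shaft_z <- c(shaft_z, Q1[3])
  shaft_pts <- cbind(0, 0, shaft_z)
  neck_t <- seq(0, 1, length.out = 9L)[-1]
  neck_pts <- t(vapply(neck_t, function(t) Q2 + t * (C - Q2), numeric(3)))
  path <- rbind(shaft_pts[-nrow(shaft_pts), , drop = FALSE], arc_pts[-13, , drop = FALSE],
                Q2, neck_pts)
  s_cum <- c(0, cumsum(row_norm(diff(path))))
  s_B <- s_cum[nrow(shaft_pts) - 1L + 7L]     # arc midpoint ~ corner apex
  s_C <- utils::tail(s_cum, 1)
  s_bottom <- -z_start - p$shaft_length        # arclength at the distal cut (=20)

  # radius profile along arclength: shaft radius -> trochanteric swell at the
  # corner -> neck radius
  smoothstep <- function(t) (1 - cos(pi * pmin(pmax(t, 0), 1))) / 2
  s_meta <- s_B - 35
  s_neck <- s_B + 0.55 * (s_C - s_B)
  radius_at <- function(s) {
    r <- rep(p$shaft_radius_outer, length(s))
    rise <- s > s_meta & s <= s_B
    r[rise] <- p$shaft_radius_outer +
      (p$greater_trochanter_extent - p$shaft_radius_outer) *
      smoothstep((s[rise] - s_meta) / (s_B - s_meta))
    fall <- s > s_B & s < s_neck
    r[fall] <- p$greater_trochanter_extent +
      (p$neck_radius - p$greater_trochanter_extent) *
      smoothstep((s[fall] - s_B) / (s_neck - s_B))
    r[s >= s_neck] <- p$neck_radius
    r
  }

  tube_sdf <- function(pts) {
    cl <- polyline_closest(pts, path, s_cum)
    pmin(radius_at(cl$s) - cl$dist, pts[, 3] + p$shaft_length)
  }
  head_sdf_fn <- function(pts) {
    pmin(p$head_radius -
           sqrt((pts[, 1] - C[1])^2 + (pts[, 2] - C[2])^2 + (pts[, 3] - C[3])^2),
         pts[, 3] + p$shaft_length)
  }
  sdf <- function(pts) {
    pts <- as_points(pts)
    pmax(tube_sdf(pts), head_sdf_fn(pts))
  }
  inside <- function(pts) sdf(pts) >= 0

  pad <- 0.5
  bbox <- rbind(
    c(-p$greater_trochanter_extent, min(-p$greater_trochanter_extent, C[2] - p$head_radius),
      -p$shaft_length),
    c(max(p$greater_trochanter_extent, C[1] + p$head_radius, apex[1] + 1),
      p$greater_trochanter_extent,
      max(C[3] + p$head_radius, s_B))
  )
  bbox[1, ] <- bbox[1, ] - pad
  bbox[2, ] <- bbox[2, ] + pad
  solid <- new_solid(inside, sdf, bbox, "femur")

  # landmarks
  lt_dir <- unit(c(-1, -1, 0))                 # posteromedial
  R_lt <- boundary_radius(solid, z = 0, dir = lt_dir)
  axis_top <- axial_extent(solid)              # highest in-bone point on shaft axis
  landmarks <- list(
    neck_base = B, neck_dir = u_neck, head_center = C, head_apex = apex,
    lesser_trochanter = c(R_lt * lt_dir[1], R_lt * lt_dir[2], 0),
    axis_top = axis_top, s_C = s_C, s_B = s_B,
    distal_z = -p$shaft_length
  )
  list(params = p, solid = solid, path = path, s_cum = s_cum,
       radius_at = radius_at, landmarks = landmarks,
       loft = list(s_bottom = s_bottom, s_C = s_C))
}

as_points <- function(p) {
  if (is.null(dim(p))) matrix(p, ncol = 3) else as.matrix(p)
}

# boundary radius of a solid from the shaft axis at height z along direction
# dir (unit, in the xy-plane), by bisection on the membership test
boundary_radius <- function(solid, z, dir, r_max = 80) {
  lo <- 0; hi <- r_max
  for (k in 1:60) {
    mid <- (lo + hi) / 2
    if (solid$inside(matrix(c(mid * dir[1], mid * dir[2], z), 1))) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

# highest z on the shaft axis still inside the solid
axial_extent <- function(solid, z_max = 120) {
  lo <- 0; hi <- z_max
  for (k in 1:60) {
    mid <- (lo + hi) / 2
    if (solid$inside(matrix(c(0, 0, mid), 1))) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

# ---- implant geometry ------------------------------------------------------

# Placement of the implant in a femur geometry: nail down the shaft axis from
# just below the entry point, blade along an axis through the head centre at
# the blade angle, tip short of the head apex by the distance that realises
# the target TAD, locking screw through the distal nail.
implant_geometry <- function(geom, spec = implant_spec()) {
  check_that(inherits(spec, "implant_spec"), "spec must be implant_spec()")
  p <- geom$params
  lm <- geom$landmarks
  canal_radius <- p$shaft_radius_outer - p$cortical_thickness
  if (spec$nail_radius >= canal_radius) {
    stop_input("implant does not fit: nail_radius (%.2f) >= canal radius (%.2f)",
               spec$nail_radius, canal_radius)
  }
  nail_top <- lm$axis_top - 2
  nail_bottom <- nail_top - spec$nail_length
  if (nail_bottom < lm$distal_z + 4) {
    stop_input("nail_length %.0f mm exceeds the shaft: nail tip at z=%.1f, distal cut at z=%.1f",
               spec$nail_length, nail_bottom, lm$distal_z)
  }

  theta_b <- deg2rad(180 - spec$blade_angle)
  av <- deg2rad(p$anteversion)
  u_blade <- c(sin(av) * sin(theta_b), -cos(av) * sin(theta_b), cos(theta_b))
  C <- lm$head_center
  # blade axis passes through the head centre; distance of that line to the
  # nail (z) axis decides whether the blade can cross the nail
  w <- C - c(0, 0, 0)
  cross_zu <- c(-u_blade[2], u_blade[1], 0)    # z x u_blade
  line_dist <- abs(sum(w * cross_zu)) / sqrt(sum(cross_zu^2))
  if (line_dist >= spec$nail_radius) {
    stop_input("blade axis misses the nail (axis distance %.2f mm >= nail radius %.2f mm)",
               line_dist, spec$nail_radius)
  }
  apex_b <- C + p$head_radius * u_blade        # head apex along the blade axis
  # tip set back from the apex along the blade axis by t such that the
  # two-projection TAD equals the target
  proj <- sqrt(u_blade[1]^2 + u_blade[3]^2) + sqrt(u_blade[2]^2 + u_blade[3]^2)
  t_back <- spec$target_tad / proj
  blade_tip <- apex_b - t_back * u_blade
  # blade rear end: just beyond the lateral cortex exit on the blade axis
  lo <- 0; hi <- 120
  for (k in 1:60) {
    mid <- (lo + hi) / 2
    if (geom$solid$inside(matrix(C - mid * u_blade, 1))) lo <- mid else hi <- mid
  }
  blade_rear <- C - ((lo + hi) / 2 + 1) * u_blade

  parts <- list(
    nail = cylinder_solid(c(0, 0, nail_bottom), c(0, 0, nail_top),
                          spec$nail_radius, "nail"),
    blade = cylinder_solid(blade_rear, blade_tip, spec$blade_radius, "blade")
  )
  screw_z <- nail_bottom + 15
  if (isTRUE(spec$include_screw)) {
    parts$screw <- cylinder_solid(c(0, -(p$shaft_radius_outer + 1), screw_z),
                                  c(0, p$shaft_radius_outer + 1, screw_z),
                                  spec$locking_screw_radius, "screw")
  }
  # height at which the blade axis crosses the nail axis
  tt <- -(C[1] * u_blade[1] + C[2] * u_blade[2]) / (u_blade[1]^2 + u_blade[2]^2)
  junction_z <- C[3] + tt * u_blade[3]
  list(spec = spec, parts = parts,
       placement = list(
         nail_axis = c(0, 0, 1), nail_top = nail_top, nail_bottom = nail_bottom,
         blade_dir = u_blade, blade_tip = blade_tip, blade_rear = blade_rear,
         head_apex_blade = apex_b, tad = spec$target_tad, screw_z = screw_z,
         blade_nail_junction_z = junction_z
       ))
}
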