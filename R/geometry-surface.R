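# Triangulated surface meshes: the femur loft, implant cylinders, and the
# generic closed-surface utilities (watertightness, Euler characteristic,
# enclosed volume, point-in-surface ray casting).

#' Construct a triangulated surface mesh
#'
#' @param vertices n x 3 numeric matrix, mm.
#' @param triangles m x 3 integer matrix of vertex indices (1-based),
#'   consistently outward-oriented.
#' @param part_label One of `"head_neck_fragment"`, `"shaft_fragment"`,
#'   `"nail"`, `"blade"`, `"screw"`, or a free label such as `"femur"`.
#' @return Object of class `surface_mesh`.
#' @export
surface_mesh <- function(vertices, triangles, part_label = "femur") {
  vertices <- as.matrix(vertices)
  triangles <- matrix(as.integer(as.matrix(triangles)), ncol = 3)
  check_that(ncol(vertices) == 3, "vertices must be n x 3")
  check_that(all(is.finite(vertices)), "vertex coordinates must be finite")
  check_that(min(triangles) >= 1 && max(triangles) <= nrow(vertices),
             "triangle indices out of range")
  a <- triangle_areas(vertices, triangles)
  check_that(all(a > 0), "surface has %d degenerate (zero-area) triangle(s)",
             sum(a <= 0))
  structure(list(vertices = vertices, triangles = triangles,
                 part_label = part_label),
            class = "surface_mesh")
}

triangle_areas <- function(v, tri) {
  e1 <- v[tri[, 2], , drop = FALSE] - v[tri[, 1], , drop = FALSE]
  e2 <- v[tri[, 3], , drop = FALSE] - v[tri[, 1], , drop = FALSE]
  cx <- e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2]
  cy <- e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3]
  cz <- e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1]
  0.5 * sqrt(cx^2 + cy^2 + cz^2)
}

#' Closed-surface checks and measures
#'
#' `surface_is_watertight()` verifies that every undirected edge is shared by
#' exactly two triangles and that orientation is consistent (each directed
#' edge used once). `euler_characteristic()` returns V - E + F (2 for a
#' closed genus-0 surface). `surface_volume()` integrates the enclosed volume
#' by the divergence theorem (positive for outward orientation).
#'
#' @param surf A `surface_mesh`.
#' @return Logical / integer / numeric (mm^3) respectively.
#' @export
surface_is_watertight <- function(surf) {
  tri <- surf$triangles
  dir_edges <- rbind(tri[, 1:2], tri[, 2:3], tri[, c(3, 1)])
  und <- cbind(pmin(dir_edges[, 1], dir_edges[, 2]),
               pmax(dir_edges[, 1], dir_edges[, 2]))
  und_key <- paste(und[, 1], und[, 2])
  dir_key <- paste(dir_edges[, 1], dir_edges[, 2])
  all(table(und_key) == 2L) && !anyDuplicated(dir_key)
}

#' @rdname surface_is_watertight
#' @export
surface_is_closed <- function(surf) {
  # every undirected edge bounds an even number of triangles: the surface
  # encloses a volume even where voxel fragments pinch (non-manifold edges)
  tri <- surf$triangles
  dir_edges <- rbind(tri[, 1:2], tri[, 2:3], tri[, c(3, 1)])
  und_key <- paste(pmin(dir_edges[, 1], dir_edges[, 2]),
                   pmax(dir_edges[, 1], dir_edges[, 2]))
  all(table(und_key) %% 2L == 0L)
}

#' @rdname surface_is_watertight
#' @export
euler_characteristic <- function(surf) {
  tri <- surf$triangles
  v <- length(unique(as.vector(tri)))
  dir_edges <- rbind(tri[, 1:2], tri[, 2:3], tri[, c(3, 1)])
  und <- unique(cbind(pmin(dir_edges[, 1], dir_edges[, 2]),
                      pmax(dir_edges[, 1], dir_edges[, 2])))
  v - nrow(und) + nrow(tri)
}

#' @rdname surface_is_watertight
#' @export
surface_volume <- function(surf) {
  v <- surf$vertices
  tri <- surf$triangles
  a <- v[tri[, 1], , drop = FALSE]
  b <- v[tri[, 2], , drop = FALSE]
  d <- v[tri[, 3], , drop = FALSE]
  sum(a[, 1] * (b[, 2] * d[, 3] - b[, 3] * d[, 2]) -
      a[, 2] * (b[, 1] * d[, 3] - b[, 3] * d[, 1]) +
      a[, 3] * (b[, 1] * d[, 2] - b[, 2] * d[, 1])) / 6
}

#' Point-in-surface test by ray casting
#'
#' Robust membership test for arbitrary watertight triangle surfaces, used
#' when tetrahedralizing user-supplied meshes (e.g. imported STL). Casts a
#' fixed irrationally-oriented ray from each point and counts triangle
#' crossings (Moller-Trumbore, vectorised over points).
#'
#' @param points n x 3 matrix of query points.
#' @param surf A watertight `surface_mesh`.
#' @return Logical vector: point inside the surface.
#' @export
point_in_surface <- function(points, surf) {
  p <- as_points(points)
  v <- surf$vertices
  tri <- surf$triangles
  dir <- unit(c(0.5377513, 0.3060321, 0.7854077))  # fixed generic direction
  count <- integer(nrow(p))
  for (k in seq_len(nrow(tri))) {
    v0 <- v[tri[k, 1], ]
    e1 <- v[tri[k, 2], ] - v0
    e2 <- v[tri[k, 3], ] - v0
    h <- c(dir[2] * e2[3] - dir[3] * e2[2],
           dir[3] * e2[1] - dir[1] * e2[3],
           dir[1] * e2[2] - dir[2] * e2[1])
    a <- sum(e1 * h)
    if (abs(a) < 1e-12) next
    f <- 1 / a
    sx <- p[, 1] - v0[1]; sy <- p[, 2] - v0[2]; sz <- p[, 3] - v0[3]
    u <- f * (sx * h[1] + sy * h[2] + sz * h[3])
    qx <- sy * e1[3] - sz * e1[2]
    qy <- sz * e1[1] - sx * e1[3]
    qz <- sx * e1[2] - sy * e1[1]
    vv <- f * (dir[1] * qx + dir[2] * qy + dir[3] * qz)
    t <- f * (e2[1] * qx + e2[2] * qy + e2[3] * qz)
    hit <- u >= 0 & u <= 1 & vv >= 0 & (u + vv) <= 1 & t > 0
    count <- count + hit
  }
  (count %% 2L) == 1L
}

# ---- femur loft ------------------------------------------------------------

#' Build the synthetic proximal femur surface
#'
#' Generates a watertight, consistently oriented triangulated surface of the
#' femur surrogate: a loft of circular rings swept along the bent medial
#' axis (flat distal cap, shaft, trochanteric swell, neck) that hands over
#' to exact sphere rings across the femoral head, closed by an apex pole.
#' Ring vertices across the head lie exactly on the head sphere and one ring
#' sits exactly on the equator, so the head diameter is represented exactly.
#' The implicit solid and the landmark set are attached as attributes
#' (`"solid"`, `"geometry"`) and reused by downstream operations.
#'
#' @param params A [femur_params()].
#' @param n_ring Vertices per ring (even; default 32).
#' @param station_spacing Approximate ring spacing along the axis, mm.
#' @return A `surface_mesh` with attributes `solid`, `geometry`, and
#'   `vertex_region` (`"shaft"`, `"neck"`, or `"head"` per vertex).
#' @export
build_femur <- function(params = femur_params(), n_ring = 32,
                        station_spacing = 6) {
  geom <- femur_geometry(params)
  p <- params
  path <- geom$path
  s_cum <- geom$s_cum
  s_bot <- geom$loft$s_bottom
  s_C <- geom$loft$s_C
  R <- p$head_radius

  # arclength where the sphere profile overtakes the neck tube
  a_hand <- -sqrt(max(R^2 - p$neck_radius^2, 0))
  stations_tube <- seq(s_bot, s_C + a_hand, by = station_spacing)
  if (utils::tail(stations_tube, 1) < s_C + a_hand - 1e-9) {
    stations_tube <- c(stations_tube, s_C + a_hand)
  }
  # sphere stations by polar angle, including the equator (a = 0) exactly;
  # drop the first (coincides with the hand-over station) and the pole
  phi <- seq(asin(a_hand / R), pi / 2, length.out = 14L)
  phi <- sort(unique(c(phi, 0)))
  phi <- phi[-c(1L, length(phi))]
  stations_head <- s_C + R * sin(phi)
  stations <- c(stations_tube, stations_head)
  region <- c(ifelse(stations_tube < geom$landmarks$s_B - 10, "shaft", "neck"),
              rep("head", length(stations_head)))

  point_at <- function(s) {
    i <- findInterval(s, s_cum, rightmost.closed = TRUE)
    i <- min(max(i, 1L), nrow(path) - 1L)
    t <- (s - s_cum[i]) / (s_cum[i + 1] - s_cum[i])
    list(pt = path[i, ] + t * (path[i + 1, ] - path[i, ]),
         tan = unit(path[i + 1, ] - path[i, ]))
  }
  # extend beyond the path end along the neck direction for head stations
  u_end <- unit(path[nrow(path), ] - path[nrow(path) - 1, ])
  C <- geom$landmarks$head_center

  ring_radius <- function(s) {
    r_tube <- geom$radius_at(s)
    a <- s - s_C
    r_head <- if (abs(a) <= R) sqrt(R^2 - a^2) else -Inf
    max(r_tube * (s <= s_C + 1e-9), r_head)
  }

  phis <- 2 * pi * (seq_len(n_ring) - 1) / n_ring
  verts <- matrix(0, 0, 3)
  vreg <- character(0)
  for (i in seq_along(stations)) {
    s <- stations[i]
    if (s <= utils::tail(s_cum, 1)) {
      pa <- point_at(s)
      ctr <- pa$pt; tg <- pa$tan
    } else {
      ctr <- C + (s - s_C) * u_end; tg <- u_end
    }
    if (region[i] == "head") { ctr <- C + (s - s_C) * u_end; tg <- u_end }
    r <- ring_radius(s)
    e1 <- unit(vec_cross(tg, c(1, 0, 0)))
    e2 <- unit(vec_cross(tg, e1))
    ring <- t(vapply(phis, function(ph) ctr + r * (cos(ph) * e1 + sin(ph) * e2),
                     numeric(3)))
    verts <- rbind(verts, ring)
    vreg <- c(vreg, rep(region[i], n_ring))
  }
  bot_pole <- c(0, 0, -p$shaft_length)
  top_pole <- C + R * u_end
  verts <- rbind(verts, bot_pole, top_pole)
  vreg <- c(vreg, "shaft", "head")
  i_bot <- nrow(verts) - 1L
  i_top <- nrow(verts)

  n_st <- length(stations)
  tris <- matrix(0L, 0, 3)
  ring_idx <- function(i) ((i - 1L) * n_ring + 1L):(i * n_ring)
  # bottom cap fan (faces outward = -z)
  r1 <- ring_idx(1)
  nxt <- c(r1[-1], r1[1])
  tris <- rbind(tris, cbind(i_bot, nxt, r1))
  # side quads
  for (i in seq_len(n_st - 1L)) {
    ra <- ring_idx(i); rb <- ring_idx(i + 1L)
    ra2 <- c(ra[-1], ra[1]); rb2 <- c(rb[-1], rb[1])
    tris <- rbind(tris, cbind(ra, ra2, rb), cbind(ra2, rb2, rb))
  }
  # top cap fan
  rt <- ring_idx(n_st)
  rt2 <- c(rt[-1], rt[1])
  tris <- rbind(tris, cbind(i_top, rt, rt2))

  surf <- surface_mesh(verts, tris, part_label = "femur")
  if (surface_volume(surf) < 0) surf$triangles <- surf$triangles[, c(1, 3, 2)]
  attr(surf, "solid") <- geom$solid
  attr(surf, "geometry") <- geom
  attr(surf, "vertex_region") <- vreg
  surf
}

vec_cross <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2], a[3] * b[1] - a[1] * b[3], a[1] * b[2] - a[2] * b[1])
}

# closed cylinder surface between a and b
cylinder_surface <- function(a, b, r, n_ring = 24, part_label = "cylinder") {
  ax <- unit(b - a)
  e1 <- vec_cross(ax, if (abs(ax[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0))
  e1 <- unit(e1)
  e2 <- unit(vec_cross(ax, e1))
  phis <- 2 * pi * (seq_len(n_ring) - 1) / n_ring
  ring_a <- t(vapply(phis, function(ph) a + r * (cos(ph) * e1 + sin(ph) * e2), numeric(3)))
  ring_b <- t(vapply(phis, function(ph) b + r * (cos(ph) * e1 + sin(ph) * e2), numeric(3)))
  verts <- rbind(ring_a, ring_b, a, b)
  ia <- seq_len(n_ring); ib <- n_ring + ia
  pa <- 2L * n_ring + 1L; pb <- 2L * n_ring + 2L
  ia2 <- c(ia[-1], ia[1]); ib2 <- c(ib[-1], ib[1])
  tris <- rbind(cbind(pa, ia2, ia),
                cbind(ia, ia2, ib), cbind(ia2, ib2, ib),
                cbind(pb, ib, ib2))
  surf <- surface_mesh(verts, tris, part_label = part_label)
  if (surface_volume(surf) < 0) surf$triangles <- surf$triangles[, c(1, 3, 2)]
  attr(surf, "axis") <- ax
  surf
}

#' Build the implant surfaces
#'
#' Generates closed surfaces for the intramedullary nail, the helical blade
#' (equivalent-radius cylinder surrogate), and optionally the distal locking
#' screw, placed in the given femur. The blade axis passes through the head
#' centre at `spec$blade_angle` to the nail axis, with the tip set back from
#' the head apex so that the tip-apex distance equals `spec$target_tad`.
#'
#' @param spec An [implant_spec()].
#' @param femur A surface from [build_femur()] (its geometry attribute drives
#'   placement) or a [femur_params()] object.
#' @param n_ring Vertices per cylinder ring.
#' @return Named list of `surface_mesh` (`nail`, `blade`, and `screw` unless
#'   omitted), with the placement record attached as attribute `"placement"`.
#' @export
build_implant <- function(spec = implant_spec(), femur = femur_params(),
                          n_ring = 24) {
  geom <- if (inherits(femur, "femur_params")) femur_geometry(femur)
          else attr(femur, "geometry")
  check_that(!is.null(geom), "femur must be femur_params() or a build_femur() surface")
  imp <- implant_geometry(geom, spec)
  pl <- imp$placement
  out <- list(
    nail = cylinder_surface(c(0, 0, pl$nail_bottom), c(0, 0, pl$nail_top),
                            spec$nail_radius, n_ring, "nail"),
    blade = cylinder_surface(pl$blade_rear, pl$blade_tip, spec$blade_radius,
                             n_ring, "blade")
  )
  if (isTRUE(spec$include_screw)) {
    pr <- geom$params$shaft_radius_outer + 1
    out$screw <- cylinder_surface(c(0, -pr, pl$screw_z), c(0, pr, pl$screw_z),
                                  spec$locking_screw_radius, n_ring, "screw")
  }
  attr(out, "placement") <- pl
  attr(out, "implant_geometry") <- imp
  out
}
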