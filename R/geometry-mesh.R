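# Tetrahedral meshing on a structured background grid: each grid cell is
# split into six tetrahedra (Kuhn triangulation, face-compatible across
# cells), and elements are kept when their centroid lies inside the solid.
# Element-based classification makes all downstream volume bookkeeping
# (fragments, defects, implant channels) exactly conservative.

# permutations of (1,2,3) and their signs, for the Kuhn split
.kuhn_perms <- list(c(1, 2, 3), c(1, 3, 2), c(2, 1, 3),
                    c(2, 3, 1), c(3, 1, 2), c(3, 2, 1))
.kuhn_signs <- c(1, -1, -1, 1, 1, -1)

# Build the candidate grid tets over a bounding box. Returns node grid info
# and a function materialising tets lazily is overkill here; we materialise.
grid_tets <- function(bbox, target_edge) {
  lo <- bbox[1, ]; hi <- bbox[2, ]
  ext <- hi - lo
  nc <- pmax(1L, ceiling(ext / target_edge))
  h <- ext / nc
  nn <- nc + 1L
  node_id <- function(i, j, k) 1L + i + nn[1] * (j + nn[2] * k)
  # cube origins
  cube <- expand.grid(i = 0:(nc[1] - 1L), j = 0:(nc[2] - 1L), k = 0:(nc[3] - 1L))
  tets <- vector("list", 6L)
  cents <- vector("list", 6L)
  for (m in seq_len(6L)) {
    perm <- .kuhn_perms[[m]]
    offs <- matrix(0L, 4, 3)
    for (r in 2:4) {
      offs[r, ] <- offs[r - 1, ]
      offs[r, perm[r - 1]] <- 1L
    }
    if (.kuhn_signs[m] < 0) offs <- offs[c(1, 2, 4, 3), ]  # fix orientation
    ids <- sapply(1:4, function(r) {
      node_id(cube$i + offs[r, 1], cube$j + offs[r, 2], cube$k + offs[r, 3])
    })
    tets[[m]] <- ids
    cent_off <- colMeans(offs)
    cents[[m]] <- cbind(lo[1] + (cube$i + cent_off[1]) * h[1],
                        lo[2] + (cube$j + cent_off[2]) * h[2],
                        lo[3] + (cube$k + cent_off[3]) * h[3])
  }
  list(
    nc = nc, nn = nn, h = h, lo = lo,
    tets = do.call(rbind, tets),
    centroids = do.call(rbind, cents),
    node_coords = function(ids) {
      ids0 <- ids - 1L
      i <- ids0 %% nn[1]
      j <- (ids0 %/% nn[1]) %% nn[2]
      k <- ids0 %/% (nn[1] * nn[2])
      cbind(lo[1] + i * h[1], lo[2] + j * h[2], lo[3] + k * h[3])
    }
  )
}

# evaluate a predicate in chunks to bound memory in the distance sweeps
chunked_lgl <- function(points, fn, chunk = 40000L) {
  n <- nrow(points)
  out <- logical(n)
  i <- 1L
  while (i <= n) {
    j <- min(i + chunk - 1L, n)
    out[i:j] <- fn(points[i:j, , drop = FALSE])
    i <- j + 1L
  }
  out
}

resolve_membership <- function(x) {
  if (inherits(x, "trochfem_solid")) {
    return(list(inside = x$inside, bbox = x$bbox, solid = x))
  }
  if (inherits(x, "surface_mesh")) {
    solid <- attr(x, "solid")
    if (!is.null(solid)) {
      return(list(inside = solid$inside, bbox = solid$bbox, solid = solid))
    }
    if (!surface_is_watertight(x)) {
      stop_input("cannot tetrahedralize part '%s': surface is not watertight",
                 x$part_label)
    }
    bbox <- rbind(apply(x$vertices, 2, min), apply(x$vertices, 2, max))
    return(list(inside = function(p) point_in_surface(p, x), bbox = bbox,
                solid = NULL))
  }
  stop_input("cannot tetrahedralize object of class %s", class(x)[1])
}

#' Tetrahedralize a solid or watertight surface
#'
#' Fills the input with a conforming tetrahedral mesh on a structured
#' background grid (six tetrahedra per grid cell), keeping elements whose
#' centroid lies inside. Accepts an implicit solid (as attached to surfaces
#' built by this package) or any watertight `surface_mesh` (membership then
#' falls back to ray casting), or a named list of either — parts earlier in
#' the list take precedence where they overlap.
#'
#' @param x A `trochfem_solid`, a watertight `surface_mesh`, or a named list
#'   of them (e.g. implant parts before bone).
#' @param target_edge Grid spacing upper bound, mm.
#' @param order 1 for 4-node (linear) or 2 for 10-node (quadratic, midside
#'   nodes) tetrahedra.
#' @return Object of class `volume_mesh`: `nodes` (n x 3 mm), `tets`
#'   (m x 4 or m x 10, corner nodes first), `element_part` (character),
#'   `element_volume` (mm^3), `order`, `h` (grid spacing used).
#' @export
tetrahedralize <- function(x, target_edge, order = 1) {
  check_that(order %in% c(1, 2), "order must be 1 (TET4) or 2 (TET10)")
  parts <- if (inherits(x, c("trochfem_solid", "surface_mesh"))) {
    lab <- if (inherits(x, "surface_mesh")) x$part_label else x$label
    stats::setNames(list(x), lab %||% "solid")
  } else {
    check_that(is.list(x) && length(x) >= 1, "x must be a solid, surface, or list of parts")
    x
  }
  mem <- lapply(parts, resolve_membership)
  bboxes <- lapply(mem, `[[`, "bbox")
  bbox <- rbind(do.call(pmin, lapply(bboxes, function(b) b[1, ])),
                do.call(pmax, lapply(bboxes, function(b) b[2, ])))
  g <- grid_tets(bbox, target_edge)
  label <- rep(NA_character_, nrow(g$centroids))
  todo <- rep(TRUE, nrow(g$centroids))
  for (nm in names(mem)) {
    if (!any(todo)) break
    idx <- which(todo)
    hit <- chunked_lgl(g$centroids[idx, , drop = FALSE], mem[[nm]]$inside)
    label[idx[hit]] <- nm
    todo[idx[hit]] <- FALSE
  }
  keep <- !is.na(label)
  check_that(any(keep), "tetrahedralize: no element centroid falls inside the input")
  build_volume_mesh(g, which(keep), label[keep], order,
                    solid = mem[[1]]$solid)
}

# assemble a volume_mesh from grid tets selected by index, with labels
build_volume_mesh <- function(g, keep_idx, labels, order, solid = NULL) {
  tets <- g$tets[keep_idx, , drop = FALSE]
  used <- sort(unique(as.vector(tets)))
  remap <- integer(max(used))
  remap[used] <- seq_along(used)
  tets <- matrix(remap[tets], ncol = 4)
  nodes <- g$node_coords(used)
  vol <- tet_volumes(nodes, tets)
  check_that(all(vol > 0), "tetrahedralize produced %d inverted element(s)",
             sum(vol <= 0))
  mesh <- structure(
    list(nodes = nodes, tets = tets, element_part = labels,
         element_volume = vol, order = 1L, h = g$h),
    class = "volume_mesh"
  )
  if (order == 2) mesh <- tet4_to_tet10(mesh)
  attr(mesh, "solid") <- solid
  mesh
}

#' Signed tetrahedron volumes
#'
#' @param nodes n x 3 node coordinates.
#' @param tets m x 4 (or m x 10; corners first) connectivity.
#' @return Numeric vector of volumes, mm^3 (positive for consistent ordering).
#' @export
tet_volumes <- function(nodes, tets) {
  a <- nodes[tets[, 1], , drop = FALSE]
  e1 <- nodes[tets[, 2], , drop = FALSE] - a
  e2 <- nodes[tets[, 3], , drop = FALSE] - a
  e3 <- nodes[tets[, 4], , drop = FALSE] - a
  (e1[, 1] * (e2[, 2] * e3[, 3] - e2[, 3] * e3[, 2]) -
   e1[, 2] * (e2[, 1] * e3[, 3] - e2[, 3] * e3[, 1]) +
   e1[, 3] * (e2[, 1] * e3[, 2] - e2[, 2] * e3[, 1])) / 6
}

#' @export
print.volume_mesh <- function(x, ...) {
  cat(sprintf("volume_mesh: %d nodes, %d %s elements, %.0f mm^3\n",
              nrow(x$nodes), nrow(x$tets),
              if (ncol(x$tets) == 10) "TET10" else "TET4",
              sum(x$element_volume)))
  print(table(x$element_part))
  invisible(x)
}

element_centroids <- function(mesh) {
  t4 <- mesh$tets[, 1:4, drop = FALSE]
  (mesh$nodes[t4[, 1], , drop = FALSE] + mesh$nodes[t4[, 2], , drop = FALSE] +
   mesh$nodes[t4[, 3], , drop = FALSE] + mesh$nodes[t4[, 4], , drop = FALSE]) / 4
}

# convert a TET4 mesh to TET10 by inserting midside nodes
# (ordering: corners 1-4, then edges (1,2),(2,3),(1,3),(1,4),(2,4),(3,4))
tet4_to_tet10 <- function(mesh) {
  check_that(ncol(mesh$tets) == 4, "mesh is already quadratic")
  tets <- mesh$tets
  edges <- list(c(1, 2), c(2, 3), c(1, 3), c(1, 4), c(2, 4), c(3, 4))
  ea <- do.call(cbind, lapply(edges, function(e) pmin(tets[, e[1]], tets[, e[2]])))
  eb <- do.call(cbind, lapply(edges, function(e) pmax(tets[, e[1]], tets[, e[2]])))
  key <- paste(ea, eb)
  uk <- unique(key)
  mid_id <- match(key, uk) + nrow(mesh$nodes)
  first <- match(uk, key)
  mid_coords <- (mesh$nodes[ea[first], , drop = FALSE] +
                 mesh$nodes[eb[first], , drop = FALSE]) / 2
  mesh$nodes <- rbind(mesh$nodes, mid_coords)
  mesh$tets <- cbind(tets, matrix(mid_id, ncol = 6))
  mesh$order <- 2L
  mesh
}

# boundary faces of a set of elements (corner-node faces used exactly once),
# outward-oriented for positively oriented tets
boundary_faces <- function(mesh, elements = seq_len(nrow(mesh$tets))) {
  t4 <- mesh$tets[elements, 1:4, drop = FALSE]
  faces <- rbind(t4[, c(1, 3, 2)], t4[, c(1, 2, 4)],
                 t4[, c(2, 3, 4)], t4[, c(1, 4, 3)])
  key <- paste(pmin(faces[, 1], pmin(faces[, 2], faces[, 3])),
               faces[, 1] + faces[, 2] + faces[, 3],
               pmax(faces[, 1], pmax(faces[, 2], faces[, 3])))
  cnt <- table(key)
  faces[key %in% names(cnt)[cnt == 1L], , drop = FALSE]
}

#' Extract the boundary surface of a volume mesh part
#'
#' @param mesh A `volume_mesh`.
#' @param part Part label(s) to extract, or `NULL` for the whole mesh.
#' @return A `surface_mesh` of the boundary triangles.
#' @export
extract_surface <- function(mesh, part = NULL) {
  el <- if (is.null(part)) seq_len(nrow(mesh$tets)) else which(mesh$element_part %in% part)
  check_that(length(el) > 0, "no elements with part %s", paste(part, collapse = "/"))
  faces <- boundary_faces(mesh, el)
  used <- sort(unique(as.vector(faces)))
  remap <- integer(max(used))
  remap[used] <- seq_along(used)
  surface_mesh(mesh$nodes[used, , drop = FALSE],
               matrix(remap[faces], ncol = 3),
               part_label = if (is.null(part)) "assembly" else part[1])
}
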