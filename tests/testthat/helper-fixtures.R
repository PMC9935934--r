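# Shared fixtures, built in code at test time.

# watertight unit-cube surface with outward orientation
cube_surface <- function() {
  v <- as.matrix(expand.grid(x = 0:1, y = 0:1, z = 0:1))
  tris <- rbind(
    c(1, 3, 2), c(2, 3, 4),   # z = 0
    c(5, 6, 7), c(6, 8, 7),   # z = 1
    c(1, 2, 5), c(2, 6, 5),   # y = 0
    c(3, 7, 4), c(4, 7, 8),   # y = 1
    c(1, 5, 3), c(3, 5, 7),   # x = 0
    c(2, 4, 6), c(4, 8, 6)    # x = 1
  )
  surface_mesh(v, tris, "cube")
}

# axis-aligned box as an implicit solid
box_solid <- function(lo = c(0, 0, 0), hi = c(1, 1, 1)) {
  trochfem:::new_solid(
    inside = function(p) {
      p[, 1] >= lo[1] & p[, 1] <= hi[1] &
      p[, 2] >= lo[2] & p[, 2] <= hi[2] &
      p[, 3] >= lo[3] & p[, 3] <= hi[3]
    },
    sdf = function(p) {
      apply(cbind(p[, 1] - lo[1], hi[1] - p[, 1],
                  p[, 2] - lo[2], hi[2] - p[, 2],
                  p[, 3] - lo[3], hi[3] - p[, 3]), 1, min)
    },
    bbox = rbind(lo, hi), label = "box"
  )
}

# one-element TET4 mesh from explicit nodes
single_tet_mesh <- function(nodes) {
  tets <- matrix(1:4, 1)
  if (tet_volumes(nodes, tets) < 0) nodes <- nodes[c(1, 2, 4, 3), ]
  structure(list(nodes = nodes, tets = matrix(1:4, 1), element_part = "bone",
                 element_volume = tet_volumes(nodes, matrix(1:4, 1)),
                 order = 1L, h = c(1, 1, 1)),
            class = "volume_mesh")
}

# independent brute-force TET4 stiffness: exact second differences of the
# strain energy, with the strain obtained by solving the 4x4 linear
# interpolation system (no shared code with the assembly path)
oracle_tet4_stiffness <- function(nodes, E, nu) {
  V <- abs(det(cbind(nodes[2, ] - nodes[1, ], nodes[3, ] - nodes[1, ],
                     nodes[4, ] - nodes[1, ]))) / 6
  lam <- E * nu / ((1 + nu) * (1 - 2 * nu))
  mu <- E / (2 * (1 + nu))
  energy <- function(uvec) {
    u <- matrix(uvec, 4, 3, byrow = TRUE)
    Cmat <- cbind(1, nodes)
    G <- matrix(0, 3, 3)                 # G[i, j] = d u_i / d x_j
    for (i in 1:3) {
      coef <- solve(Cmat, u[, i])
      G[i, ] <- coef[2:4]
    }
    eps <- (G + t(G)) / 2
    V * (0.5 * lam * sum(diag(eps))^2 + mu * sum(eps * eps))
  }
  K <- matrix(0, 12, 12)
  for (i in 1:12) {
    for (j in 1:12) {
      ei <- numeric(12); ei[i] <- 1
      ej <- numeric(12); ej[j] <- 1
      K[i, j] <- energy(ei + ej) - energy(ei) - energy(ej)  # exact: quadratic
    }
  }
  K
}

uniform_materials <- function(mesh, E = 1000, nu = 0.3) {
  n <- nrow(mesh$tets)
  list(E = rep(E, n), nu = rep(nu, n), is_bone = rep(TRUE, n))
}

# small shared assembly cache so geometry is built once per test file set
.fixture_env <- new.env(parent = emptyenv())

coarse_assembly <- function(variant = "BASIC", seed = 1, target_edge = 5) {
  key <- paste(variant, seed, target_edge)
  if (is.null(.fixture_env[[key]])) {
    .fixture_env[[key]] <- build_assembly(variant = variant, seed = seed,
                                          target_edge = target_edge)
  }
  .fixture_env[[key]]
}
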