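# Finite-element solver: stiffness oracle, boundary conditions, benchmark
# limits, contact behaviour.

test_that("TET4 element stiffness matches the brute-force energy oracle", {
  set.seed(31)
  for (k in 1:5) {
    nodes <- matrix(rnorm(12), 4, 3)
    mesh <- single_tet_mesh(nodes)
    E <- runif(1, 1, 1000); nu <- runif(1, 0.05, 0.45)
    K <- as.matrix(assemble(mesh, list(E = E, nu = nu))$K)
    Ko <- oracle_tet4_stiffness(mesh$nodes, E, nu)
    expect_lt(max(abs(K - Ko)) / max(abs(Ko)), 1e-10)
  }
})

test_that("a two-element patch matches the brute-force oracle", {
  nodes <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(0, 0, 1), c(1, 1, 1))
  tets <- rbind(c(1, 2, 3, 4), c(2, 3, 4, 5))
  stopifnot(all(tet_volumes(nodes, tets) > 0))
  mesh <- structure(list(nodes = nodes, tets = tets,
                         element_part = c("bone", "bone"),
                         element_volume = tet_volumes(nodes, tets),
                         order = 1L, h = c(1, 1, 1)), class = "volume_mesh")
  E <- 11; nu <- 0.3
  K <- as.matrix(assemble(mesh, list(E = c(E, E), nu = c(nu, nu)))$K)
  Ko <- matrix(0, 15, 15)
  for (e in 1:2) {
    Ke <- oracle_tet4_stiffness(nodes[tets[e, ], ], E, nu)
    dofs <- as.vector(rbind(3 * (tets[e, ] - 1) + 1, 3 * (tets[e, ] - 1) + 2,
                            3 * (tets[e, ] - 1) + 3))
    Ko[dofs, dofs] <- Ko[dofs, dofs] + Ke
  }
  expect_lt(max(abs(K - Ko)) / max(abs(Ko)), 1e-10)
})

test_that("operator is linear in E and annihilates rigid motions", {
  m <- tetrahedralize(box_solid(), target_edge = 0.5)
  K1 <- assemble(m, uniform_materials(m, E = 100))$K
  K2 <- assemble(m, uniform_materials(m, E = 200))$K
  expect_equal(as.matrix(K2), 2 * as.matrix(K1), tolerance = 1e-12)
  # rigid translation and rotation produce zero force
  n <- nrow(m$nodes)
  trans <- as.numeric(t(matrix(c(1, -2, 0.5), n, 3, byrow = TRUE)))
  rot <- as.numeric(t(cbind(-m$nodes[, 2], m$nodes[, 1], 0)))
  scale <- max(abs(K1))
  expect_lt(max(abs(K1 %*% trans)) / scale, 1e-8)
  expect_lt(max(abs(K1 %*% rot)) / scale, 1e-8)
})

test_that("unconstrained operator has exactly six zero-energy modes", {
  m <- tetrahedralize(box_solid(), target_edge = 0.5)
  op <- assemble(m, uniform_materials(m))
  ev <- eigen(as.matrix(op$K), symmetric = TRUE, only.values = TRUE)$values
  expect_identical(sum(abs(ev) < max(ev) * 1e-10), 6L)
  # after constraining one face, no zero eigenvalue remains
  bc <- apply_boundary(op, which(m$nodes[, 3] < 1e-9))
  evc <- eigen(as.matrix(op$K[bc$free, bc$free]), symmetric = TRUE,
               only.values = TRUE)$values
  expect_gt(min(evc), 0)
  expect_error(apply_boundary(op, integer(0)), "empty")
})

test_that("fixing everything forces the zero solution", {
  m <- tetrahedralize(box_solid(), target_edge = 0.5)
  op <- assemble(m, uniform_materials(m))
  bc <- apply_boundary(op, seq_len(nrow(m$nodes)))
  expect_length(bc$free, 0)
})

test_that("cantilever bar reproduces FL/EA under axial load", {
  bar <- box_solid(c(0, 0, 0), c(10, 1, 1))
  m <- tetrahedralize(bar, target_edge = 0.5)
  E <- 1000
  mats <- uniform_materials(m, E = E, nu = 0)
  op <- assemble(m, mats)
  bc <- apply_boundary(op, which(m$nodes[, 1] < 1e-9))
  # consistent (area-weighted) axial traction on the x = 10 face
  bnd <- trochfem:::boundary_faces(m)
  fc <- (m$nodes[bnd[, 1], 1] + m$nodes[bnd[, 2], 1] + m$nodes[bnd[, 3], 1]) / 3
  tf <- bnd[fc > 10 - 1e-9, ]
  ar <- trochfem:::triangle_areas(m$nodes, tf)
  share <- numeric(nrow(m$nodes))
  for (c0 in 1:3) {
    t <- tapply(ar / 3, tf[, c0], sum)
    share[as.integer(names(t))] <- share[as.integer(names(t))] + t
  }
  Ftot <- 5
  f <- numeric(3 * nrow(m$nodes))
  f[3 * (seq_len(nrow(m$nodes)) - 1) + 1] <- Ftot * share
  u <- numeric(length(f))
  u[bc$free] <- as.numeric(Matrix::solve(
    Matrix::Cholesky(Matrix::forceSymmetric(op$K[bc$free, bc$free]), LDL = FALSE),
    f[bc$free]))
  um <- matrix(u, ncol = 3, byrow = TRUE)
  tip <- mean(um[m$nodes[, 1] > 10 - 1e-9, 1])
  expect_lt(abs(tip - Ftot * 10 / (E * 1)) / (Ftot * 10 / E), 0.01)
  # equilibrium residual at free dofs
  resid <- as.numeric(op$K %*% u) - f
  expect_lt(sqrt(sum(resid[bc$free]^2)) / sqrt(sum(f^2)), 1e-8)
  # uniform uniaxial stress field (patch-test limit)
  sig <- trochfem:::element_stresses(trochfem:::element_strains(m, um), mats)
  expect_lt(max(abs(sig[, 1] - Ftot / 1)) / (Ftot / 1), 0.01)
  expect_lt(max(abs(sig[, 2:6])) / (Ftot / 1), 0.01)
})

test_that("TET10 bar reproduces FL/EA", {
  bar <- box_solid(c(0, 0, 0), c(8, 1, 1))
  m <- tetrahedralize(bar, target_edge = 1, order = 2)
  E <- 500
  mats <- uniform_materials(m, E = E, nu = 0)
  op <- assemble(m, mats)
  corner <- m$nodes[, 1] < 1e-9
  bc <- apply_boundary(op, which(corner))
  end_nodes <- which(m$nodes[, 1] > 8 - 1e-9)
  f <- numeric(3 * nrow(m$nodes))
  # equal shares are not consistent for quadratic elements, but the axial
  # resultant and therefore the mean end displacement remain exact for nu=0
  f[3 * (end_nodes - 1) + 1] <- 4 / length(end_nodes)
  u <- numeric(length(f))
  u[bc$free] <- as.numeric(Matrix::solve(
    Matrix::Cholesky(Matrix::forceSymmetric(op$K[bc$free, bc$free]), LDL = FALSE),
    f[bc$free]))
  um <- matrix(u, ncol = 3, byrow = TRUE)
  expect_lt(abs(mean(um[end_nodes, 1]) - 4 * 8 / (E * 1)) / (4 * 8 / E), 0.05)
})

test_that("static solve of a model satisfies global equilibrium", {
  a <- coarse_assembly("BASIC")
  hu <- synthesize_hu(a$mesh, hu_field_spec(seed = 2))
  mats <- assign_materials(a$mesh, hu, n_bins = 10)
  r <- solve_static(a, mats, load_case("static_walking"))
  expect_lt(r$equilibrium$relative_residual, 1e-6)
  expect_equal(r$equilibrium$reaction, -r$equilibrium$applied,
               tolerance = 1e-3)
  # fixed nodes do not move
  expect_equal(max(abs(r$u[a$distal_fixed_nodes, ])), 0)
  expect_true(all(is.finite(r$u)))
})

test_that("tied fracture interface matches a merged-node mesh", {
  a <- coarse_assembly("BASIC")
  hu <- synthesize_hu(a$mesh, hu_field_spec(seed = 2))
  mats <- assign_materials(a$mesh, hu, n_bins = 10)
  r_tied <- solve_static(a, mats, load_case("static_walking"),
                         contact = contact_spec(fracture_mode = "tied"))
  # merged-mesh oracle: rewrite the connectivity to reuse the distal nodes
  a2 <- a
  map <- seq_len(nrow(a$mesh$nodes))
  map[a$fracture_pairs$proximal] <- a$fracture_pairs$distal
  a2$mesh$tets <- matrix(map[a$mesh$tets], ncol = ncol(a$mesh$tets))
  a2$distal_fixed_nodes <- c(a2$distal_fixed_nodes, a$fracture_pairs$proximal)
  a2$fracture_pairs <- a$fracture_pairs[0, ]
  r_merged <- solve_static(a2, mats, load_case("static_walking"))
  d_tied <- -r_tied$u[a$head_vertex, 3]
  d_merged <- -r_merged$u[a$head_vertex, 3]
  expect_lt(abs(d_tied - d_merged) / abs(d_merged), 0.01)
})

test_that("penalty contact opens in tension and converges", {
  a <- coarse_assembly("BASIC")
  hu <- synthesize_hu(a$mesh, hu_field_spec(seed = 2))
  mats <- assign_materials(a$mesh, hu, n_bins = 10)
  r <- solve_static(a, mats, load_case("static_climbing"),
                    contact = contact_spec(fracture_mode = "penalty_normal"))
  expect_true(any(r$contact_status == "open"))
  expect_true(any(r$contact_status != "open"))
  expect_lte(r$iterations, contact_spec()$max_iterations)
  expect_gt(as.numeric(fracture_gap(r, a)), 0)
  expect_lt(r$equilibrium$relative_residual, 1e-6)
})

test_that("doubling the load doubles displacement under fixed contact state", {
  a <- coarse_assembly("BASIC")
  hu <- synthesize_hu(a$mesh, hu_field_spec(seed = 2))
  mats <- assign_materials(a$mesh, hu, n_bins = 10)
  ctx <- trochfem:::fe_context(a, mats, contact_spec())
  r1 <- solve_static(a, mats, load_case("static_walking"), scale = 1, ctx = ctx)
  r2 <- solve_static(a, mats, load_case("static_walking"), scale = 2, ctx = ctx)
  expect_equal(r2$u, 2 * r1$u, tolerance = 1e-8)
})

test_that("gait envelope degenerates to the static solution for one phase", {
  a <- coarse_assembly("BASIC")
  hu <- synthesize_hu(a$mesh, hu_field_spec(seed = 2))
  mats <- assign_materials(a$mesh, hu, n_bins = 10)
  ctx <- trochfem:::fe_context(a, mats, contact_spec())
  lc <- load_case("dynamic_walking")
  tpl <- gait_template("custom", phases = 0.5, scales = 1)
  g <- solve_gait(a, mats, lc, template = tpl, ctx = ctx)
  r <- solve_static(a, mats, load_case("static_walking"), ctx = ctx)
  expect_equal(g$envelope$vms, von_mises(r$stress), tolerance = 1e-9)
  expect_equal(g$envelope$head_displacement,
               as.numeric(head_displacement(r, a$head_vertex)), tolerance = 1e-9)
  ind_g <- extract_indicators(g, a)
  ind_r <- extract_indicators(r, a)
  for (k in trochfem:::default_indicator_columns()) {
    expect_equal(ind_g[[k]], ind_r[[k]], tolerance = 1e-8)
  }
})

test_that("gait envelope dominates the static solution when peak scale >= 1", {
  a <- coarse_assembly("BASIC")
  hu <- synthesize_hu(a$mesh, hu_field_spec(seed = 2))
  mats <- assign_materials(a$mesh, hu, n_bins = 10)
  ctx <- trochfem:::fe_context(a, mats, contact_spec())
  tpl <- gait_template("climbing", n_phases = 5)
  expect_equal(tpl$peak_scale, 1.15)
  g <- solve_gait(a, mats, load_case("dynamic_climbing"), template = tpl, ctx = ctx)
  r <- solve_static(a, mats, load_case("static_climbing"), ctx = ctx)
  expect_true(all(g$envelope$vms >= von_mises(r$stress) - 1e-9))
  expect_gte(g$envelope$head_displacement,
             as.numeric(head_displacement(r, a$head_vertex)) - 1e-9)
})

test_that("head displacement is mesh-converged at the study resolution", {
  # refining past the study resolution (4 mm) changes the head-vertex
  # displacement by a few percent at most; the coarse grids (>= 5 mm) are
  # still resolution-limited because the blade diameter spans ~2 cells
  hu_spec <- hu_field_spec(seed = 2, noise_sd = 0)
  disp <- vapply(c(4, 3), function(h) {
    a <- build_assembly(variant = "BASIC", seed = 1, target_edge = h)
    hu <- synthesize_hu(a$mesh, hu_spec)
    mats <- assign_materials(a$mesh, hu, n_bins = 10)
    r <- solve_static(a, mats, load_case("static_walking"),
                      contact = contact_spec(fracture_mode = "tied"))
    -r$u[a$head_vertex, 3]
  }, numeric(1))
  expect_lt(abs(disp[2] - disp[1]) / disp[2], 0.1)
})
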