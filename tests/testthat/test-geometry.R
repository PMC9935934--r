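# Surrogate geometry: femur surface, implant placement, fracture split,
# defect carving, tetrahedralization.

test_that("femur surface is closed, oriented, and deterministic", {
  s <- build_femur()
  expect_true(surface_is_watertight(s))
  expect_identical(euler_characteristic(s), 2L)
  expect_gt(surface_volume(s), 0)
  s2 <- build_femur()
  expect_identical(s$vertices, s2$vertices)
  expect_identical(s$triangles, s2$triangles)
})

test_that("head region of the femur surface has the prescribed diameter", {
  s <- build_femur(femur_params(head_radius = 24))
  hv <- s$vertices[attr(s, "vertex_region") == "head", , drop = FALSE]
  dia <- max(dist(hv))
  expect_gte(dia, 47.9)
  expect_lte(dia, 48.1)
})

test_that("femur parameter invariants are enforced", {
  expect_error(femur_params(head_radius = -1), "> 0")
  expect_error(femur_params(cortical_thickness = 20, shaft_radius_outer = 14),
               "cortical_thickness")
  expect_error(femur_params(neck_shaft_angle = 100), "neck_shaft_angle")
})

test_that("implant surfaces are closed with the prescribed blade angle", {
  imp <- build_implant(implant_spec(nail_length = 200, blade_angle = 125))
  expect_named(imp, c("nail", "blade", "screw"))
  for (s in imp) expect_true(surface_is_watertight(s))
  pl <- attr(imp, "placement")
  ang <- acos(sum(pl$blade_dir * c(0, 0, -1))) * 180 / pi
  expect_lt(abs(ang - 125), 0.1)
  # 90 degree blade is perpendicular to the nail axis
  imp90 <- build_implant(implant_spec(blade_angle = 90))
  expect_lt(abs(sum(attr(imp90, "placement")$blade_dir * c(0, 0, 1))), 1e-6)
  # screw can be omitted
  imp2 <- build_implant(implant_spec(include_screw = FALSE))
  expect_named(imp2, c("nail", "blade"))
})

test_that("implant must fit the canal and the shaft", {
  expect_error(build_implant(implant_spec(nail_radius = 12)), "canal")
  expect_error(build_implant(implant_spec(nail_length = 400)), "exceeds the shaft")
})

test_that("tip-apex distance follows the two-projection definition", {
  # pure frontal-plane (x) offset contributes only to the frontal projection
  expect_equal(trochfem:::tad_from_points(c(3, 0, 0), c(0, 0, 0)), 3)
  expect_equal(trochfem:::tad_from_points(c(0, 4, 0), c(0, 0, 0)), 4)
  expect_equal(trochfem:::tad_from_points(c(0, 0, 2), c(0, 0, 0)), 4)
  expect_equal(trochfem:::tad_from_points(c(0, 0, 0), c(0, 0, 0)), 0)
  # default placement realises the 15 mm target; other targets generalise
  expect_lt(abs(compute_tad(position_implant(femur_params())) - 15), 0.5)
  p25 <- position_implant(femur_params(), implant_spec(target_tad = 25))
  expect_lt(abs(compute_tad(p25) - 25), 0.5)
})

test_that("implant placement is identical across defect variants", {
  aM <- coarse_assembly("M")
  aL <- coarse_assembly("L")
  for (f in c("blade_tip", "blade_dir", "nail_top", "nail_bottom", "screw_z")) {
    expect_identical(aM$landmarks[[f]], aL$landmarks[[f]])
  }
  # implant element centroids coincide (same background grid)
  cm <- trochfem:::element_centroids(aM$mesh)[aM$mesh$element_part == "nail", ]
  cl <- trochfem:::element_centroids(aL$mesh)[aL$mesh$element_part == "nail", ]
  expect_identical(cm, cl)
})

test_that("tetrahedralization conserves volume and refines properly", {
  m <- tetrahedralize(cube_surface(), target_edge = 0.5)
  expect_equal(sum(m$element_volume), 1, tolerance = 1e-6)
  expect_true(all(m$element_volume > 0))
  m2 <- tetrahedralize(cube_surface(), target_edge = 0.25)
  expect_gte(nrow(m2$tets) / nrow(m$tets), 2)
  m10 <- tetrahedralize(cube_surface(), target_edge = 0.5, order = 2)
  expect_identical(ncol(m10$tets), 10L)
  expect_equal(sum(m10$element_volume), 1, tolerance = 1e-6)
  # non-watertight input is rejected with the part named
  open_surf <- cube_surface()
  open_surf$triangles <- open_surf$triangles[-1, ]
  expect_error(tetrahedralize(open_surf, 0.5), "cube.*not watertight")
})

test_that("fracture split conserves volume and is seed-deterministic", {
  fem <- build_femur()
  fr0 <- apply_fracture(fem, seed = 1, amplitude = 0, target_edge = 5)
  expect_equal(fr0$volumes[["proximal"]] + fr0$volumes[["distal"]],
               fr0$volumes[["whole"]], tolerance = 0.005)
  fr1a <- apply_fracture(fem, seed = 1, amplitude = 3, target_edge = 5)
  fr1b <- apply_fracture(fem, seed = 1, amplitude = 3, target_edge = 5)
  expect_identical(fr1a$proximal$vertices, fr1b$proximal$vertices)
  fr2 <- apply_fracture(fem, seed = 2, amplitude = 3, target_edge = 5)
  expect_false(identical(fr1a$interface$distal, fr2$interface$distal))
  expect_equal(fr2$volumes[["proximal"]] + fr2$volumes[["distal"]],
               fr2$volumes[["whole"]], tolerance = 0.005)
  # fragment boundaries enclose their tet volumes (closed, outward-oriented;
  # voxel fragments may pinch, so 2-manifold watertightness is not required)
  expect_true(surface_is_closed(fr1a$proximal))
  expect_true(surface_is_closed(fr1a$distal))
  expect_equal(surface_volume(fr1a$proximal), fr1a$volumes[["proximal"]])
  expect_equal(surface_volume(fr1a$distal), fr1a$volumes[["distal"]])
  # an absurd amplitude leaves the trochanteric zone
  expect_error(apply_fracture(fem, seed = 1, amplitude = 60), "zone")
})

test_that("defect carving follows the partition identities", {
  fem <- build_femur()
  fr <- apply_fracture(fem, seed = 1, amplitude = 3, target_edge = 5)
  rules <- defect_rules(pl_upper_height = 0)  # PL without the upper region
  rem <- vapply(c("BASIC", "M", "AM", "PM", "L", "AL", "PL"), function(v) {
    carve_defect(fr, rules, v)$removed_volume
  }, numeric(1))
  expect_identical(rem[["BASIC"]], 0)
  expect_lt(abs(rem[["AM"]] + rem[["PM"]] - rem[["M"]]) / rem[["M"]], 0.01)
  expect_lt(abs(rem[["AL"]] + rem[["PL"]] - rem[["L"]]) / rem[["L"]], 0.01)
  # PML removes PM, PL, and the interposed posterior bone
  rules_full <- defect_rules()
  rem_pm <- carve_defect(fr, rules_full, "PM")$removed_volume
  rem_pl <- carve_defect(fr, rules_full, "PL")$removed_volume
  rem_pml <- carve_defect(fr, rules_full, "PML")$removed_volume
  expect_gte(rem_pml, rem_pm + rem_pl)
  expect_error(carve_defect(fr, rules, "XX"), "unknown fracture variant")
})

test_that("assembly volume bookkeeping is conservative for every variant", {
  for (v in fracture_variants()) {
    a <- coarse_assembly(v)
    expect_lt(abs(a$bone_volume + a$removed_volume - a$basic_bone_volume) /
                a$basic_bone_volume, 0.01)
    expect_true(all(a$mesh$element_volume > 0))
  }
})

test_that("assembly landmarks satisfy their contracts", {
  a <- coarse_assembly("BASIC")
  # head vertex belongs to the proximal fragment and is its highest node
  prox_nodes <- unique(as.vector(
    a$mesh$tets[a$mesh$element_part == "head_neck_fragment", 1:4]))
  expect_true(a$head_vertex %in% prox_nodes)
  expect_equal(a$mesh$nodes[a$head_vertex, 3], max(a$mesh$nodes[prox_nodes, 3]))
  # distal fixed nodes sit on the distal face
  expect_gt(length(a$distal_fixed_nodes), 3)
  expect_true(all(abs(a$mesh$nodes[a$distal_fixed_nodes, 3] -
                        min(a$mesh$nodes[, 3])) < 1e-8))
  # fracture pairs start coincident (zero initial separation)
  d <- a$mesh$nodes[a$fracture_pairs$distal, , drop = FALSE] -
       a$mesh$nodes[a$fracture_pairs$proximal, , drop = FALSE]
  expect_lt(max(abs(d)), 0.1)
  expect_equal(compute_tad(a), 15, tolerance = 0.5)
})

test_that("surface I/O round-trips through STL", {
  s <- cube_surface()
  fa <- tempfile(fileext = ".stl")
  fb <- tempfile(fileext = ".stl")
  write_stl(s, fa, binary = FALSE)
  write_stl(s, fb, binary = TRUE)
  ra <- read_stl(fa)
  rb <- read_stl(fb)
  expect_true(surface_is_watertight(ra))
  expect_true(surface_is_watertight(rb))
  expect_equal(surface_volume(ra), 1)
  expect_equal(surface_volume(rb), 1)
  unlink(c(fa, fb))
})
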