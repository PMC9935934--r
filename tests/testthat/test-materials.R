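# Hounsfield-unit calibration and material assignment.

test_that("density calibration reproduces the affine map", {
  cal <- material_calibration()
  expect_equal(hu_to_density(0, cal), 131)
  expect_equal(hu_to_density(1000, cal), 131 + 1.067 * 1000)  # 1198
  expect_equal(hu_to_density(-131 / 1.067, cal), 0)
})

test_that("modulus calibration applies the affine map with a positive floor", {
  cal <- material_calibration()
  expect_equal(density_to_modulus(1198, cal), -331 + 4.56 * 1198)  # 5131.88
  expect_equal(density_to_modulus(0, cal), cal$e_floor)
  expect_equal(density_to_modulus(331 / 4.56, cal), cal$e_floor)
})

test_that("composed HU -> E map is strictly increasing above the clamp", {
  cal <- material_calibration()
  hu <- seq(-200, 3000, by = 7)
  E <- density_to_modulus(hu_to_density(hu, cal), cal)
  above <- E > cal$e_floor
  expect_true(all(diff(E[above]) > 0))
  expect_true(all(E >= cal$e_floor))
  # pre-clamp maps are strictly increasing everywhere
  expect_true(all(diff(hu_to_density(hu, cal)) > 0))
})

test_that("calibration constructor validates physical ranges", {
  expect_error(material_calibration(e_floor = 0), "e_floor")
  expect_error(material_calibration(nu_bone = 0.5), "nu_bone")
  expect_error(material_calibration(rho_slope = -1), "slopes")
})

test_that("HU synthesis is seeded, two-phase, and deterministic", {
  m <- tetrahedralize(box_solid(c(0, 0, 0), c(10, 10, 10)), target_edge = 1)
  m$element_part <- rep("bone", nrow(m$tets))
  spec0 <- hu_field_spec(noise_sd = 0, cortical_shell_thickness = 2, seed = 4)
  hu0 <- synthesize_hu(m, spec0)
  expect_identical(sort(unique(hu0)), sort(c(spec0$trabecular_hu_mean,
                                             spec0$cortical_hu_mean)))
  spec <- hu_field_spec(seed = 4)
  expect_identical(synthesize_hu(m, spec), synthesize_hu(m, spec))
  spec2 <- hu_field_spec(seed = 5)
  expect_false(identical(synthesize_hu(m, spec), synthesize_hu(m, spec2)))
})

test_that("cortical element fraction tracks the geometric shell fraction", {
  # sphere of radius 12 with a 3 mm shell: exact shell volume fraction
  R <- 12; t <- 3
  sph <- trochfem:::sphere_solid(c(0, 0, 0), R)
  m <- tetrahedralize(sph, target_edge = 0.8)
  m$element_part <- rep("bone", nrow(m$tets))
  hu <- synthesize_hu(m, hu_field_spec(noise_sd = 0, cortical_shell_thickness = t))
  cort <- attr(hu, "cortical")
  frac_mesh <- sum(m$element_volume[cort]) / sum(m$element_volume)
  frac_geom <- 1 - ((R - t) / R)^3
  expect_lt(abs(frac_mesh - frac_geom), 0.05)
})

test_that("assignment separates implant and bone and respects the floor", {
  m <- tetrahedralize(box_solid(c(0, 0, 0), c(4, 4, 8)), target_edge = 1)
  n <- nrow(m$tets)
  m$element_part <- rep(c("bone", "nail"), length.out = n)
  hu <- rep(NA_real_, n)
  hu[m$element_part == "bone"] <- seq(-500, 2000, length.out = sum(m$element_part == "bone"))
  cal <- material_calibration()
  mat <- assign_materials(m, hu, cal)
  imp <- m$element_part == "nail"
  expect_true(all(mat$E[imp] == cal$e_implant))
  expect_true(all(mat$nu[imp] == cal$nu_implant))
  expect_true(all(mat$E[!imp] >= cal$e_floor))
  expect_true(all(mat$nu[!imp] == cal$nu_bone))
  # continuous assignment equals the composed formulas
  expect_equal(mat$E[!imp],
               density_to_modulus(hu_to_density(hu[!imp], cal), cal))
  # missing HU for a bone element is an error naming the element
  hu2 <- hu; hu2[which(!imp)[1]] <- NA
  expect_error(assign_materials(m, hu2, cal), "missing HU")
})

test_that("modulus binning conserves the mean and collapses for one bin", {
  m <- tetrahedralize(box_solid(c(0, 0, 0), c(6, 6, 6)), target_edge = 1)
  n <- nrow(m$tets)
  m$element_part <- rep("bone", n)
  hu <- seq(100, 1900, length.out = n)
  cal <- material_calibration()
  e_cont <- assign_materials(m, hu, cal)$E
  e_b10 <- assign_materials(m, hu, cal, n_bins = 10)$E
  expect_lt(abs(mean(e_b10) - mean(e_cont)) / mean(e_cont), 0.02)
  expect_lte(length(unique(e_b10)), 10)
  e_b1 <- assign_materials(m, hu, cal, n_bins = 1)$E
  expect_equal(unique(e_b1), mean(e_cont))
})
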