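# Outcome-indicator post-processing.

test_that("von Mises handles the closed-form cases", {
  p <- 3.7
  expect_equal(von_mises(diag(c(p, p, p))), 0)
  expect_equal(von_mises(diag(c(p, 0, 0))), p)
  tau <- 1.3
  sh <- matrix(0, 3, 3); sh[1, 2] <- sh[2, 1] <- tau
  expect_equal(von_mises(sh), sqrt(3) * tau)
  expect_error(von_mises(matrix(c(0, 1, 0, 0, 0, 0, 0, 0, 0), 3)), "symmetric")
})

test_that("von Mises is invariant under rotation of the stress tensor", {
  set.seed(21)
  for (k in 1:10) {
    S <- matrix(rnorm(9), 3); S <- (S + t(S)) / 2
    Q <- qr.Q(qr(matrix(rnorm(9), 3)))
    expect_equal(von_mises(Q %*% S %*% t(Q)), von_mises(S), tolerance = 1e-10)
  }
})

test_that("principal strains sort diagonal tensors and are rotation-invariant", {
  expect_equal(as.numeric(principal_strains(diag(c(0.2, -0.1, 0.5)))),
               c(0.5, 0.2, -0.1))
  set.seed(22)
  for (k in 1:10) {
    S <- matrix(rnorm(9), 3); S <- (S + t(S)) / 2
    Q <- qr.Q(qr(matrix(rnorm(9), 3)))
    expect_equal(as.numeric(principal_strains(Q %*% S %*% t(Q))),
                 as.numeric(principal_strains(S)), tolerance = 1e-10)
  }
})

test_that("principal strains agree with an independent eigen solver", {
  set.seed(23)
  voigt <- matrix(rnorm(600, sd = 0.01), 100, 6)
  mine <- principal_strains(voigt)
  for (k in seq_len(nrow(voigt))) {
    v <- voigt[k, ]
    Tm <- matrix(c(v[1], v[4] / 2, v[6] / 2,
                   v[4] / 2, v[2], v[5] / 2,
                   v[6] / 2, v[5] / 2, v[3]), 3, byrow = TRUE)
    ref <- sort(eigen(Tm, symmetric = TRUE, only.values = TRUE)$values,
                decreasing = TRUE)
    expect_equal(as.numeric(mine[k, ]), ref, tolerance = 1e-9)
  }
})

test_that("risky volume classifier equals a direct element loop", {
  th <- risk_thresholds()
  vols <- rep(2.5, 10)
  eps1 <- rep(0.001, 10); eps1[c(2, 5, 9)] <- 0.01
  eps3 <- rep(-0.001, 10); eps3[c(1, 4)] <- -0.02
  rv <- risky_volumes(vols, eps1, eps3, th)
  # independent loop
  tv <- 0; cv <- 0
  for (i in 1:10) {
    if (eps1[i] > th$tensile_limit) tv <- tv + vols[i]
    if (eps3[i] < th$compressive_limit) cv <- cv + vols[i]
  }
  expect_equal(rv$tensile_volume, tv)
  expect_equal(rv$compressive_volume, cv)
  expect_equal(rv$tensile_ratio, 0.3)
  expect_equal(rv$compressive_ratio, 0.2)
})

test_that("risk thresholds use strict inequalities at the boundary", {
  th <- risk_thresholds()
  rv <- risky_volumes(c(1, 1, 1), c(0.009, 0.0090001, 0.0089999),
                      c(-0.009, -0.0090001, -0.0089999), th)
  expect_equal(rv$tensile_volume, 1)      # only the strictly-above element
  expect_equal(rv$compressive_volume, 1)  # only the strictly-below element
  rv0 <- risky_volumes(rep(1, 4), rep(0, 4), rep(0, 4), th)
  expect_equal(rv0$tensile_volume, 0)
  expect_equal(rv0$tensile_ratio, 0)
  expect_equal(rv0$compressive_volume, 0)
  expect_equal(rv0$compressive_ratio, 0)
})

test_that("head displacement measures the distal component", {
  fake <- list(u = rbind(c(0, 0, 0), c(1, 2, -3.5)))
  expect_equal(as.numeric(head_displacement(fake, 1)), 0)
  hd <- head_displacement(fake, 2)
  expect_equal(as.numeric(hd), 3.5)
  expect_equal(attr(hd, "magnitude"), sqrt(1 + 4 + 3.5^2))
})

test_that("fracture gap floors closing motion and reports rigid opening", {
  a <- coarse_assembly("BASIC")
  n <- nrow(a$mesh$nodes)
  # zero deformation
  r0 <- list(u = matrix(0, n, 3))
  expect_equal(as.numeric(fracture_gap(r0, a)), 0)
  # rigid proximal translation along +normal opens every pair by g
  g <- 0.25
  u <- matrix(0, n, 3)
  nbar <- colMeans(as.matrix(a$fracture_pairs[, c("nx", "ny", "nz")]))
  nbar <- nbar / sqrt(sum(nbar^2))
  prox_nodes <- unique(as.vector(
    a$mesh$tets[a$mesh$element_part == "head_neck_fragment", 1:4]))
  u[prox_nodes, ] <- matrix(g * nbar, length(prox_nodes), 3, byrow = TRUE)
  gap <- fracture_gap(list(u = u), a)
  # pair normals vary slightly around nbar; opening is close to g
  expect_gt(as.numeric(gap), 0.9 * g)
  expect_lte(as.numeric(gap), g + 1e-9)
  # rigid closing motion floors to zero
  u2 <- -u
  expect_equal(as.numeric(fracture_gap(list(u = u2), a)), 0)
})
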