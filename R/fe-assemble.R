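# Small-strain linear-elastic tetrahedral stiffness assembly (TET4 and
# TET10), fully vectorised over elements. Units: mm, N, MPa.
#
# For an isotropic element with Lame parameters (lambda, mu) and constant
# shape-function gradients b_a, the nodal stiffness blocks are
#   K_ab[i,j] = V * (lambda b_a[i] b_b[j] + mu (b_a . b_b) delta_ij
#                    + mu b_a[j] b_b[i])
# which TET4 satisfies exactly; TET10 integrates the same form with a
# 4-point Gauss rule (exact for straight-edged quadratic tets).

# constant gradients b (list of 4 M x 3 matrices) and volumes of the corner
# tets of a mesh
tet_gradients <- function(nodes, tets) {
  a <- nodes[tets[, 1], , drop = FALSE]
  e1 <- nodes[tets[, 2], , drop = FALSE] - a
  e2 <- nodes[tets[, 3], , drop = FALSE] - a
  e3 <- nodes[tets[, 4], , drop = FALSE] - a
  det <- e1[, 1] * (e2[, 2] * e3[, 3] - e2[, 3] * e3[, 2]) -
         e1[, 2] * (e2[, 1] * e3[, 3] - e2[, 3] * e3[, 1]) +
         e1[, 3] * (e2[, 1] * e3[, 2] - e2[, 2] * e3[, 1])
  if (any(det <= 0)) {
    stop_input("assembly error: %d element(s) with non-positive volume", sum(det <= 0))
  }
  # grad N2 = (e2 x e3)/det, grad N3 = (e3 x e1)/det, grad N4 = (e1 x e2)/det
  b2 <- cbind(e2[, 2] * e3[, 3] - e2[, 3] * e3[, 2],
              e2[, 3] * e3[, 1] - e2[, 1] * e3[, 3],
              e2[, 1] * e3[, 2] - e2[, 2] * e3[, 1]) / det
  b3 <- cbind(e3[, 2] * e1[, 3] - e3[, 3] * e1[, 2],
              e3[, 3] * e1[, 1] - e3[, 1] * e1[, 3],
              e3[, 1] * e1[, 2] - e3[, 2] * e1[, 1]) / det
  b4 <- cbind(e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
              e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
              e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1]) / det
  b1 <- -(b2 + b3 + b4)
  list(b = list(b1, b2, b3, b4), V = det / 6)
}

lame_parameters <- function(materials) {
  E <- materials$E
  nu <- materials$nu
  list(lambda = E * nu / ((1 + nu) * (1 - 2 * nu)), mu = E / (2 * (1 + nu)))
}

# 4-point Gauss rule on the reference tet (barycentric), degree-2 exact
.tet10_gauss <- {
  a <- 0.5854101966249685
  b <- 0.1381966011250105
  list(L = rbind(c(a, b, b, b), c(b, a, b, b), c(b, b, a, b), c(b, b, b, a)),
       w = rep(0.25, 4))
}
.tet10_edges <- list(c(1, 2), c(2, 3), c(1, 3), c(1, 4), c(2, 4), c(3, 4))

# gradient coefficient matrix C (10 x 4) at barycentric point L:
# grad N_a = sum_k C[a, k] * b_k
tet10_grad_coefs <- function(L) {
  C <- matrix(0, 10, 4)
  for (k in 1:4) C[k, k] <- 4 * L[k] - 1
  for (e in seq_along(.tet10_edges)) {
    ij <- .tet10_edges[[e]]
    C[4 + e, ij[1]] <- 4 * L[ij[2]]
    C[4 + e, ij[2]] <- 4 * L[ij[1]]
  }
  C
}

#' Assemble the global stiffness operator
#'
#' Builds the sparse symmetric stiffness matrix of a tetrahedral mesh under
#' isotropic linear elasticity with per-element constants. Before any
#' boundary constraint the operator has exactly six rigid-body zero-energy
#' modes.
#'
#' @param mesh A `volume_mesh` (TET4 or TET10).
#' @param materials An `element_materials` from [assign_materials()], or a
#'   list with per-element `E` (MPa) and `nu`.
#' @return Object of class `fe_operator`: sparse `K` (3n x 3n,
#'   `Matrix::dsCMatrix`), `n_nodes`, `order`.
#' @export
assemble <- function(mesh, materials) {
  check_that(inherits(mesh, "volume_mesh"), "mesh must be a volume_mesh")
  nel <- nrow(mesh$tets)
  check_that(length(materials$E) == nel && length(materials$nu) == nel,
             "materials must provide E and nu for all %d elements", nel)
  K <- if (ncol(mesh$tets) == 4) assemble_tet4(mesh, materials)
       else assemble_tet10(mesh, materials)
  structure(list(K = K, n_nodes = nrow(mesh$nodes),
                 order = if (ncol(mesh$tets) == 10) 2L else 1L),
            class = "fe_operator")
}

assemble_tet4 <- function(mesh, materials) {
  g <- tet_gradients(mesh$nodes, mesh$tets)
  lp <- lame_parameters(materials)
  nel <- nrow(mesh$tets)
  ndof <- 3L * nrow(mesh$nodes)
  lamV <- lp$lambda * g$V
  muV <- lp$mu * g$V
  ii <- vector("list", 144L); jj <- ii; xx <- ii
  m <- 0L
  for (a in 1:4) {
    ba <- g$b[[a]]
    na <- mesh$tets[, a]
    for (b in 1:4) {
      bb <- g$b[[b]]
      nb <- mesh$tets[, b]
      dot <- rowSums(ba * bb)
      for (i in 1:3) {
        for (j in 1:3) {
          m <- m + 1L
          val <- lamV * ba[, i] * bb[, j] + muV * ba[, j] * bb[, i]
          if (i == j) val <- val + muV * dot
          ii[[m]] <- 3L * (na - 1L) + i
          jj[[m]] <- 3L * (nb - 1L) + j
          xx[[m]] <- val
        }
      }
    }
  }
  K <- Matrix::sparseMatrix(i = unlist(ii), j = unlist(jj), x = unlist(xx),
                            dims = c(ndof, ndof))
  Matrix::forceSymmetric(K)
}

assemble_tet10 <- function(mesh, materials) {
  t10 <- mesh$tets
  g <- tet_gradients(mesh$nodes, t10[, 1:4, drop = FALSE])
  lp <- lame_parameters(materials)
  ndof <- 3L * nrow(mesh$nodes)
  nel <- nrow(t10)
  # accumulate 3x3 blocks for each (a, b) pair over Gauss points
  blocks <- vector("list", 100L)
  for (gp in 1:4) {
    C <- tet10_grad_coefs(.tet10_gauss$L[gp, ])
    w <- .tet10_gauss$w[gp]
    G <- vector("list", 10L)
    for (a in 1:10) {
      G[[a]] <- C[a, 1] * g$b[[1]] + C[a, 2] * g$b[[2]] +
                C[a, 3] * g$b[[3]] + C[a, 4] * g$b[[4]]
    }
    lamV <- w * lp$lambda * g$V
    muV <- w * lp$mu * g$V
    m <- 0L
    for (a in 1:10) {
      for (b in 1:10) {
        m <- m + 1L
        Ga <- G[[a]]; Gb <- G[[b]]
        dot <- rowSums(Ga * Gb)
        blk <- blocks[[m]] %||% matrix(0, nel, 9L)
        q <- 0L
        for (i in 1:3) {
          for (j in 1:3) {
            q <- q + 1L
            add <- lamV * Ga[, i] * Gb[, j] + muV * Ga[, j] * Gb[, i]
            if (i == j) add <- add + muV * dot
            blk[, q] <- blk[, q] + add
          }
        }
        blocks[[m]] <- blk
      }
    }
  }
  ii <- vector("list", 900L); jj <- ii; xx <- ii
  m <- 0L; q_all <- 0L
  for (a in 1:10) {
    na <- t10[, a]
    for (b in 1:10) {
      m <- m + 1L
      nb <- t10[, b]
      blk <- blocks[[m]]
      q <- 0L
      for (i in 1:3) {
        for (j in 1:3) {
          q <- q + 1L
          q_all <- q_all + 1L
          ii[[q_all]] <- 3L * (na - 1L) + i
          jj[[q_all]] <- 3L * (nb - 1L) + j
          xx[[q_all]] <- blk[, q]
        }
      }
    }
  }
  K <- Matrix::sparseMatrix(i = unlist(ii), j = unlist(jj), x = unlist(xx),
                            dims = c(ndof, ndof))
  Matrix::forceSymmetric(K)
}

# per-element strains (Voigt xx, yy, zz, xy, yz, zx with engineering shear)
# from nodal displacements; TET10 strains evaluated at the centroid
element_strains <- function(mesh, u) {
  t4 <- mesh$tets[, 1:4, drop = FALSE]
  g <- tet_gradients(mesh$nodes, t4)
  eff <- if (ncol(mesh$tets) == 10) {
    # at the centroid the corner shape gradients vanish; edge node gradients
    # are b_i + b_j
    lapply(seq_len(10), function(a) {
      if (a <= 4) NULL else {
        ij <- .tet10_edges[[a - 4L]]
        g$b[[ij[1]]] + g$b[[ij[2]]]
      }
    })
  } else g$b
  nel <- nrow(mesh$tets)
  eps <- matrix(0, nel, 6)
  for (a in seq_len(ncol(mesh$tets))) {
    ga <- eff[[a]]
    if (is.null(ga)) next
    ua <- u[mesh$tets[, a], , drop = FALSE]
    eps[, 1] <- eps[, 1] + ga[, 1] * ua[, 1]
    eps[, 2] <- eps[, 2] + ga[, 2] * ua[, 2]
    eps[, 3] <- eps[, 3] + ga[, 3] * ua[, 3]
    eps[, 4] <- eps[, 4] + ga[, 2] * ua[, 1] + ga[, 1] * ua[, 2]
    eps[, 5] <- eps[, 5] + ga[, 3] * ua[, 2] + ga[, 2] * ua[, 3]
    eps[, 6] <- eps[, 6] + ga[, 3] * ua[, 1] + ga[, 1] * ua[, 3]
  }
  colnames(eps) <- c("xx", "yy", "zz", "xy", "yz", "zx")
  eps
}

element_stresses <- function(eps, materials) {
  lp <- lame_parameters(materials)
  tr <- eps[, 1] + eps[, 2] + eps[, 3]
  sig <- cbind(
    lp$lambda * tr + 2 * lp$mu * eps[, 1],
    lp$lambda * tr + 2 * lp$mu * eps[, 2],
    lp$lambda * tr + 2 * lp$mu * eps[, 3],
    lp$mu * eps[, 4],
    lp$mu * eps[, 5],
    lp$mu * eps[, 6]
  )
  colnames(sig) <- colnames(eps)
  sig
}
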