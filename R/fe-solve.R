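# Static and quasi-static solution of the assembled models: distal full
# constraint, hip-contact load distributed over a polar cap of the femoral
# head, tied or penalty (compressive-only, optionally Coulomb) contact
# across the fracture interface, and envelope extraction over gait phases.

#' Hip-contact load cases
#'
#' The four load cases: static and quasi-static ("dynamic") hip joint
#' contact forces for level walking and stair climbing of a 70 kg subject,
#' magnitudes (647, 236, 1351) N at 2.0 body weights for walking and
#' (711, 436, 1393) N at 2.1 body weights for climbing. In the model frame
#' (+x anterior, +y lateral, +z proximal) the components act medially,
#' posteriorly and distally: walking (-236, -647, -1351), climbing
#' (-436, -711, -1393). The medial component presses the femoral head onto
#' the calcar (the varus-compression mode that drives trochanteric fixation
#' failure, with compressive strain concentrating at the medial/inferior
#' cortex and tensile strain at the lateral fracture surface); the
#' anterior-posterior component points posteriorly, as instrumented-hip
#' measurements report for level walking and, more strongly, stair
#' climbing. Dynamic cases reuse the static vector scaled along a gait
#' curve ([gait_template()]).
#'
#' @param name One of `"static_walking"`, `"static_climbing"`,
#'   `"dynamic_walking"`, `"dynamic_climbing"`.
#' @param force_vector Optional length-3 override of the contact force, N.
#' @param patch_angle Half-angle of the spherical load cap on the femoral
#'   head, degrees.
#' @return Object of class `load_case`.
#' @export
load_case <- function(name = c("static_walking", "static_climbing",
                               "dynamic_walking", "dynamic_climbing"),
                      force_vector = NULL, patch_angle = 30) {
  name <- match.arg(name)
  gait <- if (grepl("walking", name)) "walking" else "climbing"
  default_force <- if (gait == "walking") c(-236, -647, -1351) else c(-436, -711, -1393)
  f <- force_vector %||% default_force
  check_that(length(f) == 3 && all(is.finite(f)) && any(f != 0),
             "force_vector must be a nonzero length-3 vector")
  structure(
    list(name = name, force_vector = as.numeric(f),
         bw_multiple = if (gait == "walking") 2.0 else 2.1,
         dynamic = grepl("^dynamic", name), gait = gait,
         patch_angle = patch_angle),
    class = "load_case"
  )
}

#' Gait load-scaling templates
#'
#' Quasi-static gait curves: per-phase multipliers of the static hip-contact
#' vector over one cycle. The walking template is double-peaked (peaks 1.0
#' and 0.9 of the static vector); the climbing template is single-peaked at
#' 1.15. These are configurable stand-ins for published instrumented-hip
#' curves; any user curve can be supplied as `(phase, scale)` pairs.
#'
#' @param gait `"walking"` or `"climbing"`, or `"custom"` with `phases` and
#'   `scales` given.
#' @param n_phases Number of phases over the cycle.
#' @param phases,scales Custom curve (phase fractions in `[0, 1]`,
#'   non-negative multipliers).
#' @return Object of class `gait_template` with fields `phase_fractions`,
#'   `scale_factors`, `peak_scale`.
#' @export
gait_template <- function(gait = c("walking", "climbing", "custom"),
                          n_phases = 16, phases = NULL, scales = NULL) {
  gait <- match.arg(gait)
  if (gait == "custom") {
    check_that(!is.null(phases) && !is.null(scales) && length(phases) == length(scales),
               "custom template needs matching phases and scales")
  } else {
    phases <- seq(0, 1, length.out = n_phases)
    raw <- if (gait == "walking") {
      exp(-((phases - 0.18) / 0.10)^2) + 0.9 * exp(-((phases - 0.50) / 0.10)^2) +
        0.08
    } else {
      exp(-((phases - 0.40) / 0.14)^2) + 0.08
    }
    peak <- if (gait == "walking") 1.0 else 1.15
    scales <- raw / max(raw) * peak
  }
  check_that(all(scales >= 0), "gait scale factors must be >= 0")
  structure(list(phase_fractions = as.numeric(phases),
                 scale_factors = as.numeric(scales),
                 peak_scale = max(scales), gait = gait),
            class = "gait_template")
}

#' Interface contact specification
#'
#' Contact handling per interface class. The fracture surface defaults to
#' penalty contact with compressive-only normal springs on the duplicated
#' node pairs (optionally with Coulomb stick/slip using the bone-bone
#' friction coefficient); bone-implant and implant-implant interfaces are
#' tied (they share mesh nodes). Friction coefficients carried for the
#' Coulomb option: bone-bone 0.46, bone-implant 0.42, implant-implant 0.2.
#'
#' @param fracture_mode `"penalty_normal"` (default), `"penalty_coulomb"`,
#'   or `"tied"`.
#' @param mu_bone_bone,mu_bone_implant,mu_implant_implant Friction
#'   coefficients (>= 0).
#' @param penalty_stiffness Penalty pressure stiffness, N/mm^3; `NULL` for
#'   the default 1000 x mean bone modulus / grid spacing.
#' @param max_iterations Active-set iteration cap.
#' @return Object of class `contact_spec`.
#' @export
contact_spec <- function(fracture_mode = c("penalty_normal", "penalty_coulomb",
                                           "tied"),
                         mu_bone_bone = 0.46, mu_bone_implant = 0.42,
                         mu_implant_implant = 0.2,
                         penalty_stiffness = NULL, max_iterations = 30L) {
  fracture_mode <- match.arg(fracture_mode)
  check_that(all(c(mu_bone_bone, mu_bone_implant, mu_implant_implant) >= 0),
             "friction coefficients must be >= 0")
  check_that(is.null(penalty_stiffness) || penalty_stiffness > 0,
             "penalty_stiffness must be > 0")
  structure(list(fracture_mode = fracture_mode, mu_bone_bone = mu_bone_bone,
                 mu_bone_implant = mu_bone_implant,
                 mu_implant_implant = mu_implant_implant,
                 penalty_stiffness = penalty_stiffness,
                 max_iterations = as.integer(max_iterations)),
            class = "contact_spec")
}

#' Constrain a stiffness operator at fully fixed nodes
#'
#' Fixes all three displacement components of the given nodes to zero and
#' returns the reduced system. The constrained operator of a connected model
#' is positive-definite (no remaining rigid-body modes).
#'
#' @param op An `fe_operator` from [assemble()].
#' @param fixed_nodes Integer node ids to fix (nonempty).
#' @return List with `K` (full), `free` (free dof indices), `fixed_dofs`.
#' @export
apply_boundary <- function(op, fixed_nodes) {
  check_that(inherits(op, "fe_operator"), "op must be an fe_operator")
  fixed_nodes <- unique(as.integer(fixed_nodes))
  check_that(length(fixed_nodes) > 0, "boundary error: fixed node set is empty")
  ndof <- 3L * op$n_nodes
  fixed_dofs <- as.vector(rbind(3L * (fixed_nodes - 1L) + 1L,
                                3L * (fixed_nodes - 1L) + 2L,
                                3L * (fixed_nodes - 1L) + 3L))
  list(K = op$K, free = setdiff(seq_len(ndof), fixed_dofs),
       fixed_dofs = fixed_dofs)
}

# ---- solver context --------------------------------------------------------

# Precomputed state shared between the phases of one model/load-case family:
# base stiffness, fixed dofs, contact pairs, and a factorization cache keyed
# by the contact status signature.
fe_context <- function(assembly, materials, contact = contact_spec()) {
  mesh <- assembly$mesh
  pairs <- assembly$fracture_pairs
  tied <- contact$fracture_mode == "tied" && nrow(pairs) > 0
  tets <- mesh$tets
  orphan_nodes <- integer(0)
  if (tied) {
    map <- seq_len(nrow(mesh$nodes))
    map[pairs$proximal] <- pairs$distal
    tets <- matrix(map[tets], ncol = ncol(tets))
    orphan_nodes <- pairs$proximal
  }
  mesh_solve <- mesh
  mesh_solve$tets <- tets
  op <- assemble(mesh_solve, materials)
  fixed_nodes <- unique(c(assembly$distal_fixed_nodes, orphan_nodes))
  bc <- apply_boundary(op, fixed_nodes)
  kpen <- contact$penalty_stiffness %||%
    (1000 * mean(materials$E[materials$is_bone]) / mean(mesh$h))
  env <- new.env(parent = emptyenv())
  list(assembly = assembly, materials = materials, contact = contact,
       mesh = mesh, mesh_solve = mesh_solve, op = op, bc = bc,
       pairs = pairs, tied = tied, kpen = kpen, cache = env)
}

# contact stiffness for the given per-pair status ("open"/"stick"/"slip")
contact_matrix <- function(ctx, status) {
  pairs <- ctx$pairs
  act <- which(status != "open")
  if (length(act) == 0) return(NULL)
  n <- cbind(pairs$nx, pairs$ny, pairs$nz)[act, , drop = FALSE]
  kn <- ctx$kpen * pairs$area[act]
  stick <- status[act] == "stick"
  ii <- integer(0); jj <- integer(0); xx <- numeric(0)
  dn <- pairs$distal[act]; pn <- pairs$proximal[act]
  for (i in 1:3) {
    for (j in 1:3) {
      kij <- kn * n[, i] * n[, j]
      if (any(stick)) {
        # tangential stick springs: k (I - n n^T)
        kij[stick] <- kij[stick] +
          kn[stick] * ((i == j) - n[stick, i] * n[stick, j])
      }
      ii <- c(ii, 3L * (dn - 1L) + i, 3L * (pn - 1L) + i,
              3L * (dn - 1L) + i, 3L * (pn - 1L) + i)
      jj <- c(jj, 3L * (dn - 1L) + j, 3L * (pn - 1L) + j,
              3L * (pn - 1L) + j, 3L * (dn - 1L) + j)
      xx <- c(xx, kij, kij, -kij, -kij)
    }
  }
  Matrix::sparseMatrix(i = ii, j = jj, x = xx,
                       dims = dim(ctx$op$K))
}

context_factor <- function(ctx, status) {
  key <- paste0("k", paste(status, collapse = ""))
  if (!is.null(ctx$cache[[key]])) return(ctx$cache[[key]])
  Kc <- ctx$op$K
  cm <- contact_matrix(ctx, status)
  if (!is.null(cm)) Kc <- Kc + cm
  Kff <- Kc[ctx$bc$free, ctx$bc$free, drop = FALSE]
  fact <- Matrix::Cholesky(Matrix::forceSymmetric(Kff), LDL = FALSE)
  val <- list(factor = fact, K = Kc)
  ctx$cache[[key]] <- val
  val
}

# active-set penalty solve for one right-hand side
context_solve <- function(ctx, f, warm_status = NULL) {
  npair <- nrow(ctx$pairs)
  ndof <- length(f)
  if (all(f == 0)) {
    return(list(u = matrix(0, ctx$op$n_nodes, 3),
                status = rep("open", npair), iterations = 0L,
                K = ctx$op$K, f = f))
  }
  penalty <- !ctx$tied && npair > 0
  coulomb <- ctx$contact$fracture_mode == "penalty_coulomb"
  status <- if (!penalty) rep("open", npair) else {
    warm_status %||% rep(if (coulomb) "stick" else "slip", npair)
  }
  # in penalty_normal mode "slip" means closed with free tangential motion
  it <- 0L
  repeat {
    it <- it + 1L
    fac <- context_factor(ctx, if (penalty) status else character(0))
    u <- numeric(ndof)
    u[ctx$bc$free] <- as.numeric(Matrix::solve(fac$factor, f[ctx$bc$free]))
    if (!penalty) {
      um <- matrix(u, ncol = 3, byrow = TRUE)
      if (ctx$tied && npair > 0) um[ctx$pairs$proximal, ] <- um[ctx$pairs$distal, ]
      return(list(u = um, status = status, iterations = it, K = fac$K, f = f))
    }
    um <- matrix(u, ncol = 3, byrow = TRUE)
    du <- um[ctx$pairs$proximal, , drop = FALSE] - um[ctx$pairs$distal, , drop = FALSE]
    nrm <- cbind(ctx$pairs$nx, ctx$pairs$ny, ctx$pairs$nz)
    gap <- rowSums(du * nrm) + ctx$pairs$g0
    closed <- gap < 0
    new_status <- ifelse(closed, if (coulomb) "stick" else "slip", "open")
    if (coulomb && any(closed)) {
      kn <- ctx$kpen * ctx$pairs$area
      fn <- kn * pmax(-gap, 0)
      tang <- du - gap * nrm
      ft <- kn * row_norm(tang)
      was_stick <- status == "stick" & closed
      slipping <- was_stick & ft > ctx$contact$mu_bone_bone * fn + 1e-9
      new_status[closed & status == "slip"] <- "slip"  # keep slipping pairs slipping
      new_status[slipping] <- "slip"
    }
    if (identical(new_status, status)) {
      return(list(u = um, status = status, iterations = it, K = fac$K, f = f))
    }
    if (it >= ctx$contact$max_iterations) {
      stop_input("contact iteration did not converge in %d iterations (%d pairs changing)",
                 it, sum(new_status != status))
    }
    status <- new_status
  }
}

# nodal force vector for a load case (equal shares over the head cap patch)
head_load_vector <- function(assembly, load, scale = 1) {
  cand <- assembly$head_surface_nodes
  check_that(length(cand) > 0, "assembly has no head surface nodes")
  C <- assembly$landmarks$head_center
  F <- load$force_vector * scale
  dir <- -unit(load$force_vector)         # outward direction of the loaded cap
  rel <- assembly$mesh$nodes[cand, , drop = FALSE] -
    matrix(C, length(cand), 3, byrow = TRUE)
  cosang <- (rel %*% dir) / row_norm(rel)
  patch <- cand[cosang >= cos(deg2rad(load$patch_angle))]
  if (length(patch) == 0) patch <- cand[which.max(cosang)]
  f <- numeric(3L * nrow(assembly$mesh$nodes))
  for (i in 1:3) f[3L * (patch - 1L) + i] <- F[i] / length(patch)
  attr(f, "patch") <- patch
  f
}

# ---- public solves ---------------------------------------------------------

#' Solve one static load case
#'
#' Assembles and solves the constrained linear-elastic system for a model
#' assembly: the distal end fully fixed, the hip-contact force distributed
#' in equal nodal shares over the femoral-head cap facing the load, and the
#' fracture interface handled per the contact specification (active-set
#' penalty iteration for the compressive-only springs). Verifies global
#' equilibrium of reactions against the applied load.
#'
#' @param assembly A `model_assembly`.
#' @param materials An `element_materials`.
#' @param load A [load_case()].
#' @param contact A [contact_spec()].
#' @param scale Scalar multiplier of the load vector.
#' @param ctx Optional precomputed context (internal reuse across phases).
#' @return Object of class `solve_result`: nodal displacements `u` (n x 3,
#'   mm), element `strain` and `stress` (Voigt, engineering shear),
#'   `contact_status`, `iterations`, and an `equilibrium` record (relative
#'   residual, reaction and applied force sums).
#' @export
solve_static <- function(assembly, materials, load = load_case("static_walking"),
                         contact = contact_spec(), scale = 1, ctx = NULL) {
  check_that(inherits(assembly, "model_assembly"), "assembly must be a model_assembly")
  ctx <- ctx %||% fe_context(assembly, materials, contact)
  f <- head_load_vector(assembly, load, scale)
  sol <- context_solve(ctx, as.numeric(f))
  u <- sol$u
  eps <- element_strains(ctx$mesh, u)
  sig <- element_stresses(eps, materials)
  uvec <- as.numeric(t(u))
  resid <- as.numeric(sol$K %*% uvec) - as.numeric(f)
  fnorm <- sqrt(sum(f^2))
  rel_res <- if (fnorm > 0) sqrt(sum(resid[ctx$bc$free]^2)) / fnorm else 0
  fixed <- ctx$bc$fixed_dofs
  reaction <- c(sum(resid[fixed[fixed %% 3L == 1L]]),
                sum(resid[fixed[fixed %% 3L == 2L]]),
                sum(resid[fixed[fixed %% 3L == 0L]]))
  structure(
    list(u = u, strain = eps, stress = sig,
         contact_status = sol$status, iterations = sol$iterations,
         equilibrium = list(relative_residual = rel_res,
                            reaction = reaction,
                            applied = load$force_vector * scale),
         load = load, scale = scale,
         patch = attr(f, "patch")),
    class = "solve_result"
  )
}

#' Solve a quasi-static gait series and its envelope
#'
#' Runs one static solve per gait phase with the force scaled along the gait
#' template (no inertial effects: the load-time curve is traversed
#' quasi-statically) and accumulates the envelope: per-element maxima of von
#' Mises stress and maximum principal strain, per-element minima of minimum
#' principal strain, per-node maximum displacement magnitude, and the
#' maximum fracture gap.
#'
#' @inheritParams solve_static
#' @param template A [gait_template()]; defaults to the template matching
#'   `load$gait`.
#' @return Object of class `gait_result`: `phases` (data frame), `envelope`
#'   (list of per-element/per-node envelope fields), `peak_scale`, and the
#'   `solve_result` of the peak phase as `$peak`.
#' @export
solve_gait <- function(assembly, materials, load = load_case("dynamic_walking"),
                       template = NULL, contact = contact_spec(), ctx = NULL) {
  template <- template %||% gait_template(load$gait)
  ctx <- ctx %||% fe_context(assembly, materials, contact)
  nel <- nrow(assembly$mesh$tets)
  nnode <- nrow(assembly$mesh$nodes)
  env_vms <- rep(0, nel)
  env_eps1 <- rep(-Inf, nel)
  env_eps3 <- rep(Inf, nel)
  env_disp <- rep(0, nnode)
  env_gap <- 0
  env_gap_mean <- 0
  phases <- data.frame(phase = template$phase_fractions,
                       scale = template$scale_factors,
                       head_displacement = NA_real_, peak_vms = NA_real_,
                       iterations = NA_integer_)
  warm <- NULL
  peak_idx <- which.max(template$scale_factors)
  peak_result <- NULL
  for (k in seq_along(template$scale_factors)) {
    s <- template$scale_factors[k]
    f <- head_load_vector(assembly, load, s)
    sol <- context_solve(ctx, as.numeric(f), warm_status = warm)
    warm <- sol$status
    eps <- element_strains(ctx$mesh, sol$u)
    sig <- element_stresses(eps, ctx$materials)
    vms <- von_mises(sig)
    pr <- principal_strains(eps)
    env_vms <- pmax(env_vms, vms)
    env_eps1 <- pmax(env_eps1, pr[, 1])
    env_eps3 <- pmin(env_eps3, pr[, 3])
    env_disp <- pmax(env_disp, row_norm(sol$u))
    gap <- pair_gaps(assembly, sol$u)
    if (length(gap)) {
      cm <- assembly$fracture_pairs$common
      gsub <- if (!is.null(cm) && any(cm)) gap[cm] else gap
      env_gap <- max(env_gap, max(gsub))
      env_gap_mean <- max(env_gap_mean, mean(gsub))
    }
    phases$head_displacement[k] <- max(0, -sol$u[assembly$head_vertex, 3])
    phases$peak_vms[k] <- max(vms)
    phases$iterations[k] <- sol$iterations
    if (k == peak_idx) {
      peak_result <- structure(
        list(u = sol$u, strain = eps, stress = sig,
             contact_status = sol$status, iterations = sol$iterations,
             equilibrium = NULL, load = load, scale = s),
        class = "solve_result")
    }
  }
  structure(
    list(phases = phases,
         envelope = list(vms = env_vms, eps1 = env_eps1, eps3 = env_eps3,
                         disp_mag = env_disp, gap_max = env_gap,
                         gap_mean = env_gap_mean,
                         head_displacement = max(phases$head_displacement)),
         peak_scale = template$peak_scale,
         peak = peak_result, template = template, load = load),
    class = "gait_result"
  )
}

# per-pair normal opening (floored at zero) for a displacement field
pair_gaps <- function(assembly, u) {
  pairs <- assembly$fracture_pairs
  if (nrow(pairs) == 0) return(numeric(0))
  du <- u[pairs$proximal, , drop = FALSE] - u[pairs$distal, , drop = FALSE]
  nrm <- cbind(pairs$nx, pairs$ny, pairs$nz)
  pmax(rowSums(du * nrm) + pairs$g0, 0)
}
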