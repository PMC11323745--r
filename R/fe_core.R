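# Quasi-static nonlinear FE solver: total-Lagrangian assembly (compiled),
# follower pressure loads, symmetry boundary conditions, adaptive incremental
# load stepping with full Newton iteration. Linear solves use sparse Cholesky
# (CHOLMOD via Matrix) on the symmetrised tangent, with a diagonal-shift
# (damped Newton) ladder when the tangent is indefinite. Assembly order is
# fixed, so identical inputs give bit-identical solutions.

#' Solver configuration
#'
#' @param newton_tol relative residual tolerance: convergence requires
#'   `||r|| <= newton_tol * max(||f_ext||, 1e-8)` on the free dofs.
#' @param max_iters maximum Newton iterations per load increment.
#' @param max_cutbacks maximum recursive bisections of a load increment.
#' @param du_max cap on the largest nodal displacement increment per Newton
#'   update, mm (guards against overshoot in the strongly stiffening
#'   material).
#' @param verbose print per-iteration residuals (solver diagnostics).
#' @return an object of class `apdi_solver_config`.
#' @export
solver_config <- function(newton_tol = 1e-6, max_iters = 40,
                          max_cutbacks = 5, du_max = 0.5, verbose = FALSE) {
  stopifnot(newton_tol > 0, max_iters >= 1, du_max > 0)
  structure(list(newton_tol = newton_tol, max_iters = max_iters,
                 max_cutbacks = max_cutbacks, du_max = du_max,
                 verbose = isTRUE(verbose)),
            class = "apdi_solver_config")
}

#' Boundary conditions for the globe model
#'
#' Quarter model: zero normal displacement on both symmetry faces (z = 0
#' sagittal plane, y = 0 axial plane) and a fully fixed node at the most
#' posterior point of the globe. Half model: sagittal symmetry only, the
#' fixed posterior node, plus `u_y = 0` at the corneal apex to remove the
#' remaining in-plane rotation.
#'
#' @param mesh an `apdi_mesh`.
#' @return an object of class `apdi_bcs`: list with `dofs` (1-based dof
#'   indices) and `values` (prescribed displacements, mm).
#' @export
boundary_conditions <- function(mesh) {
  sag <- mesh$sets$sagittal_nodes
  pole <- mesh$sets$pole_node
  dofs <- c(3L * sag,                 # u_z = 0 on sagittal plane
            3L * pole - 2L, 3L * pole - 1L, 3L * pole)
  if (identical(mesh$model %||% "quarter", "half")) {
    apex <- which.max(mesh$nodes[, 1])
    dofs <- c(dofs, 3L * apex - 1L)   # pin the in-plane rotation
  } else {
    dofs <- c(dofs, 3L * mesh$sets$axial_nodes - 1L)  # u_y = 0 on axial plane
  }
  dofs <- sort(unique(dofs))
  structure(list(dofs = dofs, values = numeric(length(dofs))),
            class = "apdi_bcs")
}

#' Prescribed-displacement boundary conditions
#' @param dofs 1-based dof indices (`3*(node-1) + component`).
#' @param values prescribed displacements, mm (recycled).
#' @return an `apdi_bcs` object.
#' @export
dirichlet_bcs <- function(dofs, values = 0) {
  o <- order(dofs)
  structure(list(dofs = as.integer(dofs[o]),
                 values = rep_len(values, length(dofs))[o]),
            class = "apdi_bcs")
}

# Symbolic structure: reduced sparse pattern and CSC write maps for the
# volume elements and the two loaded surfaces. Depends only on connectivity,
# constrained dofs and the loaded face sets — not on node positions — so it
# is shared across all geometries with the same mesh topology (memoised
# below; parameter studies sweep geometry at fixed topology).
.fe_structure_cache <- new.env(parent = emptyenv())

fe_structure_cached <- function(mesh, bcs) {
  key <- rlang::hash(list(mesh$divisions, dim(mesh$conn), bcs$dofs,
                          mesh$sets$airpuff_idx))
  hit <- .fe_structure_cache[[key]]
  if (!is.null(hit)) return(hit)
  st <- fe_structure(mesh, bcs)
  keys <- ls(.fe_structure_cache)
  if (length(keys) >= 2) rm(list = keys[1], envir = .fe_structure_cache)
  .fe_structure_cache[[key]] <- st
  st
}

fe_structure <- function(mesh, bcs) {
  ndof <- 3L * nrow(mesh$nodes)
  free <- setdiff(seq_len(ndof), bcs$dofs)
  fmap <- integer(ndof)
  fmap[free] <- seq_along(free)

  tv <- .fem_triplets(mesh$conn)
  ti <- fmap[tv$i]; tj <- fmap[tv$j]
  sel <- ti > 0L & tj > 0L
  K0 <- Matrix::sparseMatrix(i = ti[sel], j = tj[sel], x = 0,
                             dims = c(length(free), length(free)))
  K0 <- methods::as(K0, "CsparseMatrix")
  map_vol <- .csc_locate(ti, tj, K0@p, K0@i)

  surf_map <- function(faces) {
    tf <- .surf_triplets(faces)
    .csc_locate(fmap[tf$i], fmap[tf$j], K0@p, K0@i)
  }
  patch <- mesh$sets$outer_faces[mesh$sets$airpuff_idx, , drop = FALSE]

  # symmetrisation bookkeeping: pattern entry list, transpose positions, and
  # a dsC template holding the upper triangle in matching order
  ent_i <- K0@i + 1L
  ent_j <- rep.int(seq_len(ncol(K0)), diff(K0@p))
  tpos <- .csc_locate(ent_j, ent_i, K0@p, K0@i)
  upper <- which(ent_i <= ent_j)
  Ks0 <- Matrix::forceSymmetric(K0, uplo = "U")
  diag_pos_sym <- which(ent_i[upper] == ent_j[upper])

  list(free = free, fmap = fmap, K0 = K0, nnz = length(K0@x),
       map_vol = map_vol,
       inner_faces = mesh$sets$inner_faces,
       map_inner = surf_map(mesh$sets$inner_faces),
       patch_faces = patch,
       map_patch = surf_map(patch),
       upper = upper, tpos_upper = tpos[upper], Ks0 = Ks0,
       diag_pos_sym = diag_pos_sym)
}

# One Newton solve at fixed load (iop_mpa, puff scale). kernel_gp: Fp x 9
# matrix of unit-peak kernel values at the patch gauss points; peak_mpa the
# peak pressure. With `cavity` (list: bulk_mpa, V0), the inner pressure is
# iop + bulk * (V0 - V(u)) / V0 and its compliance enters the tangent as a
# rank-one update, applied by Sherman-Morrison. Returns
# list(u, converged, iters, resid).
newton_solve <- function(nodes, mesh, field, st, u, iop_mpa, puff,
                         kernel_gp, peak_mpa, cfg, cavity = NULL,
                         precomp = NULL) {
  free <- st$free
  Fi <- nrow(st$inner_faces)
  pgp_in <- matrix(iop_mpa, Fi, 9)
  puff_on <- puff > 0 && !is.null(kernel_gp)
  if (puff_on) pgp_puff <- kernel_gp * (puff * peak_mpa)
  rn_prev <- Inf
  rn_first <- Inf
  u_prev <- NULL
  du_prev <- NULL
  alpha <- 1
  back <- 0L
  max_it <- if (is.null(cfg$attempt_iters)) cfg$max_iters
            else min(cfg$attempt_iters, cfg$max_iters)
  for (it in seq_len(max_it)) {
    va <- .fem_assemble(nodes, mesh$conn, u, field$mu_el, field$nhalf,
                        field$kappa, st$map_vol, st$nnz, TRUE, precomp)
    bad <- !va$ok
    if (!bad) {
      Qf <- NULL
      cav_c <- 0
      if (!is.null(cavity)) {
        V <- cavity_volume_at_faces(nodes, u, st$inner_faces)
        p_in <- iop_mpa + cavity$bulk_mpa * (cavity$V0 - V) / cavity$V0
        pgp_in <- matrix(p_in, Fi, 9)
        Qu <- .surface_load(nodes, u, st$inner_faces,
                            matrix(1, Fi, 9), st$map_inner, st$nnz, FALSE)
        Qf <- as.numeric(Qu$fext)[free]
        cav_c <- cavity$bulk_mpa / cavity$V0
      }
      sl <- .surface_load(nodes, u, st$inner_faces, pgp_in, st$map_inner,
                          st$nnz, TRUE)
      fext <- as.numeric(sl$fext)
      xK <- as.numeric(va$x) - as.numeric(sl$x)
      if (puff_on) {
        sp <- .surface_load(nodes, u, st$patch_faces, pgp_puff, st$map_patch,
                            st$nnz, TRUE)
        fext <- fext + as.numeric(sp$fext)
        xK <- xK - as.numeric(sp$x)
      }
      r <- (fext - as.numeric(va$fint))[free]
      rn <- sqrt(sum(r^2))
      fn <- sqrt(sum(fext[free]^2))
      if (cfg$verbose)
        cat(sprintf("    it %2d  |r| %.3e  |f| %.3e  back %d\n",
                    it, rn, fn, back), file = stderr())
      # converged on force balance, or on a vanishing displacement update
      # (the force residual has a roundoff floor ~ |K| * eps that a very stiff
      # material cannot undercut relative to |f|)
      if (rn <= cfg$newton_tol * max(fn, 1e-8) ||
          (back == 0L && !is.null(du_prev) &&
             alpha * max(abs(du_prev)) < 1e-9))
        return(list(u = u, converged = TRUE, iters = it, resid = rn))
      bad <- !is.finite(rn)
      if (it == 1) rn_first <- rn
      # stalled: no net progress after 12 iterations means the start point is
      # outside the Newton basin; give up early so the increment is bisected
      if (it >= 12 && rn > rn_first)
        return(list(u = u, converged = FALSE, iters = it, resid = rn))
    } else if (cfg$verbose) {
      cat(sprintf("    it %2d  element inversion (el %d)\n", it,
                  va$bad_element), file = stderr())
    }
    # backtracking on element inversion, non-finite residual, or catastrophic
    # overshoot. The residual of this strongly stiffening material routinely
    # grows ~1e3x for one iteration before entering the quadratic basin, so a
    # monotone line search would stall; only growth beyond 1e4x is treated as
    # an overshoot worth damping.
    if ((bad || rn > 1e4 * rn_prev) && !is.null(u_prev) && back < 6L) {
      alpha <- alpha / 2
      u <- u_prev
      u[free] <- u[free] + alpha * du_prev
      back <- back + 1L
      next
    }
    if (bad)
      return(list(u = u, converged = FALSE, iters = it, resid = NA))
    rn_prev <- rn
    Ks <- st$Ks0
    Ks@x <- (xK[st$upper] + xK[st$tpos_upper]) * 0.5
    du <- solve_tangent(st, Ks, r)
    if (!is.null(du) && !is.null(Qf) && cav_c > 0) {
      # rank-one cavity compliance via Sherman-Morrison
      y <- solve_tangent(st, Ks, Qf)
      if (is.null(y)) du <- NULL
      else du <- du - y * (cav_c * sum(Qf * du)) / (1 + cav_c * sum(Qf * y))
    }
    if (is.null(du) || any(!is.finite(du)))
      return(list(u = u, converged = FALSE, iters = it, resid = rn))
    cap <- max(abs(du))
    if (cap > cfg$du_max) du <- du * (cfg$du_max / cap)
    u_prev <- u
    du_prev <- du
    alpha <- 1
    back <- 0L
    u[free] <- u[free] + du
  }
  list(u = u, converged = FALSE, iters = cfg$max_iters, resid = rn)
}

# Sparse Cholesky of the symmetrised tangent. An indefinite tangent
# (possible at deep indentation) is refactorised with a growing diagonal
# shift, i.e. a damped Newton direction. The factor is built fresh each time:
# at these sizes the symbolic analysis is cheap, and refactorising an
# existing CHMfactor with an indefinite matrix is pathological in CHOLMOD.
solve_tangent <- function(st, Ks, r) {
  scl <- mean(abs(Ks@x[st$diag_pos_sym]))
  if (!is.finite(scl) || scl <= 0) return(NULL)
  # simplicial LDL': unlike the supernodal LL' path it completes on an
  # indefinite matrix (no failure path to leak CHOLMOD memory through), and
  # its pivots reveal indefiniteness so the same diagonal-shift ladder can be
  # walked explicitly.
  for (tau in c(0, 1e-6, 1e-4, 1e-2) * scl) {
    ch <- suppressWarnings(tryCatch(
      Matrix::Cholesky(Ks, LDL = TRUE, super = FALSE, Imult = tau),
      error = function(e) NULL))
    if (is.null(ch)) next
    piv <- suppressWarnings(Matrix::diag(ch))
    if (!all(is.finite(piv)) || min(piv) <= 0) next
    du <- tryCatch(as.numeric(Matrix::solve(ch, r)), error = function(e) NULL)
    if (!is.null(du) && all(is.finite(du))) return(du)
  }
  NULL
}

# Adaptive sub-stepping between two scheduled load states. The substep
# fraction is halved on failure and carried over (re-grown after repeated
# easy convergence), so one difficult regime does not make every later
# scheduled step re-fail at full size.
solve_increment <- function(nodes, mesh, field, st, u, load_from, load_to,
                            kernel_gp, peak_mpa, cfg, frac_env,
                            cavity = NULL, precomp = NULL) {
  frac_min <- 0.5^cfg$max_cutbacks
  s <- 0           # progress through [load_from, load_to]
  iters <- 0L
  easy <- 0L
  last <- NULL
  while (s < 1) {
    frac <- frac_env$frac
    s_try <- min(1, s + frac)
    load_try <- load_from + s_try * (load_to - load_from)
    if (cfg$verbose)
      cat(sprintf("  substep -> iop %.4g MPa, puff %.3f (frac %.4g)\n",
                  load_try[1], load_try[2], frac), file = stderr())
    res <- newton_solve(nodes, mesh, field, st, u, load_try[1], load_try[2],
                        kernel_gp, peak_mpa, cfg, cavity = cavity,
                        precomp = precomp)
    iters <- iters + res$iters
    if (cfg$verbose)
      cat(sprintf("    -> %s in %d its\n",
                  if (res$converged) "converged" else "FAILED", res$iters), file = stderr())
    if (res$converged) {
      u <- res$u
      s <- s_try
      last <- res
      easy <- if (res$iters <= 8) easy + 1L else 0L
      if (easy >= 2L && frac < 1) {
        frac_env$frac <- min(1, frac * 2)
        easy <- 0L
      }
    } else {
      if (frac <= frac_min) {
        res$iters <- iters
        return(res)
      }
      frac_env$frac <- frac / 2
      easy <- 0L
    }
  }
  last$iters <- iters
  last
}

#' Quasi-static nonlinear solve over a load schedule
#'
#' Incrementally applies intraocular pressure and air-puff load, solving each
#' step with full Newton iteration on the total-Lagrangian equations.
#' Pressures are follower loads: they act on the deformed surface along its
#' current normal, and their load stiffness enters the tangent. A step that
#' fails to converge is bisected recursively before the solver gives up.
#'
#' @param mesh an `apdi_mesh`.
#' @param field an `apdi_material_field`.
#' @param bcs an `apdi_bcs` (see [boundary_conditions()]).
#' @param schedule data frame with columns `iop_mmhg` and `puff_frac` (0-1
#'   fraction of the peak air-puff pressure), one row per load step.
#' @param profile an [airpuff_profile()] if any `puff_frac > 0`.
#' @param cfg a [solver_config()].
#' @param nodes optional node coordinates overriding `mesh$nodes` (used by
#'   the stress-free iteration).
#' @param u0 optional initial displacement guess (3N vector).
#' @param structure internal: reuse a precomputed symbolic structure.
#' @param kernel_gp internal: precomputed kernel values at the air-puff patch
#'   gauss points (computed from `nodes` + `u0` if needed and absent).
#' @param cavity optional volume-coupled cavity: list with `bulk_mpa`
#'   (pressure rise, MPa, per unit relative cavity-volume reduction) and `V0`
#'   (reference cavity volume, mm^3). The inner-surface pressure then becomes
#'   `iop + bulk * (V0 - V(u)) / V0`, solved monolithically.
#' @return an object of class `apdi_solution`: nodal positions at every load
#'   step (step 0 = reference configuration), per-step convergence data, and
#'   the inputs needed to post-process.
#' @export
solve_static <- function(mesh, field, bcs, schedule, profile = NULL,
                         cfg = solver_config(), nodes = mesh$nodes,
                         u0 = NULL, structure = NULL, kernel_gp = NULL,
                         cavity = NULL) {
  stopifnot(inherits(mesh, "apdi_mesh"), inherits(field, "apdi_material_field"))
  schedule <- as.data.frame(schedule)
  stopifnot(all(c("iop_mmhg", "puff_frac") %in% names(schedule)))
  st <- structure %||% fe_structure_cached(mesh, bcs)
  ndof <- 3L * nrow(mesh$nodes)
  u <- u0 %||% numeric(ndof)
  u[bcs$dofs] <- bcs$values

  needs_puff <- any(schedule$puff_frac > 0)
  peak_mpa <- 0
  if (needs_puff) {
    if (is.null(profile)) stop("air-puff schedule requires a profile")
    peak_mpa <- kpa_to_mpa(profile$peak_kpa)
    if (is.null(kernel_gp))
      kernel_gp <- airpuff_kernel_gp(mesh, profile, nodes = nodes, u = u)
  }

  precomp <- .fem_precompute(nodes, mesh$conn)
  if (!precomp$ok)
    stop("invalid geometry: non-positive jacobian in element ",
         precomp$bad_element)

  K <- nrow(schedule)
  U <- matrix(0, ndof, K + 1)
  U[, 1] <- 0
  info <- vector("list", K)
  load_prev <- c(0, 0)
  frac_env <- new.env(parent = emptyenv())
  frac_env$frac <- 1
  for (k in seq_len(K)) {
    load_k <- c(mmhg_to_mpa(schedule$iop_mmhg[k]), schedule$puff_frac[k])
    res <- solve_increment(nodes, mesh, field, st, u, load_prev, load_k,
                           kernel_gp, peak_mpa, cfg, frac_env,
                           cavity = cavity, precomp = precomp)
    if (!res$converged) {
      sol <- build_solution(mesh, field, nodes, U[, seq_len(k), drop = FALSE],
                            schedule[seq_len(k - 1), , drop = FALSE], info)
      stop(structure(class = c("apdi_solver_error", "error", "condition"),
                     list(message = sprintf(
                       "solver failed at step %d (iop %.3g mmHg, puff %.3g)",
                       k, schedule$iop_mmhg[k], schedule$puff_frac[k]),
                       call = sys.call(-1), last_solution = sol)))
    }
    u <- res$u
    U[, k + 1] <- u
    info[[k]] <- c(iters = res$iters, resid = res$resid)
    load_prev <- load_k
  }
  build_solution(mesh, field, nodes, U, schedule, info)
}

build_solution <- function(mesh, field, nodes, U, schedule, info) {
  K <- ncol(U) - 1L
  it <- vapply(info[seq_len(K)], function(z) unname(z["iters"]), 0)
  rs <- vapply(info[seq_len(K)], function(z) unname(z["resid"]), 0)
  steps <- tibble::tibble(
    step = 0:K,
    iop_mmhg = c(0, schedule$iop_mmhg[seq_len(K)]),
    puff_frac = c(0, schedule$puff_frac[seq_len(K)]),
    converged = TRUE,
    iters = c(0L, as.integer(it)),
    resid = c(0, rs))
  structure(list(mesh = mesh, field = field, nodes0 = nodes, U = U,
                 steps = steps),
            class = "apdi_solution")
}

#' @export
print.apdi_solution <- function(x, ...) {
  cat(sprintf("FE solution: %d load steps on %d dofs\n",
              nrow(x$steps) - 1L, nrow(x$U)))
  print(x$steps, n = nrow(x$steps))
  invisible(x)
}

#' Nodal positions at a load step
#' @param sol an `apdi_solution`.
#' @param step step index (0 = reference configuration).
#' @return N x 3 matrix of positions, mm.
#' @export
node_positions <- function(sol, step) {
  stopifnot(step >= 0, step <= nrow(sol$steps) - 1)
  sol$nodes0 + matrix(sol$U[, step + 1L], ncol = 3, byrow = TRUE)
}

#' Follower pressure load vector on a face set
#'
#' Consistent nodal forces of a pressure acting on the deformed surface along
#' minus the stored face normal (which points away from the material).
#'
#' @param mesh an `apdi_mesh`.
#' @param faces face matrix (F x 8 node ids), e.g. `mesh$sets$inner_faces`.
#' @param pressure scalar (MPa) or F x 9 matrix of gauss-point pressures.
#' @param u displacement vector (3N), default zero.
#' @return load vector of length 3N, Newtons.
#' @export
follower_pressure_load <- function(mesh, faces, pressure, u = NULL) {
  u <- u %||% numeric(3L * nrow(mesh$nodes))
  if (is.matrix(pressure)) pgp <- pressure
  else pgp <- matrix(pressure, nrow(faces), 9)
  as.numeric(.surface_load(mesh$nodes, u, faces, pgp, integer(0), 0L,
                           FALSE)$fext)
}

#' Cavity volume enclosed by the inner surface
#'
#' Volume of the fluid cavity bounded by the inner wall surface and the two
#' symmetry planes, by divergence-theorem quadrature over the inner faces.
#'
#' @param mesh an `apdi_mesh`.
#' @param u displacement vector (3N), default zero.
#' @return volume, mm^3 (quarter model).
#' @export
cavity_volume <- function(mesh, u = NULL) {
  u <- u %||% numeric(3L * nrow(mesh$nodes))
  cavity_volume_at_faces(mesh$nodes, u, mesh$sets$inner_faces)
}

cavity_volume_at_faces <- function(nodes, u, faces) {
  gp <- .face_gp_data(nodes, u, faces)
  # stored inner-face normals point into the cavity; the symmetry-plane
  # closures have zero x-normal, so V = -sum x * n_x dA
  -sum(gp$pos[, 1] * gp$normal[, 1] * gp$da)
}

#' Mean Cauchy stress per element
#' @param sol an `apdi_solution`.
#' @param step load step.
#' @return E x 6 matrix, Voigt order (11, 22, 33, 12, 23, 13), MPa.
#' @export
element_stresses <- function(sol, step) {
  .element_cauchy(sol$nodes0, sol$mesh$conn, sol$U[, step + 1L],
                  sol$field$mu_el, sol$field$nhalf, sol$field$kappa)
}
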