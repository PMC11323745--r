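# End-to-end forward model: one virtual eye in, deformation outputs out.

#' Run the forward air-puff deformation model
#'
#' Builds the globe, meshes it, applies the IOP preload through the
#' stress-free iteration, runs the air-puff ramp, and computes the
#' deformation outputs. This is the single code path used by the parametric
#' studies, the inverse fit, and the synthetic-data generator.
#'
#' @param params a [globe_params()].
#' @param mu,mu_post,alpha,mu_cornea,kappa_ratio material settings, see
#'   [material_field()].
#' @param iop_mmhg intraocular pressure, mmHg.
#' @param profile an [airpuff_profile()].
#' @param resolution,ns mesh resolution controls, see [generate_mesh()].
#' @param cfg a [solver_config()].
#' @param stress_free_iters iterations of [stress_free_iterate()].
#' @param reference a previous `apdi_forward` result (or `apdi_stress_free`)
#'   whose stress-free geometry is reused unchanged (`fixed_at_reference`
#'   mode: the unloaded eye is kept, only the IOP changes). Default:
#'   stress-free iteration re-run at `iop_mmhg` (`per_iop` mode).
#' @param mesh optionally reuse an existing `apdi_mesh` (must match `params`).
#' @param cavity,cavity_bulk_kpa cavity-pressure mode, see [run_airpuff()].
#' @return an object of class `apdi_forward`: list with the mesh, the
#'   stress-free state, the air-puff `apdi_solution`, the initial and final
#'   sagittal profiles, and `outputs` (one-row tibble: AD, CPR, AR, heights).
#' @export
run_forward <- function(params = globe_params(), mu = 0.083, mu_post = mu,
                        alpha = 40, mu_cornea = 0.083, kappa_ratio = 1000,
                        iop_mmhg = 18, profile = airpuff_profile(),
                        resolution = 5000, ns = 2, cfg = solver_config(),
                        stress_free_iters = 3, reference = NULL,
                        mesh = NULL,
                        cavity = "constant", cavity_bulk_kpa = 400) {
  if (is.null(reference)) {
    mesh <- mesh %||% generate_mesh(params, resolution = resolution, ns = ns)
    field <- material_field(mesh, mu = mu, mu_post = mu_post, alpha = alpha,
                            mu_cornea = mu_cornea, kappa_ratio = kappa_ratio)
    bcs <- boundary_conditions(mesh)
    sf <- stress_free_iterate(mesh, field, bcs, iop_mmhg,
                              n_iter = stress_free_iters, cfg = cfg)
  } else {
    sf <- if (inherits(reference, "apdi_forward")) reference$stress_free
          else reference
    stopifnot(inherits(sf, "apdi_stress_free"))
    if (!isTRUE(all.equal(mu, sf$field$mu)) ||
        !isTRUE(all.equal(mu_post, sf$field$mu_post)))
      stop("fixed-at-reference mode keeps the reference's material; ",
           "rebuild the reference to change mu")
    sf <- pressurize(sf, iop_mmhg, cfg = cfg)
  }
  sol <- run_airpuff(sf, profile = profile, cfg = cfg,
                     cavity = cavity, cavity_bulk_kpa = cavity_bulk_kpa)
  # release factorisation externalptrs promptly (kept alive only by pending
  # finalizers; long parameter studies run thousands of factorisations)
  gc(verbose = FALSE)
  initial <- extract_sagittal_profile(sol, step = 1L)
  final <- extract_sagittal_profile(sol, step = nrow(sol$steps) - 1L)
  outputs <- compute_output_params(initial, final)
  structure(list(mesh = sf$mesh, stress_free = sf, solution = sol,
                 profile_initial = initial, profile_final = final,
                 outputs = outputs,
                 settings = list(params = unclass(sf$mesh$params), mu = mu,
                                 mu_post = mu_post, alpha = alpha,
                                 mu_cornea = mu_cornea, iop_mmhg = iop_mmhg,
                                 profile = unclass(profile),
                                 resolution = resolution, ns = ns)),
            class = "apdi_forward")
}

#' @export
print.apdi_forward <- function(x, ...) {
  s <- x$settings
  cat(sprintf("Forward APDI model: mu = %g MPa, mu_post = %g, IOP = %g mmHg\n",
              s$mu, s$mu_post, s$iop_mmhg))
  cat(sprintf("  AD = %.4f mm, CPR = %.3f, AR = %.3f\n",
              x$outputs$AD, x$outputs$CPR, x$outputs$AR))
  invisible(x)
}

#' Apex displacement of a forward run
#' @param fwd an `apdi_forward`.
#' @return AD in mm.
#' @export
apex_displacement <- function(fwd) fwd$outputs$AD
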