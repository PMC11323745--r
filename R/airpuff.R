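# Air-puff load: spatially distributed follower pressure on the equatorial
# scleral surface, ramped linearly over quasi-static load steps.

#' Air-puff pressure profile
#'
#' The puff is modelled as a unit-peak spatial kernel centred at the
#' uppermost equatorial point, scaled by a linear temporal ramp over
#' `n_steps` quasi-static steps to `peak_kpa` at the final step. The total
#' event time is bookkeeping only (no inertia is modelled).
#'
#' The default Gaussian width (FWHM 3.35 mm) is the package's one calibrated
#' load parameter: the measured spatial pressure distribution of the air-puff
#' unit is not published, so the width is set once so that the baseline globe
#' (all inputs at their initial values) deforms by the stated 1-mm apex
#' displacement. The 2.4-mm nozzle bore remains available via
#' `airpuff_profile(fwhm_mm = 2.4)`; see the methods vignette.
#'
#' @param peak_kpa peak pressure at the puff centre, kPa.
#' @param n_steps number of quasi-static load steps.
#' @param total_time_ms nominal event duration, ms (bookkeeping only).
#' @param kernel spatial kernel: `"gaussian"` (unit peak, width set by
#'   `fwhm_mm`) or `"uniform"` (unit value within radius `fwhm_mm / 2`).
#' @param fwhm_mm kernel width parameter, mm.
#' @return an object of class `airpuff_profile`.
#' @export
airpuff_profile <- function(peak_kpa = 15.4, n_steps = 6, total_time_ms = 20,
                            kernel = c("gaussian", "uniform"),
                            fwhm_mm = 3.35) {
  kernel <- match.arg(kernel)
  stopifnot(peak_kpa > 0, n_steps >= 1, fwhm_mm > 0)
  structure(list(peak_kpa = peak_kpa, n_steps = as.integer(n_steps),
                 total_time_ms = total_time_ms, kernel = kernel,
                 fwhm_mm = fwhm_mm),
            class = "airpuff_profile")
}

kernel_value <- function(profile, r) {
  switch(profile$kernel,
         gaussian = {
           sigma <- profile$fwhm_mm / (2 * sqrt(2 * log(2)))
           exp(-r^2 / (2 * sigma^2))
         },
         uniform = as.numeric(r <= profile$fwhm_mm / 2))
}

#' Air-puff pressure at a surface point and load step
#'
#' `p(r, k) = peak * (k / n_steps) * K(r)`, where `r` is the distance from
#' the puff centre (chordal distance in the pre-puff configuration, a
#' geodesic approximation) and `K` the unit-peak spatial kernel.
#'
#' @param profile an [airpuff_profile()].
#' @param r distance(s) from the puff centre, mm.
#' @param k load-step index, `1 <= k <= n_steps`.
#' @return pressure, kPa.
#' @export
#' @examples
#' pressure_at(airpuff_profile(), r = 0, k = 6)   # 15.4
#' pressure_at(airpuff_profile(), r = 1.2, k = 6) # half the peak (r = FWHM/2)
pressure_at <- function(profile, r, k) {
  stopifnot(inherits(profile, "airpuff_profile"), k >= 1, k <= profile$n_steps)
  profile$peak_kpa * (k / profile$n_steps) * kernel_value(profile, r)
}

# Unit-peak kernel values at the gauss points of the air-puff patch faces,
# evaluated in the configuration nodes + u (the pre-puff state).
airpuff_kernel_gp <- function(mesh, profile, nodes = mesh$nodes, u = NULL) {
  u <- u %||% numeric(3L * nrow(nodes))
  patch <- mesh$sets$outer_faces[mesh$sets$airpuff_idx, , drop = FALSE]
  gp <- .face_gp_data(nodes, u, patch)
  ctr <- mesh$sets$puff_center
  r <- sqrt((gp$pos[, 1] - ctr[1])^2 + (gp$pos[, 2] - ctr[2])^2 +
              (gp$pos[, 3] - ctr[3])^2)
  matrix(kernel_value(profile, r), nrow(patch), 9, byrow = TRUE)
}

#' Apply the air-puff to a pressurised globe
#'
#' Continues a solution from the IOP-preloaded state through the air-puff
#' ramp: the intraocular pressure is held, and the puff pressure rises
#' linearly over `profile$n_steps` steps to its peak. The kernel footprint is
#' fixed in the pre-puff configuration; the load itself follows the deforming
#' surface normals.
#'
#' @param state an `apdi_stress_free` state (see [stress_free_iterate()]) or
#'   an `apdi_solution` whose last step is the IOP-only preload.
#' @param profile an [airpuff_profile()].
#' @param bcs boundary conditions (defaults to [boundary_conditions()] of the
#'   state's mesh).
#' @param cfg a [solver_config()].
#' @param cavity `"constant"` holds the IOP during the puff (default, the
#'   IOP is a prescribed independent input); `"coupled"` lets the cavity
#'   pressure rise with cavity-volume reduction, solved monolithically.
#' @param cavity_bulk_kpa effective cavity stiffness for the coupled mode:
#'   pressure increase in kPa per unit relative volume reduction. The default
#'   corresponds to an ocular-rigidity-like 4 kPa rise per 1 percent volume
#'   displaced.
#' @return an `apdi_solution` whose step 1 is the pre-puff (IOP-only) state
#'   and whose last step is the full puff.
#' @export
run_airpuff <- function(state, profile = airpuff_profile(), bcs = NULL,
                        cfg = solver_config(),
                        cavity = c("constant", "coupled"),
                        cavity_bulk_kpa = 400) {
  cavity <- match.arg(cavity)
  if (inherits(state, "apdi_stress_free")) {
    mesh <- state$mesh; field <- state$field
    nodes <- state$Xi; u_pre <- state$u_pressurized
    iop <- state$iop_mmhg
    st <- state$structure
  } else stop("state must be an apdi_stress_free object")
  bcs <- bcs %||% state$bcs %||% boundary_conditions(mesh)
  st <- st %||% fe_structure_cached(mesh, bcs)

  kernel_gp <- airpuff_kernel_gp(mesh, profile, nodes = nodes, u = u_pre)
  n <- profile$n_steps
  schedule <- data.frame(iop_mmhg = rep(iop, n + 1),
                         puff_frac = c(0, seq_len(n) / n))
  cav <- NULL
  if (cavity == "coupled") {
    # reference volume from the pre-puff state: the puff then raises the
    # cavity pressure in proportion to the relative volume it displaces
    cav <- list(bulk_mpa = kpa_to_mpa(cavity_bulk_kpa),
                V0 = cavity_volume_at_faces(nodes, u_pre,
                                            mesh$sets$inner_faces))
  }
  solve_static(mesh, field, bcs, schedule, profile = profile,
               cfg = cfg, nodes = nodes, u0 = u_pre, structure = st,
               kernel_gp = kernel_gp, cavity = cav)
}
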