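# Sagittal surface profiles and the three deformation statistics:
#   AD  = Y0 - y0                   apex displacement, mm
#   CPR = (Y0 - y0) / (Y2 - y2)     central-peripheral ratio
#   AR  = (Y2 - y2) / (Y-2 - y-2)   asymmetry ratio
# Heights Y (initial, pre-puff) and y (final) are sampled at fixed scan-frame
# stations x = -2, 0, +2 mm (Eulerian sampling, as an OCT B-scan segmentation
# measures height at fixed lateral position). The scan frame has x = 0 at the
# scleral apex and +x toward the posterior pole.

#' Extract the sagittal outer-surface profile at a load step
#'
#' Outer-surface nodes on the sagittal symmetry plane, ordered along the
#' meridian and mapped to the scan frame: `x` is the signed axial distance
#' from the scleral apex (positive toward the posterior pole), `y` the height
#' toward the air-puff source. The apex is the highest point of the pre-puff
#' configuration of the same solution, so initial/final profiles share one
#' frame.
#'
#' @param sol an `apdi_solution` (typically from [run_airpuff()]).
#' @param step load step to extract (default: last).
#' @return a tibble of class `apdi_profile` with columns `x`, `y`, `t`
#'   (meridian parameter) and `node`; attributes carry the frame origin and
#'   step.
#' @export
extract_sagittal_profile <- function(sol, step = nrow(sol$steps) - 1L) {
  mesh <- sol$mesh
  sel <- which(mesh$node_s == 1 & abs(mesh$node_psi) < 1e-12)
  sel <- sel[order(mesh$node_t[sel])]
  if (length(sel) < 5) stop("resolution error: too few sagittal surface nodes")

  pre_step <- max(sol$steps$step[sol$steps$puff_frac == 0])
  pos_pre <- node_positions(sol, pre_step)
  apex_node <- sel[which.max(pos_pre[sel, 2])]
  x_apex <- pos_pre[apex_node, 1]

  pos <- node_positions(sol, step)
  out <- tibble::tibble(
    x = x_apex - pos[sel, 1],
    y = pos[sel, 2],
    t = mesh$node_t[sel],
    node = sel)
  if (sum(out$x >= -2 & out$x <= 2) < 5)
    stop("resolution error: fewer than 5 profile nodes across [-2, 2] mm")
  structure(out, class = c("apdi_profile", class(out)),
            x_apex = x_apex, step = step, apex_node = apex_node)
}

profile_fun <- function(profile) {
  o <- order(profile$x)
  splinefun(profile$x[o], profile$y[o], method = "monoH.FC")
}

#' Surface displacement between two profiles at a scan station
#'
#' `Y(x) - y(x)` with both heights interpolated at the fixed lab-frame
#' station `x` by monotone (shape-preserving) cubic interpolation.
#'
#' @param initial,final `apdi_profile` objects sharing a frame.
#' @param x scan station(s), mm.
#' @return displacement(s), mm.
#' @export
displacement_at_x <- function(initial, final, x) {
  rng <- c(max(min(initial$x), min(final$x)),
           min(max(initial$x), max(final$x)))
  if (any(x < rng[1] | x > rng[2]))
    stop("range error: station outside both profiles")
  profile_fun(initial)(x) - profile_fun(final)(x)
}

#' Deformation output parameters AD, CPR, AR
#'
#' @param initial pre-puff `apdi_profile` (heights `Y`).
#' @param final peak-load `apdi_profile` (heights `y`).
#' @param eps denominators smaller than this (mm) make the corresponding
#'   ratio undefined; it is reported as `NA` with a warning.
#' @return a one-row tibble of class `apdi_outputs`: `AD` (mm), `CPR`, `AR`,
#'   and the six sampled heights `Y_m2, Y_0, Y_2, y_m2, y_0, y_2` (mm).
#' @export
compute_output_params <- function(initial, final, eps = 1e-6) {
  fi <- profile_fun(initial)
  ff <- profile_fun(final)
  Y <- fi(c(-2, 0, 2))
  y <- ff(c(-2, 0, 2))
  d <- Y - y                      # displacements at x = -2, 0, +2
  AD <- d[2]
  CPR <- if (abs(d[3]) < eps) {
    warning("CPR undefined: displacement at x = +2 mm below tolerance")
    NA_real_
  } else d[2] / d[3]
  AR <- if (abs(d[1]) < eps) {
    warning("AR undefined: displacement at x = -2 mm below tolerance")
    NA_real_
  } else d[3] / d[1]
  structure(tibble::tibble(
    AD = AD, CPR = CPR, AR = AR,
    Y_m2 = Y[1], Y_0 = Y[2], Y_2 = Y[3],
    y_m2 = y[1], y_0 = y[2], y_2 = y[3]),
    class = c("apdi_outputs", class(tibble::tibble())))
}

#' Read an externally segmented profile
#'
#' Accepts a two-column (x, y) CSV, e.g. a segmented OCT surface, so measured
#' curves can be scored by the same code path as simulated ones.
#'
#' @param path CSV file with columns `x` and `y` (mm).
#' @return an `apdi_profile` tibble.
#' @export
read_profile_csv <- function(path) {
  d <- readr::read_csv(path, show_col_types = FALSE)
  stopifnot(all(c("x", "y") %in% names(d)))
  out <- tibble::tibble(x = d$x, y = d$y, t = NA_real_, node = NA_integer_)
  structure(out[order(out$x), ], class = c("apdi_profile", class(out)),
            x_apex = NA_real_, step = NA_integer_)
}

#' Write a profile to CSV
#' @param profile an `apdi_profile`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_profile_csv <- function(profile, path) {
  readr::write_csv(profile[, c("x", "y")], path)
  invisible(path)
}
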