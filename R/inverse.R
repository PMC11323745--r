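# Inverse estimation of the scleral material coefficient from AD-vs-IOP data:
# bounded scalar minimization of the squared apex-displacement mismatch at
# the 10 mmHg reference, then prediction at the held-out IOPs with the
# reference stress-free geometry kept fixed.

#' AD-vs-IOP measurement curve
#'
#' @param iop_mmhg intraocular pressures, mmHg (strictly increasing).
#' @param ad_mm measured apex displacements, mm (positive).
#' @param location scleral location label (S, I, EN or ET).
#' @param eye eye label.
#' @return a tibble of class `apdi_ad_curve`.
#' @export
ad_curve <- function(iop_mmhg, ad_mm, location = NA_character_,
                     eye = NA_character_) {
  stopifnot(length(iop_mmhg) == length(ad_mm),
            all(diff(iop_mmhg) > 0), all(ad_mm > 0))
  out <- tibble::tibble(eye = eye, location = location,
                        iop_mmhg = iop_mmhg, ad_mm = ad_mm)
  structure(out, class = c("apdi_ad_curve", class(out)))
}

#' Squared apex-displacement mismatch at the reference IOP
#'
#' Runs the forward model at the reference IOP (stress-free iteration at that
#' IOP) with material coefficient `mu` and returns the squared difference
#' between the simulated and the target apex displacement. Solver failures
#' return a large finite penalty (with a warning) so that a bounded search
#' can complete.
#'
#' @param mu material coefficient, MPa.
#' @param target_ad measured apex displacement at the reference IOP, mm.
#' @param context model context from [inverse_context()].
#' @return squared error, mm^2 (the successful forward run is attached as
#'   attribute `forward` so callers can reuse it).
#' @export
f_apex <- function(mu, target_ad, context) {
  stopifnot(mu > 0)
  # the simulated AD is independent of the fitted target, so evaluations are
  # memoised on mu within a context (bracketing probes repeat across fits)
  key <- paste0("mu_", signif(mu, 15))
  fwd <- if (!is.null(context$memo)) context$memo[[key]]
  if (is.null(fwd)) {
    fwd <- tryCatch(
      run_forward(context$params, mu = mu,
                  mu_post = context$mu_post_ratio * mu,
                  alpha = context$alpha, mu_cornea = context$mu_cornea,
                  iop_mmhg = context$reference_iop, profile = context$profile,
                  resolution = context$resolution, ns = context$ns,
                  cfg = context$cfg,
                  stress_free_iters = context$stress_free_iters),
      apdi_solver_error = function(e) NULL)
    if (!is.null(fwd) && !is.null(context$memo)) context$memo[[key]] <- fwd
  }
  if (is.null(fwd)) {
    warning("forward solve failed at mu = ", signif(mu, 4),
            "; penalty value returned")
    return(structure(1e6, forward = NULL))
  }
  structure((fwd$outputs$AD - target_ad)^2, forward = fwd)
}

#' Model context for the inverse fit
#'
#' Everything the inverse fit holds fixed: the common globe geometry, the
#' posterior-coefficient ratio, the air-puff profile, mesh resolution and
#' solver settings.
#'
#' @param params a [globe_params()] (the common geometry).
#' @param mu_post_ratio posterior/equatorial coefficient ratio kept during
#'   the fit.
#' @param alpha,mu_cornea material settings.
#' @param profile an [airpuff_profile()].
#' @param resolution,ns mesh controls.
#' @param cfg a [solver_config()].
#' @param stress_free_iters stress-free iterations.
#' @param reference_iop IOP of the fitted measurement, mmHg.
#' @return a list used by [f_apex()] and [estimate_mu()].
#' @export
inverse_context <- function(params = globe_params(), mu_post_ratio = 1,
                            alpha = 40, mu_cornea = 0.083,
                            profile = airpuff_profile(),
                            resolution = 5000, ns = 2,
                            cfg = solver_config(), stress_free_iters = 3,
                            reference_iop = 10) {
  list(params = params, mu_post_ratio = mu_post_ratio, alpha = alpha,
       mu_cornea = mu_cornea, profile = profile, resolution = resolution,
       ns = ns, cfg = cfg, stress_free_iters = stress_free_iters,
       reference_iop = reference_iop,
       memo = new.env(parent = emptyenv()))
}

#' Estimate the scleral material coefficient from an AD-vs-IOP curve
#'
#' Minimises [f_apex()] over `mu` within `bounds` using bounded scalar
#' minimization (golden-section search with successive parabolic
#' interpolation, via [stats::optimize()]), fitting the apex displacement at
#' the reference IOP (10 mmHg). The fitted model is then evaluated at the
#' held-out IOPs, reusing the reference stress-free geometry unchanged, and
#' scored by RMSE against the held-out measurements.
#'
#' @param curve an [ad_curve()] with an entry at the reference IOP.
#' @param bounds search interval for `mu`, MPa.
#' @param tol absolute convergence tolerance on `mu`, MPa.
#' @param context an [inverse_context()].
#' @return an object of class `apdi_inverse_fit`: estimated `mu_hat` (MPa),
#'   objective at the optimum (mm^2), predictions at the held-out IOPs,
#'   `rmse` (mm), the evaluation trace, and a boundary flag.
#' @export
estimate_mu <- function(curve, bounds = c(0.05, 0.15), tol = 1e-4,
                        context = inverse_context()) {
  stopifnot(inherits(curve, "apdi_ad_curve"), length(bounds) == 2,
            bounds[1] > 0, bounds[1] < bounds[2])
  ref <- context$reference_iop
  if (!any(curve$iop_mmhg == ref))
    stop("input error: curve has no entry at the reference IOP (",
         ref, " mmHg)")
  target <- curve$ad_mm[curve$iop_mmhg == ref][1]

  trace <- new.env(parent = emptyenv())
  trace$mu <- numeric(0); trace$f <- numeric(0); trace$fwd <- NULL
  obj <- function(m) {
    r <- f_apex(m, target, context)
    v <- as.numeric(r)
    trace$mu <- c(trace$mu, m)
    trace$f <- c(trace$f, v)
    if (!is.null(attr(r, "forward")) && v <= min(trace$f, na.rm = TRUE))
      trace$fwd <- attr(r, "forward")
    v
  }
  opt <- optimize(obj, interval = bounds, tol = tol)
  mu_hat <- opt$minimum
  at_boundary <- min(mu_hat - bounds[1], bounds[2] - mu_hat) < 2 * tol
  if (at_boundary)
    warning("optimum at a search boundary: mu = ", signif(mu_hat, 4))

  # best evaluated forward run (the minimizer's last evaluation may not be
  # the minimum); re-run only if the kept run is not at mu_hat
  fwd_ref <- trace$fwd
  if (is.null(fwd_ref) ||
      abs(trace$mu[which.min(trace$f)] - mu_hat) > .Machine$double.eps) {
    best <- f_apex(mu_hat, target, context)
    if (!is.null(attr(best, "forward"))) fwd_ref <- attr(best, "forward")
  }
  if (is.null(fwd_ref)) stop("inverse fit failed: no successful forward solve")

  held <- curve[curve$iop_mmhg != ref, ]
  preds <- tibble::tibble(iop_mmhg = ref, ad_pred = fwd_ref$outputs$AD,
                          ad_meas = target)
  if (nrow(held)) {
    pred_ad <- vapply(held$iop_mmhg, function(iop) {
      fwd <- run_forward(context$params, mu = mu_hat,
                         mu_post = context$mu_post_ratio * mu_hat,
                         alpha = context$alpha,
                         mu_cornea = context$mu_cornea,
                         iop_mmhg = iop, profile = context$profile,
                         cfg = context$cfg, reference = fwd_ref)
      fwd$outputs$AD
    }, 0)
    preds <- dplyr::bind_rows(preds, tibble::tibble(
      iop_mmhg = held$iop_mmhg, ad_pred = pred_ad, ad_meas = held$ad_mm))
  }
  rmse_val <- if (nrow(held)) {
    rmse(preds$ad_pred[preds$iop_mmhg != ref],
         preds$ad_meas[preds$iop_mmhg != ref])
  } else NA_real_

  structure(list(mu_hat = mu_hat, objective = opt$objective,
                 predictions = preds, rmse = rmse_val,
                 trace = tibble::tibble(mu = trace$mu, f = trace$f),
                 at_boundary = at_boundary, bounds = bounds, tol = tol,
                 curve = curve, context = context,
                 reference_forward = fwd_ref),
            class = "apdi_inverse_fit")
}

#' @export
print.apdi_inverse_fit <- function(x, ...) {
  cat(sprintf("Inverse fit: mu = %.4f MPa (objective %.3g mm^2, %d evaluations)\n",
              x$mu_hat, x$objective, nrow(x$trace)))
  if (x$at_boundary) cat("  ! optimum at a search boundary\n")
  if (is.finite(x$rmse))
    cat(sprintf("  held-out RMSE = %.4f mm over IOP %s mmHg\n", x$rmse,
                paste(setdiff(x$predictions$iop_mmhg,
                              x$context$reference_iop), collapse = "/")))
  invisible(x)
}

#' Root-mean-square error between paired vectors
#'
#' Pairing is positional (by IOP in the inverse fit).
#'
#' @param predicted,measured numeric vectors of equal length.
#' @return RMSE in the units of the inputs.
#' @export
#' @examples
#' rmse(c(1.0, 0.8), c(1.1, 0.7)) # 0.1
rmse <- function(predicted, measured) {
  if (length(predicted) != length(measured))
    stop("input error: length mismatch")
  if (length(predicted) < 1) stop("input error: empty vectors")
  sqrt(mean((predicted - measured)^2))
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @rdname estimate_mu
#' @param x an `apdi_inverse_fit`.
#' @param ... unused.
#' @export
tidy.apdi_inverse_fit <- function(x, ...) {
  tibble::tibble(term = "mu", estimate = x$mu_hat,
                 objective = x$objective, at_boundary = x$at_boundary,
                 eye = x$curve$eye[1], location = x$curve$location[1])
}

#' @rdname estimate_mu
#' @export
glance.apdi_inverse_fit <- function(x, ...) {
  tibble::tibble(mu_hat = x$mu_hat, objective = x$objective,
                 rmse = x$rmse, n_evaluations = nrow(x$trace),
                 at_boundary = x$at_boundary)
}
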