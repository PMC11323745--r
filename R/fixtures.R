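# Synthetic-data generation: pseudo-experimental AD-vs-IOP tables emulating
# ex vivo air-puff measurements (several eyes, four scleral locations, IOP
# stepped over 10-25 mmHg, additive Gaussian measurement noise).

#' Generate a synthetic AD-vs-IOP experiment
#'
#' For each eye x location, draws a true material coefficient uniformly from
#' `mu_range`, forward-simulates the apex displacement at each IOP (the
#' stress-free geometry is computed at the reference IOP and reused for the
#' higher IOPs, as in the measurement protocol being emulated), and adds
#' independent Gaussian measurement noise. The default noise level (0.13 mm)
#' sits mid-way in the 0.08-0.18 mm spread of reported experimental standard
#' deviations.
#'
#' @param n_eyes number of eyes.
#' @param locations scleral location labels.
#' @param mu_range range for the true coefficient draw, MPa.
#' @param noise_sigma measurement noise standard deviation, mm.
#' @param seed RNG seed (mandatory).
#' @param iops IOP levels, mmHg; the first is the reference.
#' @param params common globe geometry.
#' @param mu_post_ratio posterior/equatorial ratio of the simulated eyes.
#' @param profile an [airpuff_profile()].
#' @param resolution,ns mesh controls.
#' @param cfg a [solver_config()].
#' @param stress_free_iters stress-free iterations at the reference IOP.
#' @return an object of class `apdi_synthetic_experiment`: `curves` (tibble:
#'   eye, location, iop_mmhg, ad_mm, ad_true), `truth` (tibble: eye,
#'   location, mu_true), plus the generator settings.
#' @export
generate_synthetic_experiment <- function(n_eyes = 3,
                                          locations = c("S", "I", "EN", "ET"),
                                          mu_range = c(0.06, 0.14),
                                          noise_sigma = 0.13, seed,
                                          iops = c(10, 15, 20, 25),
                                          params = globe_params(),
                                          mu_post_ratio = 1,
                                          profile = airpuff_profile(),
                                          resolution = 5000, ns = 2,
                                          cfg = solver_config(),
                                          stress_free_iters = 3) {
  stopifnot(!missing(seed), n_eyes >= 1, length(iops) >= 1,
            mu_range[1] > 0, mu_range[1] < mu_range[2], noise_sigma >= 0)
  set.seed(seed)
  grid <- tidyr::expand_grid(eye = paste0("Eye", seq_len(n_eyes)),
                             location = locations)
  grid$mu_true <- runif(nrow(grid), mu_range[1], mu_range[2])
  noise <- matrix(rnorm(nrow(grid) * length(iops), 0, noise_sigma),
                  nrow(grid), length(iops))

  mesh <- generate_mesh(params, resolution = resolution, ns = ns)
  curves <- vector("list", nrow(grid))
  for (i in seq_len(nrow(grid))) {
    ad_true <- tryCatch(
      forward_ad_curve(params, grid$mu_true[i], mu_post_ratio, iops, profile,
                       resolution, ns, cfg, stress_free_iters, mesh),
      apdi_solver_error = function(e) NULL)
    if (is.null(ad_true)) {
      # forward failure: redraw the coefficient for this eye/location
      grid$mu_true[i] <- runif(1, mu_range[1], mu_range[2])
      ad_true <- forward_ad_curve(params, grid$mu_true[i], mu_post_ratio,
                                  iops, profile, resolution, ns, cfg,
                                  stress_free_iters, mesh)
      warning("forward failure for ", grid$eye[i], "/", grid$location[i],
              "; coefficient redrawn")
    }
    curves[[i]] <- tibble::tibble(
      eye = grid$eye[i], location = grid$location[i],
      iop_mmhg = iops, ad_true = ad_true,
      ad_mm = pmax(ad_true + noise[i, ], 1e-3))
  }
  structure(list(curves = dplyr::bind_rows(curves),
                 truth = grid,
                 noise_sigma = noise_sigma, seed = seed,
                 mu_range = mu_range, iops = iops,
                 settings = list(params = unclass(params),
                                 mu_post_ratio = mu_post_ratio,
                                 resolution = resolution, ns = ns)),
            class = "apdi_synthetic_experiment")
}

forward_ad_curve <- function(params, mu, mu_post_ratio, iops, profile,
                             resolution, ns, cfg, stress_free_iters, mesh) {
  ref <- run_forward(params, mu = mu, mu_post = mu_post_ratio * mu,
                     iop_mmhg = iops[1], profile = profile,
                     resolution = resolution, ns = ns, cfg = cfg,
                     stress_free_iters = stress_free_iters, mesh = mesh)
  ad <- numeric(length(iops))
  ad[1] <- ref$outputs$AD
  for (k in seq_along(iops)[-1]) {
    fwd <- run_forward(params, mu = mu, mu_post = mu_post_ratio * mu,
                       iop_mmhg = iops[k], profile = profile, cfg = cfg,
                       reference = ref)
    ad[k] <- fwd$outputs$AD
  }
  ad
}

#' @export
print.apdi_synthetic_experiment <- function(x, ...) {
  cat(sprintf(
    "Synthetic APDI experiment: %d curves, noise sd %g mm, seed %s\n",
    nrow(x$truth), x$noise_sigma, format(x$seed)))
  print(x$curves, n = 8)
  invisible(x)
}

#' Write/read AD-vs-IOP curve tables
#'
#' CSV with columns `eye`, `location`, `iop_mmhg`, `ad_mm` (the synthetic
#' generator also stores `ad_true`).
#'
#' @param x an `apdi_synthetic_experiment` or a curves tibble.
#' @param path CSV path.
#' @return `path` (write) / a tibble (read), the read result split-able with
#'   [curves_by_eye_location()].
#' @export
write_ad_curves <- function(x, path) {
  curves <- if (inherits(x, "apdi_synthetic_experiment")) x$curves else x
  readr::write_csv(curves, path)
  invisible(path)
}

#' @rdname write_ad_curves
#' @export
read_ad_curves <- function(path) {
  d <- readr::read_csv(path, show_col_types = FALSE)
  stopifnot(all(c("eye", "location", "iop_mmhg", "ad_mm") %in% names(d)))
  d
}

#' Split a curves table into per-measurement [ad_curve()] objects
#' @param curves tibble with eye, location, iop_mmhg, ad_mm.
#' @return named list of `apdi_ad_curve` objects.
#' @export
curves_by_eye_location <- function(curves) {
  sp <- split(curves, paste(curves$eye, curves$location, sep = "/"))
  lapply(sp, function(d) {
    d <- d[order(d$iop_mmhg), ]
    ad_curve(d$iop_mmhg, d$ad_mm, location = d$location[1], eye = d$eye[1])
  })
}
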