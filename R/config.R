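# Run configuration: a nested list that round-trips through YAML, with a
# content hash embedded in outputs for provenance.

#' Assemble a run configuration
#'
#' @param geometry named list of [globe_params()] arguments (keys `AL`, `EL`,
#'   `THK`, ...).
#' @param material named list: `mu`, and either `mu_post` or `mu_post_ratio`,
#'   plus optional `alpha`, `mu_cornea`, `kappa_ratio`.
#' @param iop_mmhg intraocular pressure, mmHg.
#' @param airpuff named list of [airpuff_profile()] arguments (`peak_kpa`,
#'   `fwhm_mm`, `kernel`, `n_steps`).
#' @param stress_free named list: `iterations`, `mode` (`"per_iop"` or
#'   `"fixed_at_reference"`), `reference_iop`.
#' @param solver named list of [solver_config()] arguments.
#' @param mesh named list: `resolution`, `ns`.
#' @param seed RNG seed recorded with every output.
#' @return an object of class `apdi_config`.
#' @export
run_config <- function(geometry = list(), material = list(mu = 0.083),
                       iop_mmhg = 18, airpuff = list(),
                       stress_free = list(iterations = 3, mode = "per_iop",
                                          reference_iop = 10),
                       solver = list(), mesh = list(resolution = 5000, ns = 2),
                       seed = 1L) {
  cfg <- list(geometry = geometry, material = material, iop_mmhg = iop_mmhg,
              airpuff = airpuff, stress_free = stress_free, solver = solver,
              mesh = mesh, seed = seed)
  validate_config(cfg)
  structure(cfg, class = "apdi_config")
}

validate_config <- function(cfg) {
  known <- c("geometry", "material", "iop_mmhg", "airpuff", "stress_free",
             "solver", "mesh", "seed")
  extra <- setdiff(names(cfg), known)
  if (length(extra)) stop("unknown config keys: ", paste(extra, collapse = ", "))
  mode <- cfg$stress_free$mode %||% "per_iop"
  if (!mode %in% c("per_iop", "fixed_at_reference"))
    stop("config error at stress_free.mode: must be per_iop or fixed_at_reference")
  if (!is.null(cfg$material$mu) && cfg$material$mu <= 0)
    stop("config error at material.mu: must be positive")
  invisible(cfg)
}

#' Read / write a run configuration (YAML)
#' @param path YAML file.
#' @return an `apdi_config` (read); `path` invisibly (write).
#' @export
read_run_config <- function(path) {
  raw <- yaml::read_yaml(path)
  cfg <- do.call(run_config, raw[lengths(raw) > 0])
  cfg
}

#' @rdname read_run_config
#' @param cfg an `apdi_config`.
#' @export
write_run_config <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

#' Content hash of a configuration (provenance tag)
#' @param cfg an `apdi_config` (or any R object).
#' @return character hash.
#' @export
config_hash <- function(cfg) rlang::hash(unclass(cfg))

# Instantiate model pieces from a config. Note [[: `$` would partial-match
# mu_post to mu_post_ratio.
config_pieces <- function(cfg) {
  params <- do.call(globe_params, cfg$geometry)
  mat <- cfg$material
  mu <- mat[["mu"]] %||% 0.083
  mu_post <- mat[["mu_post"]] %||% (mu * (mat[["mu_post_ratio"]] %||% 1))
  profile <- do.call(airpuff_profile, cfg$airpuff)
  solver <- do.call(solver_config, cfg$solver)
  list(params = params, mu = mu, mu_post = mu_post,
       alpha = mat[["alpha"]] %||% 40,
       mu_cornea = mat[["mu_cornea"]] %||% 0.083,
       kappa_ratio = mat[["kappa_ratio"]] %||% 1000,
       profile = profile, cfg = solver,
       resolution = cfg$mesh$resolution %||% 5000, ns = cfg$mesh$ns %||% 2,
       iop_mmhg = cfg$iop_mmhg %||% 18,
       sf_iters = cfg$stress_free$iterations %||% 3,
       sf_mode = cfg$stress_free$mode %||% "per_iop",
       reference_iop = cfg$stress_free$reference_iop %||% 10)
}

#' Run the forward model from a configuration
#' @param cfg an `apdi_config`.
#' @return an `apdi_forward`.
#' @export
run_forward_config <- function(cfg) {
  p <- config_pieces(cfg)
  if (p$sf_mode == "fixed_at_reference" && p$iop_mmhg != p$reference_iop) {
    ref <- run_forward(p$params, mu = p$mu, mu_post = p$mu_post,
                       alpha = p$alpha, mu_cornea = p$mu_cornea,
                       kappa_ratio = p$kappa_ratio,
                       iop_mmhg = p$reference_iop, profile = p$profile,
                       resolution = p$resolution, ns = p$ns, cfg = p$cfg,
                       stress_free_iters = p$sf_iters)
    run_forward(p$params, mu = p$mu, mu_post = p$mu_post, alpha = p$alpha,
                mu_cornea = p$mu_cornea, iop_mmhg = p$iop_mmhg,
                profile = p$profile, cfg = p$cfg, reference = ref)
  } else {
    run_forward(p$params, mu = p$mu, mu_post = p$mu_post, alpha = p$alpha,
                mu_cornea = p$mu_cornea, kappa_ratio = p$kappa_ratio,
                iop_mmhg = p$iop_mmhg, profile = p$profile,
                resolution = p$resolution, ns = p$ns, cfg = p$cfg,
                stress_free_iters = p$sf_iters)
  }
}
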