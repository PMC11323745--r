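# One-term Ogden incompressible hyperelastic law with linear axial grading of
# the material coefficient. The 3D stress and consistent tangent are computed
# in compiled code from W = (mu/alpha) (tr(Cbar^(alpha/2)) - 3) + kappa/2 (J-1)^2,
# which reduces exactly to sigma = mu (lambda^alpha - lambda^(-alpha/2)) under
# incompressible uniaxial tension. The closed-form tensor route requires alpha
# to be a positive even integer (the model fixes alpha = 40).

#' One-term Ogden material
#'
#' @param mu material coefficient, MPa; sets the magnitude of the stress
#'   response.
#' @param alpha dimensionless exponent; sets the shape (strain stiffening) of
#'   the stress-strain curve. Must be a positive even integer for the 3D
#'   solver; fixed at 40 for the scleral model.
#' @param kappa_ratio numerical bulk modulus expressed as a multiple of
#'   `mu * alpha` (near-incompressibility penalty; a solver parameter, not a
#'   tissue property). Must be at least 1000.
#' @return an object of class `ogden_material`.
#' @export
ogden_material <- function(mu = 0.083, alpha = 40, kappa_ratio = 1000) {
  stopifnot(mu > 0, alpha > 0, kappa_ratio >= 1000)
  structure(list(mu = mu, alpha = alpha, kappa = kappa_ratio * mu * alpha,
                 kappa_ratio = kappa_ratio),
            class = "ogden_material")
}

check_even_alpha <- function(alpha) {
  if (abs(alpha - round(alpha)) > 1e-9 || round(alpha) %% 2 != 0 || alpha <= 0)
    stop("the 3D Ogden implementation requires a positive even integer alpha")
  as.integer(round(alpha)) %/% 2L
}

#' Uniaxial Cauchy stress of the one-term Ogden model
#'
#' Closed form under incompressible uniaxial tension:
#' `sigma = mu * (lambda^alpha - lambda^(-alpha/2))`.
#'
#' @param mat an [ogden_material()] (or anything with `mu` and `alpha`).
#' @param lambda stretch ratio(s), must be positive.
#' @return Cauchy stress, MPa.
#' @export
#' @examples
#' uniaxial_cauchy_stress(ogden_material(0.083, 40), 1.02)
uniaxial_cauchy_stress <- function(mat, lambda) {
  if (any(lambda <= 0)) stop("stretch ratio must be positive")
  mat$mu * (lambda^mat$alpha - lambda^(-mat$alpha / 2))
}

#' Axially graded material coefficient
#'
#' Linear decrease of the Ogden coefficient from the equator (`x = 0`) to the
#' posterior pole (`x = x_f`): `mu(x) = mu - (mu - mu_post) * x / x_f`.
#' Anterior of the equator (`x < 0`) the coefficient is held at `mu` (the
#' grading models the posterior decrease only).
#'
#' @param x signed axial distance from the equator, mm (positive posterior).
#' @param x_f distance from the equator to the most posterior scleral point, mm.
#' @param mu equatorial material coefficient, MPa.
#' @param mu_post posterior material coefficient, MPa; must satisfy
#'   `mu_post <= mu`.
#' @return material coefficient(s), MPa.
#' @export
#' @examples
#' graded_mu(x = 4.5, x_f = 9, mu = 0.10, mu_post = 0.05) # midpoint: 0.075
graded_mu <- function(x, x_f, mu, mu_post) {
  if (x_f <= 0) stop("degenerate geometry: x_f must be positive")
  if (mu_post > mu) stop("mu_post must not exceed mu")
  xc <- pmin(pmax(x, 0), x_f)
  mu - (mu - mu_post) * xc / x_f
}

#' Per-element material field with axial grading
#'
#' Assigns each scleral element the graded coefficient of [graded_mu()] from
#' its centroid position; corneal elements receive `mu_cornea`.
#'
#' @param mesh an `apdi_mesh`.
#' @param mu equatorial scleral coefficient, MPa.
#' @param mu_post posterior scleral coefficient, MPa (default: no grading).
#' @param alpha Ogden exponent (positive even integer).
#' @param mu_cornea corneal coefficient, MPa.
#' @param kappa_ratio volumetric penalty multiple of `mu * alpha`.
#' @return an object of class `apdi_material_field`.
#' @export
material_field <- function(mesh, mu = 0.083, mu_post = mu, alpha = 40,
                           mu_cornea = 0.083, kappa_ratio = 1000) {
  stopifnot(inherits(mesh, "apdi_mesh"), mu > 0, mu_post > 0, mu_cornea > 0)
  if (mu_post > mu) stop("mu_post must not exceed mu")
  nhalf <- check_even_alpha(alpha)
  ax <- compute_axial_coordinates(mesh)
  mu_el <- ifelse(mesh$region == "sclera",
                  graded_mu(ax$x, ax$x_f, mu, mu_post),
                  mu_cornea)
  structure(list(mu = mu, mu_post = mu_post, mu_cornea = mu_cornea,
                 alpha = alpha, nhalf = nhalf,
                 kappa = kappa_ratio * max(mu_el) * alpha,
                 kappa_ratio = kappa_ratio,
                 mu_el = mu_el, axial = ax),
            class = "apdi_material_field")
}

#' Cauchy stress and consistent material tangent at a deformation gradient
#'
#' Full 3D stress of the one-term Ogden model with volumetric penalty,
#' evaluated pointwise. Returns the Cauchy stress, the second Piola-Kirchhoff
#' stress and the Lagrangian material tangent `D = 2 dS/dC` in Voigt order
#' (11, 22, 33, 12, 23, 13) with engineering-shear columns.
#'
#' @param mat an [ogden_material()].
#' @param F deformation gradient, 3 x 3 matrix with positive determinant.
#' @return list with `cauchy` (3 x 3), `S` (3 x 3) and `D` (6 x 6).
#' @export
stress_and_tangent <- function(mat, F) {
  stopifnot(inherits(mat, "ogden_material"), is.matrix(F), all(dim(F) == 3))
  if (det(F) <= 0) stop("element inversion: non-positive deformation gradient")
  nhalf <- check_even_alpha(mat$alpha)
  res <- .ogden_pk2(t(F) %*% F, mat$mu, nhalf, mat$kappa)
  cauchy <- (F %*% res$S %*% t(F)) / det(F)
  list(cauchy = cauchy, S = res$S, D = res$D)
}
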