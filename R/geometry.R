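# Parametric globe geometry: exterior/interior ellipses plus a spherical-cap
# cornea. Coordinate convention (used everywhere): origin at the globe centre,
# x = optical/axial axis with the posterior pole at x = -AL/2, y = vertical
# equatorial direction ("uppermost point" = max y), z = out of the sagittal
# plane. The quarter model covers y >= 0, z >= 0.

#' Globe geometry parameters
#'
#' Defines one virtual rabbit eye: the exterior globe outline is an ellipse
#' with horizontal (axial) diameter `AL` and vertical (equatorial) diameter
#' `EL`; the interior outline is a second ellipse chosen so that the scleral
#' wall is `THK` thick at the equator and `t_post` thick at the posterior
#' pole. The cornea is a spherical cap of thickness `t_cornea` whose edge
#' (limbus) sits at parametric angle `cornea_angle` from the posterior pole
#' and whose apex protrudes `apex_offset` beyond the exterior ellipse, so the
#' total axial extent is `AL + apex_offset`.
#'
#' @param AL axial (horizontal) exterior diameter, mm.
#' @param EL equatorial (vertical) exterior diameter, mm.
#' @param THK scleral thickness at the equator (air-puff site), mm.
#' @param t_post posterior scleral thickness, mm.
#' @param t_cornea corneal thickness, mm.
#' @param cornea_angle angular position of the limbus from the optic nerve
#'   (posterior pole), degrees.
#' @param apex_offset corneal apex protrusion beyond the exterior ellipse, mm.
#' @return an object of class `globe_params` (a named list).
#' @export
#' @examples
#' globe_params() # the baseline rabbit globe
globe_params <- function(AL = 18, EL = 19, THK = 0.35, t_post = 0.6,
                         t_cornea = 0.4, cornea_angle = 120,
                         apex_offset = 1.0) {
  stopifnot(AL > 0, EL > 0, THK > 0, THK < EL / 2, t_post > 0,
            t_cornea > 0, apex_offset >= 0,
            cornea_angle > 0, cornea_angle < 180)
  structure(list(AL = AL, EL = EL, THK = THK, t_post = t_post,
                 t_cornea = t_cornea, cornea_angle = cornea_angle,
                 apex_offset = apex_offset),
            class = "globe_params")
}

#' @export
print.globe_params <- function(x, ...) {
  cat("Globe parameters (mm):\n")
  cat(sprintf("  AL = %g, EL = %g, THK = %g, t_post = %g\n",
              x$AL, x$EL, x$THK, x$t_post))
  cat(sprintf("  cornea: thickness %g, limbus at %g deg, apex offset %g\n",
              x$t_cornea, x$cornea_angle, x$apex_offset))
  invisible(x)
}

#' Planar cross-section curves of the globe
#'
#' Builds the sagittal (x, y) boundary curves of the globe wall as functions
#' of the meridian parameter `t` in `[0, pi]` (`t = 0` posterior pole,
#' `t = pi` corneal apex). The exterior curve is the `AL`-by-`EL` ellipse up
#' to the limbus and a spherical arc beyond; the interior curve is the offset
#' ellipse with semi-axes `(AL/2 - t_post, EL/2 - THK)` blended into the
#' concentric inner corneal sphere over a narrow band at the limbus.
#'
#' @param params a [globe_params()] object.
#' @param blend_deg half-width of the limbus blending band, degrees.
#' @return an object of class `apdi_cross_section`: a list with vectorised
#'   functions `outer(t)` and `inner(t)` returning two-column matrices,
#'   the limbus parameter `t_limbus`, and the corneal sphere data.
#' @export
build_globe_cross_section <- function(params, blend_deg = 6) {
  stopifnot(inherits(params, "globe_params"))
  a_out <- params$AL / 2
  b_out <- params$EL / 2
  a_in <- a_out - params$t_post
  b_in <- b_out - params$THK
  if (a_in <= 0 || b_in <= 0)
    stop("invalid geometry: interior ellipse has non-positive semi-axis")
  t_L <- params$cornea_angle * pi / 180

  # corneal sphere through the limbus ring and the protruded apex
  px <- -a_out * cos(t_L)
  py <- b_out * sin(t_L)
  ax <- a_out + params$apex_offset
  cx <- (ax^2 - px^2 - py^2) / (2 * (ax - px))
  R <- ax - cx
  if (R <= params$t_cornea)
    stop("invalid geometry: corneal sphere radius below corneal thickness")
  phi_L <- atan2(py, px - cx)

  phi_of_t <- function(t) phi_L * (pi - t) / (pi - t_L)
  ell <- function(t, a, b) cbind(-a * cos(t), b * sin(t))
  sph <- function(t, r) {
    phi <- phi_of_t(t)
    cbind(cx + r * cos(phi), r * sin(phi))
  }

  outer_fun <- function(t) {
    out <- ell(t, a_out, b_out)
    cor <- t > t_L
    if (any(cor)) out[cor, ] <- sph(t[cor], R)
    out
  }
  db <- blend_deg * pi / 180
  inner_fun <- function(t) {
    out <- ell(t, a_in, b_in)
    w <- pmin(1, pmax(0, (t_L + db - t) / (2 * db))) # 1 scleral, 0 corneal
    mix <- w < 1
    if (any(mix)) {
      sp <- sph(t[mix], R - params$t_cornea)
      out[mix, ] <- w[mix] * out[mix, ] + (1 - w[mix]) * sp
    }
    out
  }

  # validity: positive wall thickness along the whole meridian
  ts <- seq(0, pi, length.out = 721)
  gap <- sqrt(rowSums((outer_fun(ts) - inner_fun(ts))^2))
  if (any(!is.finite(gap)) || any(gap <= 0))
    stop("invalid geometry: wall thickness non-positive along the meridian")

  structure(list(params = params, outer = outer_fun, inner = inner_fun,
                 t_limbus = t_L, cornea_center = cx, cornea_R = R,
                 blend_deg = blend_deg),
            class = "apdi_cross_section")
}

#' Wall thickness along the meridian
#'
#' Distance between the interior and exterior cross-section curves at equal
#' meridian parameter, a radial-offset measure of wall thickness.
#'
#' @param cs an `apdi_cross_section` object.
#' @param t meridian parameter values in `[0, pi]`.
#' @return thickness values, mm.
#' @export
wall_thickness <- function(cs, t) {
  sqrt(rowSums((cs$outer(t) - cs$inner(t))^2))
}
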