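# Structured quarter-globe mesh of 20-node serendipity hexahedra.
# Parametrisation: meridian parameter t in [0, pi] (posterior pole -> corneal
# apex), azimuth psi in [0, pi/2] about the optical axis (psi = 0 sagittal
# plane, psi = pi/2 axial plane), through-thickness s in [0, 1] (inner ->
# outer). Elements are clustered toward the air-puff site (t = pi/2, psi = 0).
# Pole elements are collapsed hexahedra, as is standard for structured
# shell-of-revolution meshes.

# node spacing within [lo, hi] split into n elements (2n+1 grid points)
band_grid <- function(lo, hi, n) seq(lo, hi, length.out = 2 * n + 1)

meridian_bands <- function(n_theta, t_limbus) {
  # 20% posterior cap, 30% + 30% equatorial (split at pi/2 so the air-puff
  # centre is always a grid point; the output stations sit in this band),
  # remainder cornea
  n1 <- max(2L, round(0.2 * n_theta))
  n2 <- max(2L, round(0.3 * n_theta))
  n4 <- max(2L, n_theta - n1 - 2L * n2)
  bounds <- c(0, t_limbus / 2, pi / 2, t_limbus, pi)
  list(n = c(n1, n2, n2, n4), bounds = bounds)
}

azimuth_bands <- function(n_psi, model = "quarter") {
  if (model == "quarter") {
    m1 <- max(2L, round(0.6 * n_psi))
    m2 <- max(2L, n_psi - m1)
    list(n = c(m1, m2), bounds = c(0, pi / 6, pi / 2))
  } else {
    # half model: psi in [0, pi] (z >= 0), clustered toward the puff at 0
    m1 <- max(2L, round(0.4 * n_psi))
    m2 <- max(2L, round(0.3 * n_psi))
    m3 <- max(2L, n_psi - m1 - m2)
    list(n = c(m1, m2, m3), bounds = c(0, pi / 6, pi / 2, pi))
  }
}

banded_grid <- function(bands) {
  g <- band_grid(bands$bounds[1], bands$bounds[2], bands$n[1])
  for (b in seq_along(bands$n)[-1]) {
    g <- c(g, band_grid(bands$bounds[b], bands$bounds[b + 1], bands$n[b])[-1])
  }
  g
}

#' Generate the quarter-globe finite-element mesh
#'
#' Meshes the parametric globe of [build_globe_cross_section()] into 20-node
#' serendipity hexahedra on one side of the sagittal plane and one side of
#' the axial plane, with named node/face sets for boundary conditions, the
#' intraocular-pressure surface, the air-puff patch, and the sagittal output
#' section.
#'
#' @param params a [globe_params()] object.
#' @param resolution requested solid element count (the mesher honours it to
#'   within 20 percent). The default matches the element count of the
#'   reference model this geometry reproduces.
#' @param ns number of elements through the wall thickness (minimum 2).
#' @param patch_radius radius, mm, of the outer-surface patch around the
#'   uppermost equatorial point that can receive air-puff load.
#' @param blend_deg passed to [build_globe_cross_section()].
#' @param model `"quarter"` (default: both symmetry planes, as in the
#'   reference model) or `"half"` (sagittal symmetry only, azimuth spanning
#'   the full upper-lower range, for air-puff placements that are not
#'   mirror-symmetric about the axial plane).
#' @return an object of class `apdi_mesh`.
#' @export
generate_mesh <- function(params, resolution = 5000, ns = 2,
                          patch_radius = 6, blend_deg = 6,
                          model = c("quarter", "half")) {
  stopifnot(inherits(params, "globe_params"))
  model <- match.arg(model)
  if (ns < 2)
    stop("meshing error: fewer than 2 elements through the wall thickness")
  if (params$cornea_angle <= 90)
    stop("meshing error: cornea crossing the equator is not supported")
  cs <- build_globe_cross_section(params, blend_deg = blend_deg)

  n_theta <- if (model == "quarter") max(8L, round(sqrt(2 * resolution / ns)))
             else max(8L, round(sqrt(resolution / ns)))
  n_psi <- if (model == "quarter") max(4L, round(n_theta / 2))
           else max(6L, n_theta)
  mb <- meridian_bands(n_theta, cs$t_limbus)
  ab <- azimuth_bands(n_psi, model)
  tg <- banded_grid(mb)    # length 2*nt + 1
  pg <- banded_grid(ab)    # length 2*np + 1
  sg <- seq(0, 1, length.out = 2 * ns + 1)
  nt <- (length(tg) - 1L) %/% 2L
  np <- (length(pg) - 1L) %/% 2L

  nit <- length(tg); nip <- length(pg); nis <- length(sg)
  # node selection: serendipity grid, at most one odd index; poles collapse
  # all azimuths onto psi-index 0
  it <- rep(seq_len(nit) - 1L, times = nip * nis)
  ip <- rep(rep(seq_len(nip) - 1L, each = nit), times = nis)
  is_ <- rep(seq_len(nis) - 1L, each = nit * nip)
  odd <- (it %% 2L) + (ip %% 2L) + (is_ %% 2L)
  keep <- odd <= 1L
  pole <- it == 0L | it == (nit - 1L)
  keep <- keep & !(pole & ip > 0L)
  kidx <- which(keep)
  id <- integer(nit * nip * nis)
  id[kidx] <- seq_along(kidx)

  lookup <- function(i, p, s) {
    p <- ifelse(i == 0L | i == (nit - 1L), 0L, p)
    id[i + 1L + nit * (p + nip * s)]
  }

  tv <- tg[it[kidx] + 1L]
  pv <- pg[ip[kidx] + 1L]
  sv <- sg[is_[kidx] + 1L]
  qi <- cs$inner(tv); qo <- cs$outer(tv)
  q <- (1 - sv) * qi + sv * qo
  nodes <- cbind(q[, 1], q[, 2] * cos(pv), q[, 2] * sin(pv))
  N <- nrow(nodes)

  # connectivity: local (xi, eta, zeta) = (t, s, psi) for positive Jacobians
  loc <- rbind(
    c(-1, -1, -1), c(1, -1, -1), c(1, 1, -1), c(-1, 1, -1),
    c(-1, -1, 1), c(1, -1, 1), c(1, 1, 1), c(-1, 1, 1),
    c(0, -1, -1), c(1, 0, -1), c(0, 1, -1), c(-1, 0, -1),
    c(0, -1, 1), c(1, 0, 1), c(0, 1, 1), c(-1, 0, 1),
    c(-1, -1, 0), c(1, -1, 0), c(1, 1, 0), c(-1, 1, 0))
  E <- nt * np * ns
  conn <- matrix(0L, E, 20)
  elem_t <- numeric(E)
  e <- 0L
  for (ep in seq_len(np) - 1L) {
    for (es in seq_len(ns) - 1L) {
      for (et in seq_len(nt) - 1L) {
        e <- e + 1L
        bi <- 2L * et; bs <- 2L * es; bp <- 2L * ep
        conn[e, ] <- lookup(bi + loc[, 1] + 1L, bp + loc[, 3] + 1L,
                            bs + loc[, 2] + 1L)
        elem_t[e] <- tg[bi + 2L]
      }
    }
  }
  region <- ifelse(elem_t <= cs$t_limbus, "sclera", "cornea")

  # surface faces on the (t, psi) grid; normals point away from the material
  face8 <- function(slayer, flip) {
    F <- matrix(0L, nt * np, 8)
    f <- 0L
    for (ep in seq_len(np) - 1L) {
      for (et in seq_len(nt) - 1L) {
        f <- f + 1L
        bi <- 2L * et; bp <- 2L * ep
        c00 <- lookup(bi, bp, slayer); c20 <- lookup(bi + 2L, bp, slayer)
        c22 <- lookup(bi + 2L, bp + 2L, slayer); c02 <- lookup(bi, bp + 2L, slayer)
        m10 <- lookup(bi + 1L, bp, slayer); m21 <- lookup(bi + 2L, bp + 1L, slayer)
        m12 <- lookup(bi + 1L, bp + 2L, slayer); m01 <- lookup(bi, bp + 1L, slayer)
        if (!flip) {
          F[f, ] <- c(c00, c20, c22, c02, m10, m21, m12, m01)
        } else {
          F[f, ] <- c(c00, c02, c22, c20, m01, m12, m21, m10)
        }
      }
    }
    F
  }
  inner_faces <- face8(0L, flip = FALSE)          # normal toward the cavity
  outer_faces <- face8(2L * ns, flip = TRUE)      # normal outward
  face_t <- rep(tg[2L * (seq_len(nt) - 1L) + 2L], times = np)
  face_psi <- rep(pg[2L * (seq_len(np) - 1L) + 2L], each = nt)

  puff_center <- c(0, cs$outer(pi / 2)[, 2], 0)
  oc <- face_centroids(nodes, outer_faces)
  d <- sqrt(colSums((t(oc) - puff_center)^2))
  airpuff_idx <- which(d <= patch_radius)

  node_sets <- list(
    sagittal = which(abs(nodes[, 3]) < 1e-9),
    axial = which(abs(nodes[, 2]) < 1e-9),
    pole = which.min(nodes[, 1]))

  structure(list(
    nodes = nodes, conn = conn, region = region, elem_t = elem_t,
    node_t = tv, node_psi = pv, node_s = sv,
    sets = list(inner_faces = inner_faces, outer_faces = outer_faces,
                face_t = face_t, face_psi = face_psi,
                airpuff_idx = airpuff_idx, puff_center = puff_center,
                sagittal_nodes = node_sets$sagittal,
                axial_nodes = node_sets$axial,
                pole_node = node_sets$pole),
    params = params, cs = cs, model = model,
    divisions = list(n_theta = nt, n_psi = np, ns = ns),
    resolution_requested = resolution),
    class = "apdi_mesh")
}

#' @export
print.apdi_mesh <- function(x, ...) {
  cat(sprintf("%s-globe mesh: %d nodes, %d hex20 elements (%d sclera, %d cornea)\n",
              x$model %||% "quarter",
              nrow(x$nodes), nrow(x$conn), sum(x$region == "sclera"),
              sum(x$region == "cornea")))
  cat(sprintf("  divisions: %d meridian x %d azimuth x %d through-thickness\n",
              x$divisions$n_theta, x$divisions$n_psi, x$divisions$ns))
  invisible(x)
}

face_centroids <- function(nodes, faces) {
  # corner mean is enough for set selection
  (nodes[faces[, 1], , drop = FALSE] + nodes[faces[, 2], , drop = FALSE] +
     nodes[faces[, 3], , drop = FALSE] + nodes[faces[, 4], , drop = FALSE]) / 4
}

#' Number of elements and nodes of a mesh
#' @param mesh an `apdi_mesh`.
#' @return named integer vector.
#' @export
mesh_size <- function(mesh) {
  c(elements = nrow(mesh$conn), nodes = nrow(mesh$nodes))
}

#' Mesh volume by Gauss quadrature over the elements
#' @param mesh an `apdi_mesh`.
#' @param u optional displacement vector (3N); default reference configuration.
#' @return volume in mm^3.
#' @export
mesh_volume <- function(mesh, u = NULL) {
  if (is.null(u)) u <- numeric(3 * nrow(mesh$nodes))
  .mesh_volume(mesh$nodes, mesh$conn, u)
}

#' Analytic cross-section volume of the quarter globe
#'
#' Volume of revolution of the wall cross-section over a quarter turn,
#' computed by dense 2-D quadrature on the exact boundary curves. Used as the
#' mesh-independent oracle for [mesh_volume()].
#'
#' @param cs an `apdi_cross_section`.
#' @param n quadrature density.
#' @return volume in mm^3.
#' @export
cross_section_volume <- function(cs, n = 2000) {
  # V = (pi/2) * int int y |d(x,y)/d(t,s)| dt ds over the wall region
  ts <- seq(0, pi, length.out = n + 1)
  tm <- (ts[-1] + ts[-(n + 1)]) / 2
  dt <- diff(ts)
  m <- 8L
  sm <- (seq_len(m) - 0.5) / m
  V <- 0
  qi <- cs$inner(tm); qo <- cs$outer(tm)
  h <- 1e-6
  dqi <- (cs$inner(tm + h) - cs$inner(tm - h)) / (2 * h)
  dqo <- (cs$outer(tm + h) - cs$outer(tm - h)) / (2 * h)
  for (s in sm) {
    q <- (1 - s) * qi + s * qo
    dq_dt <- (1 - s) * dqi + s * dqo
    dq_ds <- qo - qi
    jac <- abs(dq_dt[, 1] * dq_ds[, 2] - dq_dt[, 2] * dq_ds[, 1])
    V <- V + sum(q[, 2] * jac * dt) / m
  }
  V * pi / 2
}

#' Axial element coordinates for the stiffness grading
#'
#' Signed axial distance of each element centroid from the equatorial plane,
#' positive toward the posterior pole, together with `x_f`, the distance from
#' the equator to the most posterior scleral material point.
#'
#' @param mesh an `apdi_mesh`.
#' @return an object of class `apdi_axial_map`: list with per-element `x`
#'   (mm) and scalar `x_f` (mm).
#' @export
compute_axial_coordinates <- function(mesh) {
  cen <- .element_centroids(mesh$nodes, mesh$conn)
  structure(list(x = -cen[, 1], x_f = mesh$params$AL / 2,
                 centroids = cen),
            class = "apdi_axial_map")
}
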