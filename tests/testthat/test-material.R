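test_that("uniaxial closed form matches direct evaluation of the law", {
  mat <- ogden_material(mu = 0.083, alpha = 40)
  expect_equal(uniaxial_cauchy_stress(mat, 1), 0)
  # mu (lambda^40 - lambda^-20) at lambda = 1.02
  expect_equal(uniaxial_cauchy_stress(mat, 1.02),
               0.083 * (1.02^40 - 1.02^-20), tolerance = 1e-15)
  expect_equal(uniaxial_cauchy_stress(mat, 1.02), 0.1274, tolerance = 1e-3)
  # strict monotonicity
  lam <- seq(0.9, 1.1, by = 0.005)
  expect_true(all(diff(uniaxial_cauchy_stress(mat, lam)) > 0))
  expect_error(uniaxial_cauchy_stress(mat, -1), "positive")
})

test_that("axial grading is linear with the stated anchors", {
  expect_equal(graded_mu(0, 9, 0.1, 0.05), 0.1)
  expect_equal(graded_mu(9, 9, 0.1, 0.05), 0.05)
  expect_equal(graded_mu(4.5, 9, 0.1, 0.05), 0.075)
  # anterior clamp and posterior clamp
  expect_equal(graded_mu(-3, 9, 0.1, 0.05), 0.1)
  expect_error(graded_mu(1, 0, 0.1, 0.05), "degenerate")
  expect_error(graded_mu(1, 9, 0.05, 0.1), "mu_post")
})

test_that("material field stays within [mu_post, mu] and grades the sclera", {
  m <- tiny_sphere_mesh()
  f <- material_field(m, mu = 0.10, mu_post = 0.05, mu_cornea = 0.08)
  sclera <- m$region == "sclera"
  expect_true(all(f$mu_el[sclera] <= 0.10 + 1e-12))
  expect_true(all(f$mu_el[sclera] >= 0.05 - 1e-12))
  expect_true(all(f$mu_el[!sclera] == 0.08))
  ax <- compute_axial_coordinates(m)
  # posterior-most scleral elements are softest
  post <- sclera & ax$x > 0.8 * ax$x_f
  expect_lt(mean(f$mu_el[post]), 0.06)
  expect_gte(f$kappa / (0.10 * 40), 1000)
})

test_that("3D stress reduces to the uniaxial law in the incompressible limit", {
  mat <- ogden_material(0.083, 40)
  for (lam in c(1.01, 1.02, 1.05)) {
    # find the lateral stretch that makes the lateral Cauchy stress vanish
    f <- function(lt) stress_and_tangent(mat, diag(c(lam, lt, lt)))$cauchy[2, 2]
    lt <- uniroot(f, c(0.8, 1.2), tol = 1e-14)$root
    s_ax <- stress_and_tangent(mat, diag(c(lam, lt, lt)))$cauchy[1, 1]
    expect_equal(s_ax, uniaxial_cauchy_stress(mat, lam), tolerance = 5e-3)
  }
  # identity deformation -> zero stress
  expect_equal(stress_and_tangent(mat, diag(3))$cauchy, matrix(0, 3, 3),
               tolerance = 1e-14)
  expect_error(stress_and_tangent(mat, diag(c(-1, 1, 1))), "inversion")
})

test_that("small-strain shear modulus equals mu * alpha / 2", {
  mat <- ogden_material(0.083, 40)
  eps <- 1e-6
  F <- diag(3); F[1, 2] <- eps
  expect_equal(stress_and_tangent(mat, F)$cauchy[1, 2] / eps,
               0.083 * 40 / 2, tolerance = 1e-4)
})

test_that("analytic tangent matches finite differences on random states", {
  VI <- c(1, 2, 3, 1, 2, 1); VJ <- c(1, 2, 3, 2, 3, 3)
  mu <- 0.083; nh <- 20L; kap <- 1000 * mu * 40
  set.seed(42)
  for (rep in 1:5) {
    F <- diag(3) + matrix(rnorm(9, 0, 0.03), 3)
    if (det(F) <= 0) next
    C0 <- t(F) %*% F
    res <- scleraAPDI:::.ogden_pk2(C0, mu, nh, kap)
    h <- 1e-7
    Dfd <- matrix(0, 6, 6)
    for (Jc in 1:6) {
      dC <- matrix(0, 3, 3)
      if (Jc <= 3) dC[VI[Jc], VJ[Jc]] <- 2 * h
      else dC[VI[Jc], VJ[Jc]] <- dC[VJ[Jc], VI[Jc]] <- h
      Sp <- scleraAPDI:::.ogden_pk2(C0 + dC, mu, nh, kap)$S
      Sm <- scleraAPDI:::.ogden_pk2(C0 - dC, mu, nh, kap)$S
      dS <- (Sp - Sm) / (2 * h)
      Dfd[, Jc] <- c(dS[1, 1], dS[2, 2], dS[3, 3], dS[1, 2], dS[2, 3], dS[1, 3])
    }
    expect_lt(max(abs(Dfd - res$D)) / max(abs(res$D)), 1e-6)
  }
})

test_that("stress is frame-indifferent under rotations of F", {
  mat <- ogden_material(0.09, 40)
  set.seed(7)
  F <- diag(3) + matrix(rnorm(9, 0, 0.02), 3)
  sig <- stress_and_tangent(mat, F)$cauchy
  for (rep in 1:3) {
    A <- matrix(rnorm(9), 3); R <- qr.Q(qr(A))
    if (det(R) < 0) R[, 1] <- -R[, 1]
    sig_rot <- stress_and_tangent(mat, R %*% F)$cauchy
    expect_equal(sig_rot, R %*% sig %*% t(R), tolerance = 1e-10)
  }
})

test_that("odd exponents are rejected by the 3D path, accepted in 1D", {
  expect_error(material_field(tiny_sphere_mesh(), alpha = 39), "even integer")
  mat <- structure(list(mu = 0.1, alpha = 39), class = "ogden_material")
  expect_gt(uniaxial_cauchy_stress(mat, 1.01), 0)
})
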