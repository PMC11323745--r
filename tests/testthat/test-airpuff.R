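test_that("pressure_at implements the ramped kernel", {
  prof <- airpuff_profile()   # defaults: 6 steps, gaussian
  expect_equal(pressure_at(prof, r = 0, k = 6), prof$peak_kpa)
  expect_equal(pressure_at(prof, r = 0, k = 3), prof$peak_kpa / 2)
  # at half the FWHM from the centre the kernel is exactly one half
  expect_equal(pressure_at(prof, r = prof$fwhm_mm / 2, k = 6),
               prof$peak_kpa / 2, tolerance = 1e-12)
  expect_error(pressure_at(prof, 0, k = 7))
  expect_error(airpuff_profile(peak_kpa = -1))
})

test_that("puff kernel integrates to the closed-form gaussian force", {
  m <- tiny_sphere_mesh()
  prof <- airpuff_profile(fwhm_mm = 2.4)
  kgp <- scleraAPDI:::airpuff_kernel_gp(m, prof)
  patch <- m$sets$outer_faces[m$sets$airpuff_idx, , drop = FALSE]
  fv <- follower_pressure_load(m, patch, kgp * 0.0154)
  Fmag <- sqrt(sum(colSums(matrix(fv, ncol = 3, byrow = TRUE))^2))
  sigma <- 2.4 / (2 * sqrt(2 * log(2)))
  R <- 9.5   # chordal kernel on a sphere integrates in closed form
  Fexact <- 0.0154 * 2 * pi * sigma^2 * (1 - exp(-2 * R^2 / sigma^2)) / 2
  expect_lt(abs(Fmag / Fexact - 1), 0.02)
})

test_that("air-puff deformation grows monotonically over the ramp", {
  fwd <- tiny_globe_forward()
  sol <- fwd$solution
  init <- extract_sagittal_profile(sol, step = 1)
  ad_k <- vapply(2:(nrow(sol$steps) - 1), function(k)
    displacement_at_x(init, extract_sagittal_profile(sol, step = k), 0), 0)
  expect_true(all(diff(ad_k) > 0))
  expect_gt(ad_k[1], 0)
  # zero peak pressure leaves the globe at its pre-puff state
  sf <- fwd$stress_free
  sched <- data.frame(iop_mmhg = rep(18, 2), puff_frac = c(0, 0))
  sol0 <- solve_static(sf$mesh, sf$field, sf$bcs, sched, nodes = sf$Xi,
                       u0 = sf$u_pressurized, structure = sf$structure)
  expect_equal(sol0$U[, 3], sol0$U[, 2], tolerance = 1e-10)
})

test_that("narrowing the kernel at fixed peak decreases AD", {
  wide <- tiny_globe_forward()   # package default width
  narrow <- run_forward(resolution = test_resolution(),
                        profile = airpuff_profile(
                          fwhm_mm = wide$settings$profile$fwhm_mm / 2))
  expect_lt(narrow$outputs$AD, wide$outputs$AD)
})

test_that("the coupled cavity stiffens the response", {
  fwd <- tiny_globe_forward()
  coupled <- run_airpuff(fwd$stress_free, profile = airpuff_profile(
    fwhm_mm = fwd$settings$profile$fwhm_mm),
    cavity = "coupled", cavity_bulk_kpa = 400)
  init <- extract_sagittal_profile(coupled, step = 1)
  fin <- extract_sagittal_profile(coupled, step = nrow(coupled$steps) - 1)
  ad_coupled <- displacement_at_x(init, fin, 0)
  expect_lt(ad_coupled, fwd$outputs$AD)
  expect_gt(ad_coupled, 0)
})
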