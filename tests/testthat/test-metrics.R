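make_profile <- function(x, y) {
  out <- tibble::tibble(x = x, y = y, t = NA_real_, node = NA_integer_)
  structure(out, class = c("apdi_profile", class(out)),
            x_apex = 0, step = 1L)
}

test_that("displacement at analytic curves matches closed forms", {
  x <- seq(-4, 4, by = 0.05)
  init <- make_profile(x, rep(10, length(x)))
  fin <- make_profile(x, 10 - exp(-x^2))
  expect_equal(displacement_at_x(init, fin, 0), 1.0, tolerance = 1e-4)
  expect_equal(displacement_at_x(init, fin, c(-2, 2)),
               rep(exp(-4), 2), tolerance = 1e-4)
  # identical profiles -> zero displacement everywhere
  expect_equal(displacement_at_x(init, init, c(-2, 0, 2)), rep(0, 3))
  expect_error(displacement_at_x(init, fin, 5), "range")
})

test_that("output parameters follow their defining arithmetic", {
  x <- c(-3, -2, -1, 0, 1, 2, 3)
  init <- make_profile(x, c(9.7, 9.9, 9.97, 10, 9.9, 9.8, 9.6))
  fin <- make_profile(x, c(9.3, 9.5, 9.2, 9.0, 9.15, 9.3, 9.2))
  out <- compute_output_params(init, fin)
  expect_equal(out$AD, 1.0)            # Y0 - y0
  expect_equal(out$CPR, 1.0 / 0.5)     # (Y0-y0)/(Y2-y2)
  expect_equal(out$AR, 0.5 / 0.4)      # (Y2-y2)/(Y-2-y-2)
  expect_equal(out$Y_0, 10); expect_equal(out$y_0, 9)
})

test_that("rigid translation of both profiles leaves outputs unchanged", {
  x <- seq(-4, 4, by = 0.1)
  init <- make_profile(x, 10 - 0.05 * x^2)
  fin <- make_profile(x, 10 - 0.05 * x^2 - exp(-x^2 / 2))
  o1 <- compute_output_params(init, fin)
  o2 <- compute_output_params(make_profile(x, init$y + 5),
                              make_profile(x, fin$y + 5))
  expect_equal(o1$AD, o2$AD, tolerance = 1e-12)
  expect_equal(o1$CPR, o2$CPR, tolerance = 1e-12)
  expect_equal(o1$AR, o2$AR, tolerance = 1e-12)
})

test_that("vanishing peripheral displacement is reported as missing", {
  x <- seq(-4, 4, by = 0.1)
  init <- make_profile(x, rep(10, length(x)))
  fin <- make_profile(x, 10 - exp(-8 * x^2))  # ~1e-15 at x = 2
  w <- capture_warnings(out <- compute_output_params(init, fin))
  expect_true(all(grepl("undefined", w)) && length(w) >= 1)
  expect_true(is.na(out$CPR) || is.na(out$AR))
  expect_equal(out$AD, 1, tolerance = 1e-3)
})

test_that("simulated profiles are extracted in the scan frame", {
  fwd <- tiny_globe_forward()
  init <- fwd$profile_initial
  # apex of the pre-puff curve is at x = 0 and is the maximum height
  expect_equal(init$x[which.max(init$y)], 0, tolerance = 1e-9)
  expect_gte(sum(init$x >= -2 & init$x <= 2), 5)
  # +x points toward the posterior pole (larger meridian distance from cornea)
  expect_gt(init$x[which.min(init$t)], 0)   # posterior pole node
  expect_lt(init$x[which.max(init$t)], 0)   # corneal apex node
  # final profile dips at the puff centre
  fin <- fwd$profile_final
  expect_gt(displacement_at_x(init, fin, 0), 0)
})

test_that("profile csv round-trips through the external-curve reader", {
  fwd <- tiny_globe_forward()
  f <- tempfile(fileext = ".csv")
  write_profile_csv(fwd$profile_initial, f)
  back <- read_profile_csv(f)
  o <- order(fwd$profile_initial$x)
  expect_equal(back$x, fwd$profile_initial$x[o], tolerance = 1e-12)
  expect_equal(back$y, fwd$profile_initial$y[o], tolerance = 1e-12)
  # outputs computed from re-read curves match the in-memory path
  f2 <- tempfile(fileext = ".csv")
  write_profile_csv(fwd$profile_final, f2)
  out1 <- compute_output_params(fwd$profile_initial, fwd$profile_final)
  out2 <- compute_output_params(read_profile_csv(f), read_profile_csv(f2))
  expect_equal(out1$AD, out2$AD, tolerance = 1e-10)
  unlink(c(f, f2))
})
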