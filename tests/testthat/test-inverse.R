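test_that("rmse follows its definition and validates input", {
  expect_equal(rmse(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_equal(rmse(c(1.0, 0.8), c(1.1, 0.7)), 0.1)
  # pairing is positional: permuting one side changes the value
  expect_false(isTRUE(all.equal(rmse(c(1.0, 0.8), c(0.7, 1.1)), 0.1)))
  expect_error(rmse(1:3, 1:2), "length mismatch")
})

test_that("ad_curve validates its invariants", {
  cv <- ad_curve(c(10, 15, 20, 25), c(1.2, 1.0, 0.8, 0.7), "S", "Eye1")
  expect_s3_class(cv, "apdi_ad_curve")
  expect_error(ad_curve(c(10, 10), c(1, 1)), "diff")
  expect_error(ad_curve(c(10, 15), c(1, -1)))
})

test_that("a noiseless forward-inverse round trip recovers mu", {
  res <- 80
  mu_true <- 0.095
  ctx <- inverse_context(resolution = res)
  truth <- scleraAPDI:::forward_ad_curve(
    globe_params(), mu_true, 1, c(10, 15, 20, 25), airpuff_profile(),
    res, 2, solver_config(), 3,
    generate_mesh(globe_params(), resolution = res))
  curve <- ad_curve(c(10, 15, 20, 25), truth, "S", "synthetic")
  fit <- estimate_mu(curve, context = ctx)
  expect_lt(abs(fit$mu_hat - mu_true) / mu_true, 0.02)
  expect_lt(fit$objective, 1e-4)
  expect_lt(fit$rmse, 0.02)
  expect_false(fit$at_boundary)
  # f_apex vanishes (to solver tolerance) at the recovered optimum
  expect_lt(min(fit$trace$f), 1e-5)
  expect_true(all(fit$trace$f >= 0))
  expect_true(all(fit$trace$mu >= 0.05 & fit$trace$mu <= 0.15))
  # predicted AD decreases with IOP
  pr <- fit$predictions[order(fit$predictions$iop_mmhg), ]
  expect_true(all(diff(pr$ad_pred) < 0))
  # broom-style accessors
  td <- tidy(fit)
  expect_equal(td$estimate, fit$mu_hat)
  gl <- glance(fit)
  expect_equal(gl$rmse, fit$rmse)
  expect_gte(gl$n_evaluations, 5)
})

test_that("an unattainable target pushes the optimum to a bound and warns", {
  res <- 80
  ctx <- inverse_context(resolution = res)
  # target far above anything the stiff end of the interval can produce
  curve <- ad_curve(10, 30, "S", "synthetic")
  expect_warning(
    fit <- estimate_mu(curve, bounds = c(0.05, 0.07), tol = 2e-3,
                       context = ctx),
    "boundary")
  expect_true(fit$at_boundary)
  # softest admissible mu gives the largest AD, so the optimum sits there
  expect_lt(fit$mu_hat, 0.055)
  expect_true(is.na(fit$rmse))  # no held-out IOPs supplied
})

test_that("a missing reference-IOP entry is an input error", {
  ctx <- inverse_context(resolution = test_resolution())
  expect_error(estimate_mu(ad_curve(c(15, 20), c(1, 0.8)), context = ctx),
               "input error")
})
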