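test_that("percent change follows its definition", {
  expect_equal(percent_change(2.5, 0.7), -72)
  expect_equal(percent_change(1.0, 1.0), 0)
  expect_equal(percent_change(0.5, 1.19), 138)
  expect_error(percent_change(0, 1), "zero baseline")
})

test_that("r_squared agrees with the least-squares definition", {
  set.seed(3)
  x <- rnorm(50)
  y <- 2 * x + rnorm(50, 0, 0.5)
  r2 <- r_squared(x, y)$r_squared
  # independent oracle: 1 - SSres/SStot of the simple linear fit, by hand
  b <- sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
  a <- mean(y) - b * mean(x)
  ols <- 1 - sum((y - a - b * x)^2) / sum((y - mean(y))^2)
  expect_equal(r2, ols, tolerance = 1e-12)
  # collinear data and self-correlation
  expect_equal(r_squared(x, 3 * x + 1)$r_squared, 1, tolerance = 1e-12)
  expect_equal(r_squared(x, x)$r_squared, 1, tolerance = 1e-12)
  # shuffled responses decorrelate
  set.seed(4)
  r2s <- replicate(20, r_squared(x, sample(y))$r_squared)
  expect_lt(mean(r2s), 3 / 50)
  expect_warning(r_squared(rep(1, 10), rnorm(10)), "zero variance")
  expect_error(r_squared(1:2, 1:2), "3 finite pairs")
})

test_that("parameter ranges carry the study's bounds and initial values", {
  rg <- parameter_ranges()
  expect_setequal(rg$param, c("mu", "thk", "iop", "mu_post_ratio", "al", "el"))
  expect_equal(rg$initial[rg$param == "mu"], 0.083)
  expect_equal(c(rg$lower[rg$param == "iop"], rg$upper[rg$param == "iop"]),
               c(10, 25))
  expect_equal(c(rg$lower[rg$param == "mu_post_ratio"],
                 rg$upper[rg$param == "mu_post_ratio"]), c(0.25, 1))
  expect_error(parameter_ranges(mu = c(0.1, 0.06, 0.083)), "lower < upper")
})

test_that("random draws are reproducible and land inside the ranges", {
  rg <- parameter_ranges()
  set.seed(11)
  d1 <- vapply(seq_len(nrow(rg)), function(i)
    runif(20, rg$lower[i], rg$upper[i]), numeric(20))
  set.seed(11)
  d2 <- vapply(seq_len(nrow(rg)), function(i)
    runif(20, rg$lower[i], rg$upper[i]), numeric(20))
  expect_identical(d1, d2)
  expect_true(all(d1 >= matrix(rg$lower, 20, 6, byrow = TRUE) &
                    d1 <= matrix(rg$upper, 20, 6, byrow = TRUE)))
})

test_that("a small sensitivity sweep produces records and percent changes", {
  sens <- sensitivity_study(n_points = 2, resolution = test_resolution(),
                            params = "iop")
  expect_equal(sort(unique(sens$records$value)), c(10, 18, 25))
  s <- sens$summary
  expect_setequal(s$output, c("AD", "CPR", "AR"))
  ad <- s[s$output == "AD", ]
  # AD falls with IOP, so the percent change over the range is negative
  expect_lt(ad$percent_change, 0)
  expect_equal(ad$percent_change,
               100 * (ad$high - ad$low) / ad$low, tolerance = 1e-12)
  # the alternative initial-to-high convention is also reported
  expect_true(is.finite(ad$percent_change_from_initial))
  expect_lt(ad$percent_change_from_initial, 0)
})

test_that("a tiny random-sampling study is reproducible end to end", {
  st1 <- random_sampling_study(n = 3, seed = 5,
                               resolution = test_resolution())
  st2 <- random_sampling_study(n = 3, seed = 5,
                               resolution = test_resolution())
  expect_identical(st1$records, st2$records)
  expect_identical(st1$r_squared, st2$r_squared)
  expect_equal(nrow(st1$records), 3 - st1$n_failed)
  expect_true(all(c("mu", "thk", "iop", "mu_post", "al", "el",
                    "AD", "CPR", "AR") %in% names(st1$records)))
  expect_true(all(st1$records$mu_post <= st1$records$mu + 1e-12))
})
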