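# Parametric studies: one-at-a-time sensitivity sweeps with percent-change
# summaries, and the random-sampling study with per-pair R^2.

#' Input-parameter ranges for the parametric studies
#'
#' The six model inputs with their initial values and evaluated intervals:
#' the "direct" parameters mu (MPa), THK (mm) and IOP (mmHg) act at the
#' air-puff site; the "indirect" parameters mu_post (drawn as a ratio of mu
#' in 0.25-1), AL and EL (mm) act away from it.
#'
#' @param mu,thk,iop,mu_post_ratio,al,el length-3 numeric vectors
#'   `c(lower, upper, initial)`.
#' @return a tibble of class `apdi_ranges` with columns `param`, `lower`,
#'   `upper`, `initial`.
#' @export
parameter_ranges <- function(mu = c(0.06, 0.10, 0.083),
                             thk = c(0.34, 0.40, 0.35),
                             iop = c(10, 25, 18),
                             mu_post_ratio = c(0.25, 1, 1),
                             al = c(17, 19, 18),
                             el = c(18.4, 19.6, 19)) {
  vals <- list(mu = mu, thk = thk, iop = iop,
               mu_post_ratio = mu_post_ratio, al = al, el = el)
  for (nm in names(vals)) {
    v <- vals[[nm]]
    if (length(v) != 3 || v[1] >= v[2] || v[3] < v[1] || v[3] > v[2])
      stop("range for ", nm, " must be c(lower, upper, initial) with ",
           "lower < upper and initial inside")
  }
  out <- tibble::tibble(
    param = names(vals),
    lower = unname(vapply(vals, `[`, 0, 1)),
    upper = unname(vapply(vals, `[`, 0, 2)),
    initial = unname(vapply(vals, `[`, 0, 3)))
  structure(out, class = c("apdi_ranges", class(out)))
}

# One forward evaluation from a named input vector, memoised on the inputs.
study_forward <- function(inputs, resolution, ns, profile, cfg,
                          stress_free_iters, cache = NULL) {
  key <- paste(signif(unlist(inputs), 12), collapse = "|")
  if (!is.null(cache) && !is.null(cache[[key]])) return(cache[[key]])
  params <- globe_params(AL = inputs$al, EL = inputs$el, THK = inputs$thk)
  fwd <- run_forward(params, mu = inputs$mu,
                     mu_post = inputs$mu_post_ratio * inputs$mu,
                     iop_mmhg = inputs$iop, profile = profile,
                     resolution = resolution, ns = ns, cfg = cfg,
                     stress_free_iters = stress_free_iters)
  out <- fwd$outputs[, c("AD", "CPR", "AR")]
  if (!is.null(cache)) cache[[key]] <- out
  out
}

#' One-at-a-time sensitivity study
#'
#' For each input parameter in turn: hold the other five at their initial
#' values, sweep the parameter over its range (evenly spaced points, with the
#' initial value added to the sweep), re-run the stress-free preload for
#' every evaluation, and record AD, CPR and AR. Percent changes are reported
#' from the low end to the high end of the range (and, alternatively, from
#' the initial value to the high end).
#'
#' @param ranges an [parameter_ranges()] tibble.
#' @param n_points sweep points per parameter (before adding the initial
#'   value).
#' @param resolution,ns mesh controls, see [generate_mesh()].
#' @param profile an [airpuff_profile()].
#' @param cfg a [solver_config()].
#' @param stress_free_iters stress-free iterations per evaluation.
#' @param params subset of parameter names to sweep (default all six).
#' @return an object of class `apdi_sensitivity`: list with `records` (one
#'   row per solve: param, value, AD, CPR, AR) and `summary` (one row per
#'   param x output: percent change over the range and from the initial
#'   value).
#' @export
sensitivity_study <- function(ranges = parameter_ranges(), n_points = 5,
                              resolution = 5000, ns = 2,
                              profile = airpuff_profile(),
                              cfg = solver_config(), stress_free_iters = 3,
                              params = ranges$param) {
  cache <- new.env(parent = emptyenv())
  initial <- as.list(setNames(ranges$initial, ranges$param))
  rec <- list()
  for (p in params) {
    row <- ranges[ranges$param == p, ]
    values <- sort(unique(c(seq(row$lower, row$upper, length.out = n_points),
                            row$initial)))
    for (v in values) {
      inputs <- initial
      inputs[[p]] <- v
      out <- tryCatch(
        study_forward(inputs, resolution, ns, profile, cfg,
                      stress_free_iters, cache),
        apdi_solver_error = function(e) {
          warning("solve failed for ", p, " = ", v, "; excluded")
          NULL
        })
      if (!is.null(out))
        rec[[length(rec) + 1L]] <- tibble::tibble(param = p, value = v, out)
    }
  }
  records <- dplyr::bind_rows(rec)
  summary <- dplyr::bind_rows(lapply(unique(records$param), function(p) {
    r <- records[records$param == p, ]
    row <- ranges[ranges$param == p, ]
    lo <- r[which.min(abs(r$value - row$lower)), ]
    hi <- r[which.max(r$value), ]
    ini <- r[which.min(abs(r$value - row$initial)), ]
    tibble::tibble(
      param = p,
      output = c("AD", "CPR", "AR"),
      low = as.numeric(lo[, c("AD", "CPR", "AR")]),
      high = as.numeric(hi[, c("AD", "CPR", "AR")]),
      at_initial = as.numeric(ini[, c("AD", "CPR", "AR")])) |>
      dplyr::mutate(
        percent_change = percent_change(.data$low, .data$high),
        percent_change_from_initial =
          percent_change(.data$at_initial, .data$high))
  }))
  structure(list(records = records, summary = summary, ranges = ranges,
                 resolution = resolution),
            class = "apdi_sensitivity")
}

#' @export
print.apdi_sensitivity <- function(x, ...) {
  cat("Sensitivity study (percent change over each parameter range):\n")
  print(tidyr::pivot_wider(x$summary[, c("param", "output", "percent_change")],
                           names_from = "output",
                           values_from = "percent_change"))
  invisible(x)
}

#' Random-sampling parametric study
#'
#' Draws `n` input sets, each parameter independently uniform over its range
#' (the posterior coefficient drawn as a ratio in 0.25-1 and multiplied by
#' the drawn mu), solves the forward model for every set with a per-IOP
#' stress-free preload, and computes the squared Pearson correlation between
#' each input and each output over the successful draws.
#'
#' @inheritParams sensitivity_study
#' @param n number of random input sets.
#' @param seed RNG seed (mandatory, for reproducibility).
#' @return an object of class `apdi_sampling`: list with `records` (inputs,
#'   outputs, draw index), `r_squared` (tibble: input, output, r_squared,
#'   p_value), `n_failed`, and the seed.
#' @export
random_sampling_study <- function(ranges = parameter_ranges(), n = 400, seed,
                                  resolution = 5000, ns = 2,
                                  profile = airpuff_profile(),
                                  cfg = solver_config(),
                                  stress_free_iters = 3) {
  stopifnot(!missing(seed))
  set.seed(seed)
  draws <- vapply(seq_len(nrow(ranges)), function(i)
    runif(n, ranges$lower[i], ranges$upper[i]), numeric(n))
  colnames(draws) <- ranges$param

  rec <- lapply(seq_len(n), function(k) {
    inputs <- as.list(draws[k, ])
    out <- tryCatch(
      study_forward(inputs, resolution, ns, profile, cfg, stress_free_iters),
      apdi_solver_error = function(e) NULL)
    if (is.null(out)) return(NULL)
    tibble::tibble(draw = k, !!!inputs,
                   mu_post = inputs$mu_post_ratio * inputs$mu, out)
  })
  failed <- vapply(rec, is.null, TRUE)
  records <- dplyr::bind_rows(rec[!failed])

  inputs <- c("mu", "thk", "iop", "mu_post", "mu_post_ratio", "al", "el")
  outputs <- c("AD", "CPR", "AR")
  r2 <- dplyr::bind_rows(lapply(inputs, function(xi)
    dplyr::bind_rows(lapply(outputs, function(yo) {
      r <- if (nrow(records) >= 3) r_squared(records[[xi]], records[[yo]])
           else list(r_squared = NA_real_, p_value = NA_real_)
      tibble::tibble(input = xi, output = yo,
                     r_squared = r$r_squared, p_value = r$p_value)
    }))))
  structure(list(records = records, r_squared = r2,
                 n = n, n_failed = sum(failed), seed = seed,
                 ranges = ranges, resolution = resolution),
            class = "apdi_sampling")
}

#' @export
print.apdi_sampling <- function(x, ...) {
  cat(sprintf("Random-sampling study: %d draws (%d failed), seed %s\n",
              x$n, x$n_failed, format(x$seed)))
  print(tidyr::pivot_wider(x$r_squared[, c("input", "output", "r_squared")],
                           names_from = "output", values_from = "r_squared"))
  invisible(x)
}

#' Percent change between two output values
#'
#' `100 * (y_high - y_low) / y_low`.
#'
#' @param y_low output at the low end (or initial value).
#' @param y_high output at the high end.
#' @return percent change.
#' @export
#' @examples
#' percent_change(2.5, 0.7)  # -72
percent_change <- function(y_low, y_high) {
  if (any(y_low == 0)) stop("percent change undefined: zero baseline")
  100 * (y_high - y_low) / y_low
}

#' Squared Pearson correlation with p-value
#'
#' Coefficient of determination of the simple linear fit of `ys` on `xs`,
#' equal to the squared Pearson correlation; the p-value is from the
#' correlation test.
#'
#' @param xs,ys numeric vectors (at least 3 finite pairs).
#' @return list with `r_squared` and `p_value` (`NA` with a warning when a
#'   variable has zero variance).
#' @export
r_squared <- function(xs, ys) {
  ok <- is.finite(xs) & is.finite(ys)
  if (sum(ok) < 3) stop("r_squared needs at least 3 finite pairs")
  if (stats::var(xs[ok]) == 0 || stats::var(ys[ok]) == 0) {
    warning("r_squared undefined: zero variance")
    return(list(r_squared = NA_real_, p_value = NA_real_))
  }
  ct <- cor.test(xs[ok], ys[ok], method = "pearson")
  list(r_squared = unname(ct$estimate^2), p_value = ct$p.value)
}
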