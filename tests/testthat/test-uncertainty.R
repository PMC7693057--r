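test_that("zero covariance draws return the point estimate exactly", {
  fit <- structure(
    list(species = "a", endpoint_class = "survival", model = "response",
         C50 = 10, beta = 2, vcov_log = matrix(0, 2, 2), sse = 0,
         n_points = 6L, R0_used = NULL, converged = TRUE),
    class = "msar_fit")
  d <- sample_curve(fit)
  expect_equal(d$C50, 10)
  expect_equal(d$beta, 2)
})

test_that("draws are seed-deterministic and reproduce the input covariance", {
  vc <- matrix(c(0.04, 0.01, 0.01, 0.09), 2, 2)
  fit <- structure(
    list(species = "a", endpoint_class = "survival", model = "response",
         C50 = 10, beta = 2, vcov_log = vc, sse = 0.1, n_points = 6L,
         R0_used = NULL, converged = TRUE),
    class = "msar_fit")
  set.seed(5)
  d1 <- sample_curve(fit)
  set.seed(5)
  d2 <- sample_curve(fit)
  expect_identical(d1$C50, d2$C50)
  expect_identical(d1$beta, d2$beta)
  # law of large numbers: sample covariance of 1e5 log draws within 3%
  set.seed(6)
  draws <- t(replicate(1e5, {
    s <- sample_curve(fit)
    c(log(s$C50), log(s$beta))
  }))
  emp <- stats::cov(draws)
  expect_lt(max(abs(emp - vc)) / max(abs(vc)), 0.03)
})

test_that("non-PSD covariances are repaired with a warning", {
  vc <- matrix(c(0.01, 0.02, 0.02, 0.01), 2, 2) # indefinite
  fit <- structure(
    list(species = "a", endpoint_class = "survival", model = "response",
         C50 = 10, beta = 2, vcov_log = vc, sse = 0.1, n_points = 6L,
         R0_used = NULL, converged = TRUE),
    class = "msar_fit")
  set.seed(1)
  expect_warning(d <- sample_curve(fit), "PSD")
  expect_true(is.finite(d$C50) && is.finite(d$beta))
})

test_that("percentile intervals follow the linear-interpolation definition", {
  expect_equal(ci_from_samples(1:100, 0.95), c(3.475, 97.525))
  expect_equal(ci_from_samples(rep(7, 10), 0.95), c(7, 7))
  # symmetric samples give an interval symmetric about the median
  s <- c(-(10:1), 10:1)
  ci <- ci_from_samples(s, 0.5)
  expect_equal(ci[1], -ci[2])
  expect_error(ci_from_samples(numeric(0)), "2 samples")
  expect_error(ci_from_samples(1:10, 1.2), "level")
})

test_that("no uncertainty in, none out: zero covariances collapse the bands", {
  panel <- generate_panel(noise_free_spec(n_species = 8), seed = 21)
  fits <- fit_panel(panel$tox, panel$traits)
  # zero out the (already ~zero, noise-free) covariances exactly
  fits$fit <- purrr::map(fits$fit, function(f) {
    f$vcov_log <- matrix(0, 2, 2)
    f
  })
  env <- msar_envelope(fits, panel$traits, n_iter = 30, seed = 2,
                       grid = default_conc_grid(fits$C50, n = 60))
  expect_equal(env$hc5_ci[1], env$hc5_ci[2], tolerance = 1e-9)
  expect_equal(env$hc5_ci[1], env$det_hc5, tolerance = 1e-9)
  expect_equal(max(abs(env$upper - env$lower)), 0, tolerance = 1e-9)
})

test_that("deterministic curve and HC5 sit inside their own envelope", {
  panel <- generate_panel(panel_spec(n_species = 10), seed = 1)
  fits <- fit_panel(abbott_correct(panel$tox), panel$traits)
  env <- msar_envelope(fits, panel$traits, n_iter = 200, seed = 1,
                       grid = default_conc_grid(fits$C50, n = 60))
  expect_true(env$det_hc5 >= env$hc5_ci[1] && env$det_hc5 <= env$hc5_ci[2])
  inside <- mean(env$lower <= env$det_msar$msa + 1e-12 &
                   env$det_msar$msa <= env$upper + 1e-12)
  expect_gte(inside, 0.9)
  expect_true(all(env$upper - env$lower >= 0))
})

test_that("identical seeds give bit-identical envelopes", {
  panel <- generate_panel(panel_spec(n_species = 6), seed = 3)
  fits <- fit_panel(panel$tox, panel$traits)
  g <- default_conc_grid(fits$C50, n = 40)
  e1 <- msar_envelope(fits, panel$traits, n_iter = 40, seed = 11, grid = g)
  e2 <- msar_envelope(fits, panel$traits, n_iter = 40, seed = 11, grid = g)
  expect_identical(e1$hc5_samples, e2$hc5_samples)
  expect_identical(e1$lower, e2$lower)
  expect_identical(e1$upper, e2$upper)
})

test_that("inflating parameter variances never narrows the band", {
  panel <- generate_panel(panel_spec(n_species = 8), seed = 14)
  fits <- fit_panel(abbott_correct(panel$tox), panel$traits)
  g <- default_conc_grid(fits$C50, n = 40)
  widths <- function(fits_tbl, seeds) {
    vapply(seeds, function(s) {
      e <- msar_envelope(fits_tbl, panel$traits, n_iter = 60, seed = s,
                         grid = g)
      median(e$upper - e$lower)
    }, numeric(1))
  }
  doubled <- fits
  doubled$fit <- purrr::map(doubled$fit, function(f) {
    f$vcov_log <- 2 * f$vcov_log
    f
  })
  seeds <- 1:5
  expect_gte(median(widths(doubled, seeds)), median(widths(fits, seeds)))
})
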