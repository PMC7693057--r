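test_that("log-logistic response has its defining closed-form values", {
  expect_equal(loglogistic_response(10, C50 = 10, beta = 0.3), 0.5)
  expect_equal(loglogistic_response(10, C50 = 10, beta = 7), 0.5)
  expect_equal(loglogistic_response(0, C50 = 10, beta = 2), 0)
  expect_equal(loglogistic_response(30, C50 = 10, beta = 2), 0.9)
  # step-response limit, closed on the right
  expect_equal(loglogistic_response(c(5, 10, 15), 10, Inf), c(0, 0.5, 1))
})

test_that("log-logistic response is monotone nondecreasing in concentration", {
  set.seed(42)
  for (i in 1:50) {
    C50 <- exp(runif(1, -3, 5))
    beta <- exp(runif(1, -2, 3))
    conc <- sort(c(0, exp(runif(20, -5, 8))))
    y <- loglogistic_response(conc, C50, beta)
    expect_true(all(diff(y) >= 0))
    expect_true(all(y >= 0 & y <= 1))
  }
})

test_that("noise-free response data are recovered exactly", {
  d <- clean_response_data(C50 = 10, beta = 2, conc = c(1, 3, 10, 30, 100))
  fit <- fit_response(d)
  expect_true(fit$converged)
  expect_equal(fit$C50, 10, tolerance = 1e-6)
  expect_equal(fit$beta, 2, tolerance = 1e-6)
  expect_lt(fit$sse, 1e-12)
  # predicted response at the fitted C50 is 0.5 by construction
  expect_equal(predict(fit, fit$C50), 0.5)
})

test_that("mean C50 under replicated noise stays within 5% of truth", {
  set.seed(101)
  c50s <- replicate(200, {
    d <- clean_response_data(10, 2, conc = c(0, 1, 3, 10, 30, 100))
    d$response <- pmin(1, pmax(0, d$response + rnorm(nrow(d), 0, 0.03)))
    fit_response(d)$C50
  })
  expect_lt(abs(mean(c50s) / 10 - 1), 0.05)
})

test_that("degenerate inputs raise the documented errors", {
  expect_error(
    fit_response(tibble::tibble(concentration = c(5, 5, 5),
                                response = c(0.1, 0.5, 0.2))),
    "3 distinct")
  expect_error(
    fit_response(tibble::tibble(concentration = c(0, 1, 10),
                                response = c(0, 0, 0))),
    "no effect")
  expect_error(
    fit_response(tibble::tibble(concentration = c(0, 1, 10),
                                response = c(0.4, 0.4, 0.4))),
    "identical")
  expect_error(
    fit_abundance_direct(clean_abundance_data(5, 1.5, R0 = 2), R0 = 1),
    "R0")
})

test_that("fit SSE beats a dense grid-search oracle on small inputs", {
  set.seed(7)
  for (i in 1:5) {
    conc <- c(0, 1, 3, 10, 30)
    resp <- pmin(1, pmax(0, loglogistic_response(conc, 8, 1.5) +
                           rnorm(5, 0, 0.05)))
    d <- tibble::tibble(concentration = conc, response = resp)
    fit <- fit_response(d)
    oracle <- grid_search_sse(conc, resp, loglogistic_response)
    expect_lte(fit$sse, oracle + 1e-10)
  }
})

test_that("direct abundance fits recover generating parameters and honour R0", {
  d <- clean_abundance_data(C50 = 5, beta = 1.5, R0 = 2)
  fit <- fit_abundance_direct(d, R0 = 2)
  expect_equal(fit$C50, 5, tolerance = 1e-6)
  expect_equal(fit$beta, 1.5, tolerance = 1e-6)
  expect_equal(fit$R0_used, 2)
  # at c = C50 the modelled K-ratio is 1 - ln(2)/ln(R0): zero when R0 = 2
  expect_equal(1 - predict(fit, fit$C50), 0, tolerance = 1e-9)
})

test_that("EC10 extraction matches its closed form and definition", {
  expect_equal(ec10_from_fit(list(C50 = 10, beta = 1, model = "response")),
               10 / 9)
  expect_equal(ec10_from_fit(list(C50 = 10, beta = 2, model = "response")),
               10 * (1 / 9)^0.5)
  # step limit: EC10 -> C50 as the slope grows
  expect_equal(ec10_from_fit(list(C50 = 10, beta = 1e9, model = "response")),
               10, tolerance = 1e-6)
  set.seed(11)
  for (i in 1:20) {
    C50 <- exp(runif(1, -2, 4)); beta <- exp(runif(1, -1.5, 2.5))
    ec10 <- ec10_from_fit(list(C50 = C50, beta = beta, model = "response"))
    expect_lt(ec10, C50)
    expect_equal(loglogistic_response(ec10, C50, beta), 0.1,
                 tolerance = 1e-9)
  }
  expect_error(ec10_from_fit(list(C50 = 1, beta = 1, model = "abundance")),
               "species_ec10")
})

test_that("fit_panel maps fitters over groups and flags weighting", {
  panel <- generate_panel(noise_free_spec(n_species = 6), seed = 5)
  fits <- fit_panel(panel$tox, panel$traits)
  # one row per (chemical, species, endpoint) group, all converged
  groups <- dplyr::distinct(panel$tox, chemical, species, endpoint_class)
  expect_equal(nrow(fits), nrow(groups))
  expect_true(all(fits$converged))
  # abundance groups error without traits to supply R0
  algae_tox <- dplyr::filter(panel$tox, endpoint_class == "abundance")
  if (nrow(algae_tox) > 0) {
    expect_error(fit_panel(algae_tox), "R0")
  }
})
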