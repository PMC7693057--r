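rep_f <- function(C50 = 10, beta = 1) list(C50 = C50, beta = beta)

test_that("lifetime-fecundity ratio multiplies endpoint survival factors", {
  expect_equal(fecundity_ratio(0, rep_f(), rep_f()), 1)
  expect_equal(fecundity_ratio(10, rep_f(10, 2), rep_f(10, 3)), 0.25)
  expect_equal(fecundity_ratio(10, surv_fit = rep_f(10, 2)), 0.5)
  expect_error(fecundity_ratio(1), "at least one")
})

test_that("abundance ratio matches hand-evaluated population-growth theory", {
  # both endpoints at their half-maximal concentration, R0 = e^4:
  # 1 - (ln 2 + ln 2)/4
  expect_equal(
    abundance_ratio(10, rep_f(10, 1), rep_f(10, 1), R0 = exp(4)),
    1 - 2 * log(2) / 4)
  # R0 = e makes the raw value 1 - 2 ln 2 < 0: clamped to zero
  expect_equal(abundance_ratio(10, rep_f(10, 1), rep_f(10, 1), R0 = exp(1)), 0)
  expect_equal(abundance_ratio(0, rep_f(), rep_f(), R0 = 2), 1)
  expect_error(abundance_ratio(1, rep_f(), R0 = 1), "R0")
})

test_that("abundance ratio is nonincreasing and within [0, 1]", {
  set.seed(33)
  conc <- sort(c(0, exp(runif(30, -4, 7))))
  for (i in 1:30) {
    r0 <- exp(runif(1, 0.2, 4))
    k <- abundance_ratio(conc,
                         rep_f(exp(runif(1, -1, 4)), exp(runif(1, -1, 2))),
                         rep_f(exp(runif(1, -1, 4)), exp(runif(1, -1, 2))),
                         R0 = r0)
    expect_true(all(diff(k) <= 1e-12))
    expect_true(all(k >= 0 & k <= 1))
    expect_equal(k[1], 1)
  }
})

test_that("adding reproduction effects never raises abundance", {
  conc <- c(0, exp(seq(-2, 6, length.out = 40)))
  surv <- rep_f(30, 2)
  both <- abundance_ratio(conc, rep_f(10, 1.5), surv, R0 = 15)
  surv_only <- abundance_ratio(conc, surv_fit = surv, R0 = 15)
  expect_true(all(both <= surv_only + 1e-12))
})

test_that("noise-free single-endpoint curves invert through the direct fit", {
  conc <- c(0, 0.5, 1, 2, 5, 10, 30)
  r0 <- 7
  k <- abundance_ratio(conc, rep_fit = rep_f(4, 1.8), R0 = r0)
  fit <- fit_abundance_direct(
    tibble::tibble(concentration = conc, response = 1 - k), R0 = r0)
  expect_equal(fit$C50, 4, tolerance = 1e-6)
  expect_equal(fit$beta, 1.8, tolerance = 1e-6)
})

test_that("R0 resolution follows experimental > clonal > allometric precedence", {
  expect_equal(r0_from_traits(list(species = "a", R0 = 50, is_clonal = TRUE)), 50)
  expect_equal(r0_from_traits(list(species = "algae", is_clonal = TRUE)), 2)
  # r = 0.1/day and Tg = 20 days give R0 = e^2
  al <- allometry_params(a_r = 0.1, b_r = 0, a_T = 20, b_T = 0)
  expect_equal(r0_from_traits(list(species = "b", body_mass = 1), al), exp(2))
  expect_error(r0_from_traits(list(species = "c")), "c")
  expect_error(r0_from_traits(list(species = "d", R0 = 0.5)), "> 1")
  expect_error(r0_from_traits(list(species = "e", body_mass = 1),
                              allometry_params()),
               "intercepts")
})

test_that("opposite allometric scaling exponents make R0 mass-independent", {
  al <- allometry_params(a_r = 0.025, b_r = -0.25, a_T = 80, b_T = 0.25)
  w <- 10^seq(-4, -2, length.out = 9) # two orders of magnitude
  r0 <- vapply(w, function(wi) {
    r0_from_traits(list(species = "x", body_mass = wi), al)
  }, numeric(1))
  expect_lt(max(r0) / min(r0) - 1, 1e-10)
  # near-opposite exponents still vary < 10% over the same range
  al2 <- allometry_params(a_r = 0.025, b_r = -0.255, a_T = 80, b_T = 0.25)
  r02 <- vapply(w, function(wi) {
    r0_from_traits(list(species = "x", body_mass = wi), al2)
  }, numeric(1))
  expect_lt(max(r02) / min(r02) - 1, 0.1)
})

test_that("curve construction records its source and evaluates sanely", {
  cv <- abundance_curve("x", rep_fit = rep_f(), surv_fit = rep_f(), R0 = 10)
  expect_equal(cv$source, "combined_surv_rep")
  expect_equal(eval_abundance(cv, 0), 1)
  cv2 <- abundance_curve("y", surv_fit = rep_f(), R0 = 10)
  expect_equal(cv2$source, "survival_only")
  step <- abundance_curve("z", step_at = 5)
  expect_equal(eval_abundance(step, c(4.99, 5, 6)), c(1, 0, 0))
  expect_error(abundance_curve("w", R0 = 5), "component")
  expect_error(abundance_curve("v", rep_fit = rep_f(), R0 = 1), "R0")
})

test_that("curves table is assembled per species with resolved R0", {
  panel <- generate_panel(noise_free_spec(n_species = 10), seed = 6)
  fits <- fit_panel(panel$tox, panel$traits)
  curves <- build_abundance_curves(fits, panel$traits)
  expect_equal(sort(curves$species), sort(unique(panel$tox$species)))
  algae <- panel$truth$species[panel$truth$type == "algae"]
  expect_true(all(curves$source[curves$species %in% algae] ==
                    "direct_abundance"))
  expect_equal(curves$R0[curves$species %in% algae],
               rep(2, length(algae)))
  # survival-only animals keep their single-endpoint flag
  so <- panel$truth$species[panel$truth$type == "survival_only"]
  expect_true(all(curves$source[curves$species %in% so] == "survival_only"))
})
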