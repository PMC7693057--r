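# shared fixtures and independent oracles, built in code

# noise-free observations from a single log-logistic response curve
clean_response_data <- function(C50, beta, conc = c(0, 1, 3, 10, 30, 100)) {
  tibble::tibble(concentration = conc,
                 response = loglogistic_response(conc, C50, beta))
}

# noise-free direct exposure-abundance observations (fraction affected)
clean_abundance_data <- function(C50, beta, R0,
                                 conc = c(0, 0.5, 1, 2, 5, 10, 20)) {
  k <- pmin(1, pmax(0, 1 - log1p((conc / C50)^beta) / log(R0)))
  tibble::tibble(concentration = conc, response = 1 - k)
}

noise_free_spec <- function(n_species = 10, ...) {
  panel_spec(n_species = n_species, binom_n = NULL, gauss_sd = 0, ...)
}

# brute-force least-squares oracle: dense log-space grid over (C50, beta)
grid_search_sse <- function(conc, resp, predict_fn,
                            c50_range = c(0.01, 1000),
                            beta_range = c(0.1, 20), n = 120) {
  c50s <- exp(seq(log(c50_range[1]), log(c50_range[2]), length.out = n))
  betas <- exp(seq(log(beta_range[1]), log(beta_range[2]), length.out = n))
  best <- Inf
  for (b in betas) {
    for (cc in c50s) {
      sse <- sum((resp - predict_fn(conc, cc, b))^2)
      if (sse < best) best <- sse
    }
  }
  best
}

# bisection oracle for the 10%-abundance-loss concentration of a direct fit
ec10_direct_bisect <- function(C50, beta, R0, tol = 1e-12) {
  f <- function(c) (1 - log1p((c / C50)^beta) / log(R0)) - 0.9
  lo <- C50 * 1e-8
  hi <- C50
  for (i in 1:200) {
    mid <- sqrt(lo * hi)
    if (f(mid) > 0) lo <- mid else hi <- mid
    if (hi / lo - 1 < tol) break
  }
  sqrt(lo * hi)
}

# independent log-logistic MLE oracle: direct likelihood optimization
ssd_mle_oracle <- function(x) {
  nll <- function(par) {
    mu <- par[1]; s <- exp(par[2])
    -sum(stats::dlogis(log(x), location = mu, scale = s, log = TRUE))
  }
  opt <- stats::optim(c(mean(log(x)), log(stats::sd(log(x)) * 0.55)), nll)
  list(scale = exp(opt$par[1]), shape = 1 / exp(opt$par[2]))
}
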