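#' Draw one plausible exposure-response curve from a fit
#'
#' Samples `(C50, beta)` from the multivariate normal distribution on
#' `(log C50, log beta)` defined by the fit's asymptotic least-squares
#' covariance, then exponentiates. Each draw defines one possible
#' exposure-response curve around the optimal fit; sampling on log scale
#' keeps both parameters positive. A covariance that is not positive
#' semi-definite (a numerical artifact of near-singular Jacobians) is
#' repaired to the nearest PSD matrix by flooring its eigenvalues at zero,
#' with a warning.
#'
#' @param fit An `msar_fit` with a valid `vcov_log`.
#' @return A copy of `fit` with `C50` and `beta` replaced by the draw and a
#'   zero covariance. Uses the current RNG state; a zero covariance returns
#'   the point estimate exactly.
#' @export
sample_curve <- function(fit) {
  vc <- fit$vcov_log
  if (any(!is.finite(vc))) abort("fit covariance contains non-finite entries")
  if (all(vc == 0)) {
    draw <- c(log(fit$C50), log(fit$beta))
  } else {
    ev <- eigen(vc, symmetric = TRUE)
    if (any(ev$values < -1e-12 * max(abs(ev$values), 1e-300))) {
      warn(sprintf("fit %s/%s: covariance not PSD; projecting to nearest PSD",
                   fit$species, fit$endpoint_class))
      vc <- ev$vectors %*% diag(pmax(ev$values, 0)) %*% t(ev$vectors)
    }
    draw <- MASS::mvrnorm(1, mu = c(log(fit$C50), log(fit$beta)), Sigma = vc)
  }
  # numerical guard for unidentified directions (near-singular Jacobians can
  # give huge log-scale variances): keep exp() finite; a slope beyond e^200
  # is indistinguishable from a step response anyway
  draw <- pmin(200, pmax(-200, draw))
  out <- fit
  out$C50 <- exp(draw[1])
  out$beta <- exp(draw[2])
  out$vcov_log <- matrix(0, 2, 2)
  out
}

#' Percentile interval from Monte-Carlo samples
#'
#' Central empirical interval at probabilities `(1-level)/2` and
#' `1-(1-level)/2`, using linear-interpolation quantiles (type 7) so results
#' are reproducible across platforms.
#'
#' @param samples Numeric vector (>= 2 values).
#' @param level Coverage level in (0, 1).
#' @return Length-2 vector `c(lower, upper)`.
#' @examples
#' ci_from_samples(1:100, 0.95)
#' @export
ci_from_samples <- function(samples, level = 0.95) {
  if (length(samples) < 2) abort("need >= 2 samples for a percentile interval")
  if (!is_scalar_number(level) || level <= 0 || level >= 1) {
    abort("level must be in (0, 1)")
  }
  alpha <- (1 - level) / 2
  quantile7(samples, c(alpha, 1 - alpha))
}

# rebuild each species' K-ratios on the grid from (possibly resampled) fits;
# spec_list rows: list(type, fit_rows, R0)
eval_species_k <- function(comp, fits, grid) {
  if (comp$type == "direct") {
    f <- fits[[comp$idx]]
    return(clamp01(1 - abundance_affected(grid, f$C50, f$beta, f$R0_used)))
  }
  num <- rep(0, length(grid))
  for (i in comp$idx) {
    f <- fits[[i]]
    num <- num - log1p((grid / f$C50)^f$beta)
  }
  clamp01(num / log(comp$R0) + 1)
}

#' Monte-Carlo uncertainty envelope around the MSAR
#'
#' Propagates dose-response fit uncertainty into the community curve: in
#' each iteration every species' curve parameters are drawn independently
#' from their fit covariances ([sample_curve()]), the species
#' exposure-abundance curves are rebuilt, aggregated into one possible MSAR,
#' refitted with the log-logistic community form, and its HC5 recorded. The
#' envelope is the pointwise 2.5th-97.5th percentile band over iterations
#' (for `level = 0.95`); the HC5 interval is derived from the per-iteration
#' HC5s via `hc5_ci_method`. Lifetime-fecundity values are held fixed: only
#' exposure-response fit uncertainty is propagated.
#'
#' @param fits Fits tibble from [fit_panel()].
#' @param traits Traits table resolving each species' R0 (see
#'   [build_abundance_curves()]).
#' @param n_iter Number of Monte-Carlo iterations (default 1000).
#' @param seed Integer seed; identical inputs and seed give a bit-identical
#'   envelope.
#' @param grid Concentration grid; defaults to [default_conc_grid()] over
#'   the fitted C50s.
#' @param level Band level (default 0.95).
#' @param allometry Passed to [build_abundance_curves()].
#' @param chemical Identifier; defaults to the panel's single chemical.
#' @param hc5_ci_method Interval estimator for the HC5: `"normal"`
#'   (default) uses the normal-theory interval on `log(HC5)` -- point
#'   estimate times `exp(+/- z * sd)` of the log Monte-Carlo samples --
#'   which stays calibrated when the sampled HC5 distribution is skewed;
#'   `"percentile"` uses the raw central percentiles of the samples. The
#'   sampled HC5 distribution is typically left-skewed (dispersed parameter
#'   draws flatten the community curve, so few draws exceed the point
#'   estimate), which makes the percentile interval undercover; see the
#'   package vignette.
#' @param sigma_uncertainty Scale each fit's covariance per iteration by an
#'   inverse-chi-squared draw on its residual degrees of freedom, making the
#'   parameter draws multivariate-t (default `TRUE`). With only a few
#'   concentrations per test the residual variance is itself uncertain;
#'   plug-in normal draws understate the tails and the HC5 interval
#'   undercovers.
#' @return Object of class `msar_envelope`: `grid`, `lower`/`upper` band,
#'   deterministic curve and fit (`det_msar`, `det_fit`, `det_hc5`),
#'   `hc5_samples`, `hc5_ci`, `a_samples`, `beta_samples`, iteration
#'   bookkeeping (`n_iter`, `n_dropped`), `seed` and `level`. Iterations
#'   whose refit fails are dropped and counted; more than 10% drops is an
#'   error.
#' @export
msar_envelope <- function(fits, traits = NULL, n_iter = 1000, seed = NULL,
                          grid = NULL, level = 0.95, allometry = NULL,
                          chemical = NULL,
                          hc5_ci_method = c("normal", "percentile"),
                          sigma_uncertainty = TRUE) {
  hc5_ci_method <- match.arg(hc5_ci_method)
  fits <- fits[fits$converged, ]
  if (nrow(fits) == 0) abort("no converged fits to simulate from")
  chemical <- chemical %||% fits$chemical[1]
  if (!is.null(seed)) set.seed(seed)

  curves <- build_abundance_curves(fits, traits, allometry)
  if (is.null(grid)) grid <- default_conc_grid(fits$C50)
  det_msar <- aggregate_msar(curves, grid, chemical)
  det_fit <- fit_msar_loglogistic(det_msar)
  det_hc5 <- hc5_from_msar(det_fit)

  # per-species component map into the fits list
  comp_map <- purrr::map(seq_len(nrow(curves)), function(i) {
    cv <- curves$curve[[i]]
    if (cv$source == "direct_abundance") {
      list(type = "direct",
           idx = which(purrr::map_lgl(fits$fit, identical, cv$direct_fit)))
    } else {
      idx <- which(fits$species == cv$species &
                     fits$endpoint_class %in% c("reproduction", "survival"))
      list(type = "endpoint", idx = idx, R0 = cv$R0)
    }
  })

  n_grid <- length(grid)
  lower_mat <- matrix(NA_real_, nrow = n_grid, ncol = n_iter)
  hc5s <- a_s <- b_s <- rep(NA_real_, n_iter)
  start_par <- c(det_fit$a, det_fit$beta)
  for (it in seq_len(n_iter)) {
    drawn <- purrr::map(fits$fit, function(f) {
      if (sigma_uncertainty) {
        df <- max(f$n_points - 2L, 1L)
        f$vcov_log <- f$vcov_log * df / stats::rchisq(1, df)
      }
      sample_curve(f)
    })
    k <- vapply(comp_map, eval_species_k, numeric(n_grid),
                fits = drawn, grid = grid)
    msa <- rowMeans(k)
    ft <- tryCatch(
      ll_fit_core(grid, 1 - msa, loglogistic_response,
                  c50_start = start_par[1],
                  beta_starts = c(start_par[2], 1, 0.5, 2, 4, 8)),
      error = function(e) NULL
    )
    if (is.null(ft)) next
    lower_mat[, it] <- msa
    a_s[it] <- exp(ft$par[1])
    b_s[it] <- exp(ft$par[2])
    hc5s[it] <- a_s[it] * (1 / 19)^(1 / b_s[it])
  }
  ok <- which(is.finite(hc5s))
  n_dropped <- n_iter - length(ok)
  if (n_dropped > 0.1 * n_iter) {
    abort(sprintf("%d of %d Monte-Carlo iterations failed to refit", n_dropped, n_iter))
  }
  alpha <- (1 - level) / 2
  band <- apply(lower_mat[, ok, drop = FALSE], 1, quantile7,
                probs = c(alpha, 1 - alpha))
  hc5_ci <- if (hc5_ci_method == "normal") {
    z <- stats::qnorm(1 - alpha)
    det_hc5 * exp(c(-1, 1) * z * stats::sd(log(hc5s[ok])))
  } else {
    ci_from_samples(hc5s[ok], level)
  }
  structure(
    list(chemical = chemical, grid = grid,
         lower = band[1, ], upper = band[2, ],
         det_msar = det_msar, det_fit = det_fit, det_hc5 = det_hc5,
         hc5_samples = hc5s[ok], hc5_ci = hc5_ci,
         hc5_ci_method = hc5_ci_method,
         a_samples = a_s[ok], beta_samples = b_s[ok],
         n_iter = n_iter, n_dropped = n_dropped,
         seed = seed, level = level),
    class = "msar_envelope"
  )
}

#' @export
print.msar_envelope <- function(x, ...) {
  cat(sprintf(
    "<msar_envelope> %s: %d iterations (%d dropped), %.0f%% band\n  HC5 = %.4g ug/L (%.4g - %.4g)\n",
    x$chemical, x$n_iter, x$n_dropped, 100 * x$level,
    x$det_hc5, x$hc5_ci[1], x$hc5_ci[2]))
  invisible(x)
}
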