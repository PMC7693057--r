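#' Two-parameter log-logistic exposure-response curve
#'
#' The canonical sigmoidal model of chronic ecotoxicity: the expected fraction
#' of individuals affected at exposure concentration `conc` is
#' \deqn{\hat{Y}(c) = 1 - \frac{1}{1 + (c / C_{50})^{\beta}}}
#' where `C50` is the half-maximal effective (or lethal) concentration and
#' `beta` the Hill slope. The curve is 0 at the control (`conc = 0`), 0.5 at
#' `C50`, and approaches 1 as `conc` grows.
#'
#' @param conc Exposure concentration(s), same units as `C50` (>= 0).
#' @param C50 Half-maximal effective concentration (> 0).
#' @param beta Hill slope (> 0). `Inf` gives an all-or-nothing step response
#'   (0 below `C50`, 1 above, 0.5 at `C50`).
#' @return Fraction affected in \[0, 1\], vectorized over `conc`.
#' @examples
#' loglogistic_response(c(0, 10, 30), C50 = 10, beta = 2)
#' @export
loglogistic_response <- function(conc, C50, beta) {
  stopifnot(all(C50 > 0), all(beta > 0), all(conc >= 0))
  # concentration 0 handled exactly: (0/C50)^beta == 0 for all beta > 0
  ratio <- (conc / C50)^beta
  out <- 1 - 1 / (1 + ratio)
  step_tie <- is.infinite(beta) & conc == C50
  out[step_tie] <- 0.5
  out
}

# fraction affected under the direct exposure-abundance model: observed
# fraction-of-control K(c)/K(0) = 1 - ln(1 + (c/C50)^beta)/ln(R0), so the
# affected fraction is ln(1 + (c/C50)^beta)/ln(R0); unclamped for fitting
abundance_affected <- function(conc, C50, beta, R0) {
  log1p((conc / C50)^beta) / log(R0)
}

new_msar_fit <- function(C50, beta, vcov_log, sse, n_points,
                         species = NA_character_, endpoint_class = NA_character_,
                         model = c("response", "abundance"), R0_used = NULL,
                         converged = TRUE, message = NULL) {
  structure(
    list(
      species = species, endpoint_class = endpoint_class,
      model = match.arg(model),
      C50 = C50, beta = beta, vcov_log = vcov_log,
      sse = sse, n_points = n_points, R0_used = R0_used,
      converged = converged, message = message
    ),
    class = "msar_fit"
  )
}

#' @export
print.msar_fit <- function(x, ...) {
  cat(sprintf(
    "<msar_fit> %s / %s [%s]\n  C50 = %.4g, beta = %.4g, SSE = %.3g, n = %d%s\n",
    x$species, x$endpoint_class, x$model, x$C50, x$beta, x$sse, x$n_points,
    if (!is.null(x$R0_used)) sprintf(", R0 = %.3g", x$R0_used) else ""
  ))
  if (!x$converged) cat("  ** did not converge:", x$message, "\n")
  invisible(x)
}

#' @export
predict.msar_fit <- function(object, conc, ...) {
  if (object$model == "response") {
    loglogistic_response(conc, object$C50, object$beta)
  } else {
    abundance_affected(conc, object$C50, object$beta, object$R0_used)
  }
}

# deterministic start for C50: geometric mean of the two tested concentrations
# bracketing the target response level; fallback median positive concentration
start_c50 <- function(conc, resp, level = 0.5) {
  ord <- order(conc)
  conc <- conc[ord]; resp <- resp[ord]
  pos <- conc > 0
  cross <- which(resp[-length(resp)] < level & resp[-1] >= level)
  cross <- cross[conc[cross] > 0 & conc[cross + 1] > 0]
  if (length(cross) > 0) {
    i <- cross[1]
    return(geomean(c(conc[i], conc[i + 1])))
  }
  stats::median(conc[pos])
}

# Levenberg-Marquardt least squares on (log C50, log beta); deterministic
# multistart over beta. predict_fn(conc, C50, beta) must return the modelled
# fraction affected.
ll_fit_core <- function(conc, resp, predict_fn, c50_start, weights = NULL,
                        beta_starts = c(1, 0.5, 2, 4, 8), ftol = 1e-10) {
  w <- if (is.null(weights)) rep(1, length(conc)) else weights / mean(weights)
  sw <- sqrt(w)
  resid_fn <- function(par) {
    sw * (resp - predict_fn(conc, exp(par[1]), exp(par[2])))
  }
  ctrl <- minpack.lm::nls.lm.control(ftol = ftol, ptol = 1e-10,
                                     maxiter = 200, maxfev = 2000)
  best <- NULL
  for (b0 in beta_starts) {
    fit <- tryCatch(
      suppressWarnings(minpack.lm::nls.lm(
        par = c(log(c50_start), log(b0)), fn = resid_fn, control = ctrl)),
      error = function(e) NULL
    )
    if (is.null(fit) || any(!is.finite(fit$par))) next
    if (is.null(best) || fit$deviance < best$deviance) best <- fit
    if (best$deviance < ftol) break
  }
  if (is.null(best)) return(NULL)
  best$accepted <- best$info %in% 1:4 || best$deviance <= ftol
  if (!best$accepted) {
    # iteration-capped fits on a flat slope manifold: accept if a restart
    # from the final parameters cannot improve the cost any further
    re <- tryCatch(
      suppressWarnings(minpack.lm::nls.lm(par = best$par, fn = resid_fn,
                                          control = ctrl)),
      error = function(e) NULL
    )
    if (!is.null(re) && all(is.finite(re$par))) {
      stalled <- (best$deviance - re$deviance) <= 1e-8 * max(best$deviance, 1e-300)
      if (re$deviance <= best$deviance) {
        re$accepted <- re$info %in% 1:4 || re$deviance <= ftol || stalled
        best <- re
      } else if (stalled) {
        best$accepted <- TRUE
      }
    }
  }
  best
}

fit_vcov_log <- function(fit, n, p = 2L, var_ceiling = 4) {
  df <- n - p
  sigma2 <- if (df > 0) fit$deviance / df else 0
  vc <- NULL
  if (all(is.finite(fit$hessian))) {
    vc <- tryCatch(sigma2 * solve(fit$hessian), error = function(e) NULL)
    if (is.null(vc) || any(!is.finite(vc))) {
      vc <- tryCatch(sigma2 * MASS::ginv(fit$hessian),
                     error = function(e) NULL)
    }
  }
  # an overflowing Jacobian (saturated step-like optimum) leaves no usable
  # curvature information: report the weakly-identified ceiling instead
  if (is.null(vc) || any(!is.finite(vc))) {
    return(diag(var_ceiling, 2))
  }
  vc <- (vc + t(vc)) / 2
  # covariance conditioning: along a flat (unidentified) direction of the
  # sum-of-squares surface -- typically the slope when the tested design has
  # a single transition point -- the asymptotic variance diverges and a
  # Gaussian on that axis is meaningless. Cap the eigenvalues at 4 (1 sigma
  # of at most two natural-log units per direction; calibrated against
  # known-truth synthetic panels) so weakly identified directions contribute
  # bounded, not unbounded, uncertainty downstream.
  ev <- eigen(vc, symmetric = TRUE)
  if (any(ev$values > var_ceiling) || any(ev$values < 0)) {
    vals <- pmin(pmax(ev$values, 0), var_ceiling)
    vc <- ev$vectors %*% diag(vals) %*% t(ev$vectors)
    vc <- (vc + t(vc)) / 2
  }
  vc
}

check_fit_input <- function(conc, resp) {
  if (length(unique(conc)) < 3) {
    abort("need >= 3 distinct concentrations for a 2-parameter fit")
  }
  if (all(resp == 0)) {
    abort("no effect observed, C50 unidentifiable")
  }
  if (length(unique(resp)) == 1) {
    abort("all responses identical; C50 and slope unidentifiable")
  }
}

#' Fit a log-logistic exposure-response model
#'
#' Least-squares fit of [loglogistic_response()] to observed (concentration,
#' fraction affected) data for one species x endpoint, optimized on
#' `(log C50, log beta)` with a deterministic multistart over the slope.
#' The parameter covariance (on log scale) is taken from the Jacobian at the
#' optimum and drives the Monte-Carlo uncertainty propagation.
#'
#' @param data Data frame with columns `concentration` and `response`
#'   (fraction affected in \[0, 1\]); optionally `n_subjects`.
#' @param weight_by_n Weight residuals by `n_subjects` (default unweighted
#'   means).
#' @param species,endpoint_class Identifiers carried into the result.
#' @return An object of class `msar_fit` with elements `C50`, `beta`,
#'   `vcov_log` (2x2 covariance of the log parameters), `sse`, `n_points`,
#'   and `converged`. A non-convergent multistart returns a fit-failure
#'   object (`converged = FALSE`) carrying diagnostics rather than `NA`s.
#' @seealso [fit_abundance_direct()] for algal abundance/growth data,
#'   [ec10_from_fit()] for the 10%-effect concentration.
#' @examples
#' d <- data.frame(concentration = c(0, 1, 3, 10, 30, 100),
#'                 response = loglogistic_response(c(0, 1, 3, 10, 30, 100), 10, 2))
#' fit_response(d)
#' @export
fit_response <- function(data, weight_by_n = FALSE,
                         species = NA_character_,
                         endpoint_class = NA_character_) {
  conc <- data$concentration
  resp <- data$response
  check_fit_input(conc, resp)
  w <- if (weight_by_n && !is.null(data$n_subjects)) data$n_subjects else NULL
  fit <- ll_fit_core(conc, resp, loglogistic_response, start_c50(conc, resp), w)
  if (is.null(fit)) {
    return(new_msar_fit(NA_real_, NA_real_, matrix(0, 2, 2), NA_real_,
                        length(conc), species, endpoint_class,
                        converged = FALSE,
                        message = "all multistarts failed"))
  }
  new_msar_fit(
    C50 = exp(fit$par[1]), beta = exp(fit$par[2]),
    vcov_log = fit_vcov_log(fit, length(conc)),
    sse = fit$deviance, n_points = length(conc),
    species = species, endpoint_class = endpoint_class,
    converged = isTRUE(fit$accepted),
    message = if (!isTRUE(fit$accepted)) fit$message else NULL
  )
}

#' Fit the direct exposure-abundance model (algae)
#'
#' For taxa whose toxicity tests measure abundance or population growth
#' directly (e.g. algal frond or cell counts), the exposure-abundance curve
#' \deqn{K(c)/K(0) = 1 - \ln(1 + (c/C_{50})^{\beta}) / \ln R_0}
#' is fitted in one step, with `R0` the undisturbed lifetime fecundity
#' (2 for clonal species, where each division yields two daughters).
#'
#' @param data Data frame with `concentration` and `response` columns;
#'   `response` is stored in the package's canonical fraction-affected
#'   orientation, i.e. `1 - K(c)/K(0)`.
#' @param R0 Undisturbed lifetime fecundity (> 1).
#' @inheritParams fit_response
#' @return An `msar_fit` with `model = "abundance"` and `R0_used` recorded.
#' @export
fit_abundance_direct <- function(data, R0, weight_by_n = FALSE,
                                 species = NA_character_,
                                 endpoint_class = "abundance") {
  if (!is_scalar_number(R0) || R0 <= 1) {
    abort("R0 must be > 1 (ln R0 must be positive)")
  }
  conc <- data$concentration
  resp <- data$response
  check_fit_input(conc, resp)
  w <- if (weight_by_n && !is.null(data$n_subjects)) data$n_subjects else NULL
  # beyond the extinction concentration the population is gone and the
  # observed loss saturates at 1; floor the modelled abundance accordingly
  # so saturated observations do not drag the slope down
  pred <- function(conc, C50, beta) pmin(1, abundance_affected(conc, C50, beta, R0))
  # at c = C50 the affected fraction is ln(2)/ln(R0); bracket that level
  lvl <- min(log(2) / log(R0), 0.9 * max(resp))
  fit <- ll_fit_core(conc, resp, pred, start_c50(conc, resp, level = lvl), w)
  if (is.null(fit)) {
    return(new_msar_fit(NA_real_, NA_real_, matrix(0, 2, 2), NA_real_,
                        length(conc), species, endpoint_class,
                        model = "abundance", R0_used = R0, converged = FALSE,
                        message = "all multistarts failed"))
  }
  new_msar_fit(
    C50 = exp(fit$par[1]), beta = exp(fit$par[2]),
    vcov_log = fit_vcov_log(fit, length(conc)),
    sse = fit$deviance, n_points = length(conc),
    species = species, endpoint_class = endpoint_class,
    model = "abundance", R0_used = R0,
    converged = isTRUE(fit$accepted),
    message = if (!isTRUE(fit$accepted)) fit$message else NULL
  )
}

#' 10%-effect concentration from a fitted curve
#'
#' Closed form of the concentration at which the fitted log-logistic response
#' reaches 0.10: `C50 * (1/9)^(1/beta)`.
#'
#' @param fit An `msar_fit` from [fit_response()].
#' @return EC10 concentration (same units as `C50`).
#' @examples
#' ec10_from_fit(list(C50 = 10, beta = 2, model = "response"))
#' @export
ec10_from_fit <- function(fit) {
  if (!is.null(fit$model) && fit$model != "response") {
    abort("ec10_from_fit() applies to log-logistic response fits; use species_ec10() for direct abundance fits")
  }
  fit$C50 * (1 / 9)^(1 / fit$beta)
}

#' Fit every (chemical, species, endpoint) group of a toxicity table
#'
#' Maps [fit_response()] (survival/reproduction) or [fit_abundance_direct()]
#' (abundance/population growth, which needs each species' `R0`) over the
#' groups of a tidy toxicity table.
#'
#' @param tox Tidy toxicity table as returned by [read_tox_table()] or
#'   [generate_panel()].
#' @param traits Optional traits table (see [r0_from_traits()]); required if
#'   any group is of class abundance/population_growth.
#' @param allometry Allometric fallback parameters, see [allometry_params()].
#' @param weight_by_n Passed on to the fitters.
#' @return A tibble with one row per (chemical, species, endpoint_class):
#'   columns `C50`, `beta`, `sse`, `n_points`, `converged` and a `fit`
#'   list-column of `msar_fit` objects.
#' @export
fit_panel <- function(tox, traits = NULL, allometry = NULL,
                      weight_by_n = FALSE) {
  grouped <- tox |>
    dplyr::group_by(.data$chemical, .data$species, .data$endpoint_class) |>
    tidyr::nest() |>
    dplyr::ungroup()
  r0_lookup <- if (!is.null(traits)) {
    setNames(
      purrr::map_dbl(seq_len(nrow(traits)),
                     function(i) tryCatch(r0_from_traits(traits[i, ], allometry),
                                          error = function(e) NA_real_)),
      traits$species
    )
  }
  grouped$fit <- purrr::pmap(
    list(grouped$data, grouped$species, grouped$endpoint_class),
    function(d, sp, ec) {
      if (ec %in% inverted_classes) {
        r0 <- if (!is.null(r0_lookup) && sp %in% names(r0_lookup)) {
          r0_lookup[[sp]]
        } else NA_real_
        if (is.na(r0)) {
          abort(sprintf("species '%s' has %s data but no usable R0 trait", sp, ec))
        }
        fit_abundance_direct(d, R0 = r0, weight_by_n = weight_by_n,
                             species = sp, endpoint_class = ec)
      } else {
        fit_response(d, weight_by_n = weight_by_n,
                     species = sp, endpoint_class = ec)
      }
    }
  )
  grouped |>
    dplyr::mutate(
      C50 = purrr::map_dbl(.data$fit, "C50"),
      beta = purrr::map_dbl(.data$fit, "beta"),
      sse = purrr::map_dbl(.data$fit, "sse"),
      n_points = purrr::map_int(.data$fit, "n_points"),
      converged = purrr::map_lgl(.data$fit, "converged")
    ) |>
    dplyr::select(-"data")
}
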