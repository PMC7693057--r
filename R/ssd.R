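#' Per-species EC10 values from a fitted panel
#'
#' Extracts one EC10 per species from the same exposure-response fits that
#' underlie the MSAR, following the most-sensitive-endpoint convention of
#' regulatory species sensitivity distributions: the minimum across that
#' species' endpoint fits. Log-logistic response fits use the closed form
#' `C50 * (1/9)^(1/beta)`; direct abundance fits use the concentration of
#' 10% abundance loss, `C50 * (R0^0.1 - 1)^(1/beta)` (solve the
#' exposure-abundance curve for `K(c)/K(0) = 0.9`).
#'
#' @param fits Fits tibble from [fit_panel()].
#' @param rule `"min"` (most sensitive endpoint, default) or
#'   `"reproduction"` (prefer the reproduction endpoint, falling back to the
#'   minimum).
#' @return Tibble with columns `species`, `ec10`; species with no converged
#'   fit are excluded with a warning.
#' @export
species_ec10 <- function(fits, rule = c("min", "reproduction")) {
  rule <- match.arg(rule)
  ok <- fits[fits$converged, ]
  dropped <- setdiff(unique(fits$species), unique(ok$species))
  if (length(dropped) > 0) {
    warn(sprintf("species with no converged fit excluded from the SSD: %s",
                 paste(dropped, collapse = ", ")))
  }
  ok$ec10 <- purrr::map_dbl(ok$fit, function(f) {
    if (f$model == "response") {
      ec10_from_fit(f)
    } else {
      f$C50 * (f$R0_used^0.1 - 1)^(1 / f$beta)
    }
  })
  ok |>
    dplyr::group_by(.data$species) |>
    dplyr::summarise(
      ec10 = if (rule == "reproduction" &&
                 any(.data$endpoint_class == "reproduction")) {
        .data$ec10[.data$endpoint_class == "reproduction"][1]
      } else {
        min(.data$ec10)
      },
      .groups = "drop"
    )
}

new_ssd_fit <- function(ec10, scale, shape, chemical = NA_character_,
                        degenerate = FALSE) {
  structure(
    list(ec10 = ec10, scale = scale, shape = shape,
         n_species = length(ec10), chemical = chemical,
         degenerate = degenerate),
    class = "ssd_fit"
  )
}

#' @export
print.ssd_fit <- function(x, ...) {
  cat(sprintf("<ssd_fit> %s: n = %d species, scale = %.4g ug/L, shape = %.4g%s\n",
              x$chemical, x$n_species, x$scale, x$shape,
              if (x$degenerate) " (degenerate: zero variance)" else ""))
  invisible(x)
}

#' Fit a log-logistic species sensitivity distribution
#'
#' Maximum-likelihood fit of a log-logistic distribution to per-species
#' EC10 values. A log-logistic on concentration is a logistic on
#' log-concentration, so the MLE is obtained by fitting a logistic
#' distribution to `log(ec10)`: `scale = exp(location)` is the median
#' sensitivity and `shape = 1/scale_logistic` the spread parameter
#' (larger = tighter distribution).
#'
#' @param ec10 Positive per-species sensitivity values (>= 3 distinct), or a
#'   tibble from [species_ec10()].
#' @param chemical Identifier carried into the result.
#' @return Object of class `ssd_fit` with `scale`, `shape`, `n_species`.
#'   All-identical input returns the degenerate distribution
#'   (`shape = Inf`) flagged via `degenerate = TRUE`.
#' @export
fit_ssd <- function(ec10, chemical = NA_character_) {
  if (is.data.frame(ec10)) ec10 <- ec10$ec10
  if (length(ec10) < 3) abort("need >= 3 species to fit an SSD")
  if (any(!is.finite(ec10) | ec10 <= 0)) abort("EC10 values must be positive")
  if (length(unique(ec10)) == 1) {
    return(new_ssd_fit(ec10, scale = ec10[1], shape = Inf,
                       chemical = chemical, degenerate = TRUE))
  }
  lx <- log(ec10)
  # logistic sd = scale * pi / sqrt(3); moment-based start, bounded away
  # from zero so near-degenerate samples still optimize
  start <- list(location = stats::median(lx),
                scale = max(stats::sd(lx) * sqrt(3) / pi, 1e-6))
  ml <- suppressWarnings(
    MASS::fitdistr(lx, densfun = "logistic", start = start,
                   lower = c(-Inf, 1e-9), method = "L-BFGS-B")
  )
  new_ssd_fit(ec10, scale = exp(unname(ml$estimate["location"])),
              shape = 1 / unname(ml$estimate["scale"]),
              chemical = chemical)
}

#' SSD cumulative distribution: potentially affected fraction
#'
#' @param fit An [fit_ssd()] object.
#' @param conc Concentration(s) >= 0.
#' @return Fraction of species whose EC10 lies at or below `conc`.
#' @export
ssd_paf <- function(fit, conc) {
  stopifnot(all(conc >= 0))
  out <- numeric(length(conc))
  pos <- conc > 0
  if (is.infinite(fit$shape)) {
    out[pos] <- as.numeric(conc[pos] >= fit$scale)
  } else {
    out[pos] <- plogis(log(conc[pos]), location = log(fit$scale),
                       scale = 1 / fit$shape)
  }
  out
}

#' Hazardous concentration for 5% of species from an SSD
#'
#' The 5th percentile of the fitted log-logistic distribution:
#' `scale * (1/19)^(1/shape)`. Fitted on EC10 values this is the HC5-EC10.
#'
#' @param fit An [fit_ssd()] object.
#' @return HC5 concentration (ug/L).
#' @examples
#' hc5_from_ssd(list(scale = 10, shape = 1)) # 10/19
#' @export
hc5_from_ssd <- function(fit) {
  if (is.infinite(fit$shape)) return(fit$scale)
  fit$scale * (1 / 19)^(1 / fit$shape)
}

#' Bootstrap confidence interval for the SSD HC5
#'
#' Nonparametric bootstrap over species: resample the EC10 values with
#' replacement, refit the distribution, and take percentile bounds of the
#' resampled HC5s. Resamples that collapse to fewer than 3 distinct values
#' are dropped.
#'
#' @param fit An [fit_ssd()] object.
#' @param n_boot Number of bootstrap resamples.
#' @param level Interval level (default 0.95).
#' @return List with `lower`, `upper`, and the vector of `samples`. Uses the
#'   current RNG state; `set.seed()` beforehand for reproducibility.
#' @export
ssd_hc5_ci <- function(fit, n_boot = 1000, level = 0.95) {
  hc5s <- purrr::map_dbl(seq_len(n_boot), function(i) {
    x <- sample(fit$ec10, replace = TRUE)
    if (length(unique(x)) < 3) return(NA_real_)
    tryCatch(hc5_from_ssd(fit_ssd(x)), error = function(e) NA_real_)
  })
  hc5s <- hc5s[is.finite(hc5s)]
  ci <- ci_from_samples(hc5s, level)
  list(lower = ci[1], upper = ci[2], samples = hc5s)
}
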