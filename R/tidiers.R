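#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy a fitted exposure-response curve
#'
#' @param x An `msar_fit`.
#' @param ... Unused.
#' @return Tibble with one row per parameter: `term`, `estimate`,
#'   `std.error` (delta-method, natural scale).
#' @method tidy msar_fit
#' @export
tidy.msar_fit <- function(x, ...) {
  se_log <- sqrt(pmax(diag(x$vcov_log), 0))
  tibble::tibble(
    term = c("C50", "beta"),
    estimate = c(x$C50, x$beta),
    std.error = c(x$C50, x$beta) * se_log
  )
}

#' @rdname tidy.msar_fit
#' @return `glance()`: one-row tibble with fit metadata (`sse`, `n_points`,
#'   `df.residual`, `converged`, `model`, `R0_used`, `ec10`).
#' @method glance msar_fit
#' @export
glance.msar_fit <- function(x, ...) {
  tibble::tibble(
    species = x$species, endpoint_class = x$endpoint_class, model = x$model,
    sse = x$sse, n_points = x$n_points, df.residual = x$n_points - 2L,
    converged = x$converged,
    R0_used = x$R0_used %||% NA_real_,
    ec10 = if (x$model == "response" && x$converged) ec10_from_fit(x) else NA_real_
  )
}

#' Tidy a community curve
#'
#' @param x An `msar_curve`.
#' @param ... Unused.
#' @return Tibble with `concentration`, `msa`, `msa_loss`.
#' @method tidy msar_curve
#' @export
tidy.msar_curve <- function(x, ...) {
  tibble::tibble(concentration = x$grid, msa = x$msa, msa_loss = 1 - x$msa)
}

#' @rdname tidy.msar_curve
#' @method glance msar_curve
#' @export
glance.msar_curve <- function(x, ...) {
  tibble::tibble(chemical = x$chemical, variant = x$variant,
                 n_species = x$n_species, n_grid = length(x$grid))
}

#' Tidy a log-logistic community fit
#'
#' @param x An `msar_loglogistic`.
#' @param ... Unused.
#' @return Tibble with `term` (`a`, `beta`) and `estimate`.
#' @method tidy msar_loglogistic
#' @export
tidy.msar_loglogistic <- function(x, ...) {
  tibble::tibble(term = c("a", "beta"), estimate = c(x$a, x$beta))
}

#' @rdname tidy.msar_loglogistic
#' @method glance msar_loglogistic
#' @export
glance.msar_loglogistic <- function(x, ...) {
  tibble::tibble(chemical = x$chemical, variant = x$variant,
                 a = x$a, beta = x$beta, sse = x$sse, n = x$n,
                 hc5 = hc5_from_msar(x))
}

#' Tidy a species sensitivity distribution fit
#'
#' @param x An `ssd_fit`.
#' @param ... Unused.
#' @return Tibble of the underlying species EC10s with fitted plotting
#'   positions (`paf`, the potentially affected fraction at each EC10).
#' @method tidy ssd_fit
#' @export
tidy.ssd_fit <- function(x, ...) {
  s <- sort(x$ec10)
  tibble::tibble(ec10 = s,
                 rank = seq_along(s),
                 empirical_paf = (seq_along(s) - 0.5) / length(s),
                 fitted_paf = ssd_paf(x, s))
}

#' @rdname tidy.ssd_fit
#' @method glance ssd_fit
#' @export
glance.ssd_fit <- function(x, ...) {
  tibble::tibble(chemical = x$chemical, scale = x$scale, shape = x$shape,
                 n_species = x$n_species, degenerate = x$degenerate,
                 hc5 = hc5_from_ssd(x))
}

#' Tidy a Monte-Carlo envelope
#'
#' @param x An `msar_envelope`.
#' @param ... Unused.
#' @return Tibble with `concentration`, deterministic `msa`, `lower`,
#'   `upper`.
#' @method tidy msar_envelope
#' @export
tidy.msar_envelope <- function(x, ...) {
  tibble::tibble(concentration = x$grid, msa = x$det_msar$msa,
                 lower = x$lower, upper = x$upper)
}

#' @rdname tidy.msar_envelope
#' @method glance msar_envelope
#' @export
glance.msar_envelope <- function(x, ...) {
  tibble::tibble(chemical = x$chemical, n_iter = x$n_iter,
                 n_dropped = x$n_dropped, level = x$level,
                 hc5 = x$det_hc5,
                 hc5_lower = x$hc5_ci[1], hc5_upper = x$hc5_ci[2])
}
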