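#' Default concentration grid for community curves
#'
#' 200 log-spaced points spanning from 1/100 of the smallest positive
#' concentration to 100 times the largest, with an exact control point
#' `c = 0` prepended. The wide log range ensures the half-maximal crossing of
#' the community curve is bracketed even when species sensitivities spread
#' over several orders of magnitude.
#'
#' @param conc Positive reference concentrations (e.g. tested concentrations
#'   or fitted C50s).
#' @param n Number of log-spaced points.
#' @param expand Multiplicative padding on each side.
#' @return Sorted concentration vector of length `n + 1` starting at 0.
#' @export
default_conc_grid <- function(conc, n = 200, expand = 100) {
  conc <- conc[is.finite(conc) & conc > 0]
  if (length(conc) == 0) abort("need at least one positive concentration")
  c(0, exp(seq(log(min(conc) / expand), log(max(conc) * expand),
               length.out = n)))
}

new_msar_curve <- function(chemical, grid, msa, curves, variant) {
  structure(
    list(chemical = chemical, grid = grid, msa = msa,
         n_species = length(curves), curves = curves, variant = variant),
    class = "msar_curve"
  )
}

#' @export
print.msar_curve <- function(x, ...) {
  cat(sprintf(
    "<msar_curve> %s (%s): %d species, grid of %d concentrations [%.3g, %.3g]\n",
    x$chemical, x$variant, x$n_species, length(x$grid), min(x$grid), max(x$grid)))
  invisible(x)
}

as_curve_list <- function(curves) {
  if (inherits(curves, "abundance_curve")) return(list(curves))
  if (is.data.frame(curves)) curves <- curves$curve
  if (!length(curves)) abort("empty set of abundance curves")
  stopifnot(all(purrr::map_lgl(curves, inherits, "abundance_curve")))
  curves
}

#' Aggregate species curves into a mean species abundance relationship
#'
#' The community-level mean species abundance at concentration `c` is the
#' unweighted arithmetic mean of the species' relative abundances:
#' \deqn{MSA(c) = \frac{1}{n}\sum_{i=1}^{n} K(c)_i / K(0)_i}
#' Evaluated over a concentration grid, this is the MSAR.
#'
#' @param curves Curves tibble from [build_abundance_curves()], a list of
#'   [abundance_curve()] objects, or a single curve.
#' @param grid Concentration grid (sorted, starting at 0); defaults to
#'   [default_conc_grid()] over the curves' C50s.
#' @param chemical Identifier carried into the result.
#' @param variant Variant label (see [variant_msar()]).
#' @return An object of class `msar_curve` with the grid, the MSA values,
#'   and the contributing curves.
#' @export
aggregate_msar <- function(curves, grid = NULL, chemical = "chemical",
                           variant = "default") {
  curves <- as_curve_list(curves)
  if (is.null(grid)) {
    refs <- unlist(purrr::map(curves, function(cv) {
      c(cv$rep_fit$C50, cv$surv_fit$C50, cv$direct_fit$C50, cv$step_at)
    }))
    grid <- default_conc_grid(refs)
  }
  if (is.unsorted(grid) || grid[1] != 0) {
    abort("grid must be sorted and start at 0")
  }
  k <- vapply(curves, eval_abundance, numeric(length(grid)), conc = grid)
  msa <- rowMeans(matrix(k, nrow = length(grid)))
  new_msar_curve(chemical, grid, msa, curves, variant)
}

new_msar_loglogistic <- function(a, beta, sse, n, chemical = NA_character_,
                                 variant = "default") {
  structure(list(a = a, beta = beta, sse = sse, n = n,
                 chemical = chemical, variant = variant),
            class = "msar_loglogistic")
}

#' @export
print.msar_loglogistic <- function(x, ...) {
  cat(sprintf("<msar_loglogistic> %s (%s): a = %.4g ug/L, beta = %.4g, SSE = %.3g\n",
              x$chemical, x$variant, x$a, x$beta, x$sse))
  invisible(x)
}

#' @export
predict.msar_loglogistic <- function(object, conc, ...) {
  1 - loglogistic_response(conc, object$a, object$beta)
}

#' Log-logistic refit of an MSAR
#'
#' Summarizes the piecewise community curve with the decreasing
#' two-parameter log-logistic form `MSA(c) = 1 / (1 + (c/a)^beta)`, the shape
#' forced by `MSA(0) = 1`. The half-maximal concentration `a` and community
#' slope `beta` are the community analogues of a species' C50 and Hill
#' slope, and HC5 extraction is defined on this fit.
#'
#' @param msar An [aggregate_msar()] result.
#' @return An object of class `msar_loglogistic` with `a`, `beta`, `sse`.
#' @export
fit_msar_loglogistic <- function(msar) {
  stopifnot(inherits(msar, "msar_curve"))
  d <- tibble::tibble(concentration = msar$grid, response = 1 - msar$msa)
  fit <- fit_response(d, species = msar$chemical, endpoint_class = "msar")
  if (!fit$converged) abort("log-logistic refit of the MSAR did not converge")
  new_msar_loglogistic(fit$C50, fit$beta, fit$sse, length(msar$grid),
                       chemical = msar$chemical, variant = msar$variant)
}

#' Hazardous concentration for 5% of species from an MSAR
#'
#' The concentration at which the fitted community curve shows a 5% loss of
#' mean species abundance: `a * (1/19)^(1/beta)`. With `on = "raw"` the 0.95
#' crossing of the piecewise MSAR itself is located by log-linear
#' interpolation instead.
#'
#' @param fit An `msar_loglogistic` fit (or, for `on = "raw"`, an
#'   `msar_curve`).
#' @param on `"fit"` (default) or `"raw"`.
#' @return HC5 concentration (ug/L).
#' @examples
#' hc5_from_msar(list(a = 10, beta = 1)) # 10/19
#' @export
hc5_from_msar <- function(fit, on = c("fit", "raw")) {
  on <- match.arg(on)
  if (on == "fit") {
    return(fit$a * (1 / 19)^(1 / fit$beta))
  }
  stopifnot(inherits(fit, "msar_curve"))
  msa <- fit$msa; grid <- fit$grid
  i <- which(msa < 0.95)[1]
  if (is.na(i)) abort("MSA never drops below 0.95 on the grid")
  if (i == 1 || grid[i - 1] == 0) return(grid[i])
  lg <- log(grid[c(i - 1, i)])
  m <- msa[c(i - 1, i)]
  exp(lg[1] + (0.95 - m[1]) * diff(lg) / diff(m))
}

#' Mean species abundance loss at a concentration
#'
#' `1 - MSA(c)`, evaluated on a fitted community curve
#' (`msar_loglogistic`) or by log-linear interpolation on a raw
#' `msar_curve`.
#'
#' @param x An `msar_loglogistic` or `msar_curve`.
#' @param conc Concentration(s), >= 0.
#' @return Fractional MSA loss in \[0, 1\].
#' @export
msa_loss_at <- function(x, conc) {
  stopifnot(all(conc >= 0))
  if (inherits(x, "msar_curve")) {
    pos <- x$grid > 0
    f <- stats::approxfun(log(x$grid[pos]), x$msa[pos], rule = 2)
    msa <- ifelse(conc == 0, 1, f(log(pmax(conc, min(x$grid[pos])))))
    return(1 - msa)
  }
  loglogistic_response(conc, x$a, x$beta)
}

#' Variant community curves: endpoint choice and intraspecies variation
#'
#' Rebuilds the MSAR under one of two alternative assumptions probed by the
#' framework:
#' * `reproduction_only` - each species contributes only its reproduction
#'   fit; species without a reproduction endpoint are dropped with a
#'   warning. Removing survival effects can only raise abundance, so this
#'   variant lies at or above the default curve.
#' * `no_intraspecies_variation` - every fitted slope is taken to infinity:
#'   each species responds all-or-nothing at its most sensitive half-maximal
#'   concentration, `min(EC50, LC50)` (the direct-fit C50 for algae). The
#'   community curve then equals 1 minus the empirical CDF of those
#'   thresholds (a species at exactly its threshold counts as lost).
#'
#' @param curves Curves tibble or list (see [aggregate_msar()]).
#' @param variant One of `"default"`, `"reproduction_only"`,
#'   `"no_intraspecies_variation"`.
#' @inheritParams aggregate_msar
#' @return An `msar_curve` with the variant flag set.
#' @export
variant_msar <- function(curves, variant = c("default", "reproduction_only",
                                             "no_intraspecies_variation"),
                         grid = NULL, chemical = "chemical") {
  variant <- match.arg(variant)
  curves <- as_curve_list(curves)
  if (variant == "default") {
    return(aggregate_msar(curves, grid, chemical, variant = "default"))
  }
  if (variant == "reproduction_only") {
    rebuilt <- purrr::map(curves, function(cv) {
      if (is.null(cv$rep_fit)) NULL
      else abundance_curve(cv$species, rep_fit = cv$rep_fit, R0 = cv$R0)
    })
    dropped <- purrr::map_lgl(rebuilt, is.null)
    if (all(dropped)) abort("reproduction_only variant: no species carries a reproduction fit")
    if (any(dropped)) {
      warn(sprintf("reproduction_only variant: dropped %d species without a reproduction endpoint",
                   sum(dropped)))
    }
    return(aggregate_msar(rebuilt[!dropped], grid, chemical,
                          variant = "reproduction_only"))
  }
  rebuilt <- purrr::map(curves, function(cv) {
    thr <- min(c(cv$rep_fit$C50, cv$surv_fit$C50, cv$direct_fit$C50,
                 cv$step_at))
    abundance_curve(cv$species, step_at = thr)
  })
  aggregate_msar(rebuilt, grid, chemical, variant = "no_intraspecies_variation")
}
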