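#' Allometric fallback parameters for lifetime fecundity
#'
#' When a species lacks an experimental lifetime fecundity `R0` and is not
#' clonal, `R0` is estimated from body mass `W` (kg) through the allometric
#' scaling of the intrinsic rate of increase, `r(W) = a_r * W^b_r` (per day),
#' and of the generation time, `Tg(W) = a_T * W^b_T` (days), combined via
#' `r = ln(R0) / Tg` into `R0 = exp(r(W) * Tg(W))`. The canonical scaling
#' exponents are opposite (`b_r = -0.25`, `b_T = +0.25`), which makes the
#' estimated `R0` largely independent of body mass; the intercepts are
#' taxon-dependent and must be supplied from the literature.
#'
#' @param a_r,b_r Intercept (per day, at 1 kg) and exponent for the intrinsic
#'   rate of increase.
#' @param a_T,b_T Intercept (days, at 1 kg) and exponent for generation time.
#' @return A list of class `allometry_params`.
#' @export
allometry_params <- function(a_r = NULL, b_r = -0.25, a_T = NULL, b_T = 0.25) {
  structure(list(a_r = a_r, b_r = b_r, a_T = a_T, b_T = b_T),
            class = "allometry_params")
}

#' Undisturbed lifetime fecundity from species traits
#'
#' Resolves one `R0` per species with fixed precedence: an experimental
#' `R0` value wins; else clonal species (algae) get `R0 = 2` (one mother,
#' two daughters); else `R0` is estimated allometrically from body mass
#' (see [allometry_params()]).
#'
#' @param traits One-row data frame or list with fields `species`, and any of
#'   `R0`, `is_clonal`, `body_mass` (kg).
#' @param allometry [allometry_params()]; needed only for the body-mass route.
#' @return Scalar `R0 > 1`.
#' @examples
#' r0_from_traits(list(species = "L. minor", is_clonal = TRUE))
#' @export
r0_from_traits <- function(traits, allometry = NULL) {
  sp <- traits$species %||% "<unknown>"
  r0 <- traits$R0
  if (!is.null(r0) && length(r0) == 1 && is.finite(r0)) {
    if (r0 <= 1) abort(sprintf("species '%s': experimental R0 must be > 1", sp))
    return(as.numeric(r0))
  }
  if (isTRUE(traits$is_clonal)) return(2)
  w <- traits$body_mass
  if (!is.null(w) && length(w) == 1 && is.finite(w) && w > 0) {
    al <- allometry %||% allometry_params()
    if (is.null(al$a_r) || is.null(al$a_T)) {
      abort(sprintf(
        "species '%s': allometric R0 needs intercepts a_r and a_T (see allometry_params())", sp))
    }
    r <- al$a_r * w^al$b_r
    tg <- al$a_T * w^al$b_T
    r0 <- exp(r * tg)
    if (!is.finite(r0) || r0 <= 1) {
      abort(sprintf("species '%s': allometric R0 = %.3g is not > 1", sp, r0))
    }
    return(r0)
  }
  abort(sprintf(
    "species '%s': no usable trait (need R0, is_clonal = TRUE, or body_mass)", sp))
}

#' Change in lifetime fecundity under exposure
#'
#' The lifetime-fecundity ratio `R0(c)/R0(0)` is the product of the
#' probability of surviving exposure and the unaffected fraction of
#' reproduction:
#' \deqn{\frac{R_0(c)}{R_0(0)} = \frac{1}{1+(c/EC_{50})^{\beta_{rep}}}
#'       \times \frac{1}{1+(c/LC_{50})^{\beta_{surv}}}}
#' A missing endpoint contributes a factor of 1 (no effect).
#'
#' @param conc Exposure concentration(s).
#' @param rep_fit,surv_fit Fitted log-logistic curves ([fit_response()]), or
#'   any list with `C50` and `beta`; at least one must be supplied.
#' @return Ratio in \[0, 1\], vectorized over `conc`.
#' @export
fecundity_ratio <- function(conc, rep_fit = NULL, surv_fit = NULL) {
  if (is.null(rep_fit) && is.null(surv_fit)) {
    abort("at least one of rep_fit, surv_fit must be supplied")
  }
  out <- rep(1, length(conc))
  if (!is.null(rep_fit)) out <- out * (1 - loglogistic_response(conc, rep_fit$C50, rep_fit$beta))
  if (!is.null(surv_fit)) out <- out * (1 - loglogistic_response(conc, surv_fit$C50, surv_fit$beta))
  out
}

#' Relative abundance (carrying capacity) under exposure
#'
#' Under logistic growth with `r = ln(R0)/Tg` and a generation time
#' unaffected by the chemical, the relative intrinsic rate of increase -- and
#' with it the relative carrying capacity, i.e. relative abundance -- is
#' \deqn{\frac{K(c)}{K(0)} = \frac{r(c)}{r(0)} =
#'   \frac{-\ln(1+(c/EC_{50})^{\beta_{rep}}) - \ln(1+(c/LC_{50})^{\beta_{surv}})}
#'        {\ln R_0} + 1}
#' A missing endpoint drops its log term. Values below 0 (population no
#' longer viable) are clamped to 0 so the ratio stays a valid abundance
#' fraction.
#'
#' @inheritParams fecundity_ratio
#' @param R0 Undisturbed lifetime fecundity (> 1).
#' @return K-ratio in \[0, 1\], vectorized over `conc`; exactly 1 at `conc = 0`.
#' @examples
#' f <- list(C50 = 10, beta = 1)
#' abundance_ratio(c(0, 10), rep_fit = f, surv_fit = f, R0 = exp(4))
#' @export
abundance_ratio <- function(conc, rep_fit = NULL, surv_fit = NULL, R0) {
  if (is.null(rep_fit) && is.null(surv_fit)) {
    abort("at least one of rep_fit, surv_fit must be supplied")
  }
  if (!is_scalar_number(R0) || R0 <= 1) abort("R0 must be > 1 (ln R0 <= 0)")
  num <- rep(0, length(conc))
  if (!is.null(rep_fit)) num <- num - log1p((conc / rep_fit$C50)^rep_fit$beta)
  if (!is.null(surv_fit)) num <- num - log1p((conc / surv_fit$C50)^surv_fit$beta)
  clamp01(num / log(R0) + 1)
}

curve_source <- function(rep_fit, surv_fit, direct_fit) {
  if (!is.null(direct_fit)) return("direct_abundance")
  if (!is.null(rep_fit) && !is.null(surv_fit)) return("combined_surv_rep")
  if (!is.null(surv_fit)) return("survival_only")
  "reproduction_only"
}

#' Species-level exposure-abundance curve
#'
#' Bundles a species' fitted endpoint curves and its lifetime fecundity into
#' a single exposure-abundance evaluator `K(c)/K(0)` (see
#' [abundance_ratio()]); algal species fitted directly on abundance or
#' growth data use their one-step curve. `step_at` builds the degenerate
#' all-or-nothing curve (infinite slope) used by the no-intraspecies-variation
#' community variant: abundance 1 strictly below the threshold, 0 at or above
#' it.
#'
#' @param species Species identifier.
#' @param rep_fit,surv_fit,direct_fit `msar_fit` components (any subset; a
#'   `direct_fit` excludes the others).
#' @param R0 Lifetime fecundity (> 1); not needed for step curves.
#' @param step_at Optional threshold concentration for an all-or-nothing
#'   curve.
#' @return An object of class `abundance_curve`.
#' @seealso [eval_abundance()], [build_abundance_curves()]
#' @export
abundance_curve <- function(species, rep_fit = NULL, surv_fit = NULL,
                            direct_fit = NULL, R0 = NULL, step_at = NULL) {
  if (!is.null(step_at)) {
    return(structure(list(species = species, source = "step",
                          step_at = step_at, R0 = R0),
                     class = "abundance_curve"))
  }
  if (!is.null(direct_fit) && (!is.null(rep_fit) || !is.null(surv_fit))) {
    abort("a direct abundance fit cannot be combined with endpoint fits")
  }
  if (is.null(direct_fit) && is.null(rep_fit) && is.null(surv_fit)) {
    abort(sprintf("species '%s': no fitted component supplied", species))
  }
  r0 <- R0 %||% direct_fit$R0_used
  if (!is_scalar_number(r0) || r0 <= 1) {
    abort(sprintf("species '%s': R0 must be > 1", species))
  }
  structure(
    list(species = species,
         source = curve_source(rep_fit, surv_fit, direct_fit),
         rep_fit = rep_fit, surv_fit = surv_fit, direct_fit = direct_fit,
         R0 = r0),
    class = "abundance_curve"
  )
}

#' Evaluate an exposure-abundance curve
#'
#' @param curve An [abundance_curve()].
#' @param conc Concentration vector.
#' @return K-ratios in \[0, 1\]; exactly 1 at `conc = 0`.
#' @export
eval_abundance <- function(curve, conc) {
  switch(
    curve$source,
    step = as.numeric(conc < curve$step_at),
    direct_abundance = clamp01(
      1 - abundance_affected(conc, curve$direct_fit$C50,
                             curve$direct_fit$beta, curve$R0)),
    abundance_ratio(conc, rep_fit = curve$rep_fit, surv_fit = curve$surv_fit,
                    R0 = curve$R0)
  )
}

#' @export
print.abundance_curve <- function(x, ...) {
  cat(sprintf("<abundance_curve> %s [%s], R0 = %s\n", x$species, x$source,
              if (is.null(x$R0)) "-" else format(x$R0, digits = 4)))
  invisible(x)
}

#' Build exposure-abundance curves for a fitted panel
#'
#' Combines each species' converged endpoint fits with its lifetime fecundity
#' into one [abundance_curve()] per species. Animal species use survival
#' and/or reproduction fits through population-growth theory; species with a
#' direct abundance/growth fit use it as is. Species with only one endpoint
#' are retained (the missing endpoint is treated as no-effect) and flagged by
#' the curve's `source`.
#'
#' @param fits Fits tibble from [fit_panel()].
#' @param traits Traits table with one row per species (fields `species` and
#'   any of `R0`, `is_clonal`, `body_mass`); not needed for species whose
#'   only fit is a direct abundance fit (its `R0_used` is reused).
#' @param allometry [allometry_params()] for the body-mass fallback.
#' @return Tibble with columns `species`, `source`, `R0` and a `curve`
#'   list-column.
#' @export
build_abundance_curves <- function(fits, traits = NULL, allometry = NULL) {
  fits <- fits[fits$converged, ]
  if (nrow(fits) == 0) abort("no converged fits to build curves from")
  by_sp <- split(seq_len(nrow(fits)), fits$species)
  rows <- purrr::map(names(by_sp), function(sp) {
    idx <- by_sp[[sp]]
    comp <- setNames(fits$fit[idx], fits$endpoint_class[idx])
    direct <- comp[["abundance"]] %||% comp[["population_growth"]]
    if (!is.null(direct)) {
      cv <- abundance_curve(sp, direct_fit = direct)
    } else {
      tr <- if (!is.null(traits)) traits[traits$species == sp, ]
      if (is.null(tr) || nrow(tr) == 0) {
        abort(sprintf("species '%s' needs traits to resolve R0", sp))
      }
      r0 <- r0_from_traits(tr, allometry)
      cv <- abundance_curve(sp, rep_fit = comp[["reproduction"]],
                            surv_fit = comp[["survival"]], R0 = r0)
    }
    tibble::tibble(species = sp, source = cv$source, R0 = cv$R0,
                   curve = list(cv))
  })
  dplyr::bind_rows(rows)
}
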