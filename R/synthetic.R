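#' Specification for a synthetic multi-species toxicity panel
#'
#' Describes the study conditions a synthetic panel emulates: a metal-like
#' chemical tested on a mixed community of animal species (chronic survival
#' and reproduction tests) and clonal algae (direct abundance/growth tests),
#' with interspecies sensitivity spread over about an order of magnitude.
#' Defaults mirror the scale of real chronic data compilations: 15 species,
#' 6 test concentrations including a control, binomial counting noise on
#' survival groups and truncated Gaussian noise on fractional responses.
#'
#' @param n_species Number of species in the panel.
#' @param mix Named fractions (summing to 1) of species types:
#'   `both` animals with survival + reproduction tests, `survival_only`
#'   animals, `algae` with a direct abundance test.
#' @param c50_meanlog,c50_sdlog Log-normal interspecies distribution of the
#'   reproduction EC50 (ug/L); the default sd of 1.15 spreads central
#'   species over roughly one order of magnitude.
#' @param surv_factor_meanlog,surv_factor_sdlog Log-normal factor by which a
#'   species' LC50 exceeds its EC50 (reproduction is typically the more
#'   sensitive chronic endpoint).
#' @param beta_range Uniform range of Hill slopes.
#' @param r0_meanlog,r0_sdlog Log-normal lifetime fecundity of animal
#'   species (floored at 1.2); algae are clonal with `R0 = 2`.
#' @param n_conc Tested concentrations per study, including the control.
#' @param conc_span Geometric half-width of the tested range around each
#'   study's target C50; the default of 10 with 5 positive concentrations
#'   gives a spacing factor of ~3.2 between consecutive concentrations, the
#'   usual chronic-test dilution series.
#' @param binom_n Animals per survival test group (binomial noise);
#'   `NULL` disables survival noise.
#' @param gauss_sd Standard deviation of truncated Gaussian noise on
#'   fractional (reproduction/abundance) responses; 0 disables it.
#' @param chemical Chemical identifier stamped on all records.
#' @param seed Integer seed used by [generate_panel()].
#' @return List of class `panel_spec`.
#' @export
panel_spec <- function(n_species = 15,
                       mix = c(both = 0.6, survival_only = 0.2, algae = 0.2),
                       c50_meanlog = log(10), c50_sdlog = 1.15,
                       surv_factor_meanlog = log(3), surv_factor_sdlog = 0.3,
                       beta_range = c(1, 4),
                       r0_meanlog = log(20), r0_sdlog = 0.5,
                       n_conc = 6, conc_span = 10,
                       binom_n = 20, gauss_sd = 0.05,
                       chemical = "synthetic", seed = 1) {
  stopifnot(n_species >= 1, n_conc >= 3, conc_span > 1,
            all(beta_range > 0), c50_sdlog >= 0, gauss_sd >= 0)
  if (abs(sum(mix) - 1) > 1e-8) abort("mix fractions must sum to 1")
  if (!all(names(mix) %in% c("both", "survival_only", "algae"))) {
    abort("mix names must be both / survival_only / algae")
  }
  structure(as.list(environment()), class = "panel_spec")
}

# largest-remainder apportionment of n_species over the mix fractions
mix_counts <- function(n, mix) {
  raw <- n * mix
  base <- floor(raw)
  left <- n - sum(base)
  if (left > 0) {
    extra <- order(raw - base, decreasing = TRUE)[seq_len(left)]
    base[extra] <- base[extra] + 1
  }
  base
}

#' Generate a synthetic toxicity panel with known ground truth
#'
#' Draws per-species true curve parameters from the panel specification,
#' simulates the chronic tests at log-spaced concentrations (plus a control
#' at 0) with the specified noise, and returns the observations together
#' with the generating parameters so that every downstream stage can be
#' checked against truth.
#'
#' @param spec A [panel_spec()].
#' @param seed Overrides `spec$seed` when given.
#' @return List with elements `tox` (tidy toxicity tibble, fraction-affected
#'   orientation), `traits` (species traits tibble) and `truth` (one row per
#'   species: type, true `ec50_rep`, `beta_rep`, `lc50_surv`, `beta_surv`,
#'   `c50_direct`, `beta_direct`, `r0`).
#' @export
generate_panel <- function(spec, seed = NULL) {
  stopifnot(inherits(spec, "panel_spec"))
  set.seed(seed %||% spec$seed)
  counts <- mix_counts(spec$n_species, spec$mix)
  types <- rep(names(counts), counts)
  n <- length(types)
  sp_ids <- sprintf("sp%02d", seq_len(n))

  truth <- tibble::tibble(
    species = sp_ids, type = types,
    ec50_rep = NA_real_, beta_rep = NA_real_,
    lc50_surv = NA_real_, beta_surv = NA_real_,
    c50_direct = NA_real_, beta_direct = NA_real_,
    r0 = NA_real_
  )
  base_c50 <- rlnorm(n, spec$c50_meanlog, spec$c50_sdlog)
  rbeta_ <- function(k) runif(k, spec$beta_range[1], spec$beta_range[2])
  for (i in seq_len(n)) {
    if (types[i] == "both") {
      truth$ec50_rep[i] <- base_c50[i]
      truth$beta_rep[i] <- rbeta_(1)
      truth$lc50_surv[i] <- base_c50[i] *
        rlnorm(1, spec$surv_factor_meanlog, spec$surv_factor_sdlog)
      truth$beta_surv[i] <- rbeta_(1)
      truth$r0[i] <- max(1.2, rlnorm(1, spec$r0_meanlog, spec$r0_sdlog))
    } else if (types[i] == "survival_only") {
      truth$lc50_surv[i] <- base_c50[i]
      truth$beta_surv[i] <- rbeta_(1)
      truth$r0[i] <- max(1.2, rlnorm(1, spec$r0_meanlog, spec$r0_sdlog))
    } else {
      truth$c50_direct[i] <- base_c50[i]
      truth$beta_direct[i] <- rbeta_(1)
      truth$r0[i] <- 2
    }
  }

  noisy_frac <- function(p) {
    if (spec$gauss_sd > 0) clamp01(p + rnorm(length(p), 0, spec$gauss_sd)) else p
  }
  rows <- list()
  for (i in seq_len(n)) {
    target <- min(c(truth$ec50_rep[i], truth$lc50_surv[i],
                    truth$c50_direct[i]), na.rm = TRUE)
    conc <- c(0, exp(seq(log(target / spec$conc_span),
                         log(target * spec$conc_span),
                         length.out = spec$n_conc - 1)))
    add <- function(ec, resp, n_subj = NA_integer_) {
      rows[[length(rows) + 1]] <<- tibble::tibble(
        chemical = spec$chemical, species = sp_ids[i], endpoint_class = ec,
        concentration = conc, response = resp, n_subjects = n_subj)
    }
    if (types[i] %in% c("both", "survival_only")) {
      p <- loglogistic_response(conc, truth$lc50_surv[i], truth$beta_surv[i])
      obs <- if (!is.null(spec$binom_n) && is.finite(spec$binom_n)) {
        rbinom(length(p), spec$binom_n, p) / spec$binom_n
      } else p
      add("survival", obs,
          if (!is.null(spec$binom_n)) as.integer(spec$binom_n) else NA_integer_)
    }
    if (types[i] == "both") {
      p <- loglogistic_response(conc, truth$ec50_rep[i], truth$beta_rep[i])
      add("reproduction", noisy_frac(p))
    }
    if (types[i] == "algae") {
      k <- clamp01(1 - abundance_affected(conc, truth$c50_direct[i],
                                          truth$beta_direct[i], truth$r0[i]))
      # stored in canonical fraction-affected orientation
      add("abundance", 1 - noisy_frac(k))
    }
  }
  tox <- dplyr::bind_rows(rows)
  traits <- tibble::tibble(
    species = sp_ids,
    body_mass = NA_real_,
    R0 = ifelse(types == "algae", NA_real_, truth$r0),
    Tg = NA_real_,
    is_clonal = types == "algae"
  )
  list(tox = tox, traits = traits, truth = truth)
}

# abundance curves from true generator parameters (no fitting)
truth_curves <- function(truth) {
  purrr::map(seq_len(nrow(truth)), function(i) {
    tr <- truth[i, ]
    if (tr$type == "algae") {
      abundance_curve(
        tr$species,
        direct_fit = new_msar_fit(tr$c50_direct, tr$beta_direct,
                                  matrix(0, 2, 2), 0, 0L,
                                  species = tr$species,
                                  endpoint_class = "abundance",
                                  model = "abundance", R0_used = tr$r0))
    } else {
      abundance_curve(
        tr$species,
        rep_fit = if (!is.na(tr$ec50_rep)) list(C50 = tr$ec50_rep, beta = tr$beta_rep),
        surv_fit = if (!is.na(tr$lc50_surv)) list(C50 = tr$lc50_surv, beta = tr$beta_surv),
        R0 = tr$r0)
    }
  })
}

#' Ground-truth community curve of a synthetic panel
#'
#' Builds the MSAR directly from the generating parameters (no fitting),
#' through the same population-growth and aggregation code paths as the
#' estimation pipeline. This is the recovery target for end-to-end
#' validation.
#'
#' @param truth Truth tibble from [generate_panel()].
#' @param grid Concentration grid; defaults to [default_conc_grid()] over
#'   the true C50s.
#' @param chemical Identifier.
#' @return An `msar_curve`.
#' @export
true_msar <- function(truth, grid = NULL, chemical = "synthetic") {
  curves <- truth_curves(truth)
  if (is.null(grid)) {
    grid <- default_conc_grid(
      c(truth$ec50_rep, truth$lc50_surv, truth$c50_direct))
  }
  aggregate_msar(curves, grid, chemical)
}

#' @rdname true_msar
#' @return `true_hc5()`: the HC5 of the log-logistic refit of the
#'   ground-truth MSAR.
#' @export
true_hc5 <- function(truth, grid = NULL, chemical = "synthetic") {
  hc5_from_msar(fit_msar_loglogistic(true_msar(truth, grid, chemical)))
}
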