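#' Assemble a run configuration
#'
#' Collects everything one end-to-end analysis needs. Either file inputs
#' (`tox`, `traits` paths) or a simulation spec must be given.
#'
#' @param tox,traits Paths to input CSVs ([read_tox_table()] schema), or
#'   `NULL` when simulating.
#' @param simulate A [panel_spec()] to generate the inputs instead.
#' @param chemical Chemical to analyse (defaults to the single chemical
#'   present).
#' @param endpoint_map Label table for [categorize_endpoint()].
#' @param allometry [allometry_params()].
#' @param grid_n,grid_expand Grid settings for [default_conc_grid()].
#' @param variant MSAR variants to compute in addition to the default.
#' @param n_iter Monte-Carlo iterations for the envelope.
#' @param n_boot Bootstrap resamples for the SSD HC5 interval.
#' @param seed Integer seed recorded in every output.
#' @param out_dir Output directory (created if missing); `NULL` disables
#'   file output.
#' @return List of class `msar_config`.
#' @export
msar_config <- function(tox = NULL, traits = NULL, simulate = NULL,
                        chemical = NULL, endpoint_map = endpoint_label_map(),
                        allometry = NULL, grid_n = 200, grid_expand = 100,
                        variant = c("reproduction_only",
                                    "no_intraspecies_variation"),
                        n_iter = 1000, n_boot = 1000, seed = 1,
                        out_dir = NULL) {
  cfg <- structure(as.list(environment()), class = "msar_config")
  if (is.null(simulate)) {
    if (is.null(tox)) abort("config needs either input paths or a simulation spec")
    for (p in c(tox, traits)) {
      if (!file.exists(p)) abort(sprintf("input file not found: %s", p))
    }
  }
  cfg
}

#' Load a run configuration from YAML
#'
#' Reads a flat YAML file whose keys mirror the [msar_config()] arguments
#' (with `simulate:` holding [panel_spec()] arguments and `allometry:`
#' holding [allometry_params()] arguments).
#'
#' @param path YAML file.
#' @return An `msar_config`.
#' @export
read_config <- function(path) {
  y <- yaml::read_yaml(path)
  if (!is.null(y$simulate)) y$simulate <- do.call(panel_spec, y$simulate)
  if (!is.null(y$allometry)) y$allometry <- do.call(allometry_params, y$allometry)
  if (!is.null(y$variant)) y$variant <- unlist(y$variant)
  do.call(msar_config, y)
}

write_stage_json <- function(x, path, config_hash, seed) {
  jsonlite::write_json(
    c(list(config_hash = config_hash, seed = seed), x),
    path, auto_unbox = TRUE, digits = NA, null = "null", pretty = TRUE)
  invisible(path)
}

#' Compare MSAR- and SSD-based hazardous concentrations
#'
#' Builds the headline comparison for one chemical: the MSAR HC5 (5% loss
#' of mean species abundance) with its Monte-Carlo interval, the SSD
#' HC5-EC10 (5th percentile of the EC10 distribution) with its bootstrap
#' interval, their ratio, and the MSA loss the community curve predicts at
#' the SSD's own HC5-EC10 (with interval from the envelope's per-iteration
#' curves).
#'
#' @param envelope An [msar_envelope()] (or a bare `msar_loglogistic` fit,
#'   in which case intervals are omitted).
#' @param ssd An [fit_ssd()] result.
#' @param ssd_ci Optional [ssd_hc5_ci()] result.
#' @return One-row tibble.
#' @export
report_comparison <- function(envelope, ssd, ssd_ci = NULL) {
  has_env <- inherits(envelope, "msar_envelope")
  fit <- if (has_env) envelope$det_fit else envelope
  chem_m <- if (has_env) envelope$chemical else fit$chemical
  if (!is.na(chem_m) && !is.na(ssd$chemical) &&
      !identical(chem_m, ssd$chemical)) {
    abort(sprintf("chemical mismatch: MSAR '%s' vs SSD '%s'", chem_m, ssd$chemical))
  }
  msar_hc5 <- hc5_from_msar(fit)
  ssd_hc5 <- hc5_from_ssd(ssd)
  loss <- msa_loss_at(fit, ssd_hc5)
  loss_ci <- if (has_env) {
    ci_from_samples(
      loglogistic_response(ssd_hc5, envelope$a_samples, envelope$beta_samples),
      envelope$level)
  } else c(NA_real_, NA_real_)
  tibble::tibble(
    chemical = chem_m,
    msar_hc5 = msar_hc5,
    msar_hc5_lower = if (has_env) envelope$hc5_ci[1] else NA_real_,
    msar_hc5_upper = if (has_env) envelope$hc5_ci[2] else NA_real_,
    ssd_hc5_ec10 = ssd_hc5,
    ssd_hc5_lower = ssd_ci$lower %||% NA_real_,
    ssd_hc5_upper = ssd_ci$upper %||% NA_real_,
    hc5_ratio = msar_hc5 / ssd_hc5,
    msa_loss_at_ssd_hc5 = loss,
    msa_loss_lower = loss_ci[1],
    msa_loss_upper = loss_ci[2]
  )
}

#' Run the full exposure-to-risk workflow
#'
#' Executes the complete analysis for one chemical: read (or simulate) the
#' toxicity panel, fit every species x endpoint exposure-response curve,
#' convert to exposure-abundance curves, aggregate into the MSAR and refit
#' it, derive the MSAR HC5, build the companion EC10-based SSD and its
#' HC5-EC10, compute the requested variant curves, propagate fit
#' uncertainty with a Monte-Carlo envelope, and assemble the comparison
#' report. When `config$out_dir` is set, each stage is serialized to JSON
#' (`fits.json`, `msar.json`, `ssd.json`, `env.json`, `report.json`) plus a
#' `report.csv`, every file stamped with the seed and a hash of the
#' configuration.
#'
#' @param config An [msar_config()] or path to a YAML file for
#'   [read_config()].
#' @return (Invisibly) a list with `tox`, `traits`, `fits`, `curves`,
#'   `msar`, `msar_fit`, `msar_hc5`, `variants` (named list of
#'   `msar_curve`/`msar_loglogistic` pairs), `ec10`, `ssd`, `ssd_hc5`,
#'   `ssd_ci`, `envelope`, `report`.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_config(config)
  stopifnot(inherits(config, "msar_config"))
  cfg_hash <- rlang::hash(config[setdiff(names(config), "out_dir")])
  set.seed(config$seed)

  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      abort(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)))
    })
  }

  if (!is.null(config$simulate)) {
    panel <- stage("simulate", generate_panel(config$simulate, seed = config$seed))
    tox <- abbott_correct(panel$tox)
    traits <- panel$traits
  } else {
    tox <- stage("read", read_tox_table(config$tox,
                                        endpoint_map = config$endpoint_map))
    traits <- if (!is.null(config$traits)) {
      stage("read", readr::read_csv(config$traits, show_col_types = FALSE,
                                    progress = FALSE))
    }
  }
  chemical <- config$chemical %||% tox$chemical[1]
  tox <- tox[tox$chemical == chemical, ]
  if (nrow(tox) == 0) abort(sprintf("no records for chemical '%s'", chemical))

  fits <- stage("fit", fit_panel(tox, traits, config$allometry))
  curves <- stage("curves",
                  build_abundance_curves(fits, traits, config$allometry))
  grid <- default_conc_grid(fits$C50[fits$converged],
                            n = config$grid_n, expand = config$grid_expand)
  msar <- stage("msar", aggregate_msar(curves, grid, chemical))
  msar_fit <- stage("msar", fit_msar_loglogistic(msar))
  msar_hc5 <- hc5_from_msar(msar_fit)

  variants <- purrr::map(setNames(nm = config$variant), function(v) {
    stage(paste0("variant:", v), {
      vc <- variant_msar(curves, v, grid, chemical)
      list(curve = vc, fit = fit_msar_loglogistic(vc))
    })
  })

  ec10 <- stage("ssd", species_ec10(fits))
  ssd <- stage("ssd", fit_ssd(ec10, chemical))
  ssd_hc5 <- hc5_from_ssd(ssd)
  ssd_ci <- stage("ssd", ssd_hc5_ci(ssd, n_boot = config$n_boot))

  envelope <- stage("envelope",
                    msar_envelope(fits, traits, n_iter = config$n_iter,
                                  seed = config$seed, grid = grid,
                                  allometry = config$allometry,
                                  chemical = chemical))
  report <- stage("report", report_comparison(envelope, ssd, ssd_ci))

  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    out <- function(f) file.path(config$out_dir, f)
    write_fits(fits, out("fits.json"))
    write_stage_json(
      list(chemical = chemical, grid = msar$grid, msa = msar$msa,
           n_species = msar$n_species,
           fit = list(a = msar_fit$a, beta = msar_fit$beta,
                      sse = msar_fit$sse),
           hc5 = msar_hc5,
           variants = purrr::map(variants, function(v) {
             list(a = v$fit$a, beta = v$fit$beta, hc5 = hc5_from_msar(v$fit))
           })),
      out("msar.json"), cfg_hash, config$seed)
    write_stage_json(
      list(chemical = chemical, ec10 = ec10,
           scale = ssd$scale, shape = ssd$shape, n_species = ssd$n_species,
           hc5_ec10 = ssd_hc5,
           hc5_ci = list(lower = ssd_ci$lower, upper = ssd_ci$upper)),
      out("ssd.json"), cfg_hash, config$seed)
    write_stage_json(
      list(chemical = chemical, grid = envelope$grid,
           lower = envelope$lower, upper = envelope$upper,
           hc5 = envelope$det_hc5,
           hc5_ci = list(lower = envelope$hc5_ci[1],
                         upper = envelope$hc5_ci[2]),
           n_iter = envelope$n_iter, n_dropped = envelope$n_dropped),
      out("env.json"), cfg_hash, config$seed)
    write_stage_json(as.list(report), out("report.json"), cfg_hash, config$seed)
    readr::write_csv(report, out("report.csv"))
  }

  invisible(list(
    tox = tox, traits = traits, fits = fits, curves = curves,
    msar = msar, msar_fit = msar_fit, msar_hc5 = msar_hc5,
    variants = variants, ec10 = ec10, ssd = ssd, ssd_hc5 = ssd_hc5,
    ssd_ci = ssd_ci, envelope = envelope, report = report,
    config_hash = cfg_hash
  ))
}
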