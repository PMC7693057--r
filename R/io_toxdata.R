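#' Default endpoint label table
#'
#' Maps raw endpoint labels from toxicity studies onto the four endpoint
#' classes the framework distinguishes: `survival` and `reproduction` for
#' animal tests, `abundance` and `population_growth` for algal tests.
#' Extend or replace it to match your data source's vocabulary.
#'
#' @return Named character vector: `names` are lower-case raw labels,
#'   values are endpoint classes.
#' @export
endpoint_label_map <- function() {
  c(
    "survival" = "survival", "mortality" = "survival",
    "lethality" = "survival", "immobilisation" = "survival",
    "immobilization" = "survival",
    "reproduction" = "reproduction", "fecundity" = "reproduction",
    "hatchability" = "reproduction", "offspring" = "reproduction",
    "number of offspring" = "reproduction",
    "number of gravid adult females" = "reproduction",
    "eggs per female" = "reproduction", "spawning" = "reproduction",
    "abundance" = "abundance", "frond count" = "abundance",
    "cell density" = "abundance", "cell count" = "abundance",
    "biomass" = "abundance",
    "population growth" = "population_growth",
    "growth rate" = "population_growth",
    "intrinsic rate of increase" = "population_growth"
  )
}

#' Categorize raw endpoint labels
#'
#' @param raw_label Character vector of study endpoint labels.
#' @param mapping Label table, see [endpoint_label_map()].
#' @param strict Error on an unmapped label (`TRUE`) or return `NA` with a
#'   warning so the record can be skipped (`FALSE`).
#' @return Character vector of endpoint classes (or `NA` where unmapped).
#' @examples
#' categorize_endpoint(c("mortality", "Hatchability"))
#' @export
categorize_endpoint <- function(raw_label, mapping = endpoint_label_map(),
                                strict = TRUE) {
  key <- tolower(trimws(raw_label))
  # labels already given as one of the four classes pass through
  direct <- key %in% endpoint_classes
  out <- ifelse(direct, key, unname(mapping[key]))
  if (anyNA(out)) {
    bad <- unique(raw_label[is.na(out)])
    msg <- sprintf("unmapped endpoint label(s): %s", paste(bad, collapse = ", "))
    if (strict) abort(msg) else warn(paste(msg, "- records will be skipped"))
  }
  out
}

#' Abbott-style control correction
#'
#' When control groups show non-zero response (e.g. background mortality),
#' observed effect fractions are rescaled to the control:
#' `(r - r0) / (1 - r0)`, floored at 0, where `r0` is the mean response of
#' the concentration-0 group (or the lowest tested concentration if no true
#' control exists). Applied per (chemical, species, endpoint_class) group.
#'
#' @param tox Tidy toxicity table (fraction-affected orientation).
#' @return The table with corrected `response`.
#' @export
abbott_correct <- function(tox) {
  tox |>
    dplyr::group_by(.data$chemical, .data$species, .data$endpoint_class) |>
    dplyr::mutate(
      .r0 = mean(.data$response[.data$concentration == min(.data$concentration)]),
      response = ifelse(.data$.r0 > 0 & .data$.r0 < 1,
                        pmax(0, (.data$response - .data$.r0) / (1 - .data$.r0)),
                        .data$response)
    ) |>
    dplyr::ungroup() |>
    dplyr::select(-".r0")
}

default_tox_schema <- function() {
  c(chemical = "chemical", species = "species", endpoint = "endpoint",
    concentration = "concentration", response = "response",
    n_subjects = "n_subjects", survivors = "survivors", unit = "unit")
}

#' Read and validate a toxicity test table
#'
#' Reads a CSV/TSV of chronic toxicity observations into the package's
#' canonical tidy form: one row per (chemical, species, endpoint_class,
#' concentration) with `response` as *fraction affected* (0 at an unaffected
#' control). Count data (`survivors` of `n_subjects`) are converted to
#' fractions; abundance and population-growth records, which arrive as
#' fraction-of-control, are stored as `1 - fraction_of_control` so that a
#' single orientation flows through the whole pipeline (the endpoint class
#' records which records were inverted, preventing double inversion when the
#' direct abundance model is fitted).
#'
#' @param path CSV or TSV file with a header.
#' @param schema Named character vector mapping canonical field names
#'   (`chemical`, `species`, `endpoint`, `concentration`, `response`,
#'   `n_subjects`, `survivors`, `unit`) to the file's column names; unnamed
#'   fields default to their canonical names.
#' @param endpoint_map Label table for [categorize_endpoint()].
#' @param strict Error on unmapped endpoint labels.
#' @param control_correct Apply [abbott_correct()] (default `TRUE`).
#' @param unit_factors Optional named vector of multiplicative factors to
#'   micrograms per litre, looked up against the `unit` column (e.g.
#'   `c("mg/L" = 1000, "ug/L" = 1)`); concentrations are converted at read
#'   time so everything downstream is in ug/L.
#' @return Tibble with columns `chemical`, `species`, `endpoint_class`,
#'   `concentration` (ug/L), `response`, `n_subjects`.
#' @export
read_tox_table <- function(path, schema = NULL,
                           endpoint_map = endpoint_label_map(),
                           strict = TRUE, control_correct = TRUE,
                           unit_factors = NULL) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  reader <- if (grepl("\\.tsv$", path)) readr::read_tsv else readr::read_csv
  raw <- reader(path, show_col_types = FALSE, progress = FALSE)
  sc <- default_tox_schema()
  if (!is.null(schema)) sc[names(schema)] <- schema
  need <- c("chemical", "species", "endpoint", "concentration")
  missing_cols <- need[!sc[need] %in% names(raw)]
  if (length(missing_cols) > 0) {
    abort(sprintf("schema error: missing required column(s): %s",
                  paste(sc[missing_cols], collapse = ", ")))
  }
  has <- function(f) sc[[f]] %in% names(raw)
  col <- function(f) raw[[sc[[f]]]]

  tbl <- tibble::tibble(
    chemical = as.character(col("chemical")),
    species = as.character(col("species")),
    endpoint_raw = as.character(col("endpoint")),
    concentration = as.numeric(col("concentration")),
    n_subjects = if (has("n_subjects")) as.integer(col("n_subjects")) else NA_integer_,
    unit = if (has("unit")) as.character(col("unit")) else NA_character_
  )
  if (has("response")) {
    tbl$response <- as.numeric(col("response"))
  } else if (has("survivors") && has("n_subjects")) {
    tbl$response <- 1 - as.numeric(col("survivors")) / as.numeric(col("n_subjects"))
  } else {
    abort("schema error: need a 'response' column or 'survivors' + 'n_subjects'")
  }
  tbl$endpoint_class <- categorize_endpoint(tbl$endpoint_raw, endpoint_map,
                                            strict = strict)
  tbl <- tbl[!is.na(tbl$endpoint_class), ]

  if (has("unit") && !is.null(unit_factors)) {
    fac <- unit_factors[tbl$unit]
    if (anyNA(fac)) abort("unit column contains units absent from unit_factors")
    tbl$concentration <- tbl$concentration * as.numeric(fac)
  }

  # abundance / growth records arrive as fraction-of-control; invert
  inv <- tbl$endpoint_class %in% inverted_classes
  tbl$response[inv] <- 1 - tbl$response[inv]

  tbl <- dplyr::select(tbl, "chemical", "species", "endpoint_class",
                       "concentration", "response", "n_subjects")
  validate_tox_table(tbl)
  if (control_correct) tbl <- abbott_correct(tbl)
  tbl
}

#' Validate a tidy toxicity table
#'
#' Enforces the invariants stable 2-parameter fits rely on: non-negative
#' concentrations, responses in \[0, 1\], and every (chemical, species,
#' endpoint_class) group holding at least 3 distinct concentrations including
#' a control at or below the lowest effect level.
#'
#' @param tox Tidy toxicity table.
#' @param require_groups Also check the per-group invariants.
#' @return `tox`, invisibly, or an error listing offending rows.
#' @export
validate_tox_table <- function(tox, require_groups = TRUE) {
  bad_conc <- which(!is.finite(tox$concentration) | tox$concentration < 0)
  if (length(bad_conc) > 0) {
    abort(sprintf("validation error: negative/non-finite concentration in row(s) %s",
                  paste(head(bad_conc, 10), collapse = ", ")))
  }
  bad_resp <- which(!is.finite(tox$response) | tox$response < 0 | tox$response > 1)
  if (length(bad_resp) > 0) {
    abort(sprintf("validation error: response outside [0, 1] in row(s) %s",
                  paste(head(bad_resp, 10), collapse = ", ")))
  }
  if (require_groups) {
    chk <- tox |>
      dplyr::group_by(.data$chemical, .data$species, .data$endpoint_class) |>
      dplyr::summarise(
        n_conc = dplyr::n_distinct(.data$concentration),
        has_control = min(.data$concentration) == 0 ||
          .data$response[which.min(.data$concentration)][1] <= 0.05,
        .groups = "drop"
      )
    weak <- chk[chk$n_conc < 3 | !chk$has_control, ]
    if (nrow(weak) > 0) {
      abort(sprintf(
        "validation error: group(s) with < 3 distinct concentrations or no control: %s",
        paste(sprintf("%s/%s/%s", weak$chemical, weak$species,
                      weak$endpoint_class), collapse = "; ")))
    }
  }
  invisible(tox)
}

#' Write a tidy toxicity table to CSV
#'
#' Round-trips with [read_tox_table()] (with `control_correct = FALSE`): the
#' written file uses canonical column names and the internal fraction-affected
#' orientation is converted back to each endpoint's native orientation.
#'
#' @param tox Tidy toxicity table.
#' @param path Output CSV path.
#' @export
write_tox_table <- function(tox, path) {
  out <- tox
  inv <- out$endpoint_class %in% inverted_classes
  out$response[inv] <- 1 - out$response[inv]
  out <- dplyr::rename(out, endpoint = "endpoint_class")
  readr::write_csv(out, path)
  invisible(path)
}

#' Serialize a fitted panel
#'
#' `write_fits()` writes the per-group fit parameters to CSV (flat table)
#' and/or JSON (full objects including the log-scale covariance);
#' `read_fits()` restores the JSON form into the same fits tibble.
#'
#' @param fits Fits tibble from [fit_panel()].
#' @param path Output path; format chosen by extension (`.csv` or `.json`).
#' @export
write_fits <- function(fits, path) {
  if (grepl("\\.csv$", path)) {
    readr::write_csv(dplyr::select(fits, -"fit"), path)
  } else {
    recs <- purrr::map2(fits$fit, fits$chemical, function(f, chem) {
      list(species = f$species, endpoint_class = f$endpoint_class,
           chemical = chem,
           model = f$model, C50 = f$C50, beta = f$beta,
           vcov_log = f$vcov_log, sse = f$sse, n_points = f$n_points,
           R0_used = f$R0_used, converged = f$converged)
    })
    jsonlite::write_json(recs, path, auto_unbox = TRUE, digits = NA,
                         null = "null", pretty = TRUE)
  }
  invisible(path)
}

#' @rdname write_fits
#' @export
read_fits <- function(path) {
  recs <- jsonlite::read_json(path)
  fits <- purrr::map(recs, function(r) {
    new_msar_fit(
      C50 = r$C50, beta = r$beta,
      vcov_log = matrix(unlist(r$vcov_log), 2, 2),
      sse = r$sse, n_points = r$n_points,
      species = r$species, endpoint_class = r$endpoint_class,
      model = r$model, R0_used = r$R0_used,
      converged = isTRUE(r$converged)
    )
  })
  tibble::tibble(
    chemical = purrr::map_chr(recs, ~ .x$chemical %||% NA_character_),
    species = purrr::map_chr(fits, "species"),
    endpoint_class = purrr::map_chr(fits, "endpoint_class"),
    fit = fits,
    C50 = purrr::map_dbl(fits, "C50"),
    beta = purrr::map_dbl(fits, "beta"),
    sse = purrr::map_dbl(fits, "sse"),
    n_points = purrr::map_int(fits, "n_points"),
    converged = purrr::map_lgl(fits, "converged")
  )
}
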