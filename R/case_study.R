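#' Reproduce the metals case study from a compiled data set
#'
#' Runs the full workflow for each chemical in a user-supplied compilation
#' of chronic toxicity tests (e.g. the published cadmium/copper/zinc
#' compilation, which must be obtained separately and exported to CSV) and
#' returns the MSAR HC5 and SSD HC5-EC10 per chemical. The directory must
#' contain `tox.csv` (readable by [read_tox_table()]) and `traits.csv`
#' (fields of [r0_from_traits()]).
#'
#' @param dir Directory holding `tox.csv` and `traits.csv`.
#' @param n_iter,n_boot,seed Passed to [msar_config()].
#' @return Tibble with one row per chemical: the [report_comparison()]
#'   columns.
#' @export
reproduce_case_study <- function(dir, n_iter = 1000, n_boot = 1000, seed = 1) {
  tox_path <- file.path(dir, "tox.csv")
  traits_path <- file.path(dir, "traits.csv")
  if (!file.exists(tox_path) || !file.exists(traits_path)) {
    abort(sprintf(
      "case-study data not found under '%s' (need tox.csv and traits.csv; the compiled data set is distributed separately)",
      dir))
  }
  chems <- unique(readr::read_csv(tox_path, show_col_types = FALSE,
                                  progress = FALSE)$chemical)
  purrr::map_dfr(chems, function(ch) {
    res <- run_pipeline(msar_config(
      tox = tox_path, traits = traits_path, chemical = ch,
      n_iter = n_iter, n_boot = n_boot, seed = seed))
    res$report
  })
}
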