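#' @importFrom ggplot2 autoplot ggplot aes geom_line geom_point geom_ribbon
#'   geom_vline scale_x_log10 labs theme_minimal
#' @export
ggplot2::autoplot

log_breaks_x <- function() scale_x_log10()

#' Plot species exposure-abundance curves
#'
#' One relative-abundance curve `K(c)/K(0)` per species, on a log
#' concentration axis.
#'
#' @param curves Curves tibble from [build_abundance_curves()].
#' @param conc_range Concentration range; defaults to the curves' span.
#' @param n Points per curve.
#' @return A ggplot object.
#' @export
plot_abundance_curves <- function(curves, conc_range = NULL, n = 200) {
  cl <- as_curve_list(curves)
  if (is.null(conc_range)) {
    refs <- unlist(purrr::map(cl, function(cv) {
      c(cv$rep_fit$C50, cv$surv_fit$C50, cv$direct_fit$C50, cv$step_at)
    }))
    conc_range <- range(default_conc_grid(refs)[-1])
  }
  grid <- exp(seq(log(conc_range[1]), log(conc_range[2]), length.out = n))
  df <- purrr::map_dfr(cl, function(cv) {
    tibble::tibble(species = cv$species, source = cv$source,
                   concentration = grid, k_ratio = eval_abundance(cv, grid))
  })
  ggplot(df, aes(x = .data$concentration, y = .data$k_ratio,
                 colour = .data$species, linetype = .data$source)) +
    geom_line() +
    log_breaks_x() +
    labs(x = "concentration (µg/L)", y = "relative abundance K(c)/K(0)",
         colour = "species", linetype = "curve source") +
    theme_minimal()
}

#' @method autoplot msar_curve
#' @export
autoplot.msar_curve <- function(object, fit = NULL, ...) {
  df <- tidy.msar_curve(object)
  df <- df[df$concentration > 0, ]
  p <- ggplot(df, aes(x = .data$concentration, y = .data$msa)) +
    geom_line() +
    log_breaks_x() +
    labs(x = "concentration (µg/L)", y = "mean species abundance",
         title = sprintf("MSAR: %s (%s, n = %d species)", object$chemical,
                         object$variant, object$n_species)) +
    theme_minimal()
  if (!is.null(fit)) {
    fd <- tibble::tibble(concentration = df$concentration,
                         msa = predict(fit, df$concentration))
    p <- p + geom_line(data = fd, colour = "red", linetype = "dashed")
  }
  p
}

#' @method autoplot msar_envelope
#' @export
autoplot.msar_envelope <- function(object, ...) {
  df <- tidy.msar_envelope(object)
  df <- df[df$concentration > 0, ]
  ggplot(df, aes(x = .data$concentration)) +
    geom_ribbon(aes(ymin = .data$lower, ymax = .data$upper),
                fill = "grey70", alpha = 0.6) +
    geom_line(aes(y = .data$msa)) +
    geom_vline(xintercept = object$det_hc5, linetype = "dotted") +
    log_breaks_x() +
    labs(x = "concentration (µg/L)", y = "mean species abundance",
         title = sprintf("%s: MSAR with %.0f%% Monte-Carlo band (%d iterations)",
                         object$chemical, 100 * object$level, object$n_iter)) +
    theme_minimal()
}

#' @method autoplot ssd_fit
#' @export
autoplot.ssd_fit <- function(object, ...) {
  pts <- tidy.ssd_fit(object)
  grid <- exp(seq(log(min(object$ec10) / 10), log(max(object$ec10) * 10),
                  length.out = 200))
  cdf <- tibble::tibble(concentration = grid, paf = ssd_paf(object, grid))
  ggplot(pts, aes(x = .data$ec10, y = .data$empirical_paf)) +
    geom_point() +
    geom_line(data = cdf, aes(x = .data$concentration, y = .data$paf)) +
    geom_vline(xintercept = hc5_from_ssd(object), linetype = "dotted") +
    log_breaks_x() +
    labs(x = "EC10 (µg/L)", y = "potentially affected fraction",
         title = sprintf("SSD: %s (n = %d species)", object$chemical,
                         object$n_species)) +
    theme_minimal()
}
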