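#' Plot null Z-squared curves against divergence
#'
#' Mean Z-squared (log10 scale) as a function of target Ka, one line per
#' simulation setting, with Monte-Carlo standard errors; the horizontal
#' reference marks the equal-rates, uniform-sites expectation of 1.
#'
#' @param curves Tibble from \code{\link{null_curve}} or
#'   \code{\link{unequal_length_effect}}; an optional \code{lengths} (or
#'   any single extra grouping) column maps to colour.
#' @param colour Name of the grouping column (default \code{"lengths"} if
#'   present).
#' @return A ggplot object.
#' @export
plot_null_curve <- function(curves, colour = NULL) {
  if (is.null(colour) && "lengths" %in% names(curves)) colour <- "lengths"
  aes <- if (is.null(colour)) {
    ggplot2::aes(x = .data$target_ka, y = .data$mean_z2)
  } else {
    ggplot2::aes(x = .data$target_ka, y = .data$mean_z2,
                 colour = .data[[colour]], group = .data[[colour]])
  }
  ggplot2::ggplot(curves, aes) +
    ggplot2::geom_hline(yintercept = 1, linetype = 2, colour = "grey50") +
    ggplot2::geom_pointrange(ggplot2::aes(
      ymin = .data$mean_z2 - .data$se_z2,
      ymax = .data$mean_z2 + .data$se_z2)) +
    ggplot2::geom_line() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = expression(K[a]), y = expression(mean ~ Z^2)) +
    ggplot2::theme_minimal()
}

#' Paralog versus singleton substitution rates
#'
#' Scatter of the mean paralog clade Ka against the singleton outgroup
#' clade Ka per duplication (log scales), coloured by age class when
#' available; points above the diagonal are duplications whose paralogs
#' evolve faster than their nearest singleton ortholog.
#'
#' @param analysis An \code{asym_analysis}.
#' @return A ggplot object.
#' @export
plot_rate_comparison <- function(analysis) {
  stopifnot(inherits(analysis, "asym_analysis"))
  wide <- tidyr::pivot_wider(
    dplyr::select(analysis$rates, "family", "dup_node", "role", "ka"),
    names_from = "role", values_from = "ka")
  wide <- dplyr::mutate(wide, paralog_mean = (.data$paralog1 + .data$paralog2) / 2)
  wide <- dplyr::left_join(
    wide, dplyr::select(analysis$triplets, "family", "dup_node", "age_class"),
    by = c("family", "dup_node"))
  ggplot2::ggplot(wide, ggplot2::aes(x = .data$singleton,
                                     y = .data$paralog_mean,
                                     colour = .data$age_class)) +
    ggplot2::geom_abline(linetype = 2, colour = "grey50") +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::scale_x_log10() + ggplot2::scale_y_log10() +
    ggplot2::labs(x = expression(K[a] ~ (singleton)),
                  y = expression(K[a] ~ (paralogs)),
                  colour = "age class") +
    ggplot2::theme_minimal()
}

#' Polarized expression divergence against rate asymmetry
#'
#' Binned means of a polarized pair difference (default \code{d_me})
#' against log10 Z-squared, with standard errors: the layout in which a
#' negative trend in mean-expression difference reveals the faster copy
#' losing expression.
#'
#' @param pairs Pair-record tibble from \code{\link{build_pair_records}}.
#' @param measure Column to plot (default \code{"d_me"}).
#' @param bin_width Bin width in log10 Z-squared units (default 0.5).
#' @return A ggplot object.
#' @export
plot_polarized_divergence <- function(pairs, measure = "d_me", bin_width = 0.5) {
  df <- dplyr::filter(pairs, !is.na(.data$z2) & .data$z2 > 0 &
                        !is.na(.data[[measure]]))
  df$bin <- floor(log10(df$z2) / bin_width) * bin_width + bin_width / 2
  sm <- dplyr::summarise(
    dplyr::group_by(df, .data$bin),
    n = dplyr::n(), m = mean(.data[[measure]]),
    se = stats::sd(.data[[measure]]) / sqrt(dplyr::n()), .groups = "drop")
  ggplot2::ggplot(sm, ggplot2::aes(x = .data$bin, y = .data$m)) +
    ggplot2::geom_hline(yintercept = 0, linetype = 2, colour = "grey50") +
    ggplot2::geom_pointrange(ggplot2::aes(ymin = .data$m - .data$se,
                                          ymax = .data$m + .data$se)) +
    ggplot2::labs(x = expression(log[10] ~ Z^2), y = measure) +
    ggplot2::theme_minimal()
}
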