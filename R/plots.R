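# Convenience figures. These mirror the displays such studies publish:
# stacked state compositions per species, U values against the critical
# line, and calibrator-relative transcript abundances.

#' Stacked methylation-state composition per sample
#'
#' @param profiles A profile tibble from [build_profiles()].
#' @return A ggplot: one bar per sample (ordered by ploidy, then sample),
#'   stacked by methylation state.
#' @export
plot_profiles <- function(profiles) {
  assert_cols(profiles, c("sample", "p_non", "p_full", "p_hemi"),
              "profile table")
  long <- profiles |>
    dplyr::mutate(sample = factor(
      .data$sample,
      levels = .data$sample[order(.data$ploidy, .data$sample)]
    )) |>
    tidyr::pivot_longer(c("p_non", "p_full", "p_hemi"),
                        names_to = "state", values_to = "proportion") |>
    dplyr::mutate(state = factor(
      .data$state, levels = c("p_non", "p_hemi", "p_full"),
      labels = c("non-methylated", "hemi-methylated", "fully methylated")
    ))
  ggplot2::ggplot(long, ggplot2::aes(.data$sample, .data$proportion,
                                     fill = .data$state)) +
    ggplot2::geom_col() +
    ggplot2::scale_y_continuous(labels = function(x) 100 * x,
                                name = "% of informative CCGG sites") +
    ggplot2::labs(x = NULL, fill = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 60,
                                                       hjust = 1))
}

#' U values against the significance threshold
#'
#' @param u A tibble of U results ([midvalue_comparisons()] or
#'   [cross_ploidy_comparisons()]).
#' @param critical_value Horizontal reference line (default 1.96).
#' @return A ggplot faceted by measure.
#' @export
plot_u_values <- function(u, critical_value = 1.96) {
  assert_cols(u, c("measure", "u"), "U table")
  x_var <- if ("ploidy" %in% names(u)) "ploidy" else "ploidy_1"
  ggplot2::ggplot(u, ggplot2::aes(factor(.data[[x_var]]), .data$u)) +
    ggplot2::geom_jitter(width = 0.08, height = 0, alpha = 0.8) +
    ggplot2::geom_hline(yintercept = critical_value, linetype = 2) +
    ggplot2::facet_wrap(~measure) +
    ggplot2::labs(x = "ploidy level", y = "U") +
    ggplot2::theme_minimal()
}

#' @describeIn chained_normalization Bar chart of calibrator-relative
#'   quantities (mean +/- SE) per species and target gene.
#' @param object A `chained_norm` object.
#' @param ... Unused.
#' @exportS3Method ggplot2::autoplot
autoplot.chained_norm <- function(object, ...) {
  s <- object$summary |>
    dplyr::mutate(species = factor(
      .data$species,
      levels = unique(.data$species[order(.data$ploidy)])
    ))
  ggplot2::ggplot(s, ggplot2::aes(.data$species, .data$quantity,
                                  fill = .data$gene)) +
    ggplot2::geom_col(position = ggplot2::position_dodge(0.8),
                      width = 0.7) +
    ggplot2::geom_errorbar(
      ggplot2::aes(ymin = .data$quantity - .data$se,
                   ymax = .data$quantity + .data$se),
      position = ggplot2::position_dodge(0.8), width = 0.2
    ) +
    ggplot2::labs(x = NULL, fill = NULL,
                  y = sprintf("relative quantity (%s = 1)",
                              object$calibrator)) +
    ggplot2::theme_minimal()
}
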