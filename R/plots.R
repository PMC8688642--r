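#' Plot an averted-cases curve from a quit-proportion sweep
#'
#' @param object A `menthol_sweep` tibble from [quit_proportion_sweep()].
#' @param ... Unused.
#' @return A ggplot object: averted MI and stroke cases per million versus
#'   the proportion of menthol smokers who quit.
#' @method autoplot menthol_sweep
#' @export
autoplot.menthol_sweep <- function(object, ...) {
  long <- tidyr::pivot_longer(
    tibble::as_tibble(object),
    cols = c("averted_mi_per_million", "averted_stroke_per_million"),
    names_to = "outcome", values_to = "averted"
  )
  long$outcome <- ifelse(long$outcome == "averted_mi_per_million",
                         "Myocardial infarction", "Stroke")
  ggplot2::ggplot(long,
                  ggplot2::aes(x = .data$quit_proportion, y = .data$averted,
                               colour = .data$outcome)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(
      x = "Proportion of menthol smokers who quit",
      y = "Averted cases per million adults over the horizon",
      colour = NULL
    ) +
    ggplot2::theme_minimal()
}

#' Plot subgroup reductions from a comparison report
#'
#' Bar chart of within-cell percent reductions in MI and stroke by sex and
#' race/ethnicity, the disparity view of the policy effect.
#'
#' @param report A `menthol_report` from [comparison_report()].
#' @return A ggplot object.
#' @export
plot_subgroup_reductions <- function(report) {
  stopifnot(inherits(report, "menthol_report"))
  long <- tidyr::pivot_longer(
    report$subgroups,
    cols = c("mi_reduction_pct", "stroke_reduction_pct"),
    names_to = "outcome", values_to = "reduction_pct"
  )
  long$outcome <- ifelse(long$outcome == "mi_reduction_pct",
                         "Myocardial infarction", "Stroke")
  ggplot2::ggplot(long,
                  ggplot2::aes(x = .data$race_ethnicity,
                               y = .data$reduction_pct,
                               fill = .data$sex)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::facet_wrap(~outcome) +
    ggplot2::labs(x = NULL, y = "Percent reduction", fill = NULL) +
    ggplot2::theme_minimal()
}
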