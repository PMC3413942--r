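#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot counterfactual outcomes and the distribution of true responses
#'
#' Scatter of the two counterfactual weight changes per subject-period,
#' with each subject's true response \eqn{D_i} shown as the vertical gap.
#'
#' @param object A [simulate_potential_outcomes()] result.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.rrd_potential_outcomes <- function(object, ...) {
  dat <- tibble::as_tibble(object) |>
    tidyr::pivot_longer(c("y_control", "y_treat"),
                        names_to = "arm", values_to = "outcome") |>
    dplyr::mutate(arm = ifelse(.data$arm == "y_treat", "treatment", "control"))
  ggplot2::ggplot(dat, ggplot2::aes(.data$period, .data$outcome,
                                    colour = .data$arm,
                                    group = interaction(.data$subject_id, .data$arm))) +
    ggplot2::geom_line(alpha = 0.5) +
    ggplot2::geom_point(size = 1) +
    ggplot2::labs(x = "period", y = "weight change (kg)",
                  colour = NULL,
                  title = "Counterfactual outcomes by period",
                  subtitle = "vertical gap between a subject's lines = individual response D") +
    ggplot2::theme_minimal()
}

#' Plot individual-effect estimates
#'
#' Dot-and-interval plot of \eqn{\hat d_i} per subject, sorted by estimate.
#'
#' @param effects A tibble from [individual_effects()].
#' @return A ggplot.
#' @export
plot_individual_effects <- function(effects) {
  dat <- effects |>
    dplyr::arrange(.data$d_hat) |>
    dplyr::mutate(rank = dplyr::row_number())
  ggplot2::ggplot(dat, ggplot2::aes(.data$rank, .data$d_hat)) +
    ggplot2::geom_hline(yintercept = 0, linetype = 2) +
    ggplot2::geom_pointrange(ggplot2::aes(
      ymin = .data$d_hat - 1.96 * .data$std_error,
      ymax = .data$d_hat + 1.96 * .data$std_error), size = 0.2) +
    ggplot2::labs(x = "subject (sorted)", y = "estimated individual effect (kg)",
                  title = "Individual treatment-effect estimates") +
    ggplot2::theme_minimal()
}

#' Plot a design-efficiency comparison
#'
#' @param object An [run_efficiency()] result.
#' @param ... Unused.
#' @return A ggplot of relative efficiency vs the parallel-groups design.
#' @export
autoplot.rrd_efficiency <- function(object, ...) {
  dat <- tidy(object)
  ggplot2::ggplot(dat, ggplot2::aes(.data$design, .data$re_mean_effect)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::geom_errorbar(ggplot2::aes(
      ymin = .data$re_mean_effect - .data$re_se,
      ymax = .data$re_mean_effect + .data$re_se), width = 0.2) +
    ggplot2::geom_hline(yintercept = 1, linetype = 2) +
    ggplot2::labs(y = "relative efficiency vs PGD (Var ratio)", x = NULL,
                  title = "Design efficiency for the mean treatment effect") +
    ggplot2::theme_minimal()
}

#' Plot survey item distributions
#'
#' Stacked response-category proportions per item (after reverse-scoring),
#' the standard view for paired Likert comparisons.
#'
#' @param data A survey tibble (columns `q2`..`q5`, `q4`/`q5` on the
#'   administered reversed scale).
#' @return A ggplot.
#' @export
plot_survey_items <- function(data) {
  dat <- data |>
    dplyr::mutate(q4 = reverse_score(.data$q4),
                  q5 = reverse_score(.data$q5)) |>
    tidyr::pivot_longer(c("q2", "q3", "q4", "q5"),
                        names_to = "item", values_to = "score")
  ggplot2::ggplot(dat, ggplot2::aes(.data$item, fill = factor(.data$score))) +
    ggplot2::geom_bar(position = "fill") +
    ggplot2::scale_fill_brewer(palette = "RdYlGn", direction = 1) +
    ggplot2::labs(y = "proportion", fill = "score (5 = most positive)",
                  title = "Survey response distributions") +
    ggplot2::theme_minimal()
}
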