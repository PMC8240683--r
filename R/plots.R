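#' @importFrom ggplot2 autoplot ggplot aes geom_line geom_point geom_step
#'   geom_col geom_histogram labs coord_cartesian theme_minimal
NULL

#' @export
ggplot2::autoplot

#' PR curve of a fitness-model evaluation
#'
#' @param object a `commfit_eval` from [evaluate_fitness()].
#' @param ... unused.
#' @return a ggplot of the test-set precision-recall curve.
#' @export
autoplot.commfit_eval <- function(object, ...) {
  ggplot(object$test$pr_curve, aes(x = .data$recall, y = .data$precision)) +
    geom_step(direction = "vh") +
    coord_cartesian(xlim = c(0, 1), ylim = c(0, 1)) +
    labs(
      title = "Community fitness function, held-out PR curve",
      subtitle = sprintf("average precision = %.3f", object$test$average_precision),
      x = "Recall", y = "Precision"
    ) +
    theme_minimal()
}

#' Co-complex edge PR curve of an evaluation report
#'
#' @param object a `commfit_report` from [evaluate_communities()].
#' @param ... unused.
#' @return a ggplot; co-complex edge PR sweep when scores were available,
#'   otherwise a bar chart of the headline measures.
#' @export
autoplot.commfit_report <- function(object, ...) {
  if (!is.null(object$cocomplex_edge_pr)) {
    ggplot(object$cocomplex_edge_pr,
           aes(x = .data$recall, y = .data$precision)) +
      geom_line() + geom_point(size = 0.8) +
      coord_cartesian(xlim = c(0, 1), ylim = c(0, 1)) +
      labs(title = "Co-complex edge classification PR curve",
           x = "Recall", y = "Precision") +
      theme_minimal()
  } else {
    tidy(object) |>
      ggplot(aes(x = .data$measure, y = .data$value)) +
      geom_col() +
      coord_cartesian(ylim = c(0, 1)) +
      labs(title = "Community-set evaluation measures", x = NULL, y = "Value") +
      theme_minimal()
  }
}

#' Histogram of community sizes
#'
#' The size distribution drives the growth-step budget
#' ([max_steps_smart()]); inspecting it is the recommended way to sanity
#' check that budget.
#'
#' @param comms a community tibble.
#' @return a ggplot histogram of `size`.
#' @export
plot_community_sizes <- function(comms) {
  ggplot(comms, aes(x = .data$size)) +
    geom_histogram(binwidth = 1, boundary = 0.5) +
    labs(title = "Community size distribution", x = "Nodes per community",
         y = "Communities") +
    theme_minimal()
}
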