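# ggplot2 graphics for the main result types.

#' @importFrom ggplot2 ggplot aes geom_point geom_abline geom_col geom_boxplot
#'   geom_jitter geom_hline labs coord_flip theme_minimal autoplot
#'   stat_summary
NULL

#' @method autoplot cv_result
#' @export
autoplot.cv_result <- function(object, ...) {
  pred <- dplyr::filter(object$predictions, .data$rep == 1)
  ggplot(pred, aes(x = .data$observed, y = .data$predicted)) +
    geom_point(alpha = 0.6) +
    geom_abline(linetype = "dashed", colour = "grey50") +
    labs(title = sprintf("Cross-validated predictions (%s)", object$algorithm),
         subtitle = sprintf("mean r over repeats = %.3f", object$r_mean),
         x = "observed trait score", y = "out-of-fold prediction") +
    theme_minimal()
}

#' Specification-curve view of a multiverse sweep
#'
#' One point per design point (mean fold correlation), grouped by outcome and
#' ordered by the outcome's median performance.
#'
#' @param table a [run_multiverse()] result.
#' @return a ggplot object.
#' @export
plot_multiverse <- function(table) {
  summ <- summarise_multiverse(table)
  ord <- summ |>
    dplyr::group_by(.data$outcome) |>
    dplyr::summarise(med = stats::median(.data$r_mean)) |>
    dplyr::arrange(.data$med)
  summ$outcome <- factor(summ$outcome, levels = ord$outcome)
  ggplot(summ, aes(x = .data$outcome, y = .data$r_mean)) +
    geom_hline(yintercept = 0, colour = "grey60") +
    geom_jitter(width = 0.15, alpha = 0.5, size = 1) +
    geom_boxplot(outlier.shape = NA, fill = NA) +
    coord_flip() +
    labs(x = NULL, y = "cross-validated r (per model)",
         title = "Multiverse of brain-trait models") +
    theme_minimal()
}

#' Bar chart of design-factor importance
#' @param importance a [design_importance()] result.
#' @return a ggplot object.
#' @export
plot_design_importance <- function(importance) {
  imp <- dplyr::mutate(importance,
                       factor = stats::reorder(.data$factor,
                                               .data$importance_rmse))
  ggplot(imp, aes(x = .data$factor, y = .data$importance_rmse)) +
    geom_col(fill = "steelblue") +
    coord_flip() +
    labs(x = NULL, y = "increase in OOB RMSE when permuted",
         title = "Design-factor importance",
         subtitle = sprintf("forest explains %.0f%% of variance in fold r",
                            100 * attr(importance, "r_squared"))) +
    theme_minimal()
}

#' Bar chart of the variance decomposition
#' @param decomposition a [variance_decomposition()] result.
#' @return a ggplot object.
#' @export
plot_variance_decomposition <- function(decomposition) {
  ggplot(decomposition,
         aes(x = stats::reorder(.data$component, .data$sd), y = .data$sd)) +
    geom_col(fill = "darkorange") +
    coord_flip() +
    labs(x = NULL, y = "SD of fold correlations attributable to factor",
         title = "Variance decomposition of the multiverse") +
    theme_minimal()
}

#' Hold-out correlation change under virtual lesions
#' @param lesions a [lesion_analysis()] result.
#' @return a ggplot object.
#' @export
plot_lesion <- function(lesions) {
  ggplot(lesions,
         aes(x = stats::reorder(.data$unit, .data$delta_r),
             y = .data$delta_r)) +
    geom_col(fill = "firebrick") +
    geom_hline(yintercept = 0, colour = "grey40") +
    coord_flip() +
    labs(x = NULL, y = expression(Delta * r ~ "(lesioned - full model)"),
         title = sprintf("Virtual lesions (full-model hold-out r = %.3f)",
                         attr(lesions, "r_full"))) +
    theme_minimal()
}
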