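# ggplot2 displays for the main result types.

#' Volcano plot of a differential-expression comparison
#'
#' @param object A `tp53_de` result.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.tp53_de <- function(object, ...) {
  df <- as_tibble(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$log2_fc,
                                   y = -log10(pmax(.data$q_value,
                                                   1e-300)),
                                   colour = .data$passing)) +
    ggplot2::geom_point(alpha = 0.6, size = 0.8) +
    ggplot2::scale_colour_manual(values = c(`TRUE` = "firebrick",
                                            `FALSE` = "grey60")) +
    ggplot2::labs(
      x = "log2 fold change (group a / group b)",
      y = "-log10 FDR",
      colour = "passing",
      title = sprintf("%s: %s vs %s", attr(object, "cancer_type"),
                      attr(object, "group_a"), attr(object, "group_b"))) +
    ggplot2::theme_minimal()
}

#' Kaplan-Meier curves of a survival comparison
#'
#' @param object A `tp53_survcomp` result (not skipped).
#' @param ... Unused.
#' @return A ggplot of the per-stratum step curves.
#' @export
autoplot.tp53_survcomp <- function(object, ...) {
  if (object$skipped) {
    abort(paste0("comparison was skipped: ", object$reason),
          class = "tp53_validation_error")
  }
  curves <- object$curves |>
    group_by(.data$stratum) |>
    dplyr::group_modify(~ bind_rows(
      tibble(time = 0, survival = 1), select(.x, "time", "survival"))) |>
    ungroup()
  ggplot2::ggplot(curves, ggplot2::aes(x = .data$time,
                                       y = .data$survival,
                                       colour = .data$stratum)) +
    ggplot2::geom_step() +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = "time (months)", y = "survival probability",
                  title = sprintf("%s, log-rank p = %.3g",
                                  object$endpoint,
                                  object$test$p_value)) +
    ggplot2::theme_minimal()
}

#' Bar chart of variant-class proportions
#'
#' @param proportions Tibble from [class_proportions()].
#' @return A ggplot.
#' @export
plot_class_proportions <- function(proportions) {
  df <- mutate(proportions,
               variant_class = factor(.data$variant_class,
                                      levels = variant_classes()))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$variant_class,
                                   y = .data$proportion)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(x = NULL, y = "proportion of mutation records") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45,
                                                       hjust = 1))
}
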