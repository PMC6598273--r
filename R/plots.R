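# ggplot2 displays and broom-style summaries for fitted models and results.

#' Plot the backward-selection OOB curve of a model
#'
#' @param object An `ot_model` carrying a `selection_curve`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.ot_model <- function(object, ...) {
  if (is.null(object$selection_curve)) {
    abort("model carries no selection curve; fit with train_activity_model()")
  }
  sel <- length(object$features)
  ggplot2::ggplot(object$selection_curve,
                  ggplot2::aes(x = .data$n_features, y = .data$oob)) +
    ggplot2::geom_line(colour = "grey40") +
    ggplot2::geom_point(size = 0.6) +
    ggplot2::geom_vline(xintercept = sel, linetype = "dashed",
                        colour = "firebrick") +
    ggplot2::scale_x_reverse() +
    ggplot2::labs(x = "Features retained", y = "OOB error",
                  title = "Backward feature selection",
                  subtitle = sprintf("%d features selected", sel)) +
    ggplot2::theme_minimal()
}

#' Plot mean predicted activity per concentration tier
#'
#' @param tiers Tibble from [concentration_correlation()].
#' @return A ggplot.
#' @export
plot_tier_activity <- function(tiers) {
  d <- tiers[!is.na(tiers$min_active_concentration), , drop = FALSE]
  d$tier <- factor(d$min_active_concentration,
                   levels = sort(unique(d$min_active_concentration)))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$tier, y = .data$mean_prob)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(x = "Minimal active concentration (nM)",
                  y = "Mean predicted activity probability") +
    ggplot2::theme_minimal()
}

#' Plot the TPR/FPR trade-off over probability thresholds
#'
#' @param curve Tibble from [threshold_curve()].
#' @return A ggplot.
#' @export
plot_threshold_tradeoff <- function(curve) {
  long <- tidyr::pivot_longer(curve[, c("threshold", "tpr", "fpr")],
                              c("tpr", "fpr"), names_to = "rate",
                              values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$threshold, y = .data$value,
                                     colour = .data$rate)) +
    ggplot2::geom_line() +
    ggplot2::scale_colour_manual(values = c(tpr = "steelblue", fpr = "firebrick"),
                                 labels = c(tpr = "TPR", fpr = "FPR")) +
    ggplot2::labs(x = "Probability threshold", y = "Rate", colour = NULL) +
    ggplot2::theme_minimal()
}

#' Plot the mismatch-count distribution of a hit set
#'
#' @param hits Hits tibble.
#' @return A ggplot.
#' @export
plot_mismatch_distribution <- function(hits) {
  ggplot2::ggplot(hits, ggplot2::aes(x = factor(.data$n_mismatches),
                                     fill = .data$source)) +
    ggplot2::geom_bar() +
    ggplot2::labs(x = "Mismatches", y = "Off-target sites", fill = "Source") +
    ggplot2::theme_minimal()
}

#' Tidy an activity model into its importance table
#'
#' @param x An `ot_model`.
#' @param ... Unused.
#' @return Tibble (`feature`, `importance`) in descending importance.
#' @export
tidy.ot_model <- function(x, ...) {
  dplyr::arrange(x$importance, dplyr::desc(.data$importance), .data$feature)
}

#' One-row model summary
#'
#' @param x An `ot_model`.
#' @param ... Unused.
#' @return A one-row tibble with OOB error, tree and feature counts, the
#'   chosen repeat and the schema version.
#' @export
glance.ot_model <- function(x, ...) {
  tibble::tibble(oob = x$oob, ntree = x$ntree,
                 n_features = length(x$features),
                 repeat_index = x$repeat_index,
                 n_repeats = length(x$oob_all),
                 schema_version = x$schema_version)
}
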