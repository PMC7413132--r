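# ggplot2 visualizations for each result type.

#' @method autoplot gm_fit
#' @export
autoplot.gm_fit <- function(object, ...) {
  tidy(object) |>
    tidyr::pivot_longer(c("accuracy", "propensity"), names_to = "parameter") |>
    ggplot(aes(x = .data$value, y = .data$lf)) +
    geom_point() +
    facet_wrap(~parameter) +
    xlim(0, 1) +
    labs(x = NULL, y = NULL,
         title = "Generative label model: estimated LF parameters") +
    theme_minimal()
}

#' @method autoplot xm_classifier
#' @export
autoplot.xm_classifier <- function(object, ...) {
  object$training_log |>
    tidyr::pivot_longer(c("train_loss", "dev_loss"), names_to = "split") |>
    filter(!is.na(.data$value)) |>
    ggplot(aes(.data$epoch, .data$value, color = .data$split)) +
    geom_line() +
    geom_vline(xintercept = object$best_epoch, linetype = "dashed") +
    labs(y = "noise-aware loss",
         title = sprintf("%s model training (best epoch %d)",
                         object$spec$modality, object$best_epoch)) +
    theme_minimal()
}

#' @method autoplot xm_ablation
#' @export
autoplot.xm_ablation <- function(object, ...) {
  object$summary |>
    mutate(source = factor(.data$source,
                           levels = c("MV", "GM", "DM-MV", "DM-GM", "FS"))) |>
    ggplot(aes(.data$source, .data$mean)) +
    geom_pointrange(aes(ymin = .data$lower, ymax = .data$upper)) +
    facet_wrap(~metric, scales = "free_y") +
    labs(x = "label source", y = NULL,
         title = "Label-source ablation (mean ± 95% CI over seeds)") +
    theme_minimal()
}

#' @method autoplot xm_scaling
#' @export
autoplot.xm_scaling <- function(object, ...) {
  if (!"alpha_error" %in% names(object$summary)) {
    p <- ggplot(object$summary, aes(.data$n, .data$test_auc)) +
      geom_point() + geom_line() + scale_x_log10() +
      labs(x = "unlabeled training size n", y = "test ROC-AUC",
           title = "Weakly supervised performance vs dataset size") +
      theme_minimal()
    return(p)
  }
  ref <- object$summary$alpha_error[1] *
    sqrt(object$summary$n[1] / object$summary$n)
  ggplot(object$summary, aes(.data$n, .data$alpha_error)) +
    geom_point() + geom_line() +
    geom_line(aes(y = ref), linetype = "dotted") +
    scale_x_log10() + scale_y_log10() +
    labs(x = "unlabeled training size n",
         y = "mean |estimated - true| LF accuracy",
         title = sprintf(
           "Accuracy-estimation error vs n (slope %.2f; dotted: n^-1/2)",
           object$slope)) +
    theme_minimal()
}

#' ROC curve plot
#'
#' @param scores Numeric scores.
#' @param labels Binary labels.
#' @return A ggplot.
#' @export
plot_roc <- function(scores, labels) {
  y <- normalize_binary_labels(labels)
  ord <- order(scores, decreasing = TRUE)
  tpr <- c(0, cumsum(y[ord] == 1) / sum(y == 1))
  fpr <- c(0, cumsum(y[ord] == 0) / sum(y == 0))
  tibble(fpr = fpr, tpr = tpr) |>
    ggplot(aes(.data$fpr, .data$tpr)) +
    geom_line() +
    geom_abline(linetype = "dashed", color = "grey60") +
    coord_equal() +
    labs(x = "false positive rate", y = "true positive rate",
         title = sprintf("ROC curve (AUC = %.3f)", roc_auc(scores, y))) +
    theme_minimal()
}
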