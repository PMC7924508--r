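#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @importFrom tibble as_tibble
#' @export
tibble::as_tibble

#' Tidy the training history of a fitted embedder
#'
#' @param x A `trained_embedder`.
#' @param ... Unused.
#' @return Long tibble: `epoch`, `component`, `value`.
#' @method tidy trained_embedder
#' @export
tidy.trained_embedder <- function(x, ...) {
  tidyr::pivot_longer(x$history, -"epoch",
                      names_to = "component", values_to = "value")
}

#' One-row summary of a fitted embedder
#'
#' @param x A `trained_embedder`.
#' @param ... Unused.
#' @return Tibble with mapping, architecture, parameter count, epochs run,
#'   best epoch and its validation objective.
#' @method glance trained_embedder
#' @export
glance.trained_embedder <- function(x, ...) {
  tibble::tibble(mapping = x$config$mapping, depth = x$config$depth,
                 width = x$config$width, lambda = x$config$lambda,
                 bypass = x$config$bypass, d = x$d,
                 n_parameters = length(flatten_params(x$params)),
                 epochs = nrow(x$history), best_epoch = x$best_epoch,
                 val_objective = min(x$history$val_objective))
}

#' Per-fold metrics of a cross-validation result
#'
#' @param x A `cv_result`.
#' @param ... Unused.
#' @return Tibble with one row per fold (scores/labels list columns dropped).
#' @method tidy cv_result
#' @export
tidy.cv_result <- function(x, ...) {
  dplyr::select(x$folds, !dplyr::any_of(c("scores", "labels")))
}

#' Aggregate metrics of a cross-validation result
#'
#' Reports both the fold-averaged metrics (primary) and the pooled-score
#' metrics.
#'
#' @param x A `cv_result`.
#' @param ... Unused.
#' @return One-row tibble.
#' @method glance cv_result
#' @export
glance.cv_result <- function(x, ...) {
  scores <- unlist(x$folds$scores); labels <- unlist(x$folds$labels)
  tibble::tibble(method = x$method, k = nrow(x$folds),
                 mean_pr_auc = mean(x$folds$pr_auc),
                 sd_pr_auc = sd(x$folds$pr_auc),
                 mean_log_loss = mean(x$folds$log_loss),
                 sd_log_loss = sd(x$folds$log_loss),
                 pooled_pr_auc = pr_auc(scores, labels),
                 pooled_log_loss = logistic_loss(scores, labels))
}

#' Plot training-loss curves
#'
#' @param object A `trained_embedder`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot trained_embedder
#' @export
autoplot.trained_embedder <- function(object, ...) {
  df <- tidy.trained_embedder(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$epoch, y = .data$value,
                                   colour = .data$component)) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = object$best_epoch, linetype = 2) +
    ggplot2::labs(x = "epoch", y = "loss",
                  title = "Training history (dashed: best epoch)") +
    ggplot2::theme_minimal()
}

#' Plot per-fold cross-validation metrics
#'
#' @param object A `cv_result`.
#' @param metric `"pr_auc"` or `"log_loss"`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot cv_result
#' @export
autoplot.cv_result <- function(object, metric = "pr_auc", ...) {
  df <- tidy.cv_result(object)
  ggplot2::ggplot(df, ggplot2::aes(x = factor(.data$fold), y = .data[[metric]])) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(x = "fold", y = metric,
                  title = paste0(object$method, ": per-fold ", metric)) +
    ggplot2::theme_minimal()
}

#' Plot the scenario matrix
#'
#' @param object A `scenario_result`.
#' @param metric `"mean_pr_auc"`, `"mean_log_loss"`, or a pooled variant.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot scenario_result
#' @export
autoplot.scenario_result <- function(object, metric = "mean_pr_auc", ...) {
  ggplot2::ggplot(object$summary,
                  ggplot2::aes(x = .data$subset, y = .data[[metric]],
                               fill = .data$method)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(x = "observed screening tests", y = metric) +
    ggplot2::theme_minimal()
}

#' Heatmap of feature impacts on the embedding
#'
#' @param object An `impact_matrix`.
#' @param which `"max"` or `"mean"` aggregation.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot impact_matrix
#' @export
autoplot.impact_matrix <- function(object, which = "max", ...) {
  M <- object[[which]]
  df <- tibble::as_tibble(as.data.frame(M, check.names = FALSE))
  df$feature <- rownames(M)
  df <- tidyr::pivot_longer(df, -"feature", names_to = "unit",
                            values_to = "impact")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$unit, y = .data$feature,
                                   fill = .data$impact)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::labs(x = "embedding unit", y = NULL,
                  title = paste0("Feature impact (", which, ")")) +
    ggplot2::theme_minimal()
}

#' Scatter plot of a 2-D embedding projection
#'
#' @param object An `embedding_projection`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot embedding_projection
#' @export
autoplot.embedding_projection <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$dim1, y = .data$dim2,
                                       colour = factor(.data$label))) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::labs(colour = "class") +
    ggplot2::theme_minimal()
}
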