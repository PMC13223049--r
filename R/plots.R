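#' @importFrom ggplot2 autoplot ggplot aes geom_tile geom_text geom_line
#'   geom_point labs theme_minimal scale_fill_gradient facet_wrap
#' @export
ggplot2::autoplot

#' Plot a confusion matrix as an annotated heatmap
#'
#' @param object A [confusion()] matrix.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.confusion_matrix <- function(object, ...) {
  df <- as_tibble(as.data.frame(unclass(object)), rownames = "truth") |>
    tidyr::pivot_longer(-"truth", names_to = "predicted", values_to = "count") |>
    group_by(.data$truth) |>
    mutate(frac = .data$count / sum(.data$count)) |>
    ungroup()
  ggplot(df, aes(.data$predicted, .data$truth, fill = .data$frac)) +
    geom_tile() +
    geom_text(aes(label = .data$count)) +
    scale_fill_gradient(low = "white", high = "steelblue", limits = c(0, 1)) +
    labs(x = "Predicted", y = "Ground truth", fill = "Row fraction") +
    theme_minimal()
}

#' Plot the elbow and silhouette curves of a cluster selection
#'
#' @param object A [select_k()] result.
#' @param ... Unused.
#' @export
autoplot.cluster_selection <- function(object, ...) {
  df <- tidyr::pivot_longer(object$curve, -"k",
                            names_to = "criterion", values_to = "value")
  ggplot(df, aes(.data$k, .data$value)) +
    geom_line() + geom_point() +
    facet_wrap(~criterion, scales = "free_y") +
    labs(x = "K", y = NULL,
         title = sprintf("Selected K = %d (silhouette argmax)", object$selected_k)) +
    theme_minimal()
}

#' Plot the cumulative PCA explained-variance curve of a baseline model
#'
#' @param object A `baseline_model`.
#' @param ... Unused.
#' @export
autoplot.baseline_model <- function(object, ...) {
  df <- tibble(component = seq_along(object$pca$cumulative_variance),
               cumulative_variance = object$pca$cumulative_variance)
  ggplot(df, aes(.data$component, .data$cumulative_variance)) +
    geom_line() +
    labs(x = "Principal component", y = "Cumulative explained variance") +
    theme_minimal()
}

#' Plot per-epoch training curves of a CNN fit
#'
#' @param object A `cnn_fit`.
#' @param ... Unused.
#' @export
autoplot.cnn_fit <- function(object, ...) {
  df <- tidyr::pivot_longer(object$history, -"epoch",
                            names_to = "metric", values_to = "value")
  ggplot(df, aes(.data$epoch, .data$value)) +
    geom_line() +
    facet_wrap(~metric, scales = "free_y") +
    theme_minimal()
}

#' Scatter a t-SNE embedding colored by label
#'
#' @param embedding Tibble from [tsne_embed()].
#' @param labels Point labels (e.g. sex).
#' @return A ggplot.
#' @export
plot_tsne <- function(embedding, labels) {
  df <- mutate(embedding, label = as.character(labels))
  ggplot(df, aes(.data$tsne1, .data$tsne2, color = .data$label)) +
    geom_point(alpha = 0.8) +
    labs(x = "t-SNE 1", y = "t-SNE 2", color = NULL) +
    theme_minimal()
}
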