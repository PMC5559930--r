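#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a contribution report
#'
#' One row per feature with the per-class contribution columns (and the
#' observed-value `condition` column for class averages), ordered by
#' target-class contribution when a target class is set.
#'
#' @param x An `lspf_contribs` object.
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.lspf_contribs <- function(x, ...) {
  if (!is.null(x$target_class)) return(x$ranking)
  tibble::tibble(
    feature = rownames(x$per_feature),
    tibble::as_tibble(as.data.frame(x$per_feature, check.names = FALSE)))
}

#' @rdname tidy.lspf_contribs
#' @export
glance.lspf_contribs <- function(x, ...) {
  tibble::tibble(
    n_instances = x$n_instances,
    target_class = if (is.null(x$target_class)) NA_character_ else x$target_class,
    n_features = nrow(x$per_feature),
    conservation_error = max(abs(x$prediction -
                                   (x$bias + colSums(x$per_feature)))))
}

#' Tidy methods for fitted models and reports
#'
#' `tidy.lspf_forest` summarises per-tree structure; `glance.lspf_forest`
#' gives forest-level statistics. `tidy.lspf_eval` returns the per-class
#' metric table; `glance.lspf_eval` the weighted averages.
#' `tidy.lspf_dp_selection` renders the selected discriminative
#' patterns.
#'
#' @param x The object.
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.lspf_forest <- function(x, ...) {
  tibble::tibble(
    tree = seq_len(x$num_trees),
    n_nodes = vapply(x$trees, function(t) length(t$terminal), integer(1)),
    n_leaves = vapply(x$trees, function(t) sum(t$terminal), integer(1)))
}

#' @rdname tidy.lspf_forest
#' @export
glance.lspf_forest <- function(x, ...) {
  tibble::tibble(num_trees = x$num_trees, mtry = x$mtry,
                 n_features = length(x$feature_names),
                 n_classes = length(x$classes),
                 oob_accuracy = x$oob_accuracy)
}

#' @rdname tidy.lspf_forest
#' @export
tidy.lspf_eval <- function(x, ...) x$per_class

#' @rdname tidy.lspf_forest
#' @export
glance.lspf_eval <- function(x, ...) {
  tibble::tibble(accuracy = x$overall_accuracy,
                 precision = unname(x$weighted["precision"]),
                 recall = unname(x$weighted["recall"]),
                 f1 = unname(x$weighted["f1"]),
                 n = x$n)
}

#' @rdname tidy.lspf_forest
#' @export
tidy.lspf_dp_selection <- function(x, ...) {
  tibble::tibble(
    rank = seq_len(nrow(x$selected)),
    pattern = vapply(x$selected$rules, format_pattern, character(1)),
    leaf_class = x$selected$leaf_class,
    impurity = x$selected$impurity,
    accuracy = x$accuracies)
}

#' Plot a contribution report
#'
#' Horizontal bar chart of the top feature contributions per class,
#' in the layout of a per-class discriminative-feature table.
#'
#' @param object An `lspf_contribs` object.
#' @param top_n Number of features to show (default 10).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.lspf_contribs <- function(object, top_n = 10, ...) {
  td <- tidy(object)
  if ("condition" %in% names(td)) td$condition <- NULL
  td <- head(td, top_n)
  long <- tidyr::pivot_longer(td, -"feature", names_to = "class",
                              values_to = "contribution")
  long$feature <- factor(long$feature, levels = rev(td$feature))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$contribution,
                                     y = .data$feature,
                                     fill = .data$class)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::geom_vline(xintercept = 0, linewidth = 0.3) +
    ggplot2::labs(x = "feature contribution", y = NULL,
                  title = if (!is.null(object$target_class))
                    sprintf("Top feature contributions: %s sentences",
                            object$target_class)
                  else "Feature contributions") +
    ggplot2::theme_minimal()
}

#' Plot an evaluation report
#'
#' Per-class precision/recall/F1 bars with the weighted averages.
#'
#' @param object An `lspf_eval` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.lspf_eval <- function(object, ...) {
  td <- tidy(object)[, c("class", "precision", "recall", "f1")]
  long <- tidyr::pivot_longer(td, -"class", names_to = "metric",
                              values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$class, y = .data$value,
                                     fill = .data$metric)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::geom_hline(yintercept = object$overall_accuracy,
                        linetype = "dashed") +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(y = "metric value", x = NULL,
                  caption = "dashed line: overall accuracy") +
    ggplot2::theme_minimal()
}

#' Plot mined pattern support/confidence
#'
#' @param patterns A [select_flsps()] tibble.
#' @param top_n Patterns to show (by support).
#' @return A ggplot object.
#' @export
plot_patterns <- function(patterns, top_n = 20) {
  td <- head(patterns[order(-patterns$support), ], top_n)
  td$pattern_lab <- paste0("(", gsub("\\|", ", ", td$pattern_id), ")")
  td$pattern_lab <- factor(td$pattern_lab, levels = rev(td$pattern_lab))
  ggplot2::ggplot(td, ggplot2::aes(x = .data$support, y = .data$pattern_lab,
                                   fill = .data$target_class)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = "support", y = NULL, fill = "class") +
    ggplot2::theme_minimal()
}
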