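#' Plot a Jaccard similarity curve
#'
#' @param curve Output of [jaccard_curve()].
#' @return A ggplot: mean pairwise Jaccard (solid) and three-way Jaccard
#'   (dashed) against prefix depth k.
#' @export
plot_jaccard_curve <- function(curve) {
  ggplot2::ggplot(curve, ggplot2::aes(x = .data$k)) +
    ggplot2::geom_line(ggplot2::aes(y = .data$mean_jaccard)) +
    ggplot2::geom_line(ggplot2::aes(y = .data$jaccard_all), linetype = 2) +
    ggplot2::labs(x = "top-k prefix", y = "Jaccard similarity",
                  title = "Rank-list concordance",
                  subtitle = "solid: mean pairwise; dashed: three-way") +
    ggplot2::ylim(0, 1) +
    ggplot2::theme_minimal()
}

#' Plot per-sample silhouettes
#'
#' @param sil Output of [silhouette_from_data()] or [silhouette_from_tree()].
#' @return A ggplot bar chart of s(i) grouped by class, annotated with the
#'   overall SC.
#' @export
plot_silhouette <- function(sil) {
  df <- dplyr::arrange(sil$samples, .data$class, dplyr::desc(.data$silhouette))
  df$sample_id <- factor(df$sample_id, levels = df$sample_id)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$sample_id, y = .data$silhouette,
                                   fill = .data$class)) +
    ggplot2::geom_col() +
    ggplot2::coord_flip() +
    ggplot2::labs(y = "silhouette s(i)", x = NULL,
                  title = sprintf("Silhouette, SC = %.3f", sil$overall)) +
    ggplot2::theme_minimal()
}

#' Autoplot a DCV report as a confusion heat map
#'
#' @param object A `dcv_report`.
#' @param ... Unused.
#' @return A ggplot tile plot of the outer-fold confusion matrix.
#' @method autoplot dcv_report
#' @export
autoplot.dcv_report <- function(object, ...) {
  df <- as.data.frame(as.table(object$confusion))
  names(df) <- c("truth", "predicted", "n")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$predicted, y = .data$truth,
                                   fill = .data$n)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = .data$n)) +
    ggplot2::scale_fill_gradient(low = "white", high = "steelblue") +
    ggplot2::labs(title = sprintf("%s: accuracy %.1f%%, N = %d",
                                  object$method, 100 * object$accuracy,
                                  object$optimal_N)) +
    ggplot2::theme_minimal()
}

#' Autoplot an NSC fit: shrunken centroid deviations
#'
#' @param object An `nsc_fit`.
#' @param top Show the `top` features by max |d| (default 30).
#' @param ... Unused.
#' @return A ggplot of d'_ik per class for the top features.
#' @method autoplot nsc_fit
#' @export
autoplot.nsc_fit <- function(object, top = 30, ...) {
  td <- tidy(object)
  keep <- td |>
    dplyr::group_by(.data$feature) |>
    dplyr::summarise(s = max(abs(.data$d)), .groups = "drop") |>
    dplyr::arrange(dplyr::desc(.data$s)) |>
    utils::head(top)
  td <- dplyr::filter(td, .data$feature %in% keep$feature)
  td$feature <- factor(td$feature, levels = rev(keep$feature))
  ggplot2::ggplot(td, ggplot2::aes(x = .data$d_shrunk, y = .data$feature,
                                   fill = .data$class)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(x = "shrunken standardized deviation d'",
                  y = NULL) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
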