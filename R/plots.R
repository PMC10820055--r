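# ggplot2 figure methods for the result objects.

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @exportS3Method ggplot2::autoplot
autoplot.rfe_trace <- function(object, ...) {
  df <- object$steps
  sel <- df[df$n_features == length(object$selected_feature_ids), ]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$n_features, y = .data$rmse_cv)) +
    ggplot2::geom_line(colour = "grey40") +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::geom_point(data = sel, colour = "red", size = 2) +
    ggplot2::geom_vline(xintercept = sel$n_features, linetype = "dashed",
                        colour = "orange") +
    ggplot2::labs(x = "number of features", y = "RMSE (cross-validated)",
                  title = "Recursive feature elimination trace") +
    ggplot2::theme_minimal()
}

#' @exportS3Method ggplot2::autoplot
autoplot.qsar_yrand <- function(object, binwidth = 0.05, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$q2)) +
    ggplot2::geom_histogram(binwidth = binwidth, fill = "seagreen",
                            colour = "white") +
    ggplot2::geom_vline(xintercept = object$original_q2, colour = "orange",
                        linewidth = 1) +
    ggplot2::labs(x = expression(Q^2), y = "frequency",
                  title = "Y-randomization: randomized vs original model") +
    ggplot2::theme_minimal()
}

#' @exportS3Method ggplot2::autoplot
autoplot.activity_shift <- function(object, ...) {
  df <- tidyr::pivot_longer(object$histogram,
                            c("count_with", "count_without"),
                            names_to = "group", values_to = "count")
  df$group <- ifelse(df$group == "count_with", "with features",
                     "without features")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$bin_low, y = .data$count,
                                   fill = .data$group)) +
    ggplot2::geom_col(position = "identity", alpha = 0.6, just = 0,
                      width = df$bin_high[1] - df$bin_low[1]) +
    ggplot2::labs(x = "p-activity", y = "compounds", fill = NULL,
                  title = "Activity distribution by feature presence") +
    ggplot2::theme_minimal()
}

#' @exportS3Method ggplot2::autoplot
autoplot.bit_substructure <- function(object, match = 1L, ...) {
  mol <- object$mol
  hit <- object$matches[match, ]
  atoms <- hit$atoms[[1]]
  co <- as.data.frame(mol$coords)
  names(co) <- c("x", "y")
  co$highlight <- seq_len(mol$n_atoms) %in% atoms
  co$central <- seq_len(mol$n_atoms) %in% hit$center
  co$element <- mol$element
  seg <- data.frame(
    x = co$x[mol$bonds$i], y = co$y[mol$bonds$i],
    xend = co$x[mol$bonds$j], yend = co$y[mol$bonds$j],
    order = factor(mol$bonds$order)
  )
  ggplot2::ggplot() +
    ggplot2::geom_segment(data = seg,
                          ggplot2::aes(x = .data$x, y = .data$y,
                                       xend = .data$xend, yend = .data$yend,
                                       linewidth = .data$order),
                          colour = "grey30", show.legend = FALSE) +
    ggplot2::scale_linewidth_manual(values = c(`1` = 0.5, `2` = 1.1,
                                               `3` = 1.6)) +
    ggplot2::geom_point(data = co[co$highlight, ],
                        ggplot2::aes(x = .data$x, y = .data$y),
                        colour = "green3", size = 7, alpha = 0.4) +
    ggplot2::geom_point(data = co[co$central, ],
                        ggplot2::aes(x = .data$x, y = .data$y),
                        colour = "purple", size = 3) +
    ggplot2::geom_text(data = co,
                       ggplot2::aes(x = .data$x, y = .data$y,
                                    label = .data$element), size = 3) +
    ggplot2::coord_equal() +
    ggplot2::theme_void() +
    ggplot2::labs(title = paste0(object$family, " bit ", object$bit_index))
}

#' Chemical-space map of a train/test split
#'
#' Scatter of the leading principal components coloured by subset.
#'
#' @param pca Result of [chemspace_pca()].
#' @param split A `scaffold_split`.
#' @return A ggplot object.
#' @export
plot_chemspace <- function(pca, split) {
  df <- pca$coordinates
  df$subset <- "train"
  df$subset[split$test_indices] <- "test"
  ggplot2::ggplot(df, ggplot2::aes(x = .data$PC1, y = .data$PC2,
                                   colour = .data$subset)) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::labs(
      x = sprintf("PC1 (%.1f%%)", 100 * pca$explained_variance[1]),
      y = sprintf("PC2 (%.1f%%)", 100 * pca$explained_variance[2]),
      colour = NULL, title = "Chemical space (PCA)") +
    ggplot2::theme_minimal()
}

#' Predicted-versus-experimental scatter plot
#'
#' @param model A `qsar_model`.
#' @param X_train,y_train,X_test,y_test Feature matrices and responses.
#' @return A ggplot object.
#' @export
plot_predictions <- function(model, X_train, y_train, X_test = NULL,
                             y_test = NULL) {
  df <- tibble::tibble(observed = y_train,
                       predicted = stats::predict(model, X_train),
                       subset = "train")
  if (!is.null(X_test)) {
    df <- dplyr::bind_rows(df, tibble::tibble(
      observed = y_test, predicted = stats::predict(model, X_test),
      subset = "test"))
  }
  ggplot2::ggplot(df, ggplot2::aes(x = .data$observed, y = .data$predicted,
                                   colour = .data$subset)) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed") +
    ggplot2::labs(x = "experimental p-activity", y = "predicted p-activity",
                  colour = NULL) +
    ggplot2::theme_minimal()
}
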