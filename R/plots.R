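#' Plot a labeled time-series dataset
#'
#' Spaghetti plot of all series, one line per sample, colored by class —
#' the quickest visual check of whether the two classes differ in shape.
#'
#' @param object A dataset with `label` and `series` columns (raw from
#'   [simulate_cpet()] or processed from [build_dataset()]).
#' @param alpha Line transparency.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.ts_dataset <- function(object, alpha = 0.6, ...) {
  plot_series_tbl(object, alpha)
}

#' @rdname autoplot.ts_dataset
#' @param data Dataset to plot (function form usable on plain tibbles that
#'   carry `label` and `series` columns).
#' @export
plot_series <- function(data, alpha = 0.6) {
  plot_series_tbl(data, alpha)
}

plot_series_tbl <- function(data, alpha) {
  long <- tibble::tibble(
    sample_id = rep(if ("sample_id" %in% names(data)) data$sample_id else seq_len(nrow(data)),
                    lengths(data$series)),
    label = rep(as.character(data$label), lengths(data$series)),
    index = unlist(purrr::map(data$series, seq_along)),
    value = unlist(data$series)
  )
  ggplot2::ggplot(long, ggplot2::aes(x = .data$index, y = .data$value,
                                     group = .data$sample_id,
                                     color = .data$label)) +
    ggplot2::geom_line(alpha = alpha) +
    ggplot2::labs(x = "breath index", y = "value", color = "class") +
    ggplot2::theme_minimal()
}

#' Plot a cross-validation report as a confusion heat map
#'
#' @param object A `cv_report` from [loo_cv()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.cv_report <- function(object, ...) {
  counts <- tidy(object$confusion)
  ggplot2::ggplot(counts, ggplot2::aes(x = .data$estimate, y = .data$truth,
                                       fill = .data$count)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = .data$count), color = "white") +
    ggplot2::labs(
      title = sprintf("LOO CV (%s, k = %s): accuracy %.3f, F1 %.3f",
                      object$classifier, object$k, object$accuracy, object$f1),
      x = "predicted", y = "truth") +
    ggplot2::theme_minimal()
}

#' Plot grid-search accuracy across sparse factors
#'
#' @param object A `grid_search_k` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.grid_search_k <- function(object, ...) {
  res <- tidy(object)
  long <- tidyr::pivot_longer(res, c("accuracy", "f1"),
                              names_to = "metric", values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$k, y = .data$value,
                                     color = .data$metric)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::geom_vline(xintercept = object$best_k, linetype = "dashed") +
    ggplot2::labs(x = "sparse factor k", y = NULL,
                  title = paste("LOO metrics by sparse factor; best k =",
                                object$best_k)) +
    ggplot2::theme_minimal()
}

#' Plot the K-SVD learning curve of an SRC-AL model
#'
#' Total squared reconstruction error of the augmented training set after
#' each dictionary-learning sweep (sweep 0 is the raw DCT dictionary).
#'
#' @param object An `srcal_model` from [srcal_fit()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.srcal_model <- function(object, ...) {
  tr <- tibble::tibble(sweep = seq_along(object$objective) - 1L,
                       objective = object$objective)
  ggplot2::ggplot(tr, ggplot2::aes(x = .data$sweep, y = .data$objective)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(x = "K-SVD sweep", y = "total squared reconstruction error") +
    ggplot2::theme_minimal()
}
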