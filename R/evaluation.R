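#' Binary confusion matrix and derived metrics
#'
#' Tallies TP/FP/FN/TN for an explicit positive class and derives
#' accuracy \eqn{(TP+TN)/N}, precision \eqn{TP/(TP+FP)}, recall
#' \eqn{TP/(TP+FN)} and the F1-score \eqn{2PR/(P+R)} (harmonic mean of
#' precision and recall). When precision or recall is undefined (no
#' predicted or no true positives), F1 is reported as 0 with a warning.
#'
#' @param truth True class labels.
#' @param estimate Predicted class labels, same length.
#' @param positive The positive class (default: first level of `truth`).
#' @return A `confusion_matrix` object (list of counts + metrics); use
#'   [glance.confusion_matrix()] for a one-row metric tibble or
#'   [tidy.confusion_matrix()] for the long count table.
#' @examples
#' cm <- confusion(c("a", "a", "b"), c("a", "b", "b"), positive = "a")
#' glance(cm)
#' @export
confusion <- function(truth, estimate, positive = NULL) {
  truth <- as.character(truth)
  estimate <- as.character(estimate)
  if (!length(truth)) stop("empty input", call. = FALSE)
  if (length(truth) != length(estimate)) {
    stop("truth and estimate lengths differ", call. = FALSE)
  }
  classes <- union(unique(truth), unique(estimate))
  if (length(classes) > 2L) {
    stop("confusion() handles binary labels; got: ",
         paste(classes, collapse = ", "), call. = FALSE)
  }
  if (is.null(positive)) positive <- classes[[1L]]
  if (!positive %in% classes) stop("positive class not present in labels", call. = FALSE)

  tp <- sum(truth == positive & estimate == positive)
  fp <- sum(truth != positive & estimate == positive)
  fn <- sum(truth == positive & estimate != positive)
  tn <- sum(truth != positive & estimate != positive)

  accuracy <- (tp + tn) / length(truth)
  precision <- if (tp + fp > 0) tp / (tp + fp) else NA_real_
  recall <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
  if (is.na(precision) || is.na(recall) || precision + recall == 0) {
    if (is.na(precision) || is.na(recall)) {
      warning("F1 undefined (no predicted or no true positives); reporting 0",
              call. = FALSE)
    }
    f1 <- 0
  } else {
    f1 <- 2 * precision * recall / (precision + recall)
  }

  structure(
    list(TP = tp, FP = fp, FN = fn, TN = tn,
         positive = positive,
         accuracy = accuracy, precision = precision, recall = recall, f1 = f1),
    class = "confusion_matrix"
  )
}

#' @export
print.confusion_matrix <- function(x, ...) {
  cat("<confusion_matrix> positive =", x$positive, "\n")
  m <- matrix(c(x$TP, x$FP, x$FN, x$TN), 2L, 2L,
              dimnames = list(truth = c(x$positive, paste0("not ", x$positive)),
                              predicted = c(x$positive, paste0("not ", x$positive))))
  print(m)
  cat(sprintf("accuracy %.3f  precision %.3f  recall %.3f  F1 %.3f\n",
              x$accuracy, x$precision, x$recall, x$f1))
  invisible(x)
}

#' @describeIn confusion One-row tibble of accuracy, precision, recall, F1.
#' @param x A `confusion_matrix`.
#' @param ... Unused.
#' @export
glance.confusion_matrix <- function(x, ...) {
  tibble::tibble(accuracy = x$accuracy, precision = x$precision,
                 recall = x$recall, f1 = x$f1, n = x$TP + x$FP + x$FN + x$TN,
                 positive = x$positive)
}

#' @describeIn confusion Long tibble of the four cell counts.
#' @export
tidy.confusion_matrix <- function(x, ...) {
  tibble::tibble(
    truth = c(x$positive, paste0("not ", x$positive))[c(1L, 1L, 2L, 2L)],
    estimate = c(x$positive, paste0("not ", x$positive))[c(1L, 2L, 1L, 2L)],
    count = c(x$TP, x$FN, x$FP, x$TN)
  )
}

# Resolve the classifier argument of loo_cv()/grid_search_k() into a
# fit function (data, k, ...) -> model with a predict() method.
resolve_classifier <- function(classifier) {
  if (is.function(classifier)) return(classifier)
  switch(match.arg(classifier, c("srcal", "src")),
         srcal = function(data, k, ...) srcal_fit(data, k = k, ...),
         src = function(data, k, ...) src_fit(data))
}

#' Leave-one-out cross-validation of a time-series classifier
#'
#' Each of the `n` samples is predicted exactly once by a model fitted on the
#' remaining `n - 1` (for SRC-AL the dictionary is re-learned in every fold,
#' so no information leaks from the held-out sample). Suited to the very
#' small cohorts this package targets, where k-fold splits would be too
#' coarse.
#'
#' @param data A dataset with `label` and equal-length `series` columns.
#' @param classifier `"srcal"` (default), `"src"`, or a factory function
#'   `function(train_data, k, ...)` returning a model with a `predict()`
#'   method that yields a `.pred_class` column — the plug-in point for
#'   third-party classifiers.
#' @param k Sparse factor passed to the factory and to `predict()`.
#' @param ... Further arguments for the factory (e.g. `iterations` for
#'   SRC-AL).
#' @return A `cv_report`: list with `predictions` (tibble: `fold`,
#'   `sample_id`, `truth`, `.pred_class`), `confusion`, `accuracy`, `f1`,
#'   `k`, `classifier` label, and the call's extra config. Methods:
#'   [glance.cv_report()], [tidy.cv_report()], [autoplot.cv_report()].
#' @examples
#' \donttest{
#' ds <- simulate_cpet(n_per_class = 4, length_range = c(30, 40), seed = 1) |>
#'   build_dataset(target_length = 40)
#' loo_cv(ds, "srcal", k = 3, iterations = 5) |> glance()
#' }
#' @export
loo_cv <- function(data, classifier = "srcal", k = 5L, ...) {
  data <- assert_ts_dataset(data)
  n <- nrow(data)
  if (n < 2L) stop("need at least 2 samples for leave-one-out", call. = FALSE)
  if (nlevels(droplevels(data$label)) < 2L) {
    stop("both classes must be present", call. = FALSE)
  }
  fit_fun <- resolve_classifier(classifier)
  extra <- list(...)

  folds <- purrr::map(seq_len(n), function(i) {
    train <- data[-i, , drop = FALSE]
    if (nlevels(droplevels(train$label)) < nlevels(data$label)) {
      warning("fold ", i, ": a class is absent from the training split",
              call. = FALSE)
    }
    model <- do.call(fit_fun, c(list(train, k = k), extra))
    pred <- stats::predict(model, data[i, , drop = FALSE], k = k)
    tibble::tibble(
      fold = i,
      sample_id = if ("sample_id" %in% names(data)) data$sample_id[[i]] else i,
      truth = as.character(data$label[[i]]),
      .pred_class = as.character(pred$.pred_class[[1L]])
    )
  })
  predictions <- dplyr::bind_rows(folds)

  positive <- levels(data$label)[[1L]]
  cm <- confusion(predictions$truth, predictions$.pred_class, positive = positive)

  structure(
    list(predictions = predictions,
         confusion = cm,
         accuracy = cm$accuracy,
         f1 = cm$f1,
         k = k,
         classifier = if (is.character(classifier)) classifier else "custom",
         config = extra),
    class = "cv_report"
  )
}

#' @export
print.cv_report <- function(x, ...) {
  cat("<cv_report> ", x$classifier, ", ", nrow(x$predictions),
      " LOO folds, k = ", x$k,
      sprintf(": accuracy %.3f, F1 %.3f\n", x$accuracy, x$f1), sep = "")
  invisible(x)
}

#' @describeIn loo_cv One-row tibble: classifier, k, accuracy, F1, fold count.
#' @param x A `cv_report`.
#' @export
glance.cv_report <- function(x, ...) {
  tibble::tibble(classifier = x$classifier, k = x$k,
                 accuracy = x$accuracy, f1 = x$f1,
                 n_folds = nrow(x$predictions))
}

#' @describeIn loo_cv Per-fold prediction tibble with a `correct` flag.
#' @export
tidy.cv_report <- function(x, ...) {
  dplyr::mutate(x$predictions, correct = .data$truth == .data$.pred_class)
}

#' Serialize a cross-validation report
#'
#' Writes the aggregate metrics and configuration as JSON and, optionally,
#' the per-fold predictions as CSV.
#'
#' @param report A `cv_report`.
#' @param json_path Output path for the JSON summary.
#' @param csv_path Optional output path for per-fold predictions.
#' @return `json_path`, invisibly.
#' @export
write_cv_report <- function(report, json_path, csv_path = NULL) {
  stopifnot(inherits(report, "cv_report"))
  summary <- list(
    classifier = report$classifier,
    k = report$k,
    accuracy = report$accuracy,
    f1 = report$f1,
    n_folds = nrow(report$predictions),
    confusion = report$confusion[c("TP", "FP", "FN", "TN", "positive")],
    config = report$config
  )
  jsonlite::write_json(summary, json_path, auto_unbox = TRUE, digits = NA)
  if (!is.null(csv_path)) {
    readr::write_csv(report$predictions, csv_path)
  }
  invisible(json_path)
}

#' Grid search over the sparse factor
#'
#' Runs [loo_cv()] once per candidate sparse factor `k` and selects the value
#' maximizing LOO accuracy (ties: the smallest k, preferring the sparser
#' code). Selection and reporting share the same LOO split — an optimistic
#' protocol appropriate for exploring which sparsity a cohort supports;
#' treat the winning accuracy as an upper bound rather than an unbiased
#' estimate.
#'
#' @inheritParams loo_cv
#' @param k_values Candidate sparse factors (each >= 1 and at most the
#'   signal length).
#' @return A `grid_search_k` object: list with `results` (per-k tibble of
#'   accuracy/F1), `best_k`, `best_report` (its `cv_report`), and `reports`
#'   (all of them).
#' @export
grid_search_k <- function(data, classifier = "srcal", k_values = 1:15, ...) {
  data <- assert_ts_dataset(data)
  k_values <- as.integer(k_values)
  if (!length(k_values)) stop("k_values is empty", call. = FALSE)
  m <- length(data$series[[1L]])
  if (any(k_values < 1L) || any(k_values > m)) {
    stop("k_values must lie in 1..signal length (", m, ")", call. = FALSE)
  }
  reports <- purrr::map(k_values, function(k) loo_cv(data, classifier, k = k, ...))
  results <- dplyr::bind_rows(purrr::map(reports, glance))
  best_idx <- which.max(results$accuracy)  # first max -> smallest k wins ties
  structure(
    list(results = results,
         best_k = k_values[[best_idx]],
         best_report = reports[[best_idx]],
         reports = stats::setNames(reports, k_values)),
    class = "grid_search_k"
  )
}

#' @export
print.grid_search_k <- function(x, ...) {
  cat("<grid_search_k> best k =", x$best_k,
      sprintf("(accuracy %.3f, F1 %.3f)\n",
              x$best_report$accuracy, x$best_report$f1))
  print(x$results)
  invisible(x)
}

#' @describeIn grid_search_k Per-k accuracy/F1 tibble with a `best` flag.
#' @param x A `grid_search_k` object.
#' @param ... Unused.
#' @export
tidy.grid_search_k <- function(x, ...) {
  dplyr::mutate(x$results, best = .data$k == x$best_k)
}

#' @describeIn grid_search_k One-row tibble for the winning k.
#' @export
glance.grid_search_k <- function(x, ...) {
  glance(x$best_report)
}
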