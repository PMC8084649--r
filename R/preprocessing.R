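#' Resample a series to a fixed length by linear interpolation
#'
#' Breath-by-breath CPET records have one sample per breath, so patients with
#' different exercise durations produce series of different lengths (85 to
#' 270 breaths in the exercise phase of the cohort this package targets).
#' Classifiers need a common dimension; this maps the original indices onto
#' `[0, L - 1]` and evaluates the piecewise-linear interpolant on a uniform
#' grid of `target_length` points over the same closed interval, so the first
#' and last observations are preserved exactly.
#'
#' @param values Numeric vector, length >= 2.
#' @param target_length Desired output length (>= 2).
#' @return Numeric vector of length `target_length`.
#' @examples
#' resample_linear(c(0, 10), 5)
#' @export
resample_linear <- function(values, target_length) {
  values <- as.numeric(values)
  if (length(values) < 2L) stop("series must have length >= 2", call. = FALSE)
  if (!all(is.finite(values))) stop("series contains non-finite values", call. = FALSE)
  target_length <- as.integer(target_length)
  if (is.na(target_length) || target_length < 2L) {
    stop("target_length must be an integer >= 2", call. = FALSE)
  }
  if (length(values) == target_length) return(values)
  stats::approx(x = seq_along(values) - 1, y = values,
                xout = seq(0, length(values) - 1, length.out = target_length))$y
}

#' Scale a signal to unit l2 norm
#'
#' Every sample is normalized before entering a dictionary or a sparse coder,
#' which makes classification invariant to the overall scale of the recording.
#' A zero vector (a perfectly flat, centered series) has no direction and is
#' rejected.
#'
#' @param x Numeric vector with positive l2 norm.
#' @return `x / sqrt(sum(x^2))`.
#' @examples
#' l2_normalize(c(3, 4))
#' @export
l2_normalize <- function(x) {
  x <- as.numeric(x)
  if (!all(is.finite(x))) stop("signal contains non-finite values", call. = FALSE)
  nrm <- sqrt(sum(x^2))
  if (nrm <= 0) stop("cannot normalize a zero signal", call. = FALSE)
  x / nrm
}

#' One-hot encode a class label
#'
#' @param label A single label present in `class_order`.
#' @param class_order Character vector fixing the class positions.
#' @return Numeric vector of length `length(class_order)` with a single 1 at
#'   the label's position.
#' @examples
#' one_hot("strong", c("strong", "weak"))
#' @export
one_hot <- function(label, class_order) {
  label <- as.character(label)
  class_order <- as.character(class_order)
  pos <- match(label, class_order)
  if (is.na(pos)) {
    stop("label '", label, "' is not in class_order (",
         paste(class_order, collapse = ", "), ")", call. = FALSE)
  }
  out <- numeric(length(class_order))
  out[pos] <- 1
  out
}

# Default common length per CPET phase: the longest series observed in that
# phase for the target cohort, so no record is ever downsampled.
phase_target_lengths <- c(exercise = 270L, warmup = 81L, recovery = 195L)

#' Assemble a labeled, equal-length, normalized time-series dataset
#'
#' Takes raw variable-length series (one row per recording, with the series
#' in a list-column), resamples every series to a common length with
#' [resample_linear()], normalizes each to unit l2 norm, and returns a
#' `ts_dataset` tibble ready for [src_fit()], [srcal_fit()] or [loo_cv()].
#' Records from different CPET phases have incompatible dimensions (a
#' dictionary learned on one phase cannot code another), so mixing phases in
#' one dataset is an error.
#'
#' The common length defaults per phase to the longest series seen in that
#' phase for the cohort this package was built around: exercise 270, warm-up
#' 81, recovery 195 breaths. Without a `phase` column (or for other phases)
#' pass `target_length` explicitly; it then defaults to the longest input
#' series.
#'
#' @param data Data frame with columns `label` and `series` (list of numeric
#'   vectors); optional `sample_id`, `phase`, `indicator` columns are carried
#'   through (and `phase`/`indicator` must each be constant).
#' @param target_length Common length; see above for defaults.
#' @param class_order Optional character vector fixing class positions;
#'   defaults to the sorted unique labels.
#' @return A `ts_dataset`: tibble with `sample_id`, `label` (factor with
#'   levels `class_order`) and unit-norm equal-length `series`, plus a
#'   `target_length` attribute.
#' @examples
#' raw <- tibble::tibble(label = c("a", "b"),
#'                       series = list(sin(1:40 / 4), cos(1:55 / 5)))
#' build_dataset(raw, target_length = 50)
#' @export
build_dataset <- function(data, target_length = NULL, class_order = NULL) {
  if (!is.data.frame(data) || !nrow(data)) stop("data must be a nonempty data frame", call. = FALSE)
  if (!all(c("label", "series") %in% names(data))) {
    stop("data must have `label` and `series` columns", call. = FALSE)
  }
  for (col in c("phase", "indicator")) {
    if (col %in% names(data) && length(unique(data[[col]])) > 1L) {
      stop("all records must share one ", col, "; found: ",
           paste(unique(data[[col]]), collapse = ", "), call. = FALSE)
    }
  }
  if (is.null(target_length)) {
    phase <- if ("phase" %in% names(data)) as.character(data$phase[[1L]])
    target_length <- if (!is.null(phase) && phase %in% names(phase_target_lengths)) {
      phase_target_lengths[[phase]]
    } else {
      max(lengths(data$series))
    }
  }
  if (is.null(class_order)) {
    class_order <- if (is.factor(data$label)) levels(data$label) else sort(unique(as.character(data$label)))
  }
  ids <- if ("sample_id" %in% names(data)) data$sample_id else seq_len(nrow(data))

  series <- purrr::map(seq_len(nrow(data)), function(i) {
    tryCatch(
      l2_normalize(resample_linear(data$series[[i]], target_length)),
      error = function(e) {
        stop("record ", ids[[i]], ": ", conditionMessage(e), call. = FALSE)
      }
    )
  })

  out <- tibble::tibble(
    sample_id = ids,
    label = factor(as.character(data$label), levels = class_order),
    series = series
  )
  if (anyNA(out$label)) {
    stop("labels outside class_order: ",
         paste(setdiff(unique(as.character(data$label)), class_order), collapse = ", "),
         call. = FALSE)
  }
  new_ts_dataset(out, target_length = target_length)
}

new_ts_dataset <- function(tbl, target_length) {
  structure(tbl,
            target_length = as.integer(target_length),
            class = c("ts_dataset", class(tibble::as_tibble(tbl))))
}

#' @export
print.ts_dataset <- function(x, ...) {
  cat("<ts_dataset> ", nrow(x), " samples x ", attr(x, "target_length"),
      " points; classes: ",
      paste(sprintf("%s (%d)", levels(x$label), tabulate(x$label, nlevels(x$label))),
            collapse = ", "), "\n", sep = "")
  NextMethod()
}

# m x r matrix view of a dataset (one sample per column).
dataset_matrix <- function(data) {
  m <- length(data$series[[1L]])
  vapply(data$series, as.numeric, numeric(m))
}

class_order_of <- function(data) levels(data$label)

assert_ts_dataset <- function(data) {
  if (!is.data.frame(data) || !all(c("label", "series") %in% names(data))) {
    stop("expected a dataset with `label` and `series` columns; see build_dataset()",
         call. = FALSE)
  }
  if (!nrow(data)) stop("dataset is empty", call. = FALSE)
  if (length(unique(lengths(data$series))) != 1L) {
    stop("dataset series are not equal length; run build_dataset() first", call. = FALSE)
  }
  if (!is.factor(data$label)) data$label <- factor(data$label)
  data
}
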