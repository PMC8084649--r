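#' Simulate two-class CPET-like exercise time series
#'
#' Generates labeled univariate series emulating the shape of
#' breath-by-breath metabolic indicators (e.g. oxygen pulse, VO2/HR) during
#' the ramped exercise phase of a cardiopulmonary exercise test: a smooth
#' saturating rise under increasing load plus breath-to-breath autocorrelated
#' noise. It provides a fully reproducible stand-in for clinical CPET
#' recordings, which cannot be redistributed, so the entire
#' classification pipeline is testable end to end.
#'
#' Each series has a random length drawn uniformly from `length_range`
#' (different patients pedal for different durations) and follows a
#' saturating ramp on normalized time \eqn{t \in [0, 1]}. The `"strong"`
#' class rises as \eqn{t/(t + 0.3)} — oxygen pulse climbing steadily to
#' exhaustion. The `"weak"` class shifts amplitude, curvature and adds an
#' effect-dependent late-exercise decline:
#' \eqn{(1 + 0.2e)\, t/(t + 0.3 + 0.15e)\,(1 - e\,t)} for effect size
#' \eqn{e} — the early plateau and fall-off typical of limited
#' cardiopulmonary reserve. Amplitude differences are removed by the
#' pipeline's l2 normalization, so the curvature and decline carry the class
#' information. AR(1) noise with marginal standard deviation `noise_sd` and
#' autoregressive coefficient `ar_coefficient` is added pointwise.
#' `effect_size = 0` makes the classes exchangeable.
#'
#' @param n_per_class Samples per class (default 12, giving a 24-record
#'   cohort).
#' @param length_range Integer range of series lengths in breaths (default
#'   `c(85, 270)`, the exercise-phase range of the target cohort).
#' @param effect_size Class separation in units of the base amplitude
#'   (default 1).
#' @param noise_sd Marginal standard deviation of the additive noise
#'   (default 0.1).
#' @param ar_coefficient AR(1) coefficient in `[0, 1)` (default 0.5).
#' @param seed Integer seed; the output is a deterministic function of it.
#' @param class_labels Two labels, first = base class (default
#'   `c("strong", "weak")`).
#' @return A tibble of raw (variable-length, unnormalized) records:
#'   `sample_id`, `label`, `phase = "exercise"`, `indicator = "VO2/HR"`,
#'   `series` (list). Pipe into [build_dataset()] before fitting.
#' @examples
#' sim <- simulate_cpet(n_per_class = 3, seed = 42)
#' lengths(sim$series)
#' @export
simulate_cpet <- function(n_per_class = 12L,
                          length_range = c(85L, 270L),
                          effect_size = 1,
                          noise_sd = 0.1,
                          ar_coefficient = 0.5,
                          seed = NULL,
                          class_labels = c("strong", "weak")) {
  n_per_class <- as.integer(n_per_class)
  if (is.na(n_per_class) || n_per_class < 1L) stop("n_per_class must be >= 1", call. = FALSE)
  length_range <- as.integer(length_range)
  if (length(length_range) != 2L || any(is.na(length_range)) ||
      length_range[1L] < 2L || length_range[2L] < length_range[1L]) {
    stop("length_range must be c(min, max) with 2 <= min <= max", call. = FALSE)
  }
  if (effect_size < 0) stop("effect_size must be >= 0", call. = FALSE)
  if (noise_sd < 0) stop("noise_sd must be >= 0", call. = FALSE)
  if (ar_coefficient < 0 || ar_coefficient >= 1) {
    stop("ar_coefficient must lie in [0, 1)", call. = FALSE)
  }
  if (length(class_labels) != 2L) stop("exactly two class labels required", call. = FALSE)

  gen <- function() {
    params <- list(
      list(a = 1, b = 0.3, d = 0),
      list(a = 1 + 0.2 * effect_size, b = 0.3 + 0.15 * effect_size,
           d = 1.0 * effect_size)
    )
    rows <- purrr::map(seq_len(2L * n_per_class), function(i) {
      cls <- if (i <= n_per_class) 1L else 2L
      L <- length_range[1L] + sample.int(length_range[2L] - length_range[1L] + 1L, 1L) - 1L
      t <- seq(0, 1, length.out = L)
      p <- params[[cls]]
      base <- p$a * t / (t + p$b) * (1 - p$d * t)
      noise <- if (noise_sd > 0) ar1_noise(L, noise_sd, ar_coefficient) else numeric(L)
      tibble::tibble(
        sample_id = i,
        label = class_labels[[cls]],
        phase = "exercise",
        indicator = "VO2/HR",
        series = list(base + noise)
      )
    })
    dplyr::bind_rows(rows)
  }

  if (is.null(seed)) gen() else withr::with_seed(seed, gen())
}

# AR(1) noise with marginal sd `sd` and coefficient `phi`; stationary start.
ar1_noise <- function(n, sd, phi) {
  if (phi == 0) return(stats::rnorm(n, 0, sd))
  innov_sd <- sd * sqrt(1 - phi^2)
  as.numeric(stats::filter(stats::rnorm(n, 0, innov_sd), phi,
                           method = "recursive",
                           init = stats::rnorm(1, 0, sd)))
}

#' Write / read labeled time series in the UCR archive layout
#'
#' One record per line: the class label first, then the (equal-length)
#' series values, delimiter-separated. This is the layout of the UCR Time
#' Series Classification Archive files, so archive datasets can be dropped
#' into [build_dataset()] / [loo_cv()] directly. Reading accepts tab or
#' comma delimiters (auto-detected); writing emits tabs.
#'
#' @param data Dataset with `label` and equal-length `series` columns.
#' @param path File path.
#' @param labels_as Coerce labels on read: `"character"` (default) keeps them
#'   as-is, `"numeric"` parses numeric class codes.
#' @return `write_ucr()` returns `path` invisibly; `read_ucr()` a tibble with
#'   `sample_id`, `label`, `series`.
#' @export
write_ucr <- function(data, path) {
  if (!all(c("label", "series") %in% names(data))) {
    stop("data must have `label` and `series` columns", call. = FALSE)
  }
  if (length(unique(lengths(data$series))) != 1L) {
    stop("UCR files require equal-length samples", call. = FALSE)
  }
  lines <- vapply(seq_len(nrow(data)), function(i) {
    paste(c(as.character(data$label[[i]]),
            formatC(data$series[[i]], format = "g", digits = 17)),
          collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_ucr
#' @export
read_ucr <- function(path, labels_as = c("character", "numeric")) {
  labels_as <- match.arg(labels_as)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) stop("empty UCR file: ", path, call. = FALSE)
  delim <- if (grepl("\t", lines[[1L]])) "\t" else ","
  parsed <- strsplit(lines, delim, fixed = TRUE)
  lens <- lengths(parsed)
  if (length(unique(lens)) != 1L) {
    bad <- which(lens != stats::median(lens))[[1L]]
    stop("ragged UCR file: line ", bad, " has ", lens[[bad]] - 1L,
         " values, expected ", stats::median(lens) - 1L, call. = FALSE)
  }
  labels <- vapply(parsed, function(p) trimws(p[[1L]]), character(1))
  series <- purrr::map(seq_along(parsed), function(i) {
    vals <- suppressWarnings(as.numeric(parsed[[i]][-1L]))
    if (anyNA(vals)) stop("non-numeric value on line ", i, " of ", path, call. = FALSE)
    vals
  })
  if (labels_as == "numeric") labels <- as.numeric(labels)
  tibble::tibble(sample_id = seq_along(labels), label = labels, series = series)
}
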