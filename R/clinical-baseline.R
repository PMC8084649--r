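#' Percent change rate of blood pressure under treatment
#'
#' The per-patient response magnitude
#' \eqn{r_i = |MBPB_i - MBPA_i| / MBPB_i \times 100} (absolute mode) or its
#' signed variant \eqn{(MBPB_i - MBPA_i)/MBPB_i \times 100}, where a BP
#' decrease is positive. BP here is the sum of systolic and diastolic
#' pressure (mmHg), and MBPB/MBPA are the 24-hour means before/after the
#' intervention. Vectorized over patients.
#'
#' @param before,after Positive BP values (mmHg), before and after treatment.
#' @param mode `"absolute"` (default) or `"signed"`.
#' @return Percent change rate(s).
#' @examples
#' change_rate(242, 202)
#' change_rate(207, 208, mode = "signed")
#' @export
change_rate <- function(before, after, mode = c("absolute", "signed")) {
  mode <- match.arg(mode)
  if (any(!is.finite(before)) || any(before <= 0)) {
    stop("`before` BP must be positive", call. = FALSE)
  }
  delta <- (before - after) / before * 100
  if (mode == "absolute") abs(delta) else delta
}

#' Standardize change rates and split a cohort into strong/weak responders
#'
#' Computes \eqn{z_i = (r_i - \mu)/\sigma} against the cohort mean and
#' standard deviation of the change rates and labels each patient `"strong"`
#' when \eqn{z_i > 0} (above-average response) and `"weak"` otherwise. The
#' default standard deviation is the population form (divide by \eqn{n}),
#' which is the convention that reproduces the reference cohort's printed
#' z-scores; the sample form (divide by \eqn{n - 1}) is available.
#'
#' @param rates Numeric vector of percent change rates (>= 2 patients).
#' @param sd_mode `"population"` (default) or `"sample"`.
#' @return A tibble with `r`, `z` and `label` (factor, levels
#'   `c("strong", "weak")`).
#' @seealso [label_responders()] for the data-frame-first wrapper.
#' @export
zscore_labels <- function(rates, sd_mode = c("population", "sample")) {
  sd_mode <- match.arg(sd_mode)
  rates <- as.numeric(rates)
  if (length(rates) < 2L) stop("need at least 2 patients", call. = FALSE)
  if (!all(is.finite(rates))) stop("rates contain non-finite values", call. = FALSE)
  mu <- mean(rates)
  sigma <- if (sd_mode == "population") {
    sqrt(mean((rates - mu)^2))
  } else {
    stats::sd(rates)
  }
  if (sigma <= 0) {
    stop("all change rates are equal (sd = 0): responder labels are undefined",
         call. = FALSE)
  }
  z <- (rates - mu) / sigma
  tibble::tibble(
    r = rates,
    z = z,
    label = factor(ifelse(z > 0, "strong", "weak"), levels = c("strong", "weak"))
  )
}

#' Label a patient cohort by standardized blood-pressure response
#'
#' Data-frame-first wrapper around [change_rate()] + [zscore_labels()]: takes
#' a cohort table with 24-hour mean BP before (`MBPB`) and after (`MBPA`)
#' treatment and appends the change rate `r`, the z-score `z` and the
#' strong/weak responder `label`.
#'
#' @param data Data frame with columns `MBPB` and `MBPA` (mmHg).
#' @param mode Change-rate mode, see [change_rate()].
#' @param sd_mode Standardization convention, see [zscore_labels()].
#' @return `data` with `r`, `z`, `label` columns appended (as a tibble).
#' @examples
#' bp_treatment_table() |> label_responders() |> dplyr::count(label)
#' @export
label_responders <- function(data, mode = "absolute", sd_mode = "population") {
  if (!all(c("MBPB", "MBPA") %in% names(data))) {
    stop("data must have MBPB and MBPA columns", call. = FALSE)
  }
  rates <- change_rate(data$MBPB, data$MBPA, mode = mode)
  dplyr::bind_cols(
    tibble::as_tibble(data[setdiff(names(data), c("r", "z", "label"))]),
    zscore_labels(rates, sd_mode = sd_mode)
  )
}

#' Clinical baseline prediction from within-test blood-pressure change
#'
#' The clinician's rule-of-thumb predictor usable from a single CPET before
#' any treatment: compare the pre-exercise resting BP (`PEBP`) with the BP at
#' the 6th minute of the recovery phase (`R6BP`). Patients whose BP failed to
#' recover below the resting value (\eqn{\Delta BP = PEBP - R6BP < 0}) are
#' predicted weak responders; all others (including \eqn{\Delta BP = 0})
#' strong.
#'
#' @param PEBP,R6BP Positive BP values (mmHg). Alternatively pass a data
#'   frame with those columns as the single first argument.
#' @return With vectors: a factor of `"strong"`/`"weak"`. With a data frame:
#'   the tibble with `delta_bp` and `.pred_class` columns appended.
#' @examples
#' baseline_predict(199, 170)
#' bp_exercise_table() |> baseline_predict()
#' @export
baseline_predict <- function(PEBP, R6BP = NULL) {
  if (is.data.frame(PEBP)) {
    data <- PEBP
    if (!all(c("PEBP", "R6BP") %in% names(data))) {
      stop("data must have PEBP and R6BP columns", call. = FALSE)
    }
    pred <- baseline_predict(data$PEBP, data$R6BP)
    return(dplyr::mutate(tibble::as_tibble(data),
                         delta_bp = PEBP - R6BP, .pred_class = pred))
  }
  if (any(!is.finite(PEBP)) || any(!is.finite(R6BP)) ||
      any(PEBP <= 0) || any(R6BP <= 0)) {
    stop("PEBP and R6BP must be positive", call. = FALSE)
  }
  factor(ifelse(PEBP - R6BP < 0, "weak", "strong"), levels = c("strong", "weak"))
}

#' Evaluate the clinical baseline against known responder labels
#'
#' Applies [baseline_predict()] to each patient and scores the predictions
#' against the true strong/weak labels with [confusion()] (positive class
#' `"strong"`).
#'
#' @param data Data frame with `PEBP`, `R6BP` and a true-label column.
#' @param truth Name of the true-label column (default `"real"`, matching
#'   [bp_exercise_table()]; `"label"` works for [label_responders()] output).
#' @return A `confusion_matrix`; see [glance.confusion_matrix()] for
#'   accuracy/F1.
#' @examples
#' bp_exercise_table() |> evaluate_baseline() |> glance()
#' @export
evaluate_baseline <- function(data, truth = "real") {
  if (!truth %in% names(data)) {
    stop("no true-label column `", truth, "` in data", call. = FALSE)
  }
  scored <- baseline_predict(data)
  confusion(truth = data[[truth]], estimate = scored$.pred_class,
            positive = "strong")
}

#' Bundled 24-patient hypertension cohort tables
#'
#' Two small tables for a cohort of 24 young adults with stage I hypertension
#' who completed a 12-week aerobic exercise program, used throughout the
#' package's examples and tests. BP values are the sum of systolic and
#' diastolic pressure in mmHg.
#'
#' `bp_treatment_table()`: per patient, the 24-hour mean BP before (`MBPB`)
#' and after (`MBPA`) the program, with the published change rate `r` (%),
#' z-score `z` and strong/weak responder `label` for cross-checking —
#' [label_responders()] reproduces all three from the raw columns.
#'
#' `bp_exercise_table()`: per patient, the pre-exercise resting BP (`PEBP`)
#' and 6th-minute recovery BP (`R6BP`) from a single pre-treatment CPET, the
#' published `dBP = PEBP - R6BP`, the baseline-rule `predicted` label and the
#' `real` responder label.
#'
#' @return A tibble with 24 rows.
#' @export
bp_treatment_table <- function() {
  read_cohort_csv("bp_cohort_treatment.csv")
}

#' @rdname bp_treatment_table
#' @export
bp_exercise_table <- function() {
  read_cohort_csv("bp_cohort_exercise.csv")
}

read_cohort_csv <- function(name) {
  path <- system.file("extdata", name, package = "srcal", mustWork = TRUE)
  tbl <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  for (col in c("label", "predicted", "real")) {
    if (col %in% names(tbl)) {
      tbl[[col]] <- factor(tolower(tbl[[col]]), levels = c("strong", "weak"))
    }
  }
  tbl
}
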