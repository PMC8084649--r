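#' Fit the classic sparse representation classifier (SRC)
#'
#' SRC uses a data-implemented dictionary: every l2-normalized training
#' sample becomes one atom, and atoms are grouped into per-class
#' sub-dictionaries \eqn{D = [D_1, \dots, D_c]}. Prediction codes an unknown
#' sample against the full dictionary and assigns the class whose atoms
#' reconstruct it with the smallest residual.
#'
#' Because the dictionary has exactly one column per training sample, it
#' cannot be overcomplete when the number of training samples is below the
#' signal dimension — the small-cohort regime this package targets. A
#' warning flags that regime; [srcal_fit()] is the remedy.
#'
#' @param data A dataset with `label` and equal-length `series` columns,
#'   typically from [build_dataset()] or [simulate_cpet()].
#' @return An `src_model` with the atom matrix, per-class column blocks and
#'   the class order.
#' @seealso [predict.src_model()], [srcal_fit()]
#' @export
src_fit <- function(data) {
  data <- assert_ts_dataset(data)
  X <- dataset_matrix(data)
  if (any(colSums(X^2) <= 0)) stop("zero-norm training sample", call. = FALSE)
  X <- normalize_columns(X)
  class_order <- class_order_of(data)
  ord <- order(match(data$label, class_order))
  X <- X[, ord, drop = FALSE]
  labels <- as.character(data$label)[ord]
  if (ncol(X) < nrow(X)) {
    warning("dictionary has fewer atoms (", ncol(X), ") than signal dimensions (",
            nrow(X), "): not overcomplete; SRC may underperform (see srcal_fit)",
            call. = FALSE)
  }
  structure(
    list(dictionary = new_dictionary(X),
         class_blocks = lapply(stats::setNames(class_order, class_order),
                               function(cl) which(labels == cl)),
         class_order = class_order,
         m = nrow(X)),
    class = "src_model"
  )
}

#' @export
print.src_model <- function(x, ...) {
  cat("<src_model> ", x$m, "-point signals, atoms per class: ",
      paste(sprintf("%s=%d", x$class_order, lengths(x$class_blocks)), collapse = ", "),
      "\n", sep = "")
  invisible(x)
}

# Per-class residuals for one signal; core of Eq.-style minimum-residual rule.
src_class_residuals <- function(model, y, k) {
  y <- l2_normalize(y)
  if (length(y) != model$m) stop("signal length does not match model", call. = FALSE)
  D <- as_dictionary_matrix(model$dictionary)
  code <- omp(y, D, k = k)
  alpha <- numeric(ncol(D))
  alpha[code$support] <- code$coefficients
  vapply(model$class_blocks, function(idx) {
    sqrt(sum((y - D[, idx, drop = FALSE] %*% alpha[idx])^2))
  }, numeric(1))
}

#' Predict with a fitted SRC model
#'
#' Each new sample is l2-normalized and sparse-coded against the full
#' training dictionary with [omp()]; the coefficient vector is then split by
#' class block and the class with the minimal class-restricted reconstruction
#' residual \eqn{\|y - D_j \alpha_j\|_2} wins. Ties go to the class listed
#' first in the model's class order.
#'
#' @param object An `src_model`.
#' @param new_data A dataset like the one used to fit (a `label` column, if
#'   present, is ignored for prediction), or a single numeric vector.
#' @param k Sparse factor for coding; defaults to 1 atom per class, capped so
#'   it never exceeds the atom count.
#' @param ... Unused.
#' @return A tibble with `sample_id`, `.pred_class` and one residual column
#'   `.resid_<class>` per class (for a single vector, a one-row tibble).
#' @export
predict.src_model <- function(object, new_data, k = NULL, ...) {
  if (is.null(k)) k <- min(length(object$class_order), ncol(object$dictionary))
  if (is.numeric(new_data) && is.null(dim(new_data))) {
    new_data <- tibble::tibble(sample_id = 1L, label = NA_character_,
                               series = list(as.numeric(new_data)))
  }
  resid <- t(vapply(new_data$series,
                    function(y) src_class_residuals(object, y, k),
                    numeric(length(object$class_order))))
  pred <- object$class_order[apply(resid, 1L, which.min)]  # which.min: earliest class wins ties
  out <- tibble::tibble(
    sample_id = if ("sample_id" %in% names(new_data)) new_data$sample_id else seq_len(nrow(new_data)),
    .pred_class = factor(pred, levels = object$class_order)
  )
  colnames(resid) <- paste0(".resid_", object$class_order)
  dplyr::bind_cols(out, tibble::as_tibble(resid))
}

#' Fit the analytic-dictionary sparse representation classifier (SRC-AL)
#'
#' SRC-AL decouples the dictionary from the training-sample count. Each
#' l2-normalized training sample of length `m` is concatenated with the
#' one-hot encoding of its label (length `c`, scaled by `label_weight`),
#' giving augmented vectors in \eqn{R^{m+c}}. An overcomplete DCT dictionary
#' of shape \eqn{(m+c) \times w(m+c)} (width factor `w`, default 2) is built
#' analytically and refined by [ksvd()] so its atoms jointly reconstruct
#' signal shape (upper block, rows `1..m`) and label (lower block, last `c`
#' rows). Overcompleteness is therefore guaranteed no matter how few
#' training samples exist.
#'
#' @inheritParams src_fit
#' @param k Sparse factor used both for dictionary learning and, by default,
#'   at prediction time.
#' @param dict_width_factor Atom count as a multiple of `m + c` (default 2).
#' @param iterations K-SVD sweeps (default 30; 0 keeps the raw DCT
#'   dictionary).
#' @param label_weight Magnitude of the one-hot block in the augmented
#'   training vectors (default 1); the augmented vector is not re-normalized,
#'   so every sample carries identical label energy.
#' @param renormalize_training If `TRUE`, re-normalize the augmented
#'   (signal + one-hot) vector to unit norm before learning; default `FALSE`.
#' @param unused_atom_policy Passed to [ksvd()].
#' @return An `srcal_model` with the learned split dictionary
#'   (`split_row = m`), class order, sparse factor, and the per-sweep
#'   learning objective trace.
#' @seealso [predict.srcal_model()]
#' @export
srcal_fit <- function(data, k = 5L, dict_width_factor = 2L, iterations = 30L,
                      label_weight = 1, renormalize_training = FALSE,
                      unused_atom_policy = "replace_with_worst_signal") {
  data <- assert_ts_dataset(data)
  class_order <- class_order_of(data)
  c_n <- length(class_order)
  if (c_n < 2L) stop("need at least 2 classes", call. = FALSE)
  X <- dataset_matrix(data)
  if (any(colSums(X^2) <= 0)) stop("zero-norm training sample", call. = FALSE)
  m <- nrow(X)
  X <- normalize_columns(X)
  H <- vapply(as.character(data$label), function(l) one_hot(l, class_order),
              numeric(c_n)) * label_weight
  if (c_n == 1L) H <- matrix(H, nrow = 1L)
  XA <- rbind(X, H)
  if (renormalize_training) XA <- normalize_columns(XA)

  D0 <- dct_dictionary(m + c_n, as.integer(dict_width_factor) * (m + c_n))
  fit <- ksvd(XA, D0, k = k, iterations = iterations,
              unused_atom_policy = unused_atom_policy)

  structure(
    list(dictionary = new_dictionary(as_dictionary_matrix(fit$dictionary), split_row = m),
         class_order = class_order,
         m = m,
         k = as.integer(k),
         label_weight = label_weight,
         objective = fit$objective),
    class = "srcal_model"
  )
}

#' @export
print.srcal_model <- function(x, ...) {
  cat("<srcal_model> ", x$m, "-point signals + ", length(x$class_order),
      " label rows; ", ncol(x$dictionary), " atoms; k = ", x$k, "\n", sep = "")
  invisible(x)
}

# Label vector L_y = D_lw' alpha_y for one signal.
srcal_label_vector <- function(model, y, k, code_against = c("renormalized", "raw")) {
  code_against <- match.arg(code_against)
  y <- l2_normalize(y)
  if (length(y) != model$m) stop("signal length does not match model", call. = FALSE)
  D <- as_dictionary_matrix(model$dictionary)
  m <- model$m
  D_up <- D[seq_len(m), , drop = FALSE]
  D_lw <- D[-seq_len(m), , drop = FALSE]
  if (code_against == "renormalized") {
    # full atoms are unit-norm but their upper blocks are not; code against
    # re-normalized upper blocks, then map coefficients back to the raw scale
    up_norms <- sqrt(colSums(D_up^2))
    usable <- up_norms > 1e-10  # atoms living purely in the label rows cannot code y
    Dn <- sweep(D_up[, usable, drop = FALSE], 2L, up_norms[usable], "/")
    code <- omp(y, Dn, k = k)
    alpha <- numeric(ncol(D))
    alpha[which(usable)[code$support]] <- code$coefficients / up_norms[usable][code$support]
  } else {
    code <- omp_unnormalized(y, D_up, k)
    alpha <- numeric(ncol(D))
    alpha[code$support] <- code$coefficients
  }
  as.numeric(D_lw %*% alpha)
}

# OMP variant tolerating non-unit atoms: selection by normalized correlation.
omp_unnormalized <- function(x, D, k) {
  norms <- sqrt(colSums(D^2))
  keep <- norms > 1e-10
  Dn <- sweep(D[, keep, drop = FALSE], 2L, norms[keep], "/")
  code <- omp(x, Dn, k = k)
  new_sparse_code(which(keep)[code$support],
                  code$coefficients / norms[keep][code$support],
                  ncol(D))
}

#' Predict with a fitted SRC-AL model
#'
#' The new sample is l2-normalized and sparse-coded with [omp()] against the
#' signal block \eqn{D_{up}'} of the learned dictionary; multiplying the
#' label block by the code gives the label vector
#' \eqn{L_y = D_{lw}' \alpha_y}, and the predicted class is the one with the
#' largest absolute entry of \eqn{L_y} (sign ignored). Ties go to the class
#' listed first in the class order.
#'
#' @param object An `srcal_model`.
#' @param new_data A dataset (as for [predict.src_model()]) or a single
#'   numeric vector.
#' @param k Sparse factor at prediction; defaults to the training value.
#' @param code_against `"renormalized"` (default) codes against unit-norm
#'   upper-block columns and rescales the coefficients back; `"raw"` selects
#'   atoms by normalized correlation but keeps raw-scale coefficients.
#' @param ... Unused.
#' @return A tibble with `sample_id`, `.pred_class` and one label-vector
#'   column `.score_<class>` per class.
#' @export
predict.srcal_model <- function(object, new_data, k = NULL,
                                code_against = "renormalized", ...) {
  if (is.null(k)) k <- object$k
  if (is.numeric(new_data) && is.null(dim(new_data))) {
    new_data <- tibble::tibble(sample_id = 1L, label = NA_character_,
                               series = list(as.numeric(new_data)))
  }
  L <- t(vapply(new_data$series,
                function(y) srcal_label_vector(object, y, k, code_against),
                numeric(length(object$class_order))))
  pred <- object$class_order[apply(abs(L), 1L, which.max)]  # first max: earliest class wins ties
  out <- tibble::tibble(
    sample_id = if ("sample_id" %in% names(new_data)) new_data$sample_id else seq_len(nrow(new_data)),
    .pred_class = factor(pred, levels = object$class_order)
  )
  colnames(L) <- paste0(".score_", object$class_order)
  dplyr::bind_cols(out, tibble::as_tibble(L))
}

#' @export
glance.srcal_model <- function(x, ...) {
  tibble::tibble(
    m = x$m,
    n_classes = length(x$class_order),
    n_atoms = ncol(x$dictionary),
    k = x$k,
    iterations = length(x$objective) - 1L,
    initial_objective = x$objective[[1L]],
    final_objective = x$objective[[length(x$objective)]]
  )
}

#' @export
tidy.srcal_model <- function(x, ...) {
  D <- as_dictionary_matrix(x$dictionary)
  L <- t(D[-seq_len(x$m), , drop = FALSE])
  colnames(L) <- x$class_order
  dplyr::bind_cols(
    tibble::tibble(atom = seq_len(ncol(D)),
                   upper_norm = sqrt(colSums(D[seq_len(x$m), , drop = FALSE]^2))),
    tibble::as_tibble(L)
  ) |>
    tidyr::pivot_longer(dplyr::all_of(x$class_order),
                        names_to = "class", values_to = "label_weight")
}

#' @export
glance.src_model <- function(x, ...) {
  tibble::tibble(
    m = x$m,
    n_classes = length(x$class_order),
    n_atoms = ncol(x$dictionary),
    overcomplete = ncol(x$dictionary) > x$m
  )
}

#' Serialize a fitted sparse classifier to plain text
#'
#' Writes the model dictionary in the [write_dictionary()] format with an
#' extra header line carrying the class order and, for SRC-AL, the sparse
#' factor and label weight (for SRC, the class block sizes).
#'
#' @param model An `src_model` or `srcal_model`.
#' @param path File path.
#' @return `write_model()` returns `path` invisibly; `read_model()` the model.
#' @export
write_model <- function(model, path) {
  if (inherits(model, "srcal_model")) {
    meta <- paste("srcal", model$k, model$label_weight,
                  paste(model$class_order, collapse = ","))
  } else if (inherits(model, "src_model")) {
    meta <- paste("src", paste(lengths(model$class_blocks), collapse = ","),
                  0, paste(model$class_order, collapse = ","))
  } else {
    stop("unsupported model type", call. = FALSE)
  }
  writeLines(meta, path)
  tmp <- tempfile()
  on.exit(unlink(tmp))
  write_dictionary(model$dictionary, tmp)
  cat(readLines(tmp), file = path, sep = "\n", append = TRUE)
  invisible(path)
}

#' @rdname write_model
#' @export
read_model <- function(path) {
  lines <- readLines(path)
  meta <- strsplit(lines[[1L]], " ", fixed = TRUE)[[1L]]
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(lines[-1L], tmp)
  dict <- read_dictionary(tmp)
  class_order <- strsplit(meta[[4L]], ",", fixed = TRUE)[[1L]]
  if (meta[[1L]] == "srcal") {
    m <- attr(dict, "split_row")
    structure(
      list(dictionary = dict, class_order = class_order, m = m,
           k = as.integer(meta[[2L]]), label_weight = as.numeric(meta[[3L]]),
           objective = numeric(0)),
      class = "srcal_model"
    )
  } else {
    sizes <- as.integer(strsplit(meta[[2L]], ",", fixed = TRUE)[[1L]])
    ends <- cumsum(sizes)
    starts <- c(1L, utils::head(ends, -1L) + 1L)
    structure(
      list(dictionary = dict,
           class_blocks = stats::setNames(
             purrr::map2(starts, ends, seq), class_order),
           class_order = class_order, m = nrow(dict)),
      class = "src_model"
    )
  }
}
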