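#' Solve a sparsity-constrained reconstruction by orthogonal matching pursuit
#'
#' Greedily approximates the NP-hard problem
#' \deqn{\min_\alpha \|x - D\alpha\|_2^2 \quad \mathrm{s.t.}\quad \|\alpha\|_0 \le k}
#' by repeatedly selecting the atom (dictionary column) most correlated with
#' the current residual and refitting all selected coefficients by least
#' squares, so that after every step the residual is orthogonal to the span of
#' the selected atoms (the "orthogonal" in OMP).
#'
#' Iteration stops when `k` atoms have been selected, or earlier when the
#' residual l2 norm drops to `residual_tol` or below, or when the residual has
#' (numerically) no correlation left with any unselected atom. Ties in atom
#' selection are broken toward the lower column index, which makes the solver
#' deterministic.
#'
#' @param x Numeric signal vector of length `m`, all entries finite.
#' @param dictionary Numeric `m x n` matrix whose columns (atoms) have unit
#'   l2 norm, e.g. from [dct_dictionary()] or [src_fit()].
#' @param k Sparse factor: maximum number of atoms to select (integer >= 1).
#' @param residual_tol Optional early-stopping threshold on the residual l2
#'   norm; the default 0 stops only on an (exactly) zero residual, so the
#'   sparse factor `k` is the binding constraint.
#' @return A `sparse_code` object: a list with `support` (1-based atom
#'   indices, in selection order), `coefficients` (least-squares fit on the
#'   support, aligned with `support`), and `ambient_size` (`n`).
#' @examples
#' D <- dct_dictionary(8, 16)
#' x <- 2 * D[, 3] + 0.5 * D[, 11]
#' code <- omp(x, D, k = 2)
#' sort(code$support)
#' residual_norm(x, D, code)
#' @seealso [reconstruct()], [residual_norm()]
#' @export
omp <- function(x, dictionary, k, residual_tol = 0) {
  D <- as_dictionary_matrix(dictionary)
  x <- as.numeric(x)
  if (!all(is.finite(x))) stop("signal contains non-finite values", call. = FALSE)
  if (!all(is.finite(D))) stop("dictionary contains non-finite values", call. = FALSE)
  if (length(x) != nrow(D)) {
    stop("signal length (", length(x), ") does not match atom length (",
         nrow(D), ")", call. = FALSE)
  }
  k <- as.integer(k)
  if (is.na(k) || k < 1L) stop("sparse factor k must be a positive integer", call. = FALSE)
  if (residual_tol < 0) stop("residual_tol must be nonnegative", call. = FALSE)

  n <- ncol(D)
  support <- integer(0)
  coefficients <- numeric(0)
  r <- x
  x_norm <- sqrt(sum(x^2))

  if (x_norm > 0) {
    for (step in seq_len(min(k, n, length(x)))) {
      rnorm2 <- sqrt(sum(r^2))
      if (rnorm2 <= residual_tol) break
      corr <- abs(as.numeric(crossprod(D, r)))
      if (length(support)) corr[support] <- -Inf
      # nothing left to explain: residual orthogonal to all remaining atoms
      if (max(corr) <= 1e-12 * x_norm) break
      support <- c(support, which.max(corr))  # which.max: first max, lower index wins ties
      coefficients <- ls_on_support(D[, support, drop = FALSE], x)
      r <- x - D[, support, drop = FALSE] %*% coefficients
    }
  }

  new_sparse_code(support, as.numeric(coefficients), n)
}

#' @export
print.sparse_code <- function(x, ...) {
  cat("<sparse_code> ", length(x$support), " of ", x$ambient_size,
      " atoms\n", sep = "")
  if (length(x$support)) {
    print(stats::setNames(x$coefficients, x$support))
  }
  invisible(x)
}

new_sparse_code <- function(support, coefficients, ambient_size) {
  structure(
    list(support = as.integer(support),
         coefficients = as.numeric(coefficients),
         ambient_size = as.integer(ambient_size)),
    class = "sparse_code"
  )
}

# Least-squares coefficients of x on the columns of Ds; pseudoinverse fallback
# when the support's Gram matrix is rank-deficient (e.g. duplicated atoms).
ls_on_support <- function(Ds, x) {
  qr_d <- qr(Ds)
  if (qr_d$rank < ncol(Ds)) {
    warning("rank-deficient support; solving by pseudoinverse", call. = FALSE)
    return(as.numeric(MASS::ginv(Ds) %*% x))
  }
  as.numeric(qr.coef(qr_d, x))
}

#' Reconstruct a signal from its sparse code
#'
#' Forms the linear combination \eqn{D\alpha} of the selected atoms weighted
#' by their coefficients. An empty code reconstructs the zero signal.
#'
#' @param dictionary Numeric matrix whose column count equals
#'   `code$ambient_size`.
#' @param code A `sparse_code` from [omp()].
#' @return Numeric vector of length `nrow(dictionary)`.
#' @export
reconstruct <- function(dictionary, code) {
  D <- as_dictionary_matrix(dictionary)
  stopifnot(inherits(code, "sparse_code"))
  if (code$ambient_size != ncol(D)) {
    stop("code ambient size (", code$ambient_size,
         ") does not match dictionary column count (", ncol(D), ")",
         call. = FALSE)
  }
  if (any(code$support < 1L | code$support > ncol(D))) {
    stop("sparse code support index out of range", call. = FALSE)
  }
  if (!length(code$support)) return(numeric(nrow(D)))
  as.numeric(D[, code$support, drop = FALSE] %*% code$coefficients)
}

#' Residual norm of a sparse approximation
#'
#' The l2 norm \eqn{\|x - D\alpha\|_2} of the reconstruction error; zero if
#' and only if the code reconstructs the signal exactly. A code with empty
#' support yields `sqrt(sum(x^2))`.
#'
#' @inheritParams reconstruct
#' @param x Numeric signal vector.
#' @return Nonnegative scalar.
#' @export
residual_norm <- function(x, dictionary, code) {
  x <- as.numeric(x)
  D <- as_dictionary_matrix(dictionary)
  if (length(x) != nrow(D)) stop("signal/dictionary dimension mismatch", call. = FALSE)
  sqrt(sum((x - reconstruct(D, code))^2))
}

# Accept plain matrices or `dictionary` objects everywhere.
as_dictionary_matrix <- function(dictionary) {
  if (inherits(dictionary, "dictionary")) return(unclass_dictionary(dictionary))
  if (!is.matrix(dictionary)) dictionary <- as.matrix(dictionary)
  storage.mode(dictionary) <- "double"
  dictionary
}
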