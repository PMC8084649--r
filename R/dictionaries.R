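#' Overcomplete discrete-cosine (DCT) analytic dictionary
#'
#' Builds the fixed-transform initial dictionary used by the analytic
#' sparse-representation classifier: entry \eqn{(i,j)} is proportional to
#' \eqn{\cos(\pi i j / n)} for row \eqn{i = 0,\dots,m-1} and column
#' \eqn{j = 0,\dots,n-1}. Non-constant columns are mean-centered so that all
#' atoms beyond the first carry no DC component, and every column is scaled
#' to unit l2 norm. Because the construction is analytic, the dictionary can
#' be made overcomplete (`cols > rows`) regardless of how many training
#' samples are available — the key advantage over a data-implemented
#' dictionary when samples are scarce.
#'
#' @param rows Atom length `m` (signal dimension).
#' @param cols Number of atoms `n`; must exceed `rows`. Defaults to
#'   `2 * rows`, the sizing used throughout this package.
#' @return A `dictionary` object: an `rows x cols` numeric matrix with
#'   unit-norm columns and a `split_row` attribute (unset here; see
#'   [srcal_fit()]).
#' @examples
#' D <- dct_dictionary(8)
#' dim(D)
#' colSums(as.matrix(D)^2)
#' @export
dct_dictionary <- function(rows, cols = 2L * rows) {
  rows <- as.integer(rows)
  cols <- as.integer(cols)
  if (is.na(rows) || rows < 1L) stop("rows must be a positive integer", call. = FALSE)
  if (is.na(cols) || cols <= rows) {
    stop("an analytic dictionary must be overcomplete: cols (", cols,
         ") must exceed rows (", rows, ")", call. = FALSE)
  }
  i <- 0:(rows - 1L)
  j <- 0:(cols - 1L)
  D <- cos(pi * outer(i, j) / cols)
  if (rows > 1L) {
    for (col in seq_len(cols)[-1L]) {
      centered <- D[, col] - mean(D[, col])
      # keep the raw column if centering degenerates it (constant column)
      if (sqrt(sum(centered^2)) > 1e-12) D[, col] <- centered
    }
  }
  D <- normalize_columns(D)
  new_dictionary(D, split_row = NULL)
}

new_dictionary <- function(atoms, split_row = NULL) {
  stopifnot(is.matrix(atoms))
  structure(atoms, split_row = if (!is.null(split_row)) as.integer(split_row),
            class = c("dictionary", class(atoms)))
}

unclass_dictionary <- function(x) {
  attr(x, "split_row") <- NULL
  class(x) <- setdiff(class(x), "dictionary")
  x
}

#' @export
print.dictionary <- function(x, ...) {
  sr <- attr(x, "split_row")
  cat("<dictionary> ", nrow(x), " x ", ncol(x),
      if (!is.null(sr)) paste0(" (signal block rows 1-", sr, ", label block rows ",
                               sr + 1L, "-", nrow(x), ")"),
      "\n", sep = "")
  invisible(x)
}

#' @export
as.matrix.dictionary <- function(x, ...) unclass_dictionary(x)

normalize_columns <- function(D) {
  nrm <- sqrt(colSums(D^2))
  bad <- nrm <= 0
  if (any(bad)) stop("cannot normalize zero columns", call. = FALSE)
  sweep(D, 2L, nrm, "/")
}

#' Refine a dictionary by K-SVD
#'
#' Alternates two stages for `iterations` sweeps: (1) sparse-code every
#' training signal against the current dictionary with [omp()] at sparse
#' factor `k`; (2) update each used atom (and, jointly, its nonzero
#' coefficients) as the leading singular pair of the residual matrix
#' restricted to the signals that use it. This minimizes the total squared
#' reconstruction error
#' \deqn{\sum_i \|x^i - D\alpha^i\|_2^2 \quad \mathrm{s.t.}\quad \|\alpha^i\|_0 \le k}
#' over the dictionary one atom at a time. After each rank-one update the
#' atom's largest-magnitude entry is forced nonnegative, removing the SVD
#' sign ambiguity so learned dictionaries are reproducible bit-for-bit.
#'
#' The coding stage is safeguarded: each signal keeps whichever of the fresh
#' greedy code and its previous code reconstructs it better (both are
#' k-sparse), so the per-sweep objective trace is non-increasing by
#' construction — pure greedy re-coding alone can occasionally move
#' backwards.
#'
#' Atoms used by no signal in a sweep are, under the default policy, replaced
#' by the currently worst-reconstructed training signals (normalized), which
#' prevents dead atoms; at most one replacement per signal with nonzero
#' residual is made per sweep.
#'
#' @param x Training signals: an `m x r` numeric matrix (one signal per
#'   column) or a list of length-`m` numeric vectors.
#' @param dictionary Initial `m x n` dictionary with unit-norm columns,
#'   typically [dct_dictionary()].
#' @param k Sparse factor used for the coding stage.
#' @param iterations Number of full sweeps (>= 0); 0 returns the initial
#'   dictionary unchanged.
#' @param unused_atom_policy `"replace_with_worst_signal"` (default) or
#'   `"keep"`.
#' @return A `ksvd_fit` object: list with `dictionary` (same shape as the
#'   input, unit-norm columns), `objective` (the total squared error logged
#'   once per sweep, preceded by the initial-dictionary value), `k`,
#'   `iterations`.
#' @examples
#' D0 <- dct_dictionary(10, 20)
#' X <- sapply(1:15, function(i) as.matrix(D0)[, (i %% 20) + 1] * 2)
#' fit <- ksvd(X, D0, k = 1, iterations = 3)
#' fit$objective
#' @export
ksvd <- function(x, dictionary, k,
                 iterations = 30L,
                 unused_atom_policy = c("replace_with_worst_signal", "keep")) {
  unused_atom_policy <- match.arg(unused_atom_policy)
  X <- signals_as_matrix(x)
  D <- as_dictionary_matrix(dictionary)
  split_row <- attr(dictionary, "split_row")
  if (ncol(X) < 1L) stop("training set is empty", call. = FALSE)
  if (nrow(X) != nrow(D)) {
    stop("training signal length (", nrow(X), ") does not match atom length (",
         nrow(D), ")", call. = FALSE)
  }
  iterations <- as.integer(iterations)
  if (is.na(iterations) || iterations < 0L) stop("iterations must be >= 0", call. = FALSE)

  n <- ncol(D)
  r <- ncol(X)
  A <- matrix(0, n, r)  # dense coefficient matrix, column i codes signal i

  # Coding stage. When a previous coefficient matrix is supplied, each signal
  # keeps whichever of {fresh OMP code, previous code} reconstructs it better:
  # both are k-sparse and feasible, and the safeguard makes the logged
  # objective provably non-increasing across sweeps (greedy re-coding alone
  # does not guarantee that).
  code_all <- function(D, A_prev = NULL) {
    A <- matrix(0, n, r)
    for (i in seq_len(r)) {
      code <- omp(X[, i], D, k = k)
      if (length(code$support)) A[code$support, i] <- code$coefficients
      if (!is.null(A_prev)) {
        new_err <- sum((X[, i] - D %*% A[, i])^2)
        old_err <- sum((X[, i] - D %*% A_prev[, i])^2)
        if (old_err < new_err) A[, i] <- A_prev[, i]
      }
    }
    A
  }
  objective_of <- function(D, A) sum((X - D %*% A)^2)

  A <- code_all(D)
  trace <- objective_of(D, A)

  for (sweep in seq_len(iterations)) {
    if (sweep > 1L) A <- code_all(D, A_prev = A)
    for (j in seq_len(n)) {
      users <- which(A[j, ] != 0)
      if (!length(users)) next
      # residual of the users with atom j's contribution added back
      E <- X[, users, drop = FALSE] - D %*% A[, users, drop = FALSE] +
        D[, j, drop = FALSE] %*% A[j, users, drop = FALSE]
      sv <- svd(E, nu = 1L, nv = 1L)
      atom <- sv$u[, 1L]
      coefs <- sv$d[1L] * sv$v[, 1L]
      flip <- sign(atom[which.max(abs(atom))])
      if (flip < 0) {
        atom <- -atom
        coefs <- -coefs
      }
      D[, j] <- atom
      A[j, users] <- coefs
    }
    if (unused_atom_policy == "replace_with_worst_signal") {
      used <- rowSums(A != 0) > 0
      unused <- which(!used)
      if (length(unused)) {
        resid2 <- colSums((X - D %*% A)^2)
        worst <- order(resid2, decreasing = TRUE)
        worst <- worst[resid2[worst] > 1e-12][seq_len(min(length(unused), sum(resid2 > 1e-12)))]
        for (idx in seq_along(worst)) {
          atom <- X[, worst[idx]]
          atom <- atom / sqrt(sum(atom^2))
          if (atom[which.max(abs(atom))] < 0) atom <- -atom
          D[, unused[idx]] <- atom
        }
      }
    }
    trace <- c(trace, objective_of(D, A))
  }

  structure(
    list(dictionary = new_dictionary(D, split_row = split_row),
         objective = trace,
         k = as.integer(k),
         iterations = iterations),
    class = "ksvd_fit"
  )
}

#' @export
print.ksvd_fit <- function(x, ...) {
  cat("<ksvd_fit> ", x$iterations, " sweeps, k = ", x$k,
      ", objective ", format(utils::head(x$objective, 1)), " -> ",
      format(utils::tail(x$objective, 1)), "\n", sep = "")
  invisible(x)
}

#' Total sparse-reconstruction objective of a dictionary on a signal set
#'
#' Codes every signal with [omp()] at sparse factor `k` and returns
#' \eqn{\sum_i \|x^i - D\alpha^i\|_2^2}, the quantity K-SVD minimizes.
#' Useful for comparing dictionaries on held-out data.
#'
#' @inheritParams ksvd
#' @return Nonnegative scalar.
#' @export
sparse_objective <- function(x, dictionary, k) {
  X <- signals_as_matrix(x)
  D <- as_dictionary_matrix(dictionary)
  sum(vapply(seq_len(ncol(X)), function(i) {
    residual_norm(X[, i], D, omp(X[, i], D, k = k))^2
  }, numeric(1)))
}

signals_as_matrix <- function(x) {
  if (is.list(x) && !is.data.frame(x)) {
    lens <- lengths(x)
    if (!length(lens)) stop("training set is empty", call. = FALSE)
    if (length(unique(lens)) != 1L) {
      stop("all training signals must have equal length", call. = FALSE)
    }
    x <- vapply(x, as.numeric, numeric(lens[[1L]]))
    if (!is.matrix(x)) x <- matrix(x, nrow = 1L)
  }
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  if (!all(is.finite(x))) stop("training signals contain non-finite values", call. = FALSE)
  x
}

#' Write / read a dictionary as plain text
#'
#' One header line `rows cols split_row` (with `NA` for an unset split), then
#' the atom matrix row by row, whitespace-separated. Round-trips through
#' full double precision.
#'
#' @param dictionary A `dictionary` object or numeric matrix.
#' @param path File path.
#' @return `write_dictionary()` returns `path` invisibly; `read_dictionary()`
#'   returns a `dictionary`.
#' @export
write_dictionary <- function(dictionary, path) {
  D <- as_dictionary_matrix(dictionary)
  sr <- attr(dictionary, "split_row")
  header <- paste(nrow(D), ncol(D), if (is.null(sr)) "NA" else sr)
  body <- apply(D, 1L, function(row) paste(formatC(row, format = "g", digits = 17), collapse = " "))
  writeLines(c(header, body), path)
  invisible(path)
}

#' @rdname write_dictionary
#' @export
read_dictionary <- function(path) {
  lines <- readLines(path)
  header <- scan(text = lines[1L], what = character(), quiet = TRUE)
  rows <- as.integer(header[1L])
  cols <- as.integer(header[2L])
  split_row <- suppressWarnings(as.integer(header[3L]))
  values <- scan(text = lines[-1L], what = double(), quiet = TRUE)
  if (length(values) != rows * cols) {
    stop("dictionary file body does not match header dimensions", call. = FALSE)
  }
  D <- matrix(values, nrow = rows, ncol = cols, byrow = TRUE)
  new_dictionary(D, split_row = if (!is.na(split_row)) split_row)
}
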