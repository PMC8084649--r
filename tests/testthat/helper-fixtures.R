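# Shared fixtures: all generated in code at test time.

# Random unit-norm dictionary with pairwise coherence below `max_coherence`,
# built by rejection sampling atom by atom.
make_low_coherence_dict <- function(m, n, max_coherence = 0.5, max_tries = 5000) {
  D <- matrix(0, m, n)
  for (j in seq_len(n)) {
    for (try in seq_len(max_tries)) {
      a <- rnorm(m)
      a <- a / sqrt(sum(a^2))
      if (j == 1L || max(abs(crossprod(D[, seq_len(j - 1L), drop = FALSE], a))) < max_coherence) {
        D[, j] <- a
        break
      }
      if (try == max_tries) stop("could not build low-coherence dictionary")
    }
  }
  D
}

# Exhaustive oracle: the size-k support minimizing the least-squares residual,
# independent of the greedy solver it checks.
best_support_exhaustive <- function(x, D, k) {
  supports <- utils::combn(ncol(D), k, simplify = FALSE)
  best <- NULL
  best_res <- Inf
  best_coef <- NULL
  for (s in supports) {
    Ds <- D[, s, drop = FALSE]
    coef <- tryCatch(solve(crossprod(Ds), crossprod(Ds, x)),
                     error = function(e) NULL)
    if (is.null(coef)) next
    res <- sum((x - Ds %*% coef)^2)
    if (res < best_res) {
      best_res <- res
      best <- s
      best_coef <- as.numeric(coef)
    }
  }
  list(support = best, coefficients = best_coef, residual2 = best_res)
}

# Tiny processed dataset for classifier tests: clearly separated smooth
# shapes, fast to fit.
toy_dataset <- function(n_per_class = 4, m = 40, noise = 0.02, seed = 11) {
  withr::with_seed(seed, {
    t <- seq(0, 1, length.out = m)
    rows <- lapply(seq_len(2 * n_per_class), function(i) {
      cls <- if (i <= n_per_class) 1L else 2L
      base <- if (cls == 1) t / (t + 0.3) else sin(pi * t)
      tibble::tibble(sample_id = i,
                     label = c("strong", "weak")[cls],
                     series = list(base + rnorm(m, 0, noise)))
    })
    build_dataset(dplyr::bind_rows(rows), target_length = m)
  })
}
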