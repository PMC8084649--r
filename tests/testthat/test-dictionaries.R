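test_that("dct_dictionary satisfies its construction contract", {
  # degenerate single-row case: both columns collapse to the scalar 1
  D1 <- dct_dictionary(1, 2)
  expect_equal(as.numeric(as.matrix(D1)), c(1, 1))

  D <- as.matrix(dct_dictionary(8, 16))
  expect_equal(dim(D), c(8L, 16L))
  expect_equal(sqrt(colSums(D^2)), rep(1, 16), tolerance = 1e-12)
  # non-constant columns are mean-centered
  expect_equal(colMeans(D)[-1], rep(0, 15), tolerance = 1e-12,
               ignore_attr = TRUE)

  # coherence strictly below 1, cross-checked against a brute-force scan
  G <- abs(crossprod(D))
  diag(G) <- 0
  brute <- max(vapply(seq_len(15), function(i) {
    max(vapply((i + 1):16, function(j) abs(sum(D[, i] * D[, j])), numeric(1)))
  }, numeric(1)))
  expect_lt(max(G), 1)
  expect_equal(max(G), brute, tolerance = 1e-12)

  expect_error(dct_dictionary(10, 10), "overcomplete")
  expect_error(dct_dictionary(10, 5), "overcomplete")
})

test_that("ksvd is a no-op at zero iterations and at an exact fixed point", {
  D0 <- dct_dictionary(10, 20)

  X <- as.matrix(D0)[, c(2, 5, 9, 14)] * 1.7
  fit0 <- ksvd(X, D0, k = 1, iterations = 0)
  expect_equal(as.matrix(fit0$dictionary), as.matrix(D0))
  expect_length(fit0$objective, 1)

  # signals that are exact atoms: objective starts at 0 and stays there
  fit <- ksvd(X, D0, k = 1, iterations = 3)
  expect_equal(fit$objective, rep(0, 4), tolerance = 1e-20)
})

test_that("ksvd decreases the reconstruction objective monotonically on planted data", {
  set.seed(42)
  Dtrue <- make_low_coherence_dict(10, 20, max_coherence = 0.7)
  X <- vapply(1:50, function(i) {
    s <- sample(20, 3)
    as.numeric(Dtrue[, s] %*% rnorm(3))
  }, numeric(10))

  fit <- ksvd(X, dct_dictionary(10, 20), k = 3, iterations = 20)

  expect_length(fit$objective, 21)
  expect_true(all(diff(fit$objective) <= 1e-6 * pmax(fit$objective[-21], 1e-12)))
  expect_lt(fit$objective[21], 0.5 * fit$objective[1])

  # cross-check via an independent code-then-reconstruct pass
  expect_equal(sparse_objective(X, dct_dictionary(10, 20), k = 3),
               fit$objective[1], tolerance = 1e-10)
  expect_lt(sparse_objective(X, fit$dictionary, k = 3), 0.5 * fit$objective[1])

  # shape and unit norms preserved by learning
  D <- as.matrix(fit$dictionary)
  expect_equal(dim(D), c(10L, 20L))
  expect_equal(sqrt(colSums(D^2)), rep(1, 20), tolerance = 1e-10)
})

test_that("ksvd learning is reproducible and the sign convention pins atoms", {
  set.seed(7)
  X <- matrix(rnorm(10 * 12), 10, 12)
  f1 <- ksvd(X, dct_dictionary(10, 20), k = 2, iterations = 5)
  f2 <- ksvd(X, dct_dictionary(10, 20), k = 2, iterations = 5)
  expect_identical(as.matrix(f1$dictionary), as.matrix(f2$dictionary))
  D <- as.matrix(f1$dictionary)
  for (j in seq_len(ncol(D))) {
    expect_gte(D[which.max(abs(D[, j])), j], 0)
  }
})

test_that("ksvd validates inputs", {
  D0 <- dct_dictionary(10, 20)
  expect_error(ksvd(list(), D0, k = 1), "empty")
  expect_error(ksvd(matrix(rnorm(8 * 3), 8, 3), D0, k = 1), "does not match")
  expect_error(ksvd(matrix(rnorm(30), 10, 3), D0, k = 1, iterations = -1), ">= 0")
})

test_that("dictionaries round-trip through the text format", {
  D <- dct_dictionary(6, 12)
  attr(D, "split_row") <- 4L
  path <- withr::local_tempfile()
  write_dictionary(D, path)
  D2 <- read_dictionary(path)
  expect_equal(as.matrix(D2), as.matrix(D), tolerance = 1e-15)
  expect_identical(attr(D2, "split_row"), 4L)

  # corrupt body is rejected
  lines <- readLines(path)
  writeLines(lines[-3], path)
  expect_error(read_dictionary(path), "does not match header")
})
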