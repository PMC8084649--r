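test_that("src_fit builds a normalized class-blocked dictionary", {
  ds <- toy_dataset(n_per_class = 2, m = 10)
  expect_warning(model <- src_fit(ds), "overcomplete")
  D <- as.matrix(model$dictionary)
  expect_equal(dim(D), c(10L, 4L))
  expect_equal(sqrt(colSums(D^2)), rep(1, 4), tolerance = 1e-12)
  expect_equal(lengths(model$class_blocks), c(strong = 2L, weak = 2L))
  # every column in exactly one block
  expect_setequal(unlist(model$class_blocks), 1:4)

  # a single sample per class still yields a usable model
  m1 <- suppressWarnings(src_fit(ds[c(1, 3), ]))
  expect_equal(lengths(m1$class_blocks), c(strong = 1L, weak = 1L))

  # the non-overcomplete regime (fewer samples than dimensions) is flagged
  expect_warning(src_fit(toy_dataset(n_per_class = 4, m = 40)), "overcomplete")
})

test_that("src_predict assigns the class with minimal class-restricted residual", {
  ds <- suppressWarnings(toy_dataset(n_per_class = 4, m = 40))
  model <- suppressWarnings(src_fit(ds))

  # a training sample is recovered with (near) zero own-class residual
  p <- predict(model, ds[1, ], k = 1)
  expect_equal(as.character(p$.pred_class), "strong")
  expect_lt(p$.resid_strong, 1e-6)

  # oracle: per-class residuals recomputed by independent dense linear algebra
  y <- l2_normalize(ds$series[[6]])
  D <- as.matrix(model$dictionary)
  code <- omp(y, D, k = 2)
  alpha <- numeric(ncol(D))
  alpha[code$support] <- code$coefficients
  oracle <- vapply(model$class_blocks, function(idx) {
    sqrt(sum((y - D[, idx, drop = FALSE] %*% alpha[idx])^2))
  }, numeric(1))
  p6 <- predict(model, ds[6, ], k = 2)
  expect_equal(unname(c(p6$.resid_strong, p6$.resid_weak)), unname(oracle),
               tolerance = 1e-10)
  expect_equal(as.character(p6$.pred_class),
               names(oracle)[which.min(oracle)])

  # coefficients partition exactly: class reconstructions sum to the full one
  recon_full <- reconstruct(D, code)
  recon_sum <- Reduce(`+`, lapply(model$class_blocks, function(idx) {
    D[, idx, drop = FALSE] %*% alpha[idx]
  }))
  expect_equal(as.numeric(recon_sum), recon_full, tolerance = 1e-12)
})

test_that("src_predict breaks exact residual ties toward the earlier class", {
  # mirror-symmetric training set: both classes reconstruct y equally badly
  tbl <- tibble::tibble(
    sample_id = 1:2,
    label = c("a", "b"),
    series = list(c(1, 0, 0, 0), c(0, 1, 0, 0))
  )
  ds <- build_dataset(tbl, target_length = 4)
  model <- suppressWarnings(src_fit(ds))
  y <- c(0, 0, 1, 1)  # orthogonal to both atoms
  p <- predict(model, y, k = 1)
  expect_equal(as.character(p$.pred_class), "a")
})

test_that("srcal_fit builds the label-augmented analytic dictionary", {
  ds <- toy_dataset(n_per_class = 2, m = 4)

  # without learning, the model dictionary is exactly the raw DCT dictionary
  model0 <- srcal_fit(ds, k = 1, iterations = 0)
  expect_equal(as.matrix(model0$dictionary), as.matrix(dct_dictionary(6, 12)))
  expect_identical(attr(model0$dictionary, "split_row"), 4L)

  # augmented training vector: normalized signal then one-hot label
  x <- srcal:::dataset_matrix(ds)[, 1]
  aug_expected <- c(l2_normalize(x), 1, 0)
  X <- rbind(srcal:::normalize_columns(srcal:::dataset_matrix(ds)),
             vapply(as.character(ds$label),
                    function(l) one_hot(l, levels(ds$label)), numeric(2)))
  expect_equal(unname(X[, 1]), aug_expected, tolerance = 1e-12)

  # learning reduces the augmented-reconstruction objective below the
  # raw-DCT starting point
  model <- srcal_fit(ds, k = 2, iterations = 5)
  expect_lt(model$objective[length(model$objective)], model$objective[1])
})

test_that("srcal_predict reads the class from the largest |label vector| entry", {
  # hand-built model: atoms with one-hot lower blocks
  m <- 6
  up <- cbind(l2_normalize(sin(1:m)), l2_normalize(cos(1:m)))
  D <- rbind(up, matrix(c(1, 0, 0, 1), 2, 2, byrow = FALSE))
  D <- sweep(D, 2, sqrt(colSums(D^2)), "/")
  # pad with orthogonal-ish extra atoms so the dictionary is wider
  set.seed(3)
  extra <- matrix(rnorm((m + 2) * 14), m + 2, 14)
  D <- cbind(D, sweep(extra, 2, sqrt(colSums(extra^2)), "/"))
  model <- structure(
    list(dictionary = srcal:::new_dictionary(D, split_row = m),
         class_order = c("strong", "weak"), m = m, k = 1L,
         label_weight = 1, objective = numeric(0)),
    class = "srcal_model"
  )

  y <- sin(1:m)  # the upper block of atom 1 (class strong)
  p <- predict(model, y, k = 1)
  expect_equal(as.character(p$.pred_class), "strong")
  scores <- c(p$.score_strong, p$.score_weak)
  expect_equal(scores / max(abs(scores)), c(1, 0), tolerance = 1e-8)

  # the decision uses |L_y|: a large negative entry still wins
  expect_equal(c("strong", "weak")[which.max(abs(c(-0.8, 0.3)))], "strong")
})

test_that("srcal predictions are scale invariant and class-permutation equivariant", {
  ds <- toy_dataset(n_per_class = 3, m = 12)
  model <- srcal_fit(ds, k = 2, iterations = 5)
  y <- ds$series[[2]]
  p1 <- predict(model, y)
  p2 <- predict(model, 17.3 * y)
  expect_identical(as.character(p1$.pred_class), as.character(p2$.pred_class))
  expect_equal(p1$.score_strong, p2$.score_strong, tolerance = 1e-10)

  # reversing the class order permutes scores and keeps the winner
  raw <- tibble::tibble(sample_id = ds$sample_id,
                        label = as.character(ds$label),
                        series = ds$series)
  ds_rev <- build_dataset(raw, target_length = 12,
                          class_order = c("weak", "strong"))
  model_rev <- srcal_fit(ds_rev, k = 2, iterations = 5)
  p_rev <- predict(model_rev, y)
  expect_equal(p_rev$.score_strong, p1$.score_strong, tolerance = 1e-10)
  expect_equal(p_rev$.score_weak, p1$.score_weak, tolerance = 1e-10)
  expect_identical(as.character(p_rev$.pred_class), as.character(p1$.pred_class))

  # scale invariance holds for SRC too
  smodel <- suppressWarnings(src_fit(ds))
  expect_identical(as.character(predict(smodel, y)$.pred_class),
                   as.character(predict(smodel, 5 * y)$.pred_class))
})

test_that("fitted models round-trip through the text serialization", {
  ds <- toy_dataset(n_per_class = 2, m = 8)
  path <- withr::local_tempfile()

  model <- srcal_fit(ds, k = 2, iterations = 3)
  write_model(model, path)
  back <- read_model(path)
  expect_equal(as.matrix(back$dictionary), as.matrix(model$dictionary),
               tolerance = 1e-15)
  expect_identical(back$class_order, model$class_order)
  expect_identical(back$k, model$k)
  p_orig <- predict(model, ds)
  p_back <- predict(back, ds)
  expect_identical(as.character(p_orig$.pred_class),
                   as.character(p_back$.pred_class))

  smodel <- suppressWarnings(src_fit(ds))
  write_model(smodel, path)
  sback <- read_model(path)
  expect_equal(as.matrix(sback$dictionary), as.matrix(smodel$dictionary),
               tolerance = 1e-15)
  expect_identical(lapply(sback$class_blocks, as.integer),
                   lapply(smodel$class_blocks, as.integer))
})

test_that("tidy and glance summarize fitted models", {
  ds <- toy_dataset(n_per_class = 2, m = 6)
  model <- srcal_fit(ds, k = 1, iterations = 2)
  g <- glance(model)
  expect_equal(g$m, 6)
  expect_equal(g$n_atoms, 16)  # 2 * (6 + 2)
  td <- tidy(model)
  expect_setequal(unique(td$class), c("strong", "weak"))
  expect_equal(nrow(td), 16 * 2)
})
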