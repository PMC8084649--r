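test_that("confusion counts and metrics follow the closed-form arithmetic", {
  # TP=7 FP=4 FN=7 TN=6: precision 7/11, recall 1/2, F1 0.56
  truth <- c(rep("strong", 14), rep("weak", 10))
  pred <- c(rep("strong", 7), rep("weak", 7), rep("strong", 4), rep("weak", 6))
  cm <- confusion(truth, pred, positive = "strong")
  expect_equal(cm$TP + cm$FP + cm$FN + cm$TN, 24)
  expect_equal(cm$precision, 7 / 11)
  expect_equal(cm$recall, 1 / 2)
  expect_equal(cm$f1, 2 * (7 / 11) * 0.5 / (7 / 11 + 0.5))
  expect_equal(round(cm$f1, 2), 0.56)
  expect_equal(cm$accuracy, 13 / 24)

  perfect <- confusion(truth, truth, positive = "strong")
  expect_equal(perfect$accuracy, 1)
  expect_equal(perfect$f1, 1)

  # degenerate: no predicted positives -> F1 reported as 0 with a warning
  expect_warning(cm0 <- confusion(c("a", "b"), c("b", "b"), positive = "a"),
                 "undefined")
  expect_equal(cm0$f1, 0)

  expect_error(confusion(character(0), character(0)), "empty")
  expect_error(confusion(c("a", "b", "c"), c("a", "b", "c")), "binary")

  g <- glance(cm)
  expect_true(all(c(g$accuracy, g$f1) >= 0 & c(g$accuracy, g$f1) <= 1))
  expect_equal(sum(tidy(cm)$count), 24)
})

test_that("loo_cv predicts every sample exactly once and aggregates metrics", {
  ds <- toy_dataset(n_per_class = 3, m = 12)

  # stub classifier that always predicts the truth -> accuracy 1
  oracle_factory <- function(train, k, ...) {
    structure(list(train = train), class = "truth_stub")
  }
  assign("predict.truth_stub",
         function(object, new_data, ...) {
           tibble::tibble(.pred_class = new_data$label)
         },
         envir = globalenv())
  on.exit(rm("predict.truth_stub", envir = globalenv()), add = TRUE)

  rep <- loo_cv(ds, oracle_factory, k = 1)
  expect_equal(nrow(rep$predictions), 6)
  expect_equal(sort(rep$predictions$sample_id), ds$sample_id)
  expect_equal(rep$accuracy, 1)
  expect_equal(rep$f1, 1)

  # SRC-AL on the cleanly separated toy: deterministic and repeatable
  r1 <- loo_cv(ds, "srcal", k = 2, iterations = 4)
  r2 <- loo_cv(ds, "srcal", k = 2, iterations = 4)
  expect_identical(r1$predictions, r2$predictions)
  expect_gte(r1$accuracy, 0.9)

  expect_error(loo_cv(ds[1, ], "src"), "at least 2")
  expect_error(loo_cv(ds[1:3, ], "src"), "both classes")
})

test_that("grid_search_k maximizes accuracy and breaks ties toward smaller k", {
  ds <- toy_dataset(n_per_class = 3, m = 12)
  gs <- grid_search_k(ds, "srcal", k_values = c(1, 2), iterations = 3)
  expect_equal(nrow(gs$results), 2)
  # best accuracy is the max over the per-k table
  expect_equal(gs$best_report$accuracy, max(gs$results$accuracy))
  # ties -> smallest k (both k achieve the same accuracy on this easy toy)
  if (gs$results$accuracy[1] == gs$results$accuracy[2]) {
    expect_equal(gs$best_k, 1L)
  }

  one <- grid_search_k(ds, "srcal", k_values = 3, iterations = 2)
  expect_equal(one$best_k, 3L)

  expect_error(grid_search_k(ds, "srcal", k_values = integer(0)), "empty")
  expect_error(grid_search_k(ds, "srcal", k_values = 50), "1..signal length")

  td <- tidy(gs)
  expect_true(td$best[td$k == gs$best_k])
})

test_that("cv reports serialize to JSON and CSV", {
  ds <- toy_dataset(n_per_class = 2, m = 10)
  rep <- suppressWarnings(loo_cv(ds, "src", k = 1))
  json <- withr::local_tempfile(fileext = ".json")
  csv <- withr::local_tempfile(fileext = ".csv")
  write_cv_report(rep, json, csv)
  parsed <- jsonlite::read_json(json)
  expect_equal(parsed$accuracy, rep$accuracy)
  expect_equal(parsed$n_folds, 4)
  back <- readr::read_csv(csv, show_col_types = FALSE)
  expect_equal(nrow(back), 4)
})
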