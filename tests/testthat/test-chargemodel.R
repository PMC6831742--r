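test_that("split_dataset honours the 1:4 default, config and determinism", {
  sp <- split_dataset(100, seed = 3)
  expect_length(sp$train_indices, 20)
  expect_length(sp$test_indices, 80)
  expect_length(intersect(sp$train_indices, sp$test_indices), 0)
  expect_setequal(c(sp$train_indices, sp$test_indices), 1:100)

  sp8 <- split_dataset(100, p_train = 0.8, seed = 3)
  expect_length(sp8$train_indices, 80)

  expect_identical(split_dataset(57, seed = 9), split_dataset(57, seed = 9))
  expect_false(identical(split_dataset(57, seed = 9)$train_indices,
                         split_dataset(57, seed = 10)$train_indices))
  expect_error(split_dataset(4), "n >= 5")
})

## small labeled table shared by the model tests
model_table <- function(n_mol = 60, seed = 501) {
  spec <- synth_spec(seed = seed)
  make_dataset(spec, n_mol)
}

test_that("metric formulas reproduce worked values exactly", {
  expect_equal(rmse(c(0.1, -0.1), c(0.1, -0.1)), 0)
  expect_equal(rmse(c(0, 0), c(0.2, -0.2)), 0.2)
  expect_equal(rmse(0.4, 0.1), 0.3)
  expect_error(rmse(1:3, 1:2), "length")

  expect_equal(nrmse(c(0, 0.4), c(0.1, 0.3)), 25.0)
  expect_equal(nrmse(c(0, 0.4), c(0, 0.4)), 0)
  expect_error(nrmse(c(0.2, 0.2), c(0.1, 0.3)), "constant")

  expect_equal(r_squared(c(0, 1, 2), c(0, 1, 2)), 1.0)
  expect_equal(r_squared(c(0, 1, 2), 2 * c(0, 1, 2) + 0.3), 1.0)
  expect_equal(r_squared(c(0, 1, 2), c(0, 1, 1)), 0.75)
  expect_error(r_squared(c(1, 1), c(0, 1)), "constant")
  expect_equal(r_squared_cod(c(0, 1, 2), c(0, 1, 2)), 1.0)
})

test_that("metrics agree with direct-summation implementations", {
  set.seed(17)
  for (rep in 1:50) {
    n <- sample(5:60, 1)
    y <- stats::rnorm(n); yh <- y + stats::rnorm(n, sd = 0.3)
    expect_equal(rmse(y, yh), rmse_direct(y, yh), tolerance = 1e-12)
    expect_equal(nrmse(y, yh), nrmse_direct(y, yh), tolerance = 1e-12)
    expect_equal(r_squared(y, yh), pearson2_direct(y, yh), tolerance = 1e-12)
  }
})

test_that("constant labels give a constant model with zero training error", {
  tab <- model_table(30)
  tab$label <- 0.1
  for (alg in c("random_forest", "knn", "linear")) {
    m <- train_element_model(tab, "C", algorithm = alg, seed = 5)
    pred <- predict_charges(list(C = m), tab[tab$element == "C", ])
    expect_equal(pred, rep(0.1, sum(tab$element == "C")), tolerance = 1e-9)
  }
})

test_that("linear models recover an exact linear label", {
  tab <- model_table(50)
  tab$label <- 0.05 * tab$degree
  sp <- split_dataset(nrow(tab), seed = 2)
  m <- train_element_model(tab[sp$train_indices, ], "C",
                           algorithm = "linear", seed = 5)
  held <- tab[sp$test_indices, ]
  held <- held[held$element == "C", ]
  pred <- predict_charges(list(C = m), held)
  expect_lt(rmse(held$label, pred), 1e-10)
})

test_that("training preconditions and hyperparameter defaults hold", {
  tab <- model_table(30)
  expect_error(train_element_model(tab[tab$element == "I", ][0:5, ], "I",
                                   seed = 1), "I")
  expect_error(train_element_model(tab, "C", algorithm = "boosted"),
               "unknown algorithm")
  no_label <- tab; no_label$label <- NULL
  expect_error(train_element_model(no_label, "C"), "label")

  m <- train_element_model(tab, "C", seed = 1)
  expect_equal(m$hyperparams$n_trees, 500L)
  expect_equal(m$fit$num.trees, 500)
  mk <- train_element_model(tab, "C", algorithm = "knn", seed = 1)
  expect_equal(mk$hyperparams$k, 7L)
})

test_that("prediction routes rows by element without leakage", {
  tab <- model_table(40)
  sp <- split_dataset(nrow(tab), seed = 4)
  train <- tab[sp$train_indices, ]
  els <- intersect(c("C", "H", "O"), names(which(table(train$element) >= 10)))
  models <- lapply(stats::setNames(els, els), function(el)
    train_element_model(train, el, algorithm = "linear", seed = 8))
  test <- tab[sp$test_indices, ]
  test <- test[test$element %in% els, ]
  pred <- predict_charges(models, test)
  perm <- sample.int(nrow(test))
  pred_perm <- predict_charges(models, test[perm, ])
  expect_equal(pred_perm, pred[perm])

  missing <- test[1:5, ]; missing$element <- "S"
  expect_error(predict_charges(models, missing), "S")
})

test_that("schema digests guard persisted and live models", {
  tab <- model_table(30)
  m <- train_element_model(tab, "C", algorithm = "linear", seed = 3)
  stale <- m; stale$schema_hash <- "00000000"
  expect_error(predict_charges(list(C = stale), tab[tab$element == "C", ]),
               "schema")

  dir <- file.path(tempdir(), "bundle_test")
  save_models(list(C = m), dir)
  loaded <- load_models(dir)
  expect_equal(predict_charges(loaded, tab[tab$element == "C", ]),
               predict_charges(list(C = m), tab[tab$element == "C", ]))
  ## corrupt the stored digest -> refuse to load
  f <- file.path(dir, "C.model.json")
  env <- jsonlite::read_json(f)
  env$schema_hash <- "deadbeef"
  jsonlite::write_json(env, f, auto_unbox = TRUE)
  expect_error(load_models(dir), "schema")
})

test_that("identical seeds give identical fits and predictions", {
  tab <- model_table(40)
  m1 <- train_element_model(tab, "C", seed = 77)
  m2 <- train_element_model(tab, "C", seed = 77)
  sub <- tab[tab$element == "C", ]
  expect_identical(predict_charges(list(C = m1), sub),
                   predict_charges(list(C = m2), sub))
})

test_that("evaluate matches a direct metric recomputation and mean row", {
  tab <- model_table(60)
  sp <- split_dataset(nrow(tab), seed = 12)
  train <- tab[sp$train_indices, ]
  els <- names(which(table(train$element) >= 10))
  models <- lapply(stats::setNames(els, els), function(el)
    train_element_model(train, el, algorithm = "linear", seed = 6))
  metrics <- evaluate(models, tab, sp)
  test <- tab[sp$test_indices, ]
  for (el in setdiff(metrics$element, "mean")) {
    sel <- test[test$element == el, ]
    yh <- predict_charges(models[el], sel)
    row <- metrics[metrics$element == el, ]
    expect_equal(row$rmse, rmse_direct(sel$label, yh), tolerance = 1e-12)
    expect_equal(row$nrmse, nrmse_direct(sel$label, yh), tolerance = 1e-12)
    expect_equal(row$r2, pearson2_direct(sel$label, yh), tolerance = 1e-12)
  }
  per_el <- metrics[metrics$element != "mean", ]
  mean_row <- metrics[metrics$element == "mean", ]
  expect_equal(mean_row$rmse, mean(per_el$rmse))
  expect_equal(mean_row$nrmse, mean(per_el$nrmse))
  expect_equal(mean_row$r2, mean(per_el$r2))

  ## a perfect model family scores rmse 0 (elements whose degree is
  ## constant trigger the documented constant-label warning)
  metrics0 <- suppressWarnings(evaluate(
    lapply(stats::setNames(els, els), function(el) {
      t2 <- tab; t2$label <- 0.05 * t2$degree
      train_element_model(t2[sp$train_indices, ], el, "linear", seed = 1)
    }),
    within(tab, label <- 0.05 * degree), sp))
  expect_true(all(metrics0$rmse < 1e-10))
})
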