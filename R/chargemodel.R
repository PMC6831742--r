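## Per-element regression models and the evaluation metrics.

#' Split a dataset into train and test indices
#'
#' A uniformly random permutation drawn from `seed`; the first
#' `ceiling(n * p_train)` permuted rows form the training set.  The
#' default `p_train = 0.2` is the literal train:test = 1:4 reading.
#'
#' @param n number of rows (must be at least 5).
#' @param p_train training proportion.
#' @param seed integer RNG seed; the split is reproducible from it.
#' @return List with `train_indices`, `test_indices`, `p_train`, `seed`.
#' @export
split_dataset <- function(n, p_train = 0.2, seed = 1L) {
  if (n < 5) stop("split_dataset needs n >= 5", call. = FALSE)
  stopifnot(p_train > 0, p_train < 1)
  perm <- with_seed(seed, sample.int(n))
  k <- ceiling(n * p_train)
  if (k >= n) stop("split leaves no test rows", call. = FALSE)
  list(train_indices = perm[seq_len(k)],
       test_indices = perm[(k + 1):n],
       p_train = p_train, seed = as.integer(seed))
}

resolve_hyperparams <- function(algorithm, hyperparams) {
  defaults <- switch(algorithm,
    random_forest = list(n_trees = 500L),
    knn = list(k = 7L, minkowski_order = 2),
    linear = list(),
    stop(sprintf("unknown algorithm '%s'", algorithm), call. = FALSE))
  utils::modifyList(defaults, hyperparams)
}

#' Train a regression model for one element
#'
#' Fits a regressor on the rows of `table` belonging to `element`, with the
#' partial-charge `label` column as the target.  Defaults follow the study
#' setup: random forests with 500 trees; k-nearest neighbors with k = 7
#' and a Minkowski distance of order 2 (Euclidean); plain least squares
#' for `"linear"`.  The 61-name schema digest is recorded so prediction
#' can refuse tables encoded under a different schema.
#'
#' @param table labeled feature table (61 schema columns + `element` +
#'   `label`).
#' @param element element symbol to train on (at least 10 rows required).
#' @param algorithm one of `"random_forest"`, `"knn"`, `"linear"`.
#' @param hyperparams named list overriding the defaults.
#' @param seed integer seed fixing all stochastic components of the fit.
#' @return An object of class `"element_model"`.
#' @export
train_element_model <- function(table, element,
                                algorithm = "random_forest",
                                hyperparams = list(), seed = 1L) {
  if (!"label" %in% names(table)) {
    stop("training table has no 'label' column", call. = FALSE)
  }
  hp <- resolve_hyperparams(algorithm, hyperparams)
  rows <- which(table$element == element)
  if (length(rows) < 10) {
    stop(sprintf("too few labeled rows for element %s (%d < 10)",
                 element, length(rows)), call. = FALSE)
  }
  x <- as.matrix(table[rows, feature_schema()])
  y <- as.numeric(table$label[rows])
  fit <- switch(algorithm,
    random_forest = {
      ranger::ranger(x = x, y = y, num.trees = hp$n_trees,
                     seed = as.integer(seed), num.threads = 1,
                     verbose = FALSE)
    },
    knn = {
      caret::knnreg(x, y, k = hp$k)
    },
    linear = {
      df <- as.data.frame(x)
      df$.y <- y
      with_seed(seed, stats::lm(.y ~ ., data = df))
    })
  structure(list(element = element, algorithm = algorithm,
                 hyperparams = hp, fit = fit,
                 schema_hash = schema_hash(), seed = as.integer(seed),
                 n_train = length(rows)),
            class = "element_model")
}

#' @export
print.element_model <- function(x, ...) {
  cat(sprintf("<element_model %s: %s (%s), %d training atoms>\n",
              x$element, x$algorithm,
              paste(names(x$hyperparams), unlist(x$hyperparams),
                    sep = "=", collapse = ", "),
              x$n_train))
  invisible(x)
}

predict_element_model <- function(model, x) {
  stopifnot(inherits(model, "element_model"))
  switch(model$algorithm,
    random_forest = stats::predict(model$fit, data = as.data.frame(x),
                                   num.threads = 1)$predictions,
    knn = stats::predict(model$fit, as.matrix(x)),
    linear = {
      newdata <- as.data.frame(x)
      suppressWarnings(unname(stats::predict(model$fit, newdata = newdata)))
    })
}

#' Predict partial charges for a feature table
#'
#' Each row is routed to the model of its element; output order equals row
#' order.  Fails when an element in the table has no model, or when a
#' model's recorded schema digest differs from the current schema.
#'
#' @param models named list mapping element symbol to
#'   [train_element_model()] output.
#' @param table feature table (61 schema columns + `element`).
#' @return Numeric vector of predicted charges in units of e.
#' @export
predict_charges <- function(models, table) {
  missing_cols <- setdiff(c(feature_schema(), "element"), names(table))
  if (length(missing_cols) > 0) {
    stop("table is missing feature columns", call. = FALSE)
  }
  present <- unique(table$element)
  absent <- setdiff(present, names(models))
  if (length(absent) > 0) {
    stop(sprintf("no trained model for element(s): %s",
                 paste(absent, collapse = ", ")), call. = FALSE)
  }
  cur_hash <- schema_hash()
  out <- numeric(nrow(table))
  for (el in present) {
    m <- models[[el]]
    if (!identical(m$schema_hash, cur_hash)) {
      stop(sprintf("schema mismatch for %s model (trained under %s, current %s)",
                   el, m$schema_hash, cur_hash), call. = FALSE)
    }
    rows <- which(table$element == el)
    out[rows] <- predict_element_model(m, table[rows, feature_schema()])
  }
  out
}

#' Root-mean-square error
#'
#' `sqrt(mean((y_pred - y_true)^2))`, in units of e.
#'
#' @param y_true,y_pred equal-length nonempty numeric vectors.
#' @return Non-negative scalar.
#' @export
rmse <- function(y_true, y_pred) {
  if (length(y_true) == 0 || length(y_true) != length(y_pred)) {
    stop("rmse needs equal nonzero-length inputs", call. = FALSE)
  }
  sqrt(mean((y_pred - y_true)^2))
}

#' Normalized RMSE (percent of the true-value range)
#'
#' `rmse / (max(y_true) - min(y_true)) * 100`.  Undefined (error) when the
#' true values are constant.
#'
#' @inheritParams rmse
#' @return Non-negative percentage.
#' @export
nrmse <- function(y_true, y_pred) {
  rng <- max(y_true) - min(y_true)
  if (rng <= 0) stop("nrmse undefined for constant y_true", call. = FALSE)
  rmse(y_true, y_pred) / rng * 100
}

#' Squared Pearson correlation between truth and prediction
#'
#' The reported R-squared is the squared Pearson correlation (the caret
#' regression convention), which is invariant under affine transforms of
#' either argument; the coefficient of determination is available via
#' `r_squared_cod()`.
#'
#' @inheritParams rmse
#' @return Value in `[0, 1]` (up to floating point).
#' @export
r_squared <- function(y_true, y_pred) {
  if (length(y_true) < 2 || length(y_true) != length(y_pred)) {
    stop("r_squared needs equal lengths >= 2", call. = FALSE)
  }
  if (stats::sd(y_true) == 0 || stats::sd(y_pred) == 0) {
    stop("r_squared undefined for constant input", call. = FALSE)
  }
  stats::cor(y_true, y_pred)^2
}

#' Coefficient of determination
#'
#' `1 - SS_res / SS_tot`; can be negative for poor predictions.
#'
#' @inheritParams rmse
#' @return Scalar at most 1.
#' @export
r_squared_cod <- function(y_true, y_pred) {
  if (length(y_true) < 2 || length(y_true) != length(y_pred)) {
    stop("r_squared_cod needs equal lengths >= 2", call. = FALSE)
  }
  ss_tot <- sum((y_true - mean(y_true))^2)
  if (ss_tot == 0) stop("r_squared_cod undefined for constant y_true",
                        call. = FALSE)
  1 - sum((y_pred - y_true)^2) / ss_tot
}

#' Evaluate trained models on the held-out split
#'
#' Computes RMSE, NRMSE and R-squared per element on the test rows, plus a
#' cross-element unweighted mean row.  Elements absent from the test split
#' are omitted with a warning.
#'
#' @param models named list of [train_element_model()] fits (trained on the
#'   train split only).
#' @param table labeled feature table the split refers to.
#' @param split a [split_dataset()] result.
#' @return data.frame with columns `element`, `n_test`, `rmse`, `nrmse`,
#'   `r2`, `r2_cod`; the last row is the mean (`element = "mean"`).
#' @export
evaluate <- function(models, table, split) {
  test <- table[split$test_indices, , drop = FALSE]
  rows <- list()
  for (el in names(models)) {
    sel <- test[test$element == el, , drop = FALSE]
    if (nrow(sel) == 0) {
      warning(sprintf("no test rows for element %s; omitted", el))
      next
    }
    y <- as.numeric(sel$label)
    yh <- predict_charges(models[el], sel)
    rng_ok <- (max(y) - min(y)) > 0
    rows[[el]] <- data.frame(
      element = el, n_test = nrow(sel),
      rmse = rmse(y, yh),
      nrmse = if (rng_ok) nrmse(y, yh) else NA_real_,
      r2 = if (rng_ok && stats::sd(yh) > 0) r_squared(y, yh) else NA_real_,
      r2_cod = if (rng_ok) r_squared_cod(y, yh) else NA_real_)
    if (!rng_ok) warning(sprintf("constant test labels for %s; NRMSE/R2 NA", el))
  }
  out <- do.call(rbind, rows)
  if (is.null(out)) stop("no element had test rows", call. = FALSE)
  mean_row <- data.frame(element = "mean", n_test = sum(out$n_test),
                         rmse = mean(out$rmse), nrmse = mean(out$nrmse),
                         r2 = mean(out$r2), r2_cod = mean(out$r2_cod))
  rownames(out) <- NULL
  rbind(out, mean_row)
}

## ---- model persistence -----------------------------------------------------

#' Save / load a per-element model bundle
#'
#' One file per element (JSON envelope with the algorithm, hyperparameters,
#' schema digest and a base64 payload of the serialized fit) plus a
#' `manifest.json`.  Loading refuses models whose schema digest differs
#' from the running package's schema.
#'
#' @param models named list of element models.
#' @param dir bundle directory (created if needed).
#' @return `save_models` returns `dir` invisibly; `load_models` the named
#'   model list.
#' @export
save_models <- function(models, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(schema_hash = schema_hash(), elements = list())
  for (el in names(models)) {
    m <- models[[el]]
    payload <- jsonlite::base64_enc(serialize(m$fit, NULL, version = 2))
    env <- list(element = m$element, algorithm = m$algorithm,
                hyperparams = m$hyperparams, schema_hash = m$schema_hash,
                seed = m$seed, n_train = m$n_train, payload = payload)
    jsonlite::write_json(env, file.path(dir, paste0(el, ".model.json")),
                         auto_unbox = TRUE)
    manifest$elements[[el]] <- list(algorithm = m$algorithm,
                                    n_train = m$n_train, seed = m$seed)
  }
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(dir)
}

#' @rdname save_models
#' @export
load_models <- function(dir) {
  files <- list.files(dir, pattern = "\\.model\\.json$", full.names = TRUE)
  if (length(files) == 0) stop(sprintf("no models found in %s", dir),
                               call. = FALSE)
  models <- list()
  for (f in files) {
    env <- jsonlite::read_json(f)
    if (!identical(env$schema_hash, schema_hash())) {
      stop(sprintf("model %s was trained under a different feature schema",
                   basename(f)), call. = FALSE)
    }
    fit <- unserialize(jsonlite::base64_dec(env$payload))
    models[[env$element]] <- structure(
      list(element = env$element, algorithm = env$algorithm,
           hyperparams = env$hyperparams, fit = fit,
           schema_hash = env$schema_hash, seed = env$seed,
           n_train = env$n_train),
      class = "element_model")
  }
  models
}
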