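# The four regression learners behind a uniform adapter interface:
# algorithm identity is data (a string + parameter list), not code branching
# at call sites. SVR-RBF is fit with e1071, bagged regression trees are
# built in-package over rpart bootstrap fits, and both boosted-tree
# families run on the xgboost library (classic gradient boosting vs the
# regularized variant). The random forest used by the feature selector and
# importance ranking is fit with ranger.

#' Default hyperparameter grids
#'
#' `svr_rbf`: C in \{0.01, 0.1, 1, 10, 100, 1000\} by gamma in
#' \{1e-4, 1e-3, 1e-2\} (18 points). Tree learners (`bagging`, `gbdt`,
#' `xgb`): number of trees 100 to 1000 in steps of 50 (19 points).
#'
#' @param algorithm One of `"svr_rbf"`, `"bagging"`, `"gbdt"`, `"xgb"`.
#' @return A data frame with one row per grid point.
#' @export
default_grid <- function(algorithm = c("svr_rbf", "bagging", "gbdt", "xgb")) {
  algorithm <- match.arg(algorithm)
  if (algorithm == "svr_rbf") {
    expand.grid(C = c(0.01, 0.1, 1, 10, 100, 1000),
                gamma = c(1e-4, 1e-3, 1e-2))
  } else {
    data.frame(n_estimators = seq(100L, 1000L, by = 50L))
  }
}

qsar_algorithms <- function() c("svr_rbf", "bagging", "gbdt", "xgb")

# --- adapter layer -----------------------------------------------------------

fit_learner <- function(algorithm, params, X, y, seed = 1L) {
  X <- as.matrix(X)
  switch(algorithm,
    svr_rbf = list(
      kind = "svr_rbf",
      fit = e1071::svm(x = X, y = y, type = "eps-regression",
                       kernel = "radial", cost = params$C,
                       gamma = params$gamma, scale = FALSE)
    ),
    bagging = fit_bagging(X, y, n_estimators = params$n_estimators,
                          seed = seed),
    gbdt = fit_xgb(X, y, nrounds = params$n_estimators, seed = seed,
                   eta = 0.1, max_depth = 3, lambda = 0, alpha = 0,
                   kind = "gbdt"),
    xgb = fit_xgb(X, y, nrounds = params$n_estimators, seed = seed,
                  eta = 0.3, max_depth = 6, lambda = 1, alpha = 0,
                  kind = "xgb"),
    rf = list(
      kind = "rf",
      fit = ranger::ranger(x = X, y = y,
                           num.trees = params$num_trees %||% 500L,
                           importance = "impurity", seed = seed,
                           num.threads = 1L)
    ),
    stop("unknown algorithm: ", algorithm)
  )
}

predict_learner <- function(model, X) {
  X <- as.matrix(X)
  switch(model$kind,
    svr_rbf = as.numeric(stats::predict(model$fit, X)),
    bagging = predict_bagging(model, X),
    gbdt = ,
    xgb = as.numeric(stats::predict(model$fit, xgboost::xgb.DMatrix(X))),
    rf = as.numeric(stats::predict(model$fit, data = X,
                                   num.threads = 1L)$predictions),
    stop("unknown model kind")
  )
}

fit_xgb <- function(X, y, nrounds, seed, eta, max_depth, lambda, alpha, kind) {
  dtrain <- xgboost::xgb.DMatrix(X, label = y)
  params <- list(objective = "reg:squarederror", eta = eta,
                 max_depth = max_depth, lambda = lambda, alpha = alpha,
                 nthread = 1L, seed = seed)
  fit <- xgboost::xgb.train(params = params, data = dtrain,
                            nrounds = nrounds, verbose = 0)
  list(kind = kind, fit = fit)
}

# --- bagged regression trees -------------------------------------------------

#' Bootstrap sample indices
#'
#' Draws `n` indices from `1..n` with replacement; the out-of-bag (OOB) set
#' is the complement. For large `n` the expected OOB fraction approaches
#' 1/e (about 36.8%).
#'
#' @param n Number of samples (>= 1).
#' @param seed Integer seed.
#' @return Integer vector of length `n` (a multiset of indices).
#' @export
bootstrap_indices <- function(n, seed) {
  assert_that(n >= 1, "n must be >= 1")
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(as.integer(seed))
  sample.int(n, n, replace = TRUE)
}

fit_bagging <- function(X, y, n_estimators, seed) {
  df <- as.data.frame(X)
  names(df) <- paste0("f", seq_len(ncol(df)))
  df$.y <- y
  ctrl <- rpart::rpart.control(cp = 0, minsplit = 5L, xval = 0L,
                               maxsurrogate = 0L, maxcompete = 0L)
  trees <- lapply(seq_len(n_estimators), function(b) {
    idx <- bootstrap_indices(nrow(df), seed = child_seed(seed, paste0("bag", b)))
    rpart::rpart(.y ~ ., data = df[idx, , drop = FALSE], method = "anova",
                 control = ctrl)
  })
  list(kind = "bagging", trees = trees, n_features = ncol(X))
}

predict_bagging <- function(model, X) {
  df <- as.data.frame(X)
  names(df) <- paste0("f", seq_len(ncol(df)))
  preds <- vapply(model$trees, function(tr) {
    as.numeric(stats::predict(tr, newdata = df))
  }, numeric(nrow(df)))
  if (is.null(dim(preds))) preds <- matrix(preds, nrow = nrow(df))
  rowMeans(preds)
}

# --- grid search -------------------------------------------------------------

#' Train a QSAR regressor under grid search
#'
#' Scores every grid point by k-fold cross-validated RMSE (frozen fold
#' partition across points), refits the winning parameters on the full
#' training data, and returns a `qsar_model`. Deterministic under `seed`.
#'
#' @param X Numeric feature matrix (rows = compounds) with feature-id
#'   column names.
#' @param y Numeric response (p-activity).
#' @param algorithm One of `"svr_rbf"`, `"bagging"`, `"gbdt"`, `"xgb"`.
#' @param grid Data frame of parameter combinations; defaults to
#'   [default_grid()].
#' @param cv_folds Number of cross-validation folds.
#' @param seed Integer seed.
#' @return A `qsar_model`: list with `algorithm`, `chosen_params`, `fit`,
#'   `feature_ids`, `cv_table` (tibble of grid point x RMSE_CV), `seed`.
#'   `glance()` summarises; `predict()` scores new matrices.
#' @export
fit_qsar <- function(X, y, algorithm = c("svr_rbf", "bagging", "gbdt", "xgb"),
                     grid = NULL, cv_folds = 5L, seed = 1L) {
  algorithm <- match.arg(algorithm)
  X <- as.matrix(X)
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  grid <- grid %||% default_grid(algorithm)
  assert_that(nrow(grid) >= 1, "grid must be non-empty")
  assert_that(nrow(X) >= cv_folds, "need at least cv_folds samples")
  folds <- make_folds(nrow(X), cv_folds, seed = child_seed(seed, "gridcv"))
  scores <- vapply(seq_len(nrow(grid)), function(g) {
    params <- as.list(grid[g, , drop = FALSE])
    errs <- vapply(seq_along(folds), function(f) {
      hold <- folds[[f]]
      fit <- fit_learner(algorithm, params, X[-hold, , drop = FALSE],
                         y[-hold], seed = child_seed(seed, paste0("g", g)))
      rmse(y[hold], predict_learner(fit, X[hold, , drop = FALSE]))
    }, numeric(1))
    mean(errs)
  }, numeric(1))
  best <- which.min(scores)
  chosen <- as.list(grid[best, , drop = FALSE])
  fit <- fit_learner(algorithm, chosen, X, y,
                     seed = child_seed(seed, "final"))
  cv_table <- tibble::as_tibble(grid)
  cv_table$rmse_cv <- scores
  structure(list(algorithm = algorithm, chosen_params = chosen, fit = fit,
                 feature_ids = colnames(X), cv_table = cv_table,
                 seed = as.integer(seed)),
            class = "qsar_model")
}

#' @export
print.qsar_model <- function(x, ...) {
  p <- paste(names(x$chosen_params), unlist(x$chosen_params),
             sep = "=", collapse = ", ")
  cat("<qsar_model> ", x$algorithm, " (", p, "), ",
      length(x$feature_ids), " features\n", sep = "")
  invisible(x)
}

#' Predict activities from a fitted QSAR model
#'
#' Columns of `newdata` are aligned to the model's training feature ids by
#' name; missing or extra features raise an error naming them.
#'
#' @param object A `qsar_model`.
#' @param newdata Numeric matrix with feature-id column names.
#' @param ... Unused.
#' @return Numeric vector of predictions.
#' @export
predict.qsar_model <- function(object, newdata, ...) {
  X <- as.matrix(newdata)
  if (is.null(colnames(X))) {
    assert_that(ncol(X) == length(object$feature_ids),
                "newdata has no column names and wrong column count")
    colnames(X) <- object$feature_ids
  }
  missing <- setdiff(object$feature_ids, colnames(X))
  extra <- setdiff(colnames(X), object$feature_ids)
  if (length(missing) || length(extra)) {
    stop("feature mismatch; missing: [",
         paste(utils::head(missing, 5), collapse = ", "), "], extra: [",
         paste(utils::head(extra, 5), collapse = ", "), "]", call. = FALSE)
  }
  predict_learner(object$fit, X[, object$feature_ids, drop = FALSE])
}
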