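#' Recursive feature elimination with random-forest importance
#'
#' Starting from the full feature set, repeatedly (1) records the k-fold
#' cross-validated RMSE of a random-forest regressor on the current
#' features, (2) fits a forest on all rows and ranks features by impurity
#' importance (variance reduction; reported under the field's customary
#' "Gini index" label), and (3) drops the `step` least important features.
#' The selected subset is the one with the lowest RMSE_CV along the trace,
#' ties broken toward fewer features. The fold partition is frozen across
#' steps so the trace is comparable.
#'
#' Constant (zero-variance) columns carry no information for a forest and
#' are excluded from the search up front when `drop_constant` is `TRUE`;
#' they are reported in the result.
#'
#' @param X Feature matrix with feature-id column names.
#' @param y Numeric response; must not be constant.
#' @param cv_folds Number of folds for RMSE_CV.
#' @param step Number of features eliminated per iteration. The literal
#'   procedure uses 1; larger values approximate it at a fraction of the
#'   cost for wide fingerprints.
#' @param min_features Stop eliminating once this many features remain.
#' @param seed Integer seed.
#' @param num_trees Forest size for both the importance fits and the CV
#'   fits.
#' @param drop_constant Exclude zero-variance columns before the search.
#' @return An `rfe_trace` object: list with `steps` (tibble: `n_features`,
#'   `rmse_cv`), `selected_feature_ids`, `eliminated` (ordered list per
#'   step), `constant_features`, `seed`. `tidy()` returns the trace tibble;
#'   `autoplot()` draws RMSE_CV against the number of features.
#' @export
rfe_rf <- function(X, y, cv_folds = 5L, step = 1L, min_features = 1L,
                   seed = 1L, num_trees = 500L, drop_constant = TRUE) {
  X <- as.matrix(X)
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  assert_that(nrow(X) == length(y), "X rows must match length(y)")
  assert_that(stats::sd(y) > 0, "constant y: nothing to select against")
  constant <- colnames(X)[apply(X, 2, function(v) min(v) == max(v))]
  current <- if (drop_constant) setdiff(colnames(X), constant)
             else colnames(X)
  assert_that(length(current) >= min_features,
              "fewer informative features than min_features")
  folds <- make_folds(nrow(X), cv_folds, seed = child_seed(seed, "rfefolds"))
  n_feat <- integer(0); rmse_cv <- numeric(0)
  sets <- list(); eliminated <- list()
  it <- 0L
  repeat {
    it <- it + 1L
    Xc <- X[, current, drop = FALSE]
    errs <- vapply(seq_along(folds), function(f) {
      hold <- folds[[f]]
      fit <- ranger::ranger(x = Xc[-hold, , drop = FALSE], y = y[-hold],
                            num.trees = num_trees, num.threads = 1L,
                            seed = child_seed(seed, paste0("rfecv", it, "_", f)))
      rmse(y[hold], as.numeric(stats::predict(fit, data = Xc[hold, , drop = FALSE],
                                              num.threads = 1L)$predictions))
    }, numeric(1))
    n_feat <- c(n_feat, length(current))
    rmse_cv <- c(rmse_cv, mean(errs))
    sets[[it]] <- current
    if (length(current) <= min_features) break
    imp_fit <- ranger::ranger(x = Xc, y = y, num.trees = num_trees,
                              importance = "impurity", num.threads = 1L,
                              seed = child_seed(seed, paste0("rfeimp", it)))
    imp <- imp_fit$variable.importance[current]
    k_drop <- min(step, length(current) - min_features)
    drop <- names(sort(imp))[seq_len(k_drop)]
    eliminated[[it]] <- drop
    current <- setdiff(current, drop)
  }
  # argmin RMSE_CV; ties toward fewer features (later steps have fewer)
  best <- which(rmse_cv == min(rmse_cv))
  best <- best[which.min(n_feat[best])]
  structure(list(
    steps = tibble::tibble(n_features = n_feat, rmse_cv = rmse_cv),
    selected_feature_ids = sets[[best]],
    selected_rmse_cv = rmse_cv[best],
    eliminated = eliminated,
    constant_features = constant,
    seed = as.integer(seed)
  ), class = "rfe_trace")
}

#' @export
print.rfe_trace <- function(x, ...) {
  cat("<rfe_trace> ", nrow(x$steps), " steps: ",
      max(x$steps$n_features), " -> ", min(x$steps$n_features),
      " features; selected ", length(x$selected_feature_ids),
      " (RMSE_CV ", signif(x$selected_rmse_cv, 4), ")\n", sep = "")
  invisible(x)
}
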