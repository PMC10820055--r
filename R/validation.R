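# Validation metrics and procedures: Q2/R2, RMSE, MAE, five-fold
# cross-validation with fold-wise mean +/- sd, and external-test evaluation.

#' Coefficient of determination
#'
#' `1 - SS_res / SS_tot` with the total sum of squares taken around the mean
#' of the observed values. Reported as Q2 when computed on cross-validation
#' folds and R2 on an external test set.
#'
#' @param y Observed values (length >= 2, not constant).
#' @param y_hat Predicted values, same length.
#' @return A single numeric value (<= 1; can be negative).
#' @export
r_squared <- function(y, y_hat) {
  assert_that(length(y) == length(y_hat), "y and y_hat lengths differ")
  assert_that(length(y) >= 2, "need at least 2 observations")
  ss_tot <- sum((y - mean(y))^2)
  assert_that(ss_tot > 0, "y is constant: coefficient of determination undefined")
  1 - sum((y_hat - y)^2) / ss_tot
}

#' Root-mean-square error and mean absolute error
#'
#' @param y Observed values (length >= 1).
#' @param y_hat Predicted values, same length.
#' @return A single numeric value.
#' @export
rmse <- function(y, y_hat) {
  assert_that(length(y) == length(y_hat), "y and y_hat lengths differ")
  assert_that(length(y) >= 1, "empty input")
  sqrt(mean((y_hat - y)^2))
}

#' @rdname rmse
#' @export
mae <- function(y, y_hat) {
  assert_that(length(y) == length(y_hat), "y and y_hat lengths differ")
  assert_that(length(y) >= 1, "empty input")
  mean(abs(y_hat - y))
}

#' Build a k-fold partition
#'
#' @param n Number of samples.
#' @param k Number of folds.
#' @param seed Integer seed.
#' @return List of `k` disjoint index vectors covering `1..n`.
#' @export
make_folds <- function(n, k, seed) {
  assert_that(n >= k, "need at least k samples")
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(as.integer(seed))
  assign_to <- sample(rep_len(seq_len(k), n))
  lapply(seq_len(k), function(f) which(assign_to == f))
}

#' Cross-validate a learner
#'
#' k-fold cross-validation: each sample is validated exactly once; Q2, RMSE
#' and MAE are computed per held-out fold and summarised as mean and
#' standard deviation across folds.
#'
#' @param X Feature matrix.
#' @param y Response vector.
#' @param algorithm Learner name (see [fit_qsar()]).
#' @param params Named list of learner parameters (a single grid point).
#' @param k Number of folds.
#' @param seed Integer seed (fold partition and stochastic learners).
#' @param folds Optional pre-built fold partition (overrides `k`/`seed` for
#'   the partition; used to freeze folds across calls).
#' @return A `qsar_cv` object: tibble with one row per fold (`fold`, `q2`,
#'   `rmse`, `mae`); `glance()` gives the mean +/- sd summary.
#' @export
cross_validate <- function(X, y, algorithm, params, k = 5L, seed = 1L,
                           folds = NULL) {
  X <- as.matrix(X)
  folds <- folds %||% make_folds(nrow(X), k, seed = child_seed(seed, "cv"))
  sizes <- lengths(folds)
  assert_that(all(sizes >= 2),
              "fold with fewer than 2 samples: per-fold Q2 undefined (choose smaller k)")
  rows <- lapply(seq_along(folds), function(f) {
    hold <- folds[[f]]
    fit <- fit_learner(algorithm, params, X[-hold, , drop = FALSE], y[-hold],
                       seed = child_seed(seed, paste0("cvfit", f)))
    pred <- predict_learner(fit, X[hold, , drop = FALSE])
    tibble::tibble(fold = f, q2 = r_squared(y[hold], pred),
                   rmse = rmse(y[hold], pred), mae = mae(y[hold], pred))
  })
  out <- dplyr::bind_rows(rows)
  class(out) <- c("qsar_cv", class(out))
  attr(out, "algorithm") <- algorithm
  attr(out, "params") <- params
  out
}

#' Evaluate a fitted model on an external test set
#'
#' @param model A `qsar_model`.
#' @param X_test,y_test Test feature matrix and responses.
#' @return A one-row tibble (`r2_test`, `rmse_test`, `mae_test`, `n_test`).
#' @export
evaluate_test <- function(model, X_test, y_test) {
  assert_that(NROW(X_test) > 0, "empty test set")
  pred <- stats::predict(model, X_test)
  tibble::tibble(r2_test = r_squared(y_test, pred),
                 rmse_test = rmse(y_test, pred),
                 mae_test = mae(y_test, pred),
                 n_test = length(y_test))
}

#' Assemble an evaluation report
#'
#' Combines fold-wise cross-validation statistics with external-test
#' metrics into the standard one-row report (mean +/- sd over folds for the
#' CV block).
#'
#' @param cv A `qsar_cv` object.
#' @param test Optional one-row tibble from [evaluate_test()].
#' @param n_train Training-set size.
#' @return A one-row tibble.
#' @export
evaluation_report <- function(cv, test = NULL, n_train = NA_integer_) {
  out <- tibble::tibble(
    q2_mean = mean(cv$q2), q2_sd = stats::sd(cv$q2),
    rmse_cv_mean = mean(cv$rmse), rmse_cv_sd = stats::sd(cv$rmse),
    mae_cv_mean = mean(cv$mae), mae_cv_sd = stats::sd(cv$mae),
    n_train = n_train
  )
  if (!is.null(test)) out <- dplyr::bind_cols(out, test)
  out
}
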