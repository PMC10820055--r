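# Independent brute-force metric implementations (explicit loops).
brute_r2 <- function(y, y_hat) {
  ybar <- sum(y) / length(y)
  num <- 0; den <- 0
  for (i in seq_along(y)) {
    num <- num + (y_hat[i] - y[i])^2
    den <- den + (ybar - y[i])^2
  }
  1 - num / den
}
brute_rmse <- function(y, y_hat) {
  s <- 0
  for (i in seq_along(y)) s <- s + (y_hat[i] - y[i])^2
  sqrt(s / length(y))
}
brute_mae <- function(y, y_hat) {
  s <- 0
  for (i in seq_along(y)) s <- s + abs(y_hat[i] - y[i])
  s / length(y)
}

test_that("metrics match closed-form and hand-computed cases", {
  y <- c(1, 2, 3); y_hat <- c(1.1, 1.9, 3.2)
  expect_equal(r_squared(y, y_hat), 1 - 0.06 / 2)
  expect_equal(rmse(y, y_hat), sqrt(0.02))
  expect_equal(mae(y, y_hat), 0.4 / 3)
  expect_equal(r_squared(y, y), 1)
  expect_equal(r_squared(y, rep(mean(y), 3)), 0)
  expect_equal(rmse(y, y), 0)
  expect_equal(mae(y, y), 0)
  expect_equal(rmse(2, 5), 3)
  expect_equal(mae(2, 5), 3)
  expect_error(r_squared(c(1, 1), c(1, 2)), "constant")
  expect_error(r_squared(1, 1), "at least 2")
  expect_error(rmse(1:3, 1:2), "differ")
  expect_error(rmse(numeric(0), numeric(0)), "empty")
})

test_that("metrics agree with brute-force loops on random vectors", {
  set.seed(123)
  for (rep in 1:1000) {
    n <- sample(2:40, 1)
    y <- rnorm(n); y_hat <- y + rnorm(n, 0, 0.5)
    if (sd(y) == 0) next
    expect_equal(r_squared(y, y_hat), brute_r2(y, y_hat), tolerance = 1e-12)
    expect_equal(rmse(y, y_hat), brute_rmse(y, y_hat), tolerance = 1e-12)
    expect_equal(mae(y, y_hat), brute_mae(y, y_hat), tolerance = 1e-12)
  }
})

test_that("fold partitions are true partitions for any seed", {
  for (seed in 1:25) {
    folds <- make_folds(53, 5, seed = seed)
    expect_length(folds, 5)
    expect_setequal(unlist(folds), 1:53)
    expect_equal(sum(lengths(folds)), 53)
  }
  expect_error(make_folds(3, 5, seed = 1), "at least k")
})

test_that("cross-validation validates each sample once and rejects k = n", {
  toy_n <- 40
  set.seed(5)
  X <- matrix(rnorm(toy_n * 4), toy_n, 4,
              dimnames = list(NULL, paste0("f", 1:4)))
  y <- X[, 1] * 2 + rnorm(toy_n, 0, 0.1)
  cv <- cross_validate(X, y, "xgb", list(n_estimators = 50), k = 5, seed = 2)
  expect_equal(nrow(cv), 5)
  expect_true(all(cv$rmse >= cv$mae)) # RMSE >= MAE per fold
  expect_true(all(cv$q2 <= 1))
  g <- glance(cv)
  expect_true(g$q2_mean > 0.5)
  expect_error(cross_validate(X, y, "xgb", list(n_estimators = 10), k = toy_n,
                              seed = 1),
               "fewer than 2")
})

test_that("a noiseless linear relationship yields per-fold Q2 of 1 for SVR proxy", {
  # perfectly learnable: y is an exact linear function; use a tiny-eps SVR
  n <- 30
  X <- cbind(a = seq_len(n) / n)
  y <- 2 * X[, "a"]
  folds <- make_folds(n, 5, seed = 1)
  preds <- numeric(n)
  for (f in folds) {
    fit <- e1071::svm(x = X[-f, , drop = FALSE], y = y[-f], kernel = "linear",
                      epsilon = 1e-6, cost = 1000, scale = FALSE)
    preds[f] <- predict(fit, X[f, , drop = FALSE])
  }
  for (f in folds) expect_gt(r_squared(y[f], preds[f]), 0.999)
})

test_that("external test evaluation returns the three finite metrics", {
  toy_n <- 50
  set.seed(8)
  X <- matrix(rbinom(toy_n * 6, 1, 0.4), toy_n, 6,
              dimnames = list(NULL, paste0("f", 1:6)))
  y <- 5 + X[, 1] + 0.5 * X[, 2] + rnorm(toy_n, 0, 0.15)
  m <- fit_qsar(X[1:35, ], y[1:35], "xgb",
                grid = data.frame(n_estimators = 80), seed = 3)
  res <- evaluate_test(m, X[36:50, ], y[36:50])
  expect_true(all(is.finite(unlist(res[1:3]))))
  expect_gte(res$rmse_test, res$mae_test)
  expect_error(evaluate_test(m, X[0, ], numeric(0)), "empty")
})

test_that("y-randomization preserves the label multiset and flags real signal", {
  lib <- test_library()
  X <- unclass(test_features("ECFP4"))
  keep <- apply(X, 2, function(v) min(v) != max(v))
  informative <- characteristic_bits(X, lib$has_methylsulfonamide)
  X <- X[, union(informative, colnames(X)[keep][1:30]), drop = FALSE]
  y <- lib$p_activity
  yr <- y_randomization(X, y, "xgb", list(n_estimators = 60),
                        repetitions = 12, seed = 21)
  expect_length(yr$randomized_q2, 12)
  expect_gte(yr$p_value, 0); expect_lte(yr$p_value, 1)
  expect_gt(yr$original_q2, max(yr$randomized_q2))
  # pure-noise response: original sits inside the randomized distribution
  set.seed(77)
  y_noise <- rnorm(nrow(X), 7, 0.5)
  yr0 <- y_randomization(X, y_noise, "xgb", list(n_estimators = 60),
                         repetitions = 12, seed = 22)
  expect_gt(mean(yr0$randomized_q2 >= yr0$original_q2), 0)
})

test_that("permuted responses are true permutations", {
  set.seed(14)
  X <- matrix(rbinom(200, 1, 0.5), 20, 10,
              dimnames = list(NULL, paste0("f", 1:10)))
  y <- rnorm(20, 7, 1)
  yr <- y_randomization(X, y, "svr_rbf", list(C = 1, gamma = 0.01),
                        repetitions = 15, cv_folds = 4, seed = 9,
                        keep_permutations = TRUE)
  for (p in yr$permutations) expect_equal(sort(p), sort(y))
  # not all permutations identical to the original ordering
  expect_true(any(vapply(yr$permutations,
                         function(p) !identical(p, y), logical(1))))
})
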