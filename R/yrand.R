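#' Y-randomization (response-scrambling) test
#'
#' Refits the chosen learner `repetitions` times on uniformly permuted
#' responses, keeping the selected features and tuned hyperparameters
#' fixed, and records the cross-validated Q2 of each randomized model. A
#' permutation preserves the response distribution exactly while destroying
#' any structure-activity relationship, so a genuine model's original Q2
#' should sit far above the randomized distribution.
#'
#' Significance is summarised two ways: a one-sample t-test of the
#' randomized Q2 sample against the original Q2 (the often-quoted
#' "paired-sample t-test" against a single original value is not
#' well-defined), and the empirical percentile of the original Q2 within
#' the randomized sample.
#'
#' @param X Selected feature matrix.
#' @param y Response vector.
#' @param algorithm,params Learner and tuned parameters (see [fit_qsar()]).
#' @param repetitions Number of permutations (>= 1).
#' @param cv_folds Folds for the Q2 computation, identical to the original
#'   model's procedure.
#' @param seed Integer seed.
#' @param keep_permutations Store the permuted response vectors in the
#'   result (for auditing; memory grows with `repetitions`).
#' @return A `qsar_yrand` object: list with `original_q2`, `randomized_q2`
#'   (length `repetitions`), `p_value` (one-sided t-test that randomized Q2
#'   is below the original), `empirical_quantile`, `seed`. `tidy()` returns
#'   the randomized sample; `autoplot()` draws the histogram with the
#'   original Q2 marked.
#' @export
y_randomization <- function(X, y, algorithm, params, repetitions = 1000L,
                            cv_folds = 5L, seed = 1L,
                            keep_permutations = FALSE) {
  assert_that(repetitions >= 1, "repetitions must be >= 1")
  X <- as.matrix(X)
  folds <- make_folds(nrow(X), cv_folds, seed = child_seed(seed, "yrfolds"))
  q2_of <- function(resp, tag) {
    cv <- cross_validate(X, resp, algorithm, params, seed = child_seed(seed, tag),
                         folds = folds)
    mean(cv$q2)
  }
  original <- q2_of(y, "orig")
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(child_seed(seed, "perm"))
  perms <- lapply(seq_len(repetitions), function(r) sample(y))
  randomized <- vapply(seq_len(repetitions), function(r) {
    q2_of(perms[[r]], paste0("rep", r))
  }, numeric(1))
  p_value <- if (repetitions >= 2 && stats::sd(randomized) > 0) {
    stats::t.test(randomized, mu = original, alternative = "less")$p.value
  } else NA_real_
  structure(list(
    original_q2 = original,
    randomized_q2 = randomized,
    p_value = p_value,
    empirical_quantile = mean(randomized < original),
    repetitions = as.integer(repetitions),
    permutations = if (keep_permutations) perms else NULL,
    seed = as.integer(seed)
  ), class = "qsar_yrand")
}

#' @export
print.qsar_yrand <- function(x, ...) {
  cat("<qsar_yrand> original Q2 ", signif(x$original_q2, 4), "; ",
      x$repetitions, " randomized Q2 in [",
      signif(min(x$randomized_q2), 3), ", ",
      signif(max(x$randomized_q2), 3), "]; t-test p ",
      format.pval(x$p_value), "\n", sep = "")
  invisible(x)
}
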