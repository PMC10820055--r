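# broom-style tidiers for the package's result objects.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @exportS3Method generics::tidy
tidy.scaffold_split <- function(x, ...) {
  tibble::tibble(
    index = c(x$train_indices, x$test_indices),
    subset = rep(c("train", "test"),
                 c(length(x$train_indices), length(x$test_indices)))
  ) |> dplyr::arrange(.data$index)
}

#' @exportS3Method generics::glance
glance.scaffold_split <- function(x, ...) {
  tibble::tibble(n = x$n, n_train = length(x$train_indices),
                 n_test = length(x$test_indices),
                 n_scaffolds = nrow(x$scaffold_assignment), seed = x$seed)
}

#' @exportS3Method generics::tidy
tidy.rfe_trace <- function(x, ...) x$steps

#' @exportS3Method generics::glance
glance.rfe_trace <- function(x, ...) {
  tibble::tibble(n_steps = nrow(x$steps),
                 n_selected = length(x$selected_feature_ids),
                 rmse_cv_selected = x$selected_rmse_cv,
                 n_constant_dropped = length(x$constant_features),
                 seed = x$seed)
}

#' @exportS3Method generics::tidy
tidy.qsar_model <- function(x, ...) x$cv_table

#' @exportS3Method generics::glance
glance.qsar_model <- function(x, ...) {
  dplyr::bind_cols(
    tibble::tibble(algorithm = x$algorithm,
                   n_features = length(x$feature_ids)),
    tibble::as_tibble(x$chosen_params),
    tibble::tibble(rmse_cv = min(x$cv_table$rmse_cv), seed = x$seed)
  )
}

#' @exportS3Method generics::glance
glance.qsar_cv <- function(x, ...) {
  tibble::tibble(
    q2_mean = mean(x$q2), q2_sd = stats::sd(x$q2),
    rmse_cv_mean = mean(x$rmse), rmse_cv_sd = stats::sd(x$rmse),
    mae_cv_mean = mean(x$mae), mae_cv_sd = stats::sd(x$mae),
    k = nrow(x)
  )
}

#' @exportS3Method generics::tidy
tidy.qsar_yrand <- function(x, ...) {
  tibble::tibble(repetition = seq_along(x$randomized_q2),
                 q2 = x$randomized_q2)
}

#' @exportS3Method generics::glance
glance.qsar_yrand <- function(x, ...) {
  tibble::tibble(original_q2 = x$original_q2,
                 randomized_q2_max = max(x$randomized_q2),
                 randomized_q2_mean = mean(x$randomized_q2),
                 p_value = x$p_value,
                 empirical_quantile = x$empirical_quantile,
                 repetitions = x$repetitions, seed = x$seed)
}

#' @exportS3Method generics::tidy
tidy.activity_shift <- function(x, ...) x$histogram

#' @exportS3Method generics::glance
glance.activity_shift <- function(x, ...) {
  tibble::tibble(n_with = x$n_with, n_without = x$n_without,
                 fraction_with = x$fraction_with,
                 mean_with = x$mean_with, mean_without = x$mean_without,
                 shift = x$shift, degenerate = x$degenerate)
}

#' @exportS3Method generics::tidy
tidy.qsar_study <- function(x, ...) x$report

#' @exportS3Method generics::glance
glance.qsar_study <- function(x, ...) {
  dplyr::bind_cols(
    tibble::tibble(endpoint = x$manifest$endpoint,
                   optimal_algorithm = x$optimal$algorithm,
                   optimal_family = x$optimal$family),
    x$optimal$metrics[, c("q2_mean", "q2_sd", "r2_test", "rmse_test",
                          "n_features")],
    tibble::tibble(yrand_p = x$yrand$p_value, seed = x$manifest$seed)
  )
}
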