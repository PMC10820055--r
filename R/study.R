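# End-to-end study per endpoint: curate/simulate -> scaffold split ->
# featurize -> RFE-RF select -> grid-search train x validate for every
# (algorithm, descriptor family) cell -> pick the optimum -> Y-randomize ->
# interpret.

#' Configure an endpoint study
#'
#' Defaults follow the full published protocol: all four descriptor
#' families crossed with all four algorithms (16 model cells per endpoint),
#' five-fold cross-validation, the full hyperparameter grids and 1000
#' Y-randomization repetitions. Scale `grids`, `rfe_step`, `rfe_num_trees`
#' and `yrand_repetitions` down for desk-scale runs.
#'
#' @param endpoint `"Ki"`, `"IC50"` or `"EC50"`.
#' @param families Descriptor families to include.
#' @param algorithms Learners to include.
#' @param generator A [generator_config()] used when no data are supplied;
#'   defaults to the endpoint preset with the study seed.
#' @param rare_threshold,train_fraction Scaffold-split parameters.
#' @param rfe_step,rfe_num_trees,rfe_min_features RFE-RF parameters.
#' @param grids Named list of hyperparameter grids per algorithm; defaults
#'   to [default_grid()] for each.
#' @param cv_folds Cross-validation folds.
#' @param yrand_repetitions Y-randomization repetitions.
#' @param top_k Number of top-importance features interpreted.
#' @param seed Master integer seed; every stage derives its own stream.
#' @return A `study_config` list.
#' @export
study_config <- function(endpoint = c("Ki", "IC50", "EC50"),
                         families = c("ECFP4", "DAYLIGHT", "MACCS", "ESTATE"),
                         algorithms = qsar_algorithms(),
                         generator = NULL,
                         rare_threshold = 5L, train_fraction = 0.8,
                         rfe_step = 1L, rfe_num_trees = 500L,
                         rfe_min_features = 1L,
                         grids = NULL, cv_folds = 5L,
                         yrand_repetitions = 1000L, top_k = 5L, seed = 1L) {
  endpoint <- match.arg(endpoint)
  families <- match.arg(families, several.ok = TRUE)
  algorithms <- match.arg(algorithms, qsar_algorithms(), several.ok = TRUE)
  grids <- grids %||% stats::setNames(lapply(algorithms, default_grid),
                                      algorithms)
  structure(list(
    endpoint = endpoint, families = families, algorithms = algorithms,
    generator = generator %||% generator_config(endpoint, seed = seed),
    rare_threshold = as.integer(rare_threshold),
    train_fraction = train_fraction,
    rfe_step = as.integer(rfe_step),
    rfe_num_trees = as.integer(rfe_num_trees),
    rfe_min_features = as.integer(rfe_min_features),
    grids = grids, cv_folds = as.integer(cv_folds),
    yrand_repetitions = as.integer(yrand_repetitions),
    top_k = as.integer(top_k), seed = as.integer(seed)
  ), class = "study_config")
}

.stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop("study stage '", name, "' failed: ", conditionMessage(e),
         call. = FALSE)
  })
}

#' Run an endpoint study
#'
#' Executes the full pipeline for one endpoint and returns every artifact:
#' the per-cell evaluation grid (one row per algorithm x family), the
#' optimal model (highest mean Q2; ties broken by higher test R2, then
#' fewer selected features), its Y-randomization result, the importance
#' ranking of its selected features and the activity-shift analysis of the
#' top features. Deterministic under the config seed.
#'
#' @param config A [study_config()].
#' @param data Optional compound tibble with `smiles` and `p_activity`
#'   columns (e.g. a curated set renamed accordingly, or a
#'   `synthetic_library`). Generated from `config$generator` when `NULL`.
#' @return A `qsar_study` object.
#' @export
run_endpoint_study <- function(config, data = NULL) {
  stopifnot(inherits(config, "study_config"))
  seed <- config$seed
  data <- .stage("simulate", data %||% generate_library(config$generator))
  assert_that(all(c("smiles", "p_activity") %in% names(data)),
              "data needs smiles and p_activity columns")
  split <- .stage("split", scaffold_split(
    data, seed = child_seed(seed, "split"),
    rare_threshold = config$rare_threshold,
    train_fraction = config$train_fraction, smiles_col = "smiles"))
  tr <- split$train_indices; te <- split$test_indices
  y_tr <- data$p_activity[tr]; y_te <- data$p_activity[te]
  cells <- list(); selections <- list(); models <- list()
  for (fam in config$families) {
    feats <- .stage(paste0("featurize/", fam),
                    featurize(data, fam, smiles_col = "smiles"))
    X_tr <- unclass(feats)[tr, , drop = FALSE]
    X_te <- unclass(feats)[te, , drop = FALSE]
    sel <- .stage(paste0("select/", fam), rfe_rf(
      X_tr, y_tr, cv_folds = config$cv_folds, step = config$rfe_step,
      min_features = config$rfe_min_features,
      seed = child_seed(seed, paste0("rfe_", fam)),
      num_trees = config$rfe_num_trees))
    selections[[fam]] <- sel
    ids <- sel$selected_feature_ids
    cv_folds_fixed <- make_folds(length(tr), config$cv_folds,
                                 seed = child_seed(seed, paste0("cv_", fam)))
    for (alg in config$algorithms) {
      key <- paste(alg, fam, sep = "/")
      model <- .stage(paste0("train/", key), fit_qsar(
        X_tr[, ids, drop = FALSE], y_tr, alg, grid = config$grids[[alg]],
        cv_folds = config$cv_folds, seed = child_seed(seed, paste0("fit_", key))))
      cv <- .stage(paste0("validate/", key), cross_validate(
        X_tr[, ids, drop = FALSE], y_tr, alg, model$chosen_params,
        seed = child_seed(seed, paste0("cvm_", key)), folds = cv_folds_fixed))
      test <- .stage(paste0("validate/", key),
                     evaluate_test(model, X_te[, ids, drop = FALSE], y_te))
      models[[key]] <- model
      cells[[key]] <- dplyr::bind_cols(
        tibble::tibble(algorithm = alg, family = fam,
                       n_features = length(ids)),
        evaluation_report(cv, test, n_train = length(tr))
      )
    }
  }
  report <- dplyr::bind_rows(cells)
  ord <- order(-report$q2_mean, -report$r2_test, report$n_features)
  opt <- report[ord[1L], ]
  opt_key <- paste(opt$algorithm, opt$family, sep = "/")
  opt_ids <- selections[[opt$family]]$selected_feature_ids
  opt_feats <- featurize(data, opt$family, smiles_col = "smiles")
  X_opt_tr <- unclass(opt_feats)[tr, opt_ids, drop = FALSE]
  yrand <- .stage("yrand", y_randomization(
    X_opt_tr, y_tr, opt$algorithm, models[[opt_key]]$chosen_params,
    repetitions = config$yrand_repetitions, cv_folds = config$cv_folds,
    seed = child_seed(seed, "yrand")))
  importance <- .stage("interpret", rank_importances(
    X_opt_tr, y_tr, seed = child_seed(seed, "imp"),
    num_trees = config$rfe_num_trees))
  top_ids <- utils::head(importance$feature_id, config$top_k)
  shift <- .stage("interpret", activity_shift(
    data, unclass(opt_feats), top_ids, mode = "all"))
  manifest <- list(
    endpoint = config$endpoint, seed = seed,
    families = config$families, algorithms = config$algorithms,
    n_compounds = nrow(data), n_train = length(tr), n_test = length(te),
    cv_folds = config$cv_folds,
    yrand_repetitions = config$yrand_repetitions,
    rfe = list(step = config$rfe_step, num_trees = config$rfe_num_trees),
    stage_seeds = list(
      split = child_seed(seed, "split"),
      rfe = stats::setNames(lapply(config$families, function(f)
        child_seed(seed, paste0("rfe_", f))), config$families),
      yrand = child_seed(seed, "yrand"), importance = child_seed(seed, "imp"))
  )
  structure(list(
    report = report,
    optimal = list(algorithm = opt$algorithm, family = opt$family,
                   model = models[[opt_key]], selected_feature_ids = opt_ids,
                   metrics = opt),
    yrand = yrand, importance = importance, shift = shift,
    selections = selections, split = split, data = data,
    manifest = manifest
  ), class = "qsar_study")
}

#' @export
print.qsar_study <- function(x, ...) {
  cat("<qsar_study> ", x$manifest$endpoint, ": ", nrow(x$report),
      " model cells (", x$manifest$n_train, " train / ",
      x$manifest$n_test, " test)\n", sep = "")
  cat("  optimum: ", x$optimal$algorithm, " x ", x$optimal$family,
      " (Q2 ", signif(x$optimal$metrics$q2_mean, 3), ", R2 ",
      signif(x$optimal$metrics$r2_test, 3), ", ",
      x$optimal$metrics$n_features, " features)\n", sep = "")
  invisible(x)
}

#' Serialize study reports to JSON/CSV
#'
#' Writes the evaluation grid, Y-randomization sample, importance ranking,
#' activity-shift histogram, split assignment and the run manifest under
#' `dir`. Output is deterministic for a given study (no timestamps), so a
#' rerun under the same config and seed reproduces the files byte for
#' byte.
#'
#' @param study A `qsar_study`.
#' @param dir Output directory (created if missing).
#' @return Invisibly, the vector of files written.
#' @export
write_study <- function(study, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  jw <- function(x, f) jsonlite::write_json(
    x, file.path(dir, f), auto_unbox = TRUE, digits = NA, pretty = TRUE)
  jw(study$report, "report.json")
  jw(list(original_q2 = study$yrand$original_q2,
          randomized_q2 = study$yrand$randomized_q2,
          p_value = study$yrand$p_value,
          empirical_quantile = study$yrand$empirical_quantile),
     "yrand.json")
  jw(study$importance, "importance.json")
  jw(list(feature_ids = study$shift$feature_ids, mode = study$shift$mode,
          n_with = study$shift$n_with, n_without = study$shift$n_without,
          fraction_with = study$shift$fraction_with,
          shift = study$shift$shift,
          histogram = study$shift$histogram), "activity_shift.json")
  jw(study$manifest, "manifest.json")
  utils::write.csv(tidy(study$split), file.path(dir, "split.csv"),
                   row.names = FALSE)
  invisible(list.files(dir, full.names = TRUE))
}
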