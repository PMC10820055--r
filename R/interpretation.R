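# Model interpretation: forest importance ranking over the selected
# features, partitioning compounds by feature presence, and mapping top
# fingerprint bits back to depictable substructures.

#' Rank feature importances
#'
#' Fits a random forest on the selected features and returns impurity
#' importances normalized to sum to one, sorted in decreasing order.
#' Importances are clipped below at zero before normalization (ranger's
#' impurity importance for regression is a variance reduction and is
#' non-negative up to numerical noise).
#'
#' @param X Selected feature matrix with feature-id column names.
#' @param y Numeric response; must not be constant.
#' @param seed Integer seed.
#' @param num_trees Forest size.
#' @return An `importance_ranking`: tibble (`feature_id`, `importance`)
#'   sorted by decreasing importance, summing to 1.
#' @export
rank_importances <- function(X, y, seed = 1L, num_trees = 500L) {
  X <- as.matrix(X)
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  assert_that(stats::sd(y) > 0, "constant y")
  fit <- ranger::ranger(x = X, y = y, num.trees = num_trees,
                        importance = "impurity", seed = as.integer(seed),
                        num.threads = 1L)
  imp <- pmax(fit$variable.importance, 0)
  if (sum(imp) == 0) imp[] <- 1 # pathological: no split improved impurity
  imp <- imp / sum(imp)
  out <- tibble::tibble(feature_id = names(imp), importance = unname(imp))
  out <- out[order(-out$importance), ]
  class(out) <- c("importance_ranking", class(out))
  out
}

#' Activity shift between feature-bearing and feature-free compounds
#'
#' Partitions the dataset by presence of the listed fingerprint features
#' (mode `"all"`: a compound must carry every listed bit; `"any"`: at least
#' one) and reports group sizes, group means and histograms of the activity
#' over shared bin edges.
#'
#' @param data Data frame with the activity column.
#' @param features Feature matrix aligned with `data` rows.
#' @param feature_ids Character vector of feature columns to test.
#' @param mode `"all"` or `"any"`.
#' @param activity_col Name of the activity column in `data`.
#' @param binwidth Histogram bin width in p-activity units.
#' @return An `activity_shift` object: list with `n_with`, `n_without`,
#'   `fraction_with`, `mean_with`, `mean_without`, `shift`
#'   (mean_with - mean_without; `NA` when a group is empty, flagged by
#'   `degenerate`), `histogram` tibble and the inputs' metadata.
#' @export
activity_shift <- function(data, features, feature_ids,
                           mode = c("all", "any"),
                           activity_col = "p_activity", binwidth = 0.5) {
  mode <- match.arg(mode)
  assert_that(length(feature_ids) > 0, "feature_ids must be non-empty")
  m <- as.matrix(features)
  missing <- setdiff(feature_ids, colnames(m))
  assert_that(length(missing) == 0,
              paste0("features absent from matrix: ",
                     paste(utils::head(missing, 5), collapse = ", ")))
  assert_that(nrow(m) == nrow(data), "features rows must match data rows")
  present <- m[, feature_ids, drop = FALSE] > 0
  with_flag <- if (mode == "all") rowSums(present) == length(feature_ids)
               else rowSums(present) > 0
  act <- data[[activity_col]]
  n_with <- sum(with_flag); n_without <- sum(!with_flag)
  degenerate <- n_with == 0 || n_without == 0
  edges <- seq(floor(min(act) / binwidth) * binwidth,
               ceiling(max(act) / binwidth) * binwidth + binwidth,
               by = binwidth)
  hist_counts <- function(v) {
    if (!length(v)) return(integer(length(edges) - 1L))
    graphics::hist(v, breaks = edges, plot = FALSE)$counts
  }
  histogram <- tibble::tibble(
    bin_low = edges[-length(edges)],
    bin_high = edges[-1],
    count_with = hist_counts(act[with_flag]),
    count_without = hist_counts(act[!with_flag])
  )
  structure(list(
    feature_ids = feature_ids, mode = mode,
    n_with = n_with, n_without = n_without,
    fraction_with = n_with / (n_with + n_without),
    mean_with = if (n_with) mean(act[with_flag]) else NA_real_,
    mean_without = if (n_without) mean(act[!with_flag]) else NA_real_,
    shift = if (!degenerate) mean(act[with_flag]) - mean(act[!with_flag])
            else NA_real_,
    degenerate = degenerate,
    with_flag = with_flag,
    histogram = histogram
  ), class = "activity_shift")
}

#' @export
print.activity_shift <- function(x, ...) {
  cat("<activity_shift> ", x$n_with, " with / ", x$n_without,
      " without (", sprintf("%.2f%%", 100 * x$fraction_with), " bearing); ",
      if (x$degenerate) "degenerate partition"
      else paste0("shift ", signif(x$shift, 3)), "\n", sep = "")
  invisible(x)
}

#' Depict the substructures behind top-ranked fingerprint bits
#'
#' For each feature, finds the first exemplar molecule in which the bit
#' fires and maps it back to atoms via [explain_bit()] (central atom and
#' radius-limited environment for ECFP4 bits; linear atom paths, with no
#' central atom, for DAYLIGHT bits).
#'
#' @param exemplars Character vector of SMILES to search.
#' @param family `"ECFP4"` or `"DAYLIGHT"`.
#' @param feature_ids Character vector of feature ids
#'   (`"<FAMILY>_<bit>"`) or integer bit indices.
#' @return A list of `bit_substructure` objects keyed by feature id; each
#'   can be drawn with `autoplot()`. Errors if a feature fires in no
#'   exemplar.
#' @export
depict_top_features <- function(exemplars, family = c("ECFP4", "DAYLIGHT"),
                                feature_ids) {
  family <- match.arg(family)
  bits <- if (is.character(feature_ids)) {
    as.integer(sub(".*_", "", feature_ids))
  } else as.integer(feature_ids)
  out <- lapply(bits, function(b) {
    for (s in exemplars) {
      hit <- tryCatch(explain_bit(s, family, b), error = function(e) NULL)
      if (!is.null(hit)) return(hit)
    }
    stop("feature ", family, "_", b, " absent from all exemplars",
         call. = FALSE)
  })
  names(out) <- paste0(family, "_", bits)
  out
}
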