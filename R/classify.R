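#' Random-forest classification of apical vs basal positions
#'
#' Trains a random forest (bootstrap-sampled trees, Gini-impurity splits,
#' `m_try` candidate features per node, trees grown to purity) to classify
#' the axial positions into apical and basal regions, using the 120 probe
#' intensity features.  Accuracy is assessed by the out-of-bag (OOB) error:
#' each position is predicted by majority vote over the trees whose
#' bootstrap sample excluded it.  Feature importance is the mean decrease in
#' Gini impurity, reported raw and rescaled to percent of total.
#'
#' @param fm A `zp_feature_matrix` (positions x features).
#' @param labels Character/factor of length `L` with exactly two classes
#'   (e.g. the `region` column of [tidy.zp_compartment()]).
#' @param n_trees Number of trees (default 500).
#' @param m_try Number of features tried at each split (default 10).
#' @param seed Integer seed making the forest fully reproducible
#'   (default 20231218).
#' @return A `zp_classification` list: `confusion` (2x2 OOB counts, rows =
#'   true class), `oob_error_pct`, `importance` (per-feature tibble with raw
#'   and percent mean decrease in Gini), `importance_by_structure`
#'   (per-(probe, replicate) means over time points, percent scale),
#'   `rf_params`, and the underlying `randomForest` fit.
#' @export
classify_regions <- function(fm, labels, n_trees = 500, m_try = 10,
                             seed = 20231218) {
  stopifnot(inherits(fm, "zp_feature_matrix"))
  n_trees <- check_scalar_count(n_trees, "n_trees")
  m_try <- check_scalar_count(m_try, "m_try")
  x <- fm$values
  if (length(labels) != nrow(x)) {
    abort("`labels` must have one entry per position",
          class = "zp_parameter_error")
  }
  y <- factor(labels)
  if (nlevels(y) != 2 || any(table(y) < 2)) {
    abort("labels must have exactly 2 classes with >= 2 members each",
          class = "zp_parameter_error")
  }
  if (m_try > ncol(x)) {
    abort("m_try exceeds the number of features",
          class = "zp_parameter_error")
  }
  set.seed(seed)
  rf <- randomForest::randomForest(x = x, y = y, ntree = n_trees,
                                   mtry = m_try, importance = FALSE)
  confusion <- rf$confusion[, 1:2, drop = FALSE]
  storage.mode(confusion) <- "double"
  imp_raw <- randomForest::importance(rf, type = 2)[, "MeanDecreaseGini"]
  imp_pct <- 100 * imp_raw / sum(imp_raw)
  importance <- mutate(fm$features,
                       mean_decrease_gini = unname(imp_raw),
                       mean_decrease_gini_pct = unname(imp_pct))
  structure(
    list(confusion = confusion,
         oob_error_pct = oob_error_from_confusion(confusion),
         importance = importance,
         importance_by_structure = aggregate_importance(importance),
         rf_params = list(n_trees = n_trees, m_try = m_try, seed = seed),
         fit = rf),
    class = "zp_classification"
  )
}

#' Out-of-bag error rate from a confusion matrix
#'
#' @param confusion 2x2 (or k x k) matrix of OOB counts, rows = true class,
#'   columns = predicted class.
#' @return Percent misclassified, rounded to 1 decimal (the reporting
#'   precision used throughout).
#' @export
#' @examples
#' oob_error_from_confusion(matrix(c(47, 1, 1, 61), 2, byrow = TRUE))
oob_error_from_confusion <- function(confusion) {
  m <- as.matrix(confusion)
  if (nrow(m) != ncol(m) || any(m < 0)) {
    abort("confusion must be a square non-negative count matrix",
          class = "zp_parameter_error")
  }
  total <- sum(m)
  if (total == 0) {
    abort("confusion matrix is empty", class = "zp_parameter_error")
  }
  round(100 * (total - sum(diag(m))) / total, 1)
}

#' Aggregate feature importance per intracellular structure
#'
#' Percent-scaled Gini importances are averaged over the `k` time points of
#' each (probe, replicate) column group, yielding one value per biological
#' replicate per structure (n = 3 per structure in the full design), the
#' unit of replication used for the Tukey-Kramer comparison.
#'
#' @param importance Per-feature importance tibble with columns `probe`,
#'   `replicate_id`, `timepoint`, `mean_decrease_gini_pct` (as produced by
#'   [classify_regions()]).
#' @return Tibble: `probe`, `replicate_id`, `mean_decrease_gini_pct`.
#' @export
aggregate_importance <- function(importance) {
  needed <- c("probe", "replicate_id", "mean_decrease_gini_pct")
  if (!all(needed %in% names(importance))) {
    abort(paste0("`importance` must have columns: ",
                 paste(needed, collapse = ", ")),
          class = "zp_parameter_error")
  }
  summarise(group_by(importance, .data$probe, .data$replicate_id),
            mean_decrease_gini_pct = mean(.data$mean_decrease_gini_pct),
            .groups = "drop")
}

#' @export
print.zp_classification <- function(x, ...) {
  cat(sprintf("<zp_classification> %d trees, mtry %d, OOB error %.1f%%\n",
              x$rf_params$n_trees, x$rf_params$m_try, x$oob_error_pct))
  print(x$confusion)
  invisible(x)
}

#' Tidy per-feature importances of a classification
#'
#' @param x A `zp_classification`.
#' @param ... Unused.
#' @return The per-feature importance tibble.
#' @exportS3Method generics::tidy
tidy.zp_classification <- function(x, ...) x$importance

#' One-row summary of a classification
#'
#' @param x A `zp_classification`.
#' @param ... Unused.
#' @return Tibble: `n_positions`, `n_features`, `n_trees`, `m_try`,
#'   `oob_error_pct`.
#' @exportS3Method generics::glance
glance.zp_classification <- function(x, ...) {
  tibble(
    n_positions = sum(x$confusion),
    n_features = nrow(x$importance),
    n_trees = x$rf_params$n_trees,
    m_try = x$rf_params$m_try,
    oob_error_pct = x$oob_error_pct
  )
}
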