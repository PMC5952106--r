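classifier_features <- function() c("age", classification_vars())

feature_frame <- function(table) {
  as.data.frame(table)[classifier_features()]
}

#' Train the random-forest reading-profile classifier
#'
#' Features are age plus the five classification test scores only; sex,
#' site, ids, labels and validation scores are never used as predictors.
#' When `mtry` is `NULL` the number of candidate predictors per split is
#' tuned by repeated stratified cross-validation (5-fold, 10 repeats by
#' default) over `tune_grid`, then a 500-tree forest is fit at the selected
#' value. Pass `mtry = 2` to pin the conventional value and skip tuning.
#'
#' @param training complete, labeled [behavioral_table()] with at least two
#'   rows per class present.
#' @param seed integer seed.
#' @param mtry predictors per split; `NULL` to tune.
#' @param num_trees trees in the final forest (default 500).
#' @param tune_grid candidate mtry values (default 1:6).
#' @param folds,repeats cross-validation layout for tuning.
#' @return a `profile_classifier` with the fitted forest and, if tuned, the
#'   `tuning_record` of cross-validated accuracies.
#' @export
train_classifier <- function(training, seed = 1L, mtry = NULL,
                             num_trees = 500, tune_grid = 1:6,
                             folds = 5, repeats = 10) {
  stopifnot(inherits(training, "behavioral_table"))
  if (!"label" %in% names(training) || any(is.na(training$label))) {
    stop("training table must be fully labeled")
  }
  feats <- feature_frame(training)
  if (any(is.na(feats))) {
    stop("training table must be complete in the classifier features")
  }
  if (any(table(factor(training$label, levels = profile_levels())) < 2)) {
    stop("need at least 2 rows per class")
  }
  y <- droplevels(training$label)
  tuning_record <- NULL
  if (is.null(mtry)) {
    tuning_record <- tune_mtry(feats, y, tune_grid, folds, repeats,
                               num_trees, seed)
    best <- tuning_record$cv_accuracy == max(tuning_record$cv_accuracy)
    mtry <- min(tuning_record$mtry[best])
  }
  forest <- ranger::ranger(x = feats, y = y, num.trees = num_trees,
                           mtry = mtry, num.threads = 1,
                           seed = child_seed(seed, 7))
  structure(list(forest = forest, mtry = mtry, num_trees = num_trees,
                 feature_order = classifier_features(),
                 tuning_record = tuning_record,
                 label_levels = levels(training$label),
                 training_seed = as.integer(seed)),
            class = "profile_classifier")
}

tune_mtry <- function(feats, y, tune_grid, folds, repeats, num_trees, seed) {
  n <- nrow(feats)
  acc <- matrix(NA_real_, folds * repeats, length(tune_grid))
  row <- 0
  for (r in seq_len(repeats)) {
    fold_id <- with_seed(child_seed(seed, 5, r), {
      id <- integer(n)
      for (cl in levels(y)) {  # stratified fold assignment
        idx <- which(y == cl)
        id[idx] <- sample(rep_len(seq_len(folds), length(idx)))
      }
      id
    })
    for (f in seq_len(folds)) {
      row <- row + 1
      tr <- fold_id != f
      for (g in seq_along(tune_grid)) {
        fit <- ranger::ranger(x = feats[tr, , drop = FALSE], y = y[tr],
                              num.trees = num_trees, mtry = tune_grid[g],
                              num.threads = 1,
                              seed = child_seed(seed, 6, r, f, g))
        pred <- stats::predict(fit, data = feats[!tr, , drop = FALSE],
                               num.threads = 1,
                               seed = child_seed(seed, 8, r, f, g))$predictions
        acc[row, g] <- mean(pred == y[!tr])
      }
    }
  }
  data.frame(mtry = tune_grid, cv_accuracy = colMeans(acc))
}

#' Classify reading profiles
#'
#' Majority vote of the forest's trees, one label per row. The table must be
#' complete in the classifier features; rows with missing features should be
#' imputed first.
#'
#' @param model a [train_classifier()] result.
#' @param table complete [behavioral_table()].
#' @return factor of predicted profile labels.
#' @export
classify <- function(model, table) {
  stopifnot(inherits(model, "profile_classifier"))
  feats <- feature_frame(table)
  if (any(is.na(feats))) {
    stop("missing feature cells: impute the table before classification")
  }
  # fixed prediction seed: tree-vote ties are broken deterministically
  p <- stats::predict(model$forest, data = feats,
                      num.threads = 1, seed = 285714L)$predictions
  factor(as.character(p), levels = profile_levels())
}

#' Pool per-imputation labels into consensus labels
#'
#' Modal label across imputations per row; ties resolved by the fixed
#' priority Control > PoorDecoder > PoorComprehender > GenerallyPoorReader.
#'
#' @param label_matrix n x m matrix (or data frame) of per-imputation
#'   labels.
#' @return factor of pooled labels with an attribute `n_ties` counting
#'   tie-broken rows.
#' @export
pool_labels <- function(label_matrix) {
  lm <- as.matrix(label_matrix)
  prio <- profile_priority()
  ties <- 0L
  pooled <- apply(lm, 1, function(r) {
    cnt <- table(factor(r, levels = prio))
    top <- names(cnt)[cnt == max(cnt)]
    if (length(top) > 1) ties <<- ties + 1L
    top[1]  # prio order: first listed wins ties
  })
  out <- factor(pooled, levels = profile_levels())
  attr(out, "n_ties") <- ties
  out
}

#' Classify every table of an imputation set and pool the labels
#'
#' @param model a [train_classifier()] result.
#' @param imps an `imputation_set`.
#' @param baseline optional complete table; if supplied its labels are
#'   reported as `baseline_labels`.
#' @return a `classification_result`: `per_imputation_labels` (n x m),
#'   `pooled_labels`, `profile_counts` (per-imputation mean and SD per
#'   profile) and optionally `baseline_labels`.
#' @export
classify_imputed <- function(model, imps, baseline = NULL) {
  stopifnot(inherits(imps, "imputation_set"))
  labels <- vapply(imps$tables, function(tb) as.character(classify(model, tb)),
                   character(nrow(imps$tables[[1]])))
  labels <- matrix(labels, ncol = imps$m)
  counts <- sapply(seq_len(imps$m), function(j) {
    table(factor(labels[, j], levels = profile_levels()))
  })
  counts <- matrix(counts, nrow = length(profile_levels()),
                   dimnames = list(profile_levels(), NULL))
  structure(list(
    per_imputation_labels = labels,
    pooled_labels = pool_labels(labels),
    profile_counts = data.frame(
      profile = profile_levels(),
      mean = rowMeans(counts),
      sd = apply(counts, 1, stats::sd)),
    baseline_labels = if (!is.null(baseline)) classify(model, baseline)),
    class = "classification_result")
}

#' Confusion metrics for four-class profile labels
#'
#' @param predicted,truth label vectors of equal length over the four
#'   profiles.
#' @return a `confusion_summary`: overall `accuracy`, one-vs-rest
#'   `sensitivity` and `specificity` per class (NA when the class is absent
#'   from `truth`), macro averages over classes present, and the 4x4
#'   confusion `table`.
#' @export
confusion_metrics <- function(predicted, truth) {
  predicted <- factor(as.character(predicted), levels = profile_levels())
  truth <- factor(as.character(truth), levels = profile_levels())
  stopifnot(length(predicted) == length(truth),
            !any(is.na(predicted)), !any(is.na(truth)))
  tab <- table(truth = truth, predicted = predicted)
  n <- length(truth)
  sens <- spec <- stats::setNames(rep(NA_real_, 4), profile_levels())
  for (cl in profile_levels()) {
    tp <- tab[cl, cl]
    fn <- sum(tab[cl, ]) - tp
    fp <- sum(tab[, cl]) - tp
    tn <- n - tp - fn - fp
    if (tp + fn > 0) sens[cl] <- tp / (tp + fn)
    spec[cl] <- if (tn + fp > 0) tn / (tn + fp) else NA_real_
  }
  structure(list(accuracy = sum(diag(tab)) / n,
                 sensitivity = sens, specificity = spec,
                 macro_sensitivity = mean(sens, na.rm = TRUE),
                 macro_specificity = mean(spec, na.rm = TRUE),
                 n = n, table = tab),
            class = "confusion_summary")
}

#' Leave-one-out accuracy of the profile classifier on a cohort
#'
#' Refits the forest n times, holding out one participant per fold.
#'
#' @param table complete, labeled [behavioral_table()].
#' @param mtry,num_trees forest hyperparameters (defaults 2 and 500).
#' @param seed integer seed.
#' @return the leave-one-out accuracy as a fraction.
#' @export
loo_accuracy <- function(table, mtry = 2, num_trees = 500, seed = 1L) {
  stopifnot(inherits(table, "behavioral_table"))
  feats <- feature_frame(table)
  y <- droplevels(table$label)
  n <- nrow(feats)
  correct <- logical(n)
  for (i in seq_len(n)) {
    fit <- ranger::ranger(x = feats[-i, , drop = FALSE], y = y[-i],
                          num.trees = num_trees, mtry = mtry,
                          num.threads = 1, seed = child_seed(seed, 9, i))
    pred <- stats::predict(fit, data = feats[i, , drop = FALSE],
                           num.threads = 1,
                           seed = child_seed(seed, 10, i))$predictions
    correct[i] <- as.character(pred) == as.character(y[i])
  }
  mean(correct)
}
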