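#' Confusion-matrix evaluation metrics
#'
#' Accuracy, sensitivity and specificity as percentages and the Matthews
#' correlation coefficient from TP/TN/FP/FN counts:
#' `Ac = 100 (TP + TN) / (TP + TN + FP + FN)`,
#' `Sn = 100 TP / (TP + FN)`, `Sp = 100 TN / (TN + FP)`,
#' `MCC = (TP TN - FP FN) / sqrt((TP+FP)(TP+FN)(TN+FP)(TN+FN))`.
#' Whenever a factor in the MCC denominator is zero, MCC is defined as 0;
#' Sn (Sp) is `NaN` when no positives (negatives) were evaluated. The
#' class `"active"` is the positive class everywhere in the package.
#'
#' @param tp,tn,fp,fn Non-negative integer counts.
#' @param context Optional label (`"training"`, `"cv"`, `"test"`).
#' @return One-row tibble: `context`, `ac`, `sn`, `sp`, `mcc`, `tp`, `tn`,
#'   `fp`, `fn`.
#' @examples
#' classification_metrics(50, 50, 0, 0)
#' @export
classification_metrics <- function(tp, tn, fp, fn, context = NA_character_) {
  counts <- c(tp, tn, fp, fn)
  if (any(counts < 0) || any(counts != round(counts))) {
    abort_erq("confusion counts must be non-negative integers", "erq_domain_error")
  }
  total <- tp + tn + fp + fn
  if (total == 0) {
    abort_erq("empty confusion matrix", "erq_domain_error")
  }
  ac <- 100 * (tp + tn) / total
  sn <- 100 * tp / (tp + fn)
  sp <- 100 * tn / (tn + fp)
  denom <- as.numeric(tp + fp) * (tp + fn) * (tn + fp) * (tn + fn)
  mcc <- if (denom == 0) 0 else {
    (as.numeric(tp) * tn - as.numeric(fp) * fn) / sqrt(denom)
  }
  tibble::tibble(
    context = context, ac = ac, sn = sn, sp = sp, mcc = mcc,
    tp = as.integer(tp), tn = as.integer(tn),
    fp = as.integer(fp), fn = as.integer(fn)
  )
}

#' Evaluate predicted against true activity labels
#' @param truth,pred Character/factor vectors over
#'   `{"active", "inactive"}`; `"active"` is the positive class.
#' @param context Optional context label.
#' @return One-row metrics tibble (see [classification_metrics()]).
#' @export
evaluate_predictions <- function(truth, pred, context = NA_character_) {
  truth <- as.character(truth)
  pred <- as.character(pred)
  stopifnot(length(truth) == length(pred))
  classification_metrics(
    tp = sum(truth == "active" & pred == "active"),
    tn = sum(truth == "inactive" & pred == "inactive"),
    fp = sum(truth == "inactive" & pred == "active"),
    fn = sum(truth == "active" & pred == "inactive"),
    context = context
  )
}

#' Model configuration for random-forest tuning
#'
#' Defaults follow the production tuning protocol: `ntree` over 100 to
#' 1,000 in steps of 100, `mtry` over 5 to 30 in steps of 5, five-fold
#' stratified cross-validation, MCC as the tuning objective.
#'
#' @param ntree_grid,mtry_grid Integer grids.
#' @param cv_folds Number of CV folds (>= 2).
#' @param tuning_metric `"mcc"` or `"ac"`.
#' @param seed Integer seed controlling fold assignment and forest
#'   randomness.
#' @return A list of class `erq_model_config`.
#' @export
model_config <- function(ntree_grid = seq(100L, 1000L, by = 100L),
                         mtry_grid = seq(5L, 30L, by = 5L),
                         cv_folds = 5L,
                         tuning_metric = c("mcc", "ac"),
                         seed = 1L) {
  tuning_metric <- match.arg(tuning_metric)
  if (length(ntree_grid) == 0 || length(mtry_grid) == 0) {
    abort_erq("tuning grids must be non-empty", "erq_config_error")
  }
  if (cv_folds < 2) {
    abort_erq("cv_folds must be at least 2", "erq_config_error")
  }
  structure(
    list(
      ntree_grid = as.integer(ntree_grid),
      mtry_grid = as.integer(mtry_grid),
      cv_folds = as.integer(cv_folds),
      tuning_metric = tuning_metric,
      seed = as.integer(seed)
    ),
    class = "erq_model_config"
  )
}

# stratified fold assignment: within each class, shuffled indices are dealt
# round-robin into k folds
stratified_folds <- function(y, k, seed) {
  y <- as.character(y)
  n <- length(y)
  if (any(table(y) < 1)) abort_erq("empty class", "erq_domain_error")
  folds <- integer(n)
  rng <- local({
    set.seed(seed)
    lapply(split(seq_len(n), y), sample)
  })
  for (idx in rng) {
    folds[idx] <- rep_len(seq_len(k), length(idx))
  }
  if (length(unique(folds)) < k) {
    abort_erq(
      sprintf("cannot form %d non-empty folds from %d samples", k, n),
      "erq_domain_error"
    )
  }
  folds
}

#' Stratified k-fold cross-validation of a random forest
#'
#' Fold assignment is stratified by class and fully determined by the
#' seed. The pooled confusion matrix is the sum of fold confusion
#' matrices; pooled metrics are computed from the pooled confusion.
#'
#' @param x Numeric feature matrix or feature tibble (without ids).
#' @param y Label vector (`active`/`inactive`).
#' @param k Number of folds.
#' @param ntree,mtry Forest parameters.
#' @param seed Seed for fold assignment and fitting.
#' @return List: `pooled` (one-row metrics tibble, context `"cv"`),
#'   `per_fold` (metrics tibble with one row per fold), `folds` (the
#'   assignment vector).
#' @export
cross_validate_rf <- function(x, y, k = 5, ntree = 500, mtry = NULL,
                              seed = 1L) {
  x <- as.matrix(x)
  y <- factor(as.character(y), levels = c("active", "inactive"))
  if (nlevels(droplevels(y)) < 2) {
    abort_erq("cross-validation needs both classes present", "erq_domain_error")
  }
  if (k < 2) abort_erq("k must be >= 2", "erq_config_error")
  mtry <- mtry %||% max(1L, floor(sqrt(ncol(x))))
  folds <- stratified_folds(y, k, seed)
  per_fold <- purrr::map_dfr(seq_len(k), function(f) {
    tr <- folds != f
    te <- !tr
    set.seed(seed + f)
    fit <- randomForest::randomForest(
      x = x[tr, , drop = FALSE], y = droplevels(y[tr]),
      ntree = ntree, mtry = min(mtry, ncol(x))
    )
    pred <- predict(fit, x[te, , drop = FALSE])
    dplyr::mutate(
      evaluate_predictions(y[te], pred, context = "cv"),
      fold = f, .before = 1
    )
  })
  pooled <- classification_metrics(
    tp = sum(per_fold$tp), tn = sum(per_fold$tn),
    fp = sum(per_fold$fp), fn = sum(per_fold$fn), context = "cv"
  )
  list(pooled = pooled, per_fold = per_fold, folds = folds)
}

#' Tune and train a random-forest activity classifier
#'
#' Scores every `(ntree, mtry)` grid pair by the mean cross-validated
#' tuning metric over stratified folds (fixed fold assignment across
#' pairs), refits the best pair on the full training set, and reports
#' resubstitution, out-of-bag and pooled-CV evaluations. Ties prefer the
#' smaller `ntree`, then the smaller `mtry`. Grid points with `mtry`
#' exceeding the feature count are skipped with a warning.
#'
#' @param x Feature matrix or tibble (feature columns only).
#' @param y Labels (`active`/`inactive`).
#' @param config An [model_config()].
#' @param target_name Optional name recorded on the model (e.g. `"ERalpha"`).
#' @return An object of class `erq_rf_model`: list with the fitted forest,
#'   `chosen_ntree`, `chosen_mtry`, `feature_names`, `config`,
#'   `training_report` (resubstitution), `oob_report`, `cv_report`,
#'   `tuning_table`.
#' @export
tune_and_train <- function(x, y, config = model_config(), target_name = NA) {
  x <- as.matrix(x)
  y <- factor(as.character(y), levels = c("active", "inactive"))
  if (nlevels(droplevels(y)) < 2) {
    abort_erq("training needs both classes present", "erq_domain_error")
  }
  if (nrow(x) < config$cv_folds) {
    abort_erq("fewer samples than CV folds", "erq_domain_error")
  }

  grid <- expand.grid(
    ntree = config$ntree_grid, mtry = config$mtry_grid,
    KEEP.OUT.ATTRS = FALSE
  )
  usable <- grid$mtry <= ncol(x)
  if (!all(usable)) {
    rlang::warn(sprintf(
      "%d grid point(s) skipped: mtry exceeds the %d available features",
      sum(!usable), ncol(x)
    ))
    grid <- grid[usable, , drop = FALSE]
  }
  if (nrow(grid) == 0) {
    abort_erq("no usable grid points (all mtry too large)", "erq_config_error")
  }

  metric_col <- config$tuning_metric
  scores <- purrr::map_dbl(seq_len(nrow(grid)), function(i) {
    cv <- cross_validate_rf(x, y,
      k = config$cv_folds,
      ntree = grid$ntree[i], mtry = grid$mtry[i], seed = config$seed
    )
    cv$pooled[[metric_col]]
  })
  tuning <- dplyr::arrange(
    dplyr::mutate(tibble::as_tibble(grid), score = scores),
    dplyr::desc(.data$score), .data$ntree, .data$mtry
  )
  best <- tuning[1, ]

  set.seed(config$seed)
  forest <- randomForest::randomForest(
    x = x, y = y, ntree = best$ntree, mtry = best$mtry, importance = TRUE
  )
  resub <- evaluate_predictions(y, predict(forest, x), context = "training")
  oob <- evaluate_predictions(y, forest$predicted, context = "training_oob")
  cv_final <- cross_validate_rf(x, y,
    k = config$cv_folds,
    ntree = best$ntree, mtry = best$mtry, seed = config$seed
  )

  structure(
    list(
      target_name = target_name,
      forest = forest,
      chosen_ntree = as.integer(best$ntree),
      chosen_mtry = as.integer(best$mtry),
      feature_names = colnames(x),
      config = config,
      training_report = resub,
      oob_report = oob,
      cv_report = cv_final$pooled,
      cv_per_fold = cv_final$per_fold,
      tuning_table = tuning
    ),
    class = "erq_rf_model"
  )
}

#' @export
print.erq_rf_model <- function(x, ...) {
  cat(sprintf(
    "<random-forest activity classifier%s: ntree=%d mtry=%d, %d features>\n",
    if (is.na(x$target_name)) "" else paste0(" [", x$target_name, "]"),
    x$chosen_ntree, x$chosen_mtry, length(x$feature_names)
  ))
  cat(sprintf(
    "  training Ac %.2f%% MCC %.3f | CV Ac %.2f%% MCC %.3f\n",
    x$training_report$ac, x$training_report$mcc,
    x$cv_report$ac, x$cv_report$mcc
  ))
  invisible(x)
}

#' Rank features by mean decrease of the Gini index
#'
#' Random-forest impurity importance (MDGI), sorted non-increasing; rank 1
#' is the most important feature.
#'
#' @param model An `erq_rf_model`.
#' @param top_k Optionally truncate to the `top_k` best (the feature
#'   interpretation analyses use the top 20).
#' @return Tibble: `feature_name`, `mdgi`, `rank`.
#' @export
rank_features <- function(model, top_k = NULL) {
  if (!inherits(model, "erq_rf_model")) {
    abort_erq("model is not a fitted erq_rf_model", "erq_state_error")
  }
  imp <- randomForest::importance(model$forest, type = 2)
  out <- tibble::tibble(
    feature_name = rownames(imp),
    mdgi = as.numeric(imp[, 1])
  )
  out <- dplyr::arrange(out, dplyr::desc(.data$mdgi), .data$feature_name)
  out$rank <- seq_len(nrow(out))
  if (!is.null(top_k)) out <- out[seq_len(min(top_k, nrow(out))), ]
  out
}

#' Predict activity labels and probabilities
#' @param object An `erq_rf_model`.
#' @param newdata Feature matrix/tibble with the model's feature columns.
#' @param ... Unused.
#' @return Tibble: `predicted_label`, `active_probability`.
#' @export
predict.erq_rf_model <- function(object, newdata, ...) {
  nd <- as.matrix(tibble::as_tibble(newdata)[, object$feature_names, drop = FALSE])
  prob <- predict(object$forest, nd, type = "prob")[, "active"]
  lab <- ifelse(prob >= 0.5, "active", "inactive")
  tibble::tibble(predicted_label = lab, active_probability = as.numeric(prob))
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a fitted activity classifier
#'
#' `tidy()` returns the per-feature MDGI importance table; `glance()`
#' returns a one-row model summary with the chosen tuning parameters and
#' the training/CV/OOB headline metrics.
#'
#' @param x An `erq_rf_model`.
#' @param ... Unused.
#' @return A tibble.
#' @exportS3Method generics::tidy
tidy.erq_rf_model <- function(x, ...) rank_features(x)

#' @rdname tidy.erq_rf_model
#' @exportS3Method generics::glance
glance.erq_rf_model <- function(x, ...) {
  tibble::tibble(
    target_name = x$target_name,
    ntree = x$chosen_ntree,
    mtry = x$chosen_mtry,
    n_features = length(x$feature_names),
    ac_training = x$training_report$ac,
    mcc_training = x$training_report$mcc,
    ac_oob = x$oob_report$ac,
    mcc_oob = x$oob_report$mcc,
    ac_cv = x$cv_report$ac,
    mcc_cv = x$cv_report$mcc
  )
}
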