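#' Train a single-target classification-SAR model from an activity table
#'
#' Runs the full per-target workflow: standardize -> curate (pIC50,
#' labels, deduplication) -> dictionary fingerprints -> near-constant
#' filter -> Kennard-Stone 80/20 split -> grid-tuned random forest with
#' stratified cross-validation -> external-test evaluation -> PCA
#' bounding-box applicability domain. The feature filter is fitted on the
#' full curated set before splitting, mirroring the production protocol;
#' the filter record flags this as a known leakage source.
#'
#' @param activity Activity tibble (five standard columns) or a file path
#'   readable by [read_activity_table()].
#' @param dictionary An `erq_fp_dictionary`, or a family name accepted by
#'   [builtin_dictionary()].
#' @param mode Fingerprint mode, `"presence"` or `"count"`.
#' @param config A [model_config()].
#' @param split_fraction Internal-set fraction for the Kennard-Stone split.
#' @param sd_threshold Near-constant filter threshold.
#' @param target_name Name recorded on the model (e.g. `"ERalpha"`).
#' @param ad_components Components for the applicability domain box.
#' @param active_threshold,inactive_threshold pIC50 labelling thresholds.
#' @return An object of class `erq_target_model`: the fitted `model`
#'   (`erq_rf_model`), `domain`, `dictionary`, `mode`, `filter`,
#'   `split`, `reports` (training/CV/test metrics tibble), `curated`,
#'   `features` (the filtered feature matrix), `top_features`.
#' @export
train_target <- function(activity,
                         dictionary = "demo24",
                         mode = "presence",
                         config = model_config(),
                         split_fraction = 0.8,
                         sd_threshold = 0.1,
                         target_name = NA,
                         ad_components = 2,
                         active_threshold = 6,
                         inactive_threshold = 5) {
  if (is.character(activity) && length(activity) == 1) {
    activity <- read_activity_table(activity)
  }
  if (is.character(dictionary)) {
    dictionary <- builtin_dictionary(dictionary)
  }

  curated <- curate_activity(activity,
    active_threshold = active_threshold,
    inactive_threshold = inactive_threshold
  )
  fpmat <- compute_fingerprints(curated, dictionary, mode = mode)
  filtered <- variance_filter(fpmat, sd_threshold = sd_threshold)
  frec <- filter_record(filtered)

  split <- kennard_stone_split(filtered, fraction = split_fraction)
  internal_ids <- attr(split, "internal_ids")
  external_ids <- attr(split, "external_ids")
  int_rows <- match(internal_ids, filtered$compound_id)
  ext_rows <- match(external_ids, filtered$compound_id)
  feat_cols <- setdiff(names(filtered), "compound_id")

  y <- curated$label[match(filtered$compound_id, curated$compound_id)]
  model <- tune_and_train(
    filtered[int_rows, feat_cols], y[int_rows],
    config = config, target_name = target_name
  )

  test_report <- if (length(ext_rows) > 0) {
    pred <- predict(model, filtered[ext_rows, feat_cols])
    evaluate_predictions(y[ext_rows], pred$predicted_label, context = "test")
  } else {
    NULL
  }

  domain <- fit_domain(filtered[int_rows, ], n_components = ad_components)

  reports <- dplyr::bind_rows(
    model$training_report, model$oob_report, model$cv_report, test_report
  )

  structure(
    list(
      target_name = target_name,
      model = model,
      domain = domain,
      dictionary = dictionary,
      mode = mode,
      filter = frec,
      split = split,
      reports = reports,
      curated = curated,
      features = filtered,
      labels = y,
      top_features = rank_features(model, top_k = 20),
      standardizer = "openbabel-canonical/1",
      thresholds = c(
        active = active_threshold, inactive = inactive_threshold
      )
    ),
    class = "erq_target_model"
  )
}

#' @export
print.erq_target_model <- function(x, ...) {
  cat(sprintf(
    "<CSAR target model%s: %s/%s, %d compounds (%d internal / %d external)>\n",
    if (is.na(x$target_name)) "" else paste0(" [", x$target_name, "]"),
    dictionary_name(x$dictionary), x$mode,
    nrow(x$features),
    length(attr(x$split, "internal_ids")),
    length(attr(x$split, "external_ids"))
  ))
  print(x$reports[, c("context", "ac", "sn", "sp", "mcc")])
  invisible(x)
}

#' Train the dual-target (ERalpha/ERbeta) pipeline
#'
#' Trains one [train_target()] model per subtype from two activity tables
#' and bundles them for selectivity prediction.
#'
#' @param alpha_activity,beta_activity Activity tibbles or file paths.
#' @param ... Passed to [train_target()] (shared settings).
#' @return An object of class `erq_pipeline` with elements `alpha`, `beta`.
#' @export
train_pipeline <- function(alpha_activity, beta_activity, ...) {
  structure(
    list(
      alpha = train_target(alpha_activity, target_name = "ERalpha", ...),
      beta = train_target(beta_activity, target_name = "ERbeta", ...)
    ),
    class = "erq_pipeline"
  )
}

#' @export
print.erq_pipeline <- function(x, ...) {
  cat("<dual-target CSAR pipeline>\n-- ERalpha --\n")
  print(x$alpha)
  cat("-- ERbeta --\n")
  print(x$beta)
  invisible(x)
}

featurize_for_model <- function(target, smiles, ids) {
  std <- standardize_molecules(smiles, id = ids, on_error = "keep")
  ok <- is.na(std$error)
  feat_cols <- setdiff(names(target$features), "compound_id")
  fp <- if (any(ok)) {
    full <- compute_fingerprints(
      tibble::tibble(
        compound_id = std$id[ok],
        smiles_canonical = std$smiles_canonical[ok]
      ),
      target$dictionary,
      mode = target$mode
    )
    full[, c("compound_id", feat_cols)]
  } else {
    NULL
  }
  list(std = std, ok = ok, fp = fp, feat_cols = feat_cols)
}

predict_one_target <- function(target, fp) {
  pred <- predict(target$model, fp[setdiff(names(fp), "compound_id")])
  ad <- in_domain(target$domain, fp)
  tibble::tibble(
    predicted_label = pred$predicted_label,
    active_probability = pred$active_probability,
    in_ad = ad$in_domain
  )
}

#' Selectivity call from two subtype labels
#'
#' Pure function of the two predicted labels: active against alpha only ->
#' `alpha_selective`; beta only -> `beta_selective`; both ->
#' `dual_active`; neither -> `dual_inactive`.
#'
#' @param alpha_label,beta_label Character vectors over
#'   `{"active", "inactive"}`.
#' @return Character vector of selectivity calls.
#' @export
selectivity_call <- function(alpha_label, beta_label) {
  dplyr::case_when(
    alpha_label == "active" & beta_label == "active" ~ "dual_active",
    alpha_label == "active" ~ "alpha_selective",
    beta_label == "active" ~ "beta_selective",
    TRUE ~ "dual_inactive"
  )
}

#' Batch-predict subtype activity and selectivity
#'
#' Featurization replays the training-time dictionary, mode and feature
#' filter of each target model, so predicting the training compounds
#' reproduces the stored resubstitution confusion exactly. Out-of-domain
#' compounds still receive predictions but are flagged. Rows whose SMILES
#' fail to parse are reported with an `error` and NA predictions; the
#' remaining rows proceed.
#'
#' @param pipeline An `erq_pipeline`.
#' @param smiles Character vector of SMILES, a tibble with a `smiles`
#'   column, or a `.smi` file path.
#' @param ids Optional compound ids.
#' @return A prediction tibble: `compound_id`, `smiles`,
#'   `smiles_canonical`, `pred_ERa`, `prob_ERa`, `in_AD_ERa`, `pred_ERb`,
#'   `prob_ERb`, `in_AD_ERb`, `selectivity_call`, `error`.
#' @export
predict_selectivity <- function(pipeline, smiles, ids = NULL) {
  stopifnot(inherits(pipeline, "erq_pipeline"))
  if (is.character(smiles) && length(smiles) == 1 && file.exists(smiles)) {
    tab <- read_smiles_file(smiles)
    smiles <- tab$smiles
    ids <- ids %||% tab$compound_id
  } else if (is.data.frame(smiles)) {
    ids <- ids %||% smiles$compound_id
    smiles <- smiles$smiles
  }
  ids <- ids %||% paste0("mol", seq_along(smiles))

  fa <- featurize_for_model(pipeline$alpha, smiles, ids)
  fb <- featurize_for_model(pipeline$beta, smiles, ids)

  n <- length(smiles)
  na_col <- rep(NA_character_, n)
  out <- tibble::tibble(
    compound_id = ids, smiles = smiles,
    smiles_canonical = fa$std$smiles_canonical,
    pred_ERa = na_col, prob_ERa = rep(NA_real_, n), in_AD_ERa = rep(NA, n),
    pred_ERb = na_col, prob_ERb = rep(NA_real_, n), in_AD_ERb = rep(NA, n),
    selectivity_call = na_col,
    error = fa$std$error
  )
  ok <- fa$ok
  if (any(ok)) {
    pa <- predict_one_target(pipeline$alpha, fa$fp)
    pb <- predict_one_target(pipeline$beta, fb$fp)
    out$pred_ERa[ok] <- pa$predicted_label
    out$prob_ERa[ok] <- pa$active_probability
    out$in_AD_ERa[ok] <- pa$in_ad
    out$pred_ERb[ok] <- pb$predicted_label
    out$prob_ERb[ok] <- pb$active_probability
    out$in_AD_ERb[ok] <- pb$in_ad
    out$selectivity_call[ok] <- selectivity_call(
      pa$predicted_label, pb$predicted_label
    )
  }
  out
}

#' Save / load a trained target model as a directory artifact
#'
#' The artifact bundles everything needed to reproduce train-time
#' featurization at prediction time: the serialized forest, the full
#' fingerprint dictionary, the filter record and ordered feature list, the
#' tuning configuration and seed, the standardizer rule-set tag, the split
#' manifest and every evaluation report (JSON/TSV/CSV plus an RDS for the
#' forest object).
#'
#' @param target An `erq_target_model`.
#' @param dir Artifact directory (created).
#' @return `dir`, invisibly.
#' @export
save_model_artifact <- function(target, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  saveRDS(target$model$forest, file.path(dir, "forest.rds"))
  write_fp_dictionary(target$dictionary, file.path(dir, "dictionary.tsv"))
  write_split_manifest(target$split, file.path(dir, "split.csv"))
  readr::write_csv(target$reports, file.path(dir, "reports.csv"),
    progress = FALSE
  )
  readr::write_csv(target$features, file.path(dir, "features.csv"),
    progress = FALSE
  )
  readr::write_csv(target$curated, file.path(dir, "curated.csv"),
    progress = FALSE
  )
  meta <- list(
    target_name = target$target_name,
    dictionary_name = dictionary_name(target$dictionary),
    bit_prefix = attr(target$dictionary, "bit_prefix"),
    mode = target$mode,
    standardizer = target$standardizer,
    thresholds = as.list(target$thresholds),
    filter = target$filter,
    chosen_ntree = target$model$chosen_ntree,
    chosen_mtry = target$model$chosen_mtry,
    feature_names = target$model$feature_names,
    config = unclass(target$model$config),
    domain = list(
      n_components = target$domain$n_components,
      feature_names = target$domain$feature_names,
      center = as.list(target$domain$center),
      loadings = apply(target$domain$loadings, 2, as.numeric,
        simplify = FALSE
      ),
      box = target$domain$box
    )
  )
  jsonlite::write_json(meta, file.path(dir, "model.json"),
    auto_unbox = TRUE, digits = NA
  )
  invisible(dir)
}

#' @rdname save_model_artifact
#' @param dir Artifact directory written by [save_model_artifact()].
#' @return `load_model_artifact()`: an `erq_target_model` equivalent to the
#'   saved one for prediction and domain querying.
#' @export
load_model_artifact <- function(dir) {
  meta_path <- file.path(dir, "model.json")
  if (!file.exists(meta_path)) {
    abort_erq(sprintf("no model artifact at %s", dir), "erq_io_error")
  }
  meta <- jsonlite::read_json(meta_path, simplifyVector = TRUE)
  forest <- readRDS(file.path(dir, "forest.rds"))
  dict <- load_fp_dictionary(file.path(dir, "dictionary.tsv"),
    name = meta$dictionary_name
  )
  attr(dict, "bit_prefix") <- meta$bit_prefix
  features <- readr::read_csv(file.path(dir, "features.csv"),
    show_col_types = FALSE, progress = FALSE
  )
  curated <- readr::read_csv(file.path(dir, "curated.csv"),
    show_col_types = FALSE, progress = FALSE
  )
  split <- readr::read_csv(file.path(dir, "split.csv"),
    show_col_types = FALSE, progress = FALSE
  )
  attr(split, "internal_ids") <- split$compound_id[split$partition == "internal"]
  attr(split, "external_ids") <- split$compound_id[split$partition == "external"]
  reports <- readr::read_csv(file.path(dir, "reports.csv"),
    show_col_types = FALSE, progress = FALSE
  )
  cfg <- meta$config
  config <- model_config(
    ntree_grid = cfg$ntree_grid, mtry_grid = cfg$mtry_grid,
    cv_folds = cfg$cv_folds, tuning_metric = cfg$tuning_metric,
    seed = cfg$seed
  )
  model <- structure(
    list(
      target_name = meta$target_name,
      forest = forest,
      chosen_ntree = meta$chosen_ntree,
      chosen_mtry = meta$chosen_mtry,
      feature_names = meta$feature_names,
      config = config,
      training_report = reports[reports$context == "training", ],
      oob_report = reports[reports$context == "training_oob", ],
      cv_report = reports[reports$context == "cv", ]
    ),
    class = "erq_rf_model"
  )
  domain <- structure(
    list(
      feature_names = meta$domain$feature_names,
      center = unlist(meta$domain$center),
      loadings = matrix(
        unlist(meta$domain$loadings),
        ncol = meta$domain$n_components,
        dimnames = list(
          meta$domain$feature_names,
          paste0("PC", seq_len(meta$domain$n_components))
        )
      ),
      n_components = meta$domain$n_components,
      box = tibble::as_tibble(meta$domain$box)
    ),
    class = "erq_domain"
  )
  structure(
    list(
      target_name = meta$target_name,
      model = model,
      domain = domain,
      dictionary = dict,
      mode = meta$mode,
      filter = meta$filter,
      split = split,
      reports = reports,
      curated = curated,
      features = features,
      labels = curated$label[match(features$compound_id, curated$compound_id)],
      top_features = NULL,
      standardizer = meta$standardizer,
      thresholds = unlist(meta$thresholds)
    ),
    class = "erq_target_model"
  )
}

#' Save / load a dual-target pipeline
#' @param pipeline An `erq_pipeline`.
#' @param dir Bundle directory; per-target artifacts go to `alpha/` and
#'   `beta/` subdirectories.
#' @return `dir` (save) or an `erq_pipeline` (load).
#' @export
save_pipeline_artifact <- function(pipeline, dir) {
  save_model_artifact(pipeline$alpha, file.path(dir, "alpha"))
  save_model_artifact(pipeline$beta, file.path(dir, "beta"))
  invisible(dir)
}

#' @rdname save_pipeline_artifact
#' @export
load_pipeline_artifact <- function(dir) {
  structure(
    list(
      alpha = load_model_artifact(file.path(dir, "alpha")),
      beta = load_model_artifact(file.path(dir, "beta"))
    ),
    class = "erq_pipeline"
  )
}

#' Write a prediction CSV
#' @param predictions Tibble from [predict_selectivity()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_predictions <- function(predictions, path) {
  readr::write_csv(predictions, path, progress = FALSE)
  invisible(path)
}

#' Glance at a dual-target pipeline
#' @param x An `erq_pipeline`.
#' @param ... Unused.
#' @return Tibble with one row per target and evaluation context.
#' @exportS3Method generics::glance
glance.erq_pipeline <- function(x, ...) {
  dplyr::bind_rows(
    dplyr::mutate(x$alpha$reports, target = "ERalpha", .before = 1),
    dplyr::mutate(x$beta$reports, target = "ERbeta", .before = 1)
  )
}
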