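#' Configuration of the Monte-Carlo gradient-boosted ensemble
#'
#' Defaults are the screen's calibrated values: 100 accepted models on
#' stratified 70:30 resampled splits, each an XGBoost classifier with
#' `learning_rate = 0.5`, `max_depth = 2`, `n_estimators = 100` and
#' `colsample_bytree = 0.5`, all other learner settings at the library
#' defaults.
#'
#' @param n_models Number of accepted models required. Default 100.
#' @param train_fraction Fraction of compounds in each training split.
#'   Default 0.7.
#' @param learning_rate,max_depth,n_estimators,colsample_bytree XGBoost
#'   hyperparameters.
#' @param scale_pos_weight Positive-class weight; 1 (off) by default.
#' @param max_attempts Cap on split attempts before the acceptance loop gives
#'   up; default `10 * n_models`.
#' @param base_seed First seed of the deterministic split-seed sequence
#'   `base_seed, base_seed + 1, ...`.
#' @return A list of class `ensemble_config`.
#' @export
ensemble_config <- function(n_models = 100L, train_fraction = 0.7,
                            learning_rate = 0.5, max_depth = 2L,
                            n_estimators = 100L, colsample_bytree = 0.5,
                            scale_pos_weight = 1,
                            max_attempts = 10L * n_models,
                            base_seed = 1L) {
  stopifnot(train_fraction > 0, train_fraction < 1, n_models >= 1)
  structure(list(n_models = as.integer(n_models),
                 train_fraction = train_fraction,
                 learning_rate = learning_rate,
                 max_depth = as.integer(max_depth),
                 n_estimators = as.integer(n_estimators),
                 colsample_bytree = colsample_bytree,
                 scale_pos_weight = scale_pos_weight,
                 max_attempts = as.integer(max_attempts),
                 base_seed = as.integer(base_seed)),
            class = "ensemble_config")
}

#' Stratified train/test split
#'
#' Partitions rows into train and test sets preserving the class proportions
#' to rounding: each class contributes `round(n_class * train_fraction)` rows
#' to the training set. With 3561 compounds (103 positive) at fraction 0.7
#' this gives the 2493 / 1068 split.
#'
#' @param labels Binary labels.
#' @param train_fraction Training fraction in (0, 1).
#' @param seed Integer seed; the same seed always yields the same partition.
#' @return List with integer index vectors `train` and `test` (disjoint,
#'   exhaustive).
#' @export
stratified_split <- function(labels, train_fraction, seed) {
  labels <- as.integer(labels)
  classes <- unique(labels)
  if (length(classes) < 2) stop_glio("both classes must be present",
                                     "input_error")
  if (any(table(labels) < 2)) stop_glio("a class has fewer than 2 members",
                                        "input_error")
  # largest-remainder apportionment: class quotas n_class * fraction are
  # floored, then the remainder up to round(n * fraction) goes to the
  # classes with the largest fractional parts
  sizes <- table(labels)[as.character(classes)]
  target <- round(length(labels) * train_fraction)
  quota <- as.numeric(sizes) * train_fraction
  n_train_cl <- floor(quota)
  rem <- order(quota - n_train_cl, decreasing = TRUE)
  short <- target - sum(n_train_cl)
  if (short > 0) {
    bump <- rem[seq_len(min(short, length(rem)))]
    n_train_cl[bump] <- n_train_cl[bump] + 1L
  }
  n_train_cl <- pmin(pmax(n_train_cl, 1L), as.numeric(sizes) - 1L)
  train <- with_seed(seed, {
    unlist(lapply(seq_along(classes), function(i) {
      idx <- which(labels == classes[i])
      sample(idx, n_train_cl[i])
    }))
  })
  train <- sort(train)
  list(train = train, test = setdiff(seq_along(labels), train))
}

#' Train and evaluate one Monte-Carlo member
#'
#' Splits the data with [stratified_split()], fits the z-score scaler on the
#' training rows only, trains one XGBoost classifier and computes its test
#' metrics at the 0.5 decision threshold.
#'
#' @param features Feature matrix (selected, unscaled).
#' @param labels Binary labels (0/1) aligned to rows.
#' @param cfg An [ensemble_config()].
#' @param seed Seed for this member's split and learner.
#' @return List of class `ensemble_member`: `model` (raw serialised XGBoost
#'   booster), `scaler`, `seed`, `metrics` (a `metrics_record`), `split`
#'   sizes. Returns `NULL` (a rejected attempt) when the split leaves a
#'   single-class training set.
#' @export
train_one <- function(features, labels, cfg = ensemble_config(), seed = 1L) {
  labels <- as.integer(labels)
  sp <- stratified_split(labels, cfg$train_fraction, seed)
  y_train <- labels[sp$train]
  if (length(unique(y_train)) < 2) return(NULL)
  scaled <- zscore_features(features, fit_rows = sp$train)
  scaler <- attr(scaled, "scaler")
  x_train <- unclass(scaled)[sp$train, , drop = FALSE]
  x_test <- unclass(scaled)[sp$test, , drop = FALSE]
  params <- xgboost::xgb.params(
    objective = "binary:logistic", eta = cfg$learning_rate,
    max_depth = cfg$max_depth, colsample_bytree = cfg$colsample_bytree,
    scale_pos_weight = cfg$scale_pos_weight, nthread = 1, seed = seed)
  bst <- xgboost::xgb.train(
    params = params, data = xgboost::xgb.DMatrix(x_train, label = y_train),
    nrounds = cfg$n_estimators, verbose = 0)
  probs <- predict(bst, xgboost::xgb.DMatrix(x_test))
  structure(list(model = xgboost::xgb.save.raw(bst), scaler = scaler,
                 seed = seed, metrics = compute_metrics(labels[sp$test], probs),
                 n_train = length(sp$train), n_test = length(sp$test)),
            class = "ensemble_member")
}

#' Train a Monte-Carlo ensemble gated on the naive baseline
#'
#' Repeats [stratified_split()] + [train_one()] with the deterministic seed
#' sequence `base_seed, base_seed + 1, ...`, accepting models whose test
#' accuracy strictly exceeds the majority-class baseline, until `n_models`
#' are accepted or `max_attempts` splits have been tried. Resampling the
#' splits ensures every positive compound is used for training by some
#' member.
#'
#' @inheritParams train_one
#' @return A list of class `trained_ensemble`: `members` (accepted
#'   `ensemble_member`s), `baseline`, `feature_names`, `config`, `attempts`,
#'   `acceptance_rate`.
#' @export
train_ensemble <- function(features, labels, cfg = ensemble_config()) {
  labels <- as.integer(labels)
  baseline <- naive_baseline(labels)
  members <- vector("list", cfg$n_models)
  n_accepted <- 0L
  attempts <- 0L
  seed <- cfg$base_seed
  while (n_accepted < cfg$n_models && attempts < cfg$max_attempts) {
    attempts <- attempts + 1L
    member <- train_one(features, labels, cfg, seed = seed)
    seed <- seed + 1L
    if (!is.null(member) && member$metrics$accuracy > baseline) {
      n_accepted <- n_accepted + 1L
      members[[n_accepted]] <- member
    }
  }
  if (n_accepted < cfg$n_models) {
    stop_glio(sprintf(
      "only %d of %d models exceeded the baseline (%.4f) in %d attempts (acceptance rate %.3f)",
      n_accepted, cfg$n_models, baseline, attempts, n_accepted / attempts),
      "ensemble_acceptance_error")
  }
  structure(list(members = members, baseline = baseline,
                 feature_names = colnames(features), config = cfg,
                 attempts = attempts,
                 acceptance_rate = n_accepted / attempts),
            class = "trained_ensemble")
}

#' Summarise per-member test metrics across the ensemble
#'
#' @param ensemble A `trained_ensemble`.
#' @return Data.frame with one row per metric (precision, recall, f1,
#'   accuracy, roc_auc, pr_auc): mean, sd and quartiles across members.
#' @export
summarise_metrics <- function(ensemble) {
  metric_names <- c("precision", "recall", "f1", "accuracy",
                    "roc_auc", "pr_auc")
  vals <- sapply(metric_names, function(mn)
    vapply(ensemble$members, function(m) m$metrics[[mn]], 0))
  vals <- matrix(vals, ncol = length(metric_names),
                 dimnames = list(NULL, metric_names))
  data.frame(
    metric = metric_names,
    mean = colMeans(vals, na.rm = TRUE),
    sd = apply(vals, 2, stats::sd, na.rm = TRUE),
    q25 = apply(vals, 2, stats::quantile, 0.25, na.rm = TRUE),
    median = apply(vals, 2, stats::median, na.rm = TRUE),
    q75 = apply(vals, 2, stats::quantile, 0.75, na.rm = TRUE),
    row.names = NULL)
}

#' @export
print.trained_ensemble <- function(x, ...) {
  cat(sprintf(
    "Monte-Carlo ensemble: %d members above baseline %.4f (%d attempts)\n",
    length(x$members), x$baseline, x$attempts))
  print(summarise_metrics(x), digits = 3)
  invisible(x)
}

#' Persist / restore a trained ensemble
#'
#' The ensemble is written as a directory: a JSON manifest (config, baseline,
#' seeds, per-member metrics, scalers, feature names) plus one serialised
#' XGBoost model file per member.
#'
#' @param ensemble A `trained_ensemble`.
#' @param dir Directory to create.
#' @return `dir` (`save_ensemble`) or the restored `trained_ensemble`
#'   (`load_ensemble`).
#' @export
save_ensemble <- function(ensemble, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(
    baseline = ensemble$baseline, feature_names = ensemble$feature_names,
    config = unclass(ensemble$config), attempts = ensemble$attempts,
    acceptance_rate = ensemble$acceptance_rate,
    members = lapply(ensemble$members, function(m) list(
      seed = m$seed, metrics = unclass(m$metrics)[
        c("tp", "fp", "tn", "fn", "precision", "recall", "f1", "accuracy",
          "roc_auc", "pr_auc", "threshold")],
      scaler = lapply(m$scaler, as.list),
      n_train = m$n_train, n_test = m$n_test)))
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  for (i in seq_along(ensemble$members)) {
    writeBin(ensemble$members[[i]]$model,
             file.path(dir, sprintf("member_%03d.ubj", i)))
  }
  invisible(dir)
}

#' @rdname save_ensemble
#' @export
load_ensemble <- function(dir) {
  manifest <- jsonlite::read_json(file.path(dir, "manifest.json"),
                                  simplifyVector = FALSE)
  members <- lapply(seq_along(manifest$members), function(i) {
    path <- file.path(dir, sprintf("member_%03d.ubj", i))
    raw <- readBin(path, "raw", n = file.size(path))
    mi <- manifest$members[[i]]
    null_to_na <- function(v) vapply(v, function(x) {
      if (is.null(x)) NA_real_ else as.numeric(x)
    }, 0)
    structure(list(model = raw,
                   scaler = list(mean = null_to_na(mi$scaler$mean),
                                 sd = null_to_na(mi$scaler$sd)),
                   seed = mi$seed,
                   metrics = structure(
                     lapply(mi$metrics, function(x) x %||% NA_real_),
                     class = "metrics_record"),
                   n_train = mi$n_train, n_test = mi$n_test),
              class = "ensemble_member")
  })
  cfg <- do.call(ensemble_config, manifest$config)
  structure(list(members = members, baseline = manifest$baseline,
                 feature_names = unlist(manifest$feature_names),
                 config = cfg, attempts = manifest$attempts,
                 acceptance_rate = manifest$acceptance_rate),
            class = "trained_ensemble")
}
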