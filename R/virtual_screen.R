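#' Prepare an external compound library for ensemble scoring
#'
#' Canonicalises library SMILES, removes duplicates within and across
#' libraries and compounds whose canonical structure already appears in the
#' training set, then featurises the survivors on the ensemble's feature
#' list. Every removal is recorded in an exclusion log with its reason;
#' unparsable SMILES go to a quarantine list.
#'
#' @param libraries A data.frame (or list of data.frames / CSV paths) with
#'   columns `compound_id` and `smiles`.
#' @param training_smiles Canonical SMILES of the training compounds
#'   (already canonicalised keys).
#' @param feature_names Feature list of the trained ensemble. Default: all
#'   computed descriptors.
#' @param features Optional precomputed raw feature matrix (rownames =
#'   compound ids); when supplied, descriptor computation is skipped —
#'   intended for synthetic libraries that carry generated feature vectors.
#' @return List: `features` (raw-scale matrix for the surviving compounds),
#'   `compounds` (data.frame `compound_id`, `smiles`, `canonical_smiles`),
#'   `exclusions` (data.frame with `compound_id`, `reason` in
#'   `"duplicate"` / `"in_training"`), `quarantine` (unparsable SMILES).
#' @export
prepare_screen_library <- function(libraries, training_smiles,
                                   feature_names = NULL, features = NULL) {
  if (is.data.frame(libraries)) libraries <- list(libraries)
  tabs <- lapply(libraries, function(x) {
    if (is.character(x)) x <- utils::read.csv(x, stringsAsFactors = FALSE)
    data.frame(compound_id = as.character(x$compound_id),
               smiles = as.character(x$smiles))
  })
  lib <- do.call(rbind, tabs)
  can <- canonicalise_smiles(lib$smiles, on_error = "na")
  quarantine <- data.frame(compound_id = lib$compound_id[is.na(can)],
                           smiles = lib$smiles[is.na(can)])
  lib <- lib[!is.na(can), , drop = FALSE]
  can <- can[!is.na(can)]
  dup <- duplicated(can)
  in_train <- !dup & can %in% training_smiles
  exclusions <- rbind(
    data.frame(compound_id = lib$compound_id[dup],
               reason = rep("duplicate", sum(dup))),
    data.frame(compound_id = lib$compound_id[in_train],
               reason = rep("in_training", sum(in_train))))
  keep <- !dup & !in_train
  compounds <- data.frame(compound_id = lib$compound_id[keep],
                          smiles = lib$smiles[keep],
                          canonical_smiles = can[keep])
  if (is.null(features)) {
    features <- compute_descriptors(
      stats::setNames(compounds$canonical_smiles, compounds$compound_id))
  } else {
    missing <- setdiff(compounds$compound_id, rownames(features))
    if (length(missing) > 0) {
      stop_glio("feature rows missing for surviving compounds",
                "feature_mismatch")
    }
    features <- features[compounds$compound_id, , drop = FALSE]
  }
  if (!is.null(feature_names)) {
    if (!all(feature_names %in% colnames(features))) {
      stop_glio("library features do not cover the ensemble feature list",
                "feature_mismatch")
    }
    features <- features[, feature_names, drop = FALSE]
  }
  list(features = features, compounds = compounds,
       exclusions = exclusions, quarantine = quarantine)
}

#' Score a compound library with a trained ensemble
#'
#' Each accepted member scores every compound after applying that member's
#' own training-split scaler; the ensemble score is the arithmetic mean of
#' the per-member positive-class probabilities. Rows with non-finite feature
#' values are reported as missing, not silently zeroed.
#'
#' @param ensemble A `trained_ensemble` (in memory or via [load_ensemble()]).
#' @param features Raw-scale feature matrix on the ensemble's feature list
#'   (rownames = compound ids).
#' @return A data.frame of class `screen_predictions` with `compound_id`,
#'   `mean_score` and `rank` (1 = highest score), ordered by rank, carrying
#'   the per-member probability matrix as attribute `prob_matrix` and any
#'   skipped rows as attribute `missing`.
#' @export
score_library <- function(ensemble, features) {
  if (!setequal(colnames(features), ensemble$feature_names)) {
    stop_glio("feature names do not match the ensemble manifest",
              "feature_mismatch")
  }
  features <- features[, ensemble$feature_names, drop = FALSE]
  if (nrow(features) == 0) {
    out <- data.frame(compound_id = character(), mean_score = numeric(),
                      rank = integer())
    class(out) <- c("screen_predictions", class(out))
    return(out)
  }
  ok <- apply(features, 1, function(r) all(is.finite(r)))
  missing <- rownames(features)[!ok]
  if (length(missing) > 0) {
    warning(length(missing), " compound(s) with non-finite features skipped")
  }
  feat <- features[ok, , drop = FALSE]
  probs <- vapply(ensemble$members, function(m) {
    bst <- xgboost::xgb.load.raw(m$model)
    predict(bst, xgboost::xgb.DMatrix(apply_scaler(feat, m$scaler)))
  }, numeric(nrow(feat)))
  probs <- matrix(probs, nrow = nrow(feat),
                  dimnames = list(rownames(feat), NULL))
  mean_score <- rowMeans(probs)
  out <- data.frame(compound_id = rownames(feat), mean_score = mean_score,
                    row.names = NULL)
  out$rank <- rank(-out$mean_score, ties.method = "first")
  out <- out[order(out$rank), ]
  rownames(out) <- NULL
  attr(out, "prob_matrix") <- probs
  attr(out, "missing") <- missing
  class(out) <- c("screen_predictions", class(out))
  out
}

#' Select predicted hits above an ensemble-score cutoff
#'
#' @param predictions A `screen_predictions` table from [score_library()].
#' @param threshold Minimum mean ensemble score (inclusive). Default 0.22.
#' @return A list of class `hit_report`: `hits` (selected rows, ranked by
#'   descending score), `threshold`, `n_library`, `selectivity_percent`
#'   (hits / library size x 100).
#' @export
select_hits <- function(predictions, threshold = 0.22) {
  if (!is.numeric(threshold) || threshold <= 0 || threshold >= 1) {
    stop_glio("threshold must lie in (0, 1)", "config_error")
  }
  hits <- predictions[predictions$mean_score >= threshold, , drop = FALSE]
  hits <- hits[order(-hits$mean_score), , drop = FALSE]
  rownames(hits) <- NULL
  structure(list(hits = as.data.frame(hits), threshold = threshold,
                 n_library = nrow(predictions),
                 selectivity_percent =
                   if (nrow(predictions) > 0)
                     100 * nrow(hits) / nrow(predictions) else NA_real_),
            class = "hit_report")
}

#' Flag predicted hits with close training-set analogues
#'
#' Computes each hit's minimum continuous-Tanimoto distance to the training
#' positives (both sides on the same normalised feature scale) and flags
#' hits closer than `distance_threshold`. Flagged hits stay in the report —
#' the exclusion decision is left to the analyst.
#'
#' @param report A `hit_report` from [select_hits()].
#' @param hit_features Normalised feature matrix for the hits (rownames =
#'   compound ids).
#' @param training_positive_features Normalised feature matrix of the
#'   training positives, same feature space and scaling.
#' @param distance_threshold Flagging distance on the continuous-Tanimoto
#'   scale. Default 0.3.
#' @return The `hit_report` with `hits` gaining columns
#'   `nearest_training_distance`, `nearest_training_id` and `analogue_flag`.
#' @export
flag_training_analogues <- function(report, hit_features,
                                    training_positive_features,
                                    distance_threshold = 0.3) {
  if (is.null(training_positive_features) ||
      nrow(training_positive_features) == 0) {
    stop_glio("no training positives supplied", "input_error")
  }
  hits <- report$hits
  if (nrow(hits) == 0) {
    hits$nearest_training_distance <- numeric(0)
    hits$nearest_training_id <- character(0)
    hits$analogue_flag <- logical(0)
    report$hits <- hits
    return(report)
  }
  hf <- hit_features[hits$compound_id, , drop = FALSE]
  d <- tanimoto_distance_matrix(hf, training_positive_features)
  nearest <- apply(d, 1, which.min)
  hits$nearest_training_distance <- d[cbind(seq_len(nrow(d)), nearest)]
  hits$nearest_training_id <-
    (rownames(training_positive_features) %||%
       as.character(seq_len(nrow(training_positive_features))))[nearest]
  hits$analogue_flag <- hits$nearest_training_distance < distance_threshold
  report$hits <- hits
  report$distance_threshold <- distance_threshold
  report
}

#' @export
print.hit_report <- function(x, ...) {
  cat(sprintf("%d hit(s) of %d compounds at threshold %.2f (selectivity %.3f%%)\n",
              nrow(x$hits), x$n_library, x$threshold,
              x$selectivity_percent))
  if (nrow(x$hits) > 0) print(utils::head(x$hits, 10))
  invisible(x)
}
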