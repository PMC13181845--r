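# small trained ensemble + matching library, reused across blocks
fixture_ensemble <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      gen <- generate_labelled_features(80, 720, n_features = 20,
                                        n_informative = 10, effect_size = 3,
                                        seed = 51)
      ens <- train_ensemble(gen$features, gen$labels,
                            ensemble_config(n_models = 5, base_seed = 7))
      cache <<- list(gen = gen, ens = ens)
    }
    cache
  }
})

test_that("library preparation removes duplicates and training overlaps", {
  train_smiles <- canonicalise_smiles(drug_smiles[1:5])
  lib <- generate_screen_library(n_unique = 265, n_dup = 20,
                                 n_training_overlap = 15,
                                 training_smiles = train_smiles[1:3],
                                 seed = 52)
  # 3 training structures re-sampled with replacement into 15 overlap slots
  expect_equal(nrow(lib$library), 265 + 20 + 15)
  prep <- prepare_screen_library(lib$library, train_smiles,
                                 features = lib$features)
  expect_equal(nrow(prep$compounds), 265)
  expect_equal(sum(prep$exclusions$reason == "in_training"), 3)
  expect_equal(sum(prep$exclusions$reason == "duplicate"), 20 + 12)
  expect_true(all(!prep$compounds$canonical_smiles %in% train_smiles))
})

test_that("two libraries sharing compounds reduce to the union", {
  smi <- random_smiles <- canonicalise_smiles(drug_smiles)
  libA <- data.frame(compound_id = paste0("A", seq_along(smi)), smiles = smi)
  libB <- data.frame(compound_id = paste0("B", 1:3), smiles = smi[1:3])
  prep <- prepare_screen_library(list(libA, libB),
                                 training_smiles = character(0))
  expect_equal(nrow(prep$compounds), length(smi))
  expect_equal(sum(prep$exclusions$reason == "duplicate"), 3)
})

test_that("unparsable library SMILES are quarantined", {
  lib <- data.frame(compound_id = c("A", "B"),
                    smiles = c("CCO", "zzz_bad"))
  prep <- prepare_screen_library(lib, character(0))
  expect_equal(prep$quarantine$compound_id, "B")
  expect_equal(prep$compounds$compound_id, "A")
})

test_that("ensemble scores average the member probabilities", {
  fx <- fixture_ensemble()
  lib <- generate_screen_library(n_unique = 60, positive_like_fraction = 0.2,
                                 feature_template = list(n_features = 20,
                                                         n_informative = 10,
                                                         effect_size = 3),
                                 seed = 53)
  preds <- score_library(fx$ens, unclass(lib$features))
  pm <- attr(preds, "prob_matrix")
  expect_equal(ncol(pm), 5)
  # oracle: member-at-a-time recomputation
  for (k in 1:5) {
    m <- fx$ens$members[[k]]
    bst <- xgboost::xgb.load.raw(m$model)
    pk <- predict(bst, xgboost::xgb.DMatrix(
      apply_scaler(unclass(lib$features), m$scaler)))
    expect_equal(unname(pm[, k]), unname(pk), tolerance = 1e-7)
  }
  expect_equal(preds$mean_score,
               unname(rowMeans(pm)[preds$compound_id]))
  expect_equal(sort(preds$rank), seq_len(nrow(preds)))
  # planted positive-like compounds are separable by mean score
  is_pos <- preds$compound_id %in% lib$positive_like
  auroc <- mean(outer(preds$mean_score[is_pos],
                      preds$mean_score[!is_pos], ">") + 0.5 *
                  outer(preds$mean_score[is_pos],
                        preds$mean_score[!is_pos], "=="))
  expect_gte(auroc, 0.9)
})

test_that("an empty library yields empty predictions", {
  fx <- fixture_ensemble()
  empty <- matrix(numeric(0), 0, 20,
                  dimnames = list(NULL, fx$ens$feature_names))
  expect_equal(nrow(score_library(fx$ens, empty)), 0)
})

test_that("feature-name mismatches are a hard error", {
  fx <- fixture_ensemble()
  bad <- matrix(rnorm(40), 2, 20,
                dimnames = list(c("a", "b"), paste0("x", 1:20)))
  expect_error(score_library(fx$ens, bad), class = "feature_mismatch")
})

test_that("hit selection is inclusive at the threshold and monotone", {
  preds <- structure(
    data.frame(compound_id = c("a", "b", "c"),
               mean_score = c(0.50, 0.21, 0.22), rank = c(1L, 3L, 2L)),
    class = c("screen_predictions", "data.frame"))
  rep22 <- select_hits(preds, 0.22)
  expect_equal(nrow(rep22$hits), 2)
  expect_equal(rep22$hits$compound_id, c("a", "c"))
  expect_equal(rep22$selectivity_percent, 100 * 2 / 3)
  zero <- preds; zero$mean_score <- 0
  expect_equal(nrow(select_hits(zero, 0.22)$hits), 0)
  expect_error(select_hits(preds, 1.5), class = "config_error")
  # raising the threshold never increases the hit count
  thresholds <- seq(0.05, 0.95, by = 0.1)
  counts <- vapply(thresholds, function(t) nrow(select_hits(preds, t)$hits),
                   0L)
  expect_true(all(diff(counts) <= 0))
})

test_that("training analogues are flagged by Tanimoto distance, not removed", {
  set.seed(54)
  train_pos <- matrix(rnorm(5 * 8), 5, 8,
                      dimnames = list(paste0("T", 1:5), paste0("f", 1:8)))
  hits_feat <- rbind(
    H1 = train_pos[2, ],                       # identical -> distance 0
    H2 = train_pos[3, ] + rnorm(8, sd = 0.05), # near copy -> flagged
    H3 = rnorm(8) * 5)                         # unrelated
  report <- structure(list(
    hits = data.frame(compound_id = c("H1", "H2", "H3"),
                      mean_score = c(0.9, 0.8, 0.7), rank = 1:3),
    threshold = 0.22, n_library = 3, selectivity_percent = 100),
    class = "hit_report")
  out <- flag_training_analogues(report, hits_feat, train_pos,
                                 distance_threshold = 0.3)
  expect_equal(out$hits$nearest_training_distance[1], 0)
  expect_equal(out$hits$nearest_training_id[1:2], c("T2", "T3"))
  expect_true(all(out$hits$analogue_flag[1:2]))
  expect_false(out$hits$analogue_flag[3])
  expect_equal(nrow(out$hits), 3)  # flagged, never dropped
  expect_error(flag_training_analogues(report, hits_feat,
                                       train_pos[0, , drop = FALSE]),
               class = "input_error")
})

test_that("screened libraries are disjoint from training structures", {
  train_smiles <- canonicalise_smiles(drug_smiles)
  lib <- generate_screen_library(n_unique = 40, n_training_overlap = 5,
                                 training_smiles = train_smiles,
                                 seed = 55)
  prep <- prepare_screen_library(lib$library, train_smiles,
                                 features = lib$features)
  expect_length(intersect(prep$compounds$canonical_smiles, train_smiles), 0)
})
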