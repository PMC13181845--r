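test_that("the naive baseline is the majority-class fraction", {
  labels <- c(rep(1, 103), rep(0, 3458))
  expect_equal(round(naive_baseline(labels), 3), 0.971)
  expect_equal(naive_baseline(rep(0:1, 50)), 0.5)
  expect_equal(naive_baseline(rep(1, 10)), 1)
  expect_error(naive_baseline(integer(0)), class = "input_error")
})

test_that("stratified splits preserve class proportions and sizes", {
  labels <- c(rep(1, 103), rep(0, 3458))
  sp <- stratified_split(labels, 0.7, seed = 1)
  expect_equal(length(sp$train), 2493)
  expect_equal(length(sp$test), 1068)
  expect_equal(sum(labels[sp$train]), 72)   # round(103 * 0.7)
  expect_equal(sort(c(sp$train, sp$test)), seq_along(labels))

  small <- rep(0:1, each = 5)
  sp2 <- stratified_split(small, 0.5, seed = 2)
  expect_equal(length(sp2$train), 5)
  expect_equal(sum(small[sp2$train]), 2.5, tolerance = 0.21)  # 2 or 3

  expect_identical(stratified_split(labels, 0.7, seed = 9),
                   stratified_split(labels, 0.7, seed = 9))
  expect_error(stratified_split(rep(1, 10), 0.7, 1), class = "input_error")
})

test_that("confusion-matrix metrics match their definitions", {
  # TP=3 FP=2 FN=2 TN=93 -> precision = recall = 0.6
  labels <- c(rep(1, 5), rep(0, 95))
  probs <- c(rep(0.9, 3), rep(0.1, 2), rep(0.9, 2), rep(0.1, 93))
  m <- compute_metrics(labels, probs)
  expect_equal(m$tp, 3); expect_equal(m$fp, 2)
  expect_equal(m$fn, 2); expect_equal(m$tn, 93)
  expect_equal(m$precision, 0.6)
  expect_equal(m$recall, 0.6)
  expect_equal(m$f1, 0.6)  # harmonic mean of equal values
  expect_equal(m$accuracy, 0.96)
  # perfect ranking maxes both AUCs
  p2 <- compute_metrics(c(0, 0, 1, 1), c(0.1, 0.2, 0.8, 0.9))
  expect_equal(p2$roc_auc, 1)
  expect_equal(p2$pr_auc, 1)
})

test_that("PR-AUC step estimator matches a hand-ranked example", {
  # ranking: pos, neg, pos -> precisions at positives 1/1 and 2/3
  got <- glioscreen:::pr_auc_step(c(1, 0, 1), c(0.9, 0.5, 0.3))
  expect_equal(got, mean(c(1, 2 / 3)))
})

test_that("a member separates well-separated Gaussian classes", {
  gen <- generate_labelled_features(250, 250, n_features = 20,
                                    n_informative = 10, effect_size = 3,
                                    seed = 31)
  # nearest-centroid oracle confirms separability before blaming the learner
  z <- scale(unclass(gen$features))
  mu1 <- colMeans(z[gen$labels == 1, ]); mu0 <- colMeans(z[gen$labels == 0, ])
  d1 <- rowSums(sweep(z, 2, mu1)^2); d0 <- rowSums(sweep(z, 2, mu0)^2)
  expect_gt(mean((d1 < d0) == (gen$labels == 1)), 0.99)
  member <- train_one(gen$features, gen$labels, ensemble_config(), seed = 31)
  expect_gte(member$metrics$accuracy, 0.99)
})

test_that("permuted labels perform at the naive baseline", {
  gen <- generate_labelled_features(103, 1000, n_features = 20,
                                    n_informative = 10, effect_size = 3,
                                    seed = 32)
  perm <- withr::with_seed(32, sample(gen$labels))
  b <- naive_baseline(perm)
  accs <- vapply(1:8, function(s)
    train_one(gen$features, perm, ensemble_config(), seed = s)$metrics$accuracy,
    0)
  expect_lt(abs(mean(accs) - b), 0.02)
})

test_that("the acceptance loop returns exactly n_models gated members", {
  gen <- generate_labelled_features(60, 340, n_features = 15,
                                    n_informative = 8, effect_size = 3,
                                    seed = 33)
  ens <- train_ensemble(gen$features, gen$labels,
                        ensemble_config(n_models = 8, base_seed = 3))
  expect_length(ens$members, 8)
  accs <- vapply(ens$members, function(m) m$metrics$accuracy, 0)
  expect_true(all(accs > ens$baseline))
  expect_gte(ens$attempts, 8)
  # every compound appears in some training split across the loop
  seeds <- vapply(ens$members, function(m) m$seed, 0L)
  in_train <- Reduce(`|`, lapply(seeds, function(s) {
    sp <- stratified_split(gen$labels, 0.7, s)
    seq_along(gen$labels) %in% sp$train
  }))
  expect_true(all(in_train))

  one <- train_ensemble(gen$features, gen$labels,
                        ensemble_config(n_models = 1, base_seed = 5))
  expect_length(one$members, 1)
})

test_that("signal-free features fail the gate at max_attempts", {
  gen <- generate_labelled_features(30, 370, n_features = 15,
                                    n_informative = 0, seed = 34)
  expect_error(
    train_ensemble(gen$features, gen$labels,
                   ensemble_config(n_models = 5, max_attempts = 15,
                                   base_seed = 1)),
    "acceptance rate", class = "ensemble_acceptance_error")
})

test_that("ensemble ROC-AUC is non-decreasing in class separation", {
  mean_auc <- vapply(c(0.3, 1.2, 3), function(es) {
    aucs <- vapply(1:4, function(s) {
      gen <- generate_labelled_features(80, 320, n_features = 15,
                                        n_informative = 8, effect_size = es,
                                        seed = 100 + s)
      train_one(gen$features, gen$labels, ensemble_config(),
                seed = s)$metrics$roc_auc
    }, 0)
    mean(aucs)
  }, 0)
  expect_true(all(diff(mean_auc) > 0))
})

test_that("metric summaries aggregate member records", {
  gen <- generate_labelled_features(60, 200, n_features = 10,
                                    n_informative = 6, effect_size = 3,
                                    seed = 35)
  ens <- train_ensemble(gen$features, gen$labels,
                        ensemble_config(n_models = 3, base_seed = 11))
  sm <- summarise_metrics(ens)
  expect_setequal(sm$metric, c("precision", "recall", "f1", "accuracy",
                               "roc_auc", "pr_auc"))
  precs <- vapply(ens$members, function(m) m$metrics$precision, 0)
  expect_equal(sm$mean[sm$metric == "precision"], mean(precs))
  expect_equal(sm$sd[sm$metric == "precision"], sd(precs))
})

test_that("a saved ensemble reloads and scores identically", {
  gen <- generate_labelled_features(60, 200, n_features = 10,
                                    n_informative = 6, effect_size = 3,
                                    seed = 36)
  ens <- train_ensemble(gen$features, gen$labels,
                        ensemble_config(n_models = 3, base_seed = 2))
  dir <- withr::local_tempdir()
  save_ensemble(ens, dir)
  ens2 <- load_ensemble(dir)
  expect_equal(ens2$baseline, ens$baseline)
  expect_equal(ens2$feature_names, ens$feature_names)
  p1 <- score_library(ens, unclass(gen$features))
  p2 <- score_library(ens2, unclass(gen$features))
  expect_equal(p2$mean_score, p1$mean_score, tolerance = 1e-7)
})
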