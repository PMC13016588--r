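test_that("training is deterministic and respects the configuration", {
  ps <- separable_pairset(n_per_class = 60, seed = 11)
  split <- split_train_test(ps, 0.2, seed = 11)
  cfg <- model_config(seed = 5)
  m1 <- train_similarity_model(split$train, cfg)
  m2 <- train_similarity_model(split$train, cfg)
  probe <- split$test
  expect_equal(predict_similarity(m1, probe), predict_similarity(m2, probe))
  expect_equal(m1$config$n_trees, 100L)
  expect_equal(m1$feature_order, PAIR_FEATURE_NAMES)
  # train-set fit at least as good as held-out fit (non-strict sanity)
  acc <- function(m, s) {
    pred <- as.integer(predict_similarity(m, s) >= 0.5)
    mean(pred == s$pairs$pair_label)
  }
  expect_gte(acc(m1, split$train), acc(m1, split$test))
})

test_that("a single stump fits four hand-built separable pairs perfectly", {
  feats <- tibble::tibble(
    chr_diff = c(0, 0, 10, 12), pos_diff = c(10, 20, 1e8, 2e8),
    pval_diff = c(0.1, 0.2, 30, 40), gene_diff = c(0, 0, 3, 4),
    intergenic_diff = c(0, 0, 1, 1)
  )
  ps <- snpsim:::new_pair_set(feats, c(1L, 1L, 0L, 0L),
                              ref_ids = letters[1:4], cand_ids = LETTERS[1:4])
  # with one tree the bootstrap must retain both classes for the stump to
  # see the split at all; this seed's bootstrap does
  m <- train_similarity_model(ps, model_config(n_trees = 1, max_depth = 1,
                                               seed = 3))
  pred <- as.integer(predict_similarity(m, ps) >= 0.5)
  expect_equal(pred, c(1L, 1L, 0L, 0L))
})

test_that("single-class training sets are rejected", {
  ps <- separable_pairset(30, seed = 2)
  only_sim <- snpsim:::subset_pair_set(ps, which(ps$pairs$pair_label == 1))
  expect_error(train_similarity_model(only_sim), class = "snpsim_data_error")
})

test_that("similarity scores are probabilities that separate the fixture", {
  ps <- separable_pairset(80, seed = 21)
  split <- split_train_test(ps, 0.25, seed = 21)
  m <- train_similarity_model(split$train)
  scores <- predict_similarity(m, split$test)
  expect_true(all(scores >= 0 & scores <= 1))
  lab <- split$test$pairs$pair_label
  expect_gt(mean(scores[lab == 1]), mean(scores[lab == 0]))
  # a zero difference vector must look similar to a model trained on
  # separated groups
  zero <- tibble::tibble(chr_diff = 0, pos_diff = 0, pval_diff = 0,
                         gene_diff = 0, intergenic_diff = 0)
  expect_gt(predict_similarity(m, zero), 0.5)
  expect_error(predict_similarity(m, zero[, 1:3]), class = "snpsim_data_error")
})

test_that("confusion metrics reproduce the published report from raw counts", {
  rep <- confusion_metrics(tn = 163, fp = 10, fn = 11, tp = 155)
  expect_equal(rep$accuracy, 0.938, tolerance = 5e-4)
  expect_equal(round(rep$per_class$precision, 2), c(0.94, 0.94))
  expect_equal(round(rep$per_class$recall, 2), c(0.94, 0.93))
  expect_equal(round(rep$per_class$f1, 2), c(0.94, 0.94))
  expect_equal(rep$per_class$support, c(173, 166))
  expect_equal(rep$support, 339)
  expect_equal(round(rep$macro_avg[["f1"]], 2), 0.94)
  expect_equal(round(rep$weighted_avg[["f1"]], 2), 0.94)
})

test_that("confusion metrics handle perfect, degenerate and empty cases", {
  perfect <- confusion_metrics(1, 0, 0, 1)
  expect_equal(perfect$accuracy, 1)
  expect_true(all(perfect$per_class$f1 == 1))
  worst <- confusion_metrics(0, 1, 1, 0)
  expect_equal(worst$accuracy, 0)
  expect_true(worst$zero_division)
  expect_true(all(worst$per_class$precision == 0))
  expect_error(confusion_metrics(0, 0, 0, 0), class = "snpsim_config_error")
  expect_error(confusion_metrics(-1, 0, 0, 1), class = "snpsim_config_error")
})

test_that("evaluate agrees with confusion_metrics and the AUC oracles", {
  ps <- separable_pairset(80, seed = 31)
  split <- split_train_test(ps, 0.3, seed = 31)
  m <- train_similarity_model(split$train)
  rep <- evaluate_model(m, split$test)
  lab <- split$test$pairs$pair_label
  scores <- rep$scores
  pred <- as.integer(scores >= 0.5)
  # internal consistency with count-only metrics
  again <- confusion_metrics(sum(pred == 0 & lab == 0), sum(pred == 1 & lab == 0),
                             sum(pred == 0 & lab == 1), sum(pred == 1 & lab == 1))
  expect_equal(rep$accuracy, again$accuracy)
  expect_equal(rep$per_class, again$per_class)
  expect_equal(sum(rep$confusion), length(lab))
  # ROC-AUC equals the concordance-count oracle
  expect_equal(rep$roc_auc, brute_force_auc(lab, scores), tolerance = 1e-12)
  # label inversion flips the AUC
  expect_equal(auc_score(1 - lab, scores), 1 - rep$roc_auc, tolerance = 1e-12)
  # metrics bounded
  expect_true(rep$roc_auc >= 0 && rep$roc_auc <= 1)
  expect_true(rep$average_precision >= 0 && rep$average_precision <= 1)
  # single-class test set is rejected
  only1 <- snpsim:::subset_pair_set(split$test, which(lab == 1))
  expect_error(evaluate_model(m, only1), class = "snpsim_data_error")
})

test_that("AUC and AP match brute force on randomized scored sets", {
  for (seed in 1:5) {
    withr::with_seed(seed, {
      n <- sample(20:200, 1)
      lab <- sample(0:1, n, TRUE)
      if (length(unique(lab)) < 2) lab[1:2] <- c(0L, 1L)
      scores <- round(stats::runif(n), 2)  # induces ties
    })
    expect_equal(auc_score(lab, scores), brute_force_auc(lab, scores),
                 tolerance = 1e-12)
    # AP oracle: precision at each positive hit, averaged (tie-free check)
    scores2 <- scores + seq_along(scores) * 1e-9
    ord <- order(scores2, decreasing = TRUE)
    hit <- lab[ord] == 1
    ap_oracle <- mean(cumsum(hit)[hit] / which(hit))
    expect_equal(average_precision(lab, scores2), ap_oracle, tolerance = 1e-9)
  }
})

test_that("perfect scores give accuracy 1 and AUC 1", {
  feats <- single_feature_pairset(40, seed = 8)
  m <- train_similarity_model(feats, model_config(seed = 2))
  rep <- evaluate_model(m, feats)
  expect_equal(rep$roc_auc, 1)
  expect_equal(rep$accuracy, 1)
  expect_equal(rep$average_precision, 1)
})

test_that("cross-validation stratifies folds and separates the fixture", {
  ps <- separable_pairset(60, seed = 41)
  cv <- cross_validate(ps, k = 5, model_config(seed = 3), seed = 3)
  expect_length(cv$fold_auc, 5)
  expect_gte(cv$mean_auc, 0.99)
  # fold sizes differ by <= 1 per class by construction of the assignment
  expect_error(cross_validate(ps, k = 1), class = "snpsim_config_error")
  expect_error(cross_validate(ps, k = 100), class = "snpsim_data_error")
  # k=2 on 4 trivially separable pairs -> both folds AUC 1
  feats <- tibble::tibble(chr_diff = c(0, 0, 20, 20), pos_diff = c(1, 2, 1e8, 2e8),
                          pval_diff = c(0, 0, 30, 30), gene_diff = c(0, 0, 4, 4),
                          intergenic_diff = c(0, 0, 1, 1))
  tiny <- snpsim:::new_pair_set(feats, c(1L, 1L, 0L, 0L),
                                ref_ids = letters[1:4], cand_ids = LETTERS[1:4])
  tiny_cv <- cross_validate(tiny, k = 2, model_config(n_trees = 25, seed = 1),
                            seed = 1)
  expect_equal(tiny_cv$fold_auc, c(1, 1))
})

test_that("the forest dominates the linear baselines on the separable fixture", {
  ps <- separable_pairset(80, seed = 51)
  tab <- compare_baselines(ps, model_config(seed = 4), seed = 4)
  expect_equal(dim(tab), c(3, 7))  # model column + six metrics
  expect_setequal(tab$model, c("random_forest", "logistic_regression",
                               "ridge_regression"))
  metrics <- as.matrix(tab[, -1])
  expect_true(all(metrics >= 0 & metrics <= 1))
  rf_auc <- tab$roc_auc[tab$model == "random_forest"]
  expect_gte(rf_auc, max(tab$roc_auc[tab$model != "random_forest"]))
})

test_that("feature importances are a normalized ranking of the five features", {
  ps <- separable_pairset(60, seed = 61)
  m <- train_similarity_model(ps)
  imp <- feature_importances(m)
  expect_equal(nrow(imp), 5)
  expect_setequal(imp$feature, PAIR_FEATURE_NAMES)
  expect_equal(sum(imp$importance), 1, tolerance = 1e-9)
  expect_true(all(diff(imp$importance) <= 0))
  # when only pos_diff carries signal it must rank first
  single <- single_feature_pairset(200, seed = 13)
  m2 <- train_similarity_model(single, model_config(seed = 13))
  expect_equal(feature_importances(m2)$feature[1], "pos_diff")
})

test_that("models survive a save/load round trip and reject corrupt files", {
  ps <- separable_pairset(40, seed = 71)
  m <- train_similarity_model(ps, model_config(seed = 6))
  path <- withr::local_tempfile(fileext = ".rds")
  save_model(m, path)
  back <- load_model(path)
  probe <- random_features(100, seed = 7)
  probe_pairs <- pair_features(probe[1:50, ], probe[51:100, ])
  expect_equal(predict_similarity(back, probe_pairs),
               predict_similarity(m, probe_pairs))
  expect_equal(back$config, m$config)
  expect_equal(back$feature_order, m$feature_order)
  # corrupted / foreign files error instead of mispredicting
  writeLines("not a model", path)
  expect_error(load_model(path), class = "snpsim_data_error")
  path2 <- withr::local_tempfile(fileext = ".rds")
  saveRDS(list(format = "something_else"), path2)
  expect_error(load_model(path2), class = "snpsim_data_error")
})

test_that("class weighting is invariant to duplicating a balanced training set", {
  ps <- separable_pairset(40, seed = 81)
  doubled <- snpsim:::new_pair_set(
    rbind(ps$pairs[PAIR_FEATURE_NAMES], ps$pairs[PAIR_FEATURE_NAMES]),
    rep(ps$pairs$pair_label, 2), rep(ps$ref_ids, 2), rep(ps$cand_ids, 2))
  m1 <- train_similarity_model(ps, model_config(seed = 9))
  m2 <- train_similarity_model(doubled, model_config(seed = 9))
  probe <- ps$pairs[PAIR_FEATURE_NAMES]
  p1 <- as.integer(predict_similarity(m1, probe) >= 0.5)
  p2 <- as.integer(predict_similarity(m2, probe) >= 0.5)
  expect_equal(p1, p2)
})
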