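test_that("a perfectly separable feature reaches CV accuracy one", {
  tab <- quick_table(15, 30, seed = 17)
  tab$Fp1.delta <- ifelse(tab$amyloid_label == "positive", 1, 0)
  for (cl in c("svm", "lda")) {
    rec <- evaluate_combination(tab, "Fp1.delta",
                                search_config(classifier = cl, seed = 1))
    expect_equal(rec$cv_accuracy, 1.0)
    expect_equal(rec$cv_sensitivity, 1.0)
    expect_equal(rec$cv_specificity, 1.0)
  }
})

test_that("label permutation drives CV accuracy to chance", {
  accs <- vapply(1:30, function(r) {
    tab <- quick_table(25, 25, seed = 600 + r)
    perm <- qeegamyloid:::with_seed(700 + r, sample(tab$amyloid_label))
    tab$amyloid_label <- perm
    evaluate_combination(tab, c("Fz.delta", "Cz.alpha1"),
                         quick_cfg(seed = r))$cv_accuracy
  }, numeric(1))
  expect_lt(abs(mean(accs) - 0.5), 0.05)
})

test_that("evaluation is deterministic and grouping keeps halves together", {
  tab <- holdout_split(quick_table(12, 24, seed = 18), 0.2, seed = 1)
  aug <- suppressWarnings(augment_positives(tab))
  cfg <- search_config(classifier = "lda", seed = 5)
  r1 <- evaluate_combination(aug, c("F3.delta", "Pz.alpha2"), cfg)
  r2 <- evaluate_combination(aug, c("F3.delta", "Pz.alpha2"), cfg)
  expect_identical(r1, r2)
  # the fold builder puts both halves of a subject in the same fold
  train <- dplyr::filter(aug, split == "train")
  fold <- qeegamyloid:::make_cv_folds(train, 5, 5)
  by_parent <- split(fold, ifelse(is.na(train$lineage),
                                  train$subject_id, train$lineage))
  expect_true(all(vapply(by_parent, function(f) length(unique(f)) == 1,
                         logical(1))))
})

test_that("run_generation enumerates exhaustively and tallies conserve", {
  tab <- quick_table(20, 40, seed = 19)
  pool <- feature_names()[c(1, 9, 17, 25, 33, 41)]   # 6 delta features
  cfg <- search_config(classifier = "lda", top_count = 4, seed = 2)
  gen <- run_generation(tab, pool, k = 2, cfg)
  expect_equal(gen$n_models, 15)            # C(6,2)
  expect_equal(nrow(gen$models), 15)
  expect_equal(sum(gen$freq), 2 * 4)        # k x |top_models|
  expect_equal(nrow(gen$top_models), 4)
  # budget guard
  cfg2 <- search_config(max_models = 10)
  expect_error(run_generation(tab, pool, 2, cfg2), "budget")
})

test_that("planted features dominate the frequency tally", {
  tab <- generate_feature_table(cohort_design(
    60, 60, seed = 20, profiles = planted3_profiles()))
  pool <- union(planted3_features[1:2],
                c("O2.gamma", "T5.theta", "Fp2.beta3", "T6.beta2",
                  "O1.theta", "F8.theta", "T3.beta3", "Fp1.gamma"))
  # with 20 of the 45 pairs kept, pairs containing a planted feature fill
  # the top list and both planted features out-tally every noise feature
  cfg <- search_config(classifier = "lda", top_count = 20, seed = 3)
  gen <- run_generation(tab, pool, k = 2, cfg)
  planted_freq <- gen$freq[planted3_features[1:2]]
  noise_freq <- gen$freq[setdiff(names(gen$freq), planted3_features[1:2])]
  expect_true(min(planted_freq) > max(noise_freq))
})

test_that("next_pool ranks by frequency with documented tie-breaking", {
  tab <- quick_table(20, 40, seed = 21)
  pool <- feature_names()[seq(1, 48, by = 8)]   # six delta features
  cfg <- search_config(classifier = "lda", top_count = 5, seed = 2)
  gen <- run_generation(tab, pool, 2, cfg)
  # budget >= pool size leaves the pool unchanged as a set
  expect_setequal(next_pool(gen, 10), pool)
  # a budget of one returns the single most frequent feature
  best <- next_pool(gen, 1)
  expect_equal(unname(gen$freq[best]), max(gen$freq))
  # deterministic under repetition, including ties
  expect_identical(next_pool(gen, 3), next_pool(gen, 3))
})

test_that("the heuristic matches exhaustive search on small pools", {
  # single-table check; the acceptance suite repeats this over ten tables
  tab0 <- generate_feature_table(cohort_design(
    40, 40, seed = 22, profiles = planted3_profiles(shift = 0.08)))
  pool <- union(planted3_features,
                c("O2.gamma", "T5.theta", "Fp2.beta3", "T6.beta2", "O1.theta",
                  "F8.theta", "T3.beta3", "Fp1.gamma", "T4.delta"))
  tab <- subset_features(tab0, pool)
  cfg <- search_config(k_max = 4, k_exhaustive = 3,
                       pool_size = c("4" = 8), top_min = 10,
                       classifier = "lda", retention_accuracy = 0.6, seed = 4)
  found <- run_heuristic(tab, cfg)
  best_heur <- max(found$generations[[4]]$models$cv_accuracy)
  # independent brute force over all C(12,4) combinations
  combos <- utils::combn(sort(pool), 4)
  oracle <- max(vapply(seq_len(ncol(combos)), function(i) {
    evaluate_combination(tab, combos[, i], cfg)$cv_accuracy
  }, numeric(1)))
  expect_equal(best_heur, oracle)
})

test_that("run_heuristic reports generations and retains by threshold", {
  tab <- generate_feature_table(cohort_design(
    30, 60, seed = 23, profiles = planted3_profiles()))
  cfg <- quick_cfg(seed = 6)
  res <- run_heuristic(tab, cfg)
  expect_s3_class(res, "ga_search")
  expect_equal(nrow(res$summary), 3)
  expect_equal(res$summary$n_models[1], 152)
  expect_equal(res$summary$n_models[2], count_combinations(12, 2))
  expect_true(all(res$candidates$cv_accuracy > cfg$retention_accuracy))
  td <- tidy(res)
  expect_true(all(c("combo_id", "cv_accuracy") %in% names(td)))
  gl <- glance(res)
  expect_equal(gl$n_models_evaluated, sum(res$summary$n_models))
  expect_s3_class(autoplot(res), "ggplot")
})

test_that("adding a perfectly informative feature never hurts separable CV", {
  tab <- quick_table(20, 20, seed = 24)
  tab$Fp1.delta <- ifelse(tab$amyloid_label == "positive", 1, 0)
  cfg <- search_config(classifier = "lda", seed = 7)
  base_feats <- c("O2.gamma", "T5.theta", "Fp2.beta3")
  for (f in base_feats) {
    with_inf <- evaluate_combination(tab, c("Fp1.delta", f), cfg)
    expect_equal(with_inf$cv_accuracy, 1.0)
  }
})
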