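make_small_ensemble <- function(seed = 25, n_submodels = 5) {
  tab <- holdout_split(generate_feature_table(cohort_design(
    20, 40, seed = seed, profiles = planted3_profiles())), 0.2, seed = 1)
  cfg <- quick_cfg(seed = seed, retention_accuracy = 0.6)
  found <- run_heuristic(tab, cfg)
  list(table = tab,
       ensemble = select_submodels(tab, found$candidates, cfg,
                                   n_submodels = n_submodels),
       cfg = cfg, search = found)
}

test_that("vote scores are exact fractions of positive votes", {
  fx <- make_small_ensemble()
  test <- dplyr::filter(fx$table, split == "test")
  sc <- ensemble_score(fx$ensemble, test)
  n <- fx$ensemble$n
  expect_true(all(abs(sc$score * n - round(sc$score * n)) < 1e-12))
  expect_true(all(sc$score >= 0 & sc$score <= 1))
  # hand-counted votes agree with the reported fraction
  votes <- vapply(fx$ensemble$submodels, function(sm) {
    qeegamyloid:::predict_submodel(sm, test) == "positive"
  }, logical(nrow(test)))
  expect_equal(sc$score, rowMeans(votes))
})

test_that("unanimous, split and empty votes map to scores 1, 0.5 and 0", {
  # stub sub-models with fixed predictions via degenerate LDA fits
  tab <- quick_table(10, 10, seed = 26)
  cfg <- search_config(classifier = "lda")
  always <- function(label) {
    sm <- qeegamyloid:::fit_submodel(tab, "Fp1.delta", cfg)
    sm$fit$w[] <- 0
    sm$fit$thr <- if (label == "positive") -1 else 1
    sm
  }
  mk <- function(n_pos, n_total = 20) {
    subs <- c(replicate(n_pos, always("positive"), simplify = FALSE),
              replicate(n_total - n_pos, always("negative"), simplify = FALSE))
    structure(list(submodels = subs, n = n_total, mode = "inner",
                   training_ids = tab$subject_id, cfg = cfg),
              class = "eeg_ensemble")
  }
  row1 <- tab[1, ]
  expect_equal(ensemble_score(mk(20), row1)$score, 1.0)
  expect_equal(ensemble_score(mk(10), row1)$score, 0.5)
  expect_equal(ensemble_score(mk(0), row1)$score, 0.0)
})

test_that("sub-model selection takes the requested count or warns short", {
  fx <- make_small_ensemble(seed = 27, n_submodels = 5)
  expect_equal(fx$ensemble$n, 5)
  expect_equal(length(fx$ensemble$submodels), 5)
  few <- fx$search$candidates[1:2, ]
  expect_warning(
    small <- select_submodels(fx$table, few, fx$cfg, n_submodels = 20),
    "only 2"
  )
  expect_equal(small$n, 2)
  expect_error(select_submodels(fx$table, few[0, ], fx$cfg), "no candidate")
})

test_that("sub-model selection is deterministic given seed and candidates", {
  fx1 <- make_small_ensemble(seed = 28)
  fx2 <- make_small_ensemble(seed = 28)
  expect_identical(tidy(fx1$ensemble), tidy(fx2$ensemble))
})

test_that("Youden cutoff fitting follows the documented tie rules", {
  # separable scores: any cutoff in (0.3, 0.7] has J = 1; the grid rule
  # picks the smallest observed candidate above 0.3
  scores <- c(0.1, 0.2, 0.3, 0.7, 0.8, 1.0)
  labels <- c("negative", "negative", "negative", "positive", "positive", "positive")
  cut <- fit_cutoff(scores, labels)
  expect_equal(cut$cutoff, 0.7)
  expect_equal(cut$j, 1)
  # identical distributions: J = 0 everywhere, documented fallback 0.5
  cut0 <- fit_cutoff(c(0.2, 0.6, 0.2, 0.6), c("positive", "positive",
                                              "negative", "negative"))
  expect_equal(cut0$cutoff, 0.5)
  expect_equal(cut0$j, 0)
  # fixed mode echoes the requested cutoff
  expect_equal(fit_cutoff(method = "fixed", cutoff = 0.58)$cutoff, 0.58)
  expect_error(fit_cutoff(c(1, 1), c("positive", "positive")), "both labels")
})

test_that("confusion-matrix metrics match hand-derived proportions", {
  r <- metrics_from_confusion(tp = 10, fp = 0, fn = 0, tn = 7)
  expect_equal(r$sensitivity, 1)
  expect_equal(r$specificity, 1)
  expect_equal(r$accuracy, 1)
  expect_equal(r$balanced_accuracy, 1)
  r2 <- metrics_from_confusion(3, 2, 1, 4)
  expect_equal(r2$sensitivity, 3 / 4)
  expect_equal(r2$specificity, 4 / 6)
  expect_equal(r2$accuracy, 7 / 10)
  expect_equal(r2$balanced_accuracy, (3 / 4 + 4 / 6) / 2)
  expect_error(metrics_from_confusion(0, 2, 0, 4), "no positive")
  expect_error(metrics_from_confusion(1, 0, 1, 0), "no negative")
})

test_that("raising the cutoff never raises sensitivity nor lowers specificity", {
  set.seed(29)
  scores <- sample(seq(0, 1, by = 0.05), 60, replace = TRUE)
  labels <- sample(c("positive", "negative"), 60, replace = TRUE,
                   prob = c(0.3, 0.7))
  pos <- labels == "positive"
  cuts <- seq(0, 1, by = 0.05)
  sens <- vapply(cuts, function(cc) mean(scores[pos] >= cc), numeric(1))
  spec <- vapply(cuts, function(cc) mean(scores[!pos] < cc), numeric(1))
  expect_true(all(diff(sens) <= 1e-12))
  expect_true(all(diff(spec) >= -1e-12))
})

test_that("evaluation reports agree with their own per-subject scores", {
  fx <- make_small_ensemble(seed = 30)
  test <- dplyr::filter(fx$table, split == "test")
  ev <- evaluate_ensemble(fx$ensemble, test, cutoff = 0.5)
  sc <- ev$scores
  recomputed <- metrics_from_confusion(
    tp = sum(sc$prediction == "positive" & sc$truth == "positive"),
    fp = sum(sc$prediction == "positive" & sc$truth == "negative"),
    fn = sum(sc$prediction == "negative" & sc$truth == "positive"),
    tn = sum(sc$prediction == "negative" & sc$truth == "negative")
  )
  expect_equal(ev$report, recomputed)
  expect_equal(sum(ev$report$tp, ev$report$fp, ev$report$fn, ev$report$tn),
               nrow(test))
  # the >= rule: an all-ones score vector thresholded at 0.58 is all positive
  sc1 <- sc
  expect_true(all(ifelse(rep(1, nrow(sc1)) >= 0.58, "positive", "negative")
                  == "positive"))
  expect_s3_class(autoplot(ev), "ggplot")
  expect_equal(nrow(tidy(ev)), nrow(test))
})

test_that("strict evaluation refuses leaked or unsplit test rows", {
  fx <- make_small_ensemble(seed = 31)
  train <- dplyr::filter(fx$table, split == "train")
  expect_error(evaluate_ensemble(fx$ensemble, train, 0.5), "split")
  leaked <- dplyr::mutate(train, split = "test")
  expect_error(evaluate_ensemble(fx$ensemble, leaked, 0.5), "seen in training")
  # paper-style mode is allowed when strictness is waived
  ev <- evaluate_ensemble(fx$ensemble, leaked, 0.5, strict = FALSE)
  expect_s3_class(ev, "ensemble_evaluation")
})
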