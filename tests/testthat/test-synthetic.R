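test_that("profiles validate shifts, channels and noise", {
  expect_error(group_profile("positive", band_shift = c(sigma = 0.1)),
               "unknown band")
  expect_error(group_profile("positive", band_shift = c(delta = 0.1),
                             channels = list(delta = "FpZ")),
               "unknown channel")
  expect_error(group_profile("positive", band_shift = c(gamma = -0.5)),
               "negative")
  expect_error(group_profile("positive", noise_sd = 0), "noise_sd")
})

test_that("profile templates are probability vectors per channel", {
  profs <- default_profiles()
  for (p in profs) {
    tm <- profile_template(p)
    expect_true(all(tm >= 0))
    expect_lt(max(abs(rowSums(tm) - 1)), 1e-12)
  }
  # shifted channels move in the stated directions
  tmp <- profile_template(profs$positive)
  tmn <- profile_template(profs$negative)
  expect_gt(tmp["Fz", "delta"], tmn["Fz", "delta"])
  expect_gt(tmp["F3", "beta1"], tmn["F3", "beta1"])
  expect_lt(tmp["Cz", "alpha1"], tmn["Cz", "alpha1"])
  expect_lt(tmp["T4", "gamma"], tmn["T4", "gamma"])
})

test_that("generated recordings are deterministic under a fixed seed", {
  p <- default_profiles()$negative
  r1 <- generate_recording(p, 10, 250, seed = 42)
  r2 <- generate_recording(p, 10, 250, seed = 42)
  expect_identical(r1$samples, r2$samples)
  r3 <- generate_recording(p, 10, 250, seed = 43)
  expect_false(identical(r1$samples, r3$samples))
})

test_that("suppressing the alpha bands empties alpha relative power", {
  pz <- group_profile("positive",
                      band_shift = c(alpha1 = -0.18, alpha2 = -0.12))
  rec <- generate_recording(pz, 180, 250, seed = 5)
  fv <- extract_features(rec)
  vals <- matrix(as.numeric(fv[feature_names()]), nrow = 19, byrow = TRUE,
                 dimnames = list(eeg_channels, eeg_bands()))
  expect_lt(max(vals[, "alpha1"] + vals[, "alpha2"]), 0.05)
})

test_that("positive group has higher frontal delta than negative group", {
  profs <- default_profiles()
  diffs <- vapply(1:20, function(s) {
    tab <- generate_feature_table(cohort_design(40, 40, seed = s,
                                                profiles = profs))
    mean(tab$F3.delta[tab$amyloid_label == "positive"]) -
      mean(tab$F3.delta[tab$amyloid_label == "negative"])
  }, numeric(1))
  expect_true(all(diffs > 0))
})

test_that("feature tables have the documented shape and normalization", {
  tab <- generate_feature_table(cohort_design(50, 125, seed = 2))
  expect_equal(nrow(tab), 175)
  expect_length(feature_cols(tab), 152)
  expect_equal(sum(tab$amyloid_label == "positive"), 50)
  # per-channel sums are 1 for every subject
  for (ch in eeg_channels) {
    cols <- paste0(ch, ".", eeg_bands())
    expect_lt(max(abs(rowSums(tab[, cols]) - 1)), 1e-9)
  }
})

test_that("feature tables are deterministic and extensible in n", {
  t1 <- generate_feature_table(cohort_design(5, 10, seed = 9))
  t2 <- generate_feature_table(cohort_design(5, 10, seed = 9))
  expect_identical(t1, t2)
  # growing the cohort never reshuffles existing subjects
  t3 <- generate_feature_table(cohort_design(5, 20, seed = 9))
  expect_identical(t1$Fp1.delta, t3$Fp1.delta[seq_len(15)])
})

test_that("a planted shift is detectable with high power at n=100/100", {
  # Monte-Carlo power of the Welch t-test on a shifted frontal delta feature
  rej <- vapply(1:40, function(r) {
    tab <- quick_table(100, 100, seed = 3000 + r)
    x <- tab$Fz.delta[tab$amyloid_label == "positive"]
    y <- tab$Fz.delta[tab$amyloid_label == "negative"]
    stats::t.test(x, y)$p.value < 0.01
  }, logical(1))
  expect_gt(mean(rej), 0.9)
})

test_that("group means converge to the template at large n", {
  tab <- generate_feature_table(cohort_design(500, 500, seed = 11))
  tmp <- profile_template(default_profiles()$positive)
  tmn <- profile_template(default_profiles()$negative)
  for (f in c("Cz.delta", "F3.beta1", "T4.gamma", "O2.theta")) {
    parts <- strsplit(f, ".", fixed = TRUE)[[1]]
    for (lab in c("positive", "negative")) {
      x <- tab[[f]][tab$amyloid_label == lab]
      target <- (if (lab == "positive") tmp else tmn)[parts[1], parts[2]]
      expect_lt(abs(mean(x) - target), 3 * stats::sd(x) / sqrt(length(x)))
    }
  }
})

test_that("cohorts carry one labelled recording per subject, reproducibly", {
  d <- cohort_design(7, 28, duration_s = 8, seed = 13)
  coh <- generate_cohort(d)
  expect_equal(nrow(coh), 35)
  expect_equal(sum(coh$amyloid_label == "positive"), 7)
  coh2 <- generate_cohort(d)
  expect_identical(coh$recording[[1]]$samples, coh2$recording[[1]]$samples)
  expect_identical(coh$recording[[35]]$samples, coh2$recording[[35]]$samples)
})

test_that("design validation enforces sampling and duration bounds", {
  expect_error(cohort_design(fs = 80), "Nyquist|90")
  expect_error(generate_recording(default_profiles()$negative, duration_s = 4),
               "8 s")
})
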