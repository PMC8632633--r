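# Shared fixtures: small synthetic designs and search configurations kept
# deliberately tiny so the default suite stays fast.

quick_table <- function(n_pos = 20, n_neg = 50, seed = 1, effect = 0.03,
                        noise_sd = 0.04, diagnosis = "SCD") {
  generate_feature_table(cohort_design(
    n_positive = n_pos, n_negative = n_neg, diagnosis = diagnosis, seed = seed,
    profiles = default_profiles(effect = effect, noise_sd = noise_sd)
  ))
}

null_profiles <- function(noise_sd = 0.04) {
  list(positive = group_profile("positive", noise_sd = noise_sd),
       negative = group_profile("negative", noise_sd = noise_sd))
}

# Profiles planting a strong signal on exactly three channel-band cells.
planted3_profiles <- function(shift = 0.12, noise_sd = 0.04) {
  list(
    positive = group_profile(
      "positive",
      band_shift = c(delta = shift, alpha2 = -shift * 0.8, beta1 = shift),
      channels = list(delta = "F3", alpha2 = "Pz", beta1 = "C4"),
      noise_sd = noise_sd
    ),
    negative = group_profile("negative", noise_sd = noise_sd)
  )
}
planted3_features <- c("F3.delta", "Pz.alpha2", "C4.beta1")

# Restrict a feature table to a named feature subset (metadata kept).
subset_features <- function(table, features) {
  table[, c("subject_id", "diagnosis", "amyloid_label", "split", "lineage",
            features)]
}

quick_cfg <- function(...) {
  search_config(k_max = 3, k_exhaustive = 1,
                pool_size = c("2" = 12, "3" = 8),
                top_min = 10, classifier = "lda", ...)
}

# Tiny recording helpers
flat_recording <- function(fs = 250, secs = 10, value = 0) {
  eeg_recording(matrix(value, nrow = 19, ncol = fs * secs), fs)
}

# One pure tone on channel 1, all other channels silent; after CAR the
# tone survives on channel 1 scaled by 18/19.
sine_recording <- function(freq, fs = 250, secs = 20, amp = 1) {
  t <- seq_len(fs * secs) / fs
  x <- matrix(0, 19, length(t))
  x[1, ] <- amp * sin(2 * pi * freq * t)
  eeg_recording(x, fs)
}
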