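#' Baseline eyes-closed relative-power template
#'
#' One set of relative band powers applied to every channel before group
#' shifts: a typical resting eyes-closed profile with a dominant alpha
#' rhythm and a 1/f-weighted remainder. Sums to 1.
#'
#' @return Named numeric vector over the 8 bands.
#' @export
baseline_template <- function() {
  c(delta = 0.20, theta = 0.15, alpha1 = 0.18, alpha2 = 0.12,
    beta1 = 0.08, beta2 = 0.09, beta3 = 0.10, gamma = 0.08)
}

#' Define a group spectral profile
#'
#' A profile is the expected relative-power template of one amyloid group:
#' the baseline template plus additive band shifts, optionally restricted
#' to a channel subset, renormalized to sum 1 per channel; plus the
#' between-subject standard deviation of band relative power.
#'
#' @param label `"positive"` or `"negative"`.
#' @param band_shift Named numeric vector of additive relative-power
#'   shifts, names in [eeg_bands()].
#' @param channels Named list mapping a band name to the channels its
#'   shift applies to; bands absent from the list are shifted on all 19
#'   channels.
#' @param noise_sd Between-subject standard deviation of band relative
#'   power (dimensionless, > 0).
#' @return A `group_profile`.
#' @export
group_profile <- function(label = c("positive", "negative"),
                          band_shift = numeric(0),
                          channels = list(),
                          noise_sd = 0.04) {
  label <- match.arg(label)
  if (length(band_shift)) {
    bad <- setdiff(names(band_shift), eeg_bands())
    if (length(bad)) stop("unknown band(s) in band_shift: ", paste(bad, collapse = ", "))
  }
  if (length(channels)) {
    bad <- setdiff(names(channels), eeg_bands())
    if (length(bad)) stop("channels restricts unknown band(s): ", paste(bad, collapse = ", "))
    badch <- setdiff(unlist(channels), eeg_channels)
    if (length(badch)) stop("unknown channel name(s): ", paste(badch, collapse = ", "))
  }
  if (!is.numeric(noise_sd) || noise_sd <= 0) stop("noise_sd must be > 0")
  prof <- structure(
    list(label = label, band_shift = band_shift, channels = channels,
         noise_sd = noise_sd),
    class = "group_profile"
  )
  profile_template(prof)  # validates non-negativity of the shifted template
  prof
}

#' Expected relative-power template of a profile
#'
#' @param profile A `group_profile`.
#' @return 19 x 8 matrix, rows (channels) summing to 1.
#' @export
profile_template <- function(profile) {
  stopifnot(inherits(profile, "group_profile"))
  tmpl <- matrix(rep(baseline_template(), each = length(eeg_channels)),
                 nrow = length(eeg_channels),
                 dimnames = list(eeg_channels, eeg_bands()))
  for (b in names(profile$band_shift)) {
    ch <- profile$channels[[b]] %||% eeg_channels
    tmpl[ch, b] <- tmpl[ch, b] + profile$band_shift[[b]]
  }
  if (any(tmpl < -1e-12)) {
    stop("band shifts drive expected relative power negative; reduce the shift")
  }
  tmpl[tmpl < 0] <- 0
  tmpl / rowSums(tmpl)
}

#' Default amyloid-positive and amyloid-negative profiles
#'
#' Encodes the direction of the group spectral signature the pipeline is
#' built to detect: relative delta elevated over fronto-central channels
#' and beta1 elevated frontally in the positive group, with alpha and gamma
#' reduced. A single scalar `effect` scales all shifts.
#'
#' @param effect Shift magnitude in relative-power units (default 0.03).
#' @param noise_sd Between-subject standard deviation (default 0.04).
#' @return Named list with elements `positive` and `negative`.
#' @export
default_profiles <- function(effect = 0.03, noise_sd = 0.04) {
  list(
    positive = group_profile(
      "positive",
      band_shift = c(delta = effect, beta1 = effect,
                     alpha1 = -effect / 2, alpha2 = -effect / 2,
                     gamma = -effect),
      channels = list(
        delta  = c("Fp2", "F3", "Fz", "F4", "F7", "C3", "Cz", "C4", "Pz", "P4", "T6", "O1"),
        beta1  = c("Fp1", "Fp2", "F3", "Fz", "F4", "C3"),
        alpha1 = c("Fp1", "F3", "Fz", "C3", "Cz", "C4", "Pz", "T6"),
        alpha2 = c("Fp1", "F3", "Fz", "C3", "Cz", "C4", "Pz", "T6"),
        gamma  = c("Fp2", "F7", "F8", "C4", "T3", "T4")
      ),
      noise_sd = noise_sd
    ),
    negative = group_profile("negative", noise_sd = noise_sd)
  )
}

#' Describe a synthetic cohort
#'
#' @param n_positive,n_negative Group sizes (>= 1). The defaults mirror a
#'   roughly 1:2.5 positive:negative prevalence at n = 50.
#' @param diagnosis `"SCD"` or `"MCI"` stratum tag.
#' @param duration_s Recording length in seconds (default 180).
#' @param fs Sampling rate, 200 or 250 Hz by default (any fs > 90 allowed).
#' @param seed Integer design seed; every subject's draw derives from it.
#' @param profiles List with `positive` and `negative` [group_profile()]s.
#' @return A `cohort_design`.
#' @export
cohort_design <- function(n_positive = 20, n_negative = 50,
                          diagnosis = c("SCD", "MCI"),
                          duration_s = 180, fs = 250, seed = 1,
                          profiles = default_profiles()) {
  diagnosis <- match.arg(diagnosis)
  stopifnot(n_positive >= 1, n_negative >= 1, duration_s > 0)
  if (fs <= 2 * 45) stop("fs must exceed 90 Hz (Nyquist for the 45 Hz gamma edge)")
  stopifnot(inherits(profiles$positive, "group_profile"),
            inherits(profiles$negative, "group_profile"))
  structure(
    list(n_positive = n_positive, n_negative = n_negative,
         diagnosis = diagnosis, duration_s = duration_s, fs = fs,
         seed = as.integer(seed), profiles = profiles),
    class = "cohort_design"
  )
}

# Evaluate expr with a temporary RNG seed, restoring global state after.
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

# Synthesize one multichannel recording whose expected relative band powers
# equal the rows of `tmpl`. Each channel is built in the frequency domain:
# complex Gaussian coefficients on the bins of [1,45] Hz, 1/f-shaped within
# each band and scaled so the band's expected power is tmpl * total_power.
synth_from_template <- function(tmpl, duration_s, fs, seed, total_power = 100) {
  n <- as.integer(round(duration_s * fs))
  freq <- seq(0, fs, length.out = n + 1)[seq_len(n %/% 2 + 1)][-1]  # positive bins
  bandidx <- band_of(freq)
  keep <- !is.na(bandidx)
  # carriers are flat within each band plus a narrowband 10 Hz alpha
  # resonance; the across-band envelope still decays like real EEG because
  # the band-power template itself is pink-like. Keeping the in-band shape
  # flat avoids concentrating delta energy at the 1 Hz edge, where window
  # leakage would bias the recovered template.
  shape <- ifelse(keep, 1 + 3 * stats::dnorm(freq, 10, 1.2), 0)
  with_seed(seed, {
    x <- matrix(0, nrow = length(eeg_channels), ncol = n,
                dimnames = list(eeg_channels, NULL))
    for (ci in seq_along(eeg_channels)) {
      pk <- numeric(length(freq))
      for (b in eeg_bands()) {
        sel <- which(bandidx == b)
        if (!length(sel)) next
        w <- shape[sel] / sum(shape[sel])
        pk[sel] <- w * tmpl[ci, b] * total_power
      }
      nf <- length(freq)
      coef <- (stats::rnorm(nf) + 1i * stats::rnorm(nf)) * (n * sqrt(pk) / 2)
      # constrained realization: rescale each band so the realized band
      # power equals the template exactly (random phases, fixed amplitude)
      for (b in eeg_bands()) {
        sel <- which(bandidx == b)
        if (!length(sel)) next
        got <- sum(Mod(coef[sel])^2)
        want <- tmpl[ci, b] * total_power * n^2 / 2
        if (got > 0) coef[sel] <- coef[sel] * sqrt(want / got)
      }
      spec <- complex(real = numeric(n))
      spec[1 + seq_len(nf)] <- coef
      ix <- n + 1 - seq_len(nf - (n %% 2 == 0))      # conjugate half (skip Nyquist dup)
      spec[ix] <- Conj(coef[seq_along(ix)])
      x[ci, ] <- Re(stats::fft(spec, inverse = TRUE)) / n
    }
    eeg_recording(x, fs, reference = "as-recorded")
  })
}

#' Generate one synthetic EEG recording
#'
#' Produces a 19-channel series whose per-channel expected relative band
#' powers equal the profile's shifted, renormalized template. Band content
#' is realized as band-limited Gaussian processes with a 1/f spectral
#' shape inside each band; deterministic under a fixed seed.
#'
#' @param profile A [group_profile()].
#' @param duration_s Duration in seconds (>= 8).
#' @param fs Sampling rate in Hz (> 90).
#' @param seed Integer seed.
#' @param total_power Total 1-45 Hz power per channel (microvolt^2).
#' @return An `eeg_recording` tagged `"as-recorded"`.
#' @export
generate_recording <- function(profile, duration_s = 180, fs = 250, seed = 1,
                               total_power = 100) {
  stopifnot(inherits(profile, "group_profile"))
  if (duration_s < 8) stop("duration_s must be at least 8 s for one PSD window")
  if (fs <= 2 * 45) stop("fs must exceed 90 Hz (Nyquist for the 45 Hz gamma edge)")
  synth_from_template(profile_template(profile), duration_s, fs, seed, total_power)
}

# One subject's template: profile template plus band-wise Gaussian noise,
# floored at a small positive weight and renormalized per channel.
subject_template <- function(profile, seed) {
  tmpl <- profile_template(profile)
  with_seed(seed, {
    draw <- tmpl + matrix(stats::rnorm(length(tmpl), sd = profile$noise_sd),
                          nrow = nrow(tmpl))
    draw[draw < 1e-3] <- 1e-3
    draw / rowSums(draw)
  })
}

#' Generate a subjects-by-features synthetic table
#'
#' Feature-space shortcut that bypasses signal synthesis: each subject's
#' per-channel 8-band relative powers are drawn around the group template
#' (additive Gaussian noise, floored, renormalized per channel).
#'
#' @param design A [cohort_design()].
#' @return A feature table: `n_positive + n_negative` rows, columns
#'   `subject_id`, `diagnosis`, `amyloid_label`, `split`, `lineage` and the
#'   152 features. Deterministic under the design seed.
#' @export
generate_feature_table <- function(design) {
  stopifnot(inherits(design, "cohort_design"))
  labels <- rep(c("positive", "negative"), c(design$n_positive, design$n_negative))
  vals <- t(vapply(seq_along(labels), function(i) {
    tmpl <- subject_template(design$profiles[[labels[i]]], derive_seed(design$seed, i))
    as.vector(t(tmpl))
  }, numeric(length(feature_names()))))
  colnames(vals) <- feature_names()
  dplyr::bind_cols(
    tibble::tibble(
      subject_id = sprintf("%s%03d", ifelse(labels == "positive", "P", "N"),
                           seq_along(labels)),
      diagnosis = design$diagnosis,
      amyloid_label = labels,
      split = NA_character_,
      lineage = NA_character_
    ),
    tibble::as_tibble(vals)
  )
}

#' Generate a cohort of synthetic recordings
#'
#' Each subject gets an individual template drawn around their group's
#' profile (between-subject variability) and a signal synthesized from it.
#' Per-subject seeds derive from the design seed, so the same design always
#' yields the same cohort and extending `n` never reshuffles earlier
#' subjects.
#'
#' @param design A [cohort_design()].
#' @return A tibble with columns `subject_id`, `diagnosis`,
#'   `amyloid_label`, and `recording` (list of `eeg_recording`).
#' @export
generate_cohort <- function(design) {
  stopifnot(inherits(design, "cohort_design"))
  labels <- rep(c("positive", "negative"), c(design$n_positive, design$n_negative))
  purrr::imap_dfr(labels, function(lab, i) {
    tmpl <- subject_template(design$profiles[[lab]], derive_seed(design$seed, i))
    rec <- synth_from_template(tmpl, design$duration_s, design$fs,
                               derive_seed(design$seed, i + 1000000L))
    tibble::tibble(
      subject_id = sprintf("%s%03d", ifelse(lab == "positive", "P", "N"), i),
      diagnosis = design$diagnosis,
      amyloid_label = lab,
      recording = list(rec)
    )
  })
}
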