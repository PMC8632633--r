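#' Welch power spectral density of one channel
#'
#' Averaged modified periodograms: Hann-tapered windows of length
#' `fs / resolution` samples (4 s at the default 0.25 Hz resolution), 50%
#' overlap, per-window mean removal before tapering to suppress DC leakage
#' into delta. One-sided density in microvolt^2 per Hz.
#'
#' @param x Numeric vector, one channel's samples (microvolts).
#' @param fs Sampling rate (Hz).
#' @param resolution Frequency resolution (Hz); `fs / resolution` must be a
#'   whole number of samples.
#' @return A tibble with columns `freq` (Hz, from 0 to fs/2) and `psd`.
#' @export
welch_psd <- function(x, fs, resolution = 0.25) {
  nwin <- fs / resolution
  if (abs(nwin - round(nwin)) > 1e-9) {
    stop("fs / resolution must be an integer window length (got ", nwin, ")")
  }
  nwin <- as.integer(round(nwin))
  if (length(x) < nwin) {
    stop("recording shorter than one PSD window (", nwin, " samples needed, ",
         length(x), " available)")
  }
  step <- nwin %/% 2L
  starts <- seq(1L, length(x) - nwin + 1L, by = step)
  w <- 0.5 - 0.5 * cos(2 * pi * seq_len(nwin) / nwin)   # Hann
  u <- sum(w^2)
  nfreq <- nwin %/% 2L + 1L
  acc <- numeric(nfreq)
  for (s in starts) {
    seg <- x[s:(s + nwin - 1L)]
    seg <- (seg - mean(seg)) * w
    sp <- stats::fft(seg)[seq_len(nfreq)]
    acc <- acc + (Mod(sp)^2) / (fs * u)
  }
  psd <- acc / length(starts)
  # one-sided: double everything except DC and Nyquist
  psd[2:(nfreq - 1L)] <- 2 * psd[2:(nfreq - 1L)]
  tibble::tibble(freq = seq(0, fs / 2, by = resolution), psd = psd)
}

#' Absolute band powers of a recording
#'
#' Integrates each channel's Welch PSD over the eight frequency bands
#' (half-open `[low, high)`, gamma closed at 45 Hz). The recording must be
#' common-average referenced first.
#'
#' @param rec A common-average referenced `eeg_recording`.
#' @param scheme Band scheme tibble, see [band_scheme()].
#' @param resolution PSD frequency resolution in Hz (default 0.25).
#' @return A `band_power_matrix`: 19 x 8 numeric matrix (microvolt^2) with
#'   channel rownames and band colnames, attribute `kind = "absolute"`.
#' @export
compute_band_powers <- function(rec, scheme = band_scheme(), resolution = 0.25) {
  stopifnot(inherits(rec, "eeg_recording"))
  if (rec$reference != "common-average") {
    stop("recording must be common-average referenced before spectral analysis")
  }
  band <- NULL
  out <- matrix(0, nrow = length(eeg_channels), ncol = nrow(scheme),
                dimnames = list(eeg_channels, scheme$band))
  for (ch in eeg_channels) {
    psd <- welch_psd(rec$samples[ch, ], rec$fs, resolution)
    psd$band <- band_of(psd$freq)
    bp <- psd |>
      dplyr::filter(!is.na(band)) |>
      dplyr::group_by(band) |>
      dplyr::summarise(power = sum(.data$psd) * resolution)
    out[ch, bp$band] <- bp$power
  }
  band_power_matrix(out, kind = "absolute")
}

#' Construct a band-power matrix
#' @param values 19 x 8 numeric matrix, channels x bands.
#' @param kind `"absolute"` (microvolt^2) or `"relative"` (rows sum to 1).
#' @return A `band_power_matrix`.
#' @export
band_power_matrix <- function(values, kind = c("absolute", "relative")) {
  kind <- match.arg(kind)
  stopifnot(is.matrix(values),
            nrow(values) == length(eeg_channels),
            ncol(values) == length(eeg_bands()))
  if (any(values < 0)) stop("band powers must be non-negative")
  if (kind == "relative" && any(abs(rowSums(values) - 1) > 1e-9)) {
    stop("relative band powers must sum to 1 per channel")
  }
  structure(values, kind = kind, class = c("band_power_matrix", "matrix", "array"))
}

#' Relative band powers
#'
#' Divides each channel's band powers by that channel's total over the
#' eight bands (total 1-45 Hz power), so every channel's eight values sum
#' to one.
#'
#' @param abs_powers A `band_power_matrix` of kind `"absolute"`.
#' @return A `band_power_matrix` of kind `"relative"`.
#' @export
relative_band_powers <- function(abs_powers) {
  stopifnot(inherits(abs_powers, "band_power_matrix"))
  if (attr(abs_powers, "kind") != "absolute") {
    stop("input must be an absolute band-power matrix")
  }
  tot <- rowSums(abs_powers)
  if (any(tot <= 0)) {
    stop("zero total power on channel(s): ",
         paste(rownames(abs_powers)[tot <= 0], collapse = ", "))
  }
  band_power_matrix(unclass(abs_powers) / tot, kind = "relative")
}

#' @exportS3Method generics::tidy
tidy.band_power_matrix <- function(x, ...) {
  tibble::tibble(
    channel = rep(rownames(x), times = ncol(x)),
    band = rep(colnames(x), each = nrow(x)),
    power = as.vector(unclass(x)),
    kind = attr(x, "kind")
  )
}

#' Extract the 152-dimensional relative band-power feature vector
#'
#' Re-references to the common average if needed, computes the Welch PSD
#' band powers, normalizes per channel, and flattens channel-major /
#' band-minor into the canonical 152 feature columns.
#'
#' @param rec An `eeg_recording` (raw or already common-average).
#' @param subject_id Subject identifier.
#' @param diagnosis `"SCD"`, `"MCI"` or `NA`.
#' @param amyloid_label `"positive"`, `"negative"` or `"unknown"`.
#' @param resolution PSD resolution (Hz).
#' @return A one-row tibble: `subject_id`, `diagnosis`, `amyloid_label`,
#'   `split`, `lineage`, then the 152 `channel.band` feature columns. Values
#'   grouped by channel sum to 1.
#' @export
extract_features <- function(rec, subject_id = "S1", diagnosis = NA_character_,
                             amyloid_label = "unknown", resolution = 0.25) {
  stopifnot(inherits(rec, "eeg_recording"))
  if (rec$reference != "common-average") rec <- rereference_common_average(rec)
  rel <- relative_band_powers(compute_band_powers(rec, resolution = resolution))
  vals <- as.vector(t(unclass(rel)))            # channel-major, band-minor
  names(vals) <- feature_names()
  dplyr::bind_cols(
    tibble::tibble(
      subject_id = subject_id,
      diagnosis = diagnosis,
      amyloid_label = amyloid_label,
      split = NA_character_,
      lineage = NA_character_
    ),
    tibble::as_tibble(as.list(vals))
  )
}

#' Extract a feature table from a cohort of recordings
#'
#' @param cohort A tibble as returned by [generate_cohort()]: columns
#'   `subject_id`, `diagnosis`, `amyloid_label` and a `recording`
#'   list-column.
#' @param resolution PSD resolution (Hz).
#' @return A feature table: one row per subject, 152 feature columns.
#' @export
extract_feature_table <- function(cohort, resolution = 0.25) {
  stopifnot(all(c("subject_id", "amyloid_label", "recording") %in% names(cohort)))
  purrr::pmap_dfr(
    list(cohort$recording, cohort$subject_id,
         cohort$diagnosis %||% rep(NA_character_, nrow(cohort)),
         cohort$amyloid_label),
    function(rec, id, dx, lab) extract_features(rec, id, dx, lab, resolution)
  )
}

#' The feature columns of a feature table
#' @param table A feature table.
#' @return Character vector of the 152 feature column names present.
#' @export
feature_cols <- function(table) intersect(feature_names(), names(table))
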