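#' The 19 scalp channels of the International 10-20 montage
#'
#' Canonical channel order used everywhere in the package: feature vectors
#' are flattened channel-major in this order.
#'
#' @format Character vector of length 19.
#' @export
eeg_channels <- c(
  "Fp1", "Fp2", "F7", "F3", "Fz", "F4", "F8",
  "T3", "C3", "Cz", "C4", "T4",
  "T5", "P3", "Pz", "P4", "T6",
  "O1", "O2"
)

#' The eight-band frequency scheme
#'
#' Returns the canonical band scheme: delta \[1,4), theta \[4,8),
#' alpha1 \[8,10), alpha2 \[10,12), beta1 \[12,15), beta2 \[15,20),
#' beta3 \[20,30), gamma \[30,45\]. Bands are half-open on the right except
#' gamma, which is closed at 45 Hz, so every frequency in \[1,45\] belongs to
#' exactly one band.
#'
#' @return A tibble with columns `band`, `low`, `high` (Hz), in canonical
#'   band order.
#' @export
#' @examples
#' band_scheme()
band_scheme <- function() {
  tibble::tibble(
    band = c("delta", "theta", "alpha1", "alpha2",
             "beta1", "beta2", "beta3", "gamma"),
    low  = c(1, 4, 8, 10, 12, 15, 20, 30),
    high = c(4, 8, 10, 12, 15, 20, 30, 45)
  )
}

#' Canonical band names
#' @return Character vector of length 8.
#' @export
eeg_bands <- function() band_scheme()$band

#' Canonical feature names
#'
#' The 152 feature identifiers in channel-major, band-minor order, e.g.
#' `"Fp1.delta", "Fp1.theta", ..., "O2.gamma"`.
#'
#' @return Character vector of length 152.
#' @export
#' @examples
#' head(feature_names())
#' length(feature_names())
feature_names <- function() {
  as.vector(t(outer(eeg_channels, eeg_bands(), paste, sep = ".")))
}

#' Assign frequencies to bands
#'
#' Half-open convention `[low, high)`; gamma closed at 45 Hz. Frequencies
#' outside \[1,45\] get `NA`.
#'
#' @param freq Numeric vector of frequencies (Hz).
#' @return Character vector of band names (or `NA`).
#' @export
band_of <- function(freq) {
  sch <- band_scheme()
  out <- rep(NA_character_, length(freq))
  for (i in seq_len(nrow(sch))) {
    hit <- freq >= sch$low[i] & freq < sch$high[i]
    out[hit] <- sch$band[i]
  }
  out[freq == 45] <- "gamma"
  out
}

#' Number of k-feature combinations from a pool of p features
#'
#' Exact binomial coefficient, the enumeration size of one exhaustive
#' search generation. For the full 152-feature pool:
#' `count_combinations(152, 2)` is 11,476 and `count_combinations(152, 5)`
#' is 632,671,880.
#'
#' @param p Pool size (non-negative integer).
#' @param k Combination dimension, `0 <= k <= p`.
#' @return The exact count as a double (exact for all values below 2^53).
#' @export
#' @examples
#' count_combinations(152, 2)
#' count_combinations(152, 5)
count_combinations <- function(p, k) {
  stopifnot(length(p) == 1, length(k) == 1, p >= 0, k >= 0,
            p == round(p), k == round(k))
  if (k > p) stop("k must not exceed p (asked for ", k, " of ", p, ")")
  round(choose(p, k))
}
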