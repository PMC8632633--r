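#' Stratified holdout split
#'
#' Randomly assigns a fraction of subjects to the test split within each
#' (diagnosis, amyloid_label) stratum. Per-stratum test counts are
#' largest-remainder apportionments of `round(fraction * n_total)`, so a
#' stratum of 35 at fraction 0.2 contributes exactly 7 test subjects.
#'
#' @param table An unsplit feature table.
#' @param fraction Test fraction in (0, 1).
#' @param seed Integer seed.
#' @return The table with `split` filled with `"train"` / `"test"`.
#' @export
holdout_split <- function(table, fraction = 0.2, seed = 1) {
  stopifnot(is.data.frame(table), fraction > 0, fraction < 1)
  if (any(!is.na(table$split))) stop("table already carries a split assignment")
  strata <- paste(table$diagnosis, table$amyloid_label, sep = "/")
  sizes <- table(strata)
  if (any(sizes < 2)) {
    stop("stratum with fewer than 2 subjects: ",
         paste(names(sizes)[sizes < 2], collapse = ", "))
  }
  # largest-remainder apportionment of the overall test count
  target <- round(fraction * nrow(table))
  quota <- fraction * as.vector(sizes)
  base <- floor(quota)
  rem <- target - sum(base)
  if (rem > 0) {
    ord <- order(quota - base, as.vector(sizes), decreasing = TRUE)
    base[ord[seq_len(rem)]] <- base[ord[seq_len(rem)]] + 1
  }
  names(base) <- names(sizes)
  table$split <- "train"
  with_seed(seed, {
    for (s in names(sizes)) {
      idx <- which(strata == s)
      take <- sample(idx, base[[s]])
      table$split[take] <- "test"
    }
  })
  tibble::as_tibble(table)
}

#' Split-half augmentation of amyloid-positive training subjects
#'
#' Each positive training subject's recording is divided into its first and
#' second temporal halves and each half's feature vector becomes a separate
#' training row, doubling the positive training count to rebalance the
#' classes. Lineage records the parent subject so downstream folds never
#' separate the two halves. Test rows and negative rows are untouched.
#'
#' If no recordings are available (feature-table-only workflows), rows are
#' duplicated without re-extraction — a degraded fallback flagged with a
#' warning.
#'
#' @param table A split feature table.
#' @param recordings Optional cohort tibble (see [generate_cohort()]) with
#'   `subject_id` and `recording` columns covering every positive training
#'   subject.
#' @param resolution PSD resolution for half-record feature extraction.
#' @return The augmented feature table.
#' @export
augment_positives <- function(table, recordings = NULL, resolution = 0.25) {
  stopifnot(is.data.frame(table))
  if (any(is.na(table$split))) stop("run holdout_split() first")
  pos <- table$split == "train" & table$amyloid_label == "positive"
  if (!any(pos)) return(tibble::as_tibble(table))
  parents <- table[pos, , drop = FALSE]
  if (is.null(recordings)) {
    warning("no recordings supplied: duplicating positive rows without ",
            "re-extraction (degraded feature-space augmentation)")
    halves <- purrr::map_dfr(seq_len(nrow(parents)), function(i) {
      row <- parents[i, ]
      dplyr::bind_rows(
        dplyr::mutate(row, subject_id = paste0(row$subject_id, ".h1"),
                      lineage = row$subject_id),
        dplyr::mutate(row, subject_id = paste0(row$subject_id, ".h2"),
                      lineage = row$subject_id)
      )
    })
  } else {
    stopifnot(all(c("subject_id", "recording") %in% names(recordings)))
    missing <- setdiff(parents$subject_id, recordings$subject_id)
    if (length(missing)) {
      stop("no recording for positive training subject(s): ",
           paste(missing, collapse = ", "))
    }
    halves <- purrr::map_dfr(seq_len(nrow(parents)), function(i) {
      row <- parents[i, ]
      rec <- recordings$recording[[match(row$subject_id, recordings$subject_id)]]
      hs <- split_halves(rec)
      purrr::imap_dfr(hs, function(h, tag) {
        fv <- extract_features(
          h, subject_id = paste0(row$subject_id, ".", ifelse(tag == "first", "h1", "h2")),
          diagnosis = row$diagnosis, amyloid_label = row$amyloid_label,
          resolution = resolution
        )
        fv$split <- row$split
        fv$lineage <- row$subject_id
        fv
      })
    })
  }
  dplyr::bind_rows(table[!pos, , drop = FALSE], halves)
}

#' Split-half spectral reliability of a recording
#'
#' Correlates each channel's Welch PSD over \[1,45\] Hz between the first
#' and second temporal halves of the recording. A recording passes the
#' screen when all 19 channel correlations exceed the threshold
#' (0.90 by default).
#'
#' @param rec An `eeg_recording` (re-referenced internally if needed).
#' @param resolution PSD resolution of the screen in Hz. The default,
#'   0.5 Hz, is coarser than the 0.25 Hz feature resolution: with 2 s
#'   windows each bin averages twice as many segments, so the screen
#'   reflects stationarity rather than per-bin estimator noise.
#' @param threshold Screening threshold on the per-channel correlation.
#' @return A tibble with columns `channel` and `correlation`, with
#'   attribute `pass` (logical: all correlations > threshold).
#' @export
split_half_reliability <- function(rec, resolution = 0.5, threshold = 0.90) {
  stopifnot(inherits(rec, "eeg_recording"))
  if (rec$reference != "common-average") rec <- rereference_common_average(rec)
  hs <- split_halves(rec)
  nwin <- rec$fs / resolution
  if (ncol(hs$first$samples) < nwin) {
    stop("recording too short for two PSD-valid halves")
  }
  cors <- vapply(eeg_channels, function(ch) {
    p1 <- welch_psd(hs$first$samples[ch, ], rec$fs, resolution)
    p2 <- welch_psd(hs$second$samples[ch, ], rec$fs, resolution)
    keep <- p1$freq >= 1 & p1$freq <= 45
    stats::cor(p1$psd[keep], p2$psd[keep])
  }, numeric(1))
  out <- tibble::tibble(channel = eeg_channels, correlation = unname(cors))
  attr(out, "pass") <- all(cors > threshold)
  out
}
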