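#' Write a feature table to CSV
#'
#' Plain CSV with the documented header: identifying columns then the 152
#' `channel.band` feature columns.
#'
#' @param table A feature table.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_feature_csv <- function(table, path) {
  readr::write_csv(table, path)
  invisible(path)
}

#' Read a feature table from CSV
#' @param path CSV written by [write_feature_csv()] (or any delimited
#'   table with `channel.band` feature columns).
#' @return A feature table tibble.
#' @export
read_feature_csv <- function(path) {
  tab <- readr::read_csv(path, show_col_types = FALSE)
  missing <- setdiff(feature_names(), names(tab))
  if (length(missing)) {
    stop("feature column(s) missing from ", path, ": ",
         paste(utils::head(missing, 5), collapse = ", "),
         if (length(missing) > 5) ", ..." else "")
  }
  for (col in c("split", "lineage")) {
    if (!col %in% names(tab)) tab[[col]] <- NA_character_
    tab[[col]] <- as.character(tab[[col]])   # all-NA columns parse as logical
  }
  tab
}

pad_ascii <- function(x, width) {
  x <- substr(as.character(x), 1, width)
  formatC(x, width = -width, flag = " ")
}

#' Write a recording as an EDF file
#'
#' European Data Format: 19 signals labelled with the 10-20 channel names,
#' one-second data records, 16-bit samples scaled to the recording's
#' physical range in microvolts.
#'
#' @param rec An `eeg_recording` (whole seconds are written; a trailing
#'   partial second is dropped).
#' @param path Output file.
#' @param patient_id,recording_id Header identification strings.
#' @return `path`, invisibly.
#' @export
write_edf <- function(rec, path, patient_id = "X", recording_id = "synthetic") {
  stopifnot(inherits(rec, "eeg_recording"))
  fs <- rec$fs
  if (abs(fs - round(fs)) > 1e-9) stop("EDF export needs an integer sampling rate")
  n_rec <- floor(ncol(rec$samples) / fs)
  if (n_rec < 1) stop("recording shorter than one EDF data record (1 s)")
  x <- rec$samples[, seq_len(n_rec * fs), drop = FALSE]
  # the physical range is written with two decimals in the header, so
  # quantize against that printed value, not the exact maximum
  pmax_ <- ceiling(max(abs(range(x)), 1e-6) * 100) / 100
  phys_min <- -pmax_
  phys_max <- pmax_
  dig_min <- -32768
  dig_max <- 32767
  ns <- nrow(x)
  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- paste0(
    pad_ascii("0", 8), pad_ascii(patient_id, 80), pad_ascii(recording_id, 80),
    pad_ascii("01.01.00", 8), pad_ascii("00.00.00", 8),
    pad_ascii(256 * (1 + ns), 8), pad_ascii("", 44),
    pad_ascii(n_rec, 8), pad_ascii(1, 8), pad_ascii(ns, 4)
  )
  sig <- paste0(
    paste(pad_ascii(paste("EEG", rownames(x)), 16), collapse = ""),
    paste(rep(pad_ascii("", 80), ns), collapse = ""),
    paste(rep(pad_ascii("uV", 8), ns), collapse = ""),
    paste(rep(pad_ascii(sprintf("%.2f", phys_min), 8), ns), collapse = ""),
    paste(rep(pad_ascii(sprintf("%.2f", phys_max), 8), ns), collapse = ""),
    paste(rep(pad_ascii(dig_min, 8), ns), collapse = ""),
    paste(rep(pad_ascii(dig_max, 8), ns), collapse = ""),
    paste(rep(pad_ascii("", 80), ns), collapse = ""),
    paste(rep(pad_ascii(fs, 8), ns), collapse = ""),
    paste(rep(pad_ascii("", 32), ns), collapse = "")
  )
  writeChar(paste0(hdr, sig), con, eos = NULL, useBytes = TRUE)
  scale <- (dig_max - dig_min) / (phys_max - phys_min)
  for (r in seq_len(n_rec)) {
    cols <- ((r - 1) * fs + 1):(r * fs)
    dig <- round((t(x[, cols]) - phys_min) * scale + dig_min)
    storage.mode(dig) <- "integer"
    writeBin(as.vector(dig), con, size = 2, endian = "little")
  }
  invisible(path)
}

#' Read an EDF file as a recording
#'
#' Minimal EDF reader for continuous 19-channel recordings with a uniform
#' sampling rate (as written by [write_edf()] or standard clinical
#' exporters). Channel labels may carry an `EEG ` prefix.
#'
#' @param path EDF file.
#' @return An `eeg_recording` tagged `"as-recorded"`.
#' @export
read_edf <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(n) readChar(con, n, useBytes = TRUE)
  rd(8); rd(80); rd(80); rd(8); rd(8)
  rd(8); rd(44)
  n_rec <- as.integer(rd(8))
  rec_dur <- as.numeric(rd(8))
  ns <- as.integer(rd(4))
  fld <- function(width) vapply(seq_len(ns), function(i) trimws(rd(width)), character(1))
  labels <- sub("^EEG[ .]*", "", fld(16))
  fld(80); fld(8)
  phys_min <- as.numeric(fld(8))
  phys_max <- as.numeric(fld(8))
  dig_min <- as.numeric(fld(8))
  dig_max <- as.numeric(fld(8))
  fld(80)
  spr <- as.integer(fld(8))
  fld(32)
  if (length(unique(spr)) != 1) stop("mixed sampling rates are not supported")
  fs <- spr[1] / rec_dur
  out <- matrix(0, nrow = ns, ncol = n_rec * spr[1], dimnames = list(labels, NULL))
  gain <- (phys_max - phys_min) / (dig_max - dig_min)
  for (r in seq_len(n_rec)) {
    for (s in seq_len(ns)) {
      dig <- readBin(con, "integer", n = spr[s], size = 2, endian = "little")
      out[s, ((r - 1) * spr[s] + 1):(r * spr[s])] <-
        (dig - dig_min[s]) * gain[s] + phys_min[s]
    }
  }
  eeg_recording(out, fs, reference = "as-recorded")
}

#' Write a cohort as EDF files plus a manifest
#'
#' One EDF per subject plus `manifest.csv` with columns `subject_id`,
#' `diagnosis`, `amyloid_label`, `file`.
#'
#' @param cohort Cohort tibble from [generate_cohort()].
#' @param dir Output directory (created if needed).
#' @return Path to the manifest, invisibly.
#' @export
write_cohort_edf <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- vapply(seq_len(nrow(cohort)), function(i) {
    f <- file.path(dir, paste0(cohort$subject_id[i], ".edf"))
    write_edf(cohort$recording[[i]], f, patient_id = cohort$subject_id[i])
    f
  }, character(1))
  manifest <- dplyr::select(cohort, -dplyr::any_of("recording"))
  manifest$file <- files
  mp <- file.path(dir, "manifest.csv")
  readr::write_csv(manifest, mp)
  invisible(mp)
}

#' Cohort preparation report
#'
#' Summarizes a split (optionally augmented) feature table: per-stratum
#' train/test counts and augmentation totals, optionally joined with
#' per-subject split-half reliability screens.
#'
#' @param table A split feature table.
#' @param recordings Optional cohort tibble; when given, each recording's
#'   [split_half_reliability()] minimum correlation and pass flag are
#'   reported.
#' @param path Optional path; when given, the report is also written as
#'   JSON.
#' @return A list with elements `strata` (tibble), `n_augmented`,
#'   and optionally `reliability` (tibble), invisibly when writing.
#' @export
prep_report <- function(table, recordings = NULL, path = NULL) {
  strata <- table |>
    dplyr::count(.data$diagnosis, .data$amyloid_label, .data$split) |>
    tidyr::pivot_wider(names_from = "split", values_from = "n",
                       values_fill = 0L)
  out <- list(
    strata = strata,
    n_rows = nrow(table),
    n_augmented = sum(!is.na(table$lineage))
  )
  if (!is.null(recordings)) {
    out$reliability <- purrr::map_dfr(seq_len(nrow(recordings)), function(i) {
      rel <- split_half_reliability(recordings$recording[[i]])
      tibble::tibble(subject_id = recordings$subject_id[i],
                     min_correlation = min(rel$correlation),
                     pass = attr(rel, "pass"))
    })
  }
  if (!is.null(path)) {
    jsonlite::write_json(out, path, dataframe = "rows", auto_unbox = TRUE,
                         digits = NA)
    return(invisible(out))
  }
  out
}

#' Write an ensemble evaluation as JSON
#'
#' Serializes the confusion-matrix report, the cutoff, and the
#' per-subject scores of an `ensemble_evaluation`.
#'
#' @param evaluation An `ensemble_evaluation`.
#' @param path Output JSON file.
#' @return `path`, invisibly.
#' @export
write_evaluation_json <- function(evaluation, path) {
  stopifnot(inherits(evaluation, "ensemble_evaluation"))
  jsonlite::write_json(
    list(report = evaluation$report,
         cutoff = evaluation$cutoff$cutoff,
         cutoff_method = evaluation$cutoff$method,
         scores = evaluation$scores),
    path, dataframe = "rows", auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}
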