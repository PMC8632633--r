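#' Per-feature group comparison between amyloid-positive and -negative
#'
#' Welch's two-sample t-test on every feature column. Augmented split-half
#' rows are collapsed to one row per parent subject (the mean of the
#' halves) before testing, so a subject is never counted twice.
#'
#' @param table A feature table.
#' @param on `"train"` (default) to test training rows only, `"all"` for
#'   every row. Unsplit tables are always tested in full.
#' @return A tibble with one row per feature: `feature`, `channel`, `band`,
#'   `mean_positive`, `mean_negative`, `t`, `p`, `direction`
#'   (`"higher"`/`"lower"` in the positive group).
#' @export
feature_group_tests <- function(table, on = c("train", "all")) {
  on <- match.arg(on)
  stopifnot(is.data.frame(table))
  if (on == "train" && !any(is.na(table$split))) {
    table <- dplyr::filter(table, .data$split == "train")
  }
  table <- collapse_augmented(table)
  fc <- feature_cols(table)
  pos <- table$amyloid_label == "positive"
  neg <- table$amyloid_label == "negative"
  if (!any(pos) || !any(neg)) stop("both amyloid groups must be non-empty")
  tstat <- pval <- mpos <- mneg <- numeric(length(fc))
  for (i in seq_along(fc)) {
    x <- table[[fc[i]]][pos]
    y <- table[[fc[i]]][neg]
    mpos[i] <- mean(x)
    mneg[i] <- mean(y)
    if (stats::sd(x) == 0 && stats::sd(y) == 0) {
      if (!isTRUE(all.equal(mean(x), mean(y)))) {
        stop("zero within-group variance on feature ", fc[i])
      }
      tstat[i] <- 0
      pval[i] <- 1
    } else {
      tt <- stats::t.test(x, y)
      tstat[i] <- unname(tt$statistic)
      pval[i] <- tt$p.value
    }
  }
  parts <- strsplit(fc, ".", fixed = TRUE)
  tibble::tibble(
    feature = fc,
    channel = vapply(parts, `[`, character(1), 1),
    band = vapply(parts, `[`, character(1), 2),
    mean_positive = mpos, mean_negative = mneg,
    t = tstat, p = pval,
    direction = ifelse(mpos >= mneg, "higher", "lower")
  )
}

# Replace each lineage group (two split halves) by its parent-mean row.
collapse_augmented <- function(table) {
  if (!any(!is.na(table$lineage))) return(table)
  fc <- feature_cols(table)
  aug <- dplyr::filter(table, !is.na(.data$lineage))
  rest <- dplyr::filter(table, is.na(.data$lineage))
  collapsed <- aug |>
    dplyr::group_by(.data$lineage, .data$diagnosis, .data$amyloid_label, .data$split) |>
    dplyr::summarise(dplyr::across(dplyr::all_of(fc), mean), .groups = "drop") |>
    dplyr::rename(subject_id = "lineage") |>
    dplyr::mutate(lineage = NA_character_)
  dplyr::bind_rows(rest, collapsed[, names(rest)])
}

#' Significant-feature topography
#'
#' The tabular content of a significance topomap: per band, the channels
#' whose group difference is significant at `alpha`, annotated by
#' direction.
#'
#' @param stats Output of [feature_group_tests()].
#' @param alpha Significance level; features with `p < alpha` are flagged.
#' @param adjust P-value adjustment method passed to [stats::p.adjust()]
#'   (`"none"` by default; `"BH"` for Benjamini-Hochberg).
#' @return A tibble `band`, `channel`, `direction`, `t`, `p` (adjusted if
#'   requested), ordered by band then channel canonically.
#' @export
significant_topography <- function(stats, alpha = 0.05, adjust = "none") {
  stopifnot(is.data.frame(stats), alpha >= 0, alpha <= 1)
  stats$p_used <- stats::p.adjust(stats$p, method = adjust)
  out <- stats |>
    dplyr::filter(.data$p_used < alpha) |>
    dplyr::transmute(
      band = factor(.data$band, levels = eeg_bands()),
      channel = factor(.data$channel, levels = eeg_channels),
      direction = .data$direction, t = .data$t, p = .data$p_used
    ) |>
    dplyr::arrange(.data$band, .data$channel) |>
    dplyr::mutate(band = as.character(.data$band), channel = as.character(.data$channel))
  out
}

#' Heat-map view of per-feature group statistics
#'
#' Channel-by-band tile plot of the t statistic, the tabular counterpart
#' of a significance topomap.
#'
#' @param stats Output of [feature_group_tests()].
#' @param alpha Features with `p < alpha` get a dot.
#' @return A ggplot object.
#' @export
plot_topography <- function(stats, alpha = 0.05) {
  stats <- dplyr::mutate(
    stats,
    channel = factor(.data$channel, levels = rev(eeg_channels)),
    band = factor(.data$band, levels = eeg_bands())
  )
  ggplot2::ggplot(stats, ggplot2::aes(x = .data$band, y = .data$channel,
                                      fill = .data$t)) +
    ggplot2::geom_tile() +
    ggplot2::geom_point(data = dplyr::filter(stats, .data$p < alpha), size = 1) +
    ggplot2::scale_fill_gradient2(low = "steelblue", mid = "white", high = "firebrick") +
    ggplot2::labs(x = "frequency band", y = "channel", fill = "t",
                  title = "Group difference in relative band power",
                  subtitle = paste0("dots: p < ", alpha)) +
    ggplot2::theme_minimal()
}
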