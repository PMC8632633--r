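#' Run the full amyloid-classification pipeline on a feature table
#'
#' Convenience wrapper chaining the stages: stratified holdout, split-half
#' augmentation of positive training subjects, the generational feature
#' search, sub-model selection, cutoff fitting on training-side scores
#' (one collapsed row per subject), and strict holdout evaluation.
#'
#' @param table An unsplit feature table.
#' @param cfg A [search_config()].
#' @param recordings Optional cohort tibble of recordings for signal-level
#'   augmentation; without it augmentation falls back to row duplication.
#' @param holdout_fraction Test fraction (default 0.2).
#' @param n_submodels Ensemble size (default 20).
#' @param cutoff A fixed cutoff in \[0,1\], or `NULL` (default) to fit
#'   Youden's J on training scores.
#' @param augment Apply split-half augmentation (default TRUE).
#' @return An `amyloid_pipeline`: list with `table` (split, augmented),
#'   `search`, `ensemble`, `cutoff`, `evaluation`.
#' @export
amyloid_pipeline <- function(table, cfg = search_config(), recordings = NULL,
                             holdout_fraction = 0.2, n_submodels = 20,
                             cutoff = NULL, augment = TRUE) {
  table <- holdout_split(table, holdout_fraction, seed = cfg$seed)
  if (augment) {
    table <- if (is.null(recordings)) {
      suppressWarnings(augment_positives(table))
    } else {
      augment_positives(table, recordings)
    }
  }
  search <- run_heuristic(table, cfg)
  if (nrow(search$candidates) == 0) {
    stop("search retained no candidate models; weaken retention_accuracy ",
         "or strengthen the planted effect")
  }
  ensemble <- select_submodels(table, search$candidates, cfg,
                               n_submodels = n_submodels)
  train_subjects <- collapse_augmented(training_rows(table))
  train_scores <- ensemble_score(ensemble, train_subjects)
  cut <- if (is.null(cutoff)) {
    fit_cutoff(train_scores$score, train_subjects$amyloid_label)
  } else {
    fit_cutoff(method = "fixed", cutoff = cutoff)
  }
  test <- dplyr::filter(table, .data$split == "test")
  evaluation <- evaluate_ensemble(ensemble, test, cut)
  structure(
    list(table = table, search = search, ensemble = ensemble,
         cutoff = cut, evaluation = evaluation),
    class = "amyloid_pipeline"
  )
}

#' @export
print.amyloid_pipeline <- function(x, ...) {
  cat("<amyloid_pipeline>\n")
  print(x$search)
  print(x$ensemble)
  print(x$evaluation)
  invisible(x)
}

#' @exportS3Method generics::glance
glance.amyloid_pipeline <- function(x, ...) {
  dplyr::bind_cols(
    glance(x$evaluation),
    tibble::tibble(n_candidates = nrow(x$search$candidates),
                   n_submodels = x$ensemble$n)
  )
}
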