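fit_submodel <- function(table, combo, cfg) {
  X <- as.matrix(table[, combo, drop = FALSE])
  y <- factor(table$amyloid_label, levels = c("negative", "positive"))
  mu <- colMeans(X)
  sd <- apply(X, 2, stats::sd)
  sd[sd == 0] <- 1
  Xs <- sweep(sweep(X, 2, mu), 2, sd, "/")
  fit <- if (cfg$classifier == "svm") {
    e1071::svm(Xs, y, kernel = "linear", cost = cfg$cost, scale = FALSE)
  } else {
    pos <- y == "positive"
    m1 <- colMeans(Xs[pos, , drop = FALSE])
    m0 <- colMeans(Xs[!pos, , drop = FALSE])
    S <- (crossprod(sweep(Xs[pos, , drop = FALSE], 2, m1)) +
            crossprod(sweep(Xs[!pos, , drop = FALSE], 2, m0))) / (nrow(Xs) - 2)
    w <- solve(S + diag(1e-8, ncol(S)), m1 - m0)
    list(w = w, thr = 0.5 * sum(w * (m1 + m0)) - log(sum(pos) / sum(!pos)))
  }
  list(combo = combo, center = mu, scale = sd, fit = fit,
       classifier = cfg$classifier)
}

predict_submodel <- function(sm, newdata) {
  X <- as.matrix(newdata[, sm$combo, drop = FALSE])
  Xs <- sweep(sweep(X, 2, sm$center), 2, sm$scale, "/")
  if (sm$classifier == "svm") {
    stats::predict(sm$fit, Xs)
  } else {
    factor(ifelse((Xs %*% sm$fit$w)[, 1] > sm$fit$thr, "positive", "negative"),
           levels = c("negative", "positive"))
  }
}

#' Select and fit the ensemble's sub-models
#'
#' Ranks the retained candidate models and refits the best `n_submodels`
#' (20 by default) on the full training data. The default `"inner"` mode
#' carves a stratified, lineage-grouped validation subset out of the
#' training rows and ranks candidates by the worse of CV accuracy and
#' inner-validation accuracy, so the holdout is never touched. The
#' `"holdout"` mode instead ranks by the worse of CV accuracy and accuracy
#' on a supplied holdout table — the study-style selection that reuses the
#' test data, and is labelled as such on the returned object.
#'
#' @param table The training feature table (rows with `split == "train"`
#'   are used).
#' @param candidates Candidate model records ([run_heuristic()]'s
#'   `candidates` or a compatible tibble with `combo` and `cv_accuracy`).
#' @param cfg A [search_config()] (classifier settings and seed).
#' @param n_submodels Number of sub-models (default 20); fewer candidates
#'   than requested are used in full, with a warning.
#' @param mode `"inner"` (default) or `"holdout"`.
#' @param holdout Holdout feature table, required for `mode = "holdout"`.
#' @param valid_fraction Fraction of training lineage groups carved out as
#'   inner validation (default 0.25).
#' @return An `eeg_ensemble`.
#' @export
select_submodels <- function(table, candidates, cfg = search_config(),
                             n_submodels = 20, mode = c("inner", "holdout"),
                             holdout = NULL, valid_fraction = 0.25) {
  mode <- match.arg(mode)
  train <- training_rows(table)
  if (!is.data.frame(candidates) || nrow(candidates) == 0) {
    stop("no candidate models to select from")
  }
  ids <- vapply(candidates$combo, paste, character(1), collapse = "+")
  candidates <- candidates[!duplicated(ids), ]
  if (mode == "holdout") {
    if (is.null(holdout)) stop("mode = \"holdout\" needs a holdout table")
    fit_tab <- train
    val_tab <- holdout
  } else {
    root <- ifelse(is.na(train$lineage), train$subject_id, train$lineage)
    groups <- unique(root)
    glabel <- train$amyloid_label[match(groups, root)]
    val_groups <- character(0)
    with_seed(cfg$seed + 7L, {
      for (cl in unique(glabel)) {
        g <- groups[glabel == cl]
        n_val <- max(1L, round(valid_fraction * length(g)))
        val_groups <- c(val_groups, sample(g, n_val))
      }
    })
    val_tab <- train[root %in% val_groups, ]
    fit_tab <- train[!root %in% val_groups, ]
  }
  val_acc <- vapply(candidates$combo, function(combo) {
    sm <- fit_submodel(fit_tab, combo, cfg)
    mean(predict_submodel(sm, val_tab) == val_tab$amyloid_label)
  }, numeric(1))
  score <- pmin(candidates$cv_accuracy, val_acc)
  ord <- order(-score, -candidates$cv_accuracy, seq_len(nrow(candidates)))
  n_take <- min(n_submodels, nrow(candidates))
  if (n_take < n_submodels) {
    warning("only ", n_take, " candidate model(s) available for a ",
            n_submodels, "-sub-model ensemble")
  }
  chosen <- candidates[ord[seq_len(n_take)], ]
  submodels <- lapply(chosen$combo, fit_submodel, table = train, cfg = cfg)
  structure(
    list(submodels = submodels, n = n_take, mode = mode,
         selection = dplyr::mutate(chosen, selection_accuracy = val_acc[ord[seq_len(n_take)]]),
         training_ids = unique(ifelse(is.na(train$lineage),
                                      train$subject_id, train$lineage)),
         cfg = cfg),
    class = "eeg_ensemble"
  )
}

#' @export
print.eeg_ensemble <- function(x, ...) {
  cat(sprintf("<eeg_ensemble> %d sub-model(s), %s classifier, selection mode: %s%s\n",
              x$n, x$cfg$classifier, x$mode,
              if (x$mode == "holdout") " (selection reused the holdout)" else ""))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.eeg_ensemble <- function(x, ...) {
  tibble::tibble(
    submodel = seq_len(x$n),
    combo_id = vapply(x$selection$combo, paste, character(1), collapse = "+"),
    k = lengths(x$selection$combo),
    cv_accuracy = x$selection$cv_accuracy,
    selection_accuracy = x$selection$selection_accuracy
  )
}

#' Score subjects with the voting ensemble
#'
#' Each sub-model votes positive or negative; the score is the fraction of
#' positive votes, taking values `0, 1/n, ..., 1`. All 20 positive votes
#' score 1.0, half score 0.5, none score 0.
#'
#' @param ensemble An `eeg_ensemble`.
#' @param newdata A feature table (any rows).
#' @return The identifying columns of `newdata` plus a `score` column.
#' @export
ensemble_score <- function(ensemble, newdata) {
  stopifnot(inherits(ensemble, "eeg_ensemble"))
  needed <- unique(unlist(lapply(ensemble$submodels, `[[`, "combo")))
  missing <- setdiff(needed, names(newdata))
  if (length(missing)) {
    stop("newdata lacks feature(s): ", paste(missing, collapse = ", "))
  }
  votes <- vapply(ensemble$submodels,
                  function(sm) predict_submodel(sm, newdata) == "positive",
                  logical(nrow(newdata)))
  votes <- matrix(votes, nrow = nrow(newdata))
  keep <- intersect(c("subject_id", "diagnosis", "amyloid_label", "split"),
                    names(newdata))
  dplyr::bind_cols(newdata[, keep, drop = FALSE],
                   tibble::tibble(score = rowMeans(votes)))
}

#' Choose a score cutoff
#'
#' `method = "youden"` maximizes Youden's J (sensitivity + specificity - 1)
#' over the observed score grid under the `score >= cutoff -> positive`
#' rule, breaking ties toward the lower cutoff (favoring sensitivity); if
#' no cutoff beats J = 0 the fallback is 0.5. `method = "fixed"` echoes a
#' user-supplied cutoff, e.g. a published one.
#'
#' @param scores Numeric vote-fraction scores in \[0,1\].
#' @param labels Matching `"positive"`/`"negative"` labels (unused for
#'   `method = "fixed"`).
#' @param method `"youden"` or `"fixed"`.
#' @param cutoff The fixed cutoff when `method = "fixed"`.
#' @return A `cutoff_config`: list with `cutoff`, `method`, `j`.
#' @export
fit_cutoff <- function(scores, labels = NULL, method = c("youden", "fixed"),
                       cutoff = NULL) {
  method <- match.arg(method)
  if (method == "fixed") {
    stopifnot(is.numeric(cutoff), cutoff >= 0, cutoff <= 1)
    return(structure(list(cutoff = cutoff, method = "fixed", j = NA_real_),
                     class = "cutoff_config"))
  }
  stopifnot(length(scores) == length(labels))
  if (length(unique(labels)) < 2) stop("both labels needed to fit a cutoff")
  pos <- labels == "positive"
  grid <- sort(unique(scores))
  j <- vapply(grid, function(cut) {
    sens <- mean(scores[pos] >= cut)
    spec <- mean(scores[!pos] < cut)
    sens + spec - 1
  }, numeric(1))
  if (max(j) <= 0) {
    return(structure(list(cutoff = 0.5, method = "youden", j = 0),
                     class = "cutoff_config"))
  }
  best <- grid[which(j == max(j))][1]   # ties -> lowest cutoff
  structure(list(cutoff = best, method = "youden", j = max(j)),
            class = "cutoff_config")
}

#' @export
print.cutoff_config <- function(x, ...) {
  cat(sprintf("<cutoff_config> cutoff %.3f (%s%s)\n", x$cutoff, x$method,
              if (!is.na(x$j)) sprintf(", J = %.3f", x$j) else ""))
  invisible(x)
}

#' Evaluation metrics from a confusion matrix
#'
#' @param tp,fp,fn,tn Confusion-matrix counts (positive = amyloid
#'   positive). Both class margins must be non-empty.
#' @return A one-row tibble: the four counts plus `sensitivity`,
#'   `specificity`, `accuracy`, `balanced_accuracy` as proportions.
#' @export
#' @examples
#' # e.g. 6/3/1/25 gives 85.7% sensitivity, 89.3% specificity,
#' # 88.6% accuracy, 87.5% balanced accuracy
#' metrics_from_confusion(tp = 6, fp = 3, fn = 1, tn = 25)
metrics_from_confusion <- function(tp, fp, fn, tn) {
  counts <- c(tp, fp, fn, tn)
  stopifnot(length(counts) == 4, all(counts >= 0), all(counts == round(counts)))
  if (tp + fn == 0) stop("no positive cases (tp + fn = 0)")
  if (tn + fp == 0) stop("no negative cases (tn + fp = 0)")
  sens <- tp / (tp + fn)
  spec <- tn / (tn + fp)
  tibble::tibble(
    tp = tp, fp = fp, fn = fn, tn = tn,
    sensitivity = sens, specificity = spec,
    accuracy = (tp + tn) / sum(counts),
    balanced_accuracy = (sens + spec) / 2
  )
}

#' Evaluate an ensemble on held-out subjects
#'
#' Scores every test row, classifies with the `score >= cutoff` rule,
#' builds the confusion matrix and derives the evaluation metrics. In
#' strict mode (default) the test table is audited first: every row must
#' be tagged `split == "test"` and no test subject may share a lineage
#' with a training subject.
#'
#' @param ensemble An `eeg_ensemble`.
#' @param test The test feature table.
#' @param cutoff A `cutoff_config` (or a bare numeric cutoff).
#' @param strict Audit the split before scoring (default TRUE).
#' @return An `ensemble_evaluation`: list with `report` (see
#'   [metrics_from_confusion()]), `scores` (per-subject tibble with
#'   `score`, `prediction`, `truth`), `cutoff`.
#' @export
evaluate_ensemble <- function(ensemble, test, cutoff, strict = TRUE) {
  stopifnot(inherits(ensemble, "eeg_ensemble"))
  if (is.numeric(cutoff)) cutoff <- fit_cutoff(method = "fixed", cutoff = cutoff)
  if (strict) {
    if (any(is.na(test$split)) || any(test$split != "test")) {
      stop("strict evaluation: every row must carry split == \"test\"")
    }
    roots <- unique(ifelse(is.na(test$lineage), test$subject_id, test$lineage))
    leak <- intersect(roots, ensemble$training_ids)
    if (length(leak)) {
      stop("strict evaluation: test subject(s) seen in training: ",
           paste(leak, collapse = ", "))
    }
  }
  scored <- ensemble_score(ensemble, test)
  scored$prediction <- ifelse(scored$score >= cutoff$cutoff, "positive", "negative")
  scored$truth <- test$amyloid_label
  report <- metrics_from_confusion(
    tp = sum(scored$prediction == "positive" & scored$truth == "positive"),
    fp = sum(scored$prediction == "positive" & scored$truth == "negative"),
    fn = sum(scored$prediction == "negative" & scored$truth == "positive"),
    tn = sum(scored$prediction == "negative" & scored$truth == "negative")
  )
  structure(list(report = report, scores = scored, cutoff = cutoff),
            class = "ensemble_evaluation")
}

#' @export
print.ensemble_evaluation <- function(x, ...) {
  r <- x$report
  cat(sprintf("<ensemble_evaluation> cutoff %.2f on %d subject(s)\n",
              x$cutoff$cutoff, nrow(x$scores)))
  cat(sprintf("                 true positive  true negative\n"))
  cat(sprintf("  pred positive  %13d  %13d\n", r$tp, r$fp))
  cat(sprintf("  pred negative  %13d  %13d\n", r$fn, r$tn))
  cat(sprintf(
    "  sensitivity %.1f%% | specificity %.1f%% | accuracy %.1f%% | balanced %.1f%%\n",
    100 * r$sensitivity, 100 * r$specificity, 100 * r$accuracy,
    100 * r$balanced_accuracy
  ))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.ensemble_evaluation <- function(x, ...) x$scores

#' @exportS3Method generics::glance
glance.ensemble_evaluation <- function(x, ...) {
  dplyr::mutate(x$report, cutoff = x$cutoff$cutoff)
}

#' @exportS3Method ggplot2::autoplot
autoplot.ensemble_evaluation <- function(object, ...) {
  ggplot2::ggplot(object$scores,
                  ggplot2::aes(x = .data$truth, y = .data$score)) +
    ggplot2::geom_boxplot(outlier.shape = NA, width = 0.5) +
    ggplot2::geom_jitter(width = 0.12, height = 0, alpha = 0.6) +
    ggplot2::geom_hline(yintercept = object$cutoff$cutoff, linetype = "dashed") +
    ggplot2::scale_y_continuous(limits = c(0, 1)) +
    ggplot2::labs(x = "amyloid status", y = "ensemble vote score",
                  title = "Amyloid classification score by group",
                  subtitle = sprintf("dashed line: cutoff %.2f", object$cutoff$cutoff)) +
    ggplot2::theme_minimal()
}
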