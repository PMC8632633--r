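#' Configure the generational feature search
#'
#' @param k_max Largest combination dimension searched (default 5).
#' @param k_exhaustive Largest dimension enumerated on the full feature
#'   pool (default 3); higher dimensions run on frequency-reduced pools.
#' @param top_fraction Fraction of each generation's models kept as "good
#'   models" for the feature-frequency tally (default 0.01).
#' @param top_min Floor on the number of good models per generation
#'   (default 50).
#' @param top_count Fixed number of good models, overriding the
#'   fraction/floor rule when set.
#' @param pool_size Named numeric vector mapping a dimension (as a string,
#'   e.g. `"4"`) to the candidate-feature budget of that generation.
#'   Defaults to 40 features at k = 4 and 30 at k = 5.
#' @param retention_accuracy CV-accuracy threshold a model must exceed to
#'   be retained as an ensemble candidate (default 0.75).
#' @param folds Cross-validation fold count (default 5).
#' @param classifier `"svm"` (linear-kernel SVM, the default) or `"lda"`
#'   (pooled-covariance linear discriminant, a fast option for large
#'   seeded experiments).
#' @param cost SVM regularization constant (default 1).
#' @param max_models Evaluation budget per generation; a generation whose
#'   enumeration would exceed it refuses to run and asks for a smaller
#'   pool.
#' @param seed Integer seed controlling fold assignment.
#' @return A `search_config`.
#' @export
search_config <- function(k_max = 5, k_exhaustive = 3,
                          top_fraction = 0.01, top_min = 50, top_count = NULL,
                          pool_size = c("4" = 40, "5" = 30),
                          retention_accuracy = 0.75, folds = 5,
                          classifier = c("svm", "lda"), cost = 1,
                          max_models = 2e5, seed = 1) {
  classifier <- match.arg(classifier)
  stopifnot(k_exhaustive >= 1, k_exhaustive <= k_max,
            retention_accuracy > 0.5, retention_accuracy <= 1,
            folds >= 2, cost > 0)
  structure(
    list(k_max = k_max, k_exhaustive = k_exhaustive,
         top_fraction = top_fraction, top_min = top_min, top_count = top_count,
         pool_size = pool_size, retention_accuracy = retention_accuracy,
         folds = folds, classifier = classifier, cost = cost,
         max_models = max_models, seed = as.integer(seed)),
    class = "search_config"
  )
}

# Lineage-grouped, class-stratified fold assignment. The two split halves
# of one subject always share a fold. Retries with an incremented seed if
# any fold's training part lacks a class.
make_cv_folds <- function(table, folds, seed, max_retries = 20) {
  root <- ifelse(is.na(table$lineage), table$subject_id, table$lineage)
  groups <- unique(root)
  glabel <- table$amyloid_label[match(groups, root)]
  for (try in 0:max_retries) {
    gf <- integer(length(groups))
    with_seed(seed + try, {
      for (cl in unique(glabel)) {
        idx <- which(glabel == cl)
        gf[sample(idx)] <- rep_len(seq_len(folds), length(idx))
      }
    })
    fold <- gf[match(root, groups)]
    ok <- all(vapply(seq_len(folds), function(f) {
      length(unique(table$amyloid_label[fold != f])) == 2
    }, logical(1)))
    if (ok) return(fold)
  }
  stop("could not build ", folds, "-fold CV with both classes in every ",
       "training part; groups per class: ",
       paste(table(glabel), collapse = "/"))
}

# Precompute per-fold standardized matrices once, so evaluating a feature
# combination is just a column subset plus a classifier fit.
build_evaluator <- function(table, cfg) {
  fc <- feature_cols(table)
  X <- as.matrix(table[, fc])
  y <- factor(table$amyloid_label, levels = c("negative", "positive"))
  if (any(is.na(y))) stop("all rows need an amyloid label")
  fold <- make_cv_folds(table, cfg$folds, cfg$seed)
  folds <- lapply(seq_len(cfg$folds), function(f) {
    tr <- fold != f
    mu <- colMeans(X[tr, , drop = FALSE])
    sd <- apply(X[tr, , drop = FALSE], 2, stats::sd)
    sd[sd == 0] <- 1
    list(
      Xtr = sweep(sweep(X[tr, , drop = FALSE], 2, mu), 2, sd, "/"),
      Xte = sweep(sweep(X[!tr, , drop = FALSE], 2, mu), 2, sd, "/"),
      ytr = y[tr], yte = y[!tr]
    )
  })
  if (cfg$classifier == "lda") {
    # per-fold class cross-products, so each combo needs only a k x k solve
    pre <- lapply(folds, function(fd) {
      pos <- fd$ytr == "positive"
      X1 <- fd$Xtr[pos, , drop = FALSE]
      X0 <- fd$Xtr[!pos, , drop = FALSE]
      list(P1 = crossprod(X1), P0 = crossprod(X0),
           s1 = colSums(X1), s0 = colSums(X0),
           n1 = nrow(X1), n0 = nrow(X0),
           Xte = fd$Xte, ytepos = fd$yte == "positive")
    })
    eval_cols <- function(cols) {
      acc <- numeric(length(pre))
      tp <- fp <- fn <- tn <- 0
      for (f in seq_along(pre)) {
        pd <- pre[[f]]
        m1 <- pd$s1[cols] / pd$n1
        m0 <- pd$s0[cols] / pd$n0
        S <- (pd$P1[cols, cols, drop = FALSE] - pd$n1 * tcrossprod(m1) +
                pd$P0[cols, cols, drop = FALSE] - pd$n0 * tcrossprod(m0)) /
          (pd$n1 + pd$n0 - 2)
        w <- solve(S + diag(1e-8, length(cols)), m1 - m0)
        thr <- 0.5 * sum(w * (m1 + m0)) - log(pd$n1 / pd$n0)
        predpos <- (pd$Xte[, cols, drop = FALSE] %*% w)[, 1] > thr
        acc[f] <- mean(predpos == pd$ytepos)
        tp <- tp + sum(predpos & pd$ytepos)
        fp <- fp + sum(predpos & !pd$ytepos)
        fn <- fn + sum(!predpos & pd$ytepos)
        tn <- tn + sum(!predpos & !pd$ytepos)
      }
      c(cv_accuracy = mean(acc),
        cv_sensitivity = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
        cv_specificity = if (tn + fp > 0) tn / (tn + fp) else NA_real_)
    }
    return(list(features = fc, eval_cols = eval_cols))
  }
  list(
    features = fc,
    eval_cols = function(cols) {
      acc <- numeric(length(folds))
      tp <- fp <- fn <- tn <- 0
      for (f in seq_along(folds)) {
        fd <- folds[[f]]
        m <- e1071::svm(fd$Xtr[, cols, drop = FALSE], fd$ytr,
                        kernel = "linear", cost = cfg$cost, scale = FALSE)
        pred <- stats::predict(m, fd$Xte[, cols, drop = FALSE])
        acc[f] <- mean(pred == fd$yte)
        tp <- tp + sum(pred == "positive" & fd$yte == "positive")
        fp <- fp + sum(pred == "positive" & fd$yte == "negative")
        fn <- fn + sum(pred == "negative" & fd$yte == "positive")
        tn <- tn + sum(pred == "negative" & fd$yte == "negative")
      }
      c(cv_accuracy = mean(acc),
        cv_sensitivity = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
        cv_specificity = if (tn + fp > 0) tn / (tn + fp) else NA_real_)
    }
  )
}

# Restrict a feature table to its training rows when split is assigned.
training_rows <- function(table) {
  if (!any(is.na(table$split))) dplyr::filter(table, .data$split == "train")
  else table
}

#' Evaluate one feature combination by cross-validation
#'
#' Stratified, lineage-grouped k-fold CV of the configured classifier
#' restricted to the combination's columns. Features are standardized with
#' statistics fit on each training fold. Deterministic under the config
#' seed.
#'
#' @param table A feature table (training rows are used when a split is
#'   assigned).
#' @param combo Character vector of feature names.
#' @param cfg A [search_config()].
#' @return A one-row tibble (a model record): `combo` (list-column),
#'   `k`, `cv_accuracy`, `cv_sensitivity`, `cv_specificity`.
#' @export
evaluate_combination <- function(table, combo, cfg = search_config()) {
  table <- training_rows(table)
  ev <- build_evaluator(table, cfg)
  bad <- setdiff(combo, ev$features)
  if (length(bad)) stop("unknown feature(s): ", paste(bad, collapse = ", "))
  res <- ev$eval_cols(match(combo, ev$features))
  tibble::tibble(
    combo = list(sort_features(combo)), k = length(combo),
    cv_accuracy = res[["cv_accuracy"]],
    cv_sensitivity = res[["cv_sensitivity"]],
    cv_specificity = res[["cv_specificity"]]
  )
}

sort_features <- function(x) x[order(match(x, feature_names()))]

#' Run one exhaustive search generation
#'
#' Evaluates every k-combination of the pool, selects the "good models"
#' (top `top_count`, or `max(top_min, ceiling(top_fraction * n))`, by CV
#' accuracy, ties broken by CV sensitivity then canonical combo order) and
#' tallies how often each feature occurs among them.
#'
#' @param table A feature table.
#' @param pool Character vector of candidate feature names.
#' @param k Combination dimension.
#' @param cfg A [search_config()].
#' @param evaluator Internal: reuse a prebuilt evaluator.
#' @return A `ga_generation`: list with `k`, `pool`, `models` (tibble of
#'   all evaluated records), `top_models`, `freq` (named feature
#'   occurrence counts among top models), `n_models`.
#' @export
run_generation <- function(table, pool, k, cfg = search_config(), evaluator = NULL) {
  pool <- sort_features(unique(pool))
  n_comb <- count_combinations(length(pool), k)
  if (n_comb > cfg$max_models) {
    stop("generation k=", k, " would evaluate ", format(n_comb, big.mark = ","),
         " models, over the budget of ", format(cfg$max_models, big.mark = ","),
         "; reduce the pool (pool_size) or raise max_models")
  }
  if (is.null(evaluator)) evaluator <- build_evaluator(training_rows(table), cfg)
  cols <- match(pool, evaluator$features)
  combos <- utils::combn(cols, k)
  res <- matrix(NA_real_, nrow = ncol(combos), ncol = 3)
  for (i in seq_len(ncol(combos))) {
    res[i, ] <- evaluator$eval_cols(combos[, i])
  }
  models <- tibble::tibble(
    combo = lapply(seq_len(ncol(combos)), function(i) evaluator$features[combos[, i]]),
    k = k,
    cv_accuracy = res[, 1], cv_sensitivity = res[, 2], cv_specificity = res[, 3]
  )
  n_top <- cfg$top_count %||% max(cfg$top_min, ceiling(cfg$top_fraction * nrow(models)))
  n_top <- min(n_top, nrow(models))
  ord <- order(-models$cv_accuracy, -models$cv_sensitivity, seq_len(nrow(models)))
  top <- models[ord[seq_len(n_top)], ]
  freq_tab <- table(factor(unlist(top$combo), levels = pool))
  freq <- as.integer(freq_tab)
  names(freq) <- pool
  structure(
    list(k = k, pool = pool, models = models, top_models = top,
         freq = freq, n_models = nrow(models)),
    class = "ga_generation"
  )
}

#' @export
print.ga_generation <- function(x, ...) {
  cat(sprintf(
    "<ga_generation> k=%d: %d models over %d features; top %d, best CV accuracy %.3f\n",
    x$k, x$n_models, length(x$pool), nrow(x$top_models), max(x$models$cv_accuracy)
  ))
  invisible(x)
}

# Rank features by tally (desc), then by the best CV accuracy of any top
# model containing the feature (desc), then canonical order.
rank_features <- function(candidates, freq, best_acc) {
  f <- freq[candidates]
  f[is.na(f)] <- 0
  a <- best_acc[candidates]
  a[is.na(a)] <- -Inf
  candidates[order(-f, -a, match(candidates, feature_names()))]
}

#' Select the next generation's feature pool
#'
#' The `budget` features with the highest occurrence count among the
#' generation's top models; ties broken by the best CV accuracy of any top
#' model containing the feature, then canonical feature order. With a
#' budget at least the pool size the pool is unchanged as a set.
#'
#' @param gen A `ga_generation`.
#' @param budget Maximum pool size for the next generation.
#' @return Character vector of feature names, canonical order.
#' @export
next_pool <- function(gen, budget) {
  stopifnot(inherits(gen, "ga_generation"), budget >= 1)
  best_acc <- best_accuracy_per_feature(gen$top_models)
  ranked <- rank_features(gen$pool, gen$freq, best_acc)
  sort_features(ranked[seq_len(min(budget, length(ranked)))])
}

best_accuracy_per_feature <- function(top_models) {
  long <- tibble::tibble(
    feature = unlist(top_models$combo),
    acc = rep(top_models$cv_accuracy, lengths(top_models$combo))
  )
  out <- long |>
    dplyr::group_by(.data$feature) |>
    dplyr::summarise(best = max(.data$acc))
  stats::setNames(out$best, out$feature)
}

#' Run the full generational feature search
#'
#' Dimensions `1..k_exhaustive` are enumerated on the full feature pool
#' (or a budgeted pool when `pool_size` names that dimension); each higher
#' dimension runs on a pool restricted to the features occurring most
#' often in the good models of all completed generations (tallies merged
#' across generations). Returns every model whose CV accuracy exceeds the
#' retention threshold, plus a per-generation performance summary.
#'
#' @param table A feature table (training rows are used when split).
#' @param cfg A [search_config()].
#' @return A `ga_search`: list with `generations`, `candidates` (retained
#'   model records), `summary` (per-generation tibble), `cfg`.
#' @export
run_heuristic <- function(table, cfg = search_config()) {
  train <- training_rows(table)
  evaluator <- build_evaluator(train, cfg)
  all_features <- evaluator$features
  merged_freq <- stats::setNames(numeric(length(all_features)), all_features)
  merged_best <- stats::setNames(rep(-Inf, length(all_features)), all_features)
  pool <- all_features
  generations <- list()
  for (k in seq_len(cfg$k_max)) {
    budget <- unname(cfg$pool_size[as.character(k)])
    if (k > 1 && (k > cfg$k_exhaustive || !is.na(budget %||% NA))) {
      budget <- if (!is.null(budget) && !is.na(budget)) budget else length(pool)
      pool <- sort_features(
        rank_features(pool, merged_freq, merged_best)[seq_len(min(budget, length(pool)))]
      )
    }
    gen <- run_generation(train, pool, k, cfg, evaluator = evaluator)
    generations[[k]] <- gen
    merged_freq[names(gen$freq)] <- merged_freq[names(gen$freq)] + gen$freq
    ba <- best_accuracy_per_feature(gen$top_models)
    merged_best[names(ba)] <- pmax(merged_best[names(ba)], ba)
    pool <- gen$pool
  }
  models <- dplyr::bind_rows(lapply(generations, `[[`, "models"))
  candidates <- models |>
    dplyr::filter(.data$cv_accuracy > cfg$retention_accuracy) |>
    dplyr::arrange(dplyr::desc(.data$cv_accuracy), dplyr::desc(.data$cv_sensitivity))
  summary <- purrr::map_dfr(generations, function(g) {
    tibble::tibble(
      k = g$k, pool_size = length(g$pool), n_models = g$n_models,
      mean_cv_accuracy = mean(g$models$cv_accuracy),
      max_cv_accuracy = max(g$models$cv_accuracy),
      mean_top_cv_accuracy = mean(g$top_models$cv_accuracy)
    )
  })
  out <- structure(
    list(generations = generations, candidates = candidates,
         summary = summary, cfg = cfg),
    class = "ga_search"
  )
  if (nrow(candidates) == 0) {
    message("no model exceeded the retention CV accuracy of ",
            cfg$retention_accuracy, "; best was ",
            round(max(models$cv_accuracy), 3))
  }
  out
}

#' @export
print.ga_search <- function(x, ...) {
  cat("<ga_search>", length(x$generations), "generations,",
      nrow(x$candidates), "retained candidate model(s)\n")
  print(x$summary)
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.ga_search <- function(x, ...) {
  dplyr::mutate(x$candidates,
                combo_id = vapply(.data$combo, paste, character(1), collapse = "+"),
                .before = 1)
}

#' @exportS3Method generics::glance
glance.ga_search <- function(x, ...) {
  best <- x$candidates[1, ]
  tibble::tibble(
    n_generations = length(x$generations),
    n_models_evaluated = sum(x$summary$n_models),
    n_candidates = nrow(x$candidates),
    best_cv_accuracy = if (nrow(x$candidates)) best$cv_accuracy else
      max(x$summary$max_cv_accuracy),
    best_k = if (nrow(x$candidates)) best$k else NA_integer_
  )
}

#' @exportS3Method ggplot2::autoplot
autoplot.ga_search <- function(object, ...) {
  long <- tidyr::pivot_longer(
    object$summary,
    c("mean_cv_accuracy", "max_cv_accuracy", "mean_top_cv_accuracy"),
    names_to = "measure", values_to = "accuracy"
  )
  ggplot2::ggplot(long, ggplot2::aes(x = .data$k, y = .data$accuracy,
                                     colour = .data$measure)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::labs(x = "combination dimension (features per model)",
                  y = "cross-validated accuracy",
                  title = "Model performance by generation") +
    ggplot2::theme_minimal()
}
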