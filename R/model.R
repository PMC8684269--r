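#' Random-forest hyperparameter search space
#'
#' Uniform integer ranges for the three tuned forest hyperparameters. The
#' lower bound of \code{min_samples_split} defaults to 5 so nodes can still
#' split on infrequent diagnosis codes; smaller lower bounds are rejected.
#'
#' @param n_estimators integer range (length-2) for the number of trees.
#' @param min_samples_split integer range for the minimum samples required
#'   to split a node; lower bound at least 5.
#' @param min_samples_leaf integer range for the minimum terminal node
#'   size.
#' @param n_iterations random-search iterations (default 50).
#' @param n_folds cross-validation folds (default 3, at least 2).
#' @return object of class \code{search_space}.
#' @export
search_space <- function(n_estimators = c(50L, 500L),
                         min_samples_split = c(5L, 50L),
                         min_samples_leaf = c(1L, 20L),
                         n_iterations = 50L,
                         n_folds = 3L) {
  chk <- function(r, nm) {
    if (length(r) != 2 || any(r != floor(r)) || r[1] > r[2] || r[1] < 1)
      stop(nm, " must be an increasing integer range")
    as.integer(r)
  }
  n_estimators <- chk(n_estimators, "n_estimators")
  min_samples_split <- chk(min_samples_split, "min_samples_split")
  min_samples_leaf <- chk(min_samples_leaf, "min_samples_leaf")
  if (min_samples_split[1] < 5)
    stop("min_samples_split lower bound must be at least 5")
  if (n_folds < 2) stop("n_folds must be at least 2")
  if (n_iterations < 1) stop("n_iterations must be at least 1")
  structure(list(n_estimators = n_estimators,
                 min_samples_split = min_samples_split,
                 min_samples_leaf = min_samples_leaf,
                 n_iterations = as.integer(n_iterations),
                 n_folds = as.integer(n_folds)),
            class = "search_space")
}

#' Deterministic train/test split of stay ids
#'
#' @param ids stay ids (at least 10).
#' @param fraction training fraction in (0, 1); the training size is
#'   \code{round(fraction * n)} (round-half-even, as in base R).
#' @param seed integer seed; the same seed reproduces the same partition.
#' @return list with \code{train} and \code{test} id vectors, a disjoint
#'   exhaustive partition of \code{ids}.
#' @export
split_train_test <- function(ids, fraction = 0.8, seed = 1) {
  if (fraction <= 0 || fraction >= 1) stop("fraction must be in (0, 1)")
  n <- length(ids)
  if (n < 10) stop("need at least 10 stays to split")
  n_train <- round(fraction * n)
  with_seed(seed, {
    train <- sort(sample(seq_len(n), n_train))
  })
  list(train = ids[train], test = ids[-train])
}

sample_range <- function(r) {
  if (r[1] == r[2]) return(r[1])  # sample(n, 1) would read n as 1:n
  r[1] + sample.int(r[2] - r[1] + 1L, 1L) - 1L
}

fold_assignment <- function(n, k) {
  # deterministic under the caller's RNG state; shuffled round-robin so
  # fold sizes differ by at most one
  sample(rep_len(seq_len(k), n))
}

#' Fit a random-forest long-stay classifier
#'
#' Thin wrapper around [ranger::ranger()] fixing the settings used
#' throughout: classification by majority vote over the ensemble, impurity
#' (Gini) feature importance, single-threaded deterministic fits under a
#' seed. Hyperparameters map as n_estimators -> \code{num.trees},
#' min_samples_split -> \code{min.node.size}, min_samples_leaf ->
#' \code{min.bucket}.
#'
#' @param x numeric feature matrix.
#' @param y 0/1 labels.
#' @param params named list with \code{n_estimators},
#'   \code{min_samples_split}, \code{min_samples_leaf}.
#' @param seed integer seed for the forest's bootstrap and splits.
#' @return object of class \code{los_forest}.
#' @export
fit_forest <- function(x, y, params, seed = 1) {
  if (!nrow(x)) stop("empty feature matrix")
  if (nrow(x) != length(y)) stop("x and y sizes differ")
  need <- c("n_estimators", "min_samples_split", "min_samples_leaf")
  if (!all(need %in% names(params)))
    stop("params must contain ", paste(need, collapse = ", "))
  df <- as.data.frame(x)
  names(df) <- make.names(colnames(x), unique = TRUE)
  df$.outcome <- factor(y, levels = c(0, 1))
  fit <- ranger::ranger(
    dependent.variable.name = ".outcome", data = df,
    num.trees = params$n_estimators,
    min.node.size = params$min_samples_split,
    min.bucket = params$min_samples_leaf,
    importance = "impurity", seed = seed, num.threads = 1,
    verbose = FALSE)
  structure(list(model = fit, params = params,
                 feature_names = colnames(x), seed = seed),
            class = "los_forest")
}

#' @export
print.los_forest <- function(x, ...) {
  cat("<los_forest> ", x$params$n_estimators, " trees, min split ",
      x$params$min_samples_split, ", min leaf ", x$params$min_samples_leaf,
      ", ", length(x$feature_names), " features\n", sep = "")
  invisible(x)
}

#' @export
predict.los_forest <- function(object, newdata, ...) {
  df <- as.data.frame(newdata)
  names(df) <- make.names(colnames(newdata), unique = TRUE)
  # fixed seed: majority-vote ties are broken reproducibly, so prediction
  # is a pure function of the fitted object
  as.integer(as.character(
    stats::predict(object$model, data = df, num.threads = 1,
                   seed = object$seed)$predictions))
}

#' Normalized feature importances of a fitted forest
#'
#' @param object a [fit_forest()] result.
#' @return data.frame (feature, importance) sorted decreasing; importances
#'   are impurity importances rescaled to sum to 1.
#' @export
importance_scores <- function(object) {
  imp <- object$model$variable.importance
  tot <- sum(imp)
  imp <- if (tot > 0) imp / tot else rep(1 / length(imp), length(imp))
  df <- data.frame(feature = object$feature_names,
                   importance = unname(imp), stringsAsFactors = FALSE)
  df[order(-df$importance, df$feature), , drop = FALSE]
}

#' Random search with k-fold cross-validation
#'
#' Samples hyperparameter combinations uniformly from the space, scores
#' each by mean accuracy over the folds (the fold assignment is drawn once
#' per call and shared by every candidate), and returns the best. Ties go
#' to the earliest sampled candidate.
#'
#' @param x training feature matrix.
#' @param y training 0/1 labels.
#' @param space a [search_space()].
#' @param seed integer seed driving the fold shuffle, the candidate draws
#'   and the per-fit forest seeds.
#' @return list with \code{best_params}, \code{best_score} (mean CV
#'   accuracy), and \code{results} (one row per candidate).
#' @export
random_search_cv <- function(x, y, space, seed = 1) {
  stopifnot(inherits(space, "search_space"))
  with_seed(seed, {
    folds <- fold_assignment(nrow(x), space$n_folds)
    for (f in seq_len(space$n_folds)) {
      if (length(unique(y[folds != f])) < 2)
        stop("fold ", f, " leaves a one-class training set; ",
             "use a larger cohort or fewer folds")
    }
    cand <- lapply(seq_len(space$n_iterations), function(i)
      list(n_estimators = sample_range(space$n_estimators),
           min_samples_split = sample_range(space$min_samples_split),
           min_samples_leaf = sample_range(space$min_samples_leaf)))
    # one seed per fold, shared by all candidates: identical candidates
    # score identically and comparisons between candidates are paired
    fit_seeds <- sample.int(2147483629, space$n_folds)
    scores <- numeric(space$n_iterations)
    for (i in seq_len(space$n_iterations)) {
      acc <- numeric(space$n_folds)
      for (f in seq_len(space$n_folds)) {
        hold <- folds == f
        fit <- fit_forest(x[!hold, , drop = FALSE], y[!hold], cand[[i]],
                          seed = fit_seeds[f])
        acc[f] <- mean(predict(fit, x[hold, , drop = FALSE]) == y[hold])
      }
      scores[i] <- mean(acc)
    }
    best <- which.max(scores)
    res <- cbind(do.call(rbind, lapply(cand, as.data.frame)),
                 cv_accuracy = scores)
    list(best_params = cand[[best]], best_score = scores[best],
         results = res)
  })
}

#' Classification metrics against the long-stay truth
#'
#' Computes the confusion counts and the derived metric suite with long
#' stays as the positive class: recall (sensitivity), specificity,
#' precision, accuracy and F1.
#'
#' @param predictions 0/1 predicted classes.
#' @param labels 0/1 true classes, same length.
#' @return object of class \code{los_metrics}: tp, tn, fp, fn, recall,
#'   specificity, precision, accuracy, f1.
#' @export
evaluate <- function(predictions, labels) {
  if (length(predictions) != length(labels))
    stop("predictions and labels differ in length")
  p <- as.integer(predictions); l <- as.integer(labels)
  if (any(!p %in% 0:1) || any(!l %in% 0:1))
    stop("predictions and labels must be 0/1")
  tp <- sum(p == 1 & l == 1); tn <- sum(p == 0 & l == 0)
  fp <- sum(p == 1 & l == 0); fn <- sum(p == 0 & l == 1)
  recall <- tp / (tp + fn)
  specificity <- tn / (tn + fp)
  precision <- tp / (tp + fp)
  accuracy <- (tp + tn) / (tp + tn + fp + fn)
  f1 <- 2 * precision * recall / (precision + recall)
  structure(list(tp = tp, tn = tn, fp = fp, fn = fn, recall = recall,
                 specificity = specificity, precision = precision,
                 accuracy = accuracy, f1 = f1),
            class = "los_metrics")
}

#' @export
print.los_metrics <- function(x, digits = 3, ...) {
  cat(sprintf(
    "<los_metrics> n=%d  acc=%.*f  recall=%.*f  spec=%.*f  prec=%.*f  f1=%.*f\n",
    x$tp + x$tn + x$fp + x$fn, digits, x$accuracy, digits, x$recall,
    digits, x$specificity, digits, x$precision, digits, x$f1))
  invisible(x)
}

#' Prediction concordance of two models
#'
#' @param preds_a,preds_b 0/1 predictions on the same test stays in the
#'   same order.
#' @return list with \code{fraction} (share of identical predictions) and
#'   \code{table} (2x2 cross-tabulation of the two models' classes).
#' @export
concordance <- function(preds_a, preds_b) {
  if (length(preds_a) != length(preds_b))
    stop("prediction vectors differ in length")
  a <- factor(as.integer(preds_a), levels = 0:1,
              labels = c("short", "long"))
  b <- factor(as.integer(preds_b), levels = 0:1,
              labels = c("short", "long"))
  list(fraction = mean(a == b),
       table = table(model_a = a, model_b = b))
}

#' Configuration of a structured-vs-unstructured comparison run
#'
#' @param seed master seed; every stage seed (split, tuning, final fits)
#'   derives from it deterministically.
#' @param train_fraction training share of the 80/20 split.
#' @param space a [search_space()].
#' @param srf an [srf_params()].
#' @param icu_subgroup if TRUE the comparison is repeated on the
#'   intensive-care subset with its own split and tuning.
#' @param stratify if TRUE the split preserves class proportions.
#' @return object of class \code{comparison_config}.
#' @export
comparison_config <- function(seed = 1, train_fraction = 0.8,
                              space = search_space(), srf = srf_params(),
                              icu_subgroup = FALSE, stratify = FALSE) {
  stopifnot(inherits(space, "search_space"), inherits(srf, "srf_params"))
  structure(list(seed = as.integer(seed), train_fraction = train_fraction,
                 space = space, srf = srf,
                 icu_subgroup = isTRUE(icu_subgroup),
                 stratify = isTRUE(stratify)),
            class = "comparison_config")
}

stratified_split <- function(ids, labels, fraction, seed) {
  with_seed(seed, {
    train <- unlist(lapply(split(seq_along(ids), labels), function(idx) {
      idx[sort(sample(seq_along(idx), round(fraction * length(idx))))]
    }), use.names = FALSE)
  })
  train <- sort(train)
  list(train = ids[train], test = ids[-train])
}

compare_on_split <- function(stays, stay_concepts, config, split) {
  feats <- list(
    structured = build_feature_matrix(stays, NULL, "structured",
                                      train_ids = split$train,
                                      params = config$srf),
    unstructured = build_feature_matrix(stays, stay_concepts, "unstructured",
                                        train_ids = split$train,
                                        params = config$srf))
  ids <- as.character(stays$stay_id)
  tr <- ids %in% split$train
  out <- list()
  preds <- list()
  for (m in names(feats)) {
    fx <- feats[[m]]
    tune_seed <- derive_seed(config$seed, if (m == "structured") 11L else 12L)
    fit_seed <- derive_seed(config$seed, if (m == "structured") 21L else 22L)
    search <- random_search_cv(fx$x[tr, , drop = FALSE], fx$y[tr],
                               config$space, seed = tune_seed)
    fit <- fit_forest(fx$x[tr, , drop = FALSE], fx$y[tr],
                      search$best_params, seed = fit_seed)
    pr <- predict(fit, fx$x[!tr, , drop = FALSE])
    preds[[m]] <- pr
    out[[m]] <- list(metrics = evaluate(pr, fx$y[!tr]),
                     best_params = search$best_params,
                     cv_score = search$best_score,
                     importances = importance_scores(fit),
                     n_features = ncol(fx$x))
  }
  y_test <- feats$structured$y[!tr]
  metric_names <- c("recall", "specificity", "precision", "accuracy", "f1")
  deltas <- vapply(metric_names, function(nm)
    out$unstructured$metrics[[nm]] - out$structured$metrics[[nm]], 0)
  list(structured = out$structured, unstructured = out$unstructured,
       deltas = deltas,
       concordance = concordance(preds$structured, preds$unstructured),
       majority_rate = max(mean(y_test), 1 - mean(y_test)),
       n_train = sum(tr), n_test = sum(!tr),
       test_ids = ids[!tr],
       predictions = preds, y_test = y_test)
}

#' Run the structured-vs-unstructured model comparison
#'
#' The central analysis: labels stays as long/short at the configured
#' threshold, draws one 80/20 train/test partition that is shared by both
#' models, builds the structured and unstructured feature matrices with all
#' data-driven encodings fitted on the training rows, tunes each model
#' independently by random search with cross-validation, fits both on the
#' identical training set, and evaluates both on the identical test set.
#' Optionally repeats the whole procedure within the intensive-care
#' subgroup.
#'
#' @param stays stay table.
#' @param stay_concepts named list stay_id -> concept ids.
#' @param config a [comparison_config()].
#' @return object of class \code{los_comparison} with per-model metrics,
#'   metric deltas (unstructured minus structured), prediction concordance,
#'   normalized feature importances, chosen hyperparameters, the
#'   majority-class baseline of the test set, and (optionally) the ICU
#'   subgroup analysis under \code{$icu}.
#' @export
run_comparison <- function(stays, stay_concepts,
                           config = comparison_config()) {
  stopifnot(inherits(config, "comparison_config"))
  ids <- as.character(stays$stay_id)
  y <- label_long_stay(stays$total_los, config$srf)
  split_seed <- derive_seed(config$seed, 1L)
  split <- if (config$stratify)
    stratified_split(ids, y, config$train_fraction, split_seed)
  else split_train_test(ids, config$train_fraction, split_seed)
  res <- compare_on_split(stays, stay_concepts, config, split)
  res$config <- config
  if (config$icu_subgroup) {
    icu_rows <- if (!is.null(stays$icu)) as.logical(stays$icu)
                else stays$ward == "intensive_care"
    sub <- stays[icu_rows, , drop = FALSE]
    if (nrow(sub) >= 50) {
      sub_ids <- as.character(sub$stay_id)
      sub_split <- split_train_test(sub_ids, config$train_fraction,
                                    derive_seed(config$seed, 31L))
      icu_cfg <- config
      icu_cfg$seed <- derive_seed(config$seed, 32L)
      res$icu <- compare_on_split(sub, stay_concepts[sub_ids], icu_cfg,
                                  sub_split)
      res$icu$n_stays <- nrow(sub)
    } else {
      warning("fewer than 50 intensive-care stays; subgroup analysis skipped")
    }
  }
  class(res) <- "los_comparison"
  res
}

#' @export
print.los_comparison <- function(x, ...) {
  cat("Long-stay model comparison (", x$n_train, " train / ", x$n_test,
      " test stays)\n", sep = "")
  fmt <- function(v) sprintf("%5.1f%%", 100 * v)
  rows <- c("recall", "specificity", "precision", "accuracy", "f1")
  cat(sprintf("%-12s %12s %12s %12s\n", "", "Structured", "Unstructured",
              "Diff (pts)"))
  for (r in rows)
    cat(sprintf("%-12s %12s %12s %12.2f\n", r,
                fmt(x$structured$metrics[[r]]),
                fmt(x$unstructured$metrics[[r]]),
                100 * x$deltas[[r]]))
  cat(sprintf("Concordance: %s   Majority baseline: %s\n",
              fmt(x$concordance$fraction), fmt(x$majority_rate)))
  if (!is.null(x$icu))
    cat(sprintf("ICU subgroup (n=%d): accuracy %s vs %s\n",
                x$icu$n_stays, fmt(x$icu$structured$metrics$accuracy),
                fmt(x$icu$unstructured$metrics$accuracy)))
  invisible(x)
}

#' @export
summary.los_comparison <- function(object, n_importances = 10, ...) {
  print(object)
  cat("\nChosen hyperparameters\n")
  for (m in c("structured", "unstructured")) {
    p <- object[[m]]$best_params
    cat(sprintf("  %-12s n_estimators=%d min_samples_split=%d min_samples_leaf=%d (CV acc %.3f)\n",
                m, p$n_estimators, p$min_samples_split, p$min_samples_leaf,
                object[[m]]$cv_score))
  }
  cat("\nTop feature importances\n")
  for (m in c("structured", "unstructured")) {
    imp <- utils::head(object[[m]]$importances, n_importances)
    cat(" ", m, ":\n", sep = "")
    for (i in seq_len(nrow(imp)))
      cat(sprintf("    %-28s %.4f\n", imp$feature[i], imp$importance[i]))
  }
  invisible(object)
}

# serializable summary of a comparison (used by run_all and reports)
comparison_to_list <- function(x) {
  strip <- function(side) list(
    metrics = unclass(side$metrics),
    best_params = side$best_params,
    cv_score = side$cv_score,
    n_features = side$n_features,
    importances = utils::head(side$importances, 25))
  out <- list(
    n_train = x$n_train, n_test = x$n_test,
    majority_rate = x$majority_rate,
    structured = strip(x$structured),
    unstructured = strip(x$unstructured),
    deltas = as.list(x$deltas),
    concordance = list(fraction = x$concordance$fraction,
                       table = as.data.frame(x$concordance$table)))
  if (!is.null(x$icu)) {
    out$icu <- list(n_stays = x$icu$n_stays,
                    structured = strip(x$icu$structured),
                    unstructured = strip(x$icu$unstructured),
                    concordance = list(fraction = x$icu$concordance$fraction))
  }
  out
}
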