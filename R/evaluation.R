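#' Confusion counts and classification metrics
#'
#' Thresholds the predicted probabilities and computes the confusion
#' counts together with sensitivity `SE = TP/(TP+FN)`, specificity
#' `SP = TN/(TN+FP)`, accuracy `ACC = (TP+TN)/(TP+FP+FN+TN)` and the
#' Matthews correlation coefficient
#' `MCC = (TP*TN - FP*FN) / sqrt((TP+FP)(TP+FN)(TN+FP)(TN+FN))`.
#' A metric whose denominator is zero is reported as `NA` (an explicit
#' "undefined" marker) rather than propagating `NaN`.
#'
#' @param labels Binary truth: "positive"/"negative", logical, or 0/1.
#' @param probabilities Predicted positive-class probabilities in
#'   `[0, 1]`.
#' @param threshold Classification threshold (default 0.5).
#' @return A one-row tibble with columns `tp`, `fp`, `tn`, `fn`, `se`,
#'   `sp`, `acc`, `mcc`.
#' @export
compute_metrics <- function(labels, probabilities, threshold = 0.5) {
  if (length(labels) != length(probabilities)) {
    abort("labels and probabilities must have equal length")
  }
  if (length(labels) == 0L) abort("empty input")
  if (any(probabilities < 0 | probabilities > 1)) {
    abort("probabilities must lie in [0, 1]")
  }
  y <- label01(labels)
  pred <- as.integer(probabilities > threshold)
  metrics_from_counts(tp = sum(pred == 1L & y == 1L),
                      fp = sum(pred == 1L & y == 0L),
                      tn = sum(pred == 0L & y == 0L),
                      fn = sum(pred == 0L & y == 1L))
}

#' Metrics from raw confusion counts
#'
#' @param tp,fp,tn,fn Non-negative confusion counts.
#' @return A one-row tibble (see [compute_metrics()]).
#' @export
metrics_from_counts <- function(tp, fp, tn, fn) {
  safe_div <- function(num, den) if (den == 0) NA_real_ else num / den
  mcc_den <- sqrt(as.numeric(tp + fp)) * sqrt(as.numeric(tp + fn)) *
    sqrt(as.numeric(tn + fp)) * sqrt(as.numeric(tn + fn))
  tibble::tibble(
    tp = tp, fp = fp, tn = tn, fn = fn,
    se = safe_div(tp, tp + fn),
    sp = safe_div(tn, tn + fp),
    acc = safe_div(tp + tn, tp + fp + tn + fn),
    mcc = if (mcc_den == 0) NA_real_ else
      (as.numeric(tp) * tn - as.numeric(fp) * fn) / mcc_den
  )
}

#' ROC curve and AUC
#'
#' Sweeps the classification threshold over the distinct scores (ties
#' grouped), accumulating the true-positive rate (SE) against the
#' false-positive rate (1 - SP), and integrates by the trapezoidal rule.
#'
#' @param labels Binary truth (both classes must be present).
#' @param scores Numeric scores; larger means more positive.
#' @return A list with `roc`, a tibble of (`threshold`, `fpr`, `tpr`)
#'   points, and `auc`.
#' @export
roc_auc <- function(labels, scores) {
  y <- label01(labels)
  n_pos <- sum(y == 1L); n_neg <- sum(y == 0L)
  if (n_pos == 0L || n_neg == 0L) {
    abort("ROC requires both classes to be present")
  }
  o <- order(scores, decreasing = TRUE)
  ys <- y[o]; ss <- scores[o]
  grp_last <- c(ss[-1] != ss[-length(ss)], TRUE)
  tp_cum <- cumsum(ys)[grp_last]
  fp_cum <- cumsum(1 - ys)[grp_last]
  roc <- tibble::tibble(
    threshold = c(Inf, ss[grp_last]),
    fpr = c(0, fp_cum / n_neg),
    tpr = c(0, tp_cum / n_pos)
  )
  auc <- sum(diff(roc$fpr) * (head(roc$tpr, -1) + roc$tpr[-1]) / 2)
  structure(list(roc = roc, auc = auc), class = "phos_roc")
}

#' @export
print.phos_roc <- function(x, ...) {
  cat("<phos_roc> ", nrow(x$roc), " points, AUC = ",
      format(x$auc, digits = 4), "\n", sep = "")
  invisible(x)
}

# Call a model factory and produce a probability predictor.
# A factory is function(train_tibble) returning either an object with a
# predict method accepting (object, newdata) -> probabilities, or a
# plain function(newdata) -> probabilities.
fit_and_predictor <- function(model_factory, train) {
  fitted <- model_factory(train)
  if (is.function(fitted)) fitted else function(newdata) predict(fitted, newdata)
}

# Stratified fold assignment: within each class, cycle fold ids over a
# random permutation so fold sizes differ by at most one per class.
stratified_folds <- function(y, k, seed) {
  set.seed(seed)
  fold <- integer(length(y))
  for (cls in unique(y)) {
    idx <- which(y == cls)
    fold[idx[sample.int(length(idx))]] <- rep_len(seq_len(k), length(idx))
  }
  fold
}

#' Stratified k-fold cross-validation
#'
#' Folds are stratified by label so both classes appear in every fold;
#' every window is tested exactly once. Metrics are computed per fold and
#' averaged (fold-averaged mode; set `pooled = TRUE` to pool the
#' confusion counts over folds instead).
#'
#' @param dataset Window tibble with `sequence` and `label`.
#' @param model_factory `function(train_tibble)` returning a fitted
#'   object with a `predict(object, newdata)` probability method, or a
#'   `function(newdata)` predictor. See [cnn_factory()],
#'   [baseline_factory()].
#' @param k Number of folds (default 10).
#' @param seed Seed for the fold assignment.
#' @param threshold Classification threshold.
#' @param pooled Pool confusion counts over folds instead of averaging
#'   fold metrics.
#' @return A `phos_cv` object: `per_fold` metrics tibble (incl. AUC),
#'   `summary` (mean/sd), and `fold_ids`.
#' @export
kfold_cv <- function(dataset, model_factory, k = 10L, seed = 1L,
                     threshold = 0.5, pooled = FALSE) {
  y <- label01(dataset$label)
  if (nrow(dataset) < k) abort("dataset smaller than number of folds")
  if (min(table(y)) < k) {
    abort("too few samples of one class for stratified folding")
  }
  fold <- stratified_folds(y, k, seed)
  per_fold <- purrr::map_dfr(seq_len(k), function(f) {
    train <- dataset[fold != f, , drop = FALSE]
    test <- dataset[fold == f, , drop = FALSE]
    predictor <- fit_and_predictor(model_factory, train)
    probs <- predictor(test)
    met <- compute_metrics(test$label, probs, threshold)
    met$auc <- roc_auc(test$label, probs)$auc
    met$fold <- f
    met
  })
  structure(list(
    per_fold = per_fold,
    summary = summarize_metric_rows(per_fold, pooled),
    fold_ids = fold,
    scheme = list(kind = "kfold", k = k, seed = seed)
  ), class = "phos_cv")
}

summarize_metric_rows <- function(rows, pooled = FALSE) {
  if (pooled) {
    met <- metrics_from_counts(sum(rows$tp), sum(rows$fp),
                               sum(rows$tn), sum(rows$fn))
    met$auc <- mean(rows$auc, na.rm = TRUE)
    return(met)
  }
  cols <- intersect(c("se", "sp", "acc", "mcc", "auc"), names(rows))
  dplyr::bind_rows(
    dplyr::summarise(rows, dplyr::across(dplyr::all_of(cols),
                                         ~ mean(.x, na.rm = TRUE)),
                     stat = "mean"),
    dplyr::summarise(rows, dplyr::across(dplyr::all_of(cols),
                                         ~ sd(.x, na.rm = TRUE)),
                     stat = "sd")
  )
}

#' @export
print.phos_cv <- function(x, ...) {
  cat("<phos_cv> scheme:", x$scheme$kind, "\n")
  print(x$summary)
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.phos_cv <- function(x, ...) x$per_fold

#' @exportS3Method generics::glance
glance.phos_cv <- function(x, ...) {
  s <- x$summary
  if ("stat" %in% names(s)) s <- s[s$stat == "mean", setdiff(names(s), "stat")]
  s
}

#' Leave-one-out cross-validation
#'
#' Runs n single-window test rounds, pools the resulting confusion
#' counts, and computes the metrics once on the pooled counts (the
#' standard aggregation for very small datasets, where per-round metrics
#' are degenerate).
#'
#' @inheritParams kfold_cv
#' @return A `phos_cv` object; `per_round` holds each round's prediction.
#' @export
loo_cv <- function(dataset, model_factory, threshold = 0.5) {
  n <- nrow(dataset)
  if (n < 2L) abort("leave-one-out needs at least 2 windows")
  probs <- numeric(n)
  for (i in seq_len(n)) {
    predictor <- fit_and_predictor(model_factory,
                                   dataset[-i, , drop = FALSE])
    probs[i] <- predictor(dataset[i, , drop = FALSE])
  }
  met <- compute_metrics(dataset$label, probs, threshold)
  met$auc <- tryCatch(roc_auc(dataset$label, probs)$auc,
                      error = function(e) NA_real_)
  structure(list(
    per_round = tibble::tibble(round = seq_len(n),
                               label = dataset$label, prob = probs),
    summary = met,
    scheme = list(kind = "loo")
  ), class = "phos_cv")
}

#' Cluster-stratified repeated 90/10 splits
#'
#' Generates the split scheme used with K-means sample clusters: per
#' repeat, `train_fraction` of the windows *within each cluster* go to
#' training and the rest to testing, so every cluster contributes to both
#' sets and the data distribution is preserved. Clusters smaller than 10
#' windows are flagged and placed wholly in training for that repeat.
#'
#' @param assignments Integer cluster id per window.
#' @param repeats Number of random splits (default 100).
#' @param train_fraction Fraction per cluster in training (default 0.9).
#' @param seed Seed; splits are reproducible.
#' @return A list of `repeats` splits, each
#'   `list(train, test, flagged_clusters)` of index vectors.
#' @export
make_cluster_splits <- function(assignments, repeats = 100L,
                                train_fraction = 0.9, seed = 1L) {
  if (train_fraction <= 0 || train_fraction >= 1) {
    abort("train_fraction must be in (0, 1)")
  }
  set.seed(seed)
  clusters <- split(seq_along(assignments), assignments)
  small <- names(clusters)[vapply(clusters, length, 0L) < 10L]
  if (length(small)) {
    warn(paste0("cluster(s) ", paste(small, collapse = ", "),
                " have fewer than 10 windows; kept whole in training"))
  }
  lapply(seq_len(repeats), function(r) {
    train <- integer(0); test <- integer(0)
    for (nm in names(clusters)) {
      idx <- clusters[[nm]]
      if (nm %in% small) {
        train <- c(train, idx)
        next
      }
      n_tr <- round(train_fraction * length(idx))
      n_tr <- min(max(n_tr, 1L), length(idx) - 1L)
      tr <- sample(idx, n_tr)
      train <- c(train, tr)
      test <- c(test, setdiff(idx, tr))
    }
    list(train = sort(train), test = sort(test),
         flagged_clusters = small)
  })
}

#' Evaluate a model under cluster-stratified repeated splits
#'
#' For each repeat, trains on the 90% within-cluster sample and
#' evaluates on the held-out 10%, yielding a distribution of metrics.
#'
#' @inheritParams kfold_cv
#' @param assignments Integer cluster id per window (e.g. from
#'   [kmeans_windows()]).
#' @param repeats Number of repeats (default 100).
#' @param train_fraction Per-cluster training fraction (default 0.9).
#' @return A `phos_cv` object with `per_repeat` metrics and `splits`.
#' @export
cluster_stratified_repeats <- function(dataset, assignments, model_factory,
                                       repeats = 100L, train_fraction = 0.9,
                                       seed = 1L, threshold = 0.5) {
  stopifnot(length(assignments) == nrow(dataset))
  splits <- make_cluster_splits(assignments, repeats, train_fraction, seed)
  per_repeat <- purrr::map_dfr(seq_along(splits), function(r) {
    sp <- splits[[r]]
    predictor <- fit_and_predictor(model_factory,
                                   dataset[sp$train, , drop = FALSE])
    test <- dataset[sp$test, , drop = FALSE]
    probs <- predictor(test)
    met <- compute_metrics(test$label, probs, threshold)
    met$auc <- tryCatch(roc_auc(test$label, probs)$auc,
                        error = function(e) NA_real_)
    met$repeat_id <- r
    met
  })
  structure(list(
    per_repeat = per_repeat,
    per_fold = per_repeat,
    summary = summarize_metric_rows(per_repeat),
    splits = splits,
    scheme = list(kind = "cluster_stratified_repeats", repeats = repeats,
                  train_fraction = train_fraction, seed = seed)
  ), class = "phos_cv")
}

#' Specificity check on independent negatives
#'
#' Applies a trained model to a negatives-only set (sites never used in
#' model construction) and reports the fraction predicted negative,
#' together with the windows called positive.
#'
#' @param model A fitted model with a probability `predict` method.
#' @param negatives Window tibble of negatives matching the model length.
#' @param threshold Classification threshold.
#' @return A list: `fraction_negative`, `n`, and `positive_calls` (the
#'   rows called positive, with their probabilities).
#' @export
negative_specificity_check <- function(model, negatives, threshold = 0.5) {
  if (!nrow(negatives)) abort("empty negative set")
  probs <- predict(model, negatives)
  called_pos <- probs > threshold
  pos_rows <- negatives[called_pos, , drop = FALSE]
  pos_rows$probability <- probs[called_pos]
  list(fraction_negative = mean(!called_pos),
       n = nrow(negatives),
       positive_calls = pos_rows)
}
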