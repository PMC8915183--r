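#' Specify a classical machine-learning baseline
#'
#' The five comparison classifiers — support vector machine, naive
#' Bayes, K-nearest neighbours, random forest and gradient-boosted trees
#' — all consume the ordinal ("dictionary") encoding of the windows and
#' expose the same probability-prediction contract as the CNN. No
#' hyperparameters are inherited from elsewhere: the defaults below are
#' the conventional ones of each method's R ecosystem and are echoed in
#' every fitted object for auditability.
#'
#' @param method One of `"svm"`, `"nb"`, `"knn"`, `"rf"`, `"xgb"`.
#' @param hyperparams Named list of method-specific settings; unknown
#'   keys are rejected. Defaults: svm radial kernel, cost 1; knn k = 5;
#'   rf 200 trees; xgb 50 rounds, eta 0.3, max_depth 6.
#' @param seed Integer seed.
#' @return An object of class `baseline_spec`.
#' @export
baseline_spec <- function(method = c("svm", "nb", "knn", "rf", "xgb"),
                          hyperparams = list(), seed = 1L) {
  method <- match.arg(method)
  defaults <- switch(method,
    svm = list(kernel = "radial", cost = 1),
    nb = list(laplace = 0),
    knn = list(k = 5L),
    rf = list(ntree = 200L),
    xgb = list(nrounds = 50L, eta = 0.3, max_depth = 6L)
  )
  unknown <- setdiff(names(hyperparams), names(defaults))
  if (length(unknown)) {
    abort(paste0("unknown hyperparameter(s) for ", method, ": ",
                 paste(unknown, collapse = ", ")))
  }
  structure(list(method = method,
                 hyperparams = modifyList(defaults, hyperparams),
                 seed = as.integer(seed)),
            class = "baseline_spec")
}

#' Train a baseline classifier on ordinal-encoded windows
#'
#' @param spec A [baseline_spec()].
#' @param dataset Window tibble with `sequence` and `label` (both
#'   classes required).
#' @return An object of class `phos_baseline` with the same
#'   `predict(object, newdata)` probability contract as the CNN.
#' @export
train_baseline <- function(spec, dataset) {
  stopifnot(inherits(spec, "baseline_spec"))
  x <- ordinal_matrix(dataset)
  y <- label01(dataset$label)
  if (length(unique(y)) < 2L) abort("training data must contain both classes")
  yf <- factor(ifelse(y == 1L, "positive", "negative"),
               levels = c("negative", "positive"))
  hp <- spec$hyperparams
  set.seed(spec$seed)
  fit <- switch(spec$method,
    svm = e1071::svm(x, yf, kernel = hp$kernel, cost = hp$cost,
                     probability = TRUE,
                     scale = apply(x, 2, function(col) var(col) > 0)),
    nb = e1071::naiveBayes(x, yf, laplace = hp$laplace),
    knn = list(train_x = x, train_y = yf, k = hp$k),
    rf = randomForest::randomForest(x, yf, ntree = hp$ntree),
    xgb = xgboost::xgboost(x = x, y = yf, nrounds = hp$nrounds,
                           learning_rate = hp$eta,
                           max_depth = hp$max_depth,
                           objective = "binary:logistic",
                           verbosity = 0L, nthreads = 1L,
                           seed = spec$seed)
  )
  structure(list(spec = spec, fit = fit, input_length = ncol(x)),
            class = "phos_baseline")
}

#' @export
predict.phos_baseline <- function(object, newdata, ...) {
  x <- ordinal_matrix(newdata)
  if (ncol(x) != object$input_length) {
    abort(paste0("window length ", ncol(x),
                 " does not match trained length ", object$input_length))
  }
  fit <- object$fit
  switch(object$spec$method,
    svm = {
      pr <- attr(predict(fit, x, probability = TRUE), "probabilities")
      unname(pr[, "positive"])
    },
    nb = unname(predict(fit, x, type = "raw")[, "positive"]),
    knn = {
      pred <- class::knn(fit$train_x, x, fit$train_y, k = fit$k,
                         prob = TRUE)
      win_prob <- attr(pred, "prob")
      ifelse(pred == "positive", win_prob, 1 - win_prob)
    },
    rf = unname(predict(fit, x, type = "prob")[, "positive"]),
    xgb = as.numeric(predict(fit, x))
  )
}

#' @export
print.phos_baseline <- function(x, ...) {
  cat("<phos_baseline> method:", x$spec$method, "\n settings:",
      paste(names(x$spec$hyperparams), unlist(x$spec$hyperparams),
            sep = "=", collapse = ", "), "\n")
  invisible(x)
}

#' Model factories for the cross-validation schemes
#'
#' A factory is a `function(train_tibble)` returning a fitted object
#' whose `predict(object, newdata)` gives positive-class probabilities;
#' the evaluation schemes ([kfold_cv()], [loo_cv()],
#' [cluster_stratified_repeats()], [compare_methods()]) are agnostic to
#' the model behind the factory.
#'
#' @param hp For `cnn_factory`, a [cnn_hyperparams()] object or preset
#'   name.
#' @param spec For `baseline_factory`, a [baseline_spec()].
#' @return A factory function.
#' @export
cnn_factory <- function(hp) {
  force(hp)
  function(train) train_cnn(build_cnn(hp), train)
}

#' @rdname cnn_factory
#' @export
baseline_factory <- function(spec) {
  force(spec)
  function(train) train_baseline(spec, train)
}

#' Compare the CNN against the five classical baselines
#'
#' Runs every method on byte-identical inputs and identical random
#' splits per repeat: for each repeat a stratified `train_fraction`
#' split is drawn once and shared across all six methods, the metrics of
#' each method are computed on the common held-out set, and means and
#' standard deviations over repeats are reported.
#'
#' @param dataset Window tibble.
#' @param cnn_hp [cnn_hyperparams()] for the CNN entry.
#' @param methods Character vector of baseline methods to include.
#' @param repeats Number of random train/test selections (the published
#'   protocol used 100).
#' @param train_fraction Training fraction per repeat (default 0.9).
#' @param seed Seed; the split sequence is reproducible.
#' @param baseline_seed Seed passed to each [baseline_spec()].
#' @return A list of class `phos_comparison`: `table` (method x mean/sd
#'   of SE, SP, ACC, MCC, AUC), `per_repeat` (long form), and
#'   `split_hashes` (one hash per repeat certifying shared splits).
#' @export
compare_methods <- function(dataset, cnn_hp,
                            methods = c("svm", "nb", "knn", "rf", "xgb"),
                            repeats = 10L, train_fraction = 0.9,
                            seed = 1L, baseline_seed = 1L) {
  y <- label01(dataset$label)
  n <- nrow(dataset)
  factories <- c(
    list(cnn = cnn_factory(cnn_hp)),
    setNames(lapply(methods, function(m) {
      baseline_factory(baseline_spec(m, seed = baseline_seed))
    }), methods)
  )
  set.seed(seed)
  split_list <- lapply(seq_len(repeats), function(r) {
    tr <- unlist(lapply(split(seq_len(n), y), function(idx) {
      sample(idx, max(1L, round(train_fraction * length(idx))))
    }), use.names = FALSE)
    sort(tr)
  })
  per_repeat <- purrr::map_dfr(seq_len(repeats), function(r) {
    tr <- split_list[[r]]
    te <- setdiff(seq_len(n), tr)
    train <- dataset[tr, , drop = FALSE]
    test <- dataset[te, , drop = FALSE]
    purrr::map_dfr(names(factories), function(nm) {
      predictor <- fit_and_predictor(factories[[nm]], train)
      probs <- predictor(test)
      met <- compute_metrics(test$label, probs)
      met$auc <- roc_auc(test$label, probs)$auc
      met$method <- nm
      met$repeat_id <- r
      met
    })
  })
  table <- per_repeat |>
    dplyr::group_by(.data$method) |>
    dplyr::summarise(dplyr::across(dplyr::all_of(c("se", "sp", "acc",
                                                   "mcc", "auc")),
                                   list(mean = ~ mean(.x, na.rm = TRUE),
                                        sd = ~ sd(.x, na.rm = TRUE))),
                     .groups = "drop")
  split_hashes <- vapply(split_list, function(s) rlang::hash(s), "")
  structure(list(table = table, per_repeat = per_repeat,
                 split_hashes = split_hashes,
                 settings = list(repeats = repeats,
                                 train_fraction = train_fraction,
                                 seed = seed)),
            class = "phos_comparison")
}

#' @export
print.phos_comparison <- function(x, ...) {
  cat("<phos_comparison> ", x$settings$repeats, " repeats\n", sep = "")
  print(x$table)
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.phos_comparison <- function(x, ...) x$per_repeat

#' @exportS3Method generics::glance
glance.phos_comparison <- function(x, ...) x$table
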