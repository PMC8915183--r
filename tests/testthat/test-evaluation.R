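test_that("metrics match hand-computed confusion examples", {
  # perfect predictions
  m <- compute_metrics(c(1, 1, 0, 0), c(0.9, 0.8, 0.1, 0.2))
  expect_equal(c(m$se, m$sp, m$acc, m$mcc), c(1, 1, 1, 1))
  # TP=3 FN=1 TN=2 FP=2
  m <- metrics_from_counts(tp = 3, fp = 2, tn = 2, fn = 1)
  expect_equal(m$se, 0.75)
  expect_equal(m$sp, 0.5)
  expect_equal(m$acc, 0.625)
  expect_equal(m$mcc, (3 * 2 - 2 * 1) / sqrt(5 * 4 * 4 * 3))
  # all-positive predictions on balanced data: SP 0, MCC undefined
  m <- compute_metrics(c(1, 1, 0, 0), c(0.9, 0.9, 0.9, 0.9))
  expect_equal(m$sp, 0)
  expect_true(is.na(m$mcc))
  expect_error(compute_metrics(c(1, 0), 0.5), "length")
  expect_error(compute_metrics(numeric(0), numeric(0)), "empty")
})

test_that("metrics agree with the direct formulas on random confusion tables", {
  set.seed(77)
  for (i in 1:1000) {
    cnt <- as.list(sample(0:40, 4, replace = TRUE))
    names(cnt) <- c("tp", "fp", "tn", "fn")
    if (sum(unlist(cnt)) == 0) next
    m <- do.call(metrics_from_counts, cnt)
    with(cnt, {
      if (tp + fn > 0) expect_equal(m$se, tp / (tp + fn))
      if (tn + fp > 0) expect_equal(m$sp, tn / (tn + fp))
      expect_equal(m$acc, (tp + tn) / (tp + fp + tn + fn))
      den <- (tp + fp) * (tp + fn) * (tn + fp) * (tn + fn)
      if (den > 0) {
        expect_equal(m$mcc, (tp * tn - fp * fn) / sqrt(den))
      } else {
        expect_true(is.na(m$mcc))
      }
    })
    # algebraic identity ACC == (SE*P + SP*N)/(P+N)
    P <- cnt$tp + cnt$fn; N <- cnt$tn + cnt$fp
    if (P > 0 && N > 0) {
      expect_equal(m$acc, (m$se * P + m$sp * N) / (P + N))
    }
  }
})

test_that("trapezoidal AUC equals the Mann-Whitney concordance statistic", {
  expect_equal(roc_auc(c(1, 1, 0, 0), c(0.9, 0.8, 0.3, 0.1))$auc, 1.0)
  set.seed(5)
  for (i in 1:500) {
    n <- sample(6:25, 1)
    y <- c(rep(1, 3), rep(0, 3), rbinom(n - 6, 1, 0.5))
    s <- sample(seq(0, 1, by = 0.1), n, replace = TRUE) # ties on purpose
    auc <- roc_auc(y, s)$auc
    pos <- s[y == 1]; neg <- s[y == 0]
    cmpx <- outer(pos, neg, function(a, b) (a > b) + 0.5 * (a == b))
    expect_equal(auc, mean(cmpx), tolerance = 1e-12)
  }
  expect_error(roc_auc(c(1, 1), c(0.5, 0.6)), "both classes")
})

test_that("AUC agrees with an independent ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(9)
  y <- rbinom(300, 1, 0.5)
  s <- runif(300) + y * 0.3
  ours <- roc_auc(y, s)$auc
  theirs <- as.numeric(pROC::auc(pROC::roc(y, s, quiet = TRUE)))
  expect_equal(ours, theirs, tolerance = 1e-10)
})

test_that("AUC is centred at 0.5 under the null and monotone-invariant", {
  set.seed(123)
  aucs <- replicate(100, {
    y <- rep(c(1, 0), each = 25)
    roc_auc(y, runif(50))$auc
  })
  expect_lt(abs(mean(aucs) - 0.5), 3 * sd(aucs) / sqrt(100))
  # strictly monotone transform leaves AUC unchanged
  y <- rbinom(80, 1, 0.5); y[1:2] <- c(0, 1)
  s <- runif(80)
  expect_equal(roc_auc(y, s)$auc, roc_auc(y, qlogis(s))$auc)
})

test_that("stratified k-fold partitions the data exhaustively", {
  ds <- toy_separable_dataset(n_per_class = 23, flank = 4, seed = 10)
  cv <- kfold_cv(ds, proline_factory, k = 5, seed = 3)
  fold <- cv$fold_ids
  expect_setequal(unique(fold), 1:5)
  sizes <- table(fold)
  expect_lte(max(sizes) - min(sizes), 2L) # <=1 per class stratum
  for (cls in c("positive", "negative")) {
    cls_sizes <- table(fold[ds$label == cls])
    expect_lte(max(cls_sizes) - min(cls_sizes), 1L)
  }
  # every window tested exactly once
  expect_setequal(unlist(lapply(1:5, function(f) which(fold == f))),
                  seq_len(nrow(ds)))
  cv2 <- kfold_cv(ds, proline_factory, k = 5, seed = 3)
  expect_identical(cv$per_fold, cv2$per_fold)
  expect_error(kfold_cv(ds[1:4, ], proline_factory, k = 10), "smaller")
})

test_that("leave-one-out pools one prediction per window", {
  ds <- toy_separable_dataset(n_per_class = 2, flank = 3, seed = 11)
  calls <- 0L
  counting_factory <- function(train) {
    calls <<- calls + 1L
    expect_equal(nrow(train), 3L)
    function(test) rep(0.5, nrow(test))
  }
  cv <- loo_cv(ds, counting_factory)
  expect_equal(calls, 4L)
  expect_equal(nrow(cv$per_round), 4L)
  expect_equal(with(cv$summary, tp + fp + tn + fn), 4L)
  # memorizing 1-NN with duplicated points scores perfectly
  dup <- ds[rep(1:4, each = 2), ]
  nn1 <- function(train) {
    function(test) {
      vapply(test$sequence, function(s) {
        hit <- which(train$sequence == s)[1]
        as.numeric(train$label[hit] == "positive")
      }, 0)
    }
  }
  expect_equal(loo_cv(dup, nn1)$summary$acc, 1.0)
})

test_that("cluster-stratified splits are disjoint, exhaustive and stratified", {
  set.seed(20)
  assignments <- sample(1:3, 120, replace = TRUE)
  splits <- make_cluster_splits(assignments, repeats = 100, seed = 8)
  expect_length(splits, 100L)
  for (sp in splits[c(1, 50, 100)]) {
    expect_length(intersect(sp$train, sp$test), 0L)
    expect_setequal(c(sp$train, sp$test), seq_along(assignments))
    # every cluster of size >= 10 contributes to the test set
    for (cl in 1:3) {
      expect_gte(sum(assignments[sp$test] == cl), 1L)
    }
  }
  splits2 <- make_cluster_splits(assignments, repeats = 100, seed = 8)
  expect_identical(splits, splits2)
  # undersized clusters are flagged and kept in training
  tiny <- c(rep(1L, 60), rep(2L, 4))
  expect_warning(sp <- make_cluster_splits(tiny, repeats = 2, seed = 1),
                 "fewer than 10")
  expect_true(all(which(tiny == 2L) %in% sp[[1]]$train))
})

test_that("cluster-stratified evaluation yields per-repeat metrics", {
  ds <- toy_separable_dataset(n_per_class = 30, flank = 4, seed = 12)
  assignments <- rep(1:2, 30)
  res <- cluster_stratified_repeats(ds, assignments, proline_factory,
                                    repeats = 5, seed = 2)
  expect_equal(nrow(res$per_repeat), 5L)
  expect_true(all(res$per_repeat$acc > 0.9)) # proline rule separates
  expect_equal(tidy(res), res$per_repeat)
})

test_that("the independent-negative specificity check is exact arithmetic", {
  ds <- toy_separable_dataset(n_per_class = 12, flank = 4, seed = 13)
  negs <- ds[ds$label == "negative", ]
  always_neg <- structure(list(), class = "const0_model")
  # a model that always outputs p = 0 calls everything negative
  assign("predict.const0_model",
         function(object, newdata, ...) rep(0, nrow(newdata)),
         envir = globalenv())
  withr::defer(rm("predict.const0_model", envir = globalenv()))
  res <- negative_specificity_check(always_neg, negs)
  expect_equal(res$fraction_negative, 1.0)
  expect_equal(nrow(res$positive_calls), 0L)
  # fraction == 1 - mean(predicted label)
  model <- train_cnn(build_cnn(quick_hp(9, epochs = 4L)), ds)
  res2 <- negative_specificity_check(model, negs)
  labels <- predict(model, negs) > 0.5
  expect_equal(res2$fraction_negative, 1 - mean(labels))
  expect_equal(nrow(res2$positive_calls), sum(labels))
  expect_error(negative_specificity_check(model, negs[0, ]), "empty")
})
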