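test_that("confusion counts follow the >= threshold rule", {
  y <- c(1L, 0L, 1L, 0L)
  cm <- confusion(c(1, 0, 1, 0), y)
  expect_equal(cm$FP + cm$FN, 0L)

  cm <- confusion(rep(0.5, 4), y)     # ties predicted positive
  expect_equal(cm$TP + cm$FP, 4L)

  set.seed(20)
  sc <- runif(20); lab <- rbinom(20, 1, 0.4)
  cm <- confusion(sc, lab, 0.5)
  tp <- 0L; tn <- 0L; fp <- 0L; fn <- 0L
  for (i in 1:20) {
    pred <- sc[i] >= 0.5
    if (pred && lab[i] == 1) tp <- tp + 1L
    if (pred && lab[i] == 0) fp <- fp + 1L
    if (!pred && lab[i] == 1) fn <- fn + 1L
    if (!pred && lab[i] == 0) tn <- tn + 1L
  }
  expect_equal(unlist(unclass(cm)), c(TP = tp, TN = tn, FP = fp, FN = fn))

  expect_error(confusion(c(0.5), c(1, 0)), "length")
})

test_that("threshold metrics match plug-in arithmetic and conventions", {
  perfect <- scalar_metrics(list(TP = 50L, TN = 50L, FP = 0L, FN = 0L))
  expect_equal(unname(perfect), rep(1, 6))

  m <- scalar_metrics(list(TP = 45L, FN = 5L, TN = 35L, FP = 15L))
  expect_equal(m[["accuracy"]], 0.80)
  expect_equal(m[["sensitivity"]], 0.90)
  expect_equal(m[["specificity"]], 0.70)
  expect_equal(m[["precision"]], 0.75)
  expect_equal(m[["f1"]], 2 * 0.75 * 0.9 / (0.75 + 0.9))
  expect_equal(m[["mcc"]],
               (45 * 35 - 15 * 5) / sqrt(60 * 50 * 50 * 40))

  allneg <- scalar_metrics(list(TP = 0L, TN = 30L, FP = 0L, FN = 10L))
  expect_equal(allneg[["precision"]], 0)
  expect_equal(allneg[["mcc"]], 0)
  expect_equal(allneg[["f1"]], 0)
})

test_that("threshold metrics agree with the oracle on 1000 random tables", {
  set.seed(99)
  for (i in 1:1000) {
    cts <- as.list(rmultinom(1, sample(1:200, 1), runif(4, 0.05, 1))[, 1])
    names(cts) <- c("TP", "TN", "FP", "FN")
    m <- scalar_metrics(cts)
    o <- metrics_bruteforce(cts$TP, cts$TN, cts$FP, cts$FN)
    expect_equal(m, o, tolerance = 1e-12)
    if (m[["precision"]] + m[["sensitivity"]] > 0) {
      expect_equal(m[["f1"]],
                   2 / (1 / max(m[["precision"]], 1e-300) +
                        1 / max(m[["sensitivity"]], 1e-300)),
                   tolerance = 1e-9)
    }
  }
})

test_that("ROC AUC equals the Mann-Whitney pair count, ties at 1/2", {
  expect_equal(roc_auc(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0))$auc, 1)
  expect_equal(roc_auc(c(0.1, 0.2, 0.8, 0.9), c(1, 1, 0, 0))$auc, 0)

  sc <- c(0.5, 0.5, 0.7, 0.2, 0.7, 0.9, 0.1, 0.5, 0.3, 0.3, 0.8, 0.6)
  lb <- c(1, 0, 1, 0, 0, 1, 0, 1, 0, 1, 1, 0)
  expect_equal(roc_auc(sc, lb)$auc, auc_bruteforce(sc, lb), tolerance = 1e-15)

  set.seed(31)
  for (i in 1:60) {
    n <- sample(4:200, 1)
    lab <- c(1L, 0L, rbinom(n - 2, 1, 0.5))
    sc <- sample(seq(0, 1, 0.05), n, replace = TRUE)  # many ties
    expect_equal(roc_auc(sc, lab)$auc, auc_bruteforce(sc, lab),
                 tolerance = 1e-12)
  }

  expect_error(roc_auc(c(0.1, 0.9), c(1, 1)), "both classes")
})

test_that("ROC AUC is invariant under strictly monotone score transforms", {
  set.seed(8)
  sc <- runif(50); lab <- c(1L, 0L, rbinom(48, 1, 0.4))
  a <- roc_auc(sc, lab)$auc
  expect_equal(roc_auc(qlogis(sc / 1.0001 + 1e-5), lab)$auc, a)
  expect_equal(roc_auc(100 * sc^3, lab)$auc, a)
})

test_that("ROC AUC agrees with an independent library implementation", {
  skip_if_not_installed("pROC")
  set.seed(13)
  sc <- runif(80); lab <- c(1L, 0L, rbinom(78, 1, 0.3))
  ref <- as.numeric(pROC::auc(pROC::roc(lab, sc, quiet = TRUE,
                                        direction = "<")))
  expect_equal(roc_auc(sc, lab)$auc, ref, tolerance = 1e-12)
})

test_that("PR AUC matches the step-curve oracle and its closed forms", {
  expect_equal(pr_auc(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0))$aupr, 1)
  expect_equal(pr_auc(rep(0.4, 10), c(rep(1, 3), rep(0, 7)))$aupr, 0.3)

  set.seed(41)
  for (i in 1:30) {
    n <- sample(5:60, 1)
    lab <- c(1L, rbinom(n - 1, 1, 0.4))
    sc <- sample(seq(0, 1, 0.1), n, replace = TRUE)
    expect_equal(pr_auc(sc, lab)$aupr, aupr_bruteforce(sc, lab),
                 tolerance = 1e-12)
  }

  expect_error(pr_auc(c(0.2, 0.3), c(0, 0)), "positive")
})

test_that("stratified folds partition the data with balanced class ratios", {
  set.seed(2)
  y <- rbinom(100, 1, 0.3)
  fold <- stratified_folds(y, 10L, seed = 4L)
  expect_setequal(unique(fold), 1:10)
  expect_length(fold, 100L)
  # within each class, fold sizes differ by at most one
  for (cls in 0:1) {
    sizes <- table(factor(fold[y == cls], levels = 1:10))
    expect_lte(diff(range(sizes)), 1L)
  }
  expect_identical(fold, stratified_folds(y, 10L, seed = 4L))
})

test_that("cross-validation holds each fold out once with training-only SMOTE", {
  pairs <- make_random_pairs(15L, 45L, d_h = 8L, seed = 21L)
  cfg <- model_config(filters = c(2L, 2L), gru_hidden = 2L,
                      attention_units = 2L)
  cv <- kfold_cv(pairs, k = 3L, seed = 2L, config = cfg,
                 train = train_config(epochs = 2L), k_neighbors = 3L)
  expect_equal(nrow(cv$per_fold), 3L)
  expect_setequal(unique(cv$fold), 1:3)
  expect_length(cv$fold, 60L)
  expect_true(all(is.finite(cv$mean)))
  expect_true(all(cv$per_fold[, "auc"] >= 0 & cv$per_fold[, "auc"] <= 1))
})

test_that("imbalance protocol produces nine exact-ratio test sets", {
  pos <- make_random_pairs(191L, 0L, d_h = 2L, seed = 3L)
  neg <- make_random_pairs(0L, 2000L, d_h = 2L, seed = 4L)
  sets <- imbalanced_test_sets(pos, neg, seed = 5L)
  expect_length(sets, 9L)
  expect_named(sets, paste0("1:", 2:10))
  for (r in 2:10) {
    s <- sets[[paste0("1:", r)]]
    expect_equal(sum(s$y == 1L), 191L)
    expect_equal(sum(s$y == 0L), r * 191L)
  }
  expect_equal(nrow(sets[["1:2"]]$x), 573L)

  expect_error(imbalanced_test_sets(pos, neg, ratios = 1L), "protocol")
  small <- make_random_pairs(0L, 100L, d_h = 2L, seed = 6L)
  expect_error(imbalanced_test_sets(pos, small), "too small")

  sets2 <- imbalanced_test_sets(pos, neg, seed = 5L)
  expect_identical(sets[["1:7"]]$x, sets2[["1:7"]]$x)
})

test_that("MCC is computable on every imbalanced ratio set", {
  pos <- make_random_pairs(20L, 0L, d_h = 2L, seed = 7L)
  neg <- make_random_pairs(0L, 250L, d_h = 2L, seed = 8L)
  sets <- imbalanced_test_sets(pos, neg, seed = 9L)
  set.seed(10)
  for (s in sets) {
    m <- scalar_metrics(confusion(runif(length(s$y)), s$y))
    expect_true(is.finite(m[["mcc"]]))
  }
})
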