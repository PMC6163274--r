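# brute-force confusion matrix, written independently of evaluate()
brute_metrics <- function(pred, truth, positive) {
  tp <- 0L; fp <- 0L; tn <- 0L; fn <- 0L
  for (i in seq_along(truth)) {
    if (truth[i] == positive) {
      if (pred[i] == positive) tp <- tp + 1L else fn <- fn + 1L
    } else {
      if (pred[i] == positive) fp <- fp + 1L else tn <- tn + 1L
    }
  }
  prec <- if (tp + fp > 0) tp / (tp + fp) else 0
  rec <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
  list(tp = tp, fp = fp, tn = tn, fn = fn,
       sensitivity = rec,
       specificity = if (tn + fp > 0) tn / (tn + fp) else NA_real_,
       precision = prec,
       f1 = if (tp == 0) 0 else 2 * rec * prec / (rec + prec))
}

test_that("the stratified split honours fractions, determinism, disjointness", {
  x <- matrix(rnorm(200), ncol = 2)
  y <- rep(c("a", "b"), each = 50)
  sp <- split_train_test(x, y, seed = 3)
  expect_length(sp$train, 70)
  expect_length(sp$test, 30)
  expect_equal(as.vector(table(y[sp$train])), c(35, 35))
  expect_equal(as.vector(table(y[sp$test])), c(15, 15))
  expect_length(intersect(sp$train, sp$test), 0)
  expect_identical(sp, split_train_test(x, y, seed = 3))
  expect_false(identical(sp$train, split_train_test(x, y, seed = 4)$train))
  expect_error(split_train_test(x[1:51, ], y[c(1:50, 51)], seed = 1),
               "at least 2 members")
})

test_that("evaluate matches the worked F1 case and the brute-force oracle", {
  # TP=9 FP=1 FN=3 TN=7
  truth <- c(rep("pos", 12), rep("neg", 8))
  pred <- c(rep("pos", 9), rep("neg", 3), "pos", rep("neg", 7))
  m <- evaluate(pred, truth, positive = "pos")
  expect_equal(m[c("tp", "fp", "fn", "tn")], list(tp = 9, fp = 1, fn = 3, tn = 7))
  expect_equal(m$precision, 0.9)
  expect_equal(m$sensitivity, 0.75)
  expect_equal(round(m$f1, 4), 0.8182)

  expect_equal(evaluate(truth, truth, "pos")[c("sensitivity", "specificity", "f1")],
               list(sensitivity = 1, specificity = 1, f1 = 1))
  # no positive predictions but real positives: F1 is 0 by convention
  m0 <- evaluate(rep("neg", 5), c("pos", "pos", "neg", "neg", "neg"), "pos")
  expect_equal(m0$f1, 0)
  expect_equal(m0$specificity, 1)
  expect_error(evaluate("a", c("a", "b"), "a"), "lengths differ")
  expect_error(evaluate(character(0), character(0), "a"), "empty")

  set.seed(42)
  for (k in 1:200) {
    n <- sample(3:40, 1)
    truth <- sample(c("pos", "neg"), n, replace = TRUE)
    pred <- sample(c("pos", "neg"), n, replace = TRUE)
    expect_identical(evaluate(pred, truth, "pos"),
                     brute_metrics(pred, truth, "pos"))
  }
})

test_that("metrics are invariant under permuting the subjects", {
  set.seed(7)
  truth <- sample(c("pos", "neg"), 30, replace = TRUE)
  pred <- sample(c("pos", "neg"), 30, replace = TRUE)
  o <- sample(30)
  expect_identical(evaluate(pred, truth, "pos"),
                   evaluate(pred[o], truth[o], "pos"))
})

test_that("every classifier family separates well-separated classes", {
  set.seed(5)
  x <- rbind(matrix(rnorm(60, 0), ncol = 2), matrix(rnorm(60, 6), ncol = 2))
  colnames(x) <- c("u", "v")
  y <- rep(c("neg", "pos"), each = 30)
  for (clf in c("adaboost_tree", "logistic", "knn", "bagged_tree")) {
    fit <- train_with_cv(x, y, clf, seed = 1)
    expect_equal(fit$cv_f1_mean, 1, tolerance = 1e-9, info = clf)
    expect_equal(as.character(predict(fit, x)), y, info = clf)
  }
})

test_that("permuted labels score at chance in cross-validation", {
  set.seed(6)
  x <- matrix(rnorm(600), ncol = 10)
  colnames(x) <- paste0("f", 1:10)
  cvs <- vapply(1:20, function(k) {
    y <- sample(rep(c("neg", "pos"), each = 30))
    train_with_cv(x, y, "knn", seed = k)$cv_f1_mean
  }, numeric(1))
  expect_gt(mean(cvs), 0.3)
  expect_lt(mean(cvs), 0.7)
})

test_that("standardization statistics come from the training data only", {
  x_tr <- matrix(rnorm(40, mean = 10, sd = 2), ncol = 2)
  x_te <- matrix(rnorm(40, mean = -5, sd = 9), ncol = 2)
  sc <- ppgbp:::fit_scaler(x_tr)
  expect_equal(sc$mu, colMeans(x_tr))
  z <- ppgbp:::apply_scaler(sc, x_te)
  # test data scaled by *training* statistics, not its own
  expect_equal(z[, 1], (x_te[, 1] - mean(x_tr[, 1])) / sd(x_tr[, 1]),
               ignore_attr = TRUE)
  # imputation uses the training median
  x_na <- x_te; x_na[3, 1] <- NA
  z2 <- ppgbp:::apply_scaler(sc, x_na)
  expect_equal(z2[3, 1], (median(x_tr[, 1]) - sc$mu[[1]]) / sc$sd[[1]])
})

test_that("run_trials produces the full grid and flags missing columns", {
  set.seed(8)
  n <- c(20, 16, 14)
  tab <- data.frame(label = rep(c("normotension", "prehypertension",
                                  "hypertension"), n))
  shift <- rep(c(0, 1, 2), n)
  tab$pat <- 0.3 - 0.03 * shift + rnorm(nrow(tab), 0, 0.02)
  for (j in 1:10) tab[[paste0("f", j)]] <- shift + rnorm(nrow(tab))
  res <- run_trials(tab, seeds = 1L)
  expect_equal(nrow(res), 3 * 3 * 4)        # trials x feature sets x classifiers
  # confusion counts sum to the stratified 30% test size of each trial
  sizes <- tapply(res$tp + res$fp + res$tn + res$fn, res$trial,
                  function(v) unique(v))
  expect_equal(unname(sizes[["N_vs_P"]]), 36 - round(0.7 * 20) - round(0.7 * 16))
  expect_equal(unname(sizes[["N_vs_H"]]), 34 - round(0.7 * 20) - round(0.7 * 14))
  expect_equal(unname(sizes[["NP_vs_H"]]), 50 - round(0.7 * 36) - round(0.7 * 14))
  expect_error(run_trials(tab[, setdiff(names(tab), "pat")], seeds = 1L),
               "missing column")
  s <- summarize_trials(res)
  expect_equal(nrow(s), 36)
  expect_true(all(s$n_seeds == 1))
})
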