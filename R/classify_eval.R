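#' Stratified 70/30 train/test split
#'
#' @param x feature matrix (subjects x features).
#' @param y label vector (factor or character), length `nrow(x)`.
#' @param seed integer seed; identical seeds give identical partitions.
#' @param train_frac training fraction (default 0.7).
#' @return List with integer index vectors `train` and `test` (disjoint,
#'   exhaustive), stratified by label.
#' @export
split_train_test <- function(x, y, seed, train_frac = 0.7) {
  y <- as.factor(y)
  if (length(y) != nrow(x)) stop("x and y sizes differ")
  if (length(y) < 10L) stop("need at least 10 subjects to split")
  if (any(table(y) < 2L)) stop("every class needs at least 2 members")
  train <- integer(0)
  with_seed(seed, {
    for (cl in levels(y)) {
      idx <- which(y == cl)
      n_tr <- round(train_frac * length(idx))
      n_tr <- min(max(n_tr, 1L), length(idx) - 1L)
      train <- c(train, sample(idx, n_tr))
    }
  })
  train <- sort(train)
  list(train = train, test = setdiff(seq_along(y), train))
}

# --- classifier families ------------------------------------------------

# AdaBoost.M1 over depth-1 rpart stumps.
fit_adaboost <- function(x, y, rounds) {
  y <- factor(y)
  n <- nrow(x)
  wts <- rep(1 / n, n)
  stumps <- list()
  alphas <- numeric(0)
  df <- data.frame(y = y, x, check.names = FALSE)
  for (m in seq_len(rounds)) {
    fit <- rpart::rpart(y ~ ., data = df, weights = wts, method = "class",
                        control = rpart::rpart.control(maxdepth = 1,
                                                       minsplit = 2,
                                                       cp = -1, xval = 0))
    pred <- predict(fit, df, type = "class")
    err <- sum(wts * (pred != y)) / sum(wts)
    if (err >= 0.5) break
    err <- max(err, 1e-10)
    alpha <- 0.5 * log((1 - err) / err)
    stumps[[length(stumps) + 1L]] <- fit
    alphas <- c(alphas, alpha)
    wts <- wts * exp(alpha * ifelse(pred != y, 1, -1))
    wts <- wts / sum(wts)
    if (err < 1e-9) break
  }
  if (!length(stumps)) {
    # no usable stump: fall back to the majority class
    structure(list(majority = names(which.max(table(y))),
                   levels = levels(y)), class = "ppgbp_adaboost")
  } else {
    structure(list(stumps = stumps, alphas = alphas, levels = levels(y)),
              class = "ppgbp_adaboost")
  }
}

predict_adaboost <- function(model, x) {
  if (!is.null(model$majority)) {
    return(factor(rep(model$majority, nrow(x)), levels = model$levels))
  }
  df <- as.data.frame(x, check.names = FALSE)
  score <- numeric(nrow(x))
  pos <- model$levels[2L]
  for (m in seq_along(model$stumps)) {
    pred <- predict(model$stumps[[m]], df, type = "class")
    score <- score + model$alphas[m] * ifelse(pred == pos, 1, -1)
  }
  factor(ifelse(score > 0, model$levels[2L], model$levels[1L]),
         levels = model$levels)
}

fit_one <- function(x, y, classifier, config) {
  y <- factor(y)
  switch(classifier,
    logistic = {
      df <- data.frame(y = y, x, check.names = FALSE)
      suppressWarnings(stats::glm(y ~ ., data = df, family = stats::binomial()))
    },
    knn = list(x = x, y = y, k = config$knn_k),
    adaboost_tree = fit_adaboost(x, y, config$adaboost_rounds),
    bagged_tree = randomForest::randomForest(
      x = x, y = y, ntree = config$bagged_trees, mtry = ncol(x)),
    stop("unknown classifier family: ", classifier))
}

predict_one <- function(model, x, classifier, levels) {
  switch(classifier,
    logistic = {
      pr <- suppressWarnings(
        stats::predict(model, newdata = as.data.frame(x, check.names = FALSE),
                       type = "response"))
      factor(ifelse(pr > 0.5, levels[2L], levels[1L]), levels = levels)
    },
    knn = class::knn(model$x, x, model$y, k = model$k),
    adaboost_tree = predict_adaboost(model, x),
    bagged_tree = stats::predict(model, x))
}

# column-wise scaler fit on training data only; also records the training
# medians used to impute missing feature values.
fit_scaler <- function(x) {
  mu <- apply(x, 2, mean, na.rm = TRUE)
  sd <- apply(x, 2, stats::sd, na.rm = TRUE)
  sd[!is.finite(sd) | sd == 0] <- 1
  med <- apply(x, 2, stats::median, na.rm = TRUE)
  list(mu = mu, sd = sd, med = med)
}

apply_scaler <- function(scaler, x) {
  x <- as.matrix(x)
  for (j in seq_len(ncol(x))) {
    x[is.na(x[, j]), j] <- scaler$med[j]
  }
  scale(x, center = scaler$mu, scale = scaler$sd)
}

#' Train one classifier with cross-validated F1
#'
#' Features are standardized (and missing values imputed by the column
#' median) using statistics computed from the training portion only --
#' within each cross-validation fold, from that fold's training part.
#' The final model is refit on the full training set.
#'
#' @param x training feature matrix.
#' @param y training labels (2 levels; the second level is the positive
#'   class).
#' @param classifier one of `"adaboost_tree"`, `"logistic"`, `"knn"`,
#'   `"bagged_tree"`.
#' @param seed integer seed for fold assignment.
#' @param config a [pipeline_config()] (`cv_folds` and classifier
#'   hyperparameters).
#' @return List of class `ppgbp_model`: `model`, `scaler`, `classifier`,
#'   `levels`, `cv_f1` (per-fold F1), `cv_f1_mean`, `cv_f1_sd`.
#' @export
train_with_cv <- function(x, y, classifier, seed,
                          config = pipeline_config()) {
  x <- as.matrix(x)
  y <- factor(y)
  stopifnot(nlevels(y) == 2L)
  n <- nrow(x)
  k <- min(config$cv_folds, n)
  if (k < config$cv_folds) {
    warning("fewer subjects than folds; using ", k, "-fold CV")
  }
  folds <- with_seed(seed, sample(rep_len(seq_len(k), n)))
  cv_f1 <- rep(NA_real_, k)
  for (f in seq_len(k)) {
    tr <- folds != f
    if (nlevels(droplevels(y[tr])) < 2L) next
    sc <- fit_scaler(x[tr, , drop = FALSE])
    m <- fit_one(apply_scaler(sc, x[tr, , drop = FALSE]), y[tr],
                 classifier, config)
    pred <- predict_one(m, apply_scaler(sc, x[!tr, , drop = FALSE]),
                        classifier, levels(y))
    cv_f1[f] <- evaluate(pred, y[!tr], positive = levels(y)[2L])$f1
  }
  scaler <- fit_scaler(x)
  model <- fit_one(apply_scaler(scaler, x), y, classifier, config)
  structure(list(model = model, scaler = scaler, classifier = classifier,
                 levels = levels(y), cv_f1 = cv_f1,
                 cv_f1_mean = mean(cv_f1, na.rm = TRUE),
                 cv_f1_sd = stats::sd(cv_f1, na.rm = TRUE)),
            class = "ppgbp_model")
}

#' Predict with a trained model
#'
#' @param object a `ppgbp_model` from [train_with_cv()].
#' @param newdata feature matrix.
#' @param ... unused.
#' @return Factor of predicted labels.
#' @export
predict.ppgbp_model <- function(object, newdata, ...) {
  predict_one(object$model, apply_scaler(object$scaler, as.matrix(newdata)),
              object$classifier, object$levels)
}

#' Binary classification metrics
#'
#' Confusion counts plus sensitivity (= recall), specificity, precision and
#' F1 = 2 x Recall x Precision / (Recall + Precision). By convention F1 is
#' 0 when there are no true positives.
#'
#' @param predictions,truth equal-length label vectors.
#' @param positive the positive-class label.
#' @return List: `tp`, `fp`, `tn`, `fn`, `sensitivity`, `specificity`,
#'   `precision`, `f1`.
#' @export
#' @examples
#' evaluate(c("a", "b", "b"), c("a", "b", "a"), positive = "b")
evaluate <- function(predictions, truth, positive) {
  if (length(predictions) != length(truth)) {
    stop("predictions and truth lengths differ")
  }
  if (!length(truth)) stop("empty input")
  pred_pos <- as.character(predictions) == positive
  true_pos <- as.character(truth) == positive
  tp <- sum(pred_pos & true_pos)
  fp <- sum(pred_pos & !true_pos)
  fn <- sum(!pred_pos & true_pos)
  tn <- sum(!pred_pos & !true_pos)
  sens <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
  spec <- if (tn + fp > 0) tn / (tn + fp) else NA_real_
  prec <- if (tp + fp > 0) tp / (tp + fp) else 0
  f1 <- if (tp == 0) 0 else 2 * sens * prec / (sens + prec)
  list(tp = tp, fp = fp, tn = tn, fn = fn,
       sensitivity = sens, specificity = spec, precision = prec, f1 = f1)
}

# trial definitions: classes retained and the positive class
trial_defs <- list(
  N_vs_P  = list(classes = c("normotension", "prehypertension"),
                 positive = "prehypertension"),
  N_vs_H  = list(classes = c("normotension", "hypertension"),
                 positive = "hypertension"),
  NP_vs_H = list(classes = c("normotension", "prehypertension",
                             "hypertension"),
                 positive = "hypertension")
)

feature_set_cols <- function(feature_set) {
  switch(feature_set,
         PAT = "pat",
         PPG10 = paste0("f", 1:10),
         "PAT+PPG10" = c("pat", paste0("f", 1:10)),
         stop("unknown feature set: ", feature_set))
}

#' Run the binary classification trials
#'
#' The full experimental grid: three binary trials (normotension vs
#' prehypertension; normotension vs hypertension; normo+prehypertension vs
#' hypertension) x three feature sets (PAT only; the ten PPG features; both)
#' x the classifier families, each with a stratified 70/30 split and
#' 10-fold cross-validation on the training portion, evaluated on the test
#' set.
#'
#' @param feature_table cohort feature table from [cohort_feature_table()]
#'   (columns `label`, `pat`, `f1`..`f10`).
#' @param seeds integer vector: one split/CV seed per repetition.
#' @param trials,feature_sets,classifiers subsets of the grid to run.
#' @param config a [pipeline_config()].
#' @return data.frame with one row per (trial, feature set, classifier,
#'   seed): confusion counts, `sensitivity`, `specificity`, `precision`,
#'   `f1`, `cv_f1_mean`, `cv_f1_sd`.
#' @export
run_trials <- function(feature_table, seeds = 1L,
                       trials = names(trial_defs),
                       feature_sets = c("PAT", "PPG10", "PAT+PPG10"),
                       classifiers = c("adaboost_tree", "logistic",
                                       "knn", "bagged_tree"),
                       config = pipeline_config()) {
  trials <- match.arg(trials, names(trial_defs), several.ok = TRUE)
  need <- unique(unlist(lapply(feature_sets, feature_set_cols)))
  miss <- setdiff(c("label", need), names(feature_table))
  if (length(miss)) {
    stop("feature table is missing column(s): ", paste(miss, collapse = ", "))
  }
  out <- list()
  for (tr in trials) {
    def <- trial_defs[[tr]]
    sub <- feature_table[feature_table$label %in% def$classes, , drop = FALSE]
    ybin <- factor(ifelse(sub$label == def$positive, def$positive,
                          "negative"),
                   levels = c("negative", def$positive))
    for (sd in seeds) {
      sp <- split_train_test(sub[, need, drop = FALSE], ybin, seed = sd,
                             train_frac = config$train_frac)
      for (fset in feature_sets) {
        cols <- feature_set_cols(fset)
        xall <- as.matrix(sub[, cols, drop = FALSE])
        for (clf in classifiers) {
          fit <- train_with_cv(xall[sp$train, , drop = FALSE],
                               ybin[sp$train], clf, seed = sd,
                               config = config)
          pred <- predict(fit, xall[sp$test, , drop = FALSE])
          m <- evaluate(pred, ybin[sp$test], positive = def$positive)
          out[[length(out) + 1L]] <- data.frame(
            trial = tr, feature_set = fset, classifier = clf, seed = sd,
            tp = m$tp, fp = m$fp, tn = m$tn, fn = m$fn,
            sensitivity = m$sensitivity, specificity = m$specificity,
            precision = m$precision, f1 = m$f1,
            cv_f1_mean = fit$cv_f1_mean, cv_f1_sd = fit$cv_f1_sd,
            stringsAsFactors = FALSE)
        }
      }
    }
  }
  do.call(rbind, out)
}

#' Mean metrics across seeds
#'
#' @param results output of [run_trials()].
#' @return data.frame of per-cell means (and F1 SD) across seeds.
#' @export
summarize_trials <- function(results) {
  key <- interaction(results$trial, results$feature_set,
                     results$classifier, drop = TRUE)
  rows <- lapply(split(results, key), function(g) {
    data.frame(trial = g$trial[1L], feature_set = g$feature_set[1L],
               classifier = g$classifier[1L], n_seeds = nrow(g),
               sensitivity = mean(g$sensitivity),
               specificity = mean(g$specificity),
               precision = mean(g$precision),
               f1 = mean(g$f1), f1_sd = stats::sd(g$f1),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out[order(out$trial, out$feature_set, out$classifier), ]
}
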