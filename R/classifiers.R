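#' The accepted classifier identifiers
#'
#' Eleven classifiers: logistic regression, support vector machine,
#' decision tree, random forest, k-nearest neighbors, two gradient
#' boosting variants (depth-wise `xgboost` and leaf-wise histogram
#' boosting under the `lightgbm` identifier), bagging, and three
#' imbalance-aware ensembles (easy ensemble, balanced random forest,
#' RUSBoost). All run with standard default hyperparameters; no
#' hyperparameter search is performed anywhere in the pipeline.
#'
#' @return Character vector of identifiers.
#' @export
classifier_roster <- function() {
  c("logistic", "svm", "decision_tree", "random_forest", "knn",
    "xgboost", "lightgbm", "easy_ensemble", "balanced_random_forest",
    "rusboost", "bagging")
}

# classifiers sensitive to feature scale get train-fitted z-scoring
.scale_sensitive <- c("logistic", "svm", "knn")

#' Fit a classifier on a training fold and score a test fold
#'
#' Fits on the training data only (which may already be SMOTE-augmented)
#' and emits, for the test rows, predicted labels plus continuous
#' positive-class scores for ROC/AUC. For scale-sensitive classifiers
#' (logistic, SVM, k-NN) features are z-scored with means/sds fitted on
#' the training fold; tree ensembles see raw features. Deterministic
#' given the seed.
#'
#' @param train_x,train_y training features (matrix/data frame) and
#'   two-class labels.
#' @param test_x test features.
#' @param classifier_name one of [classifier_roster()].
#' @param seed integer seed (default 1004).
#' @param positive positive-class label.
#' @return List with `predicted` (labels for `test_x`) and `scores`
#'   (positive-class score in [0, 1]).
#' @export
fit_predict_fold <- function(train_x, train_y, test_x,
                             classifier_name = "logistic", seed = 1004,
                             positive = "positive") {
  if (!classifier_name %in% classifier_roster()) {
    stop("unknown classifier_name: ", classifier_name)
  }
  if (length(unique(train_y)) < 2) {
    stop("training fold contains a single class")
  }
  train_x <- as.matrix(train_x)
  test_x <- as.matrix(test_x)
  storage.mode(train_x) <- "double"
  storage.mode(test_x) <- "double"
  if (classifier_name %in% .scale_sensitive) {
    mu <- colMeans(train_x)
    sigma <- apply(train_x, 2, sd)
    sigma[sigma == 0] <- 1
    train_x <- sweep(sweep(train_x, 2, mu), 2, sigma, "/")
    test_x <- sweep(sweep(test_x, 2, mu), 2, sigma, "/")
  }
  y <- factor(train_y == positive, levels = c(FALSE, TRUE),
              labels = c("neg", "pos"))
  rng <- local_rng(seed, "fit", classifier_name)
  scores <- switch(
    classifier_name,
    logistic = {
      df <- data.frame(train_x)
      fit <- suppressWarnings(
        glm(y ~ ., data = cbind(df, y = y), family = binomial())
      )
      as.numeric(suppressWarnings(
        predict(fit, data.frame(test_x), type = "response")
      ))
    },
    svm = {
      fit <- e1071::svm(train_x, y, probability = TRUE, kernel = "radial")
      pr <- attr(predict(fit, test_x, probability = TRUE), "probabilities")
      as.numeric(pr[, "pos"])
    },
    decision_tree = {
      fit <- rpart::rpart(y ~ ., data = data.frame(train_x, y = y),
                          method = "class")
      predict(fit, data.frame(test_x))[, "pos"]
    },
    random_forest = {
      fit <- randomForest::randomForest(train_x, y, ntree = 200)
      predict(fit, test_x, type = "prob")[, "pos"]
    },
    knn = {
      pred <- class::knn(train_x, test_x, y, k = 5, prob = TRUE)
      win <- attr(pred, "prob")
      ifelse(pred == "pos", win, 1 - win)
    },
    xgboost = .fit_xgb(train_x, y, test_x, seed, leafwise = FALSE),
    lightgbm = .fit_xgb(train_x, y, test_x, seed, leafwise = TRUE),
    easy_ensemble = .fit_easy_ensemble(train_x, y, test_x, seed),
    balanced_random_forest = {
      m <- min(table(y))
      fit <- randomForest::randomForest(
        train_x, y, ntree = 200, strata = y,
        sampsize = c(neg = m, pos = m)
      )
      predict(fit, test_x, type = "prob")[, "pos"]
    },
    rusboost = .fit_rusboost(train_x, y, test_x, seed),
    bagging = .fit_bagging(train_x, y, test_x, seed)
  )
  list(
    predicted = ifelse(scores >= 0.5, positive,
                       setdiff(unique(train_y), positive)[1]),
    scores = as.numeric(scores)
  )
}

.fit_xgb <- function(train_x, y, test_x, seed, leafwise) {
  params <- list(
    objective = "binary:logistic", eta = 0.3, nthread = 1,
    seed = seed %% .Machine$integer.max
  )
  if (leafwise) {
    # leaf-wise histogram growth (the LightGBM tree-building strategy)
    params <- c(params, list(tree_method = "hist",
                             grow_policy = "lossguide",
                             max_leaves = 31, max_depth = 0))
  } else {
    params <- c(params, list(max_depth = 6))
  }
  dtrain <- xgboost::xgb.DMatrix(train_x, label = as.numeric(y == "pos"))
  fit <- xgboost::xgb.train(params, dtrain, nrounds = 100, verbose = 0)
  predict(fit, xgboost::xgb.DMatrix(test_x))
}

# AdaBoost.M1 with shallow rpart weak learners; returns a score function
# margin mapped to [0, 1]
.adaboost_scores <- function(train_x, y, test_x, n_rounds = 30,
                             maxdepth = 3, sample_rows = NULL) {
  n <- nrow(train_x)
  w <- rep(1 / n, n)
  margin <- numeric(nrow(test_x))
  total_alpha <- 0
  ylab <- ifelse(y == "pos", 1, -1)
  ctrl <- rpart::rpart.control(maxdepth = maxdepth, cp = 0, minsplit = 5,
                               xval = 0)
  df_train <- data.frame(train_x)
  df_test <- data.frame(test_x)
  for (m in seq_len(n_rounds)) {
    rows <- if (is.null(sample_rows)) seq_len(n) else sample_rows(w)
    fit <- rpart::rpart(y ~ ., data = cbind(df_train[rows, , drop = FALSE],
                                            y = y[rows]),
                        weights = w[rows] / sum(w[rows]),
                        method = "class", control = ctrl)
    pred_train <- ifelse(
      predict(fit, df_train)[, "pos"] >= 0.5, 1, -1
    )
    err <- sum(w * (pred_train != ylab)) / sum(w)
    if (err >= 0.5 || err == 0) {
      if (err == 0) {
        margin <- margin + 3 * ifelse(
          predict(fit, df_test)[, "pos"] >= 0.5, 1, -1)
        total_alpha <- total_alpha + 3
      }
      break
    }
    alpha <- 0.5 * log((1 - err) / err)
    w <- w * exp(-alpha * ylab * pred_train)
    w <- w / sum(w)
    margin <- margin + alpha * ifelse(
      predict(fit, df_test)[, "pos"] >= 0.5, 1, -1)
    total_alpha <- total_alpha + alpha
  }
  if (total_alpha == 0) return(rep(0.5, nrow(test_x)))
  (margin / total_alpha + 1) / 2
}

# ensemble of AdaBoost learners, each on a balanced random undersample of
# the majority class
.fit_easy_ensemble <- function(train_x, y, test_x, seed, n_bags = 10) {
  counts <- table(y)
  minority <- names(counts)[which.min(counts)]
  min_idx <- which(y == minority)
  maj_idx <- which(y != minority)
  scores <- matrix(0, nrow = nrow(test_x), ncol = n_bags)
  for (b in seq_len(n_bags)) {
    take <- sample(maj_idx, length(min_idx))
    idx <- c(min_idx, take)
    scores[, b] <- .adaboost_scores(
      train_x[idx, , drop = FALSE], y[idx], test_x
    )
  }
  rowMeans(scores)
}

# boosting with random undersampling of the majority class at each round
.fit_rusboost <- function(train_x, y, test_x, seed, n_rounds = 30) {
  counts <- table(y)
  minority <- names(counts)[which.min(counts)]
  min_idx <- which(y == minority)
  maj_idx <- which(y != minority)
  sampler <- function(w) {
    c(min_idx, sample(maj_idx, length(min_idx)))
  }
  .adaboost_scores(train_x, y, test_x, n_rounds = n_rounds,
                   sample_rows = sampler)
}

# bootstrap-aggregated decision trees
.fit_bagging <- function(train_x, y, test_x, seed, n_trees = 25) {
  df_train <- data.frame(train_x)
  df_test <- data.frame(test_x)
  ctrl <- rpart::rpart.control(cp = 0.01, xval = 0)
  scores <- matrix(0, nrow = nrow(test_x), ncol = n_trees)
  for (b in seq_len(n_trees)) {
    idx <- sample.int(nrow(train_x), replace = TRUE)
    if (length(unique(y[idx])) < 2) {
      scores[, b] <- mean(y == "pos")
      next
    }
    fit <- rpart::rpart(y ~ ., data = cbind(df_train[idx, , drop = FALSE],
                                            y = y[idx]),
                        method = "class", control = ctrl)
    scores[, b] <- predict(fit, df_test)[, "pos"]
  }
  rowMeans(scores)
}
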