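# small separable fixture: two Gaussian blobs, grouped by participant
blob_records <- function(n_per_class = 40, n_participants = 10, sep = 4,
                         seed = 99) {
  withr::with_seed(seed, {
    n <- 2 * n_per_class
    x1 <- c(rnorm(n_per_class, 0), rnorm(n_per_class, sep))
    x2 <- c(rnorm(n_per_class, 0), rnorm(n_per_class, sep))
    tibble::tibble(
      participant_id = rep_len(sprintf("p%02d", 1:n_participants), n),
      valence = rep(c("negative", "positive"), each = n_per_class),
      f1 = x1, f2 = x2
    )
  })
}

test_that("grouped folds partition participants with no overlap", {
  ids <- rep(sprintf("p%02d", 1:40), each = 3)
  for (k in c(3L, 5L, 7L)) {
    plan <- group_kfold_split(ids, k, seed = 1004)
    expect_length(plan, k)
    test_sets <- unlist(lapply(plan, `[[`, "test"))
    expect_setequal(test_sets, unique(ids))
    expect_equal(anyDuplicated(test_sets), 0L)
    for (fold in plan) {
      expect_length(intersect(fold$train, fold$test), 0)
      expect_setequal(c(fold$train, fold$test), unique(ids))
    }
  }
  plan5 <- group_kfold_split(ids, 5L, seed = 1004)
  expect_true(all(vapply(plan5, function(f) length(f$test), integer(1)) == 8L))
  expect_error(group_kfold_split(c("a", "b"), 5), "participants")
})

test_that("SMOTE balances classes by segment interpolation", {
  x <- rbind(matrix(rnorm(20), 10, 2),
             matrix(rnorm(8, mean = 5), 4, 2))
  y <- c(rep("negative", 10), rep("positive", 4))
  out <- smote_oversample(x, y, k_neighbors = 2, seed = 1)
  expect_equal(unname(table(out$labels)["positive"]), 10L)
  expect_equal(unname(table(out$labels)["negative"]), 10L)
  expect_equal(sum(out$provenance$synthetic), 6L)
  # synthetic rows derive only from minority rows
  src <- out$provenance[out$provenance$synthetic, ]
  expect_true(all(src$source_row %in% 11:14))
  expect_true(all(src$neighbor_row %in% 11:14))

  # two-point minority with k = 1: synthetic points lie on the segment
  x2 <- rbind(matrix(rnorm(40, 5), 20, 2), c(0, 0), c(1, 1))
  y2 <- c(rep("negative", 20), "positive", "positive")
  out2 <- smote_oversample(x2, y2, k_neighbors = 1, seed = 2)
  synth <- out2$features[out2$provenance$synthetic, , drop = FALSE]
  expect_true(all(abs(synth[, 1] - synth[, 2]) < 1e-9))
  expect_true(all(synth[, 1] >= 0 & synth[, 1] <= 1))

  # balanced input unchanged; too-small minority errors
  bal <- smote_oversample(x[1:8, ], rep(c("a", "b"), each = 4), 2, 1)
  expect_identical(bal$features, x[1:8, ])
  expect_error(smote_oversample(x2, y2, k_neighbors = 5, seed = 1),
               "smaller k")
  # determinism
  outA <- smote_oversample(x, y, 2, seed = 7)
  outB <- smote_oversample(x, y, 2, seed = 7)
  expect_identical(outA$features, outB$features)
})

test_that("all eleven classifiers fit, score and are deterministic", {
  rec <- blob_records()
  x <- as.matrix(rec[, c("f1", "f2")])
  tr <- c(1:30, 41:70)
  te <- c(31:40, 71:80)
  expect_length(classifier_roster(), 11)
  for (cl in classifier_roster()) {
    a <- fit_predict_fold(x[tr, ], rec$valence[tr], x[te, ], cl,
                          seed = 1004)
    b <- fit_predict_fold(x[tr, ], rec$valence[tr], x[te, ], cl,
                          seed = 1004)
    expect_identical(a$scores, b$scores)
    expect_true(all(a$scores >= 0 & a$scores <= 1))
    expect_length(a$predicted, length(te))
    # separable blobs: every classifier should do clearly better than chance
    auc <- rank_auc(rec$valence[te], a$scores)
    expect_gt(auc, 0.8)
  }
  expect_error(fit_predict_fold(x[tr, ], rec$valence[tr], x[te, ], "mlp"),
               "unknown classifier")
  expect_error(
    fit_predict_fold(x[1:10, ], rep("positive", 10), x[te, ], "logistic"),
    "single class"
  )
})

test_that("logistic separates a linearly separable training set", {
  rec <- blob_records(sep = 10)
  x <- as.matrix(rec[, c("f1", "f2")])
  fit <- fit_predict_fold(x, rec$valence, x, "logistic", seed = 1004)
  expect_equal(mean(fit$predicted == rec$valence), 1.0)
})

test_that("confusion-matrix metrics match hand-computed values", {
  # tp = 8, fn = 2, fp = 1, tn = 9
  truth <- c(rep("positive", 10), rep("negative", 10))
  pred <- c(rep("positive", 8), rep("negative", 2),
            "positive", rep("negative", 9))
  scores <- ifelse(pred == "positive", 0.9, 0.1)
  m <- compute_metrics(truth, pred, scores)
  expect_equal(m$tp, 8)
  expect_equal(m$fn, 2)
  expect_equal(m$fp, 1)
  expect_equal(m$tn, 9)
  expect_equal(m$accuracy, 17 / 20, tolerance = 1e-9)
  expect_equal(m$precision, 8 / 9, tolerance = 1e-9)
  expect_equal(m$recall, 0.8, tolerance = 1e-9)
  expect_equal(m$specificity, 0.9, tolerance = 1e-9)
  expect_equal(m$f1, 2 * (8 / 9) * 0.8 / ((8 / 9) + 0.8), tolerance = 1e-9)
  expect_equal(m$p4, 4 / (9 / 8 + 10 / 8 + 10 / 9 + 11 / 9),
               tolerance = 1e-9)

  perfect <- compute_metrics(truth, truth,
                             ifelse(truth == "positive", 1, 0))
  expect_true(all(unlist(perfect[c("accuracy", "precision", "recall",
                                   "specificity", "f1", "auc", "p4")]) == 1))
})

test_that("P4 is symmetric under class swap and flags degenerate counts", {
  expect_equal(as.numeric(p4_score(8, 1, 9, 2)),
               as.numeric(p4_score(9, 2, 8, 1)), tolerance = 1e-12)
  expect_equal(as.numeric(p4_score(5, 5, 5, 5)), 0.5)
  z <- p4_score(0, 0, 10, 0)
  expect_equal(as.numeric(z), 0)
  expect_true(attr(z, "flagged"))
})

test_that("AUC follows the tie and monotone-invariance conventions", {
  labs <- c(rep("positive", 5), rep("negative", 5))
  expect_equal(rank_auc(labs, rep(0.5, 10)), 0.5)
  withr::with_seed(13, {
    s <- runif(10)
    expect_equal(rank_auc(labs, s), rank_auc(labs, exp(3 * s)),
                 tolerance = 1e-12)
    # independent cross-check against pROC
    expect_equal(
      rank_auc(labs, s),
      as.numeric(pROC::auc(pROC::roc(labs, s, levels = c("negative",
                                                         "positive"),
                                     direction = "<", quiet = TRUE))),
      tolerance = 1e-9
    )
  })
})

test_that("run_cv keeps folds leakage-free with and without SMOTE", {
  rec <- blob_records(n_per_class = 30, n_participants = 12)
  feats <- feature_names()
  # embed the 2-d blob into the 45-feature contract
  for (f in feats) rec[[f]] <- 0
  rec$aupc <- rec$f1
  rec$s_aupc <- rec$f2
  rec$mean <- rec$f1 + rec$f2
  cfg <- run_config(cv_folds = 3, classifier_name = "logistic")
  cv_plain <- run_cv(rec, cfg)
  cfg_smote <- run_config(cv_folds = 3, classifier_name = "logistic",
                          smote_k_neighbors = 3)
  cv_smote <- run_cv(rec, cfg_smote)
  for (i in seq_along(cv_plain$fold_plan)) {
    expect_length(intersect(cv_plain$fold_plan[[i]]$train,
                            cv_plain$fold_plan[[i]]$test), 0)
  }
  # SMOTE must not alter which rows are evaluated
  expect_identical(cv_plain$fold_plan, cv_smote$fold_plan)
  expect_equal(nrow(cv_plain$per_fold), 3)
  expect_true(all(c("accuracy", "auc", "p4") %in% cv_plain$summary$metric))
})

test_that("folds with a single-class test set are flagged, not dropped", {
  rec <- blob_records(n_per_class = 21, n_participants = 3)
  # with 3 participants and 3 folds each test set is one participant;
  # make p01's trials all positive so one fold is single-class
  rec$valence[rec$participant_id == "p01"] <- "positive"
  feats <- feature_names()
  withr::with_seed(61, for (f in feats) rec[[f]] <- rnorm(nrow(rec)))
  cv <- run_cv(rec, run_config(cv_folds = 3, classifier_name = "logistic"))
  expect_equal(nrow(cv$per_fold), 3)
  expect_true(any(cv$per_fold$flagged))
})

test_that("mean ROC interpolates folds and matches fold AUC means", {
  withr::with_seed(17, {
    folds <- lapply(1:5, function(i) {
      lab <- rep(c("positive", "negative"), each = 100)
      sc <- c(rnorm(100, 1), rnorm(100, 0))
      list(labels = lab, scores = sc)
    })
    mr <- mean_roc(folds)
    expect_equal(mr$curve$fpr[1], 0)
    expect_equal(mr$curve$mean_tpr[1], 0)
    expect_equal(mr$curve$mean_tpr[101], 1)
    expect_true(all(diff(mr$curve$mean_tpr) >= -1e-9))
    expect_equal(mr$mean_auc, mean(mr$fold_auc), tolerance = 1e-12)
    # trapezoidal area under the averaged curve ~ mean fold AUC
    area <- sum(diff(mr$curve$fpr) *
                  (head(mr$curve$mean_tpr, -1) + mr$curve$mean_tpr[-1]) / 2)
    expect_lt(abs(area - mr$mean_auc), 0.02)
  })
  # one perfect fold passes through (0, 1)
  perfect <- list(list(labels = c("positive", "negative"),
                       scores = c(1, 0)))
  mp <- mean_roc(perfect)
  expect_equal(mp$curve$mean_tpr[2], 1)
  # random scores at large n stay near the diagonal
  withr::with_seed(18, {
    rand <- list(list(labels = rep(c("positive", "negative"), 2000),
                      scores = runif(4000)))
    mrnd <- mean_roc(rand)
    expect_lt(abs(mrnd$mean_auc - 0.5), 0.05)
    expect_lt(max(abs(mrnd$curve$mean_tpr - mrnd$curve$fpr)), 0.08)
  })
})

test_that("grid runs stratify cells and skip degenerate ones", {
  rec <- blob_records(n_per_class = 60, n_participants = 12)
  feats <- feature_names()
  for (f in feats) rec[[f]] <- rnorm(nrow(rec))
  rec$aupc <- rec$f1 * 3
  withr::with_seed(41, {
    rec$arousal_level <- sample(c("low", "high"), nrow(rec), replace = TRUE)
    rec$sf_level <- sample(1:2, nrow(rec), replace = TRUE)
  })
  # one cell made single-class: must be reported absent
  rec$valence[rec$arousal_level == "low" & rec$sf_level == 1] <- "positive"
  gr <- grid_run(rec, run_config(), classifiers = "logistic",
                 smote_k = NA, folds = 3L)
  expect_true(nrow(gr$cells) >= 1)
  expect_true(any(gr$absent$reason == "single class"))
  expect_true(all(c("mean_auc", "mean_p4") %in% names(gr$cells)))
  expect_equal(nrow(gr$best$by_auc),
               nrow(dplyr::distinct(gr$cells, arousal_level, sf_level)))
  # determinism
  gr2 <- grid_run(rec, run_config(), classifiers = "logistic",
                  smote_k = NA, folds = 3L)
  expect_identical(gr$cells, gr2$cells)
})

test_that("linear attribution is exact for the linear model family", {
  rec <- blob_records(n_per_class = 50, n_participants = 10, sep = 3)
  feats <- feature_names()
  for (f in feats) rec[[f]] <- rnorm(nrow(rec))
  rec$aupc <- rec$f1
  att <- feature_attribution(rec, "linear")
  expect_equal(att$method, "linear_shapley")
  # the only informative feature dominates the ranking
  expect_equal(att$ranking$feature[1], "aupc")
  # a zero-coefficient (pure noise) feature has near-zero attribution
  # relative to the signal feature
  signal <- att$full_ranking$mean_abs[att$full_ranking$feature == "aupc"]
  expect_gt(signal, 5 * median(att$full_ranking$mean_abs))
  # per-sample contributions are centered
  expect_lt(max(abs(colMeans(att$contributions))), 1e-9)
})

test_that("duplicated signal features split their linear attribution", {
  withr::with_seed(55, {
    n <- 200
    z <- rnorm(n)
    y <- ifelse(z + rnorm(n, sd = 0.5) > 0, "positive", "negative")
    rec <- tibble::tibble(participant_id = rep(sprintf("p%d", 1:10), 20),
                          valence = y)
    for (f in feature_names()) rec[[f]] <- rnorm(n)
    rec$aupc <- z
    single <- feature_attribution(rec, "linear")
    rec2 <- rec
    rec2$s_aupc <- z # exact duplicate of the signal
    dup <- feature_attribution(rec2, "linear")
    tot_single <- single$full_ranking$mean_abs[
      single$full_ranking$feature == "aupc"]
    tot_dup <- sum(dup$full_ranking$mean_abs[
      dup$full_ranking$feature %in% c("aupc", "s_aupc")])
    # combined attribution of the duplicated pair ~ the single-feature one
    expect_lt(abs(tot_dup - tot_single) / tot_single, 0.35)
  })
})
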