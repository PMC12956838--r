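#' Grouped k-fold plan over participants
#'
#' Partitions the distinct participants into k near-equal groups by a
#' seeded shuffle. All trials of a participant fall in the same fold, so
#' no participant ever appears in both the training and the test side of
#' a split.
#'
#' @param participant_ids participant id per record (duplicates fine).
#' @param k number of folds.
#' @param seed integer seed.
#' @return A `fold_plan`: list of k lists with `train` and `test`
#'   participant sets.
#' @export
group_kfold_split <- function(participant_ids, k, seed = 1004) {
  participants <- sort(unique(as.character(participant_ids)))
  if (length(participants) < k) {
    stop(sprintf("only %d participants for k = %d folds",
                 length(participants), k))
  }
  rng <- local_rng(seed, "group_kfold", k)
  shuffled <- sample(participants)
  fold_of <- rep_len(seq_len(k), length(shuffled))
  plan <- lapply(seq_len(k), function(i) {
    list(
      test = sort(shuffled[fold_of == i]),
      train = sort(shuffled[fold_of != i])
    )
  })
  structure(plan, class = "fold_plan")
}

#' Run grouped cross-validation for one configuration
#'
#' For each fold: optionally SMOTE-augment the training rows (test rows
#' are never touched, and synthetic samples derive only from training
#' rows), fit the configured classifier, and evaluate on the held-out
#' participants. A fold whose test set lacks a class is kept with its
#' metrics flagged.
#'
#' @param records tibble with `participant_id`, `valence` and the 45
#'   feature columns.
#' @param config a [run_config()]; `smote_k_neighbors = NA` disables
#'   oversampling.
#' @return List with `per_fold` (tibble of fold metrics), `summary`
#'   (mean and sd per metric), `roc` (see [mean_roc()]) and `fold_plan`.
#' @export
run_cv <- function(records, config = run_config()) {
  feats <- feature_names()
  missing_cols <- setdiff(c("participant_id", "valence", feats),
                          names(records))
  if (length(missing_cols) > 0) {
    stop("records are missing column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  plan <- group_kfold_split(records$participant_id, config$cv_folds,
                            config$random_seed)
  x_all <- as.matrix(records[, feats])
  per_fold <- vector("list", length(plan))
  roc_folds <- vector("list", length(plan))
  for (i in seq_along(plan)) {
    tr_rows <- records$participant_id %in% plan[[i]]$train
    te_rows <- records$participant_id %in% plan[[i]]$test
    train_x <- x_all[tr_rows, , drop = FALSE]
    train_y <- records$valence[tr_rows]
    if (!is.na(config$smote_k_neighbors)) {
      aug <- smote_oversample(train_x, train_y,
                              config$smote_k_neighbors,
                              seed = config$random_seed + i)
      train_x <- aug$features
      train_y <- aug$labels
    }
    fp <- fit_predict_fold(train_x, train_y,
                           x_all[te_rows, , drop = FALSE],
                           config$classifier_name,
                           seed = config$random_seed)
    m <- compute_metrics(records$valence[te_rows], fp$predicted, fp$scores)
    per_fold[[i]] <- dplyr::mutate(m, fold = i, .before = 1)
    roc_folds[[i]] <- list(labels = records$valence[te_rows],
                           scores = fp$scores)
  }
  per_fold <- dplyr::bind_rows(per_fold)
  metric_cols <- c("accuracy", "precision", "recall", "specificity",
                   "f1", "auc", "p4")
  summary <- tibble::tibble(
    metric = metric_cols,
    mean = unname(vapply(metric_cols, function(mc) mean(per_fold[[mc]]),
                         numeric(1))),
    sd = unname(vapply(metric_cols, function(mc) sd(per_fold[[mc]]),
                       numeric(1)))
  )
  list(
    per_fold = per_fold,
    summary = summary,
    roc = mean_roc(roc_folds),
    fold_plan = plan
  )
}

#' Stratified grid run over arousal x spatial-frequency cells
#'
#' Splits the records by (arousal_level, sf_level) and, within every cell
#' that has at least `cv_folds` samples of each class, runs grouped
#' cross-validation for every combination of classifier, SMOTE neighbor
#' count and fold count requested. Per cell, the best configuration is
#' recorded twice: once by mean AUC and once by mean P4 (the two
#' selection conventions used in different parts of the analysis). Cells
#' that are empty, single-class or too small are reported as absent, not
#' imputed.
#'
#' @param records feature table joined with metadata (must carry
#'   `arousal_level` and `sf_level` columns).
#' @param config a [run_config()] (supplies the seed).
#' @param classifiers subset of [classifier_roster()] to evaluate.
#' @param smote_k SMOTE neighbor values; `NA` entries mean no
#'   oversampling.
#' @param folds fold counts, each in {3, 5, 7}.
#' @return List with `cells` (per-configuration results), `best`
#'   (per-cell winners by AUC and by P4), `absent` (skipped cells), and
#'   `p4_table` (cell x best-P4 heatmap table).
#' @export
grid_run <- function(records, config = run_config(),
                     classifiers = "logistic",
                     smote_k = NA_integer_,
                     folds = 5L) {
  stopifnot(all(folds %in% c(3L, 5L, 7L)),
            all(classifiers %in% classifier_roster()))
  if (!all(c("arousal_level", "sf_level") %in% names(records))) {
    stop("records must carry `arousal_level` and `sf_level` columns")
  }
  cells <- dplyr::distinct(records, .data$arousal_level, .data$sf_level)
  cells <- dplyr::arrange(cells, .data$arousal_level, .data$sf_level)
  results <- list()
  absent <- list()
  for (ci in seq_len(nrow(cells))) {
    al <- cells$arousal_level[ci]
    sl <- cells$sf_level[ci]
    sub <- dplyr::filter(records, .data$arousal_level == al,
                         .data$sf_level == sl)
    class_counts <- table(sub$valence)
    for (kf in folds) {
      enough <- length(class_counts) == 2 && all(class_counts >= kf) &&
        length(unique(sub$participant_id)) >= kf
      if (!enough) {
        absent[[length(absent) + 1L]] <- tibble::tibble(
          arousal_level = al, sf_level = sl, cv_folds = kf,
          n_samples = nrow(sub),
          reason = if (length(class_counts) < 2) "single class"
                   else "too few samples"
        )
        next
      }
      for (cl in classifiers) {
        for (sk in smote_k) {
          # a cell whose minority class cannot support this k is absent
          # for this configuration
          if (!is.na(sk) &&
              floor(min(class_counts) * (kf - 1) / kf) <= sk) {
            next
          }
          cfg <- run_config(
            random_seed = config$random_seed, cv_folds = kf,
            smote_k_neighbors = sk, classifier_name = cl,
            frames_per_trial = config$frames_per_trial
          )
          cv <- run_cv(sub, cfg)
          sm <- tidyr::pivot_wider(cv$summary, names_from = "metric",
                                   values_from = c("mean", "sd"))
          results[[length(results) + 1L]] <- dplyr::bind_cols(
            tibble::tibble(
              arousal_level = al, sf_level = sl, cv_folds = kf,
              k_neighbors = sk, model = cl, n_samples = nrow(sub),
              n_positive = as.integer(class_counts[["positive"]]),
              n_negative = as.integer(class_counts[["negative"]])
            ),
            sm
          )
        }
      }
    }
  }
  results <- dplyr::bind_rows(results)
  best_by <- function(col) {
    if (nrow(results) == 0) return(results)
    dplyr::slice_max(
      dplyr::group_by(results, .data$arousal_level, .data$sf_level),
      order_by = .data[[col]], n = 1, with_ties = FALSE
    ) |> dplyr::ungroup()
  }
  best_auc <- best_by("mean_auc")
  best_p4 <- best_by("mean_p4")
  p4_table <- if (nrow(results) > 0) {
    tidyr::pivot_wider(
      dplyr::select(best_p4, "arousal_level", "sf_level", "mean_p4"),
      names_from = "sf_level", values_from = "mean_p4",
      names_prefix = "sf"
    )
  } else tibble::tibble()
  list(
    cells = results,
    best = list(by_auc = best_auc, by_p4 = best_p4),
    absent = dplyr::bind_rows(absent),
    p4_table = p4_table
  )
}

#' Feature attribution for a fitted-model family
#'
#' For linear (logistic) models, per-sample contributions are exact
#' Shapley values under feature independence:
#' `phi_ij = beta_j * (x_ij - mean(x_j))` on the standardized feature
#' scale. For other families a seeded permutation importance on AUC is
#' used. Features are ranked by mean absolute contribution.
#'
#' @param records tibble with `valence` and the 45 feature columns.
#' @param model_family `"linear"` or `"permutation"`.
#' @param classifier_name classifier used for permutation importance.
#' @param seed integer seed.
#' @param top_n number of features in the ranking (default 20).
#' @return List with `method`, `ranking` (tibble: feature, mean_abs),
#'   and, for the linear family, `contributions` (sample x feature
#'   matrix of signed contributions).
#' @export
feature_attribution <- function(records, model_family = c("linear",
                                                          "permutation"),
                                classifier_name = "random_forest",
                                seed = 1004, top_n = 20) {
  model_family <- match.arg(model_family)
  feats <- feature_names()
  x <- as.matrix(records[, feats])
  y <- factor(records$valence == "positive", levels = c(FALSE, TRUE),
              labels = c("neg", "pos"))
  if (model_family == "linear") {
    mu <- colMeans(x)
    sigma <- apply(x, 2, sd)
    sigma[sigma == 0] <- 1
    xs <- sweep(sweep(x, 2, mu), 2, sigma, "/")
    fit <- suppressWarnings(
      glm(y ~ ., data = data.frame(xs, y = y), family = binomial())
    )
    beta <- stats::coef(fit)[-1]
    beta[is.na(beta)] <- 0
    centered <- sweep(xs, 2, colMeans(xs))
    contrib <- sweep(centered, 2, beta, "*")
    colnames(contrib) <- feats
    ranking <- tibble::tibble(
      feature = feats,
      mean_abs = colMeans(abs(contrib))
    )
  } else {
    plan_seed <- seed
    half <- group_kfold_split(records$participant_id, 2, plan_seed)
    tr <- records$participant_id %in% half[[1]]$train
    te <- !tr
    base <- fit_predict_fold(x[tr, ], records$valence[tr], x[te, ],
                             classifier_name, seed = seed)
    base_auc <- rank_auc(records$valence[te], base$scores)
    rng <- local_rng(seed, "permutation_importance")
    drops <- vapply(seq_along(feats), function(j) {
      xp <- x[te, , drop = FALSE]
      xp[, j] <- xp[sample.int(nrow(xp)), j]
      perm <- fit_predict_fold(x[tr, ], records$valence[tr], xp,
                               classifier_name, seed = seed)
      base_auc - rank_auc(records$valence[te], perm$scores)
    }, numeric(1))
    contrib <- NULL
    ranking <- tibble::tibble(feature = feats, mean_abs = pmax(drops, 0))
  }
  ranking <- dplyr::arrange(ranking, dplyr::desc(.data$mean_abs))
  list(
    method = if (model_family == "linear") "linear_shapley"
             else paste0("permutation_", classifier_name),
    ranking = head(ranking, top_n),
    full_ranking = ranking,
    contributions = contrib
  )
}
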