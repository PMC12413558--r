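#' Grouped k-fold partitions
#'
#' Every row of a group (here: all windows and organs of one patient) falls
#' entirely inside exactly one validation fold, so no patient ever sits on
#' both sides of a train/validation boundary — the cross-validation analogue
#' of the patient-level train/test split.
#'
#' @param groups Character/factor vector, one group id per row.
#' @param k Number of folds; default 5.
#' @param seed Integer seed for the group shuffle.
#' @return List of `k` lists, each with integer row indices `train` and
#'   `validation`.
#' @export
grouped_kfold <- function(groups, k = 5L, seed = 1L) {
  groups <- as.character(groups)
  ids <- unique(groups)
  k <- as.integer(k)
  if (length(ids) < k) {
    stop("need at least k = ", k, " distinct groups, got ", length(ids),
         call. = FALSE)
  }
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()),
          add = TRUE)
  set.seed(seed)
  # shuffle group ids, deal round-robin into folds
  shuffled <- sample(ids)
  fold_of_group <- stats::setNames(rep_len(seq_len(k), length(ids)), shuffled)
  fold <- unname(fold_of_group[groups])
  lapply(seq_len(k), function(j) {
    list(train = which(fold != j), validation = which(fold == j))
  })
}

#' Random-search space for the gradient-boosted classifier
#'
#' Standard gradient-boosting ranges sized for datasets of a few hundred to a
#' few thousand rows: tree count 50-500, depth 2-8, learning rate log-uniform
#' on 0.01-0.3, row/column subsampling 0.6-1, L2 regularization 0-5.
#'
#' @param n_iter Number of sampled configurations; default 50.
#' @param seed Integer seed for sampling configurations.
#' @return A `hyperparam_space` list.
#' @export
hyperparam_space <- function(n_iter = 50L, seed = 1L) {
  structure(list(n_iter = as.integer(n_iter), seed = as.integer(seed),
                 nrounds = c(50L, 500L), max_depth = c(2L, 8L),
                 eta = c(0.01, 0.3), subsample = c(0.6, 1),
                 colsample_bytree = c(0.6, 1), lambda = c(0, 5)),
            class = "hyperparam_space")
}

sample_configs <- function(space) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()),
          add = TRUE)
  set.seed(space$seed)
  n <- space$n_iter
  data.frame(
    nrounds = sample(space$nrounds[1L]:space$nrounds[2L], n, replace = TRUE),
    max_depth = sample(space$max_depth[1L]:space$max_depth[2L], n, replace = TRUE),
    eta = exp(stats::runif(n, log(space$eta[1L]), log(space$eta[2L]))),
    subsample = stats::runif(n, space$subsample[1L], space$subsample[2L]),
    colsample_bytree = stats::runif(n, space$colsample_bytree[1L],
                                    space$colsample_bytree[2L]),
    lambda = stats::runif(n, space$lambda[1L], space$lambda[2L])
  )
}

feature_matrix <- function(dataset) {
  manifest <- aggregated_feature_names()
  missing <- setdiff(manifest, names(dataset))
  if (length(missing) > 0L) {
    stop("dataset lacks feature column(s): ",
         paste(utils::head(missing, 3L), collapse = ", "), call. = FALSE)
  }
  as.matrix(dataset[manifest])
}

fit_booster <- function(X, y, config, seed = 1L) {
  d <- xgboost::xgb.DMatrix(X, label = y, nthread = 1L)
  xgboost::xgb.train(
    params = list(objective = "binary:logistic",
                  eta = config$eta, max_depth = config$max_depth,
                  subsample = config$subsample,
                  colsample_bytree = config$colsample_bytree,
                  lambda = config$lambda, nthread = 1L, seed = seed),
    data = d, nrounds = config$nrounds, verbose = 0)
}

# balanced accuracy (mean of sensitivity and specificity) at threshold 0.5
balanced_accuracy <- function(truth, prob) {
  pred <- as.integer(prob > 0.5)
  sens <- if (any(truth == 1L)) mean(pred[truth == 1L] == 1L) else NA_real_
  spec <- if (any(truth == 0L)) mean(pred[truth == 0L] == 0L) else NA_real_
  mean(c(sens, spec), na.rm = TRUE)
}

#' Random hyperparameter search with grouped cross-validation
#'
#' Evaluates `space$n_iter` sampled configurations by mean validation
#' balanced accuracy over grouped k-fold splits of one organ's training rows,
#' and returns the best (ties broken by sampling order). Fully reproducible
#' given the space and fold seeds.
#'
#' @param train A `feature_dataset` restricted to one organ, with both label
#'   classes present.
#' @param space A [hyperparam_space()].
#' @param k Folds; default 5.
#' @return List with `best` (one-row config data frame), `best_score`, and
#'   `cv` (all configs with their mean and per-fold scores).
#' @export
random_search <- function(train, space = hyperparam_space(), k = 5L) {
  stopifnot(inherits(space, "hyperparam_space"), nrow(train) > 0L)
  y <- train$label
  if (length(unique(y)) < 2L) {
    stop("training labels are single-class; cannot cross-validate",
         call. = FALSE)
  }
  X <- feature_matrix(train)
  folds <- grouped_kfold(train$patient_id, k = k, seed = space$seed)
  configs <- sample_configs(space)
  scores <- matrix(NA_real_, nrow(configs), length(folds))
  for (i in seq_len(nrow(configs))) {
    for (j in seq_along(folds)) {
      tr <- folds[[j]]$train; va <- folds[[j]]$validation
      if (length(unique(y[tr])) < 2L) next  # degenerate fold, skip
      m <- fit_booster(X[tr, , drop = FALSE], y[tr], configs[i, ], space$seed)
      prob <- predict(m, xgboost::xgb.DMatrix(X[va, , drop = FALSE], nthread = 1L))
      scores[i, j] <- balanced_accuracy(y[va], prob)
    }
  }
  mean_score <- rowMeans(scores, na.rm = TRUE)
  best_idx <- which.max(mean_score)
  cv <- cbind(configs, score = mean_score)
  list(best = configs[best_idx, , drop = FALSE],
       best_score = mean_score[best_idx], cv = cv)
}

#' Train the final model on all training rows
#'
#' @param train A `feature_dataset` restricted to one organ (both classes
#'   present).
#' @param config One-row hyperparameter configuration, e.g. `$best` from
#'   [random_search()].
#' @param seed Integer seed for the booster.
#' @return A `trained_model`: the fitted booster plus the frozen
#'   feature-order manifest and the hyperparameters.
#' @export
train_final <- function(train, config, seed = 1L) {
  y <- train$label
  if (length(unique(y)) < 2L) {
    stop("training labels are single-class; use a constant model instead",
         call. = FALSE)
  }
  X <- feature_matrix(train)
  booster <- fit_booster(X, y, config, seed)
  structure(list(booster = booster, manifest = aggregated_feature_names(),
                 config = config, seed = seed),
            class = "trained_model")
}

#' Constant-verdict model for single-class organs
#'
#' Some organs are never mislabeled in a cohort (in the simulated defect
#' modes the pubis, urethra, bladder and vagina are always captured), leaving
#' nothing for a classifier to learn. Such organs get a model that always
#' predicts the training class, reported as such rather than dropped.
#'
#' @param label The constant class (0 or 1).
#' @return A `constant_model`.
#' @export
constant_model <- function(label) {
  stopifnot(label %in% c(0L, 1L))
  structure(list(label = as.integer(label)), class = "constant_model")
}

#' Predicted probabilities for dataset rows
#'
#' @param object A `trained_model` or `constant_model`.
#' @param newdata A `feature_dataset` (any subset of rows). Its feature
#'   columns must match the model's manifest exactly — a permuted or altered
#'   column set is rejected.
#' @param ... Unused.
#' @return Numeric vector of per-row probabilities that the organ was
#'   correctly captured.
#' @export
predict.trained_model <- function(object, newdata, ...) {
  present <- intersect(names(newdata), c(object$manifest, "patient_id",
                                         "organ", "window_index", "label"))
  feat_cols <- setdiff(present, c("patient_id", "organ", "window_index", "label"))
  if (!identical(feat_cols, object$manifest)) {
    stop("feature columns do not match the model's training manifest",
         call. = FALSE)
  }
  X <- as.matrix(newdata[object$manifest])
  predict(object$booster, xgboost::xgb.DMatrix(X, nthread = 1L))
}

#' @export
predict.constant_model <- function(object, newdata, ...) {
  rep(as.numeric(object$label), nrow(newdata))
}

#' Train one model per organ
#'
#' Runs [random_search()] and [train_final()] independently for each of the
#' eight organs on its rows of the training dataset; organs whose training
#' labels are single-class get a [constant_model()].
#'
#' @param train A `feature_dataset` (all organs).
#' @param space A [hyperparam_space()].
#' @param k Folds for the grouped cross-validation; default 5.
#' @return An `organ_models` list: per organ, the fitted model plus the CV
#'   record (`NULL` for constant models).
#' @export
train_organ_models <- function(train, space = hyperparam_space(), k = 5L) {
  models <- lapply(organ_ids(), function(org) {
    rows <- train[train$organ == org, , drop = FALSE]
    if (nrow(rows) == 0L) stop("no training rows for organ '", org, "'",
                               call. = FALSE)
    if (length(unique(rows$label)) < 2L) {
      list(model = constant_model(rows$label[1L]), cv = NULL, best_score = NA_real_)
    } else {
      search <- random_search(rows, space, k)
      list(model = train_final(rows, search$best, seed = space$seed),
           cv = search$cv, best_score = search$best_score)
    }
  })
  names(models) <- organ_ids()
  structure(models, class = "organ_models")
}

#' Per-video verdict from one patient's feature rows
#'
#' Each organ's probability is the mean of its window-row probabilities; the
#' organ verdict is `probability > 0.5`; the plane verdict is the conjunction
#' of the eight organ verdicts — a plane is correct only if every organ was
#' captured.
#'
#' @param models An `organ_models` object from [train_organ_models()].
#' @param rows `feature_dataset` rows of a single patient, covering at least
#'   one window for each organ.
#' @return A `video_verdict`: list with `patient_id`, `organ_prob`,
#'   `organ_verdict` (named over [organ_ids()]) and `plane_correct`.
#' @export
predict_video <- function(models, rows) {
  stopifnot(inherits(models, "organ_models"))
  pid <- unique(rows$patient_id)
  if (length(pid) != 1L) stop("rows must belong to exactly one patient",
                              call. = FALSE)
  prob <- vapply(organ_ids(), function(org) {
    r <- rows[rows$organ == org, , drop = FALSE]
    if (nrow(r) == 0L) stop("no rows for organ '", org, "' of patient '",
                            pid, "'", call. = FALSE)
    mean(predict(models[[org]]$model, r))
  }, numeric(1L))
  verdict <- as.integer(prob > 0.5)
  structure(list(patient_id = pid,
                 organ_prob = prob,
                 organ_verdict = stats::setNames(verdict, organ_ids()),
                 plane_correct = as.integer(all(verdict == 1L))),
            class = "video_verdict")
}

#' Verdicts for every patient of a dataset
#'
#' @param models An `organ_models` object.
#' @param dataset A `feature_dataset`.
#' @return Data frame with one row per patient: `patient_id`, one 0/1 column
#'   per organ, and `plane_correct`.
#' @export
predict_verdicts <- function(models, dataset) {
  pids <- unique(dataset$patient_id)
  rows <- lapply(pids, function(pid) {
    v <- predict_video(models, dataset[dataset$patient_id == pid, , drop = FALSE])
    as.data.frame(c(list(patient_id = pid), as.list(v$organ_verdict),
                    list(plane_correct = v$plane_correct)),
                  stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
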