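# small separable dataset: two clearly separated feature regimes by label
make_toy_train <- function(n_patients = 10L, windows = 2L, organ = "rectum",
                           seed = 1L) {
  set.seed(seed)
  rows <- list()
  for (i in seq_len(n_patients)) {
    lab <- as.integer(i %% 2 == 0)
    for (w in seq_len(windows)) {
      feats <- if (lab == 1L) runif(68, 0.6, 1) else runif(68, 0, 0.4)
      rows[[length(rows) + 1L]] <- as.data.frame(
        c(list(patient_id = sprintf("P%03d", i), organ = organ,
               window_index = w - 1L),
          as.list(setNames(feats, aggregated_feature_names())),
          list(label = lab)))
    }
  }
  out <- do.call(rbind, rows)
  class(out) <- c("feature_dataset", "data.frame")
  out
}

test_that("grouped folds keep each patient on one side of every boundary", {
  groups <- rep(sprintf("P%02d", 1:10), each = 3L)
  folds <- grouped_kfold(groups, k = 5L, seed = 3L)
  expect_length(folds, 5L)
  all_val <- sort(unlist(lapply(folds, `[[`, "validation")))
  expect_identical(all_val, seq_along(groups))  # folds partition the rows
  for (f in folds) {
    expect_length(intersect(groups[f$train], groups[f$validation]), 0L)
    expect_identical(length(unique(groups[f$validation])), 2L)
  }
  expect_error(grouped_kfold(rep(c("a", "b", "c", "d"), 2L), k = 5L),
               "distinct groups")
})

test_that("random search is reproducible and degenerates to its only candidate", {
  train <- make_toy_train()
  space1 <- hyperparam_space(n_iter = 1L, seed = 8L)
  res1 <- random_search(train, space1, k = 5L)
  expect_identical(res1$best, res1$cv[, names(res1$best)])

  space <- hyperparam_space(n_iter = 3L, seed = 8L)
  res_a <- random_search(train, space, k = 5L)
  res_b <- random_search(train, space, k = 5L)
  expect_identical(res_a$best, res_b$best)
  expect_identical(res_a$cv, res_b$cv)
  expect_gte(res_a$best_score, 0.9)  # separable toy data

  single <- train; single$label <- 1L
  expect_error(random_search(single, space), "single-class")
})

test_that("the final model is deterministic and guards its feature manifest", {
  train <- make_toy_train()
  config <- data.frame(nrounds = 50L, max_depth = 3L, eta = 0.2,
                       subsample = 0.9, colsample_bytree = 0.9, lambda = 1)
  m1 <- train_final(train, config, seed = 5L)
  m2 <- train_final(train, config, seed = 5L)
  p1 <- predict(m1, train); p2 <- predict(m2, train)
  expect_identical(p1, p2)
  expect_gte(mean((p1 > 0.5) == (train$label == 1L)), 0.95)

  permuted <- train[, c(1:3, sample(4:71), 72)]
  expect_error(predict(m1, permuted), "manifest")
  expect_error(train_final(transform(train, label = 0L), config), "single-class")
})

test_that("video verdicts are mean-then-threshold per organ, AND for the plane", {
  # stub models with fixed per-organ probabilities
  stub <- function(p) structure(list(p = p), class = "stub_model")
  .S3method("predict", "stub_model",
            function(object, newdata, ...) rep(object$p, nrow(newdata)))
  make_models <- function(probs) {
    m <- lapply(probs, function(p) list(model = stub(p)))
    names(m) <- organ_ids()
    class(m) <- "organ_models"
    m
  }
  rows <- make_toy_train(n_patients = 1L, windows = 2L)
  rows <- do.call(rbind, lapply(organ_ids(), function(o) transform(rows, organ = o)))
  class(rows) <- c("feature_dataset", "data.frame")

  v <- predict_video(make_models(rep(0.9, 8L)), rows)
  expect_identical(v$plane_correct, 1L)

  probs <- setNames(rep(0.9, 8L), organ_ids()); probs["rectum"] <- 0.2
  v2 <- predict_video(make_models(as.list(probs)), rows)
  expect_identical(unname(v2$organ_verdict["rectum"]), 0L)
  expect_identical(v2$plane_correct, 0L)

  # two windows at 0.4 and 0.8 average to 0.6 -> verdict 1
  .S3method("predict", "two_window_model",
            function(object, newdata, ...) c(0.4, 0.8))
  mm <- make_models(rep(0.9, 8L))
  mm$anus$model <- structure(list(), class = "two_window_model")
  v3 <- predict_video(mm, rows)
  expect_equal(unname(v3$organ_prob["anus"]), 0.6)
  expect_identical(unname(v3$organ_verdict["anus"]), 1L)

  expect_error(predict_video(mm, rows[rows$organ != "anus", ]), "anus")
})

test_that("constant models back single-class organs and propagate to verdicts", {
  cm <- constant_model(1L)
  expect_identical(predict(cm, data.frame(x = 1:3)), c(1, 1, 1))
  expect_error(constant_model(2L))

  train <- make_toy_train(n_patients = 6L)
  full <- do.call(rbind, lapply(organ_ids(), function(o) {
    df <- transform(train, organ = o)
    if (o == "vagina") df$label <- 1L  # degenerate organ
    df
  }))
  class(full) <- c("feature_dataset", "data.frame")
  models <- train_organ_models(full, hyperparam_space(n_iter = 1L, seed = 2L),
                               k = 3L)
  expect_s3_class(models$vagina$model, "constant_model")
  expect_s3_class(models$rectum$model, "trained_model")
  verdicts <- predict_verdicts(models, full)
  expect_true(all(verdicts$vagina == 1L))
  expect_identical(nrow(verdicts), 6L)
})
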