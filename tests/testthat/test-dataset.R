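test_that("windowing produces full windows only, with a short-video fallback", {
  cfg <- windowing_config(N = 60L, stride = 60L)
  w <- window_frames(150L, cfg)
  expect_identical(nrow(w), 2L)
  expect_identical(w$start, c(0L, 60L))
  expect_identical(w$end, c(60L, 120L))  # trailing 30 frames discarded

  expect_identical(nrow(window_frames(60L, cfg)), 1L)

  short <- window_frames(59L, cfg)
  expect_identical(c(short$start, short$end), c(0L, 59L))
  expect_error(window_frames(59L, windowing_config(N = 60L,
                                                   short_video_policy = "error")),
               "fewer than")

  overlap <- window_frames(10L, windowing_config(N = 4L, stride = 2L))
  expect_identical(overlap$start, c(0L, 2L, 4L, 6L))
})

test_that("window aggregation yields 68 ordered values with population SD", {
  expect_length(aggregated_feature_names(), 68L)

  fm <- matrix(0.3, nrow = 5, ncol = 17,
               dimnames = list(NULL, frame_feature_names()))
  agg <- aggregate_window(fm)
  expect_length(agg, 68L)
  expect_identical(names(agg), aggregated_feature_names())
  expect_equal(unname(agg[c("pred_mean__mean", "pred_mean__sd",
                            "pred_mean__max", "pred_mean__min")]),
               c(0.3, 0, 0.3, 0.3))

  fm2 <- fm[1:2, ]; fm2[, "thr_max"] <- c(0, 1)
  agg2 <- aggregate_window(fm2)
  expect_equal(unname(agg2[c("thr_max__mean", "thr_max__sd",
                             "thr_max__max", "thr_max__min")]),
               c(0.5, 0.5, 1, 0))
  expect_error(aggregate_window(fm[0, , drop = FALSE]), "non-empty")
})

test_that("aggregation matches a brute-force recomputation on random windows", {
  set.seed(11)
  for (rep in 1:20) {
    nf <- sample(2:12, 1)
    fm <- matrix(runif(nf * 17), nrow = nf, ncol = 17,
                 dimnames = list(NULL, frame_feature_names()))
    agg <- aggregate_window(fm)
    for (feat in frame_feature_names()) {
      x <- fm[, feat]
      expect_equal(unname(agg[paste0(feat, "__mean")]), mean(x), tolerance = 1e-12)
      expect_equal(unname(agg[paste0(feat, "__sd")]),
                   sqrt(mean((x - mean(x))^2)), tolerance = 1e-12)
      expect_identical(unname(agg[paste0(feat, "__max")]), max(x))
      expect_identical(unname(agg[paste0(feat, "__min")]), min(x))
    }
  }
})

test_that("dataset row counts follow the (videos x organs x windows) formula", {
  cfg <- sim_cohort_config(n_correct = 2L, n_incorrect = 2L, n_frames = 12L,
                           height = 16L, width = 16L, seed = 4L)
  sim <- simulate_cohort(cfg)
  ds <- build_dataset(sim$videos, sim$labels, windowing_config(N = 6L))
  expect_s3_class(ds, "feature_dataset")
  expect_identical(nrow(ds), 4L * 8L * 2L)
  expect_identical(ncol(ds), 72L)  # ids, organ, window + 68 + label

  one <- build_dataset(sim$videos[1], sim$labels, windowing_config(N = 5L))
  expect_identical(nrow(one), 8L * 2L)  # floor(12/5) = 2 windows

  empty <- build_dataset(list(), sim$labels, windowing_config(N = 6L))
  expect_identical(nrow(empty), 0L)

  # labels are copied per organ; row order is patient, organ enum, window
  expect_identical(unique(ds$organ), organ_ids())
  lab <- sim$labels
  for (i in sample(nrow(ds), 10)) {
    expect_identical(ds$label[i],
                     lab$organ_correct[lab$patient_id == ds$patient_id[i] &
                                       lab$organ == ds$organ[i]])
  }
})

test_that("missing labels abort dataset construction", {
  cfg <- tiny_sim_config()
  sim <- simulate_cohort(cfg)
  lab <- label_table(as.data.frame(sim$labels)[sim$labels$patient_id != "P001", ])
  expect_error(build_dataset(sim$videos, lab, windowing_config(N = 6L)),
               "P001")
})

test_that("patient-level split routes every row and rejects leakage", {
  cfg <- tiny_sim_config()
  sim <- simulate_cohort(cfg)
  ds <- build_dataset(sim$videos, sim$labels, windowing_config(N = 6L))
  ids <- sprintf("P%03d", 1:6)
  sp <- split_by_patient(ds, ids[1:4], ids[5:6])
  expect_identical(nrow(sp$train), 4L * 8L)
  expect_identical(nrow(sp$test), 2L * 8L)
  expect_length(intersect(sp$train$patient_id, sp$test$patient_id), 0L)

  expect_error(split_by_patient(ds, ids[1:4], ids[4:6]), "overlap")
  expect_error(split_by_patient(ds, ids[1:4], ids[5]), "neither")
  all_train <- split_by_patient(ds, ids, character(0))
  expect_identical(nrow(all_train$test), 0L)
})

test_that("CSV serialization round-trips the dataset through the manifest", {
  cfg <- tiny_sim_config()
  sim <- simulate_cohort(cfg)
  ds <- build_dataset(sim$videos, sim$labels, windowing_config(N = 6L))
  path <- withr::local_tempfile(fileext = ".csv")
  write_dataset(ds, path)
  header <- names(read.csv(path, nrows = 1L))
  expect_identical(header[4:6], c("f001", "f002", "f003"))
  ds2 <- read_dataset(path)
  expect_identical(names(ds2), names(as.data.frame(ds)))
  expect_equal(as.data.frame(ds2), as.data.frame(ds), tolerance = 1e-12)
  expect_identical(attr(ds2, "windowing")$N, 6L)
})
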