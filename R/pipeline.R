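#' Pipeline configuration
#'
#' One serializable object driving the whole experiment:
#' simulate a cohort, featurize and window it, split by patient, tune and
#' train the per-organ classifiers, predict the held-out videos and score
#' their concordance with the ground truth. All randomness derives from the
#' single master `seed`: the cohort uses `seed` and the hyperparameter
#' search / fold shuffles use `seed + 1`.
#'
#' @param cohort A [sim_cohort_config()]. Its `seed` is overridden by the
#'   master seed.
#' @param windowing A [windowing_config()].
#' @param n_train Number of (first) patients used for training; the rest are
#'   the held-out test set. Default 60.
#' @param n_iter Hyperparameter configurations sampled per organ; default 50.
#' @param k Cross-validation folds; default 5.
#' @param seed Master seed.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(cohort = sim_cohort_config(),
                            windowing = windowing_config(),
                            n_train = 60L, n_iter = 50L, k = 5L, seed = 7L) {
  stopifnot(inherits(cohort, "sim_cohort_config"),
            inherits(windowing, "windowing_config"))
  seed <- as.integer(seed)
  cohort$seed <- seed
  structure(list(cohort = cohort, windowing = windowing,
                 n_train = as.integer(n_train), n_iter = as.integer(n_iter),
                 k = as.integer(k), seed = seed),
            class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' The YAML mirrors the [pipeline_config()] structure, with optional
#' sections `cohort` and `windowing` and top-level `n_train`, `n_iter`, `k`,
#' `seed`; omitted fields keep their defaults.
#'
#' @param path Path to a YAML file.
#' @return A `pipeline_config`.
#' @export
load_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  cohort <- do.call(sim_cohort_config, c(
    y$cohort[setdiff(names(y$cohort), "defect_mix")],
    if (!is.null(y$cohort$defect_mix)) list(defect_mix = unlist(y$cohort$defect_mix))))
  w <- as.list(y$windowing)
  # YAML 1.1 parses a bare key `N` as boolean FALSE; map it back
  names(w)[names(w) %in% c("FALSE", "F")] <- "N"
  windowing <- do.call(windowing_config, w)
  args <- y[intersect(names(y), c("n_train", "n_iter", "k", "seed"))]
  do.call(pipeline_config,
          c(list(cohort = cohort, windowing = windowing), args))
}

# simulate the cohort video by video, featurizing each immediately so that
# only one video's maps are ever held in memory
simulate_feature_dataset <- function(cohort, windowing,
                                     layout = default_organ_layout()) {
  parts <- list()
  sim <- simulate_cohort(cohort, layout, handler = function(video, organ_correct) {
    df <- featurize_video(video, windowing)
    df$label <- as.integer(organ_correct[df$organ])
    parts[[length(parts) + 1L]] <<- df
  })
  out <- do.call(rbind, parts)
  out <- out[order(out$patient_id, match(out$organ, organ_ids()),
                   out$window_index), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "windowing") <- windowing
  class(out) <- c("feature_dataset", "data.frame")
  list(dataset = out, labels = sim$labels, plan = sim$plan)
}

#' Run the end-to-end experiment
#'
#' Simulates the cohort, builds the windowed feature dataset, splits it by
#' patient (first `n_train` patients train, the rest test), tunes and trains
#' one gradient-boosted model per organ, predicts the test videos and scores
#' the model's verdicts against the simulated ground truth.
#'
#' @param config A [pipeline_config()].
#' @param out_dir Optional directory; when given, the labels, dataset,
#'   verdicts, concordance table and a JSON report are written there.
#' @param quiet Suppress stage progress messages (written to stderr).
#' @return An `experiment_report` list: `config`, `n_videos`, `n_rows`,
#'   `n_train_rows`, `n_test_rows`, `cv_scores` (per organ), `verdicts`,
#'   `truth`, `concordance` (model vs. ground truth on the test patients)
#'   and `plane_kappa`.
#' @export
run_experiment <- function(config = pipeline_config(), out_dir = NULL,
                           quiet = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  say <- function(...) if (!quiet) message(sprintf(...))
  t0 <- proc.time()[["elapsed"]]
  stage <- function(name) say("[planeqc] %-12s t+%.1fs", name,
                              proc.time()[["elapsed"]] - t0)

  stage("simulate")
  sim <- simulate_feature_dataset(config$cohort, config$windowing)
  dataset <- sim$dataset
  labels <- sim$labels

  stage("split")
  pids <- sort(unique(dataset$patient_id))
  n <- length(pids)
  if (config$n_train < config$k || config$n_train >= n) {
    stop("n_train must lie in [k, number of patients)", call. = FALSE)
  }
  train_ids <- pids[seq_len(config$n_train)]
  test_ids <- pids[(config$n_train + 1L):n]
  split <- split_by_patient(dataset, train_ids, test_ids)

  stage("train")
  space <- hyperparam_space(n_iter = config$n_iter, seed = config$seed + 1L)
  models <- train_organ_models(split$train, space, k = config$k)

  stage("predict")
  verdicts <- predict_verdicts(models, split$test)

  stage("score")
  truth <- truth_verdicts(labels, test_ids)
  conc <- concordance_table(truth, verdicts)

  report <- structure(list(
    config = config,
    n_videos = n, n_rows = nrow(dataset),
    n_train_rows = nrow(split$train), n_test_rows = nrow(split$test),
    cv_scores = vapply(models, function(m) m$best_score, numeric(1L)),
    verdicts = verdicts, truth = truth, concordance = conc,
    plane_kappa = conc$kappa[conc$endpoint == "midsagittal_plane"]),
    class = "experiment_report")

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_labels(labels, file.path(out_dir, "labels.csv"))
    write_dataset(dataset, file.path(out_dir, "dataset.csv"))
    utils::write.csv(verdicts, file.path(out_dir, "verdicts.csv"),
                     row.names = FALSE, quote = FALSE)
    utils::write.csv(conc, file.path(out_dir, "concordance.csv"),
                     row.names = FALSE, quote = FALSE)
    jsonlite::write_json(
      list(seed = config$seed, n_videos = report$n_videos,
           n_rows = report$n_rows, n_train_rows = report$n_train_rows,
           n_test_rows = report$n_test_rows,
           cv_scores = as.list(report$cv_scores),
           plane_kappa = report$plane_kappa,
           concordance = conc),
      file.path(out_dir, "report.json"), auto_unbox = TRUE, pretty = TRUE,
      digits = NA)
  }
  stage("done")
  report
}

# ground-truth verdict table (same layout as predict_verdicts) for a set of
# patients, from a label table
truth_verdicts <- function(labels, patient_ids) {
  stopifnot(inherits(labels, "label_table"))
  plane <- plane_labels(labels)
  rows <- lapply(patient_ids, function(pid) {
    key <- labels$patient_id == pid
    v <- stats::setNames(labels$organ_correct[key], labels$organ[key])
    as.data.frame(c(list(patient_id = pid), as.list(v[organ_ids()]),
                    list(plane_correct = plane$plane_correct[plane$patient_id == pid])),
                  stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' @export
print.experiment_report <- function(x, ...) {
  cat(sprintf("<experiment_report> %d videos, %d rows (%d train / %d test)\n",
              x$n_videos, x$n_rows, x$n_train_rows, x$n_test_rows))
  pk <- x$plane_kappa
  cat(sprintf("plane kappa vs. ground truth: %s\n",
              if (is.na(pk)) "not estimable" else sprintf("%.3f", pk)))
  invisible(x)
}
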