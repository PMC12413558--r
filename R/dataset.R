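#' Frame-windowing configuration
#'
#' Frame features are aggregated over windows of `N` consecutive frames; each
#' window contributes one dataset row per organ, so a video yields multiple
#' rows — a data-augmentation device for small cohorts. Windows shorter than
#' `N` at the end of a video are discarded so that every row summarizes the
#' same number of frames; a video shorter than `N` falls back, by default, to
#' a single whole-video window rather than silently dropping the patient.
#'
#' @param N Frames per window; default 60.
#' @param stride Offset between window starts; default `N` (non-overlapping).
#' @param short_video_policy What to do when a video has fewer than `N`
#'   frames: `"single_window"` (one window over the whole video, the default)
#'   or `"error"`.
#' @return A `windowing_config` list.
#' @export
windowing_config <- function(N = 60L, stride = N,
                             short_video_policy = c("single_window", "error")) {
  N <- as.integer(N); stride <- as.integer(stride)
  stopifnot(N >= 2L, stride >= 1L)
  structure(list(N = N, stride = stride,
                 short_video_policy = match.arg(short_video_policy)),
            class = "windowing_config")
}

#' Frame-index windows for a video
#'
#' @param n_frames Number of frames in the video.
#' @param config A [windowing_config()].
#' @return Data frame with 0-based half-open ranges: columns `start`
#'   (inclusive) and `end` (exclusive), one row per window.
#' @export
window_frames <- function(n_frames, config = windowing_config()) {
  n_frames <- as.integer(n_frames)
  stopifnot(n_frames >= 1L)
  if (n_frames < config$N) {
    if (config$short_video_policy == "error") {
      stop("video has ", n_frames, " frames, fewer than the window size ",
           config$N, call. = FALSE)
    }
    return(data.frame(start = 0L, end = n_frames))
  }
  starts <- seq.int(0L, n_frames - config$N, by = config$stride)
  data.frame(start = starts, end = starts + config$N)
}

#' Names of the 68 aggregated features
#'
#' Each of the 17 frame features is aggregated over a window by its mean,
#' population standard deviation, maximum and minimum, in that order,
#' feature-major: `pred_mean__mean, pred_mean__sd, pred_mean__max,
#' pred_mean__min, pred_sd__mean, ...`. This ordering is frozen so that
#' trained models are portable across datasets.
#'
#' @return Character vector of length 68.
#' @export
aggregated_feature_names <- function() {
  as.vector(t(outer(frame_feature_names(), c("mean", "sd", "max", "min"),
                    paste, sep = "__")))
}

#' Aggregate per-frame features over one window
#'
#' @param frame_features Numeric matrix, frames x features, with columns
#'   (at least) [frame_feature_names()]; typically one element of
#'   [extract_video_features()] restricted to a window.
#' @return Named numeric vector of length 68 in the order of
#'   [aggregated_feature_names()].
#' @export
aggregate_window <- function(frame_features) {
  if (is.null(dim(frame_features)) || nrow(frame_features) < 1L) {
    stop("frame_features must be a non-empty frames x features matrix",
         call. = FALSE)
  }
  x <- frame_features[, frame_feature_names(), drop = FALSE]
  mu <- colMeans(x)
  sd <- sqrt(colMeans(x^2) - mu^2)
  sd[sd < 0 | is.nan(sd)] <- 0  # guard tiny negative values from cancellation
  out <- rbind(mean = mu, sd = sd,
               max = apply(x, 2L, max), min = apply(x, 2L, min))
  stats::setNames(as.vector(out), aggregated_feature_names())
}

# Feature rows for one video: one row per (organ, window).
featurize_video <- function(video, config = windowing_config(), tau = 0.5) {
  wins <- window_frames(video$n_frames, config)
  feats <- extract_video_features(video, tau)
  rows <- vector("list", n_organs() * nrow(wins))
  k <- 0L
  for (org in organ_ids()) {
    fm <- feats[[org]]
    for (wi in seq_len(nrow(wins))) {
      idx <- (wins$start[wi] + 1L):wins$end[wi]
      k <- k + 1L
      rows[[k]] <- c(list(patient_id = video$patient_id, organ = org,
                          window_index = wi - 1L),
                     as.list(aggregate_window(fm[idx, , drop = FALSE])))
    }
  }
  do.call(rbind, lapply(rows, function(r) as.data.frame(r, stringsAsFactors = FALSE)))
}

#' Build the labeled tabular dataset from videos and labels
#'
#' One row per (video, organ, window): 68 aggregated features plus the
#' organ-correctness label. Row order is deterministic — patient, then organ
#' enumeration order, then window index.
#'
#' @param videos List of [segmentation_video()] objects.
#' @param labels A [label_table()] covering all eight organs of every video.
#' @param config A [windowing_config()].
#' @param tau Probability threshold for the frame features; default 0.5.
#' @return A `feature_dataset`: data frame with columns `patient_id`,
#'   `organ`, `window_index`, the 68 features of
#'   [aggregated_feature_names()], and `label`.
#' @export
build_dataset <- function(videos, labels, config = windowing_config(),
                          tau = 0.5) {
  stopifnot(inherits(labels, "label_table"))
  parts <- lapply(videos, function(v) {
    df <- featurize_video(v, config, tau)
    key <- labels$patient_id == v$patient_id
    if (!any(key)) {
      stop("no labels for patient '", v$patient_id, "'", call. = FALSE)
    }
    lab <- stats::setNames(labels$organ_correct[key], labels$organ[key])
    df$label <- as.integer(lab[df$organ])
    df
  })
  out <- if (length(parts) == 0L) empty_feature_dataset() else do.call(rbind, parts)
  out <- out[order(out$patient_id, match(out$organ, organ_ids()),
                   out$window_index), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "windowing") <- config
  class(out) <- c("feature_dataset", "data.frame")
  out
}

empty_feature_dataset <- function() {
  cols <- c("patient_id", "organ", "window_index",
            aggregated_feature_names(), "label")
  df <- as.data.frame(stats::setNames(
    c(list(character(0), character(0), integer(0)),
      rep(list(numeric(0)), 68L), list(integer(0))), cols))
  df
}

#' Split a feature dataset by patient
#'
#' Routes every row by its `patient_id`, guaranteeing that no patient's rows
#' appear on both sides — the split-level counterpart of grouped
#' cross-validation's leakage guard.
#'
#' @param dataset A `feature_dataset` from [build_dataset()].
#' @param train_ids,test_ids Disjoint character vectors of patient ids
#'   jointly covering every patient in `dataset`.
#' @return List with `feature_dataset` elements `train` and `test`.
#' @export
split_by_patient <- function(dataset, train_ids, test_ids) {
  stopifnot(inherits(dataset, "feature_dataset"))
  if (length(intersect(train_ids, test_ids)) > 0L) {
    stop("train and test patient id lists overlap", call. = FALSE)
  }
  unrouted <- setdiff(unique(dataset$patient_id), c(train_ids, test_ids))
  if (length(unrouted) > 0L) {
    stop("patient(s) in neither split: ", paste(unrouted, collapse = ", "),
         call. = FALSE)
  }
  keep_class <- function(df) {
    rownames(df) <- NULL
    attr(df, "windowing") <- attr(dataset, "windowing")
    class(df) <- class(dataset)
    df
  }
  list(train = keep_class(dataset[dataset$patient_id %in% train_ids, , drop = FALSE]),
       test = keep_class(dataset[dataset$patient_id %in% test_ids, , drop = FALSE]))
}

#' Write / read a feature dataset as CSV with a JSON sidecar
#'
#' The CSV has columns `patient_id,organ,window_index,f001..f068,label`; the
#' sidecar (`<path>.json`) records the windowing configuration and the
#' feature-order manifest mapping `f001..f068` back to
#' [aggregated_feature_names()].
#'
#' @param dataset A `feature_dataset`.
#' @param path CSV output path.
#' @return `path` invisibly (for write); the `feature_dataset` (for read).
#' @export
write_dataset <- function(dataset, path) {
  stopifnot(inherits(dataset, "feature_dataset"))
  df <- as.data.frame(dataset)
  fnames <- aggregated_feature_names()
  names(df)[match(fnames, names(df))] <- sprintf("f%03d", seq_along(fnames))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  cfg <- attr(dataset, "windowing")
  sidecar <- list(windowing = list(N = cfg$N, stride = cfg$stride,
                                   short_video_policy = cfg$short_video_policy),
                  feature_order = as.list(stats::setNames(
                    fnames, sprintf("f%03d", seq_along(fnames)))))
  jsonlite::write_json(sidecar, paste0(path, ".json"), auto_unbox = TRUE,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_dataset
#' @export
read_dataset <- function(path) {
  df <- utils::read.csv(path, colClasses = c(patient_id = "character",
                                             organ = "character"))
  sidecar <- jsonlite::read_json(paste0(path, ".json"))
  fmap <- unlist(sidecar$feature_order)
  if (!identical(unname(fmap), aggregated_feature_names())) {
    stop("dataset sidecar feature order does not match this package's manifest",
         call. = FALSE)
  }
  names(df)[match(names(fmap), names(df))] <- unname(fmap)
  attr(df, "windowing") <- windowing_config(
    N = sidecar$windowing$N, stride = sidecar$windowing$stride,
    short_video_policy = sidecar$windowing$short_video_policy)
  class(df) <- c("feature_dataset", "data.frame")
  df
}
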