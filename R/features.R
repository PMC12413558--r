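#' Names of the 17 per-frame, per-organ features
#'
#' Four full-map confidence statistics, four statistics over the pixels with
#' probability strictly greater than 0.5, and nine bounding-box geometry
#' features computed on the same > 0.5 binarization. The contrast between the
#' full-map and thresholded statistics captures how confidently the segmenter
#' localized the organ; the bounding-box features capture whether its
#' location, size and aspect ratio are consistent.
#'
#' The companion `thr_empty` flag (set when no pixel exceeds the threshold)
#' is carried alongside but is not one of the 17 aggregated features.
#'
#' @return Character vector of length 17, in canonical order.
#' @export
frame_feature_names <- function() {
  c("pred_mean", "pred_sd", "pred_max", "pred_min",
    "thr_mean", "thr_sd", "thr_max", "thr_min",
    "bbox_centroid_row", "bbox_centroid_col",
    "bbox_row_min", "bbox_row_max", "bbox_col_min", "bbox_col_max",
    "bbox_width", "bbox_height", "bbox_area")
}

# population SD (divide by n, not n-1); 0 for a single value
pop_sd <- function(x) {
  m <- mean(x)
  sqrt(mean((x - m)^2))
}

assert_prob_map <- function(map) {
  if (!is.matrix(map) || length(map) == 0L) {
    stop("probability map must be a non-empty matrix", call. = FALSE)
  }
  rng <- range(map)
  if (is.na(rng[1L]) || rng[1L] < 0 || rng[2L] > 1) {
    stop("probability map has values outside [0, 1]", call. = FALSE)
  }
  invisible(map)
}

#' Full-map confidence statistics
#'
#' Population mean, population standard deviation, maximum and minimum of all
#' pixel probabilities in one map.
#'
#' @param map Numeric matrix with values in \[0, 1\] (rows = vertical axis).
#' @return Named numeric vector `pred_mean`, `pred_sd`, `pred_max`, `pred_min`.
#' @export
full_map_stats <- function(map) {
  assert_prob_map(map)
  c(pred_mean = mean(map), pred_sd = pop_sd(map),
    pred_max = max(map), pred_min = min(map))
}

#' Confidence statistics over high-probability pixels
#'
#' The same four statistics restricted to pixels with probability strictly
#' greater than `tau` (0.5 exactly is excluded). When no pixel qualifies all
#' four statistics are 0 and `thr_empty` is 1: the classifier needs finite
#' inputs, and 0 is maximally distinct from any valid confident statistic,
#' which necessarily exceeds 0.5.
#'
#' @inheritParams full_map_stats
#' @param tau Probability threshold; default 0.5.
#' @return Named numeric vector `thr_mean`, `thr_sd`, `thr_max`, `thr_min`,
#'   `thr_empty`.
#' @export
thresholded_stats <- function(map, tau = 0.5) {
  assert_prob_map(map)
  v <- map[map > tau]
  if (length(v) == 0L) {
    c(thr_mean = 0, thr_sd = 0, thr_max = 0, thr_min = 0, thr_empty = 1)
  } else {
    c(thr_mean = mean(v), thr_sd = pop_sd(v),
      thr_max = max(v), thr_min = min(v), thr_empty = 0)
  }
}

#' Bounding-box geometry of a thresholded segmentation
#'
#' The bounding box is the smallest axis-aligned rectangle containing every
#' pixel with probability strictly greater than `tau`. Coordinates are
#' 0-based (row, col), origin top-left. The centroid is the box center
#' (midpoint of the extremes, not the mask's center of mass); width and
#' height are inclusive pixel counts (`max - min + 1`); area is
#' `width * height`. An empty thresholded set yields all nine features 0.
#'
#' @inheritParams thresholded_stats
#' @return Named numeric vector of the nine `bbox_*` features.
#' @export
bounding_box_features <- function(map, tau = 0.5) {
  assert_prob_map(map)
  idx <- which(map > tau, arr.ind = TRUE)
  if (nrow(idx) == 0L) {
    return(c(bbox_centroid_row = 0, bbox_centroid_col = 0,
             bbox_row_min = 0, bbox_row_max = 0,
             bbox_col_min = 0, bbox_col_max = 0,
             bbox_width = 0, bbox_height = 0, bbox_area = 0))
  }
  rmin <- min(idx[, 1L]) - 1; rmax <- max(idx[, 1L]) - 1
  cmin <- min(idx[, 2L]) - 1; cmax <- max(idx[, 2L]) - 1
  w <- cmax - cmin + 1; h <- rmax - rmin + 1
  c(bbox_centroid_row = (rmin + rmax) / 2, bbox_centroid_col = (cmin + cmax) / 2,
    bbox_row_min = rmin, bbox_row_max = rmax,
    bbox_col_min = cmin, bbox_col_max = cmax,
    bbox_width = w, bbox_height = h, bbox_area = w * h)
}

#' Extract all 17 per-frame features from one probability map
#'
#' Concatenates [full_map_stats()], [thresholded_stats()] and
#' [bounding_box_features()], in the order of [frame_feature_names()], plus
#' the `thr_empty` flag as an 18th element (not counted among the features).
#'
#' @inheritParams thresholded_stats
#' @return Named numeric vector of length 18 (17 features + `thr_empty`).
#' @export
extract_frame_features <- function(map, tau = 0.5) {
  thr <- thresholded_stats(map, tau)
  out <- c(full_map_stats(map), thr[c("thr_mean", "thr_sd", "thr_max", "thr_min")],
           bounding_box_features(map, tau), thr["thr_empty"])
  out
}

#' Per-frame features for every organ and frame of a video
#'
#' @param video A [segmentation_video()].
#' @param tau Probability threshold; default 0.5.
#' @return Named list over [organ_ids()]; each element an
#'   `n_frames x 18` matrix (17 features + `thr_empty`), rows = frames.
#' @export
extract_video_features <- function(video, tau = 0.5) {
  stopifnot(inherits(video, "segmentation_video"))
  out <- lapply(organ_ids(), function(org) {
    arr <- video$maps[[org]]
    t(vapply(seq_len(video$n_frames),
             function(f) extract_frame_features(arr[, , f], tau),
             numeric(18L)))
  })
  names(out) <- organ_ids()
  out
}
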