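# Shared fixtures: tiny videos, cohorts and brute-force oracles.

# a toy video with constant per-organ maps (value varies by organ and frame)
toy_video <- function(patient_id = "T01", h = 6L, w = 5L, n_frames = 2L) {
  maps <- lapply(seq_along(organ_ids()), function(i) {
    arr <- array(0, dim = c(h, w, n_frames))
    for (f in seq_len(n_frames)) arr[, , f] <- (i * 0.1 + f * 0.01)
    arr
  })
  names(maps) <- organ_ids()
  segmentation_video(patient_id, maps)
}

# small fast simulator config for unit tests
tiny_sim_config <- function(...) {
  sim_cohort_config(n_correct = 3L, n_incorrect = 3L, n_frames = 6L,
                    height = 24L, width = 24L, seed = 42L, ...)
}

# label CSV text for n patients x 8 organs; `incorrect` is a named list
# patient_id -> character vector of organs labelled 0
labels_csv <- function(path, patient_ids, incorrect = list()) {
  rows <- do.call(rbind, lapply(patient_ids, function(pid) {
    data.frame(patient_id = pid, organ = organ_ids(),
               organ_correct = as.integer(!(organ_ids() %in% incorrect[[pid]])),
               stringsAsFactors = FALSE)
  }))
  write.csv(rows, path, row.names = FALSE, quote = FALSE)
  path
}

# pixel-loop oracle for the 17 frame features: explicit loops, no shared code
# with the implementation
oracle_frame_features <- function(map, tau = 0.5) {
  vals <- c(); n <- 0
  for (i in seq_len(nrow(map))) for (j in seq_len(ncol(map))) {
    vals <- c(vals, map[i, j]); n <- n + 1
  }
  m <- sum(vals) / n
  sd_full <- sqrt(sum((vals - m)^2) / n)
  thr <- c(); rows <- c(); cols <- c()
  for (i in seq_len(nrow(map))) for (j in seq_len(ncol(map))) {
    if (map[i, j] > tau) {
      thr <- c(thr, map[i, j]); rows <- c(rows, i - 1); cols <- c(cols, j - 1)
    }
  }
  if (length(thr) == 0) {
    thr_stats <- c(0, 0, 0, 0); bbox <- rep(0, 9)
  } else {
    tm <- sum(thr) / length(thr)
    thr_stats <- c(tm, sqrt(sum((thr - tm)^2) / length(thr)), max(thr), min(thr))
    rmin <- min(rows); rmax <- max(rows); cmin <- min(cols); cmax <- max(cols)
    wd <- cmax - cmin + 1; ht <- rmax - rmin + 1
    bbox <- c((rmin + rmax) / 2, (cmin + cmax) / 2, rmin, rmax, cmin, cmax,
              wd, ht, wd * ht)
  }
  c(m, sd_full, max(vals), min(vals), thr_stats, bbox)
}

# item-level brute-force Cohen's kappa: reconstruct the paired ratings and
# count agreements / marginals explicitly
oracle_kappa <- function(a, b, c, d) {
  ref <- c(rep(1, a), rep(1, b), rep(0, c), rep(0, d))
  rat <- c(rep(1, a), rep(0, b), rep(1, c), rep(0, d))
  n <- length(ref)
  po <- sum(ref == rat) / n
  pe <- mean(ref == 1) * mean(rat == 1) + mean(ref == 0) * mean(rat == 0)
  if (abs(1 - pe) < 1e-12) return(NA_real_)
  (po - pe) / (1 - pe)
}

# term-by-term binomial tail for the exact McNemar test
oracle_mcnemar <- function(b, c) {
  nd <- b + c
  if (nd == 0) return(1)
  m <- min(b, c)
  tail <- 0
  for (i in 0:m) tail <- tail + choose(nd, i) * 0.5^nd
  min(1, 2 * tail)
}
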