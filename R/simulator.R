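#' Configuration for a synthetic segmentation cohort
#'
#' The simulator stands in for an upstream CNN segmenter run on dynamic
#' transperineal ultrasound videos. Each simulated video carries, per organ
#' and frame, a probability map: present organs render as a high-confidence
#' elliptical blob over low background noise; organs lost by a bad capture
#' render as pure background. The defaults mirror the study design the
#' classifier is meant for: 45 correct-plane and 45 incorrect-plane videos.
#'
#' @param n_correct Number of correct-plane videos (default 45).
#' @param n_incorrect Number of incorrect-plane videos (default 45).
#' @param n_frames Frames per video (default 60).
#' @param height,width Image size in pixels (default 64 x 64).
#' @param blob_confidence Mean in-organ probability, in (0, 1\]; default 0.9.
#' @param background_noise Mean out-of-organ probability; background pixels
#'   are i.i.d. uniform with this mean and width
#'   `2 * min(background_noise, 1 - background_noise)` (i.e. uniform on
#'   \[0, 2 * background_noise\] for means up to 0.5); default 0.1.
#' @param jitter_sd Per-frame, per-organ centroid jitter (pixels, sd of a
#'   normal); default 2.
#' @param defect_mix Named proportions over the two defect modes
#'   `c(displacement = , rotation = )` used for incorrect videos; default
#'   half/half.
#' @param seed Integer master seed for the cohort.
#' @param allow_overlap Set `TRUE` to permit `blob_confidence <= 0.5` or
#'   `background_noise >= 0.5`; by default the separability assumption
#'   `blob_confidence > 0.5 > background_noise` is enforced.
#' @return A `sim_cohort_config` list.
#' @export
sim_cohort_config <- function(n_correct = 45L, n_incorrect = 45L,
                              n_frames = 60L, height = 64L, width = 64L,
                              blob_confidence = 0.9, background_noise = 0.1,
                              jitter_sd = 2,
                              defect_mix = c(displacement = 0.5, rotation = 0.5),
                              seed = 1L, allow_overlap = FALSE) {
  n_correct <- as.integer(n_correct); n_incorrect <- as.integer(n_incorrect)
  stopifnot(n_correct >= 0L, n_incorrect >= 0L, n_correct + n_incorrect >= 1L,
            n_frames >= 1L, height >= 8L, width >= 8L,
            blob_confidence > 0, blob_confidence <= 1,
            background_noise >= 0, background_noise < 1,
            jitter_sd >= 0)
  if (!allow_overlap && !(blob_confidence > 0.5 && background_noise < 0.5)) {
    stop("separability requires blob_confidence > 0.5 > background_noise; ",
         "pass allow_overlap = TRUE to override", call. = FALSE)
  }
  stopifnot(setequal(names(defect_mix), c("displacement", "rotation")),
            all(defect_mix >= 0), sum(defect_mix) > 0)
  defect_mix <- defect_mix[c("displacement", "rotation")] / sum(defect_mix)
  structure(list(n_correct = n_correct, n_incorrect = n_incorrect,
                 n_frames = as.integer(n_frames),
                 height = as.integer(height), width = as.integer(width),
                 blob_confidence = blob_confidence,
                 background_noise = background_noise,
                 jitter_sd = jitter_sd, defect_mix = defect_mix,
                 seed = as.integer(seed)),
            class = "sim_cohort_config")
}

#' Nominal organ layout for the simulator
#'
#' Centroids are fractions of image size, 0-based (row, col), roughly tracing
#' the midsagittal arrangement with the cranioventral region on the left:
#' pubis and urethra near the probe, bladder above, uterus mid-field, and the
#' anorectal structures to the dorsocaudal right. Half-axes are fractions of
#' `min(height, width)`. Organ location consistency across a cohort is the
#' signal the bounding-box features exploit, so the layout is fixed per
#' cohort.
#'
#' @return Data frame with columns `organ`, `row_frac`, `col_frac`,
#'   `half_row_frac`, `half_col_frac`.
#' @export
default_organ_layout <- function() {
  data.frame(
    organ = organ_ids(),
    row_frac = c(0.40, 0.52, 0.30, 0.58, 0.35, 0.68, 0.52, 0.75),
    col_frac = c(0.15, 0.28, 0.35, 0.42, 0.58, 0.60, 0.74, 0.78),
    half_row_frac = c(0.06, 0.09, 0.11, 0.08, 0.10, 0.07, 0.09, 0.05),
    half_col_frac = c(0.05, 0.05, 0.12, 0.05, 0.08, 0.05, 0.08, 0.11),
    stringsAsFactors = FALSE
  )
}

# Organs lost under each acquisition defect. Anteroposterior probe
# displacement loses the dorsocaudal structures; image rotation additionally
# loses the uterus and degrades confidence everywhere.
organs_lost <- function(condition) {
  switch(condition,
         correct = character(0),
         displacement = c("anus", "rectum", "levator_ani"),
         rotation = c("uterus", "anus", "rectum", "levator_ani"),
         stop("unknown condition '", condition, "'", call. = FALSE))
}

# Render one organ's frame: background i.i.d. uniform with mean `noise` and
# width 2*min(noise, 1-noise) — identical to U[0, 2*noise] for noise <= 0.5,
# and still a valid probability with mean `noise` beyond it. If present, an
# axis-aligned elliptical blob at blob_confidence with a linear fall-off over
# a ~2-pixel rim is composited over the background with pmax.
render_frame <- function(h, w, present, r0, c0, ar, ac, conf, noise) {
  half <- min(noise, 1 - noise)
  m <- matrix(stats::runif(h * w, noise - half, noise + half), nrow = h, ncol = w)
  if (!present) return(m)
  rows <- (seq_len(h) - 1 - r0) / ar
  cols <- (seq_len(w) - 1 - c0) / ac
  rho <- sqrt(outer(rows^2, cols^2, "+"))
  # radial pixel distance beyond the ellipse edge, approximated with the
  # mean half-axis; inside rho <= 1 the blob is at full confidence
  dpx <- pmax(rho - 1, 0) * (ar + ac) / 2
  blob <- conf * pmax(1 - dpx / 2, 0)
  pmax(m, blob)
}

#' Simulate one segmentation video
#'
#' @param layout Organ layout, see [default_organ_layout()].
#' @param condition One of `"correct"`, `"displacement"`, `"rotation"`.
#'   Displacement removes anus, rectum and levator ani; rotation removes the
#'   uterus as well and inflates the background noise of the remaining organs
#'   (the segmenter is less certain on a rotated image). Absent organs render
#'   as pure background.
#' @param config A [sim_cohort_config()]; cohort-level counts are ignored
#'   here, only the rendering parameters are used.
#' @param patient_id Identifier for the simulated patient.
#' @param seed Integer seed for this video's RNG stream.
#' @return List with elements `video` (a [segmentation_video()]) and
#'   `organ_correct` (named 0/1 vector over [organ_ids()]).
#' @export
simulate_video <- function(layout = default_organ_layout(),
                           condition = c("correct", "displacement", "rotation"),
                           config = sim_cohort_config(),
                           patient_id = "P001", seed = config$seed) {
  condition <- match.arg(condition)
  stopifnot(inherits(config, "sim_cohort_config"))
  lost <- organs_lost(condition)
  h <- config$height; w <- config$width; fmax <- config$n_frames
  scale_px <- min(h, w)
  noise <- config$background_noise
  if (condition == "rotation") noise <- min(noise * 2, 0.95)

  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()),
          add = TRUE)
  set.seed(seed)

  # Valsalva dynamics: slow monotone caudal (downward) drift of all organs,
  # linear over the video, totalling 2-10% of image height; per-video size
  # jitter of +-10% around the nominal half-axes.
  drift_total <- stats::runif(1, 0.02, 0.10) * h
  size_scale <- stats::runif(nrow(layout), 0.9, 1.1)
  drift <- if (fmax > 1) drift_total * (seq_len(fmax) - 1) / (fmax - 1) else 0

  maps <- vector("list", nrow(layout))
  names(maps) <- layout$organ
  for (i in seq_len(nrow(layout))) {
    org <- layout$organ[i]
    present <- !(org %in% lost)
    ar <- layout$half_row_frac[i] * scale_px * size_scale[i]
    ac <- layout$half_col_frac[i] * scale_px * size_scale[i]
    r_nom <- layout$row_frac[i] * (h - 1)
    c_nom <- layout$col_frac[i] * (w - 1)
    jit_r <- stats::rnorm(fmax, 0, config$jitter_sd)
    jit_c <- stats::rnorm(fmax, 0, config$jitter_sd)
    arr <- array(0, dim = c(h, w, fmax))
    for (f in seq_len(fmax)) {
      r0 <- min(max(r_nom + drift[f] + jit_r[f], ar), h - 1 - ar)
      c0 <- min(max(c_nom + jit_c[f], ac), w - 1 - ac)
      arr[, , f] <- render_frame(h, w, present, r0, c0, ar, ac,
                                 config$blob_confidence, noise)
    }
    maps[[i]] <- arr
  }
  organ_correct <- stats::setNames(as.integer(!(layout$organ %in% lost)),
                                   layout$organ)[organ_ids()]
  list(video = segmentation_video(patient_id, maps),
       organ_correct = organ_correct)
}

# Deterministic per-video plan for a cohort: patient ids P001..; conditions
# for incorrect videos drawn from defect_mix; one sub-seed per video.
cohort_plan <- function(config) {
  n <- config$n_correct + config$n_incorrect
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()),
          add = TRUE)
  set.seed(config$seed)
  conditions <- c(rep("correct", config$n_correct),
                  if (config$n_incorrect > 0L) {
                    sample(c("displacement", "rotation"), config$n_incorrect,
                           replace = TRUE, prob = config$defect_mix)
                  })
  conditions <- sample(conditions)  # interleave correct/incorrect patients
  data.frame(patient_id = sprintf("P%03d", seq_len(n)),
             condition = conditions,
             seed = sample.int(.Machine$integer.max - 1L, n),
             stringsAsFactors = FALSE)
}

#' Simulate a cohort of segmentation videos
#'
#' Generates `n_correct + n_incorrect` videos with deterministic patient ids
#' `P001, P002, ...`; the defect mode of each incorrect video is drawn from
#' `config$defect_mix`. The same config yields a bit-identical cohort.
#'
#' @param config A [sim_cohort_config()].
#' @param layout Organ layout, see [default_organ_layout()].
#' @param handler Optional `function(video, organ_correct)`; when supplied,
#'   each video is passed to it as soon as it is simulated and not retained,
#'   so arbitrarily large cohorts can be processed in bounded memory.
#' @return List with `videos` (list of [segmentation_video()], or `NULL` when
#'   a handler is used), `labels` (a [label_table()]) and `plan` (per-video
#'   condition assignments).
#' @export
simulate_cohort <- function(config = sim_cohort_config(),
                            layout = default_organ_layout(),
                            handler = NULL) {
  stopifnot(inherits(config, "sim_cohort_config"))
  plan <- cohort_plan(config)
  keep <- is.null(handler)
  videos <- if (keep) vector("list", nrow(plan))
  labs <- vector("list", nrow(plan))
  for (i in seq_len(nrow(plan))) {
    sim <- simulate_video(layout, plan$condition[i], config,
                          patient_id = plan$patient_id[i], seed = plan$seed[i])
    labs[[i]] <- data.frame(patient_id = plan$patient_id[i],
                            organ = organ_ids(),
                            organ_correct = unname(sim$organ_correct),
                            stringsAsFactors = FALSE)
    if (keep) videos[[i]] <- sim$video else handler(sim$video, sim$organ_correct)
  }
  labels <- label_table(do.call(rbind, labs))
  list(videos = videos, labels = labels, plan = plan)
}
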