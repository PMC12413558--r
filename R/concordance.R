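#' Cohen's kappa for two binary raters
#'
#' Chance-corrected agreement `kappa = (po - pe) / (1 - pe)` for a paired
#' 2x2 rating table, with the asymptotic (Fleiss-Cohen) standard error, a
#' 95% CI clipped to \[-1, 1\], a two-sided p-value for the null of no
#' agreement beyond chance (normal approximation with the null-hypothesis
#' standard error), and the agreement band of [categorize_kappa()].
#'
#' Cell convention, with the first rater as the reference (gold standard):
#' `a` both rate "correct", `b` reference correct / rater incorrect, `c`
#' reference incorrect / rater correct, `d` both "incorrect".
#'
#' When both raters are constant and identical (`po = pe = 1`) kappa is not
#' estimable; the result carries `NA` values and `estimable = FALSE`, never a
#' numeric 0 — agreement tables print such cells as missing.
#'
#' @param a,b,c,d Non-negative cell counts; alternatively pass a 2x2 matrix
#'   `rbind(c(a, b), c(c, d))` as `a`.
#' @param conf_level Confidence level for the CI; default 0.95.
#' @return A `kappa_result` list: `kappa`, `se`, `se0`, `ci` (length 2),
#'   `p`, `category`, `po`, `pe`, `n`, `estimable`.
#' @export
cohen_kappa <- function(a, b = NULL, c = NULL, d = NULL, conf_level = 0.95) {
  if (is.matrix(a)) {
    stopifnot(identical(dim(a), c(2L, 2L)))
    d <- a[2L, 2L]; c <- a[2L, 1L]; b <- a[1L, 2L]; a <- a[1L, 1L]
  }
  stopifnot(a >= 0, b >= 0, c >= 0, d >= 0)
  n <- a + b + c + d
  if (n < 1) stop("table must contain at least one pair", call. = FALSE)
  p <- matrix(c(a, c, b, d), 2L, 2L) / n  # p[i, j]: reference i, rater j
  prow <- rowSums(p); pcol <- colSums(p)
  po <- p[1L, 1L] + p[2L, 2L]
  pe <- sum(prow * pcol)
  if (1 - pe < .Machine$double.eps^0.5) {
    res <- list(kappa = NA_real_, se = NA_real_, se0 = NA_real_,
                ci = c(NA_real_, NA_real_), p = NA_real_,
                category = NA_character_, po = po, pe = pe, n = n,
                estimable = FALSE)
    return(structure(res, class = "kappa_result"))
  }
  kappa <- (po - pe) / (1 - pe)
  # Fleiss-Cohen asymptotic variance (not assuming kappa = 0)
  s1 <- sum(diag(p) * ((1 - pe) - (prow + pcol) * (1 - po))^2)
  s2 <- (1 - po)^2 * (p[1L, 2L] * (pcol[1L] + prow[2L])^2 +
                      p[2L, 1L] * (pcol[2L] + prow[1L])^2)
  s3 <- (po * pe - 2 * pe + po)^2
  se <- sqrt(max(s1 + s2 - s3, 0)) / ((1 - pe)^2 * sqrt(n))
  # variance under H0: kappa = 0
  var0 <- (pe + pe^2 - sum(prow * pcol * (prow + pcol))) / (n * (1 - pe)^2)
  se0 <- sqrt(max(var0, 0))
  z <- conf_level + (1 - conf_level) / 2
  ci <- kappa + c(-1, 1) * stats::qnorm(z) * se
  ci <- pmin(pmax(ci, -1), 1)
  pval <- if (se0 > 0) 2 * stats::pnorm(-abs(kappa) / se0) else NA_real_
  structure(list(kappa = kappa, se = se, se0 = se0, ci = ci, p = pval,
                 category = categorize_kappa(kappa), po = po, pe = pe, n = n,
                 estimable = TRUE),
            class = "kappa_result")
}

#' @export
print.kappa_result <- function(x, ...) {
  if (!x$estimable) {
    cat("Cohen's kappa: not estimable (both raters constant)\n")
  } else {
    cat(sprintf("Cohen's kappa: %.3f (95%% CI %.3f; %.3f), p = %.4g — %s agreement\n",
                x$kappa, x$ci[1L], x$ci[2L], x$p, x$category))
  }
  invisible(x)
}

#' Agreement band of a kappa value
#'
#' Bands: poor (kappa <= 0.20), weak (0.20, 0.40\], moderate (0.40, 0.60\],
#' good (0.60, 0.80\], very good (0.80, 1\]. The half-open intervals close
#' the published band edges (0.20-0.21, 0.80-0.81) so every value in
#' \[-1, 1\] gets exactly one band.
#'
#' @param kappa Numeric in \[-1, 1\] (NA allowed, giving NA).
#' @return Character: one of `"poor"`, `"weak"`, `"moderate"`, `"good"`,
#'   `"very good"`.
#' @export
categorize_kappa <- function(kappa) {
  vapply(kappa, function(k) {
    if (is.na(k)) return(NA_character_)
    if (k < -1 || k > 1) stop("kappa must lie in [-1, 1]", call. = FALSE)
    if (k <= 0.20) "poor"
    else if (k <= 0.40) "weak"
    else if (k <= 0.60) "moderate"
    else if (k <= 0.80) "good"
    else "very good"
  }, character(1L))
}

#' Exact McNemar test for paired binary ratings
#'
#' Exact binomial two-sided test on the discordant pair counts `(b, c)`:
#' `p = min(1, 2 * P(X <= min(b, c)))` with `X ~ Binomial(b + c, 1/2)`;
#' with no discordant pairs the test is vacuous and `p = 1`.
#'
#' @param b,c Discordant counts (reference correct / rater incorrect, and
#'   vice versa); alternatively a 2x2 table as in [cohen_kappa()] passed as
#'   `b`.
#' @return The two-sided p-value.
#' @export
mcnemar_exact <- function(b, c = NULL) {
  if (is.matrix(b)) {
    stopifnot(identical(dim(b), c(2L, 2L)))
    c <- b[2L, 1L]; b <- b[1L, 2L]
  }
  stopifnot(b >= 0, c >= 0)
  nd <- b + c
  if (nd == 0) return(1)
  min(1, 2 * stats::pbinom(min(b, c), nd, 0.5))
}

#' t-based confidence interval for a mean
#'
#' `mean +- t(1 - alpha/2, n - 1) * sd / sqrt(n)` — the interval used to
#' describe cohort characteristics from summary statistics.
#'
#' @param n Sample size (>= 2).
#' @param mean,sd Sample mean and standard deviation.
#' @param level Confidence level; default 0.95.
#' @return Numeric vector `c(low, high)`.
#' @export
mean_ci_t <- function(n, mean, sd, level = 0.95) {
  stopifnot(sd >= 0)
  if (n < 2) stop("need n >= 2 for a t-based interval", call. = FALSE)
  half <- stats::qt(1 - (1 - level) / 2, df = n - 1) * sd / sqrt(n)
  c(low = mean - half, high = mean + half)
}

# cross-tabulate two paired 0/1 verdict vectors into (a, b, c, d) counts
pair_counts <- function(reference, rater) {
  stopifnot(length(reference) == length(rater),
            all(reference %in% c(0L, 1L)), all(rater %in% c(0L, 1L)))
  c(a = sum(reference == 1L & rater == 1L),
    b = sum(reference == 1L & rater == 0L),
    c = sum(reference == 0L & rater == 1L),
    d = sum(reference == 0L & rater == 0L))
}

#' Endpoint-by-endpoint concordance between two raters
#'
#' Compares a rater's per-video verdicts against a reference (gold-standard)
#' rater across the nine endpoints — the midsagittal plane and the eight
#' organs — reporting for each the rater's correct count and percentage, the
#' exact McNemar p-value, kappa with its p-value, CI and agreement band.
#' Endpoints where both raters are constant and identical are reported with
#' missing kappa/McNemar values, as agreement tables print them.
#'
#' @param reference,rater Verdict data frames with column `patient_id`, one
#'   0/1 column per organ in [organ_ids()], and `plane_correct` (the layout
#'   produced by [predict_verdicts()]). Rows are matched by `patient_id`.
#' @return Data frame with one row per endpoint: `endpoint`, `n`,
#'   `rater_correct` (videos the rater judged correctly captured) and its
#'   percentage, `mcnemar_p`, `kappa`, `kappa_p`, `kappa_ci_low`,
#'   `kappa_ci_high`, `category`.
#' @export
concordance_table <- function(reference, rater) {
  endpoints <- c("plane_correct", organ_ids())
  need <- c("patient_id", endpoints)
  for (nm in c("reference", "rater")) {
    df <- get(nm)
    if (!all(need %in% names(df))) {
      stop(nm, " verdicts must have columns ", paste(need, collapse = ", "),
           call. = FALSE)
    }
  }
  if (!setequal(reference$patient_id, rater$patient_id) ||
      nrow(reference) != nrow(rater)) {
    stop("reference and rater must cover the same patients", call. = FALSE)
  }
  rater <- rater[match(reference$patient_id, rater$patient_id), , drop = FALSE]
  rows <- lapply(endpoints, function(ep) {
    cnt <- pair_counts(reference[[ep]], rater[[ep]])
    kr <- cohen_kappa(cnt["a"], cnt["b"], cnt["c"], cnt["d"])
    mcn <- if (kr$estimable || cnt["b"] + cnt["c"] > 0) {
      mcnemar_exact(cnt["b"], cnt["c"])
    } else NA_real_
    n <- sum(cnt)
    correct <- sum(cnt[c("a", "c")])  # videos the rater judged correct
    data.frame(endpoint = if (ep == "plane_correct") "midsagittal_plane" else ep,
               n = n, rater_correct = correct,
               rater_correct_pct = 100 * correct / n,
               mcnemar_p = mcn, kappa = kr$kappa, kappa_p = kr$p,
               kappa_ci_low = kr$ci[1L], kappa_ci_high = kr$ci[2L],
               category = kr$category, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
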