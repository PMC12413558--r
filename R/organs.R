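#' The eight pelvic-floor organs of the midsagittal plane
#'
#' A correctly captured midsagittal plane of the pelvic floor shows all eight
#' of these structures simultaneously. The ordering is fixed and is used
#' everywhere in the package: label tables, feature datasets, verdict vectors
#' and simulated cohorts all enumerate organs in this order.
#'
#' @return Character vector of the eight organ identifiers, in canonical order:
#'   pubis, urethra, urinary_bladder, vagina, uterus, anus, rectum, levator_ani.
#' @export
#' @examples
#' organ_ids()
organ_ids <- function() {
  c("pubis", "urethra", "urinary_bladder", "vagina",
    "uterus", "anus", "rectum", "levator_ani")
}

#' @rdname organ_ids
#' @export
n_organs <- function() 8L

# Validate a vector of organ names against the canonical set.
assert_organs <- function(organ) {
  bad <- setdiff(unique(organ), organ_ids())
  if (length(bad) > 0L) {
    stop("unknown organ name(s): ", paste(bad, collapse = ", "),
         " (expected one of: ", paste(organ_ids(), collapse = ", "), ")",
         call. = FALSE)
  }
  invisible(organ)
}
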