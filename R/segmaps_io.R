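#' Construct a segmentation video
#'
#' A `segmentation_video` holds, for one patient's dynamic ultrasound, the
#' per-frame probability maps produced by an upstream organ-segmentation
#' network: one `height x width x n_frames` array per organ, values in
#' \[0, 1\]. Pixel coordinates are 0-based `(row, column)` with the origin at
#' the top-left; rows are the vertical axis.
#'
#' @param patient_id Single string identifying the patient/video.
#' @param maps Named list with one element per organ (names must be exactly
#'   [organ_ids()]); each element a numeric array of dim
#'   `c(height, width, n_frames)` (a `height x width` matrix is accepted for a
#'   single-frame video).
#' @return An object of class `segmentation_video` with fields `patient_id`,
#'   `height`, `width`, `n_frames` and `maps`.
#' @seealso [read_video()], [write_video()]
#' @export
segmentation_video <- function(patient_id, maps) {
  stopifnot(is.character(patient_id), length(patient_id) == 1L)
  if (!is.list(maps) || is.null(names(maps))) {
    stop("'maps' must be a named list of per-organ arrays", call. = FALSE)
  }
  missing <- setdiff(organ_ids(), names(maps))
  if (length(missing) > 0L) {
    stop("missing probability map for organ(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  assert_organs(names(maps))
  maps <- lapply(maps[organ_ids()], function(m) {
    if (is.matrix(m)) m <- array(m, dim = c(dim(m), 1L))
    m
  })
  dims <- dim(maps[[1L]])
  if (length(dims) != 3L) {
    stop("each organ map must be a height x width x n_frames array",
         call. = FALSE)
  }
  for (org in organ_ids()) {
    m <- maps[[org]]
    if (!identical(dim(m), dims)) {
      stop("organ '", org, "' has dimensions ", paste(dim(m), collapse = "x"),
           "; expected ", paste(dims, collapse = "x"), call. = FALSE)
    }
    rng <- range(m)
    if (is.na(rng[1L]) || rng[1L] < 0 || rng[2L] > 1) {
      stop("organ '", org, "' has probability values outside [0, 1]",
           call. = FALSE)
    }
  }
  if (dims[3L] < 1L) stop("video must contain at least one frame", call. = FALSE)
  structure(
    list(patient_id = patient_id,
         height = as.integer(dims[1L]),
         width = as.integer(dims[2L]),
         n_frames = as.integer(dims[3L]),
         maps = maps),
    class = "segmentation_video"
  )
}

#' @export
print.segmentation_video <- function(x, ...) {
  cat(sprintf("<segmentation_video> patient %s: %d frame(s), %dx%d px, %d organs\n",
              x$patient_id, x$n_frames, x$height, x$width, length(x$maps)))
  invisible(x)
}

#' Write a segmentation video to HDF5
#'
#' On-disk layout: root attributes `patient_id` (string) and `height`,
#' `width`, `n_frames` (integers); one group per organ named exactly as in
#' [organ_ids()], each holding a float32 dataset `prob` of HDF5 shape
#' `(n_frames, height, width)`.
#'
#' @param video A [segmentation_video()].
#' @param path Output file path (overwritten if it exists).
#' @return `path`, invisibly.
#' @export
write_video <- function(video, path) {
  stopifnot(inherits(video, "segmentation_video"))
  if (file.exists(path)) unlink(path)
  ok <- try(rhdf5::h5createFile(path), silent = TRUE)
  if (inherits(ok, "try-error") || !isTRUE(ok)) {
    stop("cannot create HDF5 file at '", path, "'", call. = FALSE)
  }
  on.exit(rhdf5::H5close(), add = TRUE)
  fid <- rhdf5::H5Fopen(path)
  rhdf5::h5writeAttribute(video$patient_id, fid, "patient_id")
  rhdf5::h5writeAttribute(video$height, fid, "height")
  rhdf5::h5writeAttribute(video$width, fid, "width")
  rhdf5::h5writeAttribute(video$n_frames, fid, "n_frames")
  rhdf5::H5Fclose(fid)
  for (org in organ_ids()) {
    rhdf5::h5createGroup(path, org)
    # R dims are reversed on disk: (width, height, n_frames) in R gives the
    # documented HDF5 shape (n_frames, height, width).
    arr <- aperm(video$maps[[org]], c(2L, 1L, 3L))
    ds <- paste0(org, "/prob")
    rhdf5::h5createDataset(path, ds, dims = dim(arr),
                           H5type = "H5T_IEEE_F32LE", chunk = dim(arr))
    rhdf5::h5write(arr, path, ds)
  }
  invisible(path)
}

#' Read a segmentation video from HDF5
#'
#' Reads the layout documented in [write_video()] and validates it: every
#' organ group must be present and every probability must lie in \[0, 1\]
#' (exactly; no epsilon).
#'
#' @param path Path to an HDF5 file.
#' @return A [segmentation_video()].
#' @export
read_video <- function(path) {
  if (!file.exists(path)) stop("no such file: '", path, "'", call. = FALSE)
  on.exit(rhdf5::H5close(), add = TRUE)
  contents <- rhdf5::h5ls(path)
  groups <- contents$name[contents$group == "/" & contents$otype == "H5I_GROUP"]
  missing <- setdiff(organ_ids(), groups)
  if (length(missing) > 0L) {
    stop("HDF5 file '", path, "' is missing organ group(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  fid <- rhdf5::H5Fopen(path)
  patient_id <- as.character(rhdf5::h5readAttributes(fid, "/")$patient_id)
  rhdf5::H5Fclose(fid)
  maps <- lapply(organ_ids(), function(org) {
    arr <- rhdf5::h5read(path, paste0(org, "/prob"))
    if (length(dim(arr)) != 3L) {
      stop("dataset '", org, "/prob' is not 3-dimensional", call. = FALSE)
    }
    storage.mode(arr) <- "double"
    aperm(arr, c(2L, 1L, 3L))
  })
  names(maps) <- organ_ids()
  segmentation_video(patient_id, maps)
}

#' Read a per-organ label table
#'
#' The label CSV has header `patient_id,organ,organ_correct` with
#' `organ_correct` in `{0, 1}` and exactly one row per (patient, organ).
#' The per-patient plane verdict is never stored: `plane_correct` is always
#' derived as the conjunction of the eight organ labels, so the table cannot
#' be internally inconsistent.
#'
#' @param path Path to the CSV file.
#' @return A `label_table`: data frame with columns `patient_id`, `organ`,
#'   `organ_correct`, plus attribute `plane` — a data frame of
#'   (`patient_id`, `plane_correct`) — also retrievable with [plane_labels()].
#' @export
read_labels <- function(path) {
  df <- utils::read.csv(path, colClasses = c(patient_id = "character",
                                             organ = "character"))
  label_table(df)
}

#' @rdname read_labels
#' @param df Data frame with columns `patient_id`, `organ`, `organ_correct`.
#' @export
label_table <- function(df) {
  need <- c("patient_id", "organ", "organ_correct")
  if (!all(need %in% names(df))) {
    stop("label table must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  df <- df[need]
  df$patient_id <- as.character(df$patient_id)
  assert_organs(df$organ)
  if (!all(df$organ_correct %in% c(0L, 1L))) {
    stop("organ_correct must be 0 or 1", call. = FALSE)
  }
  df$organ_correct <- as.integer(df$organ_correct)
  key <- paste(df$patient_id, df$organ, sep = "\r")
  if (anyDuplicated(key)) {
    dup <- df[duplicated(key), , drop = FALSE][1L, ]
    stop("duplicate label row for patient '", dup$patient_id, "', organ '",
         dup$organ, "'", call. = FALSE)
  }
  per_patient <- tapply(df$organ, df$patient_id, length)
  incomplete <- names(per_patient)[per_patient != n_organs()]
  if (length(incomplete) > 0L) {
    stop("patient(s) without all ", n_organs(), " organ labels: ",
         paste(incomplete, collapse = ", "), call. = FALSE)
  }
  # canonical order: patient, then organ enum order
  df <- df[order(df$patient_id, match(df$organ, organ_ids())), , drop = FALSE]
  rownames(df) <- NULL
  plane <- tapply(df$organ_correct, df$patient_id, function(v) as.integer(all(v == 1L)))
  attr(df, "plane") <- data.frame(patient_id = names(plane),
                                  plane_correct = as.integer(plane),
                                  stringsAsFactors = FALSE)
  class(df) <- c("label_table", "data.frame")
  df
}

#' Per-patient plane labels derived from a label table
#'
#' @param labels A `label_table` from [read_labels()] or [label_table()].
#' @return Data frame with columns `patient_id` and `plane_correct` (1 iff
#'   all eight organ labels are 1).
#' @export
plane_labels <- function(labels) {
  stopifnot(inherits(labels, "label_table"))
  attr(labels, "plane")
}

#' Write a label table to CSV
#'
#' Only the per-organ rows are written; the plane column is derived, never
#' stored.
#'
#' @param labels A `label_table`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_labels <- function(labels, path) {
  stopifnot(inherits(labels, "label_table"))
  utils::write.csv(as.data.frame(labels)[c("patient_id", "organ", "organ_correct")],
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
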