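#' Write an OCT volume as a multi-page TIFF with JSON sidecar
#'
#' One TIFF page per B-scan (rows = depth, columns = A-scans), uncompressed
#' grayscale. Voxel spacings and labels go to a JSON sidecar next to the TIFF,
#' so that write -> read is lossless for integer grids.
#'
#' @param vol An [oct_volume()].
#' @param path Output TIFF path (`.tif`/`.tiff`).
#' @param sidecar_path JSON sidecar path; default replaces the TIFF extension
#'   with `.json`.
#' @return `path`, invisibly.
#' @export
write_volume <- function(vol, path, sidecar_path = sidecar_for(path)) {
  stopifnot(inherits(vol, "oct_volume"))
  ints <- vol$intensities
  if (is.double(ints))
    stop_ovm(paste0("volume has non-integer intensities; quantize first ",
                    "(e.g. round to integers within the 8- or 16-bit range)"))
  mx <- max(ints)
  if (mx > 65535L || min(ints) < 0L)
    stop_ovm("intensities out of the representable 16-bit range [0, 65535]")
  bits <- if (mx > 255L) 16L else 8L
  d <- dim(ints)
  pages <- lapply(seq_len(d[3]), function(y) ints[, , y])
  write_tiff_pages(pages, path, bits)
  meta <- list(axial_spacing_um = vol$axial_spacing_um,
               lateral_spacing_mm_x = vol$lateral_spacing_mm_x,
               lateral_spacing_mm_y = vol$lateral_spacing_mm_y,
               eye_id = vol$eye_id,
               timepoint_label = vol$timepoint_label)
  jsonlite::write_json(meta, sidecar_path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read an OCT volume from a multi-page TIFF
#'
#' Pages are mapped to B-scans (axis `y`), page rows to depth `z`, and page
#' columns to A-scans `x`. If no sidecar is found, documented default spacings
#' are used and a warning is emitted.
#'
#' @param path TIFF path.
#' @param sidecar_path JSON sidecar path; default looks next to `path`.
#' @return An [oct_volume()].
#' @export
read_volume <- function(path, sidecar_path = sidecar_for(path)) {
  if (!file.exists(path)) stop_ovm("volume file '%s' does not exist", path)
  pages <- read_tiff_pages(path)
  nz <- nrow(pages[[1]]); nx <- ncol(pages[[1]]); ny <- length(pages)
  ints <- array(0L, dim = c(nz, nx, ny))
  for (y in seq_len(ny)) ints[, , y] <- pages[[y]]
  meta <- list(axial_spacing_um = 2.0, lateral_spacing_mm_x = 0.02,
               lateral_spacing_mm_y = 0.1, eye_id = "eye", timepoint_label = "t0")
  if (!is.null(sidecar_path) && file.exists(sidecar_path)) {
    got <- jsonlite::read_json(sidecar_path, simplifyVector = TRUE)
    meta[names(got)] <- got
  } else {
    warn_ovm("no sidecar found for '%s'; using default spacings (%g um axial, %g x %g mm lateral)",
             path, meta$axial_spacing_um, meta$lateral_spacing_mm_x,
             meta$lateral_spacing_mm_y)
  }
  oct_volume(ints,
             axial_spacing_um = meta$axial_spacing_um,
             lateral_spacing_mm_x = meta$lateral_spacing_mm_x,
             lateral_spacing_mm_y = meta$lateral_spacing_mm_y,
             eye_id = meta$eye_id,
             timepoint_label = meta$timepoint_label)
}

sidecar_for <- function(path) paste0(sub("\\.tiff?$", "", path), ".json")

#' Write a boolean mask as a 0/255 multi-page TIFF
#'
#' @param mask 3D logical array indexed `(z, x, y)`.
#' @param path Output TIFF path.
#' @return `path`, invisibly.
#' @export
write_mask <- function(mask, path) {
  stopifnot(is.logical(mask), length(dim(mask)) == 3L)
  d <- dim(mask)
  pages <- lapply(seq_len(d[3]), function(y) ifelse(mask[, , y], 255L, 0L))
  write_tiff_pages(pages, path, 8L)
  invisible(path)
}

#' Read a 0/255 mask TIFF back as a logical array
#' @param path TIFF path written by [write_mask()].
#' @return 3D logical array.
#' @export
read_mask <- function(path) {
  pages <- read_tiff_pages(path)
  d <- c(nrow(pages[[1]]), ncol(pages[[1]]), length(pages))
  out <- array(FALSE, dim = d)
  for (y in seq_len(d[3])) out[, , y] <- pages[[y]] > 0L
  out
}

#' Rater measurement table
#'
#' Complete subjects x raters matrix of percent scar volume, the input to the
#' reliability analysis.
#'
#' @param values Numeric matrix, one row per subject, one column per rater;
#'   no missing cells, values >= 0.
#' @param subject_ids,rater_ids Optional dimension names.
#' @return A `rating_table` (a classed matrix).
#' @export
rating_table <- function(values, subject_ids = NULL, rater_ids = NULL) {
  values <- as.matrix(values)
  if (nrow(values) < 2L) stop_ovm("rating table needs at least 2 subjects")
  if (ncol(values) < 2L) stop_ovm("rating table needs at least 2 raters")
  if (anyNA(values)) {
    idx <- which(is.na(values), arr.ind = TRUE)
    stop_ovm("rating table has missing cells at (subject, rater): %s",
             paste(sprintf("(%d, %d)", idx[, 1], idx[, 2]), collapse = ", "))
  }
  if (!is.numeric(values)) stop_ovm("rating table values must be numeric")
  if (min(values) < 0) stop_ovm("rating table values must be >= 0")
  rownames(values) <- subject_ids %||% rownames(values) %||%
    sprintf("S%02d", seq_len(nrow(values)))
  colnames(values) <- rater_ids %||% colnames(values) %||%
    sprintf("R%d", seq_len(ncol(values)))
  class(values) <- c("rating_table", class(values))
  values
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read a subjects x raters CSV into a rating table
#'
#' Expected layout: header row of rater names, optional first column
#' `subject_id`, one row per subject, numeric cells, no gaps.
#'
#' @param path CSV path.
#' @return A [rating_table()].
#' @export
read_rating_table <- function(path) {
  if (!file.exists(path)) stop_ovm("ratings file '%s' does not exist", path)
  df <- read.csv(path, check.names = FALSE)
  subject_ids <- NULL
  if (ncol(df) && tolower(names(df)[1]) %in% c("subject", "subject_id", "id")) {
    subject_ids <- as.character(df[[1]])
    df <- df[, -1, drop = FALSE]
  }
  for (j in seq_along(df)) {
    v <- suppressWarnings(as.numeric(df[[j]]))
    bad <- which(is.na(v) & !is.na(df[[j]]))
    if (length(bad))
      stop_ovm("non-numeric cell in '%s' at row %d, column '%s'",
               path, bad[1], names(df)[j])
    df[[j]] <- v
  }
  rating_table(as.matrix(df), subject_ids = subject_ids, rater_ids = names(df))
}

#' Write per-eye, per-timepoint measurements as CSV
#'
#' @param rows A data frame of [measure_opacity()] rows (see
#'   [as.data.frame.opacity_measurement()]), or a list of
#'   `opacity_measurement` objects.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_measurements <- function(rows, path) {
  if (is.list(rows) && !is.data.frame(rows))
    rows <- do.call(rbind, lapply(rows, as.data.frame))
  stopifnot(is.data.frame(rows))
  write.csv(rows, path, row.names = FALSE)
  invisible(path)
}

#' Read a measurements CSV written by [write_measurements()]
#' @param path CSV path.
#' @return A data frame.
#' @export
read_measurements <- function(path) {
  if (!file.exists(path)) stop_ovm("measurements file '%s' does not exist", path)
  read.csv(path, check.names = FALSE)
}
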