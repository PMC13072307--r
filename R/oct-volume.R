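#' OCT volume container
#'
#' An `oct_volume` holds a 3D intensity grid indexed `(z, x, y)`:
#' axial depth `z` (increasing posteriorly, anterior surface at low `z`),
#' A-scan position `x`, and B-scan index `y` (one B-scan = one `(z, x)`
#' cross-section). Spacings give the physical size of one voxel along each
#' axis. This is the object every geometric pipeline stage transforms.
#'
#' @param intensities 3D numeric array, dimensions `(depth, ascans, bscans)`,
#'   all values >= 0. Integer-valued grids are stored as integers.
#' @param axial_spacing_um Axial voxel size in micrometres (> 0).
#' @param lateral_spacing_mm_x A-scan spacing in millimetres (> 0).
#' @param lateral_spacing_mm_y B-scan spacing in millimetres (> 0).
#' @param eye_id,timepoint_label Character metadata carried through the
#'   pipeline and into measurement rows.
#'
#' @return An object of class `oct_volume`.
#' @export
oct_volume <- function(intensities,
                       axial_spacing_um = 2.0,
                       lateral_spacing_mm_x = 0.02,
                       lateral_spacing_mm_y = 0.1,
                       eye_id = "eye",
                       timepoint_label = "t0") {
  if (!is.array(intensities) || length(dim(intensities)) != 3L)
    stop_ovm("intensities must be a 3D array indexed (z, x, y)")
  d <- dim(intensities)
  if (d[1] < 8L || d[2] < 8L || d[3] < 2L)
    stop_ovm("volume dimensions must be at least (8, 8, 2); got (%d, %d, %d)",
             d[1], d[2], d[3])
  if (anyNA(intensities) || min(intensities) < 0)
    stop_ovm("intensities must be non-negative and free of NA")
  for (nm in c("axial_spacing_um", "lateral_spacing_mm_x", "lateral_spacing_mm_y")) {
    v <- get(nm)
    if (!is_scalar_num(v) || v <= 0) stop_ovm("%s must be a positive number", nm)
  }
  if (is.double(intensities) && all(intensities == floor(intensities)))
    storage.mode(intensities) <- "integer"
  structure(
    list(intensities = intensities,
         axial_spacing_um = axial_spacing_um,
         lateral_spacing_mm_x = lateral_spacing_mm_x,
         lateral_spacing_mm_y = lateral_spacing_mm_y,
         eye_id = as.character(eye_id),
         timepoint_label = as.character(timepoint_label)),
    class = "oct_volume")
}

#' @export
print.oct_volume <- function(x, ...) {
  d <- dim(x$intensities)
  cat(sprintf("<oct_volume> %s / %s\n", x$eye_id, x$timepoint_label))
  cat(sprintf("  grid  : %d (z) x %d (x) x %d (y) voxels\n", d[1], d[2], d[3]))
  cat(sprintf("  voxel : %.3g um axial, %.3g x %.3g mm lateral\n",
              x$axial_spacing_um, x$lateral_spacing_mm_x, x$lateral_spacing_mm_y))
  cat(sprintf("  range : [%s, %s]\n", min(x$intensities), max(x$intensities)))
  invisible(x)
}

#' @export
dim.oct_volume <- function(x) dim(x$intensities)

# mm^3 of one voxel
voxel_volume_mm3 <- function(vol) {
  (vol$axial_spacing_um * 1e-3) * vol$lateral_spacing_mm_x * vol$lateral_spacing_mm_y
}

# replace intensities, keeping metadata
set_intensities <- function(vol, intensities) {
  if (is.double(intensities) && all(intensities == floor(intensities)))
    storage.mode(intensities) <- "integer"
  vol$intensities <- intensities
  vol
}
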