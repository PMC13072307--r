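#' Dual-threshold model
#'
#' Two fixed intensity cutoffs: `t_button` separates the corneal button from
#' background; `t_opacity` separates normal stroma from hyperreflective
#' (fibrotic) stroma. Voxels are corneal when `intensity >= t_button` and
#' opaque when `intensity > t_opacity` -- ties at `t_opacity` count as normal
#' tissue, the conservative scar call.
#'
#' @param t_button,t_opacity Intensity cutoffs with `t_opacity > t_button`.
#' @param calibration Provenance list (cohort sizes, method, percentile or k).
#' @return A `threshold_model`.
#' @export
threshold_model <- function(t_button, t_opacity, calibration = list()) {
  stopifnot(is_scalar_num(t_button), is_scalar_num(t_opacity))
  if (t_button < 0) stop_ovm("t_button must be >= 0")
  if (t_opacity <= t_button)
    stop_ovm("t_opacity (%g) must exceed t_button (%g); recalibrate",
             t_opacity, t_button)
  structure(list(t_button = t_button, t_opacity = t_opacity,
                 calibration = calibration),
            class = "threshold_model")
}

#' @export
print.threshold_model <- function(x, ...) {
  cat(sprintf("<threshold_model> t_button = %.3f, t_opacity = %.3f\n",
              x$t_button, x$t_opacity))
  cal <- x$calibration
  if (length(cal))
    cat(sprintf("  calibrated on %s button / %s naive volumes (%s%s)\n",
                cal$n_volumes_button %||% "?", cal$n_volumes_naive %||% "?",
                cal$method %||% "?",
                if (!is.null(cal$percentile)) sprintf(", percentile %g", cal$percentile)
                else if (!is.null(cal$k)) sprintf(", k = %g", cal$k) else ""))
  invisible(x)
}

#' Save / load a threshold model as JSON
#'
#' Fixed thresholds must be applied consistently across timepoints, so the
#' calibrated model is serialized for reuse.
#'
#' @param model A [threshold_model()].
#' @param path JSON path.
#' @return `path` (write) or the [threshold_model()] (read).
#' @export
write_threshold_model <- function(model, path) {
  stopifnot(inherits(model, "threshold_model"))
  jsonlite::write_json(unclass(model), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_threshold_model
#' @export
read_threshold_model <- function(path) {
  if (!file.exists(path)) stop_ovm("threshold model '%s' does not exist", path)
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  threshold_model(x$t_button, x$t_opacity, as.list(x$calibration))
}

#' Standard geometric preprocessing parameters
#'
#' Bundles the tunables of the geometry stages in pipeline order:
#' registration window, button crop, specular band, surface threshold and
#' smoothing, flattening reference row, anterior fraction.
#'
#' @param jitter_window_px Registration search window (voxels).
#' @param button A [button_region()].
#' @param specular_band `c(center, half_width)` or `NULL` for auto-detection.
#' @param t_surface Surface threshold; `NULL` uses the button threshold when
#'   one is supplied, otherwise an Otsu threshold of the nonzero voxels.
#' @param median_window Surface smoothing window.
#' @param ref_row Flattening reference row (0-based).
#' @param fallback_depth_px Fixed trim depth when thickness is undeterminable.
#' @return A `pipeline_params` list.
#' @export
pipeline_params <- function(jitter_window_px = 10L,
                            button = button_region(),
                            specular_band = NULL,
                            t_surface = NULL,
                            median_window = 5L,
                            ref_row = 40L,
                            fallback_depth_px = NULL) {
  structure(list(jitter_window_px = jitter_window_px, button = button,
                 specular_band = specular_band, t_surface = t_surface,
                 median_window = median_window, ref_row = ref_row,
                 fallback_depth_px = fallback_depth_px),
            class = "pipeline_params")
}

#' Run the geometric stages: register, crop, despecular, surface, flatten, trim
#'
#' @param vol A raw [oct_volume()].
#' @param params A [pipeline_params()].
#' @param t_surface Overrides `params$t_surface`.
#' @return A list: `volume` (flattened, trimmed), `surface` (pre-flattening
#'   [detect_surface()] map), `shifts` (registration corrections),
#'   `specular_band`, `trim_plane`, `t_surface`.
#' @export
preprocess_volume <- function(vol, params = pipeline_params(), t_surface = NULL) {
  stopifnot(inherits(vol, "oct_volume"))
  reg <- register_bscans(vol, params$jitter_window_px)
  cropped <- crop_button(reg$volume, params$button)
  sp <- remove_specular(cropped, params$specular_band)
  ts <- t_surface %||% params$t_surface %||% otsu_threshold(sp$volume$intensities)
  surf <- detect_surface(sp$volume, ts, params$median_window)
  flat <- flatten_volume(sp$volume, surf, params$ref_row)
  tr <- trim_anterior_fraction(flat, surf, params$button$anterior_fraction,
                               params$ref_row, params$fallback_depth_px)
  list(volume = tr$volume, surface = surf, shifts = reg$shifts,
       specular_band = sp$band, trim_plane = tr$trim_plane, t_surface = ts)
}

#' Calibrate the dual thresholds from scar-free cohorts
#'
#' `t_button` is the mean intensity over all nonzero voxels of the
#' preprocessed button-calibration cohort (normal corneas segmented from
#' background). `t_opacity` is an upper percentile (default 99.5) of the
#' corneal-voxel intensities pooled over the preprocessed naive cohort --
#' signals above the naive level are what counts as hyperreflective. A
#' `mean_sd` alternative (`mean + k * SD` of the pooled corneal voxels) is
#' available behind the `method` switch.
#'
#' @param button_cohort,naive_cohort Non-empty lists of preprocessed,
#'   scar-free [oct_volume()] objects (see [preprocess_volume()]).
#' @param opacity_percentile Percentile defining `t_opacity` (method
#'   `"percentile"`).
#' @param method `"percentile"` (default) or `"mean_sd"`.
#' @param k Multiplier for `method = "mean_sd"`.
#' @return A [threshold_model()] with calibration provenance.
#' @export
calibrate_thresholds <- function(button_cohort, naive_cohort,
                                 opacity_percentile = 99.5,
                                 method = c("percentile", "mean_sd"), k = 3) {
  method <- match.arg(method)
  if (!length(button_cohort)) stop_ovm("button cohort is empty")
  if (!length(naive_cohort)) stop_ovm("naive cohort is empty")
  if (opacity_percentile <= 0 || opacity_percentile > 100)
    stop_ovm("opacity_percentile must be in (0, 100]")
  sums <- vapply(button_cohort, function(v) {
    nz <- v$intensities[v$intensities > 0]
    c(sum(as.double(nz)), length(nz))
  }, numeric(2))
  if (sum(sums[2, ]) == 0) stop_ovm("button cohort contains no nonzero voxels")
  t_button <- sum(sums[1, ]) / sum(sums[2, ])

  interim <- threshold_model(t_button, t_button + 1)  # for segment_button only
  pooled <- unlist(lapply(naive_cohort, function(v) {
    v$intensities[segment_button(v, interim)]
  }), use.names = FALSE)
  t_opacity <- if (method == "percentile")
    as.numeric(quantile(pooled, opacity_percentile / 100, names = FALSE))
  else mean(pooled) + k * sd(pooled)
  if (t_opacity <= t_button)
    stop_ovm("calibration failed: t_opacity (%g) <= t_button (%g); recalibrate with brighter naive signal or a higher percentile",
             t_opacity, t_button)
  threshold_model(t_button, t_opacity, calibration = list(
    n_volumes_button = length(button_cohort),
    n_volumes_naive = length(naive_cohort),
    method = method,
    percentile = if (method == "percentile") opacity_percentile else NULL,
    k = if (method == "mean_sd") k else NULL))
}

#' Segment the corneal button
#'
#' Fixed threshold `intensity >= t_button`, restricted to the largest 3D
#' connected component (residual bright noise is discarded).
#'
#' @param vol A flattened, trimmed [oct_volume()].
#' @param model A [threshold_model()].
#' @param bridge_px Lateral dilation radius used only for connectivity (the
#'   specular-cleared column gap must not split the button in two).
#' @return 3D logical mask.
#' @export
segment_button <- function(vol, model, bridge_px = 8L) {
  stopifnot(inherits(vol, "oct_volume"), inherits(model, "threshold_model"))
  binary <- vol$intensities >= model$t_button
  mask <- binary & largest_component(dilate_x(binary, bridge_px))
  if (!any(mask))
    stop_ovm("button segmentation empty: no voxel reaches t_button = %g",
             model$t_button)
  mask
}

#' Segment hyperreflective (opacity) voxels within the button
#'
#' `intensity > t_opacity` intersected with the button mask; by construction
#' a subset of the button.
#'
#' @param vol The volume used for [segment_button()].
#' @param model A [threshold_model()].
#' @param button_mask Result of [segment_button()].
#' @return 3D logical mask, subset of `button_mask`.
#' @export
segment_opacity <- function(vol, model, button_mask) {
  stopifnot(inherits(vol, "oct_volume"), inherits(model, "threshold_model"))
  if (!any(button_mask)) stop_ovm("button mask is empty")
  (vol$intensities > model$t_opacity) & button_mask
}

#' Measure corneal and opacity volume
#'
#' Composes [segment_button()] and [segment_opacity()] on a preprocessed
#' volume, converts voxel counts to cubic millimetres, and reports the
#' percent opacity (computed on voxel counts, so spacing metadata cannot
#' bias the ratio).
#'
#' @param vol A flattened, trimmed [oct_volume()].
#' @param model A calibrated [threshold_model()].
#' @param surface Optional [detect_surface()] map; when it carries valid
#'   posterior surfaces, the central corneal thickness is attached.
#' @return An `opacity_measurement`.
#' @export
measure_opacity <- function(vol, model, surface = NULL) {
  button <- segment_button(vol, model)
  opacity <- segment_opacity(vol, model, button)
  vx <- voxel_volume_mm3(vol)
  cct <- NULL
  if (!is.null(surface) && any(!is.na(surface$posterior)))
    cct <- tryCatch(
      measure_cct(surface, vol$axial_spacing_um,
                  vol$lateral_spacing_mm_x, vol$lateral_spacing_mm_y),
      error = function(e) NULL)
  structure(
    list(eye_id = vol$eye_id,
         timepoint_label = vol$timepoint_label,
         corneal_volume_voxels = sum(button),
         corneal_volume_mm3 = sum(button) * vx,
         opacity_volume_voxels = sum(opacity),
         opacity_volume_mm3 = sum(opacity) * vx,
         percent_opacity = 100 * sum(opacity) / sum(button),
         thresholds = model,
         cct_um = cct),
    class = "opacity_measurement")
}

#' @export
print.opacity_measurement <- function(x, ...) {
  cat(sprintf("<opacity_measurement> %s / %s\n", x$eye_id, x$timepoint_label))
  cat(sprintf("  cornea : %d voxels = %.4f mm^3\n",
              x$corneal_volume_voxels, x$corneal_volume_mm3))
  cat(sprintf("  opacity: %d voxels = %.4f mm^3 (%.2f%%)\n",
              x$opacity_volume_voxels, x$opacity_volume_mm3, x$percent_opacity))
  if (!is.null(x$cct_um)) cat(sprintf("  CCT    : %.1f um\n", x$cct_um))
  invisible(x)
}

#' @export
as.data.frame.opacity_measurement <- function(x, ...) {
  data.frame(eye_id = x$eye_id, timepoint = x$timepoint_label,
             corneal_volume_voxels = x$corneal_volume_voxels,
             corneal_volume_mm3 = x$corneal_volume_mm3,
             opacity_volume_voxels = x$opacity_volume_voxels,
             opacity_volume_mm3 = x$opacity_volume_mm3,
             percent_opacity = x$percent_opacity,
             t_button = x$thresholds$t_button,
             t_opacity = x$thresholds$t_opacity,
             cct_um = x$cct_um %||% NA_real_,
             stringsAsFactors = FALSE)
}

#' Central corneal thickness (CCT)
#'
#' Average of 5 anterior-to-posterior distances sampled at the corneal
#' centre and at +-0.5 mm along the horizontal and vertical meridians,
#' converted to micrometres. The centre defaults to the centroid of the
#' valid surface region.
#'
#' @param surface A [detect_surface()] map with posterior surfaces.
#' @param axial_spacing_um Axial voxel size.
#' @param lateral_spacing_mm_x,lateral_spacing_mm_y Lateral voxel sizes.
#' @param center `c(x, y)` 0-based centre indices; `NULL` = valid-region
#'   centroid.
#' @param offset_mm Meridian sampling offset (default 0.5 mm).
#' @return CCT in micrometres.
#' @export
measure_cct <- function(surface, axial_spacing_um,
                        lateral_spacing_mm_x, lateral_spacing_mm_y,
                        center = NULL, offset_mm = 0.5) {
  stopifnot(inherits(surface, "surface_map"))
  if (all(is.na(surface$posterior)))
    stop_ovm("surface map carries no posterior surface; CCT undeterminable")
  d <- dim(surface$anterior)
  if (is.null(center)) {
    idx <- which(surface$valid_mask, arr.ind = TRUE)
    center <- c(round(mean(idx[, 1])) - 1L, round(mean(idx[, 2])) - 1L)
  }
  ox <- round(offset_mm / lateral_spacing_mm_x)
  oy <- round(offset_mm / lateral_spacing_mm_y)
  pts <- rbind(center,
               center + c(ox, 0), center - c(ox, 0),
               center + c(0, oy), center - c(0, oy))
  labels <- c("center", "+0.5mm x", "-0.5mm x", "+0.5mm y", "-0.5mm y")
  vals <- numeric(5)
  bad <- character(0)
  for (i in 1:5) {
    x <- pts[i, 1] + 1L; y <- pts[i, 2] + 1L
    if (x < 1L || x > d[1] || y < 1L || y > d[2] ||
        is.na(surface$anterior[x, y]) || is.na(surface$posterior[x, y])) {
      bad <- c(bad, labels[i])
    } else {
      vals[i] <- (surface$posterior[x, y] - surface$anterior[x, y]) * axial_spacing_um
    }
  }
  if (length(bad))
    stop_ovm("CCT sample point(s) invalid: %s", paste(bad, collapse = ", "))
  mean(vals)
}

#' Percent scarred area from en-face masks
#'
#' The photograph-based companion of the volumetric measure:
#' `100 * |scar| / |cornea|` on 2D masks.
#'
#' @param cornea_mask_2d,scar_mask_2d Logical matrices, `scar` a subset of
#'   `cornea`.
#' @return Scar area percentage.
#' @export
percent_scar_area <- function(cornea_mask_2d, scar_mask_2d) {
  stopifnot(is.logical(cornea_mask_2d), is.logical(scar_mask_2d),
            all(dim(cornea_mask_2d) == dim(scar_mask_2d)))
  if (!any(cornea_mask_2d)) stop_ovm("cornea mask is empty")
  if (any(scar_mask_2d & !cornea_mask_2d))
    stop_ovm("scar mask is not a subset of the cornea mask")
  100 * sum(scar_mask_2d) / sum(cornea_mask_2d)
}

#' En-face projection of a 3D mask
#' @param mask 3D logical array `(z, x, y)`.
#' @return Logical `ascans x bscans` matrix: columns containing any voxel.
#' @export
en_face_mask <- function(mask) {
  stopifnot(is.logical(mask), length(dim(mask)) == 3L)
  apply(mask, c(2, 3), any)
}
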