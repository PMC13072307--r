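# Shared fixtures: desk-scale phantoms small enough for unit tests.
# Geometry mirrors the default phantom (curved shell, clutter, specular,
# jitter) on a 160 x 80 x 16 grid over a 2 x 2 mm field.

tiny_spec <- function(...) {
  args <- list(...)
  defaults <- list(grid_dims = c(160L, 80L, 16L),
                   lateral_extent_mm = 2.0,
                   apex_depth_px = 24L,
                   jitter_amplitude_px = 4L,
                   # stripe width scales with the A-scan count
                   specular = list(column_center = NULL, half_width_px = 1L,
                                   intensity = 255),
                   seed = 1L)
  defaults[names(args)] <- args
  do.call(phantom_spec, defaults)
}

tiny_params <- function(...) {
  args <- list(...)
  defaults <- list(button = button_region(radius_mm = 1.3),
                   ref_row = 28L)
  defaults[names(args)] <- args
  do.call(pipeline_params, defaults)
}

# calibration on tiny cohorts is reused across files; memoise per run
.tiny_cache <- new.env(parent = emptyenv())

tiny_model <- function() {
  if (is.null(.tiny_cache$model)) {
    params <- tiny_params()
    base <- tiny_spec(seed = 500L)
    pre <- function(v) preprocess_volume(v, params)$volume
    button <- lapply(generate_naive_cohort(4, base, seed = 911), pre)
    naive <- lapply(generate_naive_cohort(6, base, seed = 912), pre)
    .tiny_cache$model <- calibrate_thresholds(button, naive)
  }
  .tiny_cache$model
}

# percent opacity of the truth masks restricted to the analysis field the
# pipeline measures: button cylinder (about the grid centre) intersected
# with the anterior fraction of the true stromal thickness
field_truth_percent <- function(truth, spec, radius_mm, fraction = 2 / 3) {
  ant <- truth$anterior_surface_true
  post <- truth$posterior_surface_true
  plane_off <- round(fraction * median(post - ant, na.rm = TRUE))
  d <- dim(truth$cornea_mask)
  sx <- spec$lateral_extent_mm / d[2]
  sy <- spec$lateral_extent_mm / d[3]
  xs <- (seq_len(d[2]) - (d[2] + 1) / 2) * sx
  ys <- (seq_len(d[3]) - (d[3] + 1) / 2) * sy
  cyl <- outer(xs^2, ys^2, "+") <= radius_mm^2
  cornea <- 0L
  scar <- 0L
  for (y in seq_len(d[3])) for (x in seq_len(d[2])) {
    if (is.na(ant[x, y]) || !cyl[x, y]) next
    zr <- (ant[x, y]:min(ant[x, y] + plane_off, d[1] - 1L)) + 1L
    cornea <- cornea + sum(truth$cornea_mask[zr, x, y])
    scar <- scar + sum(truth$scar_mask[zr, x, y])
  }
  100 * scar / cornea
}
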