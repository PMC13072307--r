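# Geometric pipeline stages. All public axial indices are 0-based (z = 0 is
# the most anterior row), matching the stack-of-pages TIFF convention.

#' Motion-correct B-scans by axial cross-correlation
#'
#' Compensates heartbeat/respiration motion: each B-scan is rigidly shifted
#' axially by the integer that maximizes the normalized cross-correlation of
#' its mean A-line profile against the running reference (the previous,
#' already registered B-scan). The first B-scan anchors the chain (shift 0).
#'
#' @param vol An [oct_volume()] with at least 2 B-scans.
#' @param jitter_window_px Search window: shifts in `[-w, w]` are scored.
#' @return `list(volume, shifts)`; `shifts[y]` is the correction applied to
#'   B-scan `y` (so a B-scan displaced by `+s` receives correction `-s`).
#' @export
register_bscans <- function(vol, jitter_window_px = 10L) {
  stopifnot(inherits(vol, "oct_volume"))
  ints <- vol$intensities
  d <- dim(ints)
  if (d[3] < 2L) stop_ovm("registration needs at least 2 B-scans")
  w <- as.integer(jitter_window_px)
  stopifnot(w >= 0L)
  out <- array(ints, dim = d)
  shifts <- integer(d[3])
  ref <- rowMeans(out[, , 1])
  for (y in 2:d[3]) {
    prof <- rowMeans(ints[, , y])
    if (sd(prof) == 0 || sd(ref) == 0) {
      warn_ovm("flat B-scan profile at index %d; applying zero shift", y)
      s_best <- 0L
    } else {
      s_best <- 0L
      best <- -Inf
      for (s in (-w):w) {
        nccv <- ncc_shift(prof, ref, s)
        if (!is.na(nccv) && nccv > best) {
          best <- nccv
          s_best <- s
        }
      }
    }
    shifts[y] <- s_best
    out[, , y] <- if (s_best == 0L) ints[, , y] else
      shift_plane(ints[, , y], s_best, fill = 0)
    ref <- rowMeans(out[, , y])
  }
  list(volume = set_intensities(vol, out), shifts = shifts)
}

# NCC of profile p shifted by s voxels (positive = deeper) against ref,
# over the overlapping support
ncc_shift <- function(p, ref, s) {
  n <- length(p)
  if (abs(s) >= n - 1L) return(NA_real_)
  if (s >= 0) {
    a <- p[1:(n - s)]; b <- ref[(1 + s):n]
  } else {
    a <- p[(1 - s):n]; b <- ref[1:(n + s)]
  }
  if (sd(a) == 0 || sd(b) == 0) return(NA_real_)
  stats::cor(a, b)
}

#' Standardized corneal button definition
#'
#' A cylinder along the axial direction: everything outside it is cleared so
#' that eyelids and peripheral tissue never enter the measurement. The
#' default radius is 1 mm; `anterior_fraction` records the anterior portion
#' of the stroma retained after flattening (default 2/3).
#'
#' @param center_x,center_y Cylinder axis, 0-based voxel indices; `NULL`
#'   auto-centres on the brightest-surface centroid (the apex).
#' @param radius_mm Button radius in millimetres.
#' @param anterior_fraction In (0, 1]; stored for the trim stage.
#' @return A `button_region`.
#' @export
button_region <- function(center_x = NULL, center_y = NULL,
                          radius_mm = 1.0, anterior_fraction = 2 / 3) {
  if (!is_scalar_num(radius_mm) || radius_mm <= 0)
    stop_ovm("radius_mm must be > 0")
  if (!is_scalar_num(anterior_fraction) || anterior_fraction <= 0 ||
      anterior_fraction > 1)
    stop_ovm("anterior_fraction must be in (0, 1]")
  structure(list(center_x = center_x, center_y = center_y,
                 radius_mm = radius_mm, anterior_fraction = anterior_fraction),
            class = "button_region")
}

#' Crop the standardized corneal button
#'
#' Sets voxels outside the button cylinder to zero; grid dimensions are
#' unchanged. With an omitted centre the cylinder is auto-centred at the
#' centroid of the brightest-surface A-scans (the apex region).
#'
#' @param vol An [oct_volume()].
#' @param region A [button_region()].
#' @return The cropped [oct_volume()].
#' @export
crop_button <- function(vol, region = button_region()) {
  stopifnot(inherits(vol, "oct_volume"), inherits(region, "button_region"))
  ints <- vol$intensities
  d <- dim(ints)
  cx <- region$center_x; cy <- region$center_y
  if (is.null(cx) || is.null(cy)) {
    peak <- apply(ints, c(2, 3), max)
    bright <- peak >= quantile(peak, 0.99)
    idx <- which(bright, arr.ind = TRUE)
    if (is.null(cx)) cx <- mean(idx[, 1]) - 1
    if (is.null(cy)) cy <- mean(idx[, 2]) - 1
  }
  dx_mm <- (seq_len(d[2]) - 1 - cx) * vol$lateral_spacing_mm_x
  dy_mm <- (seq_len(d[3]) - 1 - cy) * vol$lateral_spacing_mm_y
  inside <- outer(dx_mm^2, dy_mm^2, "+") <= region$radius_mm^2
  if (!any(inside))
    stop_ovm("button cylinder (centre %.1f, %.1f; radius %g mm) lies wholly outside the grid",
             cx, cy, region$radius_mm)
  if (!all(inside)) {
    keep <- array(rep(inside, each = d[1]), dim = d)
    ints[!keep] <- 0L
  }
  set_intensities(vol, ints)
}

#' Clear the specular reflection artifact
#'
#' Zeroes a constant-size axial slab of columns `|x - center| <= half_width`
#' in every B-scan. With `band = NULL` the band is auto-detected as the
#' largest contiguous group of columns whose maximum intensity saturates
#' (>= the 99.5th percentile of the volume) in at least 80% of B-scans; when
#' no saturated band exists the volume is returned unchanged with a warning.
#' Idempotent.
#'
#' @param vol An [oct_volume()].
#' @param band `c(column_center, half_width_px)` (0-based centre) or `NULL`.
#' @return `list(volume, band)`; `band` is `NULL` when nothing was cleared.
#' @export
remove_specular <- function(vol, band = NULL) {
  stopifnot(inherits(vol, "oct_volume"))
  ints <- vol$intensities
  d <- dim(ints)
  if (is.null(band)) {
    sat <- quantile(ints[ints > 0], 0.995)
    peak <- apply(ints, c(2, 3), max)          # nx x ny column maxima
    frac_sat <- rowMeans(peak >= sat)
    cand <- frac_sat >= 0.8
    if (!any(cand)) {
      warn_ovm("no saturated column band detected; volume left unchanged")
      return(list(volume = vol, band = NULL))
    }
    runs <- rle(cand)
    ends <- cumsum(runs$lengths)
    starts <- ends - runs$lengths + 1L
    k <- which(runs$values)[which.max(runs$lengths[runs$values])]
    lo <- starts[k]; hi <- ends[k]
    if (hi - lo + 1L > d[2] / 2) {
      # a "stripe" spanning most of the field is not a specular artifact
      # (e.g. a flat saturated volume); refuse to clear it
      warn_ovm("no saturated column band detected; volume left unchanged")
      return(list(volume = vol, band = NULL))
    }
    band <- c((lo + hi - 2L) %/% 2L, (hi - lo) %/% 2L)
  }
  ctr <- as.integer(band[1]); hw <- as.integer(band[2])
  if (ctr - hw < 0L || ctr + hw > d[2] - 1L)
    stop_ovm("specular band [%d, %d] outside the A-scan range [0, %d]",
             ctr - hw, ctr + hw, d[2] - 1L)
  ints[, (ctr - hw + 1L):(ctr + hw + 1L), ] <- 0L
  list(volume = set_intensities(vol, ints), band = c(ctr, hw))
}

#' Detect the anterior (and posterior) corneal surface
#'
#' Binarizes the volume at `t_surface`, keeps only the largest 3D connected
#' component (the automated replacement for manual 3D-viewer cleanup of
#' residual reflections), and takes per A-scan the first and last axial
#' indices of that component. Both maps are smoothed with a 5x5 median
#' filter. A-scans with no suprathreshold voxel in the component are marked
#' invalid; if fewer than half of the candidate A-scans (those with any
#' nonzero signal) yield a surface, detection fails.
#'
#' @param vol An [oct_volume()].
#' @param t_surface Intensity threshold; typically the button threshold.
#' @param median_window Odd window size of the surface smoothing filter.
#' @param bridge_px Lateral dilation radius used only for connectivity, so
#'   that the column gap left by specular clearing does not split the cornea
#'   into two components; the mask itself is untouched.
#' @return A `surface_map`: `anterior`, `posterior` (0-based axial indices,
#'   NA where invalid) and `valid_mask`, all `ascans x bscans`.
#' @export
detect_surface <- function(vol, t_surface, median_window = 5L, bridge_px = 8L) {
  stopifnot(inherits(vol, "oct_volume"), is_scalar_num(t_surface))
  ints <- vol$intensities
  d <- dim(ints)
  if (t_surface > max(ints))
    stop_ovm("surface not found: threshold %g exceeds the volume maximum %g",
             t_surface, max(ints))
  binary <- ints >= t_surface
  comp <- binary & largest_component(dilate_x(binary, bridge_px))
  if (!any(comp)) stop_ovm("surface not found: nothing above threshold %g", t_surface)
  m <- matrix(comp, nrow = d[1])
  first <- rep(NA_real_, ncol(m))
  last <- rep(NA_real_, ncol(m))
  hit <- colSums(m) > 0L
  first[hit] <- apply(m[, hit, drop = FALSE], 2, function(cc) which(cc)[1]) - 1
  last[hit] <- d[1] - apply(m[d[1]:1, hit, drop = FALSE], 2,
                            function(cc) which(cc)[1])
  anterior <- matrix(first, d[2], d[3])
  posterior <- matrix(last, d[2], d[3])
  candidates <- matrix(colSums(matrix(ints, nrow = d[1]) > 0) > 0L, d[2], d[3])
  valid <- !is.na(anterior)
  if (sum(valid) < 0.5 * max(1L, sum(candidates)))
    stop_ovm("surface not found: only %d of %d candidate A-scans crossed threshold %g",
             sum(valid), sum(candidates), t_surface)
  anterior <- median_filter2(anterior, median_window)
  posterior <- median_filter2(posterior, median_window)
  anterior[!valid] <- NA_real_
  posterior[!valid] <- NA_real_
  structure(list(anterior = anterior, posterior = posterior, valid_mask = valid),
            class = "surface_map")
}

#' @export
print.surface_map <- function(x, ...) {
  cat(sprintf("<surface_map> %d x %d A-scans, %.1f%% valid\n",
              nrow(x$anterior), ncol(x$anterior), 100 * mean(x$valid_mask)))
  if (any(x$valid_mask))
    cat(sprintf("  anterior depth range: [%g, %g] px\n",
                min(x$anterior, na.rm = TRUE), max(x$anterior, na.rm = TRUE)))
  invisible(x)
}

# binary dilation along the x (A-scan) axis by radius b
dilate_x <- function(mask, b) {
  d <- dim(mask)
  b <- min(b, d[2] - 1L)
  if (b <= 0L) return(mask)
  out <- mask
  for (s in seq_len(b)) {
    out[, 1:(d[2] - s), ] <- out[, 1:(d[2] - s), ] | mask[, (1 + s):d[2], ]
    out[, (1 + s):d[2], ] <- out[, (1 + s):d[2], ] | mask[, 1:(d[2] - s), ]
  }
  out
}

# Despiking 2D median filter with odd square window: an entry is replaced by
# its window median only when it deviates from it by more than max_dev (a
# residual-reflection spike). Plain smoothing would bias a curved, terraced
# surface by +-1 voxel; despiking leaves accurate detections untouched, so
# flattening onto the detected surface is exact by construction. Entries
# whose window is incomplete (valid-region or grid boundary) are kept raw.
median_filter2 <- function(m, window = 5L, max_dev = 2) {
  stopifnot(window %% 2L == 1L)
  if (window == 1L) return(m)
  h <- (window - 1L) %/% 2L
  nr <- nrow(m); nc <- ncol(m)
  stack <- array(NA_real_, dim = c(nr, nc, window^2))
  k <- 0L
  for (dy in -h:h) for (dx in -h:h) {
    k <- k + 1L
    src_r <- max(1, 1 - dx):min(nr, nr - dx)
    src_c <- max(1, 1 - dy):min(nc, nc - dy)
    stack[src_r + dx, src_c + dy, k] <- m[src_r, src_c]
  }
  complete <- apply(stack, c(1, 2), function(v) !anyNA(v))
  out <- m
  if (any(complete)) {
    med <- apply(stack, c(1, 2), median, na.rm = TRUE)
    spike <- complete & !is.na(m) & abs(m - med) > max_dev
    out[spike] <- med[spike]
  }
  out
}

#' Flatten a volume onto its anterior surface
#'
#' Shifts each A-scan axially by `ref_row - anterior(x, y)` with zero-fill,
#' so the detected anterior surface comes to lie on the single reference row
#' and corneal layers align horizontally. Invalid A-scans are left untouched.
#' Integer shifts only: intensity histograms, and therefore threshold
#' semantics, are preserved exactly up to voxels shifted off-grid.
#'
#' @param vol An [oct_volume()].
#' @param surface A [detect_surface()] result.
#' @param ref_row Target 0-based axial index of the surface.
#' @return The flattened [oct_volume()].
#' @export
flatten_volume <- function(vol, surface, ref_row = 40L) {
  stopifnot(inherits(vol, "oct_volume"), inherits(surface, "surface_map"))
  d <- dim(vol$intensities)
  ref_row <- as.integer(ref_row)
  if (ref_row < 0L || ref_row > d[1] - 1L)
    stop_ovm("ref_row %d outside the axial range [0, %d]", ref_row, d[1] - 1L)
  shift <- ref_row - round(as.vector(surface$anterior))   # per column
  m <- matrix(vol$intensities, nrow = d[1])
  out <- m
  for (s in unique(shift[!is.na(shift) & shift != 0])) {
    cols <- which(!is.na(shift) & shift == s)
    block <- matrix(0L, d[1], length(cols))
    if (s > 0) {
      if (s < d[1]) block[(1L + s):d[1], ] <- m[1L:(d[1] - s), cols]
    } else {
      if (-s < d[1]) block[1L:(d[1] + s), ] <- m[(1L - s):d[1], cols]
    }
    out[, cols] <- block
  }
  dim(out) <- d
  set_intensities(vol, out)
}

#' Trim to the anterior corneal fraction
#'
#' Zeroes all voxels deeper than `ref_row + fraction * thickness`, where the
#' thickness is the median anterior-to-posterior distance of the detected
#' surfaces. On a flattened volume this removes everything posterior to the
#' anterior stromal field -- iris and lens clutter in particular, which lies
#' below the trim plane once the cornea is flat. Restricting analysis to the
#' anterior fraction (default 2/3) also avoids the axial signal falloff that
#' would destabilize fixed thresholds.
#'
#' @param vol A flattened [oct_volume()].
#' @param surface The [detect_surface()] result used for flattening.
#' @param fraction Anterior fraction retained, in (0, 1].
#' @param ref_row The flattening reference row (0-based).
#' @param fallback_depth_px Fixed trim depth below `ref_row` used (with a
#'   warning) when no posterior surface is available.
#' @return `list(volume, trim_plane)` with `trim_plane` the last retained
#'   0-based axial index.
#' @export
trim_anterior_fraction <- function(vol, surface, fraction = 2 / 3,
                                   ref_row = 40L, fallback_depth_px = NULL) {
  stopifnot(inherits(vol, "oct_volume"), inherits(surface, "surface_map"))
  if (!is_scalar_num(fraction) || fraction <= 0 || fraction > 1)
    stop_ovm("fraction must be in (0, 1]")
  d <- dim(vol$intensities)
  thick <- surface$posterior - surface$anterior
  if (all(is.na(thick))) {
    if (is.null(fallback_depth_px))
      stop_ovm("corneal thickness undeterminable and no fallback_depth_px configured")
    warn_ovm("corneal thickness undeterminable; trimming at fixed depth %d px below ref_row",
             as.integer(fallback_depth_px))
    plane <- as.integer(ref_row + fallback_depth_px)
  } else {
    plane <- as.integer(ref_row + round(fraction * median(thick, na.rm = TRUE)))
  }
  plane <- min(plane, d[1] - 1L)
  ints <- vol$intensities
  if (plane < d[1] - 1L) ints[(plane + 2L):d[1], , ] <- 0L
  list(volume = set_intensities(vol, ints), trim_plane = plane)
}

# Otsu threshold of nonzero intensities; provisional surface threshold used
# while calibrating, before a button threshold exists
otsu_threshold <- function(ints) {
  v <- ints[ints > 0]
  breaks <- 0:ceiling(max(v))
  h <- tabulate(findInterval(v, breaks), nbins = length(breaks))
  p <- h / sum(h)
  omega <- cumsum(p)
  mu <- cumsum(p * seq_along(p))
  mu_t <- mu[length(mu)]
  sigma_b <- (mu_t * omega - mu)^2 / (omega * (1 - omega))
  sigma_b[!is.finite(sigma_b)] <- 0
  breaks[which.max(sigma_b)]
}
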