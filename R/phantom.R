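#' Phantom specification for synthetic OCT corneal volumes
#'
#' Describes the rendered geometry and artifact content of a synthetic
#' cornea: a spherical-cap anterior surface over a hyporeflective background,
#' a hyperreflective stromal shell of fixed surface-referenced thickness,
#' multiplicative speckle, exponential axial signal falloff, a saturated
#' specular stripe, per-B-scan axial jitter (heartbeat/respiration), optional
#' posterior iris/lens clutter, and an optional ellipsoidal scar of known
#' voxel volume. The defaults give a 256 x 200 x 40 desk-scale grid; the
#' acquisition-scale 1024 x 1000 x 100 geometry is available via
#' `grid_dims = c(1024, 1000, 100)`.
#'
#' The scar ellipsoid lives in the surface-referenced frame: its axial
#' coordinate is depth below the local anterior surface, so the inclusion
#' follows the stromal lamellae and its voxel count equals the continuous
#' ellipsoid volume \eqn{4/3 \pi abc} up to voxelization.
#'
#' @param grid_dims Integer triple `(depth_px, ascans_px, bscans_px)`.
#' @param lateral_extent_mm Scan width in mm (square field, default 4).
#' @param axial_spacing_um Axial voxel size in micrometres.
#' @param apex_depth_px Axial index (0-based) of the corneal apex.
#' @param curvature_radius_mm Anterior-surface sphere radius.
#' @param thickness_um Stromal thickness (surface-referenced, constant).
#' @param background_level,stroma_level Mean rendered intensities (0-255).
#' @param speckle_sd Log-scale SD of the multiplicative lognormal speckle.
#' @param falloff_per_px Exponential axial decay rate of the signal.
#' @param specular `list(column_center, half_width_px, intensity)` or `NULL`.
#'   `column_center` is a 0-based A-scan index; default is the central column.
#' @param jitter_amplitude_px Maximum absolute per-B-scan axial shift.
#' @param scar `list(center_x, center_y, depth_px, semi_axes_px,
#'   intensity_offset)` or `NULL`. `center_x`/`center_y` are 0-based voxel
#'   offsets from the grid centre, `depth_px` the ellipsoid centre's depth
#'   below the anterior surface, `semi_axes_px` the `(x, y, depth)` semi-axes
#'   in voxels. See [scar_for_fraction()] for sizing a scar to a target
#'   opacity fraction.
#' @param posterior_clutter Render iris/lens slabs posterior to the cornea.
#' @param clutter_level Base intensity of the clutter slab.
#' @param bit_depth 8 (default) or 16.
#' @param seed RNG seed making the phantom reproducible.
#'
#' @return A validated `phantom_spec`.
#' @export
phantom_spec <- function(grid_dims = c(256L, 200L, 40L),
                         lateral_extent_mm = 4.0,
                         axial_spacing_um = 2.0,
                         apex_depth_px = 30L,
                         curvature_radius_mm = 7.0,
                         thickness_um = 110,
                         background_level = 20,
                         stroma_level = 110,
                         speckle_sd = 0.10,
                         falloff_per_px = 0.002,
                         specular = list(column_center = NULL, half_width_px = 3L,
                                         intensity = 255),
                         jitter_amplitude_px = 6L,
                         scar = NULL,
                         posterior_clutter = TRUE,
                         clutter_level = 180,
                         bit_depth = 8L,
                         seed = 1L) {
  spec <- structure(
    list(grid_dims = as.integer(grid_dims),
         lateral_extent_mm = lateral_extent_mm,
         axial_spacing_um = axial_spacing_um,
         apex_depth_px = as.integer(apex_depth_px),
         curvature_radius_mm = curvature_radius_mm,
         thickness_um = thickness_um,
         background_level = background_level,
         stroma_level = stroma_level,
         speckle_sd = speckle_sd,
         falloff_per_px = falloff_per_px,
         specular = specular,
         jitter_amplitude_px = as.integer(jitter_amplitude_px),
         scar = scar,
         posterior_clutter = isTRUE(posterior_clutter),
         clutter_level = clutter_level,
         bit_depth = as.integer(bit_depth),
         seed = as.integer(seed)),
    class = "phantom_spec")
  validate_phantom_spec(spec)
  spec
}

# derived geometry shared by generator and truth computation
phantom_geometry <- function(spec) {
  nz <- spec$grid_dims[1]; nx <- spec$grid_dims[2]; ny <- spec$grid_dims[3]
  sx <- spec$lateral_extent_mm / nx       # mm per A-scan
  sy <- spec$lateral_extent_mm / ny       # mm per B-scan
  thickness_px <- max(1L, round(spec$thickness_um / spec$axial_spacing_um))
  # lateral coordinates, mm, centred on the grid
  xs <- (seq_len(nx) - (nx + 1) / 2) * sx
  ys <- (seq_len(ny) - (ny + 1) / 2) * sy
  r2 <- outer(xs^2, ys^2, "+")
  R <- spec$curvature_radius_mm
  sag_mm <- ifelse(r2 < R^2, R - sqrt(pmax(R^2 - r2, 0)), NA_real_)
  z_ant <- spec$apex_depth_px + round(sag_mm / (spec$axial_spacing_um * 1e-3))
  # clutter slab position: as deep as jitter headroom allows
  clutter_thick <- max(4L, round(nz / 13))
  clutter_z1 <- nz - 1L - spec$jitter_amplitude_px - 2L
  clutter_z0 <- clutter_z1 - clutter_thick + 1L
  floor_px <- if (spec$posterior_clutter) clutter_z0 - 10L else
    nz - 1L - spec$jitter_amplitude_px
  # the shell is rendered only where it fits above the floor
  valid <- !is.na(z_ant) & (z_ant + thickness_px - 1L) <= floor_px
  z_ant[!valid] <- NA_integer_
  list(nz = nz, nx = nx, ny = ny, spacing_x = sx, spacing_y = sy,
       thickness_px = thickness_px, z_ant = z_ant, valid = valid,
       clutter_z0 = clutter_z0, clutter_z1 = clutter_z1)
}

validate_phantom_spec <- function(spec) {
  d <- spec$grid_dims
  if (length(d) != 3L || any(d <= 0L))
    stop_ovm("grid_dims must be three positive integers")
  for (nm in c("lateral_extent_mm", "axial_spacing_um", "curvature_radius_mm",
               "thickness_um"))
    if (!is_scalar_num(spec[[nm]]) || spec[[nm]] <= 0)
      stop_ovm("%s must be > 0", nm)
  limit <- 2^spec$bit_depth - 1
  if (!spec$bit_depth %in% c(8L, 16L)) stop_ovm("bit_depth must be 8 or 16")
  for (nm in c("background_level", "stroma_level", "clutter_level"))
    if (spec[[nm]] < 0 || spec[[nm]] > limit)
      stop_ovm("%s = %g outside the representable range [0, %d]",
               nm, spec[[nm]], limit)
  if (spec$speckle_sd < 0) stop_ovm("speckle_sd must be >= 0")
  if (spec$falloff_per_px < 0) stop_ovm("falloff_per_px must be >= 0")
  if (spec$jitter_amplitude_px < 0) stop_ovm("jitter_amplitude_px must be >= 0")
  g <- phantom_geometry(spec)
  if (spec$apex_depth_px - spec$jitter_amplitude_px < 0L)
    stop_ovm("apex_depth_px (%d) minus jitter amplitude (%d) must stay >= 0",
             spec$apex_depth_px, spec$jitter_amplitude_px)
  apex_post <- spec$apex_depth_px + g$thickness_px - 1L
  if (apex_post + spec$jitter_amplitude_px > g$nz - 1L)
    stop_ovm("apex at %d px plus thickness %d px plus jitter %d px exceeds the %d px grid depth",
             spec$apex_depth_px, g$thickness_px, spec$jitter_amplitude_px, g$nz)
  if (!any(g$valid))
    stop_ovm("no A-scan fits the corneal shell inside the grid; flatten the curvature, reduce apex_depth_px or thickness_um, or deepen the grid")
  if (!is.null(spec$specular)) {
    ctr <- spec$specular$column_center %||% ((g$nx - 1L) %/% 2L)
    hw <- spec$specular$half_width_px
    if (ctr - hw < 0L || ctr + hw > g$nx - 1L)
      stop_ovm("specular band [%d, %d] falls outside the A-scan range [0, %d]",
               ctr - hw, ctr + hw, g$nx - 1L)
  }
  if (!is.null(spec$scar)) validate_scar(spec, g)
  invisible(spec)
}

validate_scar <- function(spec, g = phantom_geometry(spec)) {
  s <- spec$scar
  need <- c("center_x", "center_y", "depth_px", "semi_axes_px", "intensity_offset")
  if (!all(need %in% names(s)))
    stop_ovm("scar must provide fields: %s", paste(need, collapse = ", "))
  ax <- s$semi_axes_px
  if (length(ax) != 3L || any(ax <= 0))
    stop_ovm("scar semi_axes_px must be three positive values (x, y, depth)")
  if (s$depth_px - ax[3] < 0 || s$depth_px + ax[3] > g$thickness_px - 1L)
    stop_ovm("scar depth range [%g, %g] exceeds the stromal thickness of %d px",
             s$depth_px - ax[3], s$depth_px + ax[3], g$thickness_px)
  # every column the ellipsoid touches must carry a rendered shell
  cx <- (g$nx + 1) / 2 + s$center_x
  cy <- (g$ny + 1) / 2 + s$center_y
  xr <- range(pmax(1, floor(cx - ax[1])), pmin(g$nx, ceiling(cx + ax[1])))
  yr <- range(pmax(1, floor(cy - ax[2])), pmin(g$ny, ceiling(cy + ax[2])))
  if (cx - ax[1] < 1 || cx + ax[1] > g$nx || cy - ax[2] < 1 || cy + ax[2] > g$ny)
    stop_ovm("scar ellipsoid extends laterally outside the grid")
  xi <- xr[1]:xr[2]; yi <- yr[1]:yr[2]
  q <- outer(((xi - cx) / ax[1])^2, ((yi - cy) / ax[2])^2, "+")
  inside <- q <= 1
  if (any(inside & !g$valid[xi, yi, drop = FALSE]))
    stop_ovm("scar ellipsoid extends over A-scans with no rendered corneal shell; shrink or recentre it")
  invisible(spec)
}

#' @export
print.phantom_spec <- function(x, ...) {
  g <- phantom_geometry(x)
  cat(sprintf("<phantom_spec> %d x %d x %d grid, %.3g um axial / %.3g mm lateral extent\n",
              g$nz, g$nx, g$ny, x$axial_spacing_um, x$lateral_extent_mm))
  cat(sprintf("  cornea: R = %g mm, apex at %d px, thickness %d px; %0.1f%% of A-scans carry shell\n",
              x$curvature_radius_mm, x$apex_depth_px, g$thickness_px,
              100 * mean(g$valid)))
  cat(sprintf("  scar  : %s\n", if (is.null(x$scar)) "none" else
    sprintf("semi-axes (%g, %g, %g) px, offset +%g", x$scar$semi_axes_px[1],
            x$scar$semi_axes_px[2], x$scar$semi_axes_px[3], x$scar$intensity_offset)))
  cat(sprintf("  noise : speckle sd %g, falloff %g / px, jitter <= %d px, clutter %s\n",
              x$speckle_sd, x$falloff_per_px, x$jitter_amplitude_px,
              if (x$posterior_clutter) "on" else "off"))
  invisible(x)
}

# linear indices of the shell voxels for columns given by z-start vector
shell_indices <- function(cols, z_start, depth_count, nz) {
  base <- (cols - 1L) * nz + z_start   # 1-based z start index
  rep(base, each = depth_count) + rep.int(0L:(depth_count - 1L), length(base))
}

#' Generate a synthetic OCT corneal phantom with ground truth
#'
#' Renders the geometry described by a [phantom_spec()] and returns both the
#' volume and the analytically known truth. Truth masks are computed from the
#' geometry before any noise is applied, then shifted rigidly with the
#' injected per-B-scan jitter so they always describe the rendered volume.
#' The specular stripe is overlaid after jitter (it is a scanner-frame
#' artifact); posterior clutter is rendered before jitter so that it moves
#' with the eye, as bulk heartbeat/respiration motion does.
#'
#' @param spec A [phantom_spec()].
#' @return A list with elements `volume` (an [oct_volume()]) and `truth`, a
#'   `phantom_truth` with fields `cornea_mask`, `scar_mask`, `clutter_mask`,
#'   `true_percent_opacity`, `applied_shifts`, `anterior_surface_true`,
#'   `posterior_surface_true` (0-based axial indices, NA where no shell) and
#'   `thickness_px`.
#' @export
generate_phantom <- function(spec) {
  validate_phantom_spec(spec)
  g <- phantom_geometry(spec)
  nz <- g$nz; nx <- g$nx; ny <- g$ny
  n_col <- nx * ny

  cornea <- array(FALSE, dim = c(nz, nx, ny))
  valid_cols <- which(g$valid)                       # column-major over (x, y)
  z_start <- g$z_ant[valid_cols] + 1L                # 1-based array index
  cornea[shell_indices(valid_cols, z_start, g$thickness_px, nz)] <- TRUE

  scar <- array(FALSE, dim = c(nz, nx, ny))
  if (!is.null(spec$scar)) {
    s <- spec$scar
    ax <- s$semi_axes_px
    cx <- (nx + 1) / 2 + s$center_x
    cy <- (ny + 1) / 2 + s$center_y
    q <- outer(((seq_len(nx) - cx) / ax[1])^2, ((seq_len(ny) - cy) / ax[2])^2, "+")
    hit <- which(q <= 1 & g$valid)
    if (length(hit)) {
      h <- ax[3] * sqrt(1 - q[hit])
      dlo <- pmax(0L, as.integer(ceiling(s$depth_px - h)))
      dhi <- pmin(g$thickness_px - 1L, as.integer(floor(s$depth_px + h)))
      keep <- dhi >= dlo
      if (any(keep)) {
        counts <- (dhi - dlo + 1L)[keep]
        base <- (hit[keep] - 1L) * nz + g$z_ant[hit[keep]] + dlo[keep] + 1L
        idx <- rep(base, counts) + sequence(counts) - 1L
        scar[idx] <- TRUE
      }
    }
  }

  clutter <- array(FALSE, dim = c(nz, nx, ny))
  if (spec$posterior_clutter)
    clutter[(g$clutter_z0 + 1L):(g$clutter_z1 + 1L), , ] <- TRUE

  base <- array(spec$background_level, dim = c(nz, nx, ny))
  base[clutter] <- spec$clutter_level
  base[cornea] <- spec$stroma_level
  if (!is.null(spec$scar)) base[scar] <- spec$stroma_level + spec$scar$intensity_offset

  falloff <- exp(-spec$falloff_per_px * (seq_len(nz) - 1L))
  base <- base * falloff                              # recycles along z

  vol_truth <- with_seed(spec$seed, {
    if (spec$speckle_sd > 0) {
      noise <- rlnorm(length(base), meanlog = -spec$speckle_sd^2 / 2,
                      sdlog = spec$speckle_sd)
      base <- base * noise
    }
    shifts <- integer(ny)
    if (spec$jitter_amplitude_px > 0L && ny >= 2L) {
      walk <- cumsum(rnorm(ny))
      sm <- stats::filter(c(rep(walk[1], 2), walk, rep(walk[ny], 2)),
                          rep(1 / 5, 5), sides = 2)
      sm <- as.numeric(sm)[3:(ny + 2)]
      sm <- sm - sm[1]
      if (max(abs(sm)) > 0)
        shifts <- as.integer(round(sm / max(abs(sm)) * spec$jitter_amplitude_px))
    }
    list(vol = base, shifts = shifts)
  })
  base <- vol_truth$vol
  shifts <- vol_truth$shifts

  z_ant_shift <- g$z_ant
  if (any(shifts != 0L)) {
    for (y in seq_len(ny)) {
      s <- shifts[y]
      if (s == 0L) next
      base[, , y] <- shift_plane(base[, , y], s, fill = 0)
      cornea[, , y] <- shift_plane(cornea[, , y], s, fill = FALSE)
      scar[, , y] <- shift_plane(scar[, , y], s, fill = FALSE)
      clutter[, , y] <- shift_plane(clutter[, , y], s, fill = FALSE)
    }
    z_ant_shift <- g$z_ant + matrix(shifts, nrow = nx, ncol = ny, byrow = TRUE)
    z_ant_shift[!g$valid] <- NA_integer_
  }

  if (!is.null(spec$specular)) {
    ctr <- spec$specular$column_center %||% ((nx - 1L) %/% 2L)
    hw <- spec$specular$half_width_px
    base[, (ctr - hw + 1L):(ctr + hw + 1L), ] <- spec$specular$intensity
  }

  limit <- 2^spec$bit_depth - 1
  ints <- round(pmin(pmax(base, 0), limit))
  storage.mode(ints) <- "integer"

  volume <- oct_volume(ints,
                       axial_spacing_um = spec$axial_spacing_um,
                       lateral_spacing_mm_x = g$spacing_x,
                       lateral_spacing_mm_y = g$spacing_y,
                       eye_id = sprintf("phantom-seed%d", spec$seed))
  truth <- structure(
    list(cornea_mask = cornea,
         scar_mask = scar,
         clutter_mask = clutter,
         true_percent_opacity = if (sum(cornea)) 100 * sum(scar) / sum(cornea) else 0,
         applied_shifts = shifts,
         anterior_surface_true = z_ant_shift,
         posterior_surface_true = z_ant_shift + g$thickness_px - 1L,
         thickness_px = g$thickness_px,
         spec = spec),
    class = "phantom_truth")
  list(volume = volume, truth = truth)
}

# shift a (z, x) plane axially by s voxels (positive = deeper), zero-fill
shift_plane <- function(m, s, fill = 0) {
  nz <- nrow(m)
  out <- matrix(fill, nz, ncol(m))
  if (s >= 0) {
    if (s < nz) out[(1L + s):nz, ] <- m[1L:(nz - s), ]
  } else {
    if (-s < nz) out[1L:(nz + s), ] <- m[(1L - s):nz, ]
  }
  out
}

#' @export
print.phantom_truth <- function(x, ...) {
  cat(sprintf("<phantom_truth> %d cornea voxels, %d scar voxels (%.2f%% opacity)\n",
              sum(x$cornea_mask), sum(x$scar_mask), x$true_percent_opacity))
  cat(sprintf("  jitter: %d B-scans, shifts in [%d, %d] px\n",
              length(x$applied_shifts), min(x$applied_shifts), max(x$applied_shifts)))
  invisible(x)
}

#' Size a scar ellipsoid for a target opacity fraction
#'
#' Chooses semi-axes so that the scar occupies `fraction` percent of the
#' anterior analysis field of the phantom's cornea (the anterior
#' `anterior_fraction` of the stroma, the field the measurement pipeline
#' analyzes). The ellipsoid is laterally isotropic in millimetres and is kept
#' anterior so that the standard trim retains it fully.
#'
#' @param spec A scar-free [phantom_spec()].
#' @param fraction Target opacity, percent of the anterior corneal field.
#' @param anterior_fraction Anterior fraction defining the analysis field.
#' @param depth_px Ellipsoid centre depth below the anterior surface;
#'   default one quarter of the stromal thickness.
#' @param center_x,center_y Lateral centre, voxels from the grid centre;
#'   `center_x = NULL` offsets the scar by 7.5% of the A-scan range so it
#'   clears the apex specular stripe at small sizes.
#' @param intensity_offset Added intensity above `stroma_level`.
#' @return The `scar` list to place into [phantom_spec()].
#' @export
scar_for_fraction <- function(spec, fraction, anterior_fraction = 2 / 3,
                              depth_px = NULL, center_x = NULL, center_y = 0,
                              intensity_offset = 80) {
  stopifnot(is_scalar_num(fraction), fraction > 0, fraction < 100)
  g <- phantom_geometry(spec)
  if (is.null(center_x)) center_x <- round(0.075 * g$nx)
  field_depth <- min(g$thickness_px, round(anterior_fraction * g$thickness_px) + 1L)
  field_voxels <- sum(g$valid) * field_depth
  abc <- fraction / 100 * field_voxels * 3 / (4 * pi)
  c_ax <- max(4, round(g$thickness_px / 4))
  if (is.null(depth_px)) depth_px <- c_ax + 2
  aniso <- g$spacing_y / g$spacing_x     # a : b ratio for mm-isotropy
  b_ax <- sqrt(abc / (c_ax * aniso))
  a_ax <- aniso * b_ax
  scar <- list(center_x = center_x, center_y = center_y, depth_px = depth_px,
               semi_axes_px = c(a_ax, b_ax, c_ax),
               intensity_offset = intensity_offset)
  spec$scar <- scar
  ok <- tryCatch({ validate_scar(spec); TRUE }, error = function(e) e)
  if (!isTRUE(ok) && center_x != 0) {
    # large scars may not fit off-centre on small grids; recentre on the apex
    scar$center_x <- 0
    spec$scar <- scar
    validate_scar(spec)
  } else if (!isTRUE(ok)) {
    stop(ok)
  }
  scar
}

#' Generate a cohort of scar-free phantoms
#'
#' Per-volume seeds are derived deterministically from `seed`, so cohorts are
#' reproducible while individual volumes carry independent noise over
#' identical geometry. Used to calibrate the dual thresholds the way normal
#' and naive clear corneas calibrate them on real scans.
#'
#' @param n Number of volumes (>= 1).
#' @param base_spec A scar-free [phantom_spec()].
#' @param seed Cohort seed.
#' @return List of `n` [oct_volume()] objects.
#' @export
generate_naive_cohort <- function(n, base_spec, seed = base_spec$seed) {
  if (!is_count(n)) stop_ovm("cohort size n must be a positive integer (got %s)",
                             deparse(substitute(n)))
  if (!is.null(base_spec$scar))
    stop_ovm("base_spec for a naive cohort must be scar-free")
  lapply(seq_len(n), function(i) {
    s <- base_spec
    s$seed <- as.integer(derive_seed(seed, i))
    out <- generate_phantom(s)$volume
    out$eye_id <- sprintf("naive-%03d", i)
    out
  })
}
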