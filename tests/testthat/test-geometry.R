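test_that("registration negates injected jitter exactly", {
  for (seed in c(3, 4, 5)) {
    ph <- generate_phantom(tiny_spec(seed = seed))
    reg <- register_bscans(ph$volume, jitter_window_px = 8)
    expect_identical(reg$shifts, -ph$truth$applied_shifts)
    # second pass is the identity: all-zero corrections
    expect_true(all(register_bscans(reg$volume, jitter_window_px = 8)$shifts == 0L))
  }
})

test_that("registration is relative and handles degenerate profiles", {
  ph <- generate_phantom(tiny_spec(seed = 6, jitter_amplitude_px = 0L))
  expect_true(all(register_bscans(ph$volume)$shifts == 0L))

  # constant global offset: all B-scans displaced together, no relative motion
  shifted <- ph$volume
  d <- dim(shifted$intensities)
  moved <- array(0L, d)
  moved[4:d[1], , ] <- ph$volume$intensities[1:(d[1] - 3), , ]
  shifted$intensities <- moved
  expect_true(all(register_bscans(shifted)$shifts == 0L))

  flat <- oct_volume(array(7L, dim = c(16, 8, 2)))
  expect_warning(reg <- register_bscans(flat), "flat B-scan profile")
  expect_true(all(reg$shifts == 0L))
})

test_that("button crop converts units and clears outside the cylinder", {
  a <- array(10L, dim = c(16, 200, 40))
  v <- oct_volume(a, lateral_spacing_mm_x = 0.02, lateral_spacing_mm_y = 0.1)

  # radius larger than the whole field: unchanged
  big <- crop_button(v, button_region(center_x = 100, center_y = 20,
                                      radius_mm = 50))
  expect_identical(big$intensities, v$intensities)

  # 1 mm at 0.02 mm/voxel = 50 voxels of x-radius on the centre B-scan row
  cr <- crop_button(v, button_region(center_x = 100, center_y = 20,
                                     radius_mm = 1.0))
  row_cols <- which(cr$intensities[1, , 21] > 0)
  expect_equal(range(row_cols), c(101 - 50, 101 + 50))

  # voxel count close to the analytic cylinder volume
  va <- oct_volume(array(1L, dim = c(16, 200, 200)),
                   lateral_spacing_mm_x = 0.02, lateral_spacing_mm_y = 0.02)
  cr2 <- crop_button(va, button_region(center_x = 100, center_y = 100,
                                       radius_mm = 0.8))
  analytic <- pi * 40^2 * 16   # radius 40 voxels, 16 rows
  expect_lt(abs(sum(cr2$intensities > 0) - analytic) / analytic, 0.02)

  expect_error(crop_button(v, button_region(center_x = 2000, center_y = 20,
                                            radius_mm = 0.5)),
               "wholly outside")
})

test_that("specular clearing is idempotent and auto-detects the stripe", {
  ph <- generate_phantom(tiny_spec(seed = 9))
  auto <- remove_specular(ph$volume)
  # the injected stripe (half-width 1) sits at the central columns
  ctr <- (dim(ph$volume)[2] - 1L) %/% 2L
  expect_true(auto$band[1] - auto$band[2] <= ctr - 1 &&
                auto$band[1] + auto$band[2] >= ctr + 1)
  twice <- remove_specular(auto$volume, auto$band)
  expect_identical(twice$volume$intensities, auto$volume$intensities)

  # half-width 0 clears a single column
  v <- oct_volume(array(5L, dim = c(16, 10, 3)))
  one <- remove_specular(v, band = c(4, 0))
  expect_true(all(one$volume$intensities[, 5, ] == 0L))
  expect_true(all(one$volume$intensities[, -5, ] == 5L))

  expect_warning(none <- remove_specular(v), "no saturated column band")
  expect_identical(none$volume$intensities, v$intensities)
  expect_error(remove_specular(v, band = c(9, 3)), "outside the A-scan range")
})

test_that("surface detection matches the analytic spherical cap", {
  ph <- generate_phantom(tiny_spec(seed = 10))
  reg <- register_bscans(ph$volume)
  sp <- remove_specular(crop_button(reg$volume, button_region(radius_mm = 1.3)))
  surf <- detect_surface(sp$volume, tiny_model()$t_button)
  d <- dim(ph$volume)
  ant_true <- ph$truth$anterior_surface_true -
    matrix(ph$truth$applied_shifts, d[2], d[3], byrow = TRUE)
  both <- !is.na(surf$anterior) & !is.na(ant_true)
  expect_gt(sum(both), 0.5 * sum(!is.na(ant_true)))
  err <- surf$anterior[both] - ant_true[both]
  expect_gte(mean(abs(err) <= 1), 0.95)
  # posterior tracks the shell bottom, not the clutter slab
  post_err <- surf$posterior[both] -
    (ant_true[both] + ph$truth$thickness_px - 1L)
  expect_gte(mean(abs(post_err) <= 2), 0.95)
})

test_that("flat slabs and degenerate volumes behave at the boundaries", {
  a <- array(0L, dim = c(32, 12, 4))
  a[21:41 - 10, , ] <- 100L     # slab rows 11..31 -> 0-based depth 10..30
  v <- oct_volume(a)
  surf <- detect_surface(v, 50)
  expect_true(all(surf$anterior == 10))
  expect_true(all(surf$posterior == 30))

  bg <- oct_volume(array(3L, dim = c(16, 8, 2)))
  expect_error(detect_surface(bg, 10), "surface not found")
})

test_that("flattening aligns the surface at ref_row and conserves voxels", {
  # clutter-free phantom: every suprathreshold voxel is corneal, and the
  # reference row leaves headroom, so the count is conserved exactly
  ph <- generate_phantom(tiny_spec(seed = 12, posterior_clutter = FALSE))
  reg <- register_bscans(ph$volume)
  sp <- remove_specular(crop_button(reg$volume, button_region(radius_mm = 1.3)))
  t_b <- tiny_model()$t_button
  surf <- detect_surface(sp$volume, t_b)
  flat <- flatten_volume(sp$volume, surf, ref_row = 28)
  expect_identical(sum(flat$intensities >= t_b), sum(sp$volume$intensities >= t_b))
  re <- detect_surface(flat, t_b)
  expect_true(all(re$anterior[!is.na(re$anterior)] == 28))

  # flattening an already-flat volume onto its own surface is the identity
  slab <- array(0L, dim = c(32, 12, 4)); slab[11:31, , ] <- 100L
  sv <- oct_volume(slab)
  ssurf <- detect_surface(sv, 50)
  expect_identical(flatten_volume(sv, ssurf, ref_row = 10)$intensities,
                   sv$intensities)
  expect_error(flatten_volume(sv, ssurf, ref_row = 64), "outside the axial range")
})

test_that("anterior trim removes posterior clutter and obeys the arithmetic", {
  ph <- generate_phantom(tiny_spec(seed = 13))
  reg <- register_bscans(ph$volume)
  sp <- remove_specular(crop_button(reg$volume, button_region(radius_mm = 1.3)))
  t_b <- tiny_model()$t_button
  surf <- detect_surface(sp$volume, t_b)
  flat <- flatten_volume(sp$volume, surf, ref_row = 28)
  tr <- trim_anterior_fraction(flat, surf, 2 / 3, ref_row = 28)

  # follow the truth clutter mask through the same column shifts
  d <- dim(flat)
  clut <- matrix(ph$truth$clutter_mask, nrow = d[1])
  # clutter moved with the eye, so undo registration the way the volume did
  reg_shift <- rep(reg$shifts, each = d[2])
  col_shift <- 28 - round(as.vector(surf$anterior))
  surviving <- 0L
  for (j in which(!is.na(col_shift))) {
    z <- which(clut[, j]) + reg_shift[j] + col_shift[j]
    surviving <- surviving + sum(z >= 1 & z <= tr$trim_plane + 1)
  }
  expect_identical(surviving, 0L)
  # fraction = 1 leaves the flattened corneal band untouched
  tr_full <- trim_anterior_fraction(flat, surf, 1, ref_row = 28)
  band <- 28:(28 + ph$truth$thickness_px - 1L) + 1L
  expect_identical(tr_full$volume$intensities[band, , ], flat$intensities[band, , ])

  # plane arithmetic: thickness 60 px at fraction 2/3 -> ref_row + 40
  fake <- structure(list(anterior = matrix(10, 12, 4),
                         posterior = matrix(70, 12, 4),
                         valid_mask = matrix(TRUE, 12, 4)),
                    class = "surface_map")
  v <- oct_volume(array(1L, dim = c(80, 12, 4)))
  expect_equal(trim_anterior_fraction(v, fake, 2 / 3, ref_row = 10)$trim_plane, 50)

  # undeterminable thickness: fixed-depth fallback with warning
  nop <- structure(list(anterior = matrix(10, 12, 4),
                        posterior = matrix(NA_real_, 12, 4),
                        valid_mask = matrix(TRUE, 12, 4)),
                   class = "surface_map")
  expect_warning(fb <- trim_anterior_fraction(v, nop, 2 / 3, ref_row = 10,
                                              fallback_depth_px = 30),
                 "fixed depth")
  expect_equal(fb$trim_plane, 40)
  expect_error(trim_anterior_fraction(v, nop, 2 / 3, ref_row = 10),
               "no fallback_depth_px")
})

test_that("crop, despecular and trim commute on disjoint regions", {
  ph <- generate_phantom(tiny_spec(seed = 14))
  b <- button_region(center_x = 40, center_y = 8, radius_mm = 1.1)
  band <- c(39, 3)
  one <- remove_specular(crop_button(ph$volume, b), band)$volume
  two <- crop_button(remove_specular(ph$volume, band)$volume, b)
  expect_identical(one$intensities, two$intensities)
  # idempotence of crop
  expect_identical(crop_button(one, b)$intensities, one$intensities)
})
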