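# Water-equivalent area/diameter computations and profile metrics.

test_that("water-equivalent area is linear in mean CT number", {
  expect_equal(water_equivalent_area(0, 100), 100)     # water
  expect_equal(water_equivalent_area(-1000, 50), 0)    # air contributes nothing
  expect_equal(water_equivalent_area(-500, 200), 100)  # linear midpoint
  expect_error(water_equivalent_area(0, -1), ">= 0")
})

test_that("slice Dw matches analytic geometry for disks and ellipses", {
  for (d in c(16, 24, 32)) {
    s <- make_phantom_series(phantom_spec("disk", d, pixel_spacing = 0.8),
                             n_slices = 1L)
    expect_lt(abs(slice_dw(s$slices[[1]]) - d), 0.2)
  }
  s <- make_phantom_series(phantom_spec("ellipse", c(30, 20),
                                        pixel_spacing = 0.8), n_slices = 1L)
  expect_lt(abs(slice_dw(s$slices[[1]]) - 2 * sqrt(15 * 10)), 0.2)
})

test_that("an all-air slice has zero Dw; excess table calibration clamps", {
  air <- uniform_slice(-1000, n = 32L)
  expect_equal(slice_dw(air), 0)
  expect_warning(dw <- slice_dw(air, table_calibration(10)), "clamped")
  expect_equal(dw, 0)
})

test_that("appending pure air leaves Dw essentially unchanged", {
  small <- make_phantom_series(phantom_spec("disk", 16, pixel_spacing = 0.8,
                                            image_size = 384L), n_slices = 1L)
  big <- make_phantom_series(phantom_spec("disk", 16, pixel_spacing = 0.8,
                                          image_size = 512L), n_slices = 1L)
  expect_lt(abs(slice_dw(small$slices[[1]]) - slice_dw(big$slices[[1]])), 0.01)
})

test_that("raising HU everywhere raises Dw", {
  s <- make_phantom_series(phantom_spec("disk", 20, pixel_spacing = 0.8,
                                        image_size = 384L), n_slices = 1L)
  sl <- s$slices[[1]]
  up <- ct_slice(sl$pixels + 20, sl$pixel_spacing, sl$z_position)
  expect_gt(slice_dw(up), slice_dw(sl))
})

test_that("table calibration reproduces the table-free phantom", {
  # pure-air mask calibrates to zero
  air <- uniform_slice(-1000, n = 16L)
  mask <- matrix(TRUE, 16, 16)
  expect_equal(calibrate_table(air, mask)$aw_table, 0)
  expect_error(calibrate_table(air, mask & FALSE), "empty")

  # 100 cm^2 at -500 HU -> 50 cm^2
  strip <- uniform_slice(-500, n = 100L, spacing = 1)  # 100x100 mm
  expect_equal(calibrate_table(strip, matrix(TRUE, 100, 100))$aw_table, 50)

  # paired synthetic phantom: with-table + calibration == table-free twin
  for (noise in c(0, 10)) {
    with_t <- make_phantom_series(
      phantom_spec("disk", 24, include_table = TRUE, noise_sd = noise),
      n_slices = 1L, seed = 5L)
    without <- make_phantom_series(
      phantom_spec("disk", 24, include_table = FALSE, noise_sd = noise),
      n_slices = 1L, seed = 5L)
    cal <- calibrate_table(with_t$slices[[1]], attr(with_t, "table_mask"))
    expect_lt(abs(slice_dw(with_t$slices[[1]], cal) -
                    slice_dw(without$slices[[1]])), 0.1)
  }
})

test_that("profiles carry per-slice Dw, z and current", {
  s <- make_phantom_series(phantom_spec("disk", 24), n_slices = 10L)
  p <- dw_profile(s)
  expect_s3_class(p, "dw_profile")
  expect_length(p$dw, 10L)
  expect_lt(max(p$dw) - min(p$dw), 1e-9)       # identical slices
  p1 <- dw_profile(scan_series(s$slices[1]))
  m1 <- dw_metrics(p1)
  expect_equal(m1$dw_c, m1$dw_ave)
})

test_that("rendered anatomy series reproduces the ground-truth curve", {
  prof <- anatomy_profile("chest", 25, scan_length_mm = 60, n_slices = 7L)
  s <- profile_to_series(prof, pixel_spacing = 1, image_size = 384L,
                         noise_sd = 10, seed = 3L)
  p <- dw_profile(s)
  expect_true(all(abs(p$dw - prof$dw) <= 0.2))
  expect_lt(dw_central(p), dw_average(p))       # lung dip at mid-scan
})

test_that("mid-scan slice selection uses the z midpoint with lower-z ties", {
  expect_equal(dw_central(profile_of(c(20, 25, 30), z = c(0, 5, 10))), 25)
  # midpoint 7.5 equidistant to z = 5 and 10: lower-z slice wins
  expect_equal(dw_central(profile_of(c(20, 24, 26, 30), z = c(0, 5, 10, 15))),
               24)
  expect_equal(dw_central(profile_of(22)), 22)
})

test_that("profile metrics obey their ordering invariants", {
  expect_equal(dw_average(profile_of(c(20, 30))), 25)
  m <- dw_metrics(profile_of(c(20, 25, 30)))
  expect_equal(m$dw_range, 10)
  set.seed(42)
  for (i in 1:25) {
    p <- profile_of(runif(sample(1:40, 1), 15, 35))
    m <- dw_metrics(p)
    expect_lte(m$dw_min, m$dw_ave); expect_lte(m$dw_ave, m$dw_max)
    expect_lte(m$dw_min, m$dw_c);   expect_lte(m$dw_c, m$dw_max)
    expect_equal(m$dw_range, m$dw_max - m$dw_min)
  }
})

test_that("profile constructor validates its arrays", {
  expect_error(new_dw_profile(z = c(0, 0), dw = c(1, 2)), "strictly increasing")
  expect_error(new_dw_profile(z = c(0, 5), dw = c(1, -2)), ">= 0")
  expect_error(new_dw_profile(z = numeric(0), dw = numeric(0)), "length")
})

test_that("truncation fraction counts tissue on the border ring", {
  centered <- make_phantom_series(phantom_spec("disk", 10, pixel_spacing = 1,
                                               image_size = 128L),
                                  n_slices = 1L)
  expect_equal(truncation_fraction(centered$slices[[1]]), 0)

  # object clipped by the edge: positive fraction, equal to the direct count
  n <- 64L
  px <- matrix(-1000, n, n)
  px[, 1:20] <- 0                       # water block through the left edge
  sl <- ct_slice(px, c(1, 1), 0)
  ring <- px; ring[3:(n - 2), 3:(n - 2)] <- NA
  expect_equal(truncation_fraction(sl), mean(ring > -600, na.rm = TRUE))
  expect_gt(truncation_fraction(sl), 0)

  # water beyond the caudal edge only: about a quarter of the ring
  px2 <- matrix(-1000, n, n)
  px2[(n - 1):n, ] <- 0
  fr <- truncation_fraction(ct_slice(px2, c(1, 1), 0))
  expect_gt(fr, 0.2); expect_lt(fr, 0.3)
})
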