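# Synthetic phantoms, anatomy profiles, ATCM emulator and cohort generator.

test_that("phantom specs carry analytic ground truth and validate geometry", {
  expect_equal(phantom_spec("disk", 32)$dw_true, 32)
  expect_equal(phantom_spec("disk", 24)$dw_true, 24)
  expect_equal(phantom_spec("ellipse", c(30, 20))$dw_true, 2 * sqrt(15 * 10))
  expect_error(phantom_spec("disk", 60, image_size = 256L), "fit")
  sp <- phantom_spec("disk", 20, include_table = TRUE)
  expect_equal(sp$aw_table_true, 0.7 * 80)   # 40x2 cm strip at -300 HU
})

test_that("phantom series have the promised structure", {
  s <- make_phantom_series(phantom_spec("disk", 24), n_slices = 4L)
  expect_length(s$slices, 4L)
  expect_equal(attr(s, "dw_true"), 24)
  expect_identical(s$slices[[1]]$pixels, s$slices[[2]]$pixels)  # noise-free
  sn <- make_phantom_series(phantom_spec("disk", 24, noise_sd = 10),
                            n_slices = 2L, seed = 2L)
  expect_false(identical(sn$slices[[1]]$pixels, sn$slices[[2]]$pixels))
})

test_that("anatomy profiles meet their mean, range and mid-scan contracts", {
  for (exam in c("chest", "CAP")) {
    p <- anatomy_profile(exam, 25, scan_length_mm = if (exam == "chest")
      300 else 700)
    m <- dw_metrics(p)
    expect_lt(abs(m$dw_ave - 25), 0.05)
    expect_lt(abs(m$dw_range / m$dw_ave - 0.23), 0.01)
    if (exam == "chest") expect_lt(m$dw_c, m$dw_ave) else
      expect_gt(m$dw_c, m$dw_ave)
  }
  # nominal mid-scan offsets: about -4% (chest) and +5% (CAP) of Dw_ave
  mch <- dw_metrics(anatomy_profile("chest", 25))
  mcap <- dw_metrics(anatomy_profile("CAP", 25, scan_length_mm = 700))
  expect_equal(100 * (mch$dw_c - mch$dw_ave) / mch$dw_ave, -4, tolerance = 0.15)
  expect_equal(100 * (mcap$dw_c - mcap$dw_ave) / mcap$dw_ave, 5, tolerance = 0.15)
  # constant profile for phantoms
  expect_equal(unique(anatomy_profile("phantom", 24)$dw), 24)
})

test_that("rendered profile series are deterministic given the seed", {
  prof <- anatomy_profile("CAP", 24, scan_length_mm = 20, n_slices = 3L)
  s1 <- profile_to_series(prof, image_size = 384L, noise_sd = 10, seed = 11L)
  s2 <- profile_to_series(prof, image_size = 384L, noise_sd = 10, seed = 11L)
  expect_identical(s1$slices[[2]]$pixels, s2$slices[[2]]$pixels)
  s3 <- profile_to_series(prof, image_size = 384L, noise_sd = 10, seed = 12L)
  expect_false(identical(s1$slices[[2]]$pixels, s3$slices[[2]]$pixels))
  # per-slice analytic Dw equals the curve value
  p <- dw_profile(profile_to_series(prof, image_size = 384L))
  expect_true(all(abs(p$dw - prof$dw) < 0.1))
})

test_that("rendered series with couch match their couch-free twin", {
  prof <- anatomy_profile("chest", 24, scan_length_mm = 20, n_slices = 2L)
  with_t <- profile_to_series(prof, image_size = 384L, include_table = TRUE)
  without <- profile_to_series(prof, image_size = 384L)
  cal <- calibrate_table(with_t$slices[[1]], attr(with_t, "table_mask"))
  m1 <- dw_metrics(dw_profile(with_t, cal))
  m2 <- dw_metrics(dw_profile(without))
  expect_lt(abs(m1$dw_ave - m2$dw_ave), 0.1)
  expect_lt(abs(m1$dw_c - m2$dw_c), 0.1)
})

test_that("the ATCM emulator follows its exponential-clamp model", {
  par <- atcm_params()
  # constant profile at the reference size draws the reference current
  p_ref <- anatomy_profile("phantom", par$dw_ref)
  r <- emulate_atcm(p_ref, par)
  expect_equal(unique(r$current), par$i_ref)
  expect_equal(r$clamped_frac, 0)
  # doubling distance ln2/k doubles the dose when unclamped
  p_big <- anatomy_profile("phantom", par$dw_ref + log(2) / par$k)
  expect_equal(emulate_atcm(p_big, par)$ctdi_vol / r$ctdi_vol, 2,
               tolerance = 1e-9)
  # a very small patient pins at the Imin floor
  tiny <- emulate_atcm(anatomy_profile("phantom", 10), par)
  expect_equal(unique(tiny$current), par$imin)
  expect_equal(tiny$ctdi_vol, par$dose_const * par$imin)
})

test_that("Imin clamping flattens the dose-size response for small sizes", {
  par <- atcm_params(imin = 140)
  ctdi <- vapply(seq(16, 20, by = 1), function(dw)
    emulate_atcm(anatomy_profile("CAP", dw, scan_length_mm = 700), par)$ctdi_vol,
    0)
  expect_lt(sd_pop(ctdi) / mean(ctdi), 0.05)
})

test_that("cohorts are reproducible and respect the weight truncation", {
  cfg <- cohort_config(n_chest = 10L, n_cap = 10L, seed = 21L)
  r1 <- sample_cohort(cfg)
  r2 <- sample_cohort(cfg)
  expect_identical(r1, r2)
  big <- sample_cohort(cohort_config(n_chest = 300L, n_cap = 700L, seed = 8L))
  expect_gte(min(big$weight_kg), 43)
  expect_lte(max(big$weight_kg), 117)
  # stable membership when n grows: same substreams, same early patients
  grown <- sample_cohort(cohort_config(n_chest = 10L, n_cap = 15L, seed = 21L))
  expect_equal(grown$weight_kg[1:10], r1$weight_kg[1:10])
})

test_that("the pipeline recovers the generator's parameters", {
  rec <- default_cohort()
  # dose-model constant via log-linear fit on unclamped records
  un <- rec[rec$clamped_frac == 0, ]
  k_hat <- linear_fit(un$dwave_cm, log(un$ctdivol_mGy))$slope
  expect_lt(abs(k_hat / (log(2) / 6) - 1), 0.10)
  # image pipeline recovers each rendered exam's ground-truth Dw_ave
  cfg <- cohort_config()
  errs <- vapply(c(1L, 101L), function(i) {   # one chest, one CAP exam
    s <- render_cohort_exam(cfg, i)
    abs(dw_average(dw_profile(s)) - mean(attr(s, "dw_true")))
  }, 0)
  expect_lt(max(errs), 0.2)
})
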