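# Fits, R-squared comparisons and descriptive statistics.

test_that("BMI follows weight / height^2", {
  expect_equal(bmi(70, 167), 70 / 1.67^2)
  expect_equal(round(bmi(70, 167), 1), 25.1)
  expect_equal(bmi(100, 200), 25)
  expect_equal(round(bmi(43, 147), 1), 19.9)
  expect_error(bmi(-1, 170), "positive")
})

test_that("linear fits recover exact lines and report R-squared", {
  f <- linear_fit(1:10, 2 * (1:10) + 1)
  expect_equal(f$slope, 2)
  expect_equal(f$intercept, 1)
  expect_equal(f$r_squared, 1)

  # 4-point worked example against the closed-form OLS oracle:
  # Sxy = 5.5, Sxx = 5, Syy = 8.75 -> slope 1.1, intercept 0,
  # R^2 = Sxy^2/(Sxx*Syy) = 30.25/43.75
  f2 <- linear_fit(c(1, 2, 3, 4), c(1, 3, 2, 5))
  expect_equal(f2$slope, 5.5 / 5)
  expect_equal(f2$intercept, 2.75 - (5.5 / 5) * 2.5)
  expect_equal(f2$r_squared, 30.25 / 43.75)

  expect_warning(f3 <- linear_fit(1:5, rep(2, 5)), "constant response")
  expect_equal(f3$r_squared, 0)
  expect_error(linear_fit(rep(1, 5), 1:5), "constant predictor")
  expect_error(linear_fit(1:2, 1:2), "at least 3")
})

test_that("R-squared is invariant under affine rescaling of both axes", {
  set.seed(9)
  x <- rnorm(40); y <- 2 * x + rnorm(40)
  r0 <- linear_fit(x, y)$r_squared
  expect_equal(linear_fit(10 * x - 3, -0.5 * y + 7)$r_squared, r0)
})

test_that("metric comparison ranks a constructed exact predictor first", {
  set.seed(4)
  n <- 60
  dwave <- runif(n, 22, 32)
  rec <- data.frame(
    patient_id = sprintf("X%02d", 1:n), scanner_id = "S1", exam_type = "CAP",
    sex = rep(c("F", "M"), n / 2), weight_kg = runif(n, 50, 100),
    height_cm = runif(n, 150, 185), ctdivol_mGy = 0.5 * dwave - 2,
    dwc_cm = dwave + rnorm(n, 0, 1), dwave_cm = dwave,
    dwmin_cm = dwave - 3, dwmax_cm = dwave + 3,
    ssde_mGy = (0.5 * dwave - 2) * 1.3)
  mc <- as.data.frame(metric_comparison(rec))
  r2 <- function(m) mc$r_squared[mc$dose == "ctdi_vol" & mc$metric == m]
  expect_equal(r2("dw_ave"), 1)
  expect_lt(r2("dw_c"), 1)
  # determinism: identical strata give identical tables
  expect_identical(metric_comparison(rec), metric_comparison(rec))
})

test_that("cells without biometrics or enough records are handled", {
  rec <- default_cohort()[1:10, ]
  rec$weight_kg[1:4] <- NA
  mc <- as.data.frame(metric_comparison(rec))
  wrow <- mc[mc$metric == "weight" & mc$dose == "ctdi_vol" &
               mc$exam_type == "chest", ]
  expect_equal(wrow$n_dropped, 4L)
  tiny <- default_cohort()[1:2, ]
  mc2 <- as.data.frame(metric_comparison(tiny))
  expect_true(all(is.na(mc2$r_squared)))   # < 3 records: cell unavailable
})

test_that("difference statistics report signed percents of Dw_ave", {
  rec <- data.frame(
    exam_type = "CAP", sex = "F", dwc_cm = 24, dwave_cm = 25,
    dwmin_cm = 21, dwmax_cm = 27, ctdivol_mGy = 10, ssde_mGy = 13,
    weight_kg = 60, height_cm = 160, scanner_id = "S1")
  ds <- difference_stats(rec)
  all_row <- ds[ds$sex == "All", ]
  expect_equal(all_row$dwc_minus_dwave_pct_mean, -4)
  expect_equal(all_row$dwc_minus_dwave_cm_mean, -1)
  expect_equal(all_row$dw_range_pct_mean, 24)
  expect_equal(all_row$dw_range_cm_sd, 0)

  # constant profiles: all differences zero
  rec2 <- rec; rec2$dwc_cm <- 25; rec2$dwmin_cm <- 25; rec2$dwmax_cm <- 25
  ds2 <- difference_stats(rbind(rec2, rec2))
  expect_true(all(ds2$dwc_minus_dwave_pct_mean == 0))
  expect_true(all(ds2$dw_range_cm_mean == 0))
})

test_that("the All stratum lies between the per-sex means", {
  rec <- default_cohort()
  ds <- difference_stats(rec)
  for (exam in c("chest", "CAP")) {
    sub <- ds[ds$exam_type == exam, ]
    fm <- sub$dwc_minus_dwave_pct_mean[sub$sex %in% c("F", "M")]
    all_m <- sub$dwc_minus_dwave_pct_mean[sub$sex == "All"]
    expect_gte(all_m, min(fm)); expect_lte(all_m, max(fm))
    # sign consistency between cm and percent summaries
    expect_equal(sign(all_m), sign(sub$dwc_minus_dwave_cm_mean[sub$sex == "All"]))
  }
})

test_that("cohort summaries use population SD and are reproducible", {
  rec <- default_cohort()[1:2, ]
  rec$ctdivol_mGy <- c(10, 14); rec$ssde_mGy <- c(13, 15)
  cs <- cohort_summary(rec)
  expect_equal(cs$mean_ctdivol, 12)
  expect_equal(cs$sd_ctdivol, 2)          # population SD, not 2.83
  one <- cohort_summary(rec[1, ])
  expect_equal(one$sd_ctdivol, 0)

  # byte-identical CSV across repeated generation from the same seed
  f1 <- withr::local_tempfile(fileext = ".csv")
  f2 <- withr::local_tempfile(fileext = ".csv")
  write.csv(cohort_summary(sample_cohort(cohort_config(n_chest = 5L, n_cap = 5L,
                                                       seed = 3L))), f1,
            row.names = FALSE)
  write.csv(cohort_summary(sample_cohort(cohort_config(n_chest = 5L, n_cap = 5L,
                                                       seed = 3L))), f2,
            row.names = FALSE)
  expect_identical(readLines(f1), readLines(f2))
})
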