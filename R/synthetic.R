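# Synthetic data: analytic phantoms with known water-equivalent diameter, a
# synthetic patient couch, anatomy-shaped Dw(z) profiles, a noise-constant
# ATCM emulator, and a seeded patient cohort generator. Everything here is a
# pure function of its arguments and seed.

# --- phantom images ---------------------------------------------------------

#' Specification of an analytic phantom image
#'
#' @param shape `"disk"`, `"ellipse"` or `"half-plane"`.
#' @param dimensions For a disk, the diameter in cm; for an ellipse, the two
#'   full axes (LAT, AP) in cm; for a half-plane, the fraction of image height
#'   filled from the bottom edge.
#' @param uniform_hu Interior CT number in HU (0 = water).
#' @param pixel_spacing Isotropic pixel spacing in mm.
#' @param image_size Image side length in pixels (square image).
#' @param include_table Add a synthetic couch strip below the phantom.
#' @param noise_sd Gaussian pixel noise SD in HU (0 = noise-free).
#' @return An object of class `phantom_spec` with the analytic ground truth
#'   attached: `dw_true` (cm; `NA` for half-plane) and, when a couch is
#'   included, `aw_table_true` (cm^2).
#' @export
phantom_spec <- function(shape = c("disk", "ellipse", "half-plane"),
                         dimensions, uniform_hu = 0, pixel_spacing = 0.8,
                         image_size = 512L, include_table = FALSE,
                         noise_sd = 0) {
  shape <- match.arg(shape)
  if (noise_sd < 0) stop("'noise_sd' must be >= 0")
  fov_cm <- image_size * pixel_spacing / 10
  dw_true <- switch(shape,
    disk = {
      stop_if_not_scalar_pos(dimensions, "dimensions")
      if (dimensions >= fov_cm - 1) stop("disk does not fit inside the image")
      dimensions
    },
    ellipse = {
      if (length(dimensions) != 2L || any(dimensions <= 0))
        stop("ellipse needs two positive full axes (cm)")
      if (max(dimensions) >= fov_cm - 1)
        stop("ellipse does not fit inside the image")
      2 * sqrt(prod(dimensions / 2))
    },
    `half-plane` = NA_real_)
  structure(list(shape = shape, dimensions = dimensions,
                 uniform_hu = uniform_hu, pixel_spacing = pixel_spacing,
                 image_size = as.integer(image_size),
                 include_table = include_table, noise_sd = noise_sd,
                 dw_true = dw_true,
                 # couch geometry (cm): 40 wide x 2 thick strip near the
                 # bottom edge; Aw derives from its HU and area.
                 table_hu = -300, table_width_cm = 40, table_thick_cm = 2,
                 aw_table_true = if (include_table)
                   (1 - 300 / 1000) * 40 * 2 else NA_real_),
            class = "phantom_spec")
}

# Render one slice of a phantom spec. Returns list(pixels, table_mask).
.render_phantom <- function(spec, noise = NULL) {
  n <- spec$image_size
  s_cm <- spec$pixel_spacing / 10
  ctr <- (n + 1) / 2
  xy <- (seq_len(n) - ctr) * s_cm     # pixel-center coordinates, cm
  px <- matrix(-1000, n, n)
  X <- matrix(xy, n, n, byrow = TRUE)  # column coordinate (LAT)
  Y <- matrix(xy, n, n)                # row coordinate (AP, + down)
  inside <- switch(spec$shape,
    disk = (X^2 + Y^2) <= (spec$dimensions / 2)^2,
    ellipse = (X / (spec$dimensions[1] / 2))^2 +
              (Y / (spec$dimensions[2] / 2))^2 <= 1,
    `half-plane` = Y >= xy[n] - spec$dimensions * (xy[n] - xy[1]))
  px[inside] <- spec$uniform_hu
  table_mask <- matrix(FALSE, n, n)
  if (spec$include_table) {
    fov_cm <- n * s_cm
    y0 <- fov_cm / 2 - 3                     # top of couch, cm below center
    trows <- Y >= y0 & Y <= y0 + spec$table_thick_cm &
             abs(X) <= spec$table_width_cm / 2
    px[trows] <- spec$table_hu
    table_mask <- trows
  }
  if (!is.null(noise)) px <- px + noise
  list(pixels = px, table_mask = table_mask)
}

#' Generate a phantom CT series
#'
#' `n_slices` identical slices (plus independent per-slice pixel noise when
#' `spec$noise_sd > 0`). The analytic ground truth is attached as attributes:
#' `dw_true`, `aw_table_true`, and `table_mask` (logical matrix, for
#' \code{\link{calibrate_table}}).
#'
#' @param spec A [phantom_spec].
#' @param n_slices Number of slices.
#' @param seed Seed for the pixel noise.
#' @param slice_spacing_mm Slice spacing in mm.
#' @return A [scan_series] with `exam_type = "phantom"`.
#' @export
make_phantom_series <- function(spec, n_slices = 10L, seed = 1L,
                                slice_spacing_mm = 5) {
  stopifnot(inherits(spec, "phantom_spec"))
  n <- spec$image_size
  slices <- with_seed(seed, lapply(seq_len(n_slices), function(i) {
    noise <- if (spec$noise_sd > 0)
      matrix(stats::rnorm(n * n, 0, spec$noise_sd), n, n) else NULL
    r <- .render_phantom(spec, noise)
    ct_slice(r$pixels, rep(spec$pixel_spacing, 2L),
             z_position = (i - 1) * slice_spacing_mm, slice_id = i)
  }))
  out <- scan_series(slices, exam_type = "phantom", scanner_id = "synthetic")
  attr(out, "dw_true") <- spec$dw_true
  attr(out, "aw_table_true") <- spec$aw_table_true
  attr(out, "table_mask") <- .render_phantom(spec)$table_mask
  out
}

# --- anatomy-shaped Dw(z) profiles ------------------------------------------

# Longitudinal shape templates on anatomical coordinate u in [0, 1]
# (0 = cranial end of the scan range). Chest: caudal ramp plus a central
# low-attenuation lung dip, so the mid-scan slice sits below the scan mean.
# CAP: broad abdominal maximum in the caudal half, so the mid-scan slice
# (near the liver) sits above the scan mean. Constants are calibrated so
# that, with the default range fraction 0.23, the nominal mid-scan offset is
# -4.0% of Dw_ave for chest and +5.0% for CAP.
.anatomy_shape <- function(exam_type) {
  switch(exam_type,
         chest = function(u) 0.8 * u - exp(-((u - 0.35) / 0.25)^2),
         CAP = function(u) exp(-((u - 0.675) / 0.5)^2),
         phantom = function(u) rep(0, length(u)),
         stop("unknown exam_type: ", exam_type))
}

# Dense-grid normalization constants of a shape over the nominal window.
.shape_norm <- function(g) {
  gv <- g(seq(0, 1, length.out = 2001L))
  list(mean = mean(gv), range = max(gv) - min(gv))
}

#' Anatomy-shaped ground-truth Dw(z) curve
#'
#' Deterministic longitudinal Dw profile for one examination:
#' `dw(u) = target * (1 + range_frac * (g(u) - mean(g)) / range(g))` with `g`
#' the exam-type shape template and normalization constants taken on the
#' nominal window \eqn{[0, 1]}. The curve mean over the nominal window equals
#' `dw_ave_target` (to sampling accuracy), the max-min range is `range_frac`
#' of it, and the mid-scan value sits below the mean for chest scans and
#' above it for CAP scans. `window` shifts/stretches the sampled anatomical
#' interval (used by the cohort generator's scan-length jitter); the
#' normalization stays nominal, so a shifted window shifts the realized
#' metrics, as mispositioned scan ranges do.
#'
#' @param exam_type `"chest"`, `"CAP"` or `"phantom"` (constant profile).
#' @param dw_ave_target Target mean Dw in cm, positive.
#' @param scan_length_mm Scanned length in mm.
#' @param n_slices Number of slices; default from `scan_length_mm` at 5 mm
#'   spacing.
#' @param window Anatomical interval actually scanned; default `c(0, 1)`.
#' @param range_frac Max-min range as a fraction of `dw_ave_target`; default
#'   0.23.
#' @return A `dw_profile` (currents `NA`).
#' @export
anatomy_profile <- function(exam_type, dw_ave_target, scan_length_mm = 300,
                            n_slices = NULL, window = c(0, 1),
                            range_frac = 0.23) {
  stop_if_not_scalar_pos(dw_ave_target, "dw_ave_target")
  if (is.null(n_slices)) n_slices <- max(2L, round(scan_length_mm / 5) + 1L)
  g <- .anatomy_shape(exam_type)
  nrm <- .shape_norm(g)
  u <- seq(window[1L], window[2L], length.out = n_slices)
  dw <- if (nrm$range == 0) rep(dw_ave_target, n_slices) else
    dw_ave_target * (1 + range_frac * (g(u) - nrm$mean) / nrm$range)
  dw <- pmax(dw, 0)
  new_dw_profile(z = seq(0, scan_length_mm, length.out = n_slices), dw = dw,
                 exam_type = exam_type)
}

#' Render a Dw(z) curve as a CT image series
#'
#' Each profile value becomes a uniform water-equivalent ellipse slice with
#' fixed AP:LAT aspect ratio, so the analytic Dw of every rendered slice
#' equals the curve value. Lets the image pipeline be validated end-to-end on
#' anatomy-shaped series.
#'
#' @param profile A `dw_profile`.
#' @param pixel_spacing Pixel spacing in mm.
#' @param image_size Image side in pixels.
#' @param aspect AP/LAT axis ratio; default 0.7.
#' @param include_table Add the synthetic couch to every slice.
#' @param noise_sd Per-pixel HU noise SD.
#' @param seed Seed for the noise (`same seed => identical series`).
#' @return A [scan_series] with ground-truth attributes as in
#'   [make_phantom_series] (`dw_true` is the per-slice curve).
#' @export
profile_to_series <- function(profile, pixel_spacing = 1, image_size = 512L,
                              aspect = 0.7, include_table = FALSE,
                              noise_sd = 0, seed = 1L) {
  stopifnot(inherits(profile, "dw_profile"))
  n <- as.integer(image_size)
  slices <- with_seed(seed, lapply(seq_along(profile$dw), function(i) {
    dwi <- profile$dw[i]
    lat <- dwi / sqrt(aspect)            # full LAT axis, cm
    ap <- dwi * sqrt(aspect)
    spec <- phantom_spec("ellipse", c(lat, ap), uniform_hu = 0,
                         pixel_spacing = pixel_spacing, image_size = n,
                         include_table = include_table, noise_sd = noise_sd)
    noise <- if (noise_sd > 0)
      matrix(stats::rnorm(n * n, 0, noise_sd), n, n) else NULL
    r <- .render_phantom(spec, noise)
    ct_slice(r$pixels, rep(pixel_spacing, 2L), z_position = profile$z[i],
             tube_current = profile$current[i], slice_id = i)
  }))
  out <- scan_series(slices, ctdi_vol = profile$ctdi_vol,
                     exam_type = profile$exam_type, scanner_id = "synthetic")
  attr(out, "dw_true") <- profile$dw
  ref <- phantom_spec("disk", 10, pixel_spacing = pixel_spacing,
                      image_size = n, include_table = include_table)
  attr(out, "aw_table_true") <- ref$aw_table_true
  attr(out, "table_mask") <- .render_phantom(ref)$table_mask
  out
}

# --- ATCM emulator ----------------------------------------------------------

#' Noise-constant ATCM parameters
#'
#' The emulator models z-axis tube current modulation of a noise-constant
#' system: `I(z) = clamp(i_ref * exp(k * (dw(z) - dw_ref)), imin, imax)`, and
#' the examination dose as `ctdi_vol = dose_const * mean(I(z))`. The default
#' `k = log(2)/6` per cm makes a 6 cm increase in Dw_ave (about 24% of a
#' 25 cm patient) double the dose, the coupling strength typical of
#' noise-constant ATCM in the chest/abdomen range.
#'
#' @param k Exponential dose-size constant, per cm; positive.
#' @param dw_ref Reference Dw in cm at which `I = i_ref`.
#' @param i_ref Reference tube current in mA.
#' @param imin,imax ATCM current clamp bounds in mA, `imin < imax`.
#' @param dose_const CTDIvol per unit mean current, mGy/mA.
#' @return An object of class `atcm_params`.
#' @export
atcm_params <- function(k = log(2) / 6, dw_ref = 25, i_ref = 160,
                        imin = 80, imax = 500, dose_const = 0.05) {
  stop_if_not_scalar_pos(k, "k")
  stop_if_not_scalar_pos(imin, "imin")
  if (imax <= imin) stop("'imax' must exceed 'imin'")
  structure(list(k = k, dw_ref = dw_ref, i_ref = i_ref, imin = imin,
                 imax = imax, dose_const = dose_const),
            class = "atcm_params")
}

#' Emulate the ATCM response to a Dw(z) profile
#'
#' Deterministic: the per-examination dose noise belongs to the cohort
#' sampler, not here.
#'
#' @param profile A `dw_profile`.
#' @param params An [atcm_params].
#' @return List: `current` (mA per slice), `ctdi_vol` (mGy), `clamped_frac`
#'   (fraction of slices pinned at `imin` or `imax`).
#' @export
emulate_atcm <- function(profile, params = atcm_params()) {
  stopifnot(inherits(profile, "dw_profile"), inherits(params, "atcm_params"))
  raw <- params$i_ref * exp(params$k * (profile$dw - params$dw_ref))
  i_z <- pmin(pmax(raw, params$imin), params$imax)
  list(current = i_z, ctdi_vol = params$dose_const * mean(i_z),
       clamped_frac = mean(raw < params$imin | raw > params$imax))
}

# --- cohort generator -------------------------------------------------------

#' Synthetic cohort configuration
#'
#' Defaults emulate an adult oncological CT population scanned on a single
#' noise-constant ATCM scanner: weights lognormal with mean 68 kg and SD
#' 14 kg truncated to 43-117 kg; heights normal per sex (F: 160 +/- 7 cm on
#' 144-175, M: 169 +/- 7 cm on 145-185); Dw_ave linear in weight
#' (`14 + 0.162 * weight`, residual SD 1.2 cm, spanning roughly 21-33 cm over
#' the weight range); examination dose from the ATCM emulator with
#' multiplicative lognormal noise (sdlog 0.08); and scan-length jitter (SD 8%
#' of the scan length at each end) shifting the anatomical window, which is
#' what decouples the mid-scan metric from the scan average.
#'
#' @param n_chest,n_cap Patients per examination type.
#' @param scanner_id Scanner label.
#' @param p_female Probability of sex `"F"`.
#' @param weight_mean_kg,weight_sd_kg,weight_range_kg Lognormal weight model
#'   (arithmetic mean/SD) and truncation range.
#' @param height_f,height_m Per-sex height models:
#'   `c(mean, sd, min, max)` in cm.
#' @param dw_intercept,dw_slope,dw_resid_sd Weight to Dw_ave regression (cm,
#'   cm/kg, cm).
#' @param atcm An [atcm_params].
#' @param dose_noise_sdlog Lognormal SD of the per-exam dose noise.
#' @param scan_length_chest_mm,scan_length_cap_mm Nominal scan lengths.
#' @param slice_spacing_mm Reconstructed slice spacing.
#' @param jitter_sd Scan-length jitter SD, as a fraction of scan length.
#' @param range_frac Dw range fraction passed to [anatomy_profile].
#' @param pixel_noise_sd HU noise used when rendering series.
#' @param seed Root seed; per-patient substreams derive from it, so cohort
#'   membership is stable when `n` grows.
#' @return An object of class `cohort_config`.
#' @export
cohort_config <- function(n_chest = 80L, n_cap = 120L, scanner_id = "synth01",
                          p_female = 0.5, weight_mean_kg = 68,
                          weight_sd_kg = 14, weight_range_kg = c(43, 117),
                          height_f = c(160, 7, 144, 175),
                          height_m = c(169, 7, 145, 185),
                          dw_intercept = 14, dw_slope = 0.162,
                          dw_resid_sd = 1.2, atcm = atcm_params(),
                          dose_noise_sdlog = 0.08,
                          scan_length_chest_mm = 300,
                          scan_length_cap_mm = 700, slice_spacing_mm = 5,
                          jitter_sd = 0.08, range_frac = 0.23,
                          pixel_noise_sd = 10, seed = 1L) {
  if (dw_resid_sd < 0 || dose_noise_sdlog < 0 || jitter_sd < 0 ||
      pixel_noise_sd < 0)
    stop("all noise SDs must be >= 0")
  if (weight_range_kg[1] >= weight_range_kg[2])
    stop("invalid weight truncation range")
  cv2 <- (weight_sd_kg / weight_mean_kg)^2
  structure(list(
    n_chest = as.integer(n_chest), n_cap = as.integer(n_cap),
    scanner_id = scanner_id, p_female = p_female,
    weight_meanlog = log(weight_mean_kg) - log1p(cv2) / 2,
    weight_sdlog = sqrt(log1p(cv2)), weight_range_kg = weight_range_kg,
    height_f = height_f, height_m = height_m,
    dw_intercept = dw_intercept, dw_slope = dw_slope,
    dw_resid_sd = dw_resid_sd, atcm = atcm,
    dose_noise_sdlog = dose_noise_sdlog,
    scan_length_chest_mm = scan_length_chest_mm,
    scan_length_cap_mm = scan_length_cap_mm,
    slice_spacing_mm = slice_spacing_mm, jitter_sd = jitter_sd,
    range_frac = range_frac, pixel_noise_sd = pixel_noise_sd,
    seed = as.integer(seed)), class = "cohort_config")
}

# Truncated draws by rejection (distribution shape preserved inside bounds).
.rtrunc <- function(draw, lo, hi) {
  for (i in 1:1000) {
    x <- draw()
    if (x >= lo && x <= hi) return(x)
  }
  stop("truncated sampling failed; check distribution parameters")
}

# One patient's seeded draw: biometrics, anatomy profile, ATCM response and
# noisy dose. Deterministic given (config, seed, i).
.sample_patient <- function(config, i, seed) {
  exam <- if (i <= config$n_chest) "chest" else "CAP"
  with_seed(substream_seed(seed, i), {
    sex <- if (stats::runif(1) < config$p_female) "F" else "M"
    weight <- .rtrunc(function() stats::rlnorm(1, config$weight_meanlog,
                                               config$weight_sdlog),
                      config$weight_range_kg[1], config$weight_range_kg[2])
    hp <- if (sex == "F") config$height_f else config$height_m
    height <- .rtrunc(function() stats::rnorm(1, hp[1], hp[2]), hp[3], hp[4])
    dw_target <- max(config$dw_intercept + config$dw_slope * weight +
                       stats::rnorm(1, 0, config$dw_resid_sd), 12)
    len <- if (exam == "chest") config$scan_length_chest_mm else
      config$scan_length_cap_mm
    window <- c(stats::rnorm(1, 0, config$jitter_sd),
                1 + stats::rnorm(1, 0, config$jitter_sd))
    if (window[2] - window[1] < 0.5) window <- c(0, 1)
    prof <- anatomy_profile(exam, dw_target, scan_length_mm = len,
                            window = window, range_frac = config$range_frac)
    resp <- emulate_atcm(prof, config$atcm)
    ctdi <- resp$ctdi_vol * stats::rlnorm(1, 0, config$dose_noise_sdlog)
    list(exam = exam, sex = sex, weight = weight, height = height,
         dw_target = dw_target, scan_length = len, profile = prof,
         current = resp$current, clamped_frac = resp$clamped_frac,
         ctdi_vol = ctdi)
  })
}

#' Sample a synthetic patient cohort
#'
#' One exam record per patient: sampled biometrics, Dw_ave drawn from the
#' weight regression, an anatomy-shaped Dw(z) profile on a jittered scan
#' window, ATCM currents and noisy CTDIvol, size metrics recomputed from the
#' realized profile (not from the regression), and SSDE from CTDIvol and the
#' recomputed Dw_c.
#'
#' @param config A [cohort_config].
#' @param seed Optional override of `config$seed`.
#' @return Data frame of exam records (columns as in [metric_comparison]),
#'   plus per-patient extras: `dwave_target_cm`, `clamped_frac`,
#'   `scan_length_mm`. The per-exam tube-current vectors are attached as
#'   `attr(, "currents")` (a list, for [scenario_sweep]).
#' @export
sample_cohort <- function(config = cohort_config(), seed = NULL) {
  stopifnot(inherits(config, "cohort_config"))
  seed <- as.integer(seed %||% config$seed)
  n <- config$n_chest + config$n_cap
  ftab <- f32_table()
  rows <- vector("list", n)
  currents <- vector("list", n)
  for (i in seq_len(n)) {
    p <- .sample_patient(config, i, seed)
    m <- dw_metrics(p$profile)
    currents[[i]] <- p$current
    rows[[i]] <- data.frame(
      patient_id = sprintf("P%04d", i),
      scanner_id = config$scanner_id, exam_type = p$exam, sex = p$sex,
      weight_kg = p$weight, height_cm = p$height,
      ctdivol_mGy = p$ctdi_vol, dwc_cm = m$dw_c, dwave_cm = m$dw_ave,
      dwmin_cm = m$dw_min, dwmax_cm = m$dw_max,
      ssde_mGy = as.numeric(ssde(p$ctdi_vol, m$dw_c, ftab)),
      dwave_target_cm = p$dw_target,
      clamped_frac = p$clamped_frac, scan_length_mm = p$scan_length)
  }
  out <- do.call(rbind, rows)
  attr(out, "currents") <- currents
  attr(out, "config_seed") <- seed
  out
}

#' Render a sampled patient's examination as a CT series
#'
#' Reconstructs the patient's seeded anatomy profile and renders it with
#' [profile_to_series]; used to validate the image pipeline end-to-end on
#' cohort members.
#'
#' @param config The [cohort_config] used for the cohort.
#' @param patient_index Patient index (row number in the cohort).
#' @param seed Cohort seed (default `config$seed`).
#' @param ... Passed to [profile_to_series].
#' @return A [scan_series].
#' @export
render_cohort_exam <- function(config, patient_index, seed = NULL, ...) {
  seed <- as.integer(seed %||% config$seed)
  p <- .sample_patient(config, patient_index, seed)
  prof <- p$profile
  prof$current <- p$current
  prof$ctdi_vol <- p$ctdi_vol
  profile_to_series(prof, noise_sd = config$pixel_noise_sd,
                    seed = substream_seed(seed, patient_index), ...)
}
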