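---
title: "Water-equivalent diameter metrics for CT dose monitoring: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Water-equivalent diameter metrics for CT dose monitoring: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dwmetrics)
```

## The model

A CT slice's water-equivalent area converts its attenuation content into the
area of water with the same total attenuation. With `<CT>` the mean CT
number (HU) over an ROI of area `A_ROI`,

$$A_w = \left(\frac{\langle CT\rangle}{1000} + 1\right) A_{ROI},$$

so water (0 HU) contributes its full area and air (−1000 HU) contributes
nothing. This package uses the whole image as the ROI: it is fast, requires
no contouring, and air outside the patient is free by construction. The
price is that everything in the field of view contributes — in particular
the patient couch, whose water-equivalent area $A_w(\mathrm{table})$ is
measured once per scanner by contouring the couch in a patient-free region
(`calibrate_table`) and subtracted before converting area to diameter:

$$D_w(z) = 2\sqrt{\frac{A_w(z) - A_w(\mathrm{table})}{\pi}}.$$

Two scalar metrics summarize a scan: the mid-scan value `D_w_c` (the slice
nearest the z midpoint of the scanned range; on an exact tie between two
slices the lower-z slice is used, a convention chosen here because the
choice is arbitrary and must be deterministic) and the scan mean `D_w_ave`
(unweighted across reconstructed slices — reconstructed spacing is uniform
in practice, so no spacing weighting is applied). SSDE is
`CTDIvol * f(D_w_c)` with `f` interpolated from the packaged 32-cm
body-phantom conversion-factor table; the API also accepts `D_w_ave` and
records which metric was used, since the comparative analyses need both.

### Assumptions and scope

* Images must come from a linear, quantitative reconstruction kernel;
  HU rescaling (slope/intercept) is applied at read time and downstream code
  never sees stored values.
* Vendor padding outside the reconstruction circle (sentinels at or below
  −1500 HU, e.g. −2000/−3024) is replaced with air at read time; because air
  contributes zero water-equivalent area this leaves $D_w$ unchanged while
  removing the vendor dependence.
* Patients whose contour is partly outside the field of view bias $D_w$
  low. The package flags this (`truncation_fraction`: the fraction of the
  outermost 2-pixel border frame above −600 HU, with 0.05 a reasonable
  cutoff) but applies no correction; truncated scans should be excluded.
* CTDIvol is an explicit input (32-cm body phantom reference). Dose
  metadata parsing from dose-summary objects is out of scope.
* Only adult body examinations are in scope; 16-cm head-phantom conversion
  factors are not provided.

### The conversion-factor table

The packaged table (`f32_table()`, also shipped as
`inst/extdata/f32_conversion.csv`) tabulates the 32-cm body-phantom factors
at 1-cm steps over 6–55 cm from the standard exponential parameterization
$f(D) = 3.704369\, e^{-0.03671937 D}$ distributed with the published factor
tables; `conversion_factor()` interpolates it piecewise-linearly (monotone
preserving) and clamps with a warning outside the tabulated range. The
continuous fit is retained as `f32_fit()` and the tests check the two paths
agree to better than 1%.

## The Imin simulation

Raising the ATCM minimum tube current is simulated by clamping the recorded
current profile from below, $I'(z) = \max(I(z), I_{min})$, and scaling the
examination CTDIvol by the ratio of mean currents (dose is proportional to
mean mA at fixed kV, pitch and rotation time). This is a hard cutoff: real
ATCM systems smooth spatial variation near the limit, a discrepancy known to
be small (a few percent) but not modeled here. Only $I_{min}$ at or above
the originally applied minimum is meaningful; lower values return the
original dose with a warning. Across a cohort the simulation raises the mean
dose and *compresses* its spread — thresholding removes variance from below
— which is the signature pattern `scenario_sweep` summarizes (mean ± SD per
scenario). All SDs in this package are population SDs (n denominator),
stated in the output metadata, because the summaries describe the cohort at
hand rather than estimate a superpopulation.

## The synthetic-data generator

No public dataset pairs CT image series with per-slice currents and dose
indices at cohort scale, so the package generates its own study conditions.
The generator is first-class, tested code, and everything is a pure function
of (config, seed) with per-patient substreams, so cohort membership is
stable as `n` grows.

**Phantoms.** `make_phantom_series` renders uniform disks/ellipses of known
$D_w$ (disk: the diameter; ellipse: $2\sqrt{ab}$) on an air background at
chosen pixel spacing, optionally with Gaussian pixel noise (default 10 HU,
typical of soft-kernel body reconstructions) and a synthetic couch (40 × 2
cm strip at −300 HU, $A_w = 56\ \mathrm{cm}^2$) for calibration tests.
Pixels are classified by their center; at ≤ 1 mm spacing the resulting
$D_w$ error is a few hundredths of a cm, far inside the 0.2 cm validation
bound used throughout.

**Anatomy profiles.** `anatomy_profile` produces a deterministic
$D_w(z)$ curve per exam type: chest scans get a caudal ramp plus a central
lung dip (mid-scan value below the scan mean), chest–abdomen–pelvis (CAP)
scans a broad abdominal maximum in the caudal half (mid-scan above the
mean). Shape constants are calibrated so that at the default range fraction
(max − min = 23% of `D_w_ave`) the nominal mid-scan offsets are −4.0%
(chest) and +5.0% (CAP) of `D_w_ave` — the characteristic signed split
between the two metrics in adult body CT. The curve is normalized on the
nominal anatomical window, so shifting the sampled window (scan-length
jitter) shifts the realized metrics exactly as a mispositioned scan range
does.

**ATCM emulator.** `emulate_atcm` models a noise-constant system:
$I(z) = \mathrm{clamp}(I_{ref}\, e^{k (D_w(z) - D_{ref})}, I_{min},
I_{max})$ and `ctdi_vol = dose_const * mean(I)`. The default
$k = \ln 2 / 6\ \mathrm{cm}^{-1}$ makes a 6 cm increase in `D_w_ave`
(≈ 24% of a 25 cm patient) double the dose, the observed coupling strength
of noise-constant ATCM in the body range; defaults
($I_{ref} = 160$ mA at 25 cm, clamps 80/500 mA, 0.05 mGy/mA) put a 25 cm
patient at ≈ 8 mGy and a 31 cm patient at ≈ 16 mGy. Clamping at $I_{min}$
flattens the dose–size response for small patients; the emulator is
deterministic, with per-examination lognormal dose noise (sdlog 0.08,
representing kV/pitch/centering variability) added only by the cohort
sampler. Note the across-patient coefficient of variation below the
clamp-activation size is therefore ≈ 8% in sampled cohorts (the noise
floor), while the *deterministic* response there is constant — tests check
the flattening at the emulator level.

**Cohort.** `sample_cohort` draws, per patient: sex; weight from a
lognormal (mean 68, SD 14 kg) truncated to 43–117 kg; height per sex
(F: 160 ± 7 cm on 144–175; M: 169 ± 7 on 145–185) — adult body-CT ranges;
`D_w_ave` linear in weight (`14 + 0.162 w`, residual SD 1.2 cm, spanning
≈ 21–33 cm); a scan window jittered at each end (SD 8% of scan length); the
anatomy profile on that window; ATCM currents and noisy dose; and SSDE from
the recomputed `D_w_c`. The metrics entering the records are recomputed
from the realized profile, never copied from the regression. Scan-length
jitter is the explicit mechanism decoupling `D_w_c` from dose: it moves
the mid-scan slice across anatomy (≈ 0.6 cm SD of extra noise in `D_w_c`)
while barely moving the scan mean, which is why dose indices track
`D_w_ave` best, then `D_w_c`, then weight (whose link to `D_w_ave` carries
the 1.2 cm residual).

**What the generator does not emulate.** Real organs, bone and contrast;
helical geometry and angular modulation; vendor-specific modulation
smoothing; truncated contours; inter-scanner calibration differences.
Passing tests therefore demonstrate the correctness and internal
consistency of the computational pipeline under realistic statistical
structure — not claims about any particular clinical cohort, whose
R² values and difference magnitudes are population-specific.

## Statistical conventions

* `linear_fit` is ordinary least squares with intercept;
  $R^2 = 1 - SS_{res}/SS_{tot}$, computed directly from residuals. A
  constant response is reported as $R^2 = 0$ with a warning (the fit
  explains nothing); a constant predictor is an error. Reporting requires
  $n \ge 3$.
* `metric_comparison` stratifies by scanner × exam type, as dose protocols
  differ by scanner; `difference_stats` stratifies by exam type × sex with
  an "All" row; signed percentage differences use `D_w_ave` as denominator.
* **Common-curve check.** To ask whether chest and CAP examinations share
  one CTDIvol-vs-`D_w_ave` dependence, `common_curve_gap` compares nested
  models on the pooled records: a single line versus per-exam-type lines
  (`dose ~ dw_ave * exam_type`), reporting the $R^2$ improvement. Comparing
  the pooled $R^2$ against each stratum's own $R^2$ would conflate curve
  separation with the strata's different total variances (each stratum has
  its own $SS_{tot}$ denominator and its own sampling noise at $n \le 120$);
  the nested comparison isolates the property of interest. On default
  cohorts the gap is ≈ 0.003, i.e. separate lines explain essentially
  nothing extra.
* Display rounding is 2 decimals for diameters (cm); CSV outputs keep full
  precision.

## Numerical and degenerate-input choices

* A negative radicand in the diameter formula (couch calibration exceeding
  slice content, e.g. an air-only slice at the scan edge) clamps to zero
  with a warning instead of erroring, so edge slices cannot abort a series.
* Areas are carried in mm² internally and converted to cm² at operation
  boundaries.
* The DICOM writer emits explicit-VR little-endian single-frame CT objects
  with rescale slope 1 / intercept −1024; pixel round-trip error is bounded
  by quantization (0.5 HU), tube current by the integer mA storage unit.
  The reader rejects mixed series identifiers, missing rescale metadata and
  unsupported transfer syntaxes, and warns on nonuniform pixel spacing
  (per-slice spacing is retained).
* Seeds: every stochastic function takes an explicit seed and restores the
  caller's RNG state; per-patient substreams are derived with a fixed
  integer recurrence kept below $2^{31}$.

## Problem sizes used in the tests

Phantom validation uses 512-pixel images at 0.8 mm spacing (the clinical
body FOV scale); the default synthetic cohort is 80 chest + 120 CAP
examinations with profiles at 5 mm slice spacing, analyzed without image
rendering; end-to-end image-pipeline checks render a handful of full
examinations. These sizes make every documented property measurable in
seconds to a couple of minutes on a single CPU while matching the scale of
the study conditions the generator emulates.

## Known limitations

* The whole-image ROI method inherits the couch subtraction's assumption
  that the couch is fully inside the FOV and identical across slices.
* No automatic body contouring; published contour-based implementations
  report somewhat better accuracy and would be the natural extension.
* `D_w` estimation from localizer (scout) images is not implemented.
* The Imin simulation cannot lower the minimum below the recorded one, and
  models the clamp as a hard cutoff.
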