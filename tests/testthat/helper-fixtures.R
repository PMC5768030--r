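# Small in-code fixtures shared across test files.

# Uniform-HU square slice, spacing in mm.
uniform_slice <- function(hu, n = 32L, spacing = 1, z = 0, current = NA_real_,
                          id = 1L) {
  ct_slice(matrix(hu, n, n), rep(spacing, 2L), z_position = z,
           tube_current = current, slice_id = id)
}

# Profile fixture from explicit dw values.
profile_of <- function(dw, z = seq_along(dw) * 5 - 5, exam_type = "phantom") {
  new_dw_profile(z = z, dw = dw, exam_type = exam_type)
}

# Default seeded cohort, computed once per test run.
default_cohort <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- sample_cohort(cohort_config())
    cache
  }
})
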