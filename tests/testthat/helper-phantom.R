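# Shared fixtures, built once per session and cached. Sizes are kept small
# (few phases, modest supersampling) so the suite stays fast; the acceptance
# tests build their own full-size cohort.

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (!exists(name, envir = .fixtures)) {
    assign(name, builder(), envir = .fixtures)
  }
  get(name, envir = .fixtures)
}

# noisy Fabry-like subject, 8 phases (fast)
fix_fabry <- function() fixture("fabry_small", function() {
  spec <- draw_phantom_spec(cohort_preset("fabry"), seed = 7,
                            overrides = list(n_phases = 8L))
  build_phantom(spec, seed = 7)
})

fix_fabry_seg <- function() fixture("fabry_small_seg", function() {
  segment_subject(fix_fabry()$cine)
})

# noiseless Fabry-like subject at full phase count and odd supersampling
# (odd sub-voxel sampling avoids exact 50% partial-volume ties)
fix_noiseless <- function() fixture("fabry_noiseless", function() {
  spec <- draw_phantom_spec(cohort_preset("fabry"), seed = 7,
                            overrides = list(noise_sd = 0,
                                             supersampling_factor = 3L))
  build_phantom(spec, seed = 7)
})

fix_noiseless_seg <- function() fixture("fabry_noiseless_seg", function() {
  segment_subject(fix_noiseless()$cine)
})

# small two-group cohort (reduced phases) plus its measures
fix_cohort <- function() fixture("mini_cohort", function() {
  c(generate_cohort("control", 4, seed = 31, overrides = list(n_phases = 10L)),
    generate_cohort("fabry", 4, seed = 32, overrides = list(n_phases = 10L)))
})

fix_measures <- function() fixture("mini_measures", function() {
  measure_cohort(fix_cohort())
})

# analytic no-P&T phantom: half-ellipsoid a = b = 20 mm, c = 80 mm
fix_analytic_spec <- function(supersampling = 4L, n_phases = 4L) {
  phantom_spec(cavity_semiaxes_ed = c(20, 20), long_axis_length = 80,
               wall_thickness_ed = 8, wall_thickness_es = 10,
               papillary_count = 0L, trabecular_amplitude_ed = 0,
               trabecular_amplitude_es = 0, noise_sd = 0,
               n_phases = n_phases, supersampling_factor = supersampling)
}

mask_volume_ml <- function(arr, slices, px, dz) {
  sum(vapply(slices, function(k) sum(arr[k, , ] > 0), numeric(1))) * px * px * dz / 1000
}
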