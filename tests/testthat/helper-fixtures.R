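# Shared fixtures for the suite. Everything is generated in code; no files.

# Trial config with all measurement noise switched off: forward models must
# be exactly invertible under it.
noise_free_config <- function(seed = 1, ...) {
  trial_config(within_animal_cv = 0, gc_noise_sd = 0, fecal_noise_sd = 0,
               tube_weigh_sd = 0, seed = seed, ...)
}

# Cheap config for many-seed latent-structure checks: latent traits have the
# identical distribution as the full default, but the simulated record
# streams are much shorter.
light_config <- function(seed = 1, ...) {
  asv <- default_asv_params()
  asv$depth_mean <- 5000
  asv$depth_sd <- 500
  asv$depth_min <- 2000
  trial_config(duration_days = 28, measurement_days = 5, asv_params = asv,
               seed = seed, ...)
}

# Table of per-group mean VFA concentrations (mmol) used across tests.
group_vfa_profiles <- function() {
  list(
    CTR = vfa_profile(51.9, 11.3, 0.75, 3.49, 0.82, 0.24),
    CON = vfa_profile(50.5, 13.0, 0.63, 3.51, 0.77, 0.23),
    INT = vfa_profile(50.7, 12.3, 0.68, 3.58, 0.80, 0.27)
  )
}
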