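# Shared fixtures: small center profiles and cached preprocessed samples so
# individual test files do not re-render volumes repeatedly.

tiny_profiles <- function(noise = 2, bias = 0) {
  list(
    center_profile("A", 3, 3, native_spacing = c(1.2, 1.2, 10),
                   intensity_offset = 0, intensity_scale = 1,
                   noise_sigma = noise, bias_amplitude = bias),
    center_profile("B", 3, 3, native_spacing = c(1.5, 1.5, 5),
                   intensity_offset = 40, intensity_scale = 1.2,
                   noise_sigma = noise, bias_amplitude = bias)
  )
}

# A clean (no noise, no bias) rendered volume for one subject.
clean_volume <- function(label = "HCM", timepoint = "ED", seed = 11) {
  prof <- center_profile("clean", n_nor = 1, n_hcm = 1,
                         native_spacing = c(1, 1, 5))
  co <- generate_cohort(list(prof), master_seed = seed)
  subj <- co[co$label == label, ][1, ]
  render_phantom(subj, timepoint, prof)
}

# Synthetic analytic shell mask: annulus of inner/outer radius (mm) extruded
# over nz slices at given in-plane spacing.
shell_mask <- function(inner = 25, outer = 35, spacing = c(1, 1, 5),
                       n = 101, nz = 3) {
  x <- (seq_len(n) - (n + 1) / 2) * spacing[1]
  y <- (seq_len(n) - (n + 1) / 2) * spacing[2]
  r2 <- outer(x^2, y^2, "+")
  sl <- r2 >= inner^2 & r2 <= outer^2
  mask <- array(0L, dim = c(n, n, nz))
  for (k in seq_len(nz)) mask[, , k][sl] <- 2L
  mask
}

# A small curated sample with deterministic content.
toy_curated <- function(curation_type = "baseline", dims = c(20, 20, 4)) {
  img <- array(seq_len(prod(dims)) / prod(dims), dim = dims)
  mask <- array(0L, dim = dims)
  nx <- dims[1]
  thirds <- round(seq(nx %/% 4, nx - 1, length.out = 4))
  cols <- (nx %/% 4):(3 * nx %/% 4)
  mask[(thirds[1] + 1):thirds[2], cols, ] <- 1L
  mask[(thirds[2] + 1):thirds[3], cols, ] <- 2L
  mask[(thirds[3] + 1):thirds[4], cols, ] <- 3L
  curate(volume_sample(img, mask, c(1, 1, 1), subject_id = "toy",
                       label = "NOR", center = "A"),
         curation_type)
}

# Cached tiny two-center cohort with preprocessed (cropped) volumes; built
# once per test run.
.fixture_env <- new.env(parent = emptyenv())

tiny_pipeline_fixture <- function() {
  if (!is.null(.fixture_env$pipeline)) return(.fixture_env$pipeline)
  profiles <- tiny_profiles()
  cohort <- generate_cohort(profiles, master_seed = 7)
  config <- run_config(profiles = profiles, seeds = 0L, rounds = 5L,
                       bias_correct = FALSE)
  volumes <- fedcmr:::prepare_volumes(cohort, config)
  .fixture_env$pipeline <- list(profiles = profiles, cohort = cohort,
                                config = config, volumes = volumes)
  .fixture_env$pipeline
}
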