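# Shared fixtures: small phantoms and schemes built in code at test time.

small_spec <- function(seed = 1, n_subjects = 40, grid_shape = c(10, 10, 6),
                       ...) {
  phantom_spec(n_subjects = n_subjects, grid_shape = grid_shape,
               slab_shape = c(8, 8, 4), seed = seed, ...)
}

# Random unit vectors (seeded by the caller).
runit3 <- function(n) {
  m <- matrix(stats::rnorm(3 * n), n, 3)
  m / sqrt(rowSums(m^2))
}

# Build the PLS inputs from a phantom the same way the pipeline does
# (residualize age + pontine, 1 mm masked smoothing over the full grid).
phantom_dataset <- function(truth) {
  spec <- truth$spec
  covars <- cbind(age = truth$covariates$age, truth$pontine)
  build_voxel_dataset(truth$noddi, vox_grid(spec$grid_shape, spec$voxel_size),
                      array(TRUE, spec$grid_shape), covariates = covars,
                      fwhm_mm = 1)
}
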