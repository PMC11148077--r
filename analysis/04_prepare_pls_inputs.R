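#!/usr/bin/env Rscript
# Stage 4 -- voxel-dataset preparation.
#
# Residualizes age and the pontine control region's microstructure (4 MPM +
# 3 NODDI means) out of every NODDI condition map by voxelwise OLS, then
# applies 1 mm FWHM masked Gaussian smoothing, producing the n x p matrices
# the PLS consumes. The confound design uses the MPM means fitted in stage
# 2, mirroring a pipeline in which the control region is measured, not
# assumed.

library(idcwm)

truth <- readRDS("results/phantom.rds")
mpm <- readRDS("results/mpm_fit.rds")
tab <- generate_subject_table(truth)

grid <- vox_grid(truth$spec$grid_shape, truth$spec$voxel_size)
wm_mask <- array(TRUE, truth$spec$grid_shape)
covars <- cbind(age = tab$age, mpm$pontine_mpm,
                truth$pontine[, paste0("pontine_", c("NDI", "ODI", "FW"))])
dataset <- build_voxel_dataset(truth$noddi, grid, wm_mask,
                               covariates = covars, fwhm_mm = 1)
saveRDS(dataset, "results/pls_dataset.rds")

r <- sapply(names(dataset$X), function(cond)
  max(abs(cor(residualize_voxelwise(dataset$X[[cond]], covars), covars))))
cat("Conditions:", paste(names(dataset$X), collapse = ", "),
    "| voxels:", length(dataset$voxel_index), "\n")
cat("Max |corr| with any confound after residualization:", signif(max(r), 3), "\n")
cat("Outputs: results/pls_dataset.rds\n")
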