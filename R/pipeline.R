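# End-to-end driver: phantom -> raw-signal map fitting on the brainstem
# slab -> ROI extraction -> voxel-dataset preparation -> PLS -> biomarker
# models. The numbered scripts under analysis/ are thin wrappers over this.

#' Fit quantitative maps for every subject's brainstem slab
#'
#' Simulates the multi-echo FLASH triplet and double-angle pair from each
#' subject's slab parameter volumes and runs the full map-estimation chain,
#' then extracts ROI means for the four nuclei and the pontine control
#' region.
#'
#' @param truth A `"phantom_truth"`.
#' @param subjects Subject indices to fit (default all).
#' @param noise_sd Additive signal noise SD (0 = noiseless).
#' @return List with `behavior` (n x 16 fitted IdC metrics), `pontine_mpm`
#'   (n x 4) and the last subject's full map set (`maps_last`).
#' @export
fit_phantom_mpm <- function(truth, subjects = seq_len(truth$spec$n_subjects),
                            noise_sd = 0) {
  slab <- truth$slab
  shp <- slab$shape
  rois <- slab$rois
  wm <- as.vector(slab$wm_mask)
  trains <- default_mpm_trains()
  B <- matrix(NA_real_, length(subjects), 16,
              dimnames = list(NULL, idc_metric_names()))
  P <- matrix(NA_real_, length(subjects), 4,
              dimnames = list(NULL, paste0("pontine_", mpm_params)))
  maps <- NULL
  for (si in seq_along(subjects)) {
    i <- subjects[si]
    params <- list(A = slab$mpm$A[i, ], R1 = slab$mpm$R1[i, ],
                   R2star = slab$mpm$R2star[i, ],
                   delta = slab$mpm$MTsat[i, ] / 100)
    sig <- simulate_flash_signals(params, trains, b1 = as.vector(slab$b1),
                                  noise_sd = noise_sd)
    dam <- simulate_dam_pair(as.vector(slab$b1), noise_sd = noise_sd)
    maps <- fit_mpm_maps(sig, dam, shp, wm, trains = trains)
    for (nuc in idc_nuclei) {
      m <- rois[[nuc]]
      B[si, paste(nuc, "R1", sep = "_")] <- extract_roi_mean(array(maps$R1, shp), m)
      B[si, paste(nuc, "MTsat", sep = "_")] <- extract_roi_mean(array(maps$MTsat, shp), m)
      B[si, paste(nuc, "R2star", sep = "_")] <- extract_roi_mean(array(maps$R2star, shp), m)
      B[si, paste(nuc, "PD", sep = "_")] <- extract_roi_mean(array(maps$PD, shp), m)
    }
    P[si, ] <- vapply(c("R1", "MTsat", "R2star", "PD"), function(par)
      extract_roi_mean(array(maps[[par]], shp), rois$pontine), 0)
  }
  list(behavior = B, pontine_mpm = P, maps_last = maps)
}

#' Fit NODDI maps from simulated raw DWI for a subject subset
#'
#' Simulates the 109-measurement three-shell acquisition from the slab's
#' NODDI ground truth and refits it with the dictionary/NNLS fitter;
#' reports recovery errors. Restricted to a subset because the per-voxel
#' NNLS fit is the costly stage of the pipeline.
#'
#' @param truth A `"phantom_truth"`.
#' @param subjects Subject indices (default first two).
#' @param noise_sd Rician noise SD relative to S0 = 1 (0 = noiseless).
#' @param scheme,grid Acquisition scheme and dictionary grid.
#' @return List with per-subject fitted maps and `errors` (median absolute
#'   NDI/ODI/FW error vs truth).
#' @export
fit_phantom_noddi <- function(truth, subjects = 1:2, noise_sd = 0,
                              scheme = default_dwi_scheme(),
                              grid = noddi_grid()) {
  slab <- truth$slab
  nd <- slab$noddi
  params <- list(f_iso = as.vector(nd$FW),
                 f_ic = pmin(pmax(as.vector(nd$NDI), 0.01), 0.99),
                 kappa = kappa_from_odi(pmin(pmax(as.vector(nd$ODI), 0.01), 0.99)),
                 mu = slab$mu)
  pts <- sphere_quadrature()
  fits <- list()
  errs <- c()
  for (i in subjects) {
    dwi <- simulate_dwi_signals(params, scheme, S0 = 1, noise_sd = noise_sd,
                                noise_model = if (noise_sd > 0) "rician" else "none",
                                points = pts)
    fit <- fit_noddi_volume(dwi, scheme, grid = grid, points = pts)
    fits[[as.character(i)]] <- fit
    errs <- rbind(errs, c(NDI = stats::median(abs(fit$NDI - params$f_ic)),
                          ODI = stats::median(abs(fit$ODI - odi_from_kappa(params$kappa))),
                          FW = stats::median(abs(fit$FW - params$f_iso))))
  }
  list(fits = fits, errors = errs)
}

#' Run the complete analysis pipeline on a phantom
#'
#' phantom -> per-subject MPM map fitting and ROI extraction on the slab ->
#' NODDI refit validation on a subject subset -> voxel-dataset preparation
#' (age + pontine residualization, 1 mm FWHM masked smoothing) ->
#' multi-condition PLS with permutation and bootstrap -> cluster-filtered
#' BSR maps -> brain-score-vs-CSF regressions with an AIC delay-interaction
#' screen.
#'
#' @param spec A [phantom_spec()].
#' @param n_perm,n_boot Permutation / bootstrap counts.
#' @param n_keep LVs carried through inference.
#' @param noddi_subjects Subjects used in the raw-DWI refit validation.
#' @param group_pls Also run the two-group (APOE4) PLS (default FALSE).
#' @param out_dir Optional output directory for the declared files.
#' @param seed Seed for the inference resampling (phantom uses `spec$seed`).
#' @return List with all stage outputs.
#' @export
run_idc_pipeline <- function(spec = phantom_spec(), n_perm = 1000,
                             n_boot = 1000, n_keep = 3, noddi_subjects = 1:2,
                             group_pls = FALSE, out_dir = NULL, seed = 1) {
  truth <- make_phantom(spec)
  table <- generate_subject_table(truth)

  mpm <- fit_phantom_mpm(truth)
  noddi_val <- fit_phantom_noddi(truth, subjects = noddi_subjects)

  grid <- vox_grid(spec$grid_shape, spec$voxel_size)
  wm_mask <- array(TRUE, spec$grid_shape)
  covars <- cbind(age = table$age, mpm$pontine_mpm,
                  truth$pontine[, paste0("pontine_", noddi_conditions)])
  dataset <- build_voxel_dataset(truth$noddi, grid, wm_mask,
                                 covariates = covars, fwhm_mm = 1)

  pls <- run_pls(mpm$behavior, dataset$X, n_perm = n_perm, n_boot = n_boot,
                 seed = seed, n_keep = n_keep)
  pls_group <- if (group_pls) {
    run_pls(mpm$behavior, dataset$X, group = truth$group, n_perm = n_perm,
            n_boot = n_boot, seed = seed, n_keep = n_keep)
  } else NULL

  cluster_masks <- lapply(seq_len(pls$decomposition$n_keep), function(l)
    bsr_threshold_clusters(pls$bootstrap$bsr[, l], dataset$voxel_index,
                           spec$grid_shape))

  # Brain-score models: for each retained LV, take its driving condition
  # (largest contribution) and regress that score on each CSF biomarker.
  stats_rows <- list()
  for (l in seq_len(pls$decomposition$n_keep)) {
    cond <- rownames(pls$contributions)[which.max(pls$contributions[, l])]
    score <- pls$brain_scores[, cond, l]
    for (bm in c("ptau181", "ab42")) {
      fit <- brainscore_biomarker_regression(score, table[[bm]], table$sex,
                                             table$education_years, m = 2)
      inter <- interaction_aic_check(score, table[[bm]], table$sex,
                                     table$education_years,
                                     table$csf_mri_delay_days)
      stats_rows[[paste(l, bm)]] <- data.frame(
        lv = l, condition = cond, biomarker = bm, beta = fit$beta, t = fit$t,
        p = fit$p, p_adj = fit$p_adj, aic = fit$aic,
        interaction_kept = inter$keep, aic_interaction = inter$aic_interaction)
    }
  }
  biomarker_models <- do.call(rbind, c(stats_rows, make.row.names = FALSE))

  res <- list(spec = spec, truth = truth, subject_table = table, mpm = mpm,
              noddi_validation = noddi_val, dataset = dataset, pls = pls,
              pls_group = pls_group, cluster_masks = cluster_masks,
              biomarker_models = biomarker_models)
  if (!is.null(out_dir)) write_pipeline_outputs(res, out_dir)
  res
}

#' Write the declared pipeline output files
#'
#' Per-LV JSON summaries (singular value, covariance percent, permutation
#' p, condition contributions), TSV brain scores, NIfTI salience / BSR /
#' cluster maps, TSV behavior-correlation bars with CI bounds, the subject
#' table, and the biomarker-model table.
#'
#' @param res Result of [run_idc_pipeline()].
#' @param out_dir Output directory.
#' @return Invisibly, the directory.
#' @export
write_pipeline_outputs <- function(res, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  dec <- res$pls$decomposition
  shp <- res$spec$grid_shape
  vs <- res$spec$voxel_size
  vidx <- res$dataset$voxel_index
  for (l in seq_len(dec$n_keep)) {
    jsonlite::write_json(list(
      lv = l, singular_value = dec$s[l], cov_pct = dec$cov_pct[l],
      perm_p = res$pls$permutation$p[l],
      contributions = as.list(res$pls$contributions[, l]),
      procrustes_in_bootstrap = res$pls$settings$procrustes_in_bootstrap,
      procrustes_in_permutation = res$pls$settings$procrustes_in_permutation),
      file.path(out_dir, sprintf("LV%d_summary.json", l)),
      auto_unbox = TRUE, digits = NA)
    sal <- array(0, shp); sal[vidx] <- dec$v[, l]
    write_nifti_volume(sal, file.path(out_dir, sprintf("LV%d_salience.nii.gz", l)), vs)
    bsr <- array(0, shp); bsr[vidx] <- res$pls$bootstrap$bsr[, l]
    bsr[!is.finite(bsr)] <- 0
    write_nifti_volume(bsr, file.path(out_dir, sprintf("LV%d_bsr.nii.gz", l)), vs)
    write_nifti_volume(res$cluster_masks[[l]] * 1,
                       file.path(out_dir, sprintf("LV%d_clusters.nii.gz", l)), vs)
    co <- res$pls$bootstrap$corr_obs[, , l]
    ci <- res$pls$bootstrap$corr_ci
    bars <- data.frame(metric = rep(rownames(co), ncol(co)),
                       condition = rep(colnames(co), each = nrow(co)),
                       r = as.vector(co),
                       ci_lo = as.vector(ci$lo[, , l]),
                       ci_hi = as.vector(ci$hi[, , l]))
    utils::write.table(bars, file.path(out_dir, sprintf("LV%d_correlations.tsv", l)),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  sc <- res$pls$brain_scores
  long <- expand.grid(subject = seq_len(dim(sc)[1]),
                      condition = dimnames(sc)[[2]], lv = dimnames(sc)[[3]])
  long$score <- as.vector(sc)
  utils::write.table(long, file.path(out_dir, "brain_scores.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(res$subject_table, file.path(out_dir, "subjects.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(res$biomarker_models)) {
    utils::write.table(res$biomarker_models, file.path(out_dir, "biomarker_models.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(out_dir)
}
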