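# Seeded synthetic cohort phantom: subject tables, NODDI condition volumes
# with planted latent covariance against the 16 IdC metrics, and a small
# brainstem slab carrying ground-truth quantitative-map volumes for the
# raw-signal simulators.

# Smooth orthonormal random voxel patterns (unit Frobenius norm columns).
make_salience_patterns <- function(n_latents, grid_shape, voxel_size) {
  p <- prod(grid_shape)
  raw <- sapply(seq_len(n_latents), function(l) {
    v <- array(stats::rnorm(p), grid_shape)
    as.vector(gaussian_smooth(v, fwhm_mm = 4 * voxel_size, voxel_size = voxel_size))
  })
  qr.Q(qr(raw))  # p x L, orthonormal columns
}

# Deterministic smooth baseline field in [mean - amp, mean + amp].
baseline_field <- function(grid_shape, mean, amp, phase = 0) {
  ax <- lapply(grid_shape, function(n) seq(0, pi, length.out = n))
  f <- outer(outer(sin(ax[[1]] + phase), cos(ax[[2]] * 1.3), `+`),
             sin(ax[[3]] * 0.7 + phase), `+`) / 3
  mean + amp * as.vector(f)
}

# Slab ROI layout: four nucleus spheres plus a pontine control sphere on the
# brainstem-slab grid (voxel units).
slab_roi_masks <- function(slab_shape, voxel_size = 1) {
  grid <- vox_grid(slab_shape, voxel_size)
  q <- function(frac) (slab_shape - 1) * frac * voxel_size
  centers <- list(
    LC  = c(q(0.25)[1], q(0.25)[2], q(0.3)[3]),
    DR  = c(q(0.75)[1], q(0.25)[2], q(0.3)[3]),
    VTA = c(q(0.25)[1], q(0.75)[2], q(0.3)[3]),
    NbM = c(q(0.75)[1], q(0.75)[2], q(0.3)[3]),
    pontine = c(q(0.5)[1], q(0.5)[2], q(0.8)[3])
  )
  radii <- c(LC = 1.6, DR = 1.6, VTA = 1.6, NbM = 1.6, pontine = 2) * voxel_size
  Map(function(cc, r) sphere_roi(grid, cc, r), centers, radii[names(centers)])
}

#' Generate a synthetic cohort phantom
#'
#' Draws a full phantom from a [phantom_spec()]: standardized latent scores,
#' smooth orthonormal voxel salience patterns, three NODDI condition maps
#' carrying the planted latent covariance, the 16-metric IdC behavior table,
#' an independent pontine control region, demographics, CSF-biomarker
#' analogs, and per-subject quantitative-parameter volumes on a small
#' brainstem slab (used by the FLASH and DWI signal simulators).
#'
#' Construction per condition c:
#' `X_c = baseline_c + map_amplitude * (g_i * Z %*% diag(strength[,c]) %*% t(V) + noise)`,
#' clipped to `[0, 1]`; `g_i` is the per-subject group multiplier. The
#' behavior block is `B = means + (Z %*% W + noise) * sds / sqrt(var)`,
#' scaled so each metric's population SD equals its target SD. Latent scores
#' are column-centered so planted effects carry no spurious mean offset.
#'
#' @param spec A [phantom_spec()].
#' @return An object of class `"phantom_truth"`; see Details in the package
#'   vignette.
#' @export
make_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  set.seed(spec$seed)
  n <- spec$n_subjects
  L <- spec$n_latents
  p <- prod(spec$grid_shape)

  # Latent scores: standard-normal draws, column-centered and mutually
  # orthogonalized (sample correlation exactly 0), unit sample SD. Exact
  # orthogonality keeps the planted axes identifiable at any seed.
  Z <- matrix(stats::rnorm(n * L), n, L)
  Z <- sweep(Z, 2, colMeans(Z))
  if (L > 1) {
    for (l in 2:L) for (k in 1:(l - 1)) {
      Z[, l] <- Z[, l] - sum(Z[, l] * Z[, k]) / sum(Z[, k]^2) * Z[, k]
    }
  }
  Z <- sweep(Z, 2, apply(Z, 2, stats::sd), `/`)

  group <- stats::rbinom(n, 1, spec$group_fraction)
  gscale <- spec$group_loading_scale[group + 1]

  V <- spec$salience_patterns
  if (is.null(V)) {
    V <- make_salience_patterns(L, spec$grid_shape, spec$voxel_size)
  } else {
    V <- sapply(V, as.vector)
    stopifnot(nrow(V) == p)
  }

  # Behavior block (IdC metrics), population-scaled to the target SDs.
  W <- spec$behavior_loadings
  raw <- Z %*% W + spec$noise_sd_behavior * matrix(stats::rnorm(n * 16), n, 16)
  tot_sd <- sqrt(colSums(W^2) + spec$noise_sd_behavior^2)
  B <- sweep(sweep(raw, 2, spec$behavior_sds / tot_sd, `*`), 2,
             spec$behavior_means, `+`)
  colnames(B) <- idc_metric_names()

  # NODDI condition maps with planted covariance.
  baselines <- list(NDI = baseline_field(spec$grid_shape, 0.60, 0.05),
                    ODI = baseline_field(spec$grid_shape, 0.35, 0.05, phase = 1),
                    FW  = baseline_field(spec$grid_shape, 0.20, 0.05, phase = 2))
  noddi <- vector("list", 3)
  names(noddi) <- noddi_conditions
  for (ci in 1:3) {
    eff <- (gscale * Z) %*% (spec$latent_strength[, ci] * t(V))
    eff <- eff + spec$noise_sd_brain * matrix(stats::rnorm(n * p), n, p)
    M <- sweep(spec$map_amplitude * eff, 2, baselines[[ci]], `+`)
    noddi[[ci]] <- pmin(pmax(M, 0), 1)
  }

  # Pontine control region: generated independent of the latents.
  pont_mpm <- sweep(sweep(matrix(stats::rnorm(n * 4), n, 4), 2,
                          default_pontine_sds(), `*`), 2,
                    default_pontine_means(), `+`)
  pont_noddi <- sweep(sweep(matrix(stats::rnorm(n * 3), n, 3), 2,
                            default_pontine_noddi_sds(), `*`), 2,
                      default_pontine_noddi_means(), `+`)
  pontine <- cbind(pont_mpm, pont_noddi)
  colnames(pontine) <- c(paste0("pontine_", mpm_params),
                         paste0("pontine_", noddi_conditions))

  covariates <- data.frame(
    age = stats::rnorm(n, 67.9, 5.3),
    sex = stats::rbinom(n, 1, 38 / 133),        # 1 = male, 0 = female
    education_years = pmax(stats::rnorm(n, 15.4, 3.5), 6),
    csf_mri_delay_days = pmax(round(stats::rnorm(n, 768, 375)), 1)
  )

  z_link <- Z[, min(2, L)]  # pTau analog tracks the second planted latent
  biomarkers <- data.frame(
    ptau181 = spec$biomarker_intercept + spec$biomarker_slope * z_link +
      spec$biomarker_noise_sd * stats::rnorm(n),
    ab42 = stats::rnorm(n, 1000, 200)
  )

  slab <- make_slab_truth(spec, B, pontine)

  truth <- list(spec = spec, latent_scores = Z, group = group,
                salience_patterns = V, noddi = noddi, baselines = baselines,
                behavior = B, pontine = pontine, covariates = covariates,
                biomarkers = biomarkers, slab = slab)
  class(truth) <- "phantom_truth"
  truth
}

# Per-subject quantitative-parameter volumes on the brainstem slab. Nucleus
# and pontine ROI voxels carry the subject's table values (plus small
# within-ROI jitter); the background is generic pontine-adjacent tissue with
# mean PD 69 p.u. so that white-matter PD calibration is self-consistent.
make_slab_truth <- function(spec, B, pontine) {
  shp <- spec$slab_shape
  pv <- prod(shp)
  rois <- slab_roi_masks(shp, spec$voxel_size)
  n <- spec$n_subjects

  bg <- list(R1 = 0.75, MTsat = 1.20, R2star = 18, PD = 69)
  # Deterministic smooth spatial texture, shared across subjects.
  tex <- baseline_field(shp, 0, 1, phase = 0.5)

  mpm <- list()
  for (pidx in seq_along(mpm_params)) {
    par <- mpm_params[pidx]
    vol <- matrix(bg[[par]] * (1 + 0.02 * tex), n, pv, byrow = TRUE)
    for (nuc in idc_nuclei) {
      idx <- which(as.vector(rois[[nuc]]))
      vol[, idx] <- B[, paste(nuc, par, sep = "_")]
    }
    idxp <- which(as.vector(rois$pontine))
    vol[, idxp] <- pontine[, paste0("pontine_", par)]
    # small within-ROI jitter so ROI voxels are not exactly constant
    vol <- vol * (1 + 0.002 * matrix(stats::rnorm(n * pv), n, pv))
    mpm[[par]] <- vol
  }
  # Signal amplitude A is proportional to PD in arbitrary units.
  mpm$A <- mpm$PD * 13

  # Smooth low-order transmit-efficiency field (within ~ +/- 6%).
  ax <- lapply(shp, function(m) seq(-1, 1, length.out = m))
  b1 <- 1 + 0.04 * as.vector(outer(outer(ax[[1]]^2 - 0.5, 0.5 * ax[[2]], `+`),
                                   0.3 * ax[[3]], `+`))
  b1 <- array(b1, shp)

  # Slab NODDI truth (subject-invariant smooth fields; the DWI simulator is
  # exercised on a per-subject basis downstream).
  noddi <- list(
    NDI = pmin(pmax(baseline_field(shp, 0.60, 0.15, phase = 0.3), 0.05), 0.95),
    ODI = pmin(pmax(baseline_field(shp, 0.35, 0.20, phase = 1.1), 0.03), 0.95),
    FW  = pmin(pmax(baseline_field(shp, 0.10, 0.08, phase = 2.2), 0), 0.6)
  )
  # Smoothly varying primary fiber direction.
  th <- baseline_field(shp, 0.5, 0.4, phase = 0.9)
  mu <- cbind(sin(th), 0.3 * cos(th), sqrt(pmax(1 - sin(th)^2 - 0.09 * cos(th)^2, 0)))
  mu <- mu / sqrt(rowSums(mu^2))

  list(shape = shp, rois = rois, mpm = mpm, b1 = b1, noddi = noddi, mu = mu,
       wm_mask = !Reduce(`|`, rois))
}

#' Assemble the per-subject feature table
#'
#' Deterministically assembles the subject table from a phantom: subject id,
#' the 16 IdC metrics, pontine control means (MPM and NODDI), demographics
#' and CSF-biomarker analogs. All stochastic draws happened in
#' [make_phantom()], so the same phantom always yields the same table.
#'
#' @param truth A `"phantom_truth"` object.
#' @return A data.frame with one row per subject.
#' @export
generate_subject_table <- function(truth) {
  stopifnot(inherits(truth, "phantom_truth"))
  data.frame(
    subject_id = sprintf("sub-%03d", seq_len(truth$spec$n_subjects)),
    truth$behavior,
    truth$pontine,
    truth$covariates,
    truth$biomarkers,
    apoe4 = truth$group,
    check.names = FALSE
  )
}

#' @export
print.phantom_truth <- function(x, ...) {
  cat("phantom_truth:", x$spec$n_subjects, "subjects,",
      paste(x$spec$grid_shape, collapse = "x"), "NODDI grid,",
      x$spec$n_latents, "planted latent(s)\n")
  invisible(x)
}

#' Write a phantom to disk
#'
#' Writes the NODDI condition maps as per-subject `.nii.gz` volumes (RAS
#' affine at the grid's voxel size), the subject table as TSV, and a JSON
#' sidecar recording the generating spec and file layout.
#'
#' @param truth A `"phantom_truth"` object.
#' @param dir Output directory (created if needed).
#' @param subjects Which subjects' volumes to write (default: all).
#' @return Invisibly, the sidecar path.
#' @export
write_phantom <- function(truth, dir, subjects = seq_len(truth$spec$n_subjects)) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  shp <- truth$spec$grid_shape
  vs <- truth$spec$voxel_size
  files <- list()
  for (cond in noddi_conditions) {
    cdir <- file.path(dir, cond)
    dir.create(cdir, showWarnings = FALSE)
    for (i in subjects) {
      f <- file.path(cdir, sprintf("sub-%03d_%s.nii.gz", i, cond))
      write_nifti_volume(array(truth$noddi[[cond]][i, ], shp), f, voxel_size = vs)
      files[[cond]] <- c(files[[cond]], f)
    }
  }
  tab <- generate_subject_table(truth)
  tab_path <- file.path(dir, "subjects.tsv")
  utils::write.table(tab, tab_path, sep = "\t", quote = FALSE, row.names = FALSE)
  sidecar <- file.path(dir, "phantom.json")
  spec <- truth$spec
  spec$salience_patterns <- NULL  # voxel-level truth lives in the R object
  jsonlite::write_json(
    list(spec = unclass(spec), subject_table = basename(tab_path),
         conditions = lapply(files, basename)),
    sidecar, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(sidecar)
}
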