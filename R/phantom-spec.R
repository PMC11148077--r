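#' @keywords internal
"_PACKAGE"

# Metric naming shared across the package: 4 nuclei x 4 MPM parameters,
# nucleus-major order. These are the 16 "behavior" variables of the PLS.
idc_nuclei <- c("LC", "DR", "VTA", "NbM")
mpm_params <- c("R1", "MTsat", "R2star", "PD")
noddi_conditions <- c("NDI", "ODI", "FW")

#' Names of the 16 isodendritic-core metrics
#'
#' Nucleus-major ordering: `LC_R1, LC_MTsat, LC_R2star, LC_PD, DR_R1, ...`.
#' All behavior blocks, saliences and loadings in the package follow this
#' ordering.
#'
#' @return Character vector of length 16.
#' @export
idc_metric_names <- function() {
  as.vector(t(outer(idc_nuclei, mpm_params, paste, sep = "_")))
}

# Cohort-scale ROI means and SDs used as generator defaults (units: R1 1/s,
# MTsat p.u., R2* 1/s, PD p.u.), nucleus-major order LC, DR, VTA, NbM.
default_behavior_means <- function() {
  c(0.61, 0.90, 15.0, 76.1,   # LC
    0.58, 0.84, 14.8, 76.1,   # DR
    0.64, 0.93, 19.0, 76.6,   # VTA
    0.65, 0.91, 24.9, 77.5)   # NbM
}

default_behavior_sds <- function() {
  c(0.03, 0.10, 2.07, 1.42,
    0.03, 0.09, 1.75, 1.38,
    0.04, 0.11, 2.54, 1.84,
    0.03, 0.07, 2.48, 1.28)
}

# Pontine control region reference values (R1, MTsat, R2*, PD), plus typical
# pontine NODDI means; the control region is generated independent of the
# planted latents by construction.
default_pontine_means <- function() c(0.79, 1.44, 20.2, 68.8)
default_pontine_sds   <- function() c(0.04, 0.12, 2.48, 1.44)
default_pontine_noddi_means <- function() c(0.55, 0.30, 0.10)
default_pontine_noddi_sds   <- function() c(0.04, 0.03, 0.02)

# Default planted behavior loadings (n_latents x 16). Latent 1 mirrors a
# global pattern driven by R1/MTsat/R2* across all nuclei; latent 2 a
# tract-specific pattern with PD loading in the opposite direction. Rows are
# orthogonalized in phantom_spec() so the two planted patterns are
# identifiable.
default_behavior_loadings <- function(n_latents) {
  l1 <- rep(c(0.70, 0.60, 0.50, -0.20), 4)
  l2 <- rep(c(0.40, 0.40, 0.30, -0.55), 4) * rep(c(1, 1, -1, -1), each = 4)
  W <- rbind(l1, l2)
  if (n_latents <= 2) return(W[seq_len(n_latents), , drop = FALSE])
  extra <- t(sapply(seq_len(n_latents - 2), function(l) {
    0.5 * sin(seq_len(16) * (l + 2))
  }))
  rbind(W, extra)
}

# Default per-latent, per-condition strengths (n_latents x 3, columns NDI,
# ODI, FW). Latent 1 is NDI-dominant, latent 2 ODI-dominant, echoing the
# condition ordering of the planted patterns the pipeline must recover.
default_latent_strength <- function(n_latents) {
  S <- rbind(c(10.0, 5.0, 1.25),
             c(2.5, 7.5, 1.25))
  if (n_latents <= 2) return(S[seq_len(n_latents), , drop = FALSE])
  rbind(S, matrix(0.5, n_latents - 2, 3))
}

#' Specification of a synthetic cohort phantom
#'
#' Defines the study conditions emulated by [make_phantom()]: cohort size,
#' voxel grid, planted latent covariance between the 16 isodendritic-core
#' (IdC) metrics and the three voxelwise NODDI condition maps, demographic
#' and CSF-biomarker distributions, and an optional two-group (APOE4-like)
#' difference in expression strength.
#'
#' Defaults emulate the cohort the pipeline was designed around: 133
#' subjects, IdC metric means/SDs at published cohort values, a 24 x 24 x 12
#' voxel grid at 1 mm (6912 in-mask voxels), two planted latents (a global
#' NDI-dominant pattern and an ODI-dominant pattern), and a pTau181 analog
#' linked to the second latent.
#'
#' @param n_subjects Number of subjects.
#' @param grid_shape Integer 3-vector, voxel counts of the NODDI grid.
#' @param voxel_size Isotropic voxel size in mm.
#' @param n_latents Number of planted latents (at most 16).
#' @param latent_strength `n_latents x 3` matrix of unitless planted
#'   strengths per condition (columns NDI, ODI, FW) on the standardized
#'   latent scale.
#' @param salience_patterns Optional list of `n_latents` voxel arrays with
#'   unit Frobenius norm; generated as smooth orthogonal random fields when
#'   `NULL`.
#' @param behavior_loadings `n_latents x 16` loadings of the latents onto the
#'   IdC metrics (rows are orthogonalized).
#' @param behavior_means,behavior_sds Length-16 means and SDs of the IdC
#'   metrics (nucleus-major order, see [idc_metric_names()]).
#' @param noise_sd_brain Unitless voxel noise SD on the standardized latent
#'   scale.
#' @param noise_sd_behavior Unitless metric noise SD on the standardized
#'   latent scale.
#' @param map_amplitude Conversion from the standardized latent scale to
#'   NODDI units: the subject-deviation field (planted effects + noise) is
#'   multiplied by this before being added to the baseline maps. Linear, so
#'   it does not change correlation structure except through range clipping.
#' @param group_fraction Proportion of subjects assigned to group "1"
#'   (APOE4+ analog).
#' @param group_loading_scale Length-2 multiplier `(group 0, group 1)` on the
#'   planted brain effects; `c(1, 1)` disables group structure.
#' @param biomarker_intercept,biomarker_slope,biomarker_noise_sd pTau181
#'   analog model: `ptau = intercept + slope * latent2 + noise` (pg/ml).
#' @param slab_shape Integer 3-vector, voxel counts of the brainstem-slab
#'   grid carrying the raw-signal (MPM / DWI) simulations.
#' @param seed Integer seed; identical seeds give identical phantoms.
#' @return An object of class `"phantom_spec"`.
#' @export
phantom_spec <- function(n_subjects = 133,
                         grid_shape = c(24, 24, 12),
                         voxel_size = 1,
                         n_latents = 2,
                         latent_strength = default_latent_strength(n_latents),
                         salience_patterns = NULL,
                         behavior_loadings = default_behavior_loadings(n_latents),
                         behavior_means = default_behavior_means(),
                         behavior_sds = default_behavior_sds(),
                         noise_sd_brain = 0.5,
                         noise_sd_behavior = 0.5,
                         map_amplitude = 0.12,
                         group_fraction = 50 / 132,
                         group_loading_scale = c(1, 1),
                         biomarker_intercept = 50,
                         biomarker_slope = 6,
                         biomarker_noise_sd = 19,
                         slab_shape = c(12, 12, 6),
                         seed = 1L) {
  if (n_latents > 16) stop("n_latents must be at most 16 (the behavior block has 16 metrics)")
  if (n_latents < 1) stop("n_latents must be at least 1")
  stopifnot(length(grid_shape) == 3, all(grid_shape >= 2),
            length(slab_shape) == 3, all(slab_shape >= 2))
  if (prod(grid_shape) < 8 * n_latents) {
    stop("grid too small to hold ", n_latents, " orthogonal salience patterns")
  }
  latent_strength <- matrix(latent_strength, n_latents, 3)
  behavior_loadings <- matrix(behavior_loadings, n_latents, 16)
  # Orthogonalize loading rows (Gram-Schmidt) so planted latents are
  # identifiable on the behavior side regardless of user input.
  if (n_latents > 1) {
    for (l in 2:n_latents) {
      for (k in 1:(l - 1)) {
        wk <- behavior_loadings[k, ]
        behavior_loadings[l, ] <- behavior_loadings[l, ] -
          sum(behavior_loadings[l, ] * wk) / sum(wk * wk) * wk
      }
    }
  }
  stopifnot(length(behavior_means) == 16, length(behavior_sds) == 16)
  if (any(behavior_sds <= 0)) stop("all behavior SDs must be > 0")
  if (noise_sd_brain < 0 || noise_sd_behavior < 0) stop("noise SDs must be >= 0")
  if (group_fraction <= 0 || group_fraction >= 1) stop("group_fraction must be in (0,1)")
  if (!is.finite(biomarker_slope)) stop("biomarker_slope must be finite")
  spec <- list(
    n_subjects = as.integer(n_subjects),
    grid_shape = as.integer(grid_shape),
    voxel_size = voxel_size,
    n_latents = as.integer(n_latents),
    latent_strength = latent_strength,
    salience_patterns = salience_patterns,
    behavior_loadings = behavior_loadings,
    behavior_means = behavior_means,
    behavior_sds = behavior_sds,
    noise_sd_brain = noise_sd_brain,
    noise_sd_behavior = noise_sd_behavior,
    map_amplitude = map_amplitude,
    group_fraction = group_fraction,
    group_loading_scale = group_loading_scale,
    biomarker_intercept = biomarker_intercept,
    biomarker_slope = biomarker_slope,
    biomarker_noise_sd = biomarker_noise_sd,
    slab_shape = as.integer(slab_shape),
    seed = as.integer(seed)
  )
  class(spec) <- "phantom_spec"
  spec
}

#' @export
print.phantom_spec <- function(x, ...) {
  cat("phantom_spec:", x$n_subjects, "subjects,",
      paste(x$grid_shape, collapse = "x"), "grid,",
      x$n_latents, "latent(s), seed", x$seed, "\n")
  invisible(x)
}
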