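# ROI construction, voxel-dataset preparation and confound removal -- the
# stages between fitted maps and the PLS.

#' Define a regular 3-D sampling grid
#'
#' Minimal RAS grid description used by the ROI and smoothing utilities:
#' voxel centers lie at `origin + (index - 1) * voxel_size` along each axis.
#'
#' @param shape Integer 3-vector of voxel counts.
#' @param voxel_size Isotropic voxel size in mm.
#' @param origin mm coordinate of the center of voxel (1,1,1).
#' @return A list with class `"vox_grid"`.
#' @export
vox_grid <- function(shape, voxel_size = 1, origin = c(0, 0, 0)) {
  stopifnot(length(shape) == 3, voxel_size > 0, length(origin) == 3)
  structure(list(shape = as.integer(shape), voxel_size = voxel_size,
                 origin = as.numeric(origin)), class = "vox_grid")
}

#' Threshold a probabilistic ROI mask
#'
#' A voxel is included iff its probability is greater than or equal to the
#' threshold (inclusive boundary).
#'
#' @param prob Numeric array of probabilities in `[0, 1]`.
#' @param thr Threshold in `(0, 1)`.
#' @param name ROI name used in error messages.
#' @return Logical array of the same shape.
#' @export
threshold_mask <- function(prob, thr, name = "ROI") {
  if (thr <= 0 || thr >= 1) stop("threshold must be in (0,1)")
  mask <- prob >= thr
  if (!any(mask)) stop("thresholding leaves ROI '", name, "' empty")
  mask
}

#' Spherical ROI on a voxel grid
#'
#' Includes every voxel whose center lies within `radius_mm` of `center_mm`.
#' With the default arguments this constructs the dorsal-raphe sphere used
#' by the pipeline: a 3 mm radius sphere around MNI (0, -30, -13).
#'
#' @param grid A [vox_grid()].
#' @param center_mm Sphere center in grid mm coordinates.
#' @param radius_mm Sphere radius in mm.
#' @return Logical array with `grid$shape` dimensions.
#' @export
sphere_roi <- function(grid, center_mm, radius_mm) {
  stopifnot(inherits(grid, "vox_grid"), radius_mm >= 0)
  ax <- lapply(1:3, function(a) grid$origin[a] + (seq_len(grid$shape[a]) - 1) * grid$voxel_size)
  dx2 <- (ax[[1]] - center_mm[1])^2
  dy2 <- (ax[[2]] - center_mm[2])^2
  dz2 <- (ax[[3]] - center_mm[3])^2
  d2 <- outer(outer(dx2, dy2, `+`), dz2, `+`)
  mask <- array(d2 <= radius_mm^2, grid$shape)
  if (!any(mask)) stop("sphere at (", paste(center_mm, collapse = ", "),
                       ") mm with radius ", radius_mm, " mm lies outside the grid")
  mask
}

#' @rdname sphere_roi
#' @param exclude Optional logical array of voxels to trim from the sphere
#'   (e.g. an aqueduct mask reducing the dorsal-raphe ROI toward ~32 mm^3).
#' @export
make_dr_sphere <- function(grid, center_mm = c(0, -30, -13), radius_mm = 3,
                           exclude = NULL) {
  m <- sphere_roi(grid, center_mm, radius_mm)
  if (!is.null(exclude)) {
    stopifnot(all(dim(exclude) == dim(m)))
    m <- m & !exclude
    if (!any(m)) stop("exclusion mask removes the whole dorsal-raphe sphere")
  }
  m
}

#' Mean of a map over an ROI
#'
#' Arithmetic mean over in-mask voxels; non-finite voxels (e.g. fit
#' failures) are excluded.
#'
#' @param volume Numeric array.
#' @param mask Logical array of the same shape.
#' @return Scalar mean.
#' @export
extract_roi_mean <- function(volume, mask) {
  stopifnot(all(dim(volume) == dim(mask)))
  v <- volume[mask]
  v <- v[is.finite(v)]
  if (length(v) == 0) stop("ROI contains no finite voxels")
  mean(v)
}

#' Group white-matter mask from per-subject masks
#'
#' A voxel is kept iff the across-subject mean of the binary masks is at
#' least `thr` (default 0.95, i.e. the voxel is white matter in at least 95%
#' of subjects; the boundary is inclusive).
#'
#' @param masks List of logical/0-1 arrays on one grid, or a subjects x
#'   voxels matrix.
#' @param thr Inclusion threshold on the across-subject mean.
#' @return Logical array (or vector if a matrix was supplied).
#' @export
build_group_wm_mask <- function(masks, thr = 0.95) {
  if (is.list(masks)) {
    if (length(masks) < 2) stop("need at least 2 subjects")
    dims <- dim(masks[[1]])
    avg <- Reduce(`+`, lapply(masks, function(m) {
      stopifnot(all(dim(m) == dims))
      m * 1
    })) / length(masks)
  } else {
    if (nrow(masks) < 2) stop("need at least 2 subjects")
    avg <- colMeans(masks * 1)
  }
  keep <- avg >= thr
  if (!any(keep)) stop("group white-matter mask is empty at threshold ", thr)
  keep
}

#' Residualize voxel data on confounds
#'
#' Ordinary least squares of every column of `X` on an intercept plus the
#' confound matrix; returns residuals (mean-centered, since the intercept is
#' removed with the fit). Used to remove age and the pontine control-region
#' microstructure (4 MPM + 3 NODDI means) from each NODDI condition matrix
#' before the PLS.
#'
#' @param X `n x p` matrix (subjects x voxels).
#' @param covariates `n x k` matrix or data.frame of confounds.
#' @return `n x p` residual matrix.
#' @export
residualize_voxelwise <- function(X, covariates) {
  X <- as.matrix(X)
  D <- cbind(intercept = 1, as.matrix(covariates))
  if (nrow(X) <= ncol(D)) stop("need more subjects than confounds + intercept")
  if (!all(is.finite(D))) stop("confounds contain non-finite values")
  qrD <- qr(D)
  if (qrD$rank < ncol(D)) {
    bad <- colnames(D)[qrD$pivot[(qrD$rank + 1):ncol(D)]]
    stop("confound matrix is rank deficient; collinear columns: ",
         paste(bad, collapse = ", "))
  }
  X - qr.fitted(qrD, X)
}

# 1-D Gaussian kernel sampled at voxel offsets, truncated at 3 sigma.
gaussian_kernel_1d <- function(fwhm_mm, voxel_size) {
  sigma_vox <- fwhm_mm / sqrt(8 * log(2)) / voxel_size
  if (sigma_vox == 0) return(1)
  r <- max(1L, ceiling(3 * sigma_vox))
  k <- exp(-((-r):r)^2 / (2 * sigma_vox^2))
  k / sum(k)
}

# Convolve a 3-D array with a 1-D kernel along one axis (zero padding).
conv_axis <- function(vol, k, axis) {
  r <- (length(k) - 1L) / 2L
  if (r == 0) return(vol * k)
  out <- array(0, dim(vol))
  n <- dim(vol)[axis]
  for (o in -r:r) {
    w <- k[o + r + 1L]
    src <- seq_len(n) + o
    ok <- src >= 1L & src <= n
    idx_dst <- which(ok)
    idx_src <- src[ok]
    if (axis == 1) out[idx_dst, , ] <- out[idx_dst, , ] + w * vol[idx_src, , ]
    else if (axis == 2) out[, idx_dst, ] <- out[, idx_dst, ] + w * vol[, idx_src, ]
    else out[, , idx_dst] <- out[, , idx_dst] + w * vol[, , idx_src]
  }
  out
}

#' Masked separable Gaussian smoothing
#'
#' Separable Gaussian with `sigma = fwhm / sqrt(8 log 2)` per axis. When a
#' mask is given, kernel weights are renormalized over in-mask voxels (the
#' standard smooth(volume x mask) / smooth(mask) construction), so a
#' constant volume stays constant inside the mask and no signal bleeds in
#' from outside. `fwhm_mm = 0` is the identity.
#'
#' @param volume Numeric 3-D array.
#' @param fwhm_mm Full width at half maximum of the kernel, mm.
#' @param voxel_size Voxel size in mm.
#' @param mask Optional logical array.
#' @return Smoothed array (NA outside the mask when a mask is given).
#' @export
gaussian_smooth <- function(volume, fwhm_mm = 1, voxel_size = 1, mask = NULL) {
  if (fwhm_mm < 0) stop("fwhm must be >= 0")
  if (fwhm_mm == 0) return(volume)
  k <- gaussian_kernel_1d(fwhm_mm, voxel_size)
  sm <- function(v) conv_axis(conv_axis(conv_axis(v, k, 1), k, 2), k, 3)
  if (is.null(mask)) {
    num <- sm(volume)
    den <- sm(array(1, dim(volume)))  # renormalize at the grid edge
    return(num / den)
  }
  m <- array(as.numeric(mask), dim(volume))
  v0 <- volume
  v0[!mask] <- 0
  out <- sm(v0) / sm(m)
  out[!mask] <- NA_real_
  out
}

#' Assemble the voxel dataset for the PLS
#'
#' Smooths and residualizes each condition map and flattens it over the
#' group white-matter mask, producing the `n x p` matrices the PLS consumes.
#' Order of operations follows the pipeline: residualize confounds first,
#' then smooth within the mask.
#'
#' @param condition_maps Named list (NDI, ODI, FW) of `n x p_grid` matrices,
#'   voxels in array order of `grid`.
#' @param grid A [vox_grid()] describing the map grid.
#' @param wm_mask Logical array, the group white-matter mask.
#' @param covariates Confounds passed to [residualize_voxelwise()], or NULL
#'   to skip residualization.
#' @param fwhm_mm Smoothing kernel FWHM in mm (0 disables).
#' @return List with `X` (named list of `n x p` matrices over in-mask
#'   voxels), `voxel_index` (in-mask linear indices into the grid), `grid`
#'   and `wm_mask`.
#' @export
build_voxel_dataset <- function(condition_maps, grid, wm_mask,
                                covariates = NULL, fwhm_mm = 1) {
  stopifnot(inherits(grid, "vox_grid"))
  idx <- which(wm_mask)
  X <- lapply(condition_maps, function(M) {
    M <- as.matrix(M)
    stopifnot(ncol(M) == prod(grid$shape))
    if (!is.null(covariates)) M <- residualize_voxelwise(M, covariates)
    if (fwhm_mm > 0) {
      M <- t(apply(M, 1, function(row) {
        sm <- gaussian_smooth(array(row, grid$shape), fwhm_mm,
                              grid$voxel_size, mask = wm_mask)
        sm[idx]
      }))
    } else {
      M <- M[, idx, drop = FALSE]
    }
    M
  })
  bad <- unique(unlist(lapply(X, function(M) which(!is.finite(colSums(M))))))
  if (length(bad) > 0) {
    idx <- idx[-bad]
    X <- lapply(X, function(M) M[, -bad, drop = FALSE])
  }
  list(X = X, voxel_index = idx, grid = grid, wm_mask = wm_mask)
}
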