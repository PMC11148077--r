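# Quantitative map estimation from multi-echo FLASH triplets: joint
# log-linear R2* (ESTATICS) with one WLS reweighting pass, double-angle B1
# mapping with polynomial smoothing, the dual-flip-angle rational solution
# for R1 and amplitude, MT saturation, and white-matter PD calibration.

#' Joint multi-contrast R2* estimation (ESTATICS, WLS1)
#'
#' Fits, per voxel, the joint log-linear model
#' `ln S_c(TE) = ln S0_c - R2* TE` with one shared R2* across the three
#' contrasts and a TE = 0 intercept per contrast. The first pass is ordinary
#' least squares on the log signals; a single reweighting pass then solves
#' weighted least squares with weights equal to the squared model-predicted
#' signals (the WLS1 scheme), which undoes the log-transform noise
#' distortion.
#'
#' @param signals Named list per contrast of `n_voxel x n_echo` matrices.
#' @param trains List of [echo_train()]s matching `signals` by contrast.
#' @param mask Optional logical vector of voxels to fit.
#' @return List with `S0` (named list per contrast, TE = 0 intercepts on the
#'   natural scale) and `R2star` (1/s). Voxels with any non-positive signal
#'   are returned as NaN.
#' @export
fit_estatics <- function(signals, trains, mask = NULL) {
  contrasts <- vapply(trains, function(t) t$contrast, "")
  stopifnot(all(contrasts %in% names(signals)))
  te <- unlist(lapply(trains, function(t) t$echo_times_ms / 1000))
  if (length(te) < 2) stop("need at least 2 echoes across contrasts")
  if (length(unique(te)) == 1) stop("singular design: all echo times equal")
  cidx <- rep(seq_along(trains), vapply(trains, function(t) length(t$echo_times_ms), 1L))
  nC <- length(trains)
  Ind <- matrix(0, length(te), nC)
  Ind[cbind(seq_along(te), cidx)] <- 1
  X <- cbind(Ind, -te)
  colnames(X) <- c(contrasts, "R2star")

  Y <- do.call(cbind, signals[contrasts])      # n_voxel x n_meas
  nv <- nrow(Y)
  if (is.null(mask)) mask <- rep(TRUE, nv)
  valid <- mask & apply(Y > 0, 1, all) & apply(is.finite(Y), 1, all)

  beta <- matrix(NaN, nv, nC + 1)
  if (any(valid)) {
    logY <- log(Y[valid, , drop = FALSE])
    qrX <- qr(X)
    b_ols <- t(qr.coef(qrX, t(logY)))          # OLS pass, shared design
    # One reweighting pass; weights = squared predicted signals.
    pred2 <- exp(2 * (b_ols %*% t(X)))
    b_wls <- b_ols
    vidx <- which(valid)
    for (j in seq_along(vidx)) {
      w <- pred2[j, ]
      Xw <- X * w
      b_wls[j, ] <- solve(crossprod(Xw, X), crossprod(Xw, logY[j, ]))
    }
    beta[valid, ] <- b_wls
  }
  S0 <- lapply(seq_len(nC), function(ci) exp(beta[, ci]))
  names(S0) <- contrasts
  list(S0 = S0, R2star = beta[, nC + 1])
}

# Monomial design of total degree <= order on normalized coordinates.
# Per-axis degree is capped at the number of distinct coordinate values
# minus one, which keeps the design full rank on thin grids.
poly3d_design <- function(coords, order, axis_max = rep(order, 3)) {
  terms <- expand.grid(i = 0:min(order, axis_max[1]),
                       j = 0:min(order, axis_max[2]),
                       k = 0:min(order, axis_max[3]))
  terms <- terms[rowSums(terms) <= order, , drop = FALSE]
  D <- matrix(1, nrow(coords), nrow(terms))
  for (t in seq_len(nrow(terms))) {
    D[, t] <- coords[, 1]^terms$i[t] * coords[, 2]^terms$j[t] * coords[, 3]^terms$k[t]
  }
  D
}

#' Transmit-field (B1) map by the double-angle method
#'
#' The raw relative transmit efficiency is
#' `f = arccos(clamp(S_2a / (2 S_a), -1, 1)) / alpha_nominal`. A 3-D
#' polynomial surface of total degree `poly_order` (default 6) is then
#' least-squares fitted to the raw values within the mask and evaluated
#' everywhere, giving a smooth field robust to voxel noise.
#'
#' @param S_alpha,S_2alpha Signal arrays/vectors of the two acquisitions.
#' @param alpha_deg Nominal flip of the first acquisition, degrees, in
#'   (0, 90).
#' @param grid_shape Integer 3-vector (voxel layout of the vectors).
#' @param mask Optional logical vector; voxels with `S_alpha <= 0` are
#'   always excluded from the surface fit.
#' @param poly_order Total degree of the smoothing polynomial.
#' @return List with `f` (smoothed field, vector over the grid) and
#'   `raw` (voxelwise estimates, NaN where excluded).
#' @export
estimate_b1_dam <- function(S_alpha, S_2alpha, alpha_deg = 60, grid_shape,
                            mask = NULL, poly_order = 6) {
  if (alpha_deg <= 0 || alpha_deg >= 90) stop("alpha must be in (0, 90) degrees")
  a <- alpha_deg * pi / 180
  S1 <- as.vector(S_alpha); S2 <- as.vector(S_2alpha)
  nv <- length(S1)
  if (is.null(mask)) mask <- rep(TRUE, nv)
  ok <- mask & S1 > 0 & is.finite(S1) & is.finite(S2)
  raw <- rep(NaN, nv)
  raw[ok] <- acos(pmin(pmax(S2[ok] / (2 * S1[ok]), -1), 1)) / a

  idx <- arrayInd(seq_len(nv), grid_shape)
  coords <- sweep(sweep(idx, 2, (grid_shape + 1) / 2), 2,
                  pmax(grid_shape - 1, 1) / 2, `/`)
  axis_max <- apply(coords, 2, function(v) length(unique(v))) - 1L
  ord <- poly_order
  repeat {
    D <- poly3d_design(coords, ord, axis_max)
    if (sum(ok) >= ncol(D) || ord == 0) break
    ord <- ord - 1  # degenerate masks: drop to a degree the data supports
  }
  if (sum(ok) < ncol(D)) stop("too few valid voxels for B1 surface fit")
  coef <- qr.coef(qr(D[ok, , drop = FALSE]), raw[ok])
  f <- as.vector(D %*% coef)
  list(f = f, raw = raw)
}

#' R1 and amplitude from dual-flip-angle TE = 0 intercepts
#'
#' Solves the 2 x 2 system of the rational FLASH approximation
#' `S_c = A a_c TR_c R1 / (a_c^2/2 + TR_c R1)` for the T1- and PD-weighted
#' intercepts, with effective angles `a_c = b1 * nominal`:
#' `R1 = (S_T1 a_T1 / TR_T1 - S_PD a_PD / TR_PD) / (2 (S_PD / a_PD - S_T1 / a_T1))`,
#' and A by back-substitution into the PD-weighted equation.
#'
#' @param S0_T1w,S0_PDw TE = 0 intercept vectors from [fit_estatics()].
#' @param t1_train,pd_train The corresponding [echo_train()]s.
#' @param b1 Relative transmit efficiency per voxel (nominal 1).
#' @return List with vectors `R1` (1/s) and `A` (signal units). Non-physical
#'   signal pairs (denominator or R1 <= 0) give NaN.
#' @export
compute_r1_a <- function(S0_T1w, S0_PDw, t1_train = echo_train("T1w"),
                         pd_train = echo_train("PDw"), b1 = 1) {
  nv <- length(S0_T1w)
  b1 <- rep_len(b1, nv)
  a1 <- b1 * t1_train$flip_deg * pi / 180
  a2 <- b1 * pd_train$flip_deg * pi / 180
  num <- S0_T1w * a1 / t1_train$TR - S0_PDw * a2 / pd_train$TR
  den <- 2 * (S0_PDw / a2 - S0_T1w / a1)
  R1 <- num / den
  bad <- !is.finite(R1) | den <= 0 | R1 <= 0
  R1[bad] <- NaN
  A <- S0_PDw * (a2^2 / 2 + pd_train$TR * R1) / (a2 * pd_train$TR * R1)
  A[bad] <- NaN
  list(R1 = R1, A = A)
}

#' Magnetization-transfer saturation
#'
#' `delta = (A a / S_MT - 1) R1 TR - a^2 / 2` with the effective MT flip
#' `a = b1 * nominal`, followed by the empirical transmit-field correction
#' `delta_corr = delta (1 - C) / (1 - C b1)` with `C = 0.4`. Returned in
#' percent units (`delta * 100`).
#'
#' @param S0_MTw TE = 0 intercept vector of the MT-weighted train.
#' @param A,R1 Outputs of [compute_r1_a()].
#' @param mt_train The MT-weighted [echo_train()].
#' @param b1 Relative transmit efficiency per voxel.
#' @param corr_C Empirical B1-correction constant.
#' @return MTsat vector in percent units; NaN where `S0_MTw <= 0` or
#'   upstream maps are invalid.
#' @export
compute_mtsat <- function(S0_MTw, A, R1, mt_train = echo_train("MTw"),
                          b1 = 1, corr_C = 0.4) {
  nv <- length(S0_MTw)
  b1 <- rep_len(b1, nv)
  a <- b1 * mt_train$flip_deg * pi / 180
  delta <- (A * a / S0_MTw - 1) * R1 * mt_train$TR - a^2 / 2
  delta[S0_MTw <= 0 | !is.finite(S0_MTw)] <- NaN
  delta_corr <- delta * (1 - corr_C) / (1 - corr_C * b1)
  100 * delta_corr
}

#' Calibrate proton density to percent units
#'
#' `PD = A * target / mean(A over the white-matter mask)`; the receive
#' field is assumed uniform or already corrected.
#'
#' @param A Amplitude vector/array.
#' @param wm_mask Logical white-matter mask (same layout).
#' @param target Calibration target for mean white-matter PD, percent units.
#' @return PD in percent units.
#' @export
calibrate_pd <- function(A, wm_mask, target = 69) {
  v <- A[wm_mask]
  v <- v[is.finite(v)]
  if (length(v) == 0) stop("white-matter mask contains no finite amplitude values")
  m <- mean(v)
  if (m <= 0) stop("mean white-matter amplitude is not positive")
  A * (target / m)
}

#' Full quantitative-map fit from simulated or loaded signals
#'
#' Convenience wrapper running the whole map-estimation chain: double-angle
#' B1 surface fit, ESTATICS, R1/A, MTsat and PD calibration.
#'
#' @param signals Named list per contrast of `n_voxel x n_echo` matrices.
#' @param dam List with `S_alpha`, `S_2alpha` (see [simulate_dam_pair()]).
#' @param grid_shape Integer 3-vector.
#' @param wm_mask Logical vector used for PD calibration.
#' @param trains List of [echo_train()]s.
#' @param dam_alpha_deg Nominal first flip of the B1 pair.
#' @param mask Optional logical vector of voxels to fit.
#' @param corr_C,pd_target Passed to [compute_mtsat()] / [calibrate_pd()].
#' @return List of vectors `R1`, `A`, `MTsat`, `R2star`, `PD`, plus `b1`.
#' @export
fit_mpm_maps <- function(signals, dam, grid_shape, wm_mask,
                         trains = default_mpm_trains(), dam_alpha_deg = 60,
                         mask = NULL, corr_C = 0.4, pd_target = 69) {
  b1 <- estimate_b1_dam(dam$S_alpha, dam$S_2alpha, dam_alpha_deg,
                        grid_shape, mask = mask)$f
  est <- fit_estatics(signals, trains, mask = mask)
  tr <- stats::setNames(trains, vapply(trains, function(t) t$contrast, ""))
  ra <- compute_r1_a(est$S0$T1w, est$S0$PDw, tr$T1w, tr$PDw, b1 = b1)
  mtsat <- compute_mtsat(est$S0$MTw, ra$A, ra$R1, tr$MTw, b1 = b1, corr_C = corr_C)
  pd <- calibrate_pd(ra$A, wm_mask, target = pd_target)
  list(R1 = ra$R1, A = ra$A, MTsat = mtsat, R2star = est$R2star, PD = pd, b1 = b1)
}
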