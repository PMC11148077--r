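# Watson-dispersion NODDI forward model (intra-neurite sticks, tortuosity
# extracellular tensor, isotropic ball) and a desk-scale dictionary/NNLS
# fitter in the spirit of linearized (AMICO-style) microstructure fitting.
#
# Fixed diffusivities follow the canonical model: d_par = 1.7, d_iso = 3.0
# um^2/ms. b-values are converted from s/mm^2 to ms/um^2 internally
# (b = 1000 s/mm^2 <-> 1.0 ms/um^2).

D_PAR <- 1.7
D_ISO <- 3.0

#' Orientation dispersion index from Watson concentration
#'
#' `ODI = (2/pi) arctan(1/kappa)`; the inverse is exact.
#'
#' @param kappa Watson concentration parameter, > 0.
#' @param odi Orientation dispersion index in (0, 1].
#' @return The transformed value(s).
#' @export
odi_from_kappa <- function(kappa) {
  if (any(kappa <= 0)) stop("kappa must be > 0")
  (2 / pi) * atan(1 / kappa)
}

#' @rdname odi_from_kappa
#' @export
kappa_from_odi <- function(odi) {
  if (any(odi <= 0 | odi > 1)) stop("ODI must be in (0, 1]")
  1 / tan(pi * odi / 2)
}

#' Deterministic spherical quadrature point set
#'
#' Fibonacci-lattice points on the unit sphere with equal weights: a fixed,
#' reproducible quadrature used by every Watson integral in the package (no
#' runtime randomness in the forward model).
#'
#' @param n Number of points (default 1000).
#' @return `n x 3` matrix of unit vectors.
#' @export
sphere_quadrature <- function(n = 1000) {
  i <- seq_len(n) - 0.5
  phi <- pi * (1 + sqrt(5)) * i
  z <- 1 - 2 * i / n
  r <- sqrt(pmax(1 - z^2, 0))
  cbind(r * cos(phi), r * sin(phi), z)
}

# Normalized Watson(mu, kappa) density weights over the quadrature points.
watson_weights <- function(mu, kappa, points) {
  t2 <- (points %*% mu)^2
  w <- exp(kappa * (t2 - max(t2)))
  as.vector(w / sum(w))
}

#' Multi-shell diffusion scheme
#'
#' @param bvals b-values in s/mm^2.
#' @param bvecs `n x 3` gradient directions; unit vectors for b > 0
#'   (tolerance 1e-6), ignored for b = 0.
#' @return List of class `"dwi_scheme"` with `bvals`, `bvecs` and `b_msum2`
#'   (b in ms/um^2).
#' @export
dwi_scheme <- function(bvals, bvecs) {
  bvecs <- matrix(bvecs, ncol = 3)
  stopifnot(length(bvals) == nrow(bvecs))
  if (!any(bvals == 0)) stop("scheme must contain at least one b = 0 measurement")
  if (any(bvals < 0)) stop("negative b-values are not allowed")
  nrm <- sqrt(rowSums(bvecs^2))
  bad <- bvals > 0 & abs(nrm - 1) > 1e-6
  if (any(bad)) stop("non-unit gradient direction(s) at measurement(s) ",
                     paste(utils::head(which(bad), 5), collapse = ", "))
  structure(list(bvals = bvals, bvecs = bvecs, b_msum2 = bvals / 1000),
            class = "dwi_scheme")
}

#' Default 109-measurement three-shell scheme
#'
#' 9 b = 0, 7 b = 300, 29 b = 1000 and 64 b = 2000 s/mm^2 measurements with
#' deterministic, approximately isotropically spaced directions per shell.
#'
#' @return A [dwi_scheme()].
#' @export
default_dwi_scheme <- function() {
  shells <- c(0, 300, 1000, 2000)
  counts <- c(9, 7, 29, 64)
  bvals <- rep(shells, counts)
  dirs <- lapply(seq_along(shells), function(si) {
    if (shells[si] == 0) return(matrix(0, counts[si], 3))
    # rotate each shell's lattice a little so shells do not share directions
    pts <- sphere_quadrature(counts[si])
    th <- si * 0.7
    R <- rbind(c(cos(th), -sin(th), 0), c(sin(th), cos(th), 0), c(0, 0, 1))
    pts %*% R
  })
  dwi_scheme(bvals, do.call(rbind, dirs))
}

#' Predict the normalized NODDI signal for one voxel
#'
#' `S/S0 = (1 - f_iso) (f_ic A_ic + (1 - f_ic) A_ec) + f_iso exp(-b d_iso)`.
#' The intra-neurite term `A_ic` is the Watson-weighted spherical average of
#' stick attenuations `exp(-b d_par (g . n)^2)` over the fixed quadrature;
#' the extracellular term is an axially symmetric tensor with
#' `d_parallel = d_par`, `d_perp = d_par (1 - f_ic)` (tortuosity), its axis
#' dispersion-averaged with the same Watson weights.
#'
#' @param f_iso Free-water (isotropic) fraction in `[0, 1]`.
#' @param f_ic Intra-neurite fraction of the tissue compartment, `[0, 1]`.
#' @param kappa Watson concentration, > 0.
#' @param mu Unit fiber direction (3-vector).
#' @param scheme A [dwi_scheme()].
#' @param points Quadrature point set from [sphere_quadrature()].
#' @return Vector of `S/S0` per measurement.
#' @export
predict_noddi_signal <- function(f_iso, f_ic, kappa, mu, scheme,
                                 points = sphere_quadrature()) {
  stopifnot(inherits(scheme, "dwi_scheme"))
  stopifnot(f_iso >= 0, f_iso <= 1, f_ic >= 0, f_ic <= 1, kappa > 0)
  mu <- mu / sqrt(sum(mu^2))
  b <- scheme$b_msum2
  G <- scheme$bvecs
  w <- watson_weights(mu, kappa, points)
  gn2 <- (G %*% t(points))^2                        # n_meas x n_quad
  A_ic <- as.vector(exp(-(b * D_PAR) * gn2) %*% w)
  tau <- sum(w * (points %*% mu)^2)                  # <(mu . n)^2> under Watson
  t2 <- as.vector((G %*% mu)^2)
  d_perp <- D_PAR * (1 - f_ic)
  # g' <D> g for the Watson-averaged axially symmetric tensor
  gDg <- d_perp + (D_PAR - d_perp) * ((1 - tau) / 2 + (3 * tau - 1) / 2 * t2)
  A_ec <- exp(-b * gDg)
  S <- (1 - f_iso) * (f_ic * A_ic + (1 - f_ic) * A_ec) + f_iso * exp(-b * D_ISO)
  S[b == 0] <- 1
  S
}

#' Principal fiber direction by log-linear tensor fit
#'
#' Fits a diffusion tensor to the log-signals of all measurements with
#' b <= 1000 s/mm^2 (plus b = 0) and returns the principal eigenvector,
#' oriented to positive z (ties: positive y, then x). Near-degenerate
#' tensors (relative gap between the two largest eigenvalues below `tol`)
#' fall back to the most-attenuated gradient direction and are flagged.
#'
#' @param signals Positive signal vector (one voxel, all measurements).
#' @param scheme A [dwi_scheme()].
#' @param tol Relative eigenvalue-gap threshold for degeneracy.
#' @return List with unit 3-vector `mu` and logical `degenerate`.
#' @export
estimate_direction <- function(signals, scheme, tol = 1e-6) {
  sel <- scheme$bvals <= 1000
  if (sum(scheme$bvals > 0 & sel) < 6) stop("need at least 6 b > 0 directions")
  b <- scheme$b_msum2[sel]
  G <- scheme$bvecs[sel, , drop = FALSE]
  s <- signals[sel]
  ok <- s > 0 & is.finite(s)
  X <- cbind(1, -b * G[, 1]^2, -b * G[, 2]^2, -b * G[, 3]^2,
             -2 * b * G[, 1] * G[, 2], -2 * b * G[, 1] * G[, 3],
             -2 * b * G[, 2] * G[, 3])
  beta <- qr.coef(qr(X[ok, , drop = FALSE]), log(s[ok]))
  D <- matrix(c(beta[2], beta[5], beta[6],
                beta[5], beta[3], beta[7],
                beta[6], beta[7], beta[4]), 3, 3)
  e <- eigen(D, symmetric = TRUE)
  gap <- (e$values[1] - e$values[2]) / max(abs(e$values[1]), .Machine$double.eps)
  if (!is.finite(gap) || gap < tol) {
    bsel <- scheme$bvals > 0
    att <- signals[bsel]
    mu <- scheme$bvecs[bsel, , drop = FALSE][which.min(att), ]
    return(list(mu = orient_mu(mu), degenerate = TRUE))
  }
  list(mu = orient_mu(e$vectors[, 1]), degenerate = FALSE)
}

orient_mu <- function(mu) {
  mu <- mu / sqrt(sum(mu^2))
  s <- sign(mu[3])
  if (s == 0) s <- sign(mu[2])
  if (s == 0) s <- sign(mu[1])
  if (s < 0) mu <- -mu
  mu
}

#' Dictionary grid for the NODDI fit
#'
#' `f_ic` values equally spaced on `[0.05, 0.95]` and kappa values spaced
#' equally in ODI.
#'
#' @param n_fic,n_odi Grid sizes (default 12 x 12).
#' @param odi_range Range of the ODI grid.
#' @return List with vectors `f_ic`, `odi`, `kappa` and the expanded
#'   `atoms` data.frame (one row per tissue atom).
#' @export
noddi_grid <- function(n_fic = 12, n_odi = 12, odi_range = c(0.03, 0.95)) {
  f_ic <- seq(0.05, 0.95, length.out = n_fic)
  odi <- seq(odi_range[1], odi_range[2], length.out = n_odi)
  atoms <- expand.grid(f_ic = f_ic, odi = odi)
  list(f_ic = f_ic, odi = odi, kappa = kappa_from_odi(odi), atoms = atoms)
}

# Tissue dictionary for one voxel orientation: n_meas x n_atom matrix built
# with exactly the same quadrature as predict_noddi_signal.
noddi_dictionary <- function(mu, scheme, grid, points, gn2 = NULL) {
  b <- scheme$b_msum2
  G <- scheme$bvecs
  if (is.null(gn2)) gn2 <- (G %*% t(points))^2
  E <- exp(-(b * D_PAR) * gn2)                       # n_meas x n_quad
  W <- sapply(grid$kappa, function(k) watson_weights(mu, k, points))
  A_ic_k <- E %*% W                                  # n_meas x n_odi
  tau_k <- as.vector(t(W) %*% (points %*% mu)^2)
  t2 <- as.vector((G %*% mu)^2)
  n_atom <- nrow(grid$atoms)
  M <- matrix(0, length(b), n_atom)
  for (a in seq_len(n_atom)) {
    fic <- grid$atoms$f_ic[a]
    ki <- match(grid$atoms$odi[a], grid$odi)
    d_perp <- D_PAR * (1 - fic)
    gDg <- d_perp + (D_PAR - d_perp) * ((1 - tau_k[ki]) / 2 + (3 * tau_k[ki] - 1) / 2 * t2)
    M[, a] <- fic * A_ic_k[, ki] + (1 - fic) * exp(-b * gDg)
  }
  M[b == 0, ] <- 1
  M
}

#' Fit NODDI maps by dictionary NNLS
#'
#' Per voxel: estimate the fiber direction ([estimate_direction()]), build
#' the tissue dictionary on the `(f_ic, ODI)` grid plus one isotropic ball
#' atom, and solve nonnegative least squares with a Tikhonov penalty
#' `lambda` on the atom weights. NDI and ODI are the tissue-weight-weighted
#' means of the atoms' `f_ic` and ODI; FW is the ball atom's weight share.
#'
#' @param dwi `n_voxel x n_meas` signal matrix.
#' @param scheme A [dwi_scheme()].
#' @param mask Optional logical vector of voxels to fit.
#' @param grid A [noddi_grid()].
#' @param lambda Tikhonov penalty on atom weights (default 1e-3).
#' @param points Quadrature point set.
#' @param mu Optional `n_voxel x 3` matrix of known fiber directions,
#'   bypassing the per-voxel tensor estimate (used when the orientation is
#'   available from ground truth or an upstream model).
#' @return List of vectors `NDI`, `ODI`, `FW` (NaN outside the mask or where
#'   S0 <= 0), plus `degenerate` flags from the direction estimate.
#' @export
fit_noddi_volume <- function(dwi, scheme, mask = NULL, grid = noddi_grid(),
                             lambda = 1e-3, points = sphere_quadrature(),
                             mu = NULL) {
  stopifnot(inherits(scheme, "dwi_scheme"))
  nv <- nrow(dwi)
  if (is.null(mask)) mask <- rep(TRUE, nv)
  b0 <- scheme$bvals == 0
  gn2 <- (scheme$bvecs %*% t(points))^2
  n_atom <- nrow(grid$atoms)
  ball <- exp(-scheme$b_msum2 * D_ISO)
  reg <- diag(sqrt(lambda), n_atom + 1)
  NDI <- ODI <- FW <- rep(NaN, nv)
  degen <- rep(NA, nv)
  for (v in which(mask)) {
    s <- dwi[v, ]
    S0 <- mean(s[b0])
    if (!is.finite(S0) || S0 <= 0) next
    sn <- s / S0
    if (is.null(mu)) {
      dir <- tryCatch(estimate_direction(pmax(sn, 1e-6), scheme),
                      error = function(e) NULL)
      if (is.null(dir)) next
    } else {
      dir <- list(mu = mu[v, ] / sqrt(sum(mu[v, ]^2)), degenerate = FALSE)
    }
    M <- cbind(noddi_dictionary(dir$mu, scheme, grid, points, gn2), ball)
    C <- rbind(M, reg)
    d <- c(sn, rep(0, n_atom + 1))
    w <- pracma::lsqnonneg(C, d)$x
    tot <- sum(w)
    if (tot <= 0) next
    wt <- w[seq_len(n_atom)]
    FW[v] <- w[n_atom + 1] / tot
    st <- sum(wt)
    if (st > 0) {
      NDI[v] <- sum(wt * grid$atoms$f_ic) / st
      ODI[v] <- sum(wt * grid$atoms$odi) / st
    } else {
      NDI[v] <- 0; ODI[v] <- 0                      # pure free-water voxel
    }
    degen[v] <- dir$degenerate
  }
  list(NDI = NDI, ODI = ODI, FW = FW, degenerate = degen)
}

#' Simulate multi-shell DWI signals from NODDI ground truth
#'
#' Per voxel, the normalized forward signal from [predict_noddi_signal()]
#' scaled by `S0`, with optional Gaussian or Rician (magnitude of complex
#' Gaussian) noise.
#'
#' @param params Data.frame/list with per-voxel `f_iso`, `f_ic`, `kappa` and
#'   an `n_voxel x 3` matrix `mu`.
#' @param scheme A [dwi_scheme()].
#' @param S0 Non-diffusion-weighted signal per voxel (scalar or vector).
#' @param noise_sd Noise SD on the S0 scale.
#' @param noise_model One of `"none"`, `"gaussian"`, `"rician"`.
#' @param points Quadrature point set.
#' @return `n_voxel x n_meas` signal matrix.
#' @export
simulate_dwi_signals <- function(params, scheme, S0 = 1, noise_sd = 0,
                                 noise_model = c("none", "gaussian", "rician"),
                                 points = sphere_quadrature()) {
  noise_model <- match.arg(noise_model)
  nv <- length(params$f_ic)
  S0 <- rep_len(S0, nv)
  mu <- matrix(params$mu, ncol = 3)
  out <- matrix(0, nv, length(scheme$bvals))
  for (v in seq_len(nv)) {
    out[v, ] <- S0[v] * predict_noddi_signal(params$f_iso[v], params$f_ic[v],
                                             params$kappa[v], mu[v, ], scheme,
                                             points)
  }
  if (noise_model == "gaussian" && noise_sd > 0) {
    out <- out + matrix(stats::rnorm(length(out), sd = noise_sd), nv)
  } else if (noise_model == "rician" && noise_sd > 0) {
    re <- out + matrix(stats::rnorm(length(out), sd = noise_sd), nv)
    im <- matrix(stats::rnorm(length(out), sd = noise_sd), nv)
    out <- sqrt(re^2 + im^2)
  }
  out
}
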