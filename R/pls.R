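# Multi-condition (and multi-group) behavioral PLS correlation. The
# behavior block holds the 16 IdC metrics; each NODDI map (NDI, ODI, FW) is
# a separate condition sharing one voxel-salience map per latent variable.
# Conditions (and groups) are stacked on the behavior side of the
# crossblock correlation matrix, which is decomposed by SVD; inference is
# by row permutation (LV significance) and subject bootstrap with
# procrustes alignment (voxel reliability and correlation CIs).

#' Z-score the columns of a matrix
#'
#' Mean 0, SD 1 (denominator `n - 1`).
#'
#' @param M Numeric matrix with at least 3 rows.
#' @return The standardized matrix.
#' @export
standardize_columns <- function(M) {
  M <- as.matrix(M)
  if (nrow(M) < 3) stop("need at least 3 rows to standardize")
  sds <- apply(M, 2, stats::sd)
  if (any(sds == 0 | !is.finite(sds))) {
    bad <- which(sds == 0 | !is.finite(sds))
    nm <- colnames(M)[bad] %||% as.character(bad)
    stop("zero-variance column(s): ", paste(nm, collapse = ", "))
  }
  Z <- scale(M, center = TRUE, scale = sds)
  attr(Z, "scaled:center") <- NULL
  attr(Z, "scaled:scale") <- NULL
  Z
}

# Split subjects into groups (single "all" group when group is NULL).
split_groups <- function(n, group) {
  if (is.null(group)) return(list(all = seq_len(n)))
  stopifnot(length(group) == n)
  idx <- split(seq_len(n), group)
  if (any(lengths(idx) < 10)) stop("each group needs at least 10 subjects")
  idx
}

#' Stacked crossblock correlation matrix
#'
#' For each group g and condition c, the Pearson correlation matrix
#' `corr(B_g, X_{c,g})` (16 x p), stacked group-major then condition-major
#' into a `(G x C x 16) x p` matrix. A single-group three-condition model
#' yields 48 x p.
#'
#' @param B `n x 16` behavior block.
#' @param X Named list of `n x p` condition matrices.
#' @param group Optional group labels (length n).
#' @return The stacked matrix with attribute `blocks` (data.frame with
#'   `group`, `condition`, `metric` per row).
#' @export
stack_crossblock <- function(B, X, group = NULL) {
  B <- as.matrix(B)
  gidx <- split_groups(nrow(B), group)
  rows <- list()
  blocks <- list()
  for (g in names(gidx)) {
    for (cond in names(X)) {
      R_gc <- suppressWarnings(
        stats::cor(B[gidx[[g]], , drop = FALSE],
                   X[[cond]][gidx[[g]], , drop = FALSE]))
      if (anyNA(R_gc)) {
        bad <- which(is.na(R_gc), arr.ind = TRUE)[1, ]
        stop("NaN correlation for metric ", rownames(R_gc)[bad[1]] %||% bad[1],
             " vs voxel column ", bad[2],
             " (zero variance?) in group ", g, ", condition ", cond)
      }
      rows[[paste(g, cond)]] <- R_gc
      blocks[[paste(g, cond)]] <- data.frame(
        group = g, condition = cond,
        metric = colnames(B) %||% paste0("m", 1:ncol(B)))
    }
  }
  R <- do.call(rbind, rows)
  attr(R, "blocks") <- do.call(rbind, c(blocks, make.row.names = FALSE))
  R
}

#' Singular value decomposition into latent variables
#'
#' Thin SVD `R = U S V'`; latent variables are ordered by singular value.
#' Sign convention: each pair `(u_l, v_l)` is jointly flipped so the voxel
#' salience of largest magnitude is positive.
#'
#' @param R Stacked crossblock matrix.
#' @param n_keep Number of LVs to retain (default: all).
#' @return List with `s` (all singular values), `u` (`nrow(R) x n_keep`),
#'   `v` (`p x n_keep`), `cov_pct` (percent crossblock covariance per LV,
#'   all LVs) and the block structure.
#' @export
pls_decompose <- function(R, n_keep = NULL) {
  if (!all(is.finite(R))) stop("crossblock matrix contains non-finite values")
  K <- min(dim(R))
  n_keep <- min(n_keep %||% K, K)
  sv <- svd(R, nu = n_keep, nv = n_keep)
  u <- sv$u; v <- sv$v
  for (l in seq_len(n_keep)) {
    j <- which.max(abs(v[, l]))
    if (v[j, l] < 0) { v[, l] <- -v[, l]; u[, l] <- -u[, l] }
  }
  cov_pct <- if (all(sv$d == 0)) rep(NaN, length(sv$d)) else covariance_fraction(sv$d)
  list(s = sv$d, u = u, v = v, cov_pct = cov_pct,
       blocks = attr(R, "blocks"), n_keep = n_keep)
}

#' Percent crossblock covariance per latent variable
#'
#' `100 s_l^2 / sum(s^2)`.
#'
#' @param s Singular values.
#' @return Percentages summing to 100.
#' @export
covariance_fraction <- function(s) {
  if (length(s) == 0 || all(s == 0)) stop("all singular values are zero")
  100 * s^2 / sum(s^2)
}

#' Subject brain scores
#'
#' `score_{i,c,l}` is the dot product of subject i's standardized voxel data
#' in condition c with the voxel saliences of LV l.
#'
#' @param X Named list of `n x p` condition matrices (standardized
#'   internally).
#' @param v `p x L` voxel saliences.
#' @return Array `n x C x L` with condition and LV dimnames.
#' @export
compute_brain_scores <- function(X, v) {
  v <- as.matrix(v)
  n <- nrow(X[[1]])
  out <- array(NA_real_, c(n, length(X), ncol(v)),
               dimnames = list(NULL, names(X), paste0("LV", seq_len(ncol(v)))))
  for (ci in seq_along(X)) {
    M <- as.matrix(X[[ci]])
    if (ncol(M) != nrow(v)) stop("voxel dimension mismatch between X and v")
    # zero-variance columns contribute 0 (centered, not rescaled)
    sds <- apply(M, 2, stats::sd)
    Xz <- scale(M, center = TRUE, scale = pmax(sds, .Machine$double.eps))
    out[, ci, ] <- Xz %*% v
  }
  out
}

#' Permutation test of latent-variable significance
#'
#' Permutes subject rows of the behavior block (within group when grouped)
#' against all condition blocks jointly, recomputes the stacked crossblock
#' matrix and its singular values, and counts exceedances per LV position:
#' `p_l = (#(s_l^perm >= s_l^obs) + 1) / (n_perm + 1)`.
#'
#' @param B,X,group As in [stack_crossblock()].
#' @param n_perm Number of permutations (>= 100).
#' @param seed Integer seed.
#' @param n_keep Number of LV p-values to return.
#' @return List with `p` (per LV), `s_obs`, and `n_perm`.
#' @export
pls_permutation <- function(B, X, group = NULL, n_perm = 1000, seed = 1,
                            n_keep = NULL) {
  if (n_perm < 100) stop("n_perm must be at least 100")
  B <- as.matrix(B)
  n <- nrow(B)
  gidx <- split_groups(n, group)
  # Per-group standardized blocks: permutation of rows within a group leaves
  # column means/SDs unchanged, so correlations reduce to cross-products.
  gdat <- lapply(gidx, function(ii) {
    list(Bz = standardize_columns(B[ii, , drop = FALSE]),
         Xz = lapply(X, function(M) standardize_columns(M[ii, , drop = FALSE])),
         n = length(ii))
  })
  svals <- function(perms) {
    Rg <- lapply(names(gdat), function(g) {
      d <- gdat[[g]]
      Bp <- d$Bz[perms[[g]], , drop = FALSE]
      do.call(rbind, lapply(d$Xz, function(Xz) crossprod(Bp, Xz) / (d$n - 1)))
    })
    R <- do.call(rbind, Rg)
    ev <- eigen(tcrossprod(R), symmetric = TRUE, only.values = TRUE)$values
    sqrt(pmax(ev[seq_len(min(dim(R)))], 0))
  }
  ident <- lapply(gdat, function(d) seq_len(d$n))
  s_obs <- svals(ident)
  K <- min(n_keep %||% length(s_obs), length(s_obs))
  set.seed(seed)
  count <- numeric(K)
  for (i in seq_len(n_perm)) {
    perms <- lapply(gdat, function(d) sample.int(d$n))
    s_p <- svals(perms)
    count <- count + (s_p[seq_len(K)] >= s_obs[seq_len(K)])
  }
  list(p = (count + 1) / (n_perm + 1), s_obs = s_obs, n_perm = n_perm)
}

# Orthogonal procrustes rotation aligning columns of Ustar to U.
procrustes_rotation <- function(Ustar, U) {
  sv <- svd(crossprod(Ustar, U))
  sv$u %*% t(sv$v)
}

#' Bootstrap reliability of saliences and behavior correlations
#'
#' Resamples subjects with replacement (within group when grouped),
#' recomputes the crossblock SVD, aligns each resample to the original
#' solution by an orthogonal procrustes rotation of the behavior saliences
#' (guarding against axis reordering/reflection between resamples), and
#' accumulates: bootstrap ratios `BSR_l(voxel) = v_l / SD_boot(v_l)` and
#' 2.5/97.5 percentile CIs of the correlations between each behavior metric
#' and the brain scores, per condition and LV. Resamples with fewer than 3
#' distinct subjects in a group are redrawn (counted in `n_redrawn`).
#'
#' @param B,X,group As in [stack_crossblock()].
#' @param n_boot Number of bootstrap resamples (>= 100).
#' @param seed Integer seed.
#' @param n_keep Number of LVs to track.
#' @param procrustes Apply the alignment (default TRUE; disabling exposes
#'   axis swapping between resamples).
#' @return List with `bsr` (`p x n_keep`; +/-Inf where the bootstrap SD is
#'   zero), `v_sd`, `corr_obs`, `corr_ci` (arrays metric x condition x LV
#'   with `lo`/`hi`), and `n_redrawn`.
#' @export
pls_bootstrap <- function(B, X, group = NULL, n_boot = 1000, seed = 1,
                          n_keep = 3, procrustes = TRUE) {
  if (n_boot < 100) stop("n_boot must be at least 100")
  B <- as.matrix(B)
  n <- nrow(B)
  gidx <- split_groups(n, group)
  R_obs <- stack_crossblock(B, X, group)
  dec <- pls_decompose(R_obs, n_keep = n_keep)
  K <- dec$n_keep
  p <- ncol(R_obs)
  scores_obs <- compute_brain_scores(X, dec$v)
  corr_obs <- behavior_score_corr(B, scores_obs)

  v_sum <- matrix(0, p, K); v_sum2 <- matrix(0, p, K)
  corr_draws <- array(NA_real_, c(n_boot, dim(corr_obs)))
  n_redrawn <- 0L
  set.seed(seed)
  for (bi in seq_len(n_boot)) {
    repeat {
      idx <- unlist(lapply(gidx, function(ii) sample(ii, length(ii), replace = TRUE)),
                    use.names = FALSE)
      if (!all(vapply(gidx, function(ii)
        length(unique(intersect(idx, ii))) >= 3, TRUE))) {
        n_redrawn <- n_redrawn + 1L
        next
      }
      Bb <- B[idx, , drop = FALSE]
      Xb <- lapply(X, function(M) M[idx, , drop = FALSE])
      groupb <- if (is.null(group)) NULL else group[idx]
      # zero-variance columns in a resample also trigger a redraw
      Rb <- tryCatch(stack_crossblock(Bb, Xb, groupb), error = function(e) NULL)
      if (!is.null(Rb)) break
      n_redrawn <- n_redrawn + 1L
    }
    svb <- svd(Rb, nu = K, nv = K)
    Ub <- svb$u; Vb <- svb$v
    if (procrustes) {
      rot <- procrustes_rotation(Ub[, seq_len(K), drop = FALSE],
                                 dec$u[, seq_len(K), drop = FALSE])
      Ub <- Ub %*% rot
      Vb <- Vb %*% rot
    } else {
      # sign-only convention, no reordering protection
      for (l in seq_len(K)) {
        j <- which.max(abs(Vb[, l]))
        if (Vb[j, l] < 0) { Vb[, l] <- -Vb[, l]; Ub[, l] <- -Ub[, l] }
      }
    }
    v_sum <- v_sum + Vb
    v_sum2 <- v_sum2 + Vb^2
    scores_b <- compute_brain_scores(Xb, Vb)
    corr_draws[bi, , , ] <- behavior_score_corr(Bb, scores_b)
  }
  v_sd <- sqrt(pmax(v_sum2 / n_boot - (v_sum / n_boot)^2, 0))
  bsr <- dec$v / v_sd
  bsr[v_sd == 0] <- sign(dec$v[v_sd == 0]) * Inf
  ci <- apply(corr_draws, c(2, 3, 4), stats::quantile,
              probs = c(0.025, 0.975), na.rm = TRUE)
  lo <- array(ci[1, , , ], dim(corr_obs), dimnames = dimnames(corr_obs))
  hi <- array(ci[2, , , ], dim(corr_obs), dimnames = dimnames(corr_obs))
  list(bsr = bsr, v_sd = v_sd, corr_obs = corr_obs,
       corr_ci = list(lo = lo, hi = hi),
       n_boot = n_boot, n_redrawn = n_redrawn)
}

# Correlations of each behavior metric with each (condition, LV) brain score.
behavior_score_corr <- function(B, scores) {
  n_c <- dim(scores)[2]; n_l <- dim(scores)[3]
  out <- array(NA_real_, c(ncol(B), n_c, n_l),
               dimnames = list(colnames(B), dimnames(scores)[[2]],
                               dimnames(scores)[[3]]))
  for (ci in seq_len(n_c)) out[, ci, ] <- stats::cor(B, scores[, ci, ])
  out
}

#' Threshold bootstrap ratios and filter small clusters
#'
#' Keeps voxels with `|BSR| > bsr_thr`, labels connected components
#' separately for positive and negative signs (26-neighbor connectivity by
#' default) and drops components smaller than `min_cluster` voxels.
#'
#' @param bsr BSR values over in-mask voxels.
#' @param voxel_index Linear grid indices of those voxels.
#' @param grid_shape Integer 3-vector.
#' @param bsr_thr Reliability threshold (default 2).
#' @param min_cluster Minimum cluster size in voxels (default 32).
#' @param connectivity 6, 18 or 26.
#' @return Logical array over the grid: reliable voxels in surviving
#'   clusters.
#' @export
bsr_threshold_clusters <- function(bsr, voxel_index, grid_shape, bsr_thr = 2,
                                   min_cluster = 32, connectivity = 26) {
  vol <- array(0, grid_shape)
  vol[voxel_index] <- bsr
  keep <- array(FALSE, grid_shape)
  for (sgn in c(1, -1)) {
    mask <- array(sgn * vol > bsr_thr, grid_shape)
    if (!any(mask)) next
    lab <- label_components(mask, connectivity)
    sizes <- tabulate(lab[lab > 0])
    ok <- which(sizes >= min_cluster)
    if (length(ok) > 0) keep <- keep | array(lab %in% ok, grid_shape)
  }
  keep
}

# Connected-component labeling of a 3-D logical mask (iterative BFS).
label_components <- function(mask, connectivity = 26) {
  dims <- dim(mask)
  offs <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  nz <- rowSums(abs(offs))
  offs <- switch(as.character(connectivity),
                 "6" = offs[nz == 1, , drop = FALSE],
                 "18" = offs[nz >= 1 & nz <= 2, , drop = FALSE],
                 "26" = offs[nz >= 1, , drop = FALSE],
                 stop("connectivity must be 6, 18 or 26"))
  lab <- array(0L, dims)
  cur <- 0L
  todo <- which(mask)
  queue <- integer(length(todo))
  for (start in todo) {
    if (lab[start] != 0L) next
    cur <- cur + 1L
    lab[start] <- cur
    queue[1] <- start
    qn <- 1L
    while (qn > 0L) {
      lin <- queue[qn]; qn <- qn - 1L
      co <- arrayInd(lin, dims)[1, ]
      for (oi in seq_len(nrow(offs))) {
        nb <- co + offs[oi, ]
        if (any(nb < 1L) || any(nb > dims)) next
        nlin <- nb[1] + dims[1] * (nb[2] - 1L + dims[2] * (nb[3] - 1L))
        if (mask[nlin] && lab[nlin] == 0L) {
          lab[nlin] <- cur
          qn <- qn + 1L
          if (qn > length(queue)) queue <- c(queue, integer(length(queue)))
          queue[qn] <- nlin
        }
      }
    }
  }
  lab
}

#' Condition contributions to a latent variable
#'
#' Sums the absolute behavior saliences ("design scores") over the 16
#' metrics within each NODDI condition (across groups, when grouped) and
#' expresses them as percentages of the total.
#'
#' @param u Behavior salience vector of one LV.
#' @param blocks Block structure (from [pls_decompose()]).
#' @return Named percentage vector, one entry per condition.
#' @export
condition_contributions <- function(u, blocks) {
  stopifnot(length(u) == nrow(blocks))
  tot <- c(tapply(abs(u), blocks$condition, sum))
  tot <- tot[unique(blocks$condition)]
  100 * tot / sum(tot)
}

#' Run the full PLS analysis
#'
#' Crossblock stacking, SVD, permutation test, bootstrap, condition
#' contributions and brain scores in one call.
#'
#' @param B `n x 16` behavior block (IdC metrics).
#' @param X Named list of `n x p` condition matrices (NDI, ODI, FW).
#' @param group Optional group labels.
#' @param n_perm,n_boot Permutation / bootstrap counts.
#' @param seed Integer seed (permutation and bootstrap use derived seeds).
#' @param n_keep Number of LVs to carry through inference.
#' @return List of class `"pls_result"`.
#' @export
run_pls <- function(B, X, group = NULL, n_perm = 1000, n_boot = 1000,
                    seed = 1, n_keep = 3) {
  R <- stack_crossblock(B, X, group)
  dec <- pls_decompose(R, n_keep = n_keep)
  perm <- pls_permutation(B, X, group, n_perm = n_perm, seed = seed,
                          n_keep = dec$n_keep)
  boot <- pls_bootstrap(B, X, group, n_boot = n_boot, seed = seed + 1,
                        n_keep = dec$n_keep)
  contrib <- sapply(seq_len(dec$n_keep), function(l)
    condition_contributions(dec$u[, l], dec$blocks))
  scores <- compute_brain_scores(X, dec$v)
  structure(list(decomposition = dec, permutation = perm, bootstrap = boot,
                 contributions = contrib, brain_scores = scores,
                 settings = list(n_perm = n_perm, n_boot = n_boot, seed = seed,
                                 procrustes_in_bootstrap = TRUE,
                                 procrustes_in_permutation = FALSE)),
            class = "pls_result")
}

#' @export
print.pls_result <- function(x, ...) {
  K <- x$decomposition$n_keep
  cat("PLS correlation:", K, "LV(s) tracked\n")
  for (l in seq_len(K)) {
    cat(sprintf("  LV%d: %.1f%% crossblock covariance, perm p = %.4g\n",
                l, x$decomposition$cov_pct[l], x$permutation$p[l]))
  }
  invisible(x)
}
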