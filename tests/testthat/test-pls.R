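test_that("column standardization is exact, idempotent, and guards variance", {
  M <- cbind(a = c(1, 2, 3), b = c(5, 1, 3))
  Z <- standardize_columns(M)
  expect_equal(unname(Z[, "a"]), c(-1, 0, 1))
  expect_equal(unname(standardize_columns(Z)), unname(Z), tolerance = 1e-12)
  expect_error(standardize_columns(cbind(a = 1:3, k = rep(2, 3))), "k")
})

test_that("crossblock entries are Pearson correlations with exact limits", {
  set.seed(41)
  n <- 50
  B <- matrix(rnorm(n * 16), n, 16, dimnames = list(NULL, idc_metric_names()))
  X <- list(NDI = cbind(B[, 3], matrix(rnorm(n * 9), n, 9)),
            ODI = matrix(rnorm(n * 10), n, 10),
            FW = matrix(rnorm(n * 10), n, 10))
  R <- stack_crossblock(B, X)
  expect_equal(dim(R), c(48L, 10L))
  expect_equal(unname(R[3, 1]), 1, tolerance = 1e-12)   # behavior column == voxel column
  blocks <- attr(R, "blocks")
  expect_equal(blocks$condition, rep(c("NDI", "ODI", "FW"), each = 16))
  # two identical groups give identical group blocks
  B2 <- rbind(B, B); X2 <- lapply(X, function(M) rbind(M, M))
  g <- rep(c("a", "b"), each = n)
  R2 <- stack_crossblock(B2, X2, group = g)
  expect_equal(unname(R2[1:48, ]), unname(R2[49:96, ]), tolerance = 1e-12)
  # zero-variance voxel is reported
  Xbad <- X; Xbad$NDI[, 2] <- 5
  expect_error(stack_crossblock(B, Xbad), "NaN correlation")
})

test_that("independent blocks yield null-scale correlations", {
  set.seed(42)
  n <- 1000
  B <- matrix(rnorm(n * 16), n, 16)
  X <- list(NDI = matrix(rnorm(n * 200), n, 200))
  R <- stack_crossblock(B, X)
  expect_gt(mean(abs(R) < 0.11), 0.998)  # Fisher bound at n = 1000
  expect_lt(max(abs(R)), 0.2)
})

test_that("decomposition matches rank-1 algebra and the eigen oracle", {
  # rank-1: R = a b' has a single singular value ||a|| ||b||
  a <- c(3, -1, 2); b <- c(1, 2, 2, 4)
  dec <- pls_decompose(a %*% t(b))
  expect_equal(dec$s[1], sqrt(sum(a^2)) * sqrt(sum(b^2)), tolerance = 1e-12)
  expect_lt(max(abs(dec$s[-1])), 1e-12)
  expect_equal(abs(dec$u[, 1]), abs(a) / sqrt(sum(a^2)), tolerance = 1e-12)
  expect_equal(abs(dec$v[, 1]), abs(b) / sqrt(sum(b^2)), tolerance = 1e-12)
  # sign convention: the largest-magnitude voxel salience is positive
  expect_gt(dec$v[which.max(abs(dec$v[, 1])), 1], 0)
  # all-zero matrix: all singular values zero
  dec0 <- pls_decompose(matrix(0, 4, 6))
  expect_true(all(dec0$s == 0))
  # eigen oracle on a random instance
  set.seed(43)
  R <- matrix(rnorm(48 * 120), 48, 120)
  dec <- pls_decompose(R)
  ev <- eigen(crossprod(R), symmetric = TRUE)
  expect_equal(dec$s, sqrt(pmax(ev$values[1:48], 0)), tolerance = 1e-8)
})

test_that("covariance fractions normalize squared singular values", {
  expect_equal(covariance_fraction(c(2, 1, 1)), c(400, 100, 100) / 6,
               tolerance = 1e-12)
  expect_equal(covariance_fraction(c(3, 0)), c(100, 0))
  expect_error(covariance_fraction(c(0, 0)), "zero")
  set.seed(44)
  s <- abs(rnorm(10))
  expect_equal(sum(covariance_fraction(s)), 100, tolerance = 1e-9)
})

test_that("brain scores are projections of z-scored voxel data", {
  set.seed(45)
  X <- list(NDI = matrix(rnorm(9 * 4), 9, 4))
  v <- matrix(0, 4, 1); v[2, 1] <- 1
  sc <- compute_brain_scores(X, v)
  expect_equal(unname(sc[, 1, 1]), unname(standardize_columns(X$NDI)[, 2]),
               tolerance = 1e-12)
  # hand-computed 3 x 2 example
  Xh <- list(A = matrix(c(1, 2, 3, 2, 0, 4), 3, 2))
  vh <- matrix(c(0.6, 0.8), 2, 1)
  Zh <- standardize_columns(Xh$A)
  expect_equal(unname(compute_brain_scores(Xh, vh)[, 1, 1]),
               unname(Zh %*% vh)[, 1], tolerance = 1e-12)
  # zero matrix gives zero scores
  expect_true(all(compute_brain_scores(list(NDI = matrix(0, 5, 3)), matrix(1 / sqrt(3), 3, 1)) == 0))
})

test_that("sum of squared singular values equals the Frobenius norm", {
  tr <- make_phantom(small_spec(seed = 46, n_subjects = 30))
  R <- stack_crossblock(tr$behavior, tr$noddi)
  s <- svd(R, nu = 0, nv = 0)$d
  expect_equal(sum(s^2), sum(R^2), tolerance = 1e-8)
})

test_that("relabeling subjects identically in all blocks changes nothing", {
  tr <- make_phantom(small_spec(seed = 47, n_subjects = 25))
  perm <- sample(25)
  R1 <- stack_crossblock(tr$behavior, tr$noddi)
  R2 <- stack_crossblock(tr$behavior[perm, ], lapply(tr$noddi, function(M) M[perm, ]))
  expect_equal(R1, R2, tolerance = 1e-12)
})

test_that("permutation p-values use the add-one counting rule", {
  # strong planted signal: observed LV1 should beat every permutation
  spec <- small_spec(seed = 48, n_subjects = 60)
  tr <- make_phantom(spec)
  perm <- pls_permutation(tr$behavior, tr$noddi, n_perm = 199, seed = 5)
  expect_equal(perm$p[1], 1 / 200)
  expect_true(all(perm$p >= 1 / 200 & perm$p <= 1))
  expect_error(pls_permutation(tr$behavior, tr$noddi, n_perm = 50), "at least 100")
  # reproducible under the same seed
  perm2 <- pls_permutation(tr$behavior, tr$noddi, n_perm = 199, seed = 5)
  expect_identical(perm$p, perm2$p)
})

test_that("bootstrap flags reliable voxels and deterministic correlations", {
  set.seed(49)
  n <- 60
  z <- rnorm(n)
  B <- matrix(rnorm(n * 16), n, 16, dimnames = list(NULL, idc_metric_names()))
  # half the metrics express the latent: voxel 1 of NDI is deterministically
  # tied to the same latent, so its salience has near-zero resampling variance
  for (k in 1:8) B[, k] <- z + 0.05 * rnorm(n)
  X <- list(NDI = cbind(z + 0.01 * rnorm(n), matrix(rnorm(n * 10), n, 10)),
            ODI = matrix(rnorm(n * 11), n, 11),
            FW = matrix(rnorm(n * 11), n, 11))
  bs <- pls_bootstrap(B, X, n_boot = 200, seed = 3, n_keep = 2)
  # the tied voxel dominates LV1 and resamples agree on it
  expect_gt(abs(bs$bsr[1, 1]), 10)
  # deterministic linear pair: CI for corr(B1, NDI score) excludes 0
  lo <- bs$corr_ci$lo[1, "NDI", 1]; hi <- bs$corr_ci$hi[1, "NDI", 1]
  expect_gt(lo * hi, 0)
  expect_gt(abs(bs$corr_obs[1, "NDI", 1]), 0.9)
})

test_that("procrustes alignment stabilizes near-degenerate latent pairs", {
  # two planted latents with equal strength: resamples can swap the axes
  spec <- small_spec(seed = 50, n_subjects = 60,
                     latent_strength = rbind(c(5, 5, 1), c(5, 5, 1)) * 0.8)
  tr <- make_phantom(spec)
  X <- tr$noddi
  al <- pls_bootstrap(tr$behavior, X, n_boot = 120, seed = 7, n_keep = 2,
                      procrustes = TRUE)
  un <- pls_bootstrap(tr$behavior, X, n_boot = 120, seed = 7, n_keep = 2,
                      procrustes = FALSE)
  expect_lt(mean(al$v_sd), mean(un$v_sd))
})

test_that("cluster filtering enforces the 32-voxel floor and sign splitting", {
  shp <- c(12, 12, 6)
  vol <- array(0, shp)
  vol[1:8, 1:4, 1] <- 3                     # 32-voxel positive blob -> kept
  vol[1:8, 1:4, 3] <- 3; vol[8, 4, 3] <- 0  # 31 voxels -> removed
  keep <- bsr_threshold_clusters(as.vector(vol), seq_len(prod(shp)), shp)
  expect_equal(sum(keep[, , 1]), 32)
  expect_equal(sum(keep[, , 3]), 0)
  # all sub-threshold: empty
  expect_equal(sum(bsr_threshold_clusters(rep(1.5, prod(shp)),
                                          seq_len(prod(shp)), shp)), 0)
  # touching blobs of opposite sign are separate clusters
  v2 <- array(0, shp)
  v2[1:8, 1:4, 1] <- 3         # 32 positive
  v2[1:8, 5:8, 1] <- -3        # 32 negative, touching the first
  k2 <- bsr_threshold_clusters(as.vector(v2), seq_len(prod(shp)), shp,
                               min_cluster = 32)
  expect_equal(sum(k2), 64)
  k3 <- bsr_threshold_clusters(as.vector(v2), seq_len(prod(shp)), shp,
                               min_cluster = 33)
  expect_equal(sum(k3), 0)     # neither sign reaches 33 alone
})

test_that("condition contributions partition absolute saliences", {
  blocks <- data.frame(group = "all",
                       condition = rep(c("NDI", "ODI", "FW"), each = 16),
                       metric = rep(idc_metric_names(), 3))
  u <- rep(0, 48); u[1:16] <- 1 / 4
  expect_equal(unname(condition_contributions(u, blocks)),
               c(100, 0, 0))
  u2 <- rep(c(1, -1), 24) / sqrt(48)
  expect_equal(unname(condition_contributions(u2, blocks)),
               rep(100 / 3, 3), tolerance = 1e-12)
})

test_that("planted condition strengths order the contributions", {
  ords <- sapply(1:10, function(seed) {
    spec <- small_spec(seed = seed, n_subjects = 60,
                       latent_strength = rbind(c(6, 2, 0), c(1, 5, 0.5)))
    tr <- make_phantom(spec)
    dec <- pls_decompose(stack_crossblock(tr$behavior, tr$noddi), n_keep = 2)
    cc <- condition_contributions(dec$u[, 1], dec$blocks)
    all(cc["NDI"] > cc["ODI"], cc["ODI"] > cc["FW"])
  })
  expect_gt(mean(ords), 0.85)
})

test_that("the matched latent pair dominates brain-score correlations", {
  tr <- make_phantom(small_spec(seed = 52, n_subjects = 80))
  dec <- pls_decompose(stack_crossblock(tr$behavior, tr$noddi), n_keep = 2)
  sc <- compute_brain_scores(tr$noddi, dec$v)
  # LV1 scores track latent 1 more than latent 2 and vice versa
  c11 <- abs(stats::cor(sc[, "NDI", 1], tr$latent_scores[, 1]))
  c12 <- abs(stats::cor(sc[, "NDI", 1], tr$latent_scores[, 2]))
  c22 <- abs(stats::cor(sc[, "ODI", 2], tr$latent_scores[, 2]))
  c21 <- abs(stats::cor(sc[, "ODI", 2], tr$latent_scores[, 1]))
  expect_gt(c11, c12)
  expect_gt(c22, c21)
})

test_that("grouped PLS runs end to end with per-group blocks", {
  spec <- small_spec(seed = 53, n_subjects = 60, group_fraction = 0.5,
                     group_loading_scale = c(0.5, 1.5))
  tr <- make_phantom(spec)
  res <- run_pls(tr$behavior, tr$noddi, group = tr$group, n_perm = 100,
                 n_boot = 100, seed = 2, n_keep = 2)
  expect_equal(nrow(res$decomposition$blocks), 96L)
  expect_true(all(res$permutation$p > 0 & res$permutation$p <= 1))
  expect_s3_class(res, "pls_result")
  expect_output(print(res), "crossblock covariance")
})
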