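sch <- default_dwi_scheme()
pts <- sphere_quadrature()

test_that("ODI/kappa transform and its inverse are exact", {
  expect_equal(odi_from_kappa(1), 0.5, tolerance = 1e-12)
  expect_equal(odi_from_kappa(0.1), 2 / pi * atan(10), tolerance = 1e-12)
  expect_lt(odi_from_kappa(1e6), 1e-5)
  ks <- c(0.05, 0.5, 1, 3, 10, 100)
  expect_equal(kappa_from_odi(odi_from_kappa(ks)), ks, tolerance = 1e-12)
  expect_error(odi_from_kappa(0), "kappa")
  expect_error(kappa_from_odi(0), "ODI")
})

test_that("scheme validation enforces b0 presence and unit directions", {
  expect_error(dwi_scheme(c(300, 1000), matrix(c(1, 0, 0, 0, 1, 0), 2, byrow = TRUE)),
               "b = 0")
  expect_error(dwi_scheme(c(0, 1000), rbind(c(0, 0, 0), c(2, 0, 0))), "non-unit")
  expect_error(dwi_scheme(c(0, -5), rbind(c(0, 0, 0), c(1, 0, 0))), "negative")
  expect_equal(table(sch$bvals), table(rep(c(0, 300, 1000, 2000), c(9, 7, 29, 64))))
})

test_that("forward signal obeys its limiting cases", {
  # b = 0 normalization
  s <- predict_noddi_signal(0.2, 0.6, 2, c(0, 0, 1), sch, pts)
  expect_true(all(s[sch$bvals == 0] == 1))
  expect_true(all(s > 0 & s <= 1))
  # pure ball at b = 1000: exp(-3)
  s_ball <- predict_noddi_signal(1, 0.5, 1, c(0, 0, 1), sch, pts)
  expect_equal(unique(round(s_ball[sch$bvals == 1000], 10)),
               exp(-3), tolerance = 1e-8)
  # near-coherent stick perpendicular to the gradient barely attenuates
  sch_perp <- dwi_scheme(c(0, 2000), rbind(c(0, 0, 0), c(1, 0, 0)))
  s_stick <- predict_noddi_signal(0, 1, 64, c(0, 0, 1), sch_perp, pts)
  expect_gt(s_stick[2], 0.95)   # residual dispersion at kappa = 64 costs ~2.6%
  # dense-quadrature oracle agrees
  s_dense <- predict_noddi_signal(0, 1, 64, c(0, 0, 1), sch_perp,
                                  sphere_quadrature(10000))
  expect_equal(s_stick[2], s_dense[2], tolerance = 0.002)
})

test_that("signal is monotone non-increasing in b for fixed geometry", {
  bgrid <- seq(0, 3000, by = 250)
  g <- c(1, 1, 1) / sqrt(3)
  schm <- dwi_scheme(bgrid, rbind(c(0, 0, 0), matrix(rep(g, length(bgrid) - 1),
                                                     ncol = 3, byrow = TRUE)))
  for (par in list(c(0.1, 0.7, 3), c(0, 0.3, 0.5), c(0.5, 0.9, 20))) {
    s <- predict_noddi_signal(par[1], par[2], par[3], c(0, 0, 1), schm, pts)
    expect_true(all(diff(s) <= 1e-12))
  }
})

test_that("direction estimation finds sticks and flags isotropy", {
  p1 <- list(f_iso = 0, f_ic = 0.7, kappa = kappa_from_odi(0.08),
             mu = matrix(c(0, 0, 1), 1))
  d1 <- simulate_dwi_signals(p1, sch, points = pts)
  e1 <- estimate_direction(d1[1, ], sch)
  expect_false(e1$degenerate)
  expect_lt(acos(min(abs(sum(e1$mu * c(0, 0, 1))), 1)) * 180 / pi, 2)
  # rotational equivariance
  th <- 0.7
  R <- rbind(c(1, 0, 0), c(0, cos(th), -sin(th)), c(0, sin(th), cos(th)))
  p2 <- p1; p2$mu <- matrix(c(0, 0, 1) %*% t(R), 1)
  d2 <- simulate_dwi_signals(p2, sch, points = pts)
  e2 <- estimate_direction(d2[1, ], sch)
  expect_lt(acos(min(abs(sum(e2$mu * p2$mu)), 1)) * 180 / pi, 2)
  # isotropic voxel falls back with a flag
  iso <- list(f_iso = 1, f_ic = 0.5, kappa = 1, mu = matrix(c(0, 0, 1), 1))
  di <- simulate_dwi_signals(iso, sch, points = pts)
  expect_true(estimate_direction(di[1, ], sch)$degenerate)
})

test_that("b = 0 simulation returns S0 and free water attenuates as a ball", {
  p <- list(f_iso = c(0.3, 1), f_ic = c(0.5, 0.5), kappa = c(2, 2),
            mu = rbind(c(0, 0, 1), c(0, 0, 1)))
  dwi <- simulate_dwi_signals(p, sch, S0 = c(500, 700), points = pts)
  expect_true(all(dwi[1, sch$bvals == 0] == 500))
  expect_true(all(dwi[2, sch$bvals == 0] == 700))
  expect_equal(unname(dwi[2, which(sch$bvals == 1000)[1]]) / 700,
               exp(-3), tolerance = 1e-10)
})

test_that("dictionary fit is self-consistent on grid points", {
  grid <- noddi_grid()
  set.seed(21)
  mus <- runit3(6)
  p <- list(f_iso = c(0.1, 0.3, 0, 0.5, 0.2, 0.45),
            f_ic = grid$f_ic[c(2, 5, 8, 11, 6, 3)],
            kappa = grid$kappa[c(3, 6, 9, 12, 4, 10)], mu = mus)
  dwi <- simulate_dwi_signals(p, sch, points = pts)
  # known orientation: exact atom identification, lambda = 0
  fit <- fit_noddi_volume(dwi, sch, grid = grid, lambda = 0, points = pts,
                          mu = mus)
  expect_lt(max(abs(fit$NDI - p$f_ic)), 1e-6)
  expect_lt(max(abs(fit$ODI - odi_from_kappa(p$kappa))), 1e-6)
  expect_lt(max(abs(fit$FW - p$f_iso)), 1e-6)
  # estimated orientation: still essentially exact
  fit2 <- fit_noddi_volume(dwi, sch, grid = grid, lambda = 0, points = pts)
  expect_lt(max(abs(fit2$NDI - p$f_ic)), 0.01)
  expect_lt(max(abs(fit2$ODI - odi_from_kappa(p$kappa))), 0.01)
})

test_that("fitted compartment fractions are normalized and bounded", {
  set.seed(22)
  n <- 20
  p <- list(f_iso = runif(n, 0, 0.9), f_ic = runif(n, 0.1, 0.9),
            kappa = kappa_from_odi(runif(n, 0.05, 0.9)), mu = runit3(n))
  dwi <- simulate_dwi_signals(p, sch, S0 = 800, noise_sd = 8,
                              noise_model = "rician", points = pts)
  fit <- fit_noddi_volume(dwi, sch, points = pts)
  expect_true(all(fit$FW >= 0 & fit$FW <= 1))
  expect_true(all(fit$NDI >= 0 & fit$NDI <= 1))
  expect_true(all(fit$ODI >= 0 & fit$ODI <= 1))
})

test_that("voxels with non-positive S0 are returned as NaN", {
  p <- list(f_iso = 0.2, f_ic = 0.6, kappa = 2, mu = matrix(c(0, 0, 1), 1))
  dwi <- simulate_dwi_signals(p, sch, points = pts)
  dwi2 <- rbind(dwi, 0 * dwi)
  fit <- fit_noddi_volume(dwi2, sch, points = pts)
  expect_true(is.finite(fit$NDI[1]))
  expect_true(is.nan(fit$NDI[2]))
})

test_that("full fit is rotation-equivariant within quadrature tolerance", {
  grid <- noddi_grid()
  th <- 1.1
  R <- rbind(c(cos(th), 0, sin(th)), c(0, 1, 0), c(-sin(th), 0, cos(th)))
  mu0 <- c(0, 0, 1)
  p0 <- list(f_iso = 0.15, f_ic = 0.55, kappa = kappa_from_odi(0.3),
             mu = matrix(mu0, 1))
  p1 <- p0; p1$mu <- matrix(as.vector(R %*% mu0), 1)
  f0 <- fit_noddi_volume(simulate_dwi_signals(p0, sch, points = pts), sch,
                         grid = grid, points = pts)
  f1 <- fit_noddi_volume(simulate_dwi_signals(p1, sch, points = pts), sch,
                         grid = grid, points = pts)
  expect_equal(f0$NDI, f1$NDI, tolerance = 0.02)
  expect_equal(f0$ODI, f1$ODI, tolerance = 0.02)
  expect_equal(f0$FW, f1$FW, tolerance = 0.02)
})
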