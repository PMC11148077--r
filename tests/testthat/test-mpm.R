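test_that("log-linear fit recovers the two-point decay exactly", {
  # S(12 ms) / S(2 ms) = exp(-R2* * 10 ms) with R2* = 20 /s
  tr <- echo_train("T1w", echo_times_ms = c(2, 12))
  S <- matrix(c(100, 100 * exp(-20 * 0.010)), 1, 2)
  est <- fit_estatics(list(T1w = S), list(tr))
  expect_equal(est$R2star[1], 20, tolerance = 1e-9)
  # the TE = 0 intercept back-extrapolates the first echo
  expect_equal(est$S0$T1w[1], 100 * exp(20 * 0.002), tolerance = 1e-9)
})

test_that("constant echoes give zero decay and intercepts at the signal", {
  trains <- default_mpm_trains()
  sig <- lapply(trains, function(tr) matrix(50, 3, length(tr$echo_times_ms)))
  names(sig) <- vapply(trains, function(t) t$contrast, "")
  est <- fit_estatics(sig, trains)
  expect_equal(est$R2star, rep(0, 3), tolerance = 1e-10)
  expect_equal(est$S0$PDw, rep(50, 3), tolerance = 1e-9)
})

test_that("three-contrast noiseless trains recover R2* to 1e-6", {
  g <- expand.grid(R1 = c(0.5, 0.8, 1.2), R2star = c(10, 20, 30))
  params <- list(A = rep(1000, nrow(g)), R1 = g$R1, R2star = g$R2star,
                 delta = rep(0.01, nrow(g)))
  sig <- simulate_flash_signals(params, signal_model = "exact")
  est <- fit_estatics(sig, default_mpm_trains())
  expect_lt(max(abs(est$R2star - g$R2star)), 1e-6)
  # independent oracle: two-point log slope on the first/last T1w echoes
  tr <- echo_train("T1w")
  te <- tr$echo_times_ms / 1000
  slope <- log(sig$T1w[, 1] / sig$T1w[, length(te)]) / (te[length(te)] - te[1])
  expect_equal(est$R2star, slope, tolerance = 1e-6)
})

test_that("non-positive signals invalidate the voxel without aborting", {
  trains <- default_mpm_trains()
  sig <- lapply(trains, function(tr) matrix(50, 2, length(tr$echo_times_ms)))
  names(sig) <- vapply(trains, function(t) t$contrast, "")
  sig$T1w[2, 3] <- -1
  est <- fit_estatics(sig, trains)
  expect_true(is.finite(est$R2star[1]))
  expect_true(is.nan(est$R2star[2]))
})

test_that("double-angle ratios map to the expected transmit efficiencies", {
  shp <- c(6, 6, 4)
  nv <- prod(shp)
  # S_2a / (2 S_a) = cos(60 deg) at nominal 60 -> f = 1
  b1 <- estimate_b1_dam(rep(100, nv), rep(2 * 100 * 0.5, nv), 60, shp)
  expect_equal(b1$raw, rep(1, nv), tolerance = 1e-12)
  # S_2a = 0 -> arccos(0) -> f = 90/60 = 1.5
  b1 <- estimate_b1_dam(rep(100, nv), rep(0, nv), 60, shp)
  expect_equal(b1$raw, rep(1.5, nv), tolerance = 1e-12)
  # cos(66 deg) ratio -> f = 1.1
  b1 <- estimate_b1_dam(rep(100, nv), rep(2 * 100 * cos(66 * pi / 180), nv), 60, shp)
  expect_equal(b1$raw, rep(1.1, nv), tolerance = 1e-12)
})

test_that("polynomial surface recovers a smooth transmit field", {
  shp <- c(10, 10, 6)
  ax <- lapply(shp, function(m) seq(-1, 1, length.out = m))
  f_true <- 1 + 0.05 * as.vector(outer(outer(ax[[1]]^2, 0.4 * ax[[2]], `+`),
                                       0.2 * ax[[3]], `+`))
  dam <- simulate_dam_pair(f_true)
  b1 <- estimate_b1_dam(dam$S_alpha, dam$S_2alpha, 60, shp)
  expect_lt(max(abs(b1$f - f_true)), 1e-10)
})

test_that("rational-model signals invert exactly for R1, A and MTsat", {
  params <- list(A = c(800, 1000, 1200), R1 = c(0.6, 0.9, 1.1),
                 R2star = rep(20, 3), delta = c(0, 0.009, 0.02))
  sig <- simulate_flash_signals(params, signal_model = "rational")
  est <- fit_estatics(sig, default_mpm_trains())
  ra <- compute_r1_a(est$S0$T1w, est$S0$PDw)
  expect_equal(ra$R1, params$R1, tolerance = 1e-9)
  expect_equal(ra$A, params$A, tolerance = 1e-7)
  mt <- compute_mtsat(est$S0$MTw, ra$A, ra$R1)
  expect_equal(mt / 100, params$delta, tolerance = 1e-9)
})

test_that("closed-form R1 agrees with direct 2x2 root-finding", {
  # independent oracle: solve the rational system numerically per voxel
  t1 <- echo_train("T1w"); pd <- echo_train("PDw")
  a1 <- t1$flip_deg * pi / 180; a2 <- pd$flip_deg * pi / 180
  set.seed(1)
  R1s <- runif(20, 0.5, 1.2); As <- runif(20, 500, 1500)
  S1 <- flash_s0(As, R1s, t1$TR, a1, model = "rational")
  S2 <- flash_s0(As, R1s, pd$TR, a2, model = "rational")
  ra <- compute_r1_a(S1, S2)
  for (i in seq_along(R1s)) {
    root <- stats::uniroot(function(r1) {
      A1 <- S1[i] * (a1^2 / 2 + t1$TR * r1) / (a1 * t1$TR * r1)
      A2 <- S2[i] * (a2^2 / 2 + pd$TR * r1) / (a2 * pd$TR * r1)
      A1 - A2
    }, c(0.05, 5), tol = 1e-12)$root
    expect_equal(ra$R1[i], root, tolerance = 1e-6)
  }
})

test_that("exact-equation signals recover R1 within the approximation bound", {
  R1s <- seq(0.5, 1.2, length.out = 10)
  params <- list(A = rep(1000, 10), R1 = R1s, R2star = rep(18, 10),
                 delta = rep(0.01, 10))
  sig <- simulate_flash_signals(params, signal_model = "exact")
  est <- fit_estatics(sig, default_mpm_trains())
  ra <- compute_r1_a(est$S0$T1w, est$S0$PDw)
  expect_lt(max(abs(ra$R1 - R1s) / R1s), 0.02)
  # independent oracle: invert the exact steady-state equation by root-finding
  t1 <- echo_train("T1w"); a1 <- t1$flip_deg * pi / 180
  for (i in c(1, 5, 10)) {
    root <- stats::uniroot(function(r1)
      flash_s0(1000, r1, t1$TR, a1, "exact") - flash_s0(1000, R1s[i], t1$TR, a1, "exact"),
      c(0.05, 5), tol = 1e-12)$root
    expect_equal(root, R1s[i], tolerance = 1e-9)
  }
})

test_that("small-angle limit of the exact FLASH equation", {
  a <- 1 * pi / 180
  exact <- flash_s0(1000, 1, 0.018, a, "exact")
  approx <- flash_s0(1000, 1, 0.018, a, "rational")
  expect_lt(abs(exact - approx) / exact, 0.001)
})

test_that("MTsat is zero for an unsaturated signal and unchanged at f = 1", {
  t1 <- echo_train("T1w"); pd <- echo_train("PDw"); mt <- echo_train("MTw")
  A <- 1000; R1 <- 0.9
  a_mt <- mt$flip_deg * pi / 180
  S_mt_nosat <- A * a_mt * mt$TR * R1 / (a_mt^2 / 2 + mt$TR * R1)
  expect_equal(compute_mtsat(S_mt_nosat, A, R1), 0, tolerance = 1e-10)
  # f = 1: the empirical correction is the identity
  S <- flash_s0_mt <- A * a_mt * mt$TR * R1 / (mt$TR * R1 + 0.012 + a_mt^2 / 2)
  expect_equal(compute_mtsat(S, A, R1, b1 = 1), compute_mtsat(S, A, R1),
               tolerance = 1e-12)
})

test_that("MTsat round trip through the exact simulation stays within 5%", {
  deltas <- seq(0.005, 0.02, length.out = 6)
  params <- list(A = rep(1000, 6), R1 = rep(0.8, 6), R2star = rep(20, 6),
                 delta = deltas)
  sig <- simulate_flash_signals(params, signal_model = "exact")
  est <- fit_estatics(sig, default_mpm_trains())
  ra <- compute_r1_a(est$S0$T1w, est$S0$PDw)
  mt <- compute_mtsat(est$S0$MTw, ra$A, ra$R1)
  expect_lt(max(abs(mt / 100 - deltas) / deltas), 0.05)
})

test_that("PD calibration rescales to the white-matter target", {
  A <- c(1000, 1100)
  pd <- calibrate_pd(A, c(TRUE, TRUE))
  expect_equal(pd, c(65.71, 72.29), tolerance = 1e-3)
  expect_equal(calibrate_pd(rep(123, 5), rep(TRUE, 5)), rep(69, 5))
  # ratios are preserved under calibration
  A2 <- c(500, 800, 1200)
  pd2 <- calibrate_pd(A2, c(TRUE, FALSE, TRUE))
  expect_equal(pd2[2] / pd2[1], A2[2] / A2[1], tolerance = 1e-12)
  expect_error(calibrate_pd(c(-5, -2), c(TRUE, TRUE)), "not positive")
})

test_that("global signal scaling leaves R1, MTsat, R2* invariant", {
  params <- list(A = c(900, 1100), R1 = c(0.7, 1.0), R2star = c(15, 25),
                 delta = c(0.008, 0.015))
  sig <- simulate_flash_signals(params, signal_model = "exact")
  fit1 <- local({
    est <- fit_estatics(sig, default_mpm_trains())
    ra <- compute_r1_a(est$S0$T1w, est$S0$PDw)
    list(R1 = ra$R1, A = ra$A, R2 = est$R2star,
         MT = compute_mtsat(est$S0$MTw, ra$A, ra$R1))
  })
  sig2 <- lapply(sig, function(S) 3.7 * S)
  fit2 <- local({
    est <- fit_estatics(sig2, default_mpm_trains())
    ra <- compute_r1_a(est$S0$T1w, est$S0$PDw)
    list(R1 = ra$R1, A = ra$A, R2 = est$R2star,
         MT = compute_mtsat(est$S0$MTw, ra$A, ra$R1))
  })
  expect_equal(fit1$R1, fit2$R1, tolerance = 1e-9)
  expect_equal(fit1$R2, fit2$R2, tolerance = 1e-9)
  expect_equal(fit1$MT, fit2$MT, tolerance = 1e-9)
  expect_equal(3.7 * fit1$A, fit2$A, tolerance = 1e-7)
})

test_that("transmit-field equivariance: scaled angles with matching b1 map", {
  params <- list(A = rep(1000, 4), R1 = c(0.6, 0.8, 1.0, 1.2),
                 R2star = rep(20, 4), delta = rep(0.01, 4))
  for (b1v in c(0.85, 1.1)) {
    sig <- simulate_flash_signals(params, b1 = rep(b1v, 4),
                                  signal_model = "rational")
    est <- fit_estatics(sig, default_mpm_trains())
    ra <- compute_r1_a(est$S0$T1w, est$S0$PDw, b1 = rep(b1v, 4))
    expect_equal(ra$R1, params$R1, tolerance = 1e-8)
    mt <- compute_mtsat(est$S0$MTw, ra$A, ra$R1, b1 = rep(b1v, 4))
    expect_equal(mt / 100, params$delta, tolerance = 1e-8)
  }
})

test_that("echo train validation catches bad acquisitions", {
  expect_error(echo_train("T1w", echo_times_ms = c(5, 3)), "increasing")
  expect_error(echo_train("T1w", echo_times_ms = c(2, 30)), "inside")
  expect_error(echo_train("T1w", flip_deg = 95), "flip angle")
})
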