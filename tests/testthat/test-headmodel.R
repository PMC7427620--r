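test_that("sphere forward solution matches closed forms and is rotation-equivariant", {
  m <- test_montage()
  el <- m$positions
  sigma <- 0.33

  # central dipole: V = 3 (p . r) / (4 pi sigma) on the unit sphere
  Vc <- qeegnorm:::sphere_dipole_potential(el, c(0, 0, 0), sigma)
  expect_equal(Vc, unname(3 / (4 * pi * sigma) * el), tolerance = 1e-12)

  # linearity in the moment holds exactly (columns are unit-moment potentials)
  b <- c(0.3, -0.2, 0.4)
  V <- qeegnorm:::sphere_dipole_potential(el, b, sigma)
  q1 <- c(1, 2, -1); q2 <- c(0.5, 0, 3)
  expect_equal(V %*% (q1 + q2), V %*% q1 + V %*% q2)

  # rotating electrodes and dipole together leaves gains unchanged
  a <- 0.7
  R <- matrix(c(cos(a), -sin(a), 0, sin(a), cos(a), 0, 0, 0, 1), 3, 3, byrow = TRUE)
  V2 <- qeegnorm:::sphere_dipole_potential(el %*% t(R), as.vector(R %*% b), sigma)
  expect_lt(max(abs(V2 %*% R - V)), 1e-9 * max(abs(V)))
})

test_that("the insulating boundary condition holds: radial current vanishes at the scalp", {
  # Interior solution underlying the surface formula, rebuilt term by term in
  # the test: singular part (infinite-medium dipole, coefficients n b^(n-1)
  # r^-(n+1)) plus the regular Neumann correction B_n r^n with
  # B_n = A_n (n+1)/n.  The singular part is validated against the
  # closed-form dipole potential; the total must have zero radial derivative
  # at the scalp and agree with sphere_dipole_potential() at r = 1.
  sigma <- 0.33
  b <- c(0.2, 0.1, 0.5)
  f <- sqrt(sum(b^2)); zl <- b / f
  q <- c(1, -2, 1.5)
  series_V <- function(u, r, part = c("both", "singular")) {
    part <- match.arg(part)
    xl <- c(0, 0, 1) - zl[3] * zl; xl <- xl / sqrt(sum(xl^2))
    yl <- c(zl[2] * xl[3] - zl[3] * xl[2], zl[3] * xl[1] - zl[1] * xl[3],
            zl[1] * xl[2] - zl[2] * xl[1])
    qr <- sum(q * zl); qt1 <- sum(q * xl); qt2 <- sum(q * yl)
    ct <- sum(u * zl); st <- sqrt(max(0, 1 - ct^2))
    cphi <- sum(u * xl) / st; sphi <- sum(u * yl) / st
    tot <- 0
    Pnm1 <- 1; Pn <- ct; P1nm1 <- 0; P1n <- st
    for (n in 1:250) {
      if (n > 1) {
        Pnew <- ((2 * n - 1) * ct * Pn - (n - 1) * Pnm1) / n
        P1new <- ((2 * n - 1) * ct * P1n - n * P1nm1) / (n - 1)
        Pnm1 <- Pn; Pn <- Pnew; P1nm1 <- P1n; P1n <- P1new
      }
      rad <- r^(-(n + 1)) + if (part == "both") (n + 1) / n * r^n else 0
      tot <- tot + f^(n - 1) * rad *
        (n * qr * Pn + (qt1 * cphi + qt2 * sphi) * P1n)
    }
    tot / (4 * pi * sigma)
  }
  for (u in list(c(0, 0, 1), c(0.6, 0, 0.8), c(-0.5, 0.5, sqrt(0.5)))) {
    # singular part of the expansion equals the closed-form dipole potential
    r0 <- 0.95
    d <- r0 * u - b
    v_closed <- sum(q * d) / (4 * pi * sigma * sum(d^2)^1.5)
    expect_equal(series_V(u, r0, "singular"), v_closed, tolerance = 1e-9)
    # zero radial derivative at the boundary (centered finite difference)
    h <- 1e-4
    dVdr <- (series_V(u, 1) - series_V(u, 1 - 2 * h)) / (2 * h)
    scale_ref <- abs((series_V(u, 1 - h, "singular") -
                      series_V(u, 1 - 3 * h, "singular")) / (2 * h))
    # finite-difference truncation is O(h * V''); a missing or wrong Neumann
    # correction would leave a radial derivative of the same order as the
    # dipole field itself (ratio ~ 1)
    expect_lt(abs(dVdr), 5e-3 * max(scale_ref, 1))
    # and the interior series matches the packaged surface solution at r = 1
    Vs <- qeegnorm:::sphere_dipole_potential(rbind(u), b, sigma) %*% q
    expect_equal(series_V(u, 1 - h / 100), as.numeric(Vs), tolerance = 1e-6)
  }
})

test_that("superficial sources project more strongly than deep ones on the same ray", {
  m <- test_montage()
  n1 <- sqrt(sum(qeegnorm:::sphere_dipole_potential(m$positions, c(0, 0, 0.8), 0.33)^2))
  n2 <- sqrt(sum(qeegnorm:::sphere_dipole_potential(m$positions, c(0, 0, 0.4), 0.33)^2))
  expect_gt(n1, n2)
})

test_that("spherical lead field has sane geometry and average-referenced columns", {
  lf <- test_leadfield()
  expect_equal(nrow(lf$k), 19)
  expect_equal(ncol(lf$k), 3 * nrow(lf$voxel_xyz))
  expect_true(all(sqrt(rowSums(lf$voxel_xyz^2)) <= 0.85 + 1e-9))
  expect_lt(max(abs(colMeans(lf$k))), 1e-12 * max(abs(lf$k)))
  expect_true(all(is.finite(lf$k)))
  expect_error(spherical_leadfield(eeg_montage(c("a", "b", "c"),
                                               diag(3))), "at least 4")
})

test_that("ridge operator matches a dense-solve oracle and its limits", {
  set.seed(41)
  K <- matrix(rnorm(19 * 300), 19, 300)
  lf <- structure(list(k = K, voxel_xyz = matrix(rnorm(300), 100, 3),
                       orientation_mode = "free", conductivity = 0.33,
                       spacing = 0.2, channel_labels = paste0("c", 1:19)),
                  class = "lead_field")
  for (lam in c(0.37, 5)) {
    op <- ridge_inverse_operator(lf, lam, depth_normalize = FALSE)
    oracle <- t(K) %*% solve(K %*% t(K) + lam * diag(19))
    expect_lt(max(abs(op$t - oracle)), 1e-8 * max(abs(oracle)))
  }

  # square invertible K at lambda = 0 gives the exact inverse
  K3 <- diag(3) + 0.1 * matrix(rnorm(9), 3, 3)
  lf3 <- structure(list(k = K3, voxel_xyz = matrix(0.1, 1, 3),
                        orientation_mode = "free", conductivity = 0.33,
                        spacing = 1, channel_labels = paste0("c", 1:3)),
                   class = "lead_field")
  op3 <- ridge_inverse_operator(lf3, 0, depth_normalize = FALSE)
  expect_equal(op3$t, solve(K3), tolerance = 1e-9)

  # shrinkage: operator norm decreases monotonically in lambda, towards zero
  lams <- c(0, 1, 100, 1e12 * norm(K %*% t(K), "2"))
  nrms <- vapply(lams, function(l)
    norm(ridge_inverse_operator(lf, l, depth_normalize = FALSE)$t, "F"), 0)
  expect_true(all(diff(nrms) < 0))
  expect_lt(nrms[4], 1e-9 * nrms[1])

  # identity lead field: operator is the identity
  lfI <- structure(list(k = diag(3), voxel_xyz = matrix(0.1, 1, 3),
                        orientation_mode = "free", conductivity = 0.33,
                        spacing = 1, channel_labels = paste0("c", 1:3)),
                   class = "lead_field")
  expect_equal(ridge_inverse_operator(lfI, 0, depth_normalize = FALSE)$t, diag(3))
})

test_that("GCV matches a hand-computed toy, prefers small lambda for noiseless data", {
  # 2-channel toy, hand-computable dense route
  K <- matrix(c(2, 0, 0, 1), 2, 2)
  lf <- structure(list(k = K, voxel_xyz = matrix(c(0.1, 0, 0, 0, 0.1, 0), 2, 3,
                                                 byrow = TRUE),
                       orientation_mode = "radial", conductivity = 0.33,
                       spacing = 1, channel_labels = c("a", "b")),
                  class = "lead_field")
  N <- 8; fs <- 16
  d <- array(0, dim = c(1, N, 2))
  tt <- (0:(N - 1)) / fs
  d[1, , 1] <- 2 * cos(2 * pi * 2 * tt); d[1, , 2] <- sin(2 * pi * 2 * tt)
  e <- eeg_epochs(d, fs, c("a", "b"))
  g <- build_frequency_grid(N, fs, 4.1)
  lams <- c(0.5, 1, 2)
  sel <- select_lambda_gcv(lf, e, g, lambdas = lams, depth_normalize = FALSE)
  gcv_hand <- vapply(lams, function(lam) {
    # X: stacked Re/Im DFT coefficients over the 2 retained bins
    V <- stats::mvfft(sweep(matrix(d[1, , ], N, 2), 2, colMeans(matrix(d[1, , ], N, 2))))
    X <- cbind(t(Re(V[g$k + 1, , drop = FALSE])), t(Im(V[g$k + 1, , drop = FALSE])))
    G <- K %*% t(K) + lam * diag(2)
    Tm <- t(K) %*% solve(G)
    num <- sum(((diag(2) - K %*% Tm) %*% X)^2) / 2
    den <- (sum(diag(diag(2) - K %*% t(K) %*% solve(G))) / 2)^2
    num / den
  }, 0)
  expect_equal(attr(sel, "gcv")$gcv, gcv_hand, tolerance = 1e-9)
  expect_equal(as.numeric(sel), lams[which.min(gcv_hand)])

  # noiseless forward data select the smallest candidate penalty
  lf19 <- test_leadfield()
  sp <- dipole_sim_spec(40, "radial", freq_hz = 26 * 200 / 512,
                        snr_db = 300, n_epochs = 4)
  en <- simulate_dipole_epochs(sp, lf19, seed = 2)
  lams2 <- 10^seq(-6, 2, length.out = 9)
  expect_equal(as.numeric(select_lambda_gcv(lf19, en, lambdas = lams2)),
               min(lams2))

  # pure sensor noise (no propagated source structure) prefers heavy shrinkage
  set.seed(5)
  eno <- eeg_epochs(array(rnorm(4 * 512 * 19), dim = c(4, 512, 19)), 200,
                    lf19$channel_labels)
  expect_gte(as.numeric(select_lambda_gcv(lf19, eno, lambdas = lams2)), 1)
  expect_error(select_lambda_gcv(lf19, en, lambdas = c(1, 2)), "at least 3")
})

test_that("source power transports the scalp spectrum through the inverse", {
  # identity lead field, lambda 0: source power equals scalp power
  C <- 4
  lfI <- structure(list(k = diag(C), voxel_xyz = matrix(rnorm(3 * C) / 10, C, 3),
                        orientation_mode = "radial", conductivity = 0.33,
                        spacing = 1, channel_labels = paste0("c", 1:C)),
                   class = "lead_field")
  opI <- ridge_inverse_operator(lfI, 0, depth_normalize = FALSE)
  e <- noise_epochs(2, 64, C, fs = 128, seed = 43)
  cs <- cross_spectrum(e, build_frequency_grid(64, 128, 64))
  ss <- source_spectra(opI, cs)
  expect_equal(ss$power, unname(narrowband_power(cs)$power), tolerance = 1e-8)
  expect_true(all(ss$power >= 0))
  expect_identical(ss$level, "source")

  # zero cross-spectrum gives zero source power
  cs0 <- cs; cs0$s[] <- 0 + 0i
  expect_true(all(source_spectra(opI, cs0)$power == 0))

  # total source power is non-increasing in lambda for fixed data
  lf <- test_leadfield()
  e19 <- noise_epochs(2, 64, 19, fs = 128, seed = 47,
                      labels = lf$channel_labels)
  cs19 <- cross_spectrum(e19, build_frequency_grid(64, 128, 20))
  tot <- vapply(c(0.01, 0.1, 1, 10), function(l)
    sum(source_spectra(ridge_inverse_operator(lf, l), cs19)$power), 0)
  expect_true(all(diff(tot) < 0))
})

test_that("a simulated dipole is localized by the standardized source map", {
  lf <- test_leadfield()
  g <- build_frequency_grid(512, 200)
  k0 <- 26; f0 <- k0 * 200 / 512
  op <- ridge_inverse_operator(lf, 1e-3)
  hits <- 0; n_runs <- 25
  for (s in seq_len(n_runs)) {
    set.seed(2000 + s)
    v <- sample(nrow(lf$voxel_xyz), 1)
    sp <- dipole_sim_spec(v, "radial", freq_hz = f0, snr_db = 20, n_epochs = 24)
    e <- simulate_dipole_epochs(sp, lf, seed = s)
    ss <- source_spectra(op, cross_spectrum(e, g), standardize = "resolution")
    vhat <- which.max(ss$power[, k0])
    d <- sqrt(sum((lf$voxel_xyz[vhat, ] - lf$voxel_xyz[v, ])^2))
    hits <- hits + (d <= lf$spacing * sqrt(3) + 1e-9)
  }
  expect_gte(hits / n_runs, 0.9)
})
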