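test_that("the log10 transform is exact, monotone, and guards its domain", {
  g <- build_frequency_grid(64, 128, 20)
  p <- matrix(c(1, 100, 0.5, 2), 2, 2)
  expect_equal(transform_spectra(p), log10(p + 1e-12))
  expect_equal(transform_spectra(matrix(1))[1, 1], 0, tolerance = 1e-12)
  expect_equal(transform_spectra(matrix(100))[1, 1], 2, tolerance = 1e-12)
  expect_error(transform_spectra(matrix(-1)), "negative")
  nb <- qeegnorm:::nb_spectra(matrix(1, 1, g$n_bins), g, "Cz")
  tn <- transform_spectra(nb)
  expect_true(tn$log10)
  expect_error(transform_spectra(tn), "already")
})

test_that("a degree-0 fit reduces to the sample mean and a consistent SD", {
  set.seed(51)
  g <- build_frequency_grid(64, 128, 10)
  n <- 500
  y <- matrix(rnorm(n * 2 * g$n_bins, mean = 1.7, sd = 0.3), n)
  ages <- runif(n, 20, 60)
  nm <- fit_norm_model(y, ages, g, c("C3", "C4"), degree = 0)
  ev <- evaluate_norm(nm, 35)
  expect_equal(mean(ev$mu), 1.7, tolerance = 0.01)
  expect_equal(as.vector(ev$mu), colMeans(y)[seq_len(2 * g$n_bins)],
               tolerance = 1e-9)
  # half-normal-corrected SD estimator is consistent for the sample SD scale
  expect_equal(mean(ev$sigma), 0.3, tolerance = 0.01)
})

test_that("generator coefficients and SD are recovered without bias at cohort scale", {
  spec <- cohort_spec()              # 211 subjects, ages 5-87
  coh <- make_cohort(spec, seed = 7)
  nm <- fit_norm_model(cohort_response_matrix(coh), coh$ages, spec$grid,
                       spec$channel_labels, degree = 1)
  # truth surfaces: intercept at u = 0 (age 1) and slope (difference over one
  # decade of age)
  tr0 <- cohort_truth_mu(spec, 1)
  tr1 <- cohort_truth_mu(spec, 10) - tr0
  expect_lt(abs(mean(nm$beta_mu[, , 1] - tr0)), 0.05)   # intercept bias
  expect_lt(abs(mean(nm$beta_mu[, , 2] - tr1)), 0.05)   # slope bias
  for (age in c(10, 30, 70)) {
    ev <- evaluate_norm(nm, age)
    expect_lt(abs(mean(ev$mu - cohort_truth_mu(spec, age))), 0.05)
    expect_lt(abs(mean(ev$sigma) - spec$sigma_gen), 0.03)
    # per-fit sampling noise stays within a few SE of the tolerance scale
    expect_lt(stats::quantile(abs(ev$mu - cohort_truth_mu(spec, age)), 0.9), 0.15)
  }
})

test_that("degenerate cohorts and designs are handled explicitly", {
  g <- build_frequency_grid(64, 128, 10)
  # identical subjects: zero residuals, SD floored, no crash
  y <- matrix(1.5, 30, g$n_bins)
  nm <- fit_norm_model(y, seq(10, 68, 2), g, "Cz", degree = 1)
  ev <- evaluate_norm(nm, 30)
  expect_equal(unname(ev$sigma[1, ]), rep(nm$sigma_floor, g$n_bins))
  expect_equal(unname(ev$mu[1, ]), rep(1.5, g$n_bins), tolerance = 1e-9)
  # all ages equal: rank-deficient design is a named error
  expect_error(fit_norm_model(y, rep(30, 30), g, "Cz", degree = 1),
               "rank-deficient")
  expect_error(fit_norm_model(y[1:2, ], c(10, 20), g, "Cz", degree = 1),
               "at least")
})

test_that("norm evaluation flags extrapolation and rejects bad ages", {
  g <- build_frequency_grid(64, 128, 10)
  set.seed(53)
  nm <- fit_norm_model(matrix(rnorm(40 * g$n_bins), 40), runif(40, 5, 87),
                       g, "Cz", degree = 1)
  nm$age_range <- c(5, 87)
  expect_silent(evaluate_norm(nm, 40))
  expect_warning(evaluate_norm(nm, 4), "outside the normative range")
  expect_error(evaluate_norm(nm, -3), "positive")
})

test_that("z-scores are exact on the normative surface and match by label", {
  spec <- cohort_spec(n_subjects = 60)
  coh <- make_cohort(spec, seed = 3)
  nm <- fit_norm_model(cohort_response_matrix(coh), coh$ages, spec$grid,
                       spec$channel_labels, degree = 1)
  ev <- evaluate_norm(nm, 30)
  z0 <- z_score(ev$mu, nm, 30)
  expect_equal(max(abs(z0$z)), 0, tolerance = 1e-12)
  y2 <- ev$mu; y2[3, 7] <- y2[3, 7] + 2 * ev$sigma[3, 7]
  expect_equal(unname(z_score(y2, nm, 30)$z[3, 7]), 2, tolerance = 1e-9)

  # case-insensitive, order-free matching; extra channels dropped with warning
  perm <- sample(nrow(ev$mu))
  yy <- ev$mu[perm, ]
  rownames(yy) <- toupper(spec$channel_labels[perm])
  expect_equal(max(abs(z_score(yy, nm, 30)$z)), 0, tolerance = 1e-12)
  yx <- rbind(yy, EXTRA = 0)
  expect_warning(zx <- z_score(yx, nm, 30), "extra data locations")
  expect_equal(max(abs(zx$z)), 0, tolerance = 1e-12)
  expect_error(z_score(yy[-1, , drop = FALSE], nm, 30), "missing")
  expect_error(z_score(yy[, -1, drop = FALSE], nm, 30), "grid mismatch")
})

test_that("fresh in-model subjects pool to a standard normal z-distribution", {
  spec <- cohort_spec()
  coh <- make_cohort(spec, seed = 7)
  nm <- fit_norm_model(cohort_response_matrix(coh), coh$ages, spec$grid,
                       spec$channel_labels, degree = 1)
  fresh <- make_cohort(cohort_spec(n_subjects = 200), seed = 99)
  zs <- unlist(lapply(seq_along(fresh$ages), function(i) {
    y <- transform_spectra(fresh$spectra[[i]])
    rownames(y) <- spec$channel_labels
    as.vector(suppressWarnings(z_score(y, nm, fresh$ages[i]))$z)
  }))
  expect_gte(length(zs), 1e5)
  expect_gt(mean(zs), -0.05); expect_lt(mean(zs), 0.05)
  expect_gt(stats::sd(zs), 0.93); expect_lt(stats::sd(zs), 1.07)
  expect_lt(suppressWarnings(stats::ks.test(zs, "pnorm")$statistic), 0.02)
})

test_that("fitted norms survive the norms file round-trip bit-for-bit", {
  spec <- cohort_spec(n_subjects = 40)
  coh <- make_cohort(spec, seed = 13)
  nm <- fit_norm_model(cohort_response_matrix(coh), coh$ages, spec$grid,
                       spec$channel_labels, degree = 2)
  f <- withr::local_tempfile(fileext = ".json")
  write_norms(nm, f)
  nm2 <- read_norms(f)
  expect_equal(nm2$beta_mu, nm$beta_mu, tolerance = 1e-12)
  expect_equal(nm2$beta_sigma, nm$beta_sigma, tolerance = 1e-12)
  ev <- evaluate_norm(nm, 44); ev2 <- evaluate_norm(nm2, 44)
  expect_equal(ev2$mu, ev$mu, tolerance = 1e-12)
  expect_equal(ev2$sigma, ev$sigma, tolerance = 1e-12)
})

test_that("the two-pass GSF refit absorbs per-subject gain into the norms", {
  spec <- cohort_spec(n_subjects = 80, sigma_gen = 0.1)
  coh <- make_cohort(spec, seed = 21)
  # inject per-subject multiplicative gains (log10 offsets)
  set.seed(22)
  offs <- rnorm(80, sd = 0.5)
  Y <- cohort_response_matrix(coh) + offs
  nm_plain <- fit_norm_model(Y, coh$ages, spec$grid, spec$channel_labels,
                             degree = 1, gsf = FALSE)
  nm_gsf <- fit_norm_model(Y, coh$ages, spec$grid, spec$channel_labels,
                           degree = 1, gsf = TRUE)
  expect_true(nm_gsf$gsf_two_pass)
  # with the gain removed, the fitted SD surface approaches the generator SD;
  # without it the gain SD dominates
  s_plain <- mean(evaluate_norm(nm_plain, 30)$sigma)
  s_gsf <- mean(evaluate_norm(nm_gsf, 30)$sigma)
  expect_gt(s_plain, 0.3)
  expect_lt(abs(s_gsf - spec$sigma_gen), 0.03)
})
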