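#' Log-transform raw power spectra
#'
#' The normative models operate on log10 power (with a 1e-12 floor inside
#' the log so zero-power bins stay finite).
#'
#' @param nb an [nb_spectra] with raw power, or a non-negative matrix.
#' @param eps additive floor before the log (default 1e-12).
#' @return The same type with log10 values and the log10 flag set.
#' @export
transform_spectra <- function(nb, eps = 1e-12) {
  if (inherits(nb, "nb_spectra")) {
    if (nb$log10) stop("spectra are already log10-transformed", call. = FALSE)
    if (any(nb$power < 0)) stop("negative power is invalid", call. = FALSE)
    nb$power <- log10(nb$power + eps)
    nb$log10 <- TRUE
    return(nb)
  }
  p <- as.matrix(nb)
  if (any(p < 0)) stop("negative power is invalid", call. = FALSE)
  log10(p + eps)
}

#' Normative age-regression model
#'
#' Holds, for every location (channel or voxel) and frequency bin, the
#' polynomial coefficients in `u = log10(age)` of the normative mean and of
#' the normative standard deviation of transformed spectra (the SD
#' polynomial is floored at `sigma_floor` on evaluation).
#'
#' @param beta_mu,beta_sigma coefficient arrays
#'   `[location x bin x (degree+1)]`.
#' @param degree polynomial degree in `log10(age)`.
#' @param state recording state the cohort was measured in.
#' @param level `"scalp"` or `"source"`.
#' @param grid the [frequency_grid] of the fitted spectra.
#' @param locations location labels (channel labels or voxel ids).
#' @param n_subjects cohort size.
#' @param age_range `[min, max]` cohort ages in years.
#' @param sigma_floor lower bound on sigma in log10-power units.
#' @param gsf_two_pass logical; whether the model was refitted once after a
#'   per-subject Global Scale Factor pass.
#' @return An object of class `norm_model`.
#' @export
norm_model <- function(beta_mu, beta_sigma, degree, state, level, grid,
                       locations, n_subjects, age_range,
                       sigma_floor = 0.01, gsf_two_pass = FALSE) {
  stopifnot(identical(dim(beta_mu), dim(beta_sigma)),
            dim(beta_mu)[3] == degree + 1L,
            dim(beta_mu)[1] == length(locations),
            dim(beta_mu)[2] == grid$n_bins,
            sigma_floor > 0)
  structure(list(beta_mu = beta_mu, beta_sigma = beta_sigma,
                 degree = as.integer(degree), age_transform = "log10",
                 transform = "log10-power", state = state, level = level,
                 grid = grid, locations = as.character(locations),
                 n_subjects = as.integer(n_subjects),
                 age_range = as.numeric(age_range),
                 sigma_floor = sigma_floor, gsf_two_pass = gsf_two_pass),
            class = "norm_model")
}

#' @export
print.norm_model <- function(x, ...) {
  cat(sprintf(
    "<norm_model> %s/%s: %d locations x %d bins, degree-%d polynomial in log10(age)\n",
    x$level, x$state, length(x$locations), x$grid$n_bins, x$degree))
  cat(sprintf("  fitted on %d subjects, ages %g-%g y%s\n", x$n_subjects,
              x$age_range[1], x$age_range[2],
              if (x$gsf_two_pass) " (GSF two-pass)" else ""))
  invisible(x)
}

#' @rdname tidy
#' @export
glance.norm_model <- function(x, ...) {
  tibble::tibble(level = x$level, state = x$state,
                 n_locations = length(x$locations), n_bins = x$grid$n_bins,
                 degree = x$degree, n_subjects = x$n_subjects,
                 age_min = x$age_range[1], age_max = x$age_range[2],
                 sigma_floor = x$sigma_floor, gsf_two_pass = x$gsf_two_pass)
}


#' Fit a normative age-regression model
#'
#' For every location and bin the transformed spectra are regressed on a
#' degree-`degree` polynomial in `u = log10(age)` by least squares (one QR
#' factorization shared by all responses).  The age-dependent SD is fitted
#' heteroscedastically by regressing `|residual| * sqrt(pi/2)` — the
#' half-normal correction makes the conditional mean of the response equal
#' to `sigma(age)` for Gaussian residuals — on the same basis; evaluation
#' floors the fitted SD at `sigma_floor`, keeping it strictly positive.
#'
#' If `gsf = TRUE` a two-pass scheme is used: preliminary norms are fitted
#' without any Global Scale Factor, each subject's GSF is estimated against
#' them, and the model is refitted once on GSF-corrected spectra (one
#' iteration, fixed).
#'
#' @param y matrix `[subject x (location*bin)]` of transformed spectra (use
#'   [cohort_response_matrix()] to build it), or a list of
#'   `[location x bin]` matrices.
#' @param ages numeric vector of subject ages in years.
#' @param grid the common [frequency_grid].
#' @param locations location labels.
#' @param degree polynomial degree (default 3).
#' @param state,level model tags.
#' @param sigma_floor lower bound on sigma (default 0.01 log10-units).
#' @param gsf enable the two-pass GSF refit (default FALSE).
#' @param keep_residual_fields retain per-subject standardized residual
#'   fields (needed by the empirical maximum-statistic threshold).
#' @return A [norm_model]; if requested, residual z-fields in
#'   `$residual_z` (`[subject x location x bin]`).
#' @export
fit_norm_model <- function(y, ages, grid, locations, degree = 3L,
                           state = "EC", level = "scalp",
                           sigma_floor = 0.01, gsf = FALSE,
                           keep_residual_fields = FALSE) {
  if (is.list(y)) y <- do.call(rbind, lapply(y, as.vector))
  y <- as.matrix(y)
  n <- nrow(y)
  L <- length(locations)
  B <- grid$n_bins
  if (ncol(y) != L * B)
    stop("response width must be locations x bins", call. = FALSE)
  if (length(ages) != n) stop("one age per subject is required", call. = FALSE)
  if (any(ages <= 0) || any(ages > 120))
    stop("ages must lie in (0, 120]", call. = FALSE)
  if (n < degree + 2L)
    stop("need at least degree + 2 subjects", call. = FALSE)
  u <- log10(ages)
  X <- outer(u, 0:degree, "^")   # raw polynomial basis incl. intercept
  qx <- qr(X)
  if (qx$rank < ncol(X))
    stop("rank-deficient age design (are all ages equal?)", call. = FALSE)

  fit_once <- function(yy) {
    beta_mu <- qr.coef(qx, yy)
    r <- yy - X %*% beta_mu
    beta_sigma <- qr.coef(qx, abs(r) * sqrt(pi / 2))
    list(beta_mu = beta_mu, beta_sigma = beta_sigma, resid = r)
  }

  ft <- fit_once(y)
  if (gsf) {
    nm0 <- build_nm(ft, degree, state, level, grid, locations, n,
                    range(ages), sigma_floor, FALSE)
    for (i in seq_len(n)) {
      mu_i <- evaluate_norm(nm0, ages[i])$mu
      g <- estimate_gsf(matrix(y[i, ], L, B), mu_i)
      y[i, ] <- y[i, ] - g$log10_value
    }
    ft <- fit_once(y)
  }
  nm <- build_nm(ft, degree, state, level, grid, locations, n,
                 range(ages), sigma_floor, gsf)
  if (keep_residual_fields) {
    sig <- vapply(seq_len(n), function(i) {
      ev <- evaluate_norm(nm, ages[i])
      as.vector(ev$sigma)
    }, numeric(L * B))
    rz <- t(ft$resid) / sig             # [(loc*bin) x subject]
    nm$residual_z <- array(t(rz), dim = c(n, L, B))
  }
  nm
}

build_nm <- function(ft, degree, state, level, grid, locations, n,
                     age_range, sigma_floor, gsf_two_pass) {
  L <- length(locations); B <- grid$n_bins
  bm <- array(t(ft$beta_mu), dim = c(L, B, degree + 1L))
  bs <- array(t(ft$beta_sigma), dim = c(L, B, degree + 1L))
  norm_model(bm, bs, degree, state, level, grid, locations, n,
             age_range, sigma_floor, gsf_two_pass)
}

#' Evaluate a normative model at an age
#'
#' Polynomial evaluation at `u = log10(age)`; the SD is floored at the
#' model's `sigma_floor`.  An age outside the model's fitted range is
#' extrapolated with a warning.
#'
#' @param nm a [norm_model].
#' @param age subject age in years (> 0).
#' @return List with matrices `mu` and `sigma` `[location x bin]` and the
#'   logical `extrapolated`.
#' @export
evaluate_norm <- function(nm, age) {
  stopifnot(inherits(nm, "norm_model"))
  if (!is.numeric(age) || length(age) != 1L || age <= 0)
    stop("`age` must be a positive number of years", call. = FALSE)
  extrap <- age < nm$age_range[1] || age > nm$age_range[2]
  if (extrap)
    warning(sprintf("age %g y is outside the normative range [%g, %g]: extrapolating",
                    age, nm$age_range[1], nm$age_range[2]), call. = FALSE)
  u <- log10(age)
  up <- u^(0:nm$degree)
  L <- dim(nm$beta_mu)[1]; B <- dim(nm$beta_mu)[2]
  mu <- matrix(0, L, B, dimnames = list(nm$locations, NULL))
  lsig <- matrix(0, L, B)
  for (p in seq_along(up)) {
    mu <- mu + matrix(nm$beta_mu[, , p], L, B) * up[p]
    lsig <- lsig + matrix(nm$beta_sigma[, , p], L, B) * up[p]
  }
  sigma <- pmax(lsig, nm$sigma_floor)
  dimnames(sigma) <- dimnames(mu)
  list(mu = mu, sigma = sigma, extrapolated = extrap)
}

#' z-score spectra against a normative model
#'
#' Elementwise `z = (y - mu(age)) / sigma(age)` of transformed (and, if
#' enabled upstream, GSF-corrected) spectra against the age-evaluated
#' normative mean and SD.  Locations are matched by label,
#' case-insensitively and order-free; locations missing from the norms are
#' an error, extra data locations are dropped with a warning.
#'
#' @param y an [nb_spectra] with the log10 flag set, or a matrix
#'   `[location x bin]` with rownames.
#' @param nm a [norm_model] on a compatible grid.
#' @param age subject age in years.
#' @return An object of class `z_maps`: matrix `z` `[location x bin]`,
#'   `level`, `age_used`, the grid, and (once thresholded) the corrected
#'   cutoff.
#' @export
z_score <- function(y, nm, age) {
  stopifnot(inherits(nm, "norm_model"))
  if (inherits(y, "nb_spectra")) {
    if (!y$log10) stop("z_score() expects log10-transformed spectra", call. = FALSE)
    if (!grids_compatible(y$grid, nm$grid))
      stop("frequency grid mismatch between spectra and norms", call. = FALSE)
    ym <- y$power
  } else ym <- as.matrix(y)
  if (ncol(ym) != nm$grid$n_bins)
    stop("frequency grid mismatch between spectra and norms", call. = FALSE)
  lab <- rownames(ym) %||% nm$locations[seq_len(nrow(ym))]
  idx <- match(tolower(nm$locations), tolower(lab))
  if (anyNA(idx))
    stop("locations missing from the data: ",
         paste(nm$locations[is.na(idx)], collapse = ", "), call. = FALSE)
  if (nrow(ym) > length(nm$locations))
    warning("extra data locations dropped: ",
            paste(setdiff(tolower(lab), tolower(nm$locations)), collapse = ", "),
            call. = FALSE)
  ym <- ym[idx, , drop = FALSE]
  ev <- evaluate_norm(nm, age)
  z <- (ym - ev$mu) / ev$sigma
  dimnames(z) <- list(nm$locations, NULL)
  structure(list(z = z, level = nm$level, age_used = age, grid = nm$grid,
                 threshold = NULL, mask = NULL),
            class = "z_maps")
}

#' @export
print.z_maps <- function(x, ...) {
  cat(sprintf("<z_maps> %s level, %d locations x %d bins, age %g y\n",
              x$level, nrow(x$z), ncol(x$z), x$age_used))
  if (!is.null(x$threshold))
    cat(sprintf("  corrected |z| threshold %.3f (alpha %.3g, %s): %d suprathreshold\n",
                x$threshold$value, x$threshold$alpha, x$threshold$method,
                sum(x$mask)))
  invisible(x)
}

#' @rdname tidy
#' @export
tidy.z_maps <- function(x, ...) {
  out <- tibble::tibble(
    location = rep(rownames(x$z), times = ncol(x$z)),
    frequency = rep(grid_display_hz(x$grid), each = nrow(x$z)),
    z = as.vector(x$z))
  if (!is.null(x$mask)) out$significant <- as.vector(x$mask)
  out
}
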