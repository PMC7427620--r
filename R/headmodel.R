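#' Analytic lead field of a homogeneous conducting sphere
#'
#' Forward gain matrix mapping current-dipole moments at source voxels to
#' average-referenced scalp potentials on a unit sphere (head radius 1).
#' The potential of an eccentric dipole in a homogeneous sphere with
#' insulating exterior is evaluated by its Legendre-series solution: with
#' the dipole at radius `f` along a local z-axis and an electrode at angular
#' distance `gamma`,
#' \deqn{V = \frac{1}{4\pi\sigma}\sum_{n\ge1}\frac{2n+1}{n} f^{n-1}
#'   \left[n q_r P_n(\cos\gamma) + q_t \cos\phi\, P_n^1(\cos\gamma)\right]}
#' (and `sin(phi)` for the second tangential component; `P_n^1` without the
#' Condon-Shortley phase).  The series is truncated once `f^(n-1)` falls
#' below 1e-12.  Voxels lie on a regular Cartesian grid intersected with the
#' ball of radius 0.85; columns come in blocks of three Cartesian moment
#' components per voxel (free orientation) or a single radial projection.
#'
#' @param m an [eeg_montage] (at least 4 electrodes).
#' @param n_shells number of voxel layers along the radius; the grid spacing
#'   is `0.85 / n_shells`.  Default 4 gives roughly 250 voxels.
#' @param orientation_mode `"free"` (3 columns per voxel) or `"radial"`.
#' @param conductivity tissue conductivity in S/m (default 0.33).
#' @return An object of class `lead_field` with fields `k` (matrix
#'   `[channel x (voxel*3)]` or `[channel x voxel]`), `voxel_xyz`,
#'   `orientation_mode`, `conductivity`, `spacing`, `channel_labels`.
#' @export
spherical_leadfield <- function(m, n_shells = 4L,
                                orientation_mode = c("free", "radial"),
                                conductivity = 0.33) {
  stopifnot(inherits(m, "eeg_montage"))
  orientation_mode <- match.arg(orientation_mode)
  if (length(m$labels) < 4L)
    stop("at least 4 electrodes are required", call. = FALSE)
  spacing <- 0.85 / n_shells
  ax <- seq(-0.85, 0.85, by = spacing)
  vox <- as.matrix(expand.grid(x = ax, y = ax, z = ax))
  vox <- vox[sqrt(rowSums(vox^2)) <= 0.85 + 1e-12, , drop = FALSE]
  lf <- leadfield_at(m$positions, vox, orientation_mode, conductivity)
  structure(list(k = lf, voxel_xyz = vox, orientation_mode = orientation_mode,
                 conductivity = conductivity, spacing = spacing,
                 channel_labels = m$labels),
            class = "lead_field")
}

#' @export
print.lead_field <- function(x, ...) {
  cat(sprintf("<lead_field> %d channels x %d voxels (%s orientation), spacing %.3g\n",
              nrow(x$k), nrow(x$voxel_xyz), x$orientation_mode, x$spacing))
  invisible(x)
}

# Potential at electrodes (unit sphere, average-referenced) for every voxel
# and moment component.  electrodes [nch x 3] unit vectors, voxels [nv x 3]
# with |v| < 1.
leadfield_at <- function(electrodes, voxels, orientation_mode, conductivity) {
  nch <- nrow(electrodes)
  nv <- nrow(voxels)
  ncol_out <- if (orientation_mode == "free") 3L * nv else nv
  K <- matrix(0, nch, ncol_out)
  for (v in seq_len(nv)) {
    cols <- sphere_dipole_potential(electrodes, voxels[v, ], conductivity)
    if (orientation_mode == "free") {
      K[, (3L * v - 2L):(3L * v)] <- cols
    } else {
      b <- voxels[v, ]
      f <- sqrt(sum(b^2))
      u <- if (f > 1e-12) b / f else c(0, 0, 1)
      K[, v] <- cols %*% u
    }
  }
  sweep(K, 2L, colMeans(K))   # average reference
}

# Surface potentials of unit dipoles along x, y, z at position b (|b| < 1).
# Returns [nch x 3].
sphere_dipole_potential <- function(electrodes, b, conductivity) {
  f <- sqrt(sum(b^2))
  if (f >= 1 - 1e-9)
    stop("dipole position must be strictly inside the unit sphere", call. = FALSE)
  # local frame: z' along the dipole position (any frame for a central dipole)
  if (f > 1e-12) zl <- b / f else zl <- c(0, 0, 1)
  ref <- if (abs(zl[3]) < 0.9) c(0, 0, 1) else c(1, 0, 0)
  xl <- ref - sum(ref * zl) * zl
  xl <- xl / sqrt(sum(xl^2))
  yl <- c(zl[2] * xl[3] - zl[3] * xl[2],
          zl[3] * xl[1] - zl[1] * xl[3],
          zl[1] * xl[2] - zl[2] * xl[1])
  ct <- electrodes %*% zl          # cos(gamma), [nch]
  ct <- pmin(pmax(as.vector(ct), -1), 1)
  st <- sqrt(pmax(0, 1 - ct^2))
  ex <- as.vector(electrodes %*% xl)
  ey <- as.vector(electrodes %*% yl)
  cphi <- ifelse(st > 1e-12, ex / st, 0)
  sphi <- ifelse(st > 1e-12, ey / st, 0)

  nmax <- if (f < 1e-12) 1L else min(400L, max(1L, ceiling(1 - 12 / log10(f))))
  # Legendre recurrences
  Pnm1 <- rep(1, length(ct))   # P_0
  Pn <- ct                     # P_1
  P1nm1 <- rep(0, length(ct))  # P_0^1
  P1n <- st                    # P_1^1  (no Condon-Shortley phase)
  sr <- 3 * 1 * Pn             # sum for radial:  (2n+1)/n * f^(n-1) * n * P_n
  stg <- 3 * P1n               # sum for tangential
  fpow <- 1                    # f^(n-1) at n = 1
  if (nmax > 1L) for (n in 2L:nmax) {
    Pnew <- ((2 * n - 1) * ct * Pn - (n - 1) * Pnm1) / n
    P1new <- ((2 * n - 1) * ct * P1n - n * P1nm1) / (n - 1)
    Pnm1 <- Pn; Pn <- Pnew
    P1nm1 <- P1n; P1n <- P1new
    fpow <- fpow * f
    cf <- (2 * n + 1) / n * fpow
    sr <- sr + cf * n * Pn
    stg <- stg + cf * P1n
  }
  scale <- 1 / (4 * pi * conductivity)
  v_r <- scale * sr                       # radial (along z') unit moment
  v_t1 <- scale * stg * cphi              # tangential along x'
  v_t2 <- scale * stg * sphi              # tangential along y'
  # rotate local components back to global axes: moment e_g = (e_g.z')z' + ...
  out <- matrix(0, nrow(electrodes), 3L)
  local <- rbind(xl, yl, zl)              # rows: local axes in global coords
  for (g in 1:3) {
    q <- local[, g]                       # (q_t1, q_t2, q_r) of global axis g
    out[, g] <- q[3] * v_r + q[1] * v_t1 + q[2] * v_t2
  }
  out
}

#' Ridge inverse operator
#'
#' The minimum-norm ridge solution of the distributed inverse problem:
#' `T = K' (K K' + lambda I)^-1`, computed by Cholesky factorization of the
#' regularized Gram matrix (never an explicit matrix inverse).  For square
#' invertible `K` and `lambda = 0` this is `K^-1`.  Optionally the lead
#' field columns are rescaled to unit Frobenius norm per voxel block before
#' inversion (depth-bias mitigation); the scaling is undone when source
#' power is computed.
#'
#' @param lf a [lead_field].
#' @param lambda ridge penalty (>= 0); with 0 the Gram matrix must be
#'   invertible.
#' @param depth_normalize rescale voxel blocks to unit norm first
#'   (default TRUE).
#' @return An object of class `inverse_operator` with fields `t`
#'   `[(voxel*3|voxel) x channel]`, `lambda`, `method = "ridge"`, the voxel
#'   geometry, and the per-column depth weights.
#' @export
ridge_inverse_operator <- function(lf, lambda, depth_normalize = TRUE) {
  stopifnot(inherits(lf, "lead_field"), lambda >= 0)
  K <- lf$k
  ncomp <- if (lf$orientation_mode == "free") 3L else 1L
  nv <- nrow(lf$voxel_xyz)
  w <- rep(1, ncol(K))
  if (depth_normalize) {
    for (v in seq_len(nv)) {
      cols <- ((v - 1L) * ncomp + 1L):(v * ncomp)
      nrm <- sqrt(sum(K[, cols]^2))
      if (nrm > 0) w[cols] <- 1 / nrm
    }
    K <- sweep(K, 2L, w, "*")
  }
  G <- tcrossprod(K) + diag(lambda, nrow(K))
  ch <- tryCatch(chol(G), error = function(e)
    stop("singular system: K K' + lambda I is not positive definite (lambda = ",
         lambda, ")", call. = FALSE))
  t_mat <- t(backsolve(ch, forwardsolve(t(ch), K)))   # t(G^-1 K) = K' G^-1
  # diagonal blocks of the resolution matrix T K (one ncomp x ncomp block
  # per voxel), used by the standardized source-power estimate
  res_blocks <- array(0, dim = c(ncomp, ncomp, nv))
  for (v in seq_len(nv)) {
    cols <- ((v - 1L) * ncomp + 1L):(v * ncomp)
    res_blocks[, , v] <- t_mat[cols, , drop = FALSE] %*% K[, cols, drop = FALSE]
  }
  structure(list(t = t_mat, lambda = lambda, method = "ridge",
                 voxel_xyz = lf$voxel_xyz, orientation_mode = lf$orientation_mode,
                 depth_weights = w, res_blocks = res_blocks,
                 channel_labels = lf$channel_labels),
            class = "inverse_operator")
}

#' @export
print.inverse_operator <- function(x, ...) {
  cat(sprintf("<inverse_operator> ridge, lambda %.4g, %d source columns x %d channels\n",
              x$lambda, nrow(x$t), ncol(x$t)))
  invisible(x)
}

#' Select the ridge penalty by generalized cross-validation
#'
#' Minimizes `GCV(lambda) = (||(I - K T_lambda) X||_F^2 / n) /
#' (tr(I - K K'(K K' + lambda I)^-1) / n)^2` over a candidate grid, where
#' `X` stacks the real and imaginary parts of the per-epoch Fourier
#' coefficients across all retained bins and `n` is the channel count.
#' One global penalty is selected over all bins; ties go to the smaller
#' penalty.  Implemented through one eigendecomposition of the Gram matrix
#' shared across the whole candidate grid.
#'
#' @param lf a [lead_field].
#' @param e an [eeg_epochs] supplying the Fourier coefficients.
#' @param grid a [frequency_grid] (default from the epochs).
#' @param lambdas candidate penalties (>= 3 values on a log grid).
#' @param depth_normalize as in [ridge_inverse_operator()].
#' @return The selected penalty, with the full GCV curve as attribute
#'   `"gcv"` (a tibble with columns `lambda`, `gcv`).
#' @export
select_lambda_gcv <- function(lf, e, grid = NULL,
                              lambdas = 10^seq(-6, 2, length.out = 17),
                              depth_normalize = TRUE) {
  stopifnot(inherits(lf, "lead_field"), inherits(e, "eeg_epochs"))
  if (length(lambdas) < 3L)
    stop("provide at least 3 candidate penalties", call. = FALSE)
  N <- n_samples(e); C <- n_channels(e); E <- n_epochs(e)
  if (is.null(grid)) grid <- build_frequency_grid(N, e$fs)
  K <- lf$k
  if (nrow(K) != C) stop("lead field channel count does not match epochs", call. = FALSE)
  if (depth_normalize) {
    ncomp <- if (lf$orientation_mode == "free") 3L else 1L
    nv <- nrow(lf$voxel_xyz)
    for (v in seq_len(nv)) {
      cols <- ((v - 1L) * ncomp + 1L):(v * ncomp)
      nrm <- sqrt(sum(K[, cols]^2))
      if (nrm > 0) K[, cols] <- K[, cols] / nrm
    }
  }
  # X: [channel x (2 * E * n_bins)] stacked Re/Im Fourier coefficients
  X <- matrix(0, C, 2L * E * grid$n_bins)
  col0 <- 0L
  for (ep in seq_len(E)) {
    x <- e$data[ep, , , drop = TRUE]
    dim(x) <- c(N, C)
    x <- sweep(x, 2L, colMeans(x))
    V <- stats::mvfft(x)[grid$k + 1L, , drop = FALSE]
    X[, col0 + seq_len(grid$n_bins)] <- t(Re(V))
    X[, col0 + grid$n_bins + seq_len(grid$n_bins)] <- t(Im(V))
    col0 <- col0 + 2L * grid$n_bins
  }
  if (all(X == 0)) stop("degenerate (zero) data: GCV is undefined", call. = FALSE)
  eg <- eigen(tcrossprod(K), symmetric = TRUE)
  B <- crossprod(eg$vectors, X)          # rotate data into the eigenbasis
  d <- pmax(eg$values, 0)
  gcv <- vapply(lambdas, function(lam) {
    shrink <- lam / (d + lam)            # diagonal of I - D(D + lam)^-1
    rss <- sum((shrink * B)^2) / C
    edf <- sum(shrink) / C
    rss / edf^2
  }, 0)
  lam <- lambdas[min(which(gcv == min(gcv)))]   # ties -> smaller lambda
  attr(lam, "gcv") <- tibble::tibble(lambda = lambdas, gcv = gcv)
  lam
}

#' Source power spectra through an inverse operator
#'
#' Transports the scalp cross-spectrum to source space bin by bin: the
#' diagonal of `T s[k] T'` is extracted as row-wise sums of
#' `(T s[k]) * Conj(T)` without ever materializing the voxel-by-voxel
#' matrix, then summed over each voxel's moment components.  Depth
#' normalization applied when the operator was built is undone here so
#' power is reported in physical (dipole moment)^2 units.
#'
#' @param op an [inverse_operator].
#' @param cs a [cross_spectrum] on the same channels.
#' @param standardize `"none"` (default): report power in physical
#'   (dipole moment)^2 units, undoing the depth scaling.  `"resolution"`:
#'   standardize each voxel's power by the inverse of its diagonal
#'   resolution-matrix block (`j_v' R_vv^{-1} j_v` summed over moment
#'   components) — a dimensionless activity index whose maximum localizes
#'   a single dipole exactly in the noiseless limit, recommended when the
#'   question is *where* rather than *how much*.
#' @return An `nb_spectra` at source level: `power` `[voxel x bin]`,
#'   non-negative.
#' @export
source_spectra <- function(op, cs, standardize = c("none", "resolution")) {
  stopifnot(inherits(op, "inverse_operator"), inherits(cs, "cross_spectrum"))
  standardize <- match.arg(standardize)
  C <- length(cs$channel_labels)
  if (ncol(op$t) != C)
    stop("channel count mismatch between operator and cross-spectrum", call. = FALSE)
  ncomp <- if (op$orientation_mode == "free") 3L else 1L
  nv <- nrow(op$voxel_xyz)
  B <- cs$grid$n_bins
  pw <- matrix(0, nv, B)
  if (standardize == "none") {
    Tm <- op$t * op$depth_weights       # undo column scaling of K: j = W j_w
    grp <- rep(seq_len(nv), each = ncomp)
    for (b in seq_len(B)) {
      sb <- matrix(cs$s[b, , ], C, C)
      diagq <- rowSums(Re((Tm %*% sb) * Tm))   # T real: Conj(T) = T
      pw[, b] <- as.vector(rowsum(diagq, grp))
    }
  } else {
    Tm <- op$t
    binv <- vector("list", nv)
    for (v in seq_len(nv)) {
      blk <- op$res_blocks[, , v]
      binv[[v]] <- solve(blk + diag(1e-12, ncomp))
    }
    for (b in seq_len(B)) {
      sb <- matrix(cs$s[b, , ], C, C)
      TS <- Tm %*% sb
      for (v in seq_len(nv)) {
        cols <- ((v - 1L) * ncomp + 1L):(v * ncomp)
        cov_v <- TS[cols, , drop = FALSE] %*% t(Tm[cols, , drop = FALSE])
        pw[v, b] <- Re(sum(diag(binv[[v]] %*% cov_v)))
      }
    }
  }
  pw[pw < 0] <- 0    # clip PSD rounding at the 1e-12 level
  nb_spectra(pw, cs$grid, labels = paste0("v", seq_len(nv)),
             log10 = FALSE, level = "source")
}
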