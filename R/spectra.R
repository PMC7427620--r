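#' Narrow-band frequency grid
#'
#' The analysis grid holds the DFT bin frequencies of an epoch of
#' `n_samples` points at sampling rate `fs`: consecutive multiples of the
#' resolution `fs / n_samples`, excluding DC, strictly below `fmax_hz`.
#' For the classical 2.56-s epochs sampled at 200 Hz the resolution is
#' 0.390625 Hz, displayed rounded as 0.39 Hz; the default 49-bin grid then
#' carries displayed labels 0.39 ... 19.11 Hz.
#'
#' @param n_samples samples per epoch (>= 2).
#' @param fs sampling rate, Hz.
#' @param fmax_hz upper frequency limit (exclusive); bins at or above it are
#'   dropped.  Must not exceed the Nyquist frequency `fs/2`.
#' @return An object of class `frequency_grid` with fields `bin_hz` (exact
#'   bin frequencies), `resolution_hz` (exact), `n_bins`, and `k` (the DFT
#'   bin indices).
#' @export
build_frequency_grid <- function(n_samples, fs, fmax_hz = 19.5) {
  stopifnot(n_samples >= 2, fs > 0)
  if (fmax_hz <= 0 || fmax_hz > fs / 2)
    stop("`fmax_hz` must lie in (0, fs/2]", call. = FALSE)
  res <- fs / n_samples
  # bins strictly below fmax; when fmax coincides with a bin (e.g. the
  # Nyquist frequency on the full one-sided grid) that bin is retained so
  # Parseval holds exactly
  ratio <- fmax_hz / res
  kmax <- if (abs(ratio - round(ratio)) < 1e-9) round(ratio) else floor(ratio)
  if (kmax < 1)
    stop("`fmax_hz` is below the first frequency bin (", res, " Hz)", call. = FALSE)
  k <- seq_len(kmax)
  structure(list(bin_hz = k * res, resolution_hz = res,
                 n_bins = length(k), k = as.integer(k)),
            class = "frequency_grid")
}

frequency_grid_from_bins <- function(bin_hz, resolution_hz) {
  k <- as.integer(round(bin_hz / resolution_hz))
  structure(list(bin_hz = bin_hz, resolution_hz = resolution_hz,
                 n_bins = length(bin_hz), k = k),
            class = "frequency_grid")
}

#' Displayed (rounded) labels of a frequency grid
#'
#' Bin labels are conventionally printed on the resolution rounded to two
#' decimals: bin k is labelled `k * round(resolution, 2)`.  On the classical
#' 512-sample / 200 Hz grid this yields the familiar 0.39--19.11 Hz labels
#' while the exact frequencies (0.390625--19.140625 Hz) are kept internally.
#'
#' @param grid a [frequency_grid].
#' @return Numeric vector of displayed bin labels in Hz.
#' @export
grid_display_hz <- function(grid) {
  stopifnot(inherits(grid, "frequency_grid"))
  round(grid$k * round(grid$resolution_hz, 2), 2)
}

#' @export
print.frequency_grid <- function(x, ...) {
  lab <- grid_display_hz(x)
  cat(sprintf("<frequency_grid> %d bins, %.2f-%.2f Hz (resolution %.2f Hz; exact %g Hz)\n",
              x$n_bins, lab[1], lab[x$n_bins], round(x$resolution_hz, 2),
              x$resolution_hz))
  invisible(x)
}

grids_compatible <- function(a, b, tol = 1e-9) {
  a$n_bins == b$n_bins && all(abs(a$bin_hz - b$bin_hz) <= tol * pmax(1, a$bin_hz))
}

#' Epoch-averaged cross-spectral matrices
#'
#' Each epoch is mean-corrected per channel, optionally tapered, and
#' transformed by the FFT.  The cross-spectrum at bin k is the average over
#' epochs of the outer product of the channel Fourier coefficients,
#' normalized by `2 / (N^2 U)` (U the mean squared taper weight, 1 for no
#' taper) so that with no taper the sum of the one-sided diagonal spectrum
#' over the full grid (interior bins doubled, Nyquist not) recovers the
#' epoch-mean channel mean square — the Parseval convention of the classical
#' narrow-band model.
#'
#' @param e an [eeg_epochs].
#' @param grid a [frequency_grid] consistent with the epoch length and
#'   sampling rate; default is the standard grid below 19.5 Hz.
#' @param taper `"none"` (default; epochs are expert-selected and short) or
#'   `"hann"`.
#' @return An object of class `cross_spectrum`: complex array `s`
#'   `[bin x channel x channel]` in microvolts squared per bin (Hermitian,
#'   positive semidefinite at every bin), plus `grid`, `channel_labels`,
#'   `n_epochs`, `taper`.
#' @export
cross_spectrum <- function(e, grid = NULL, taper = c("none", "hann")) {
  stopifnot(inherits(e, "eeg_epochs"))
  taper <- match.arg(taper)
  N <- n_samples(e); C <- n_channels(e); E <- n_epochs(e)
  if (N < 2) stop("epochs must have at least 2 samples", call. = FALSE)
  if (is.null(grid)) grid <- build_frequency_grid(N, e$fs)
  if (abs(grid$resolution_hz - e$fs / N) > 1e-9 * grid$resolution_hz)
    stop("frequency grid resolution does not match epoch length and sampling rate",
         call. = FALSE)
  w <- switch(taper,
              none = rep(1, N),
              hann = 0.5 - 0.5 * cos(2 * pi * (seq_len(N) - 1) / N))
  U <- mean(w^2)
  K <- grid$k
  nyq <- (N %% 2 == 0) && any(K == N %/% 2)
  s <- array(0 + 0i, dim = c(length(K), C, C))
  for (ep in seq_len(E)) {
    x <- e$data[ep, , , drop = TRUE]
    dim(x) <- c(N, C)
    x <- sweep(x, 2L, colMeans(x))
    V <- stats::mvfft(x * w)[K + 1L, , drop = FALSE]   # [bin x channel]
    for (b in seq_along(K)) {
      # s_ij = conj(V_i) V_j: a channel lagging behind channel i gets a
      # negative phase difference
      vb <- V[b, ]
      s[b, , ] <- s[b, , ] + outer(Conj(vb), vb)
    }
  }
  s <- s * (2 / (N^2 * U * E))
  if (nyq) {  # Nyquist bin is not doubled (one-sided convention)
    b <- which(K == N %/% 2)
    s[b, , ] <- s[b, , ] / 2
  }
  structure(list(s = s, grid = grid, channel_labels = e$channel_labels,
                 n_epochs = E, taper = taper),
            class = "cross_spectrum")
}

#' @export
print.cross_spectrum <- function(x, ...) {
  cat(sprintf("<cross_spectrum> %d bins x %d channels, %d epoch(s), taper %s\n",
              x$grid$n_bins, length(x$channel_labels), x$n_epochs, x$taper))
  invisible(x)
}

#' Narrow-band power spectra (cross-spectral diagonal)
#'
#' @param cs a [cross_spectrum].
#' @return An object of class `nb_spectra`: real matrix `power`
#'   `[channel x bin]` in microvolts squared per bin, with `grid`,
#'   `channel_labels` and a `log10` flag (FALSE: raw power).
#' @export
narrowband_power <- function(cs) {
  stopifnot(inherits(cs, "cross_spectrum"))
  C <- length(cs$channel_labels)
  B <- cs$grid$n_bins
  p <- matrix(0, C, B, dimnames = list(cs$channel_labels, NULL))
  for (b in seq_len(B)) p[, b] <- Re(diag(matrix(cs$s[b, , ], C, C)))
  p[p < 0 & p > -1e-9 * max(p, 1e-300)] <- 0
  nb_spectra(p, cs$grid, cs$channel_labels, log10 = FALSE)
}

nb_spectra <- function(power, grid, labels, log10 = FALSE, level = "scalp") {
  structure(list(power = power, grid = grid, channel_labels = labels,
                 log10 = log10, level = level),
            class = "nb_spectra")
}

#' @export
print.nb_spectra <- function(x, ...) {
  cat(sprintf("<nb_spectra> %d %s location(s) x %d bins (%s)\n",
              nrow(x$power), x$level, x$grid$n_bins,
              if (x$log10) "log10 power" else "raw power, uV^2"))
  invisible(x)
}

#' @rdname tidy
#' @export
tidy.nb_spectra <- function(x, ...) {
  tibble::tibble(
    channel = rep(rownames(x$power) %||% as.character(seq_len(nrow(x$power))),
                  times = ncol(x$power)),
    frequency = rep(grid_display_hz(x$grid), each = nrow(x$power)),
    power = as.vector(x$power),
    scale = if (x$log10) "log10" else "raw")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Magnitude-squared coherence and phase differences
#'
#' Coherence between leads i and j at bin k is
#' `|s_ij|^2 / (s_ii s_jj)` (magnitude-squared convention, in \[0, 1\]);
#' phase is `arg(s_ij)` in radians.  With a single epoch the coherence of
#' every pair is identically 1 (rank-one cross-spectrum) — a documented
#' degenerate case, not an error.  Pairs involving a zero-power diagonal are
#' flagged undefined (NA) rather than raising.
#'
#' @param cs a [cross_spectrum].
#' @return An object of class `coherence_phase` with arrays `coh` and
#'   `phase` `[bin x channel x channel]` and a logical `undefined` array.
#' @export
coherence_phase <- function(cs) {
  stopifnot(inherits(cs, "cross_spectrum"))
  C <- length(cs$channel_labels)
  B <- cs$grid$n_bins
  coh <- array(NA_real_, dim = c(B, C, C))
  phase <- array(NA_real_, dim = c(B, C, C))
  undef <- array(FALSE, dim = c(B, C, C))
  for (b in seq_len(B)) {
    sb <- matrix(cs$s[b, , ], C, C)
    d <- Re(diag(sb))
    denom <- outer(d, d)
    bad <- denom <= 0
    cb <- Mod(sb)^2 / denom
    cb[bad] <- NA_real_
    cb <- pmin(pmax(cb, 0), 1)   # clip 1e-12-level rounding only
    diag(cb) <- ifelse(d > 0, 1, NA_real_)
    pb <- Arg(sb)
    pb[bad] <- NA_real_
    diag(pb) <- ifelse(d > 0, 0, NA_real_)
    coh[b, , ] <- cb
    phase[b, , ] <- pb
    undef[b, , ] <- bad
  }
  structure(list(coh = coh, phase = phase, undefined = undef,
                 grid = cs$grid, channel_labels = cs$channel_labels,
                 convention = "magnitude-squared"),
            class = "coherence_phase")
}

#' @rdname tidy
#' @export
tidy.coherence_phase <- function(x, ...) {
  C <- length(x$channel_labels)
  B <- x$grid$n_bins
  fr <- grid_display_hz(x$grid)
  tibble::tibble(
    frequency = rep(fr, times = C * C),
    channel_i = rep(rep(x$channel_labels, each = B), times = C),
    channel_j = rep(x$channel_labels, each = B * C),
    coherence = as.vector(x$coh),
    phase = as.vector(x$phase))
}
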