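#' Classical qEEG frequency bands
#'
#' Band edges on the displayed 0.39 Hz grid labels; assignment is half-open
#' `[low, high)` so no bin is counted twice.  The Total band spans the union
#' of the four classical bands.  Edges are configuration-overridable and are
#' written into every output header.
#'
#' @param delta,theta,alpha,beta numeric length-2 `[low, high)` intervals
#'   in Hz.
#' @return An object of class `band_set`: a named list of intervals plus
#'   `Total`.
#' @export
default_bands <- function(delta = c(1.56, 3.90),
                          theta = c(3.90, 7.80),
                          alpha = c(7.80, 12.87),
                          beta  = c(12.87, 19.15)) {
  bands <- list(Delta = delta, Theta = theta, Alpha = alpha, Beta = beta)
  for (b in names(bands)) {
    v <- bands[[b]]
    if (length(v) != 2L || v[1] >= v[2])
      stop("band ", b, " must be [low, high) with low < high", call. = FALSE)
  }
  bands$Total <- c(min(vapply(bands, `[`, 0, 1)), max(vapply(bands, `[`, 0, 2)))
  structure(bands, class = "band_set")
}

band_bins <- function(bands, grid) {
  lab <- grid_display_hz(grid)
  core <- setdiff(names(bands), "Total")
  idx <- lapply(bands[core], function(v) which(lab >= v[1] & lab < v[2]))
  idx$Total <- sort(unique(unlist(idx)))
  for (b in names(idx))
    if (length(idx[[b]]) == 0L)
      stop("band ", b, " contains no frequency bins on this grid", call. = FALSE)
  idx
}

#' Broad-band model parameters: AP, RP, MF
#'
#' Band-integrated spectral parameters of the classical broad-band model:
#' Absolute Power `AP_b = sum of power over the band's bins` (uV^2),
#' Relative Power `RP_b = AP_b / AP_Total` (fraction; not defined for the
#' Total band), and Mean Frequency `MF_b = sum(f * power) / sum(power)`
#' over the band (Hz).  A band with zero power gets its midpoint as MF and
#' is flagged.
#'
#' @param nb raw (non-log) [nb_spectra].
#' @param bands a [default_bands()]-style band set.
#' @return An object of class `broadband_params` with matrices `ap`
#'   `[band x channel]` (incl. Total), `rp` (excl. Total), `mf` (incl.
#'   Total), logical `mf_degenerate` flags, and the band definition.
#' @export
broadband_params <- function(nb, bands = default_bands()) {
  stopifnot(inherits(nb, "nb_spectra"))
  if (nb$log10)
    stop("broadband_params() requires raw power spectra, not log10", call. = FALSE)
  idx <- band_bins(bands, nb$grid)
  f <- nb$grid$bin_hz
  C <- nrow(nb$power)
  nm <- names(idx)
  ap <- matrix(0, length(nm), C, dimnames = list(nm, rownames(nb$power)))
  mf <- ap
  deg <- matrix(FALSE, length(nm), C, dimnames = dimnames(ap))
  for (b in nm) {
    kk <- idx[[b]]
    p <- nb$power[, kk, drop = FALSE]
    ap[b, ] <- rowSums(p)
    num <- as.vector(p %*% f[kk])
    zero <- ap[b, ] <= 0
    mf[b, ] <- ifelse(zero, mean(range(f[kk])), num / ap[b, ])
    deg[b, ] <- zero
  }
  core <- setdiff(nm, "Total")
  rp <- sweep(ap[core, , drop = FALSE], 2L, ap["Total", ], "/")
  rp[, ap["Total", ] <= 0] <- NA_real_
  structure(list(ap = ap, rp = rp, mf = mf, mf_degenerate = deg,
                 bands = bands, grid = nb$grid,
                 channel_labels = rownames(nb$power)),
            class = "broadband_params")
}

#' @export
print.broadband_params <- function(x, ...) {
  cat(sprintf("<broadband_params> %d bands x %d channels (AP uV^2, RP fraction, MF Hz)\n",
              nrow(x$ap), ncol(x$ap)))
  invisible(x)
}

#' @rdname tidy
#' @export
tidy.broadband_params <- function(x, ...) {
  stack1 <- function(m, measure) tibble::tibble(
    measure = measure,
    band = rep(rownames(m), times = ncol(m)),
    channel = rep(colnames(m) %||% as.character(seq_len(ncol(m))), each = nrow(m)),
    value = as.vector(m))
  rbind(stack1(x$ap, "AP"), stack1(x$rp, "RP"), stack1(x$mf, "MF"))
}
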