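#' Re-reference epoched EEG
#'
#' Subtracts a reference signal from every channel at every sample:
#' a named lead, the instantaneous channel mean (`"AVG"`, common average
#' reference — afterwards the channel-mean of every sample is zero), or the
#' mean of the linked earlobes A1 and A2 (`"A1A2"`).  Re-referencing to the
#' same target twice is idempotent.
#'
#' @param e an [eeg_epochs].
#' @param target a channel label present in the montage, `"AVG"`, or
#'   `"A1A2"` (requires channels A1 and A2).
#' @return A re-referenced [eeg_epochs] with its reference descriptor
#'   updated.
#' @export
rereference <- function(e, target) {
  stopifnot(inherits(e, "eeg_epochs"))
  d <- dim(e$data)
  x <- e$data
  if (identical(target, "AVG")) {
    # mean over channels at each (epoch, sample)
    m <- rowMeans(matrix(x, d[1] * d[2], d[3]))
    x <- x - array(m, dim = d)
  } else if (identical(target, "A1A2")) {
    ia <- match(c("a1", "a2"), tolower(e$channel_labels))
    if (anyNA(ia))
      stop("A1A2 re-referencing requires channels A1 and A2; missing ",
           paste(c("A1", "A2")[is.na(ia)], collapse = ", "), call. = FALSE)
    m <- (x[, , ia[1], drop = FALSE] + x[, , ia[2], drop = FALSE]) / 2
    x <- x - array(m, dim = d)
  } else {
    i <- match(tolower(target), tolower(e$channel_labels))
    if (is.na(i))
      stop("reference channel '", target, "' not present in the montage",
           call. = FALSE)
    x <- x - array(x[, , i, drop = FALSE], dim = d)
  }
  e$data <- x
  e$reference <- target
  e
}

#' Global Scale Factor
#'
#' The GSF is a subject-level multiplicative factor on spectral power that
#' absorbs recording-gain variability (amplifier calibration, electrode
#' impedance) unrelated to neurophysiology.  It is estimated on the log10
#' scale as the grand mean deviation of the subject's transformed scalp
#' spectra from the age-appropriate normative mean, so that after
#' correction the grand-mean residual is exactly zero and downstream
#' z-maps are invariant to global amplitude rescaling of the raw EEG.
#'
#' @param value multiplicative factor on power (positive).
#' @return An object of class `gsf` with fields `value` and `log10_value`.
#' @export
gsf <- function(value) {
  stopifnot(is.numeric(value), length(value) == 1L, is.finite(value), value > 0)
  structure(list(value = value, log10_value = log10(value)), class = "gsf")
}

#' @export
print.gsf <- function(x, ...) {
  cat(sprintf("<gsf> value %.6g (log10 %.6g)\n", x$value, x$log10_value))
  invisible(x)
}

#' Estimate the Global Scale Factor against normative means
#'
#' `log10(GSF)` is the arithmetic mean over all channels and frequency bins
#' of `y - mu` — the maximum-likelihood estimate under i.i.d. Gaussian
#' log-residuals, and the unique value that zeroes the grand-mean residual
#' after [apply_gsf()].
#'
#' @param y transformed (log10-power) scalp spectra, matrix
#'   `[channel x bin]`.
#' @param mu normative means evaluated at the subject's age, same shape.
#' @return A [gsf].
#' @export
estimate_gsf <- function(y, mu) {
  y <- as.matrix(y); mu <- as.matrix(mu)
  if (!all(dim(y) == dim(mu)))
    stop("`y` and `mu` must have identical shapes", call. = FALSE)
  if (length(y) == 0L) stop("empty spectra", call. = FALSE)
  if (!all(is.finite(y)) || !all(is.finite(mu)))
    stop("non-finite values in spectra or norms", call. = FALSE)
  gsf(10^mean(y - mu))
}

#' Apply a Global Scale Factor correction
#'
#' Subtracts `log10(GSF)` from transformed (log10) spectra; equivalently
#' divides raw power by the factor.
#'
#' @param y transformed spectra (matrix or [nb_spectra] with the log10 flag
#'   set).
#' @param g a [gsf].
#' @return Corrected object of the same type as `y`.
#' @export
apply_gsf <- function(y, g) {
  stopifnot(inherits(g, "gsf"))
  if (inherits(y, "nb_spectra")) {
    if (!y$log10) stop("apply_gsf() expects log10-transformed spectra", call. = FALSE)
    y$power <- y$power - g$log10_value
    return(y)
  }
  as.matrix(y) - g$log10_value
}
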