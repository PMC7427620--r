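#' Epoched multichannel EEG recordings
#'
#' An `eeg_epochs` object holds artifact-free analysis windows of a
#' multichannel EEG recording together with its sampling metadata.  Values
#' are scalp potentials in microvolts stored as a 3-way array indexed
#' `[epoch, sample, channel]`.
#'
#' @param data numeric array `[epoch x sample x channel]`, microvolts.
#' @param fs sampling rate in Hz (positive scalar).
#' @param channel_labels character vector of unique channel labels, one per
#'   channel, in recording order.
#' @param reference reference descriptor: a channel label, `"AVG"` (common
#'   average) or `"A1A2"` (linked earlobes).
#' @param age subject age in years (positive scalar).
#' @param state recording state, one of `"EC"` (eyes closed), `"EO"` (eyes
#'   open), `"HV"` (hyperventilation).
#' @param id subject identifier string.
#'
#' @return An object of class `eeg_epochs`.
#' @export
eeg_epochs <- function(data, fs, channel_labels,
                       reference = "AVG",
                       age = 30, state = "EC", id = "anonymous") {
  if (!is.array(data) || length(dim(data)) != 3L)
    stop("`data` must be a 3-way array [epoch x sample x channel]", call. = FALSE)
  storage.mode(data) <- "double"
  if (!all(is.finite(data)))
    stop("epoch data contain non-finite samples", call. = FALSE)
  if (!is.numeric(fs) || length(fs) != 1L || fs <= 0)
    stop("`fs` must be a positive scalar (Hz)", call. = FALSE)
  channel_labels <- as.character(channel_labels)
  if (length(channel_labels) != dim(data)[3L])
    stop("number of channel labels must equal the channel dimension", call. = FALSE)
  if (anyDuplicated(channel_labels))
    stop("duplicate channel label: ",
         paste(unique(channel_labels[duplicated(channel_labels)]), collapse = ", "),
         call. = FALSE)
  if (!is.numeric(age) || length(age) != 1L || age <= 0)
    stop("`age` must be a positive number of years", call. = FALSE)
  state <- match.arg(state, c("EC", "EO", "HV"))
  structure(
    list(data = data, fs = as.numeric(fs), channel_labels = channel_labels,
         reference = as.character(reference),
         subject = list(age = as.numeric(age), state = state, id = as.character(id))),
    class = "eeg_epochs")
}

#' @export
print.eeg_epochs <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<eeg_epochs> %d epoch(s) x %d samples x %d channels @ %g Hz\n",
              d[1], d[2], d[3], x$fs))
  cat(sprintf("  reference: %s | subject: %s, age %g y, state %s\n",
              x$reference, x$subject$id, x$subject$age, x$subject$state))
  invisible(x)
}

#' @export
dim.eeg_epochs <- function(x) dim(x$data)

n_epochs <- function(e) dim(e$data)[1L]
n_samples <- function(e) dim(e$data)[2L]
n_channels <- function(e) dim(e$data)[3L]

#' Tidy an epoch set into a long tibble
#'
#' @param x an [eeg_epochs] object.
#' @param ... unused.
#' @return A tibble with columns `epoch`, `time` (seconds from epoch start),
#'   `channel`, `amplitude` (microvolts).
#' @export
tidy.eeg_epochs <- function(x, ...) {
  d <- dim(x$data)
  tibble::tibble(
    epoch = rep(seq_len(d[1]), times = d[2] * d[3]),
    time = rep(rep((seq_len(d[2]) - 1) / x$fs, each = d[1]), times = d[3]),
    channel = rep(x$channel_labels, each = d[1] * d[2]),
    amplitude = as.vector(x$data))
}

#' Generic tidiers
#'
#' `tidy()` turns a qeegnorm result object into a long tibble;
#' `glance()` gives a one-row model summary.  These follow the broom
#' conventions.
#' @param x object to tidy.
#' @param ... passed to methods.
#' @export
tidy <- function(x, ...) UseMethod("tidy")

#' @rdname tidy
#' @export
glance <- function(x, ...) UseMethod("glance")
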