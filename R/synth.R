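#' Specification of a synthetic normative cohort
#'
#' Defines the generative model a synthetic cohort is drawn from: per-bin
#' log10-power means that are linear in `u = log10(age)` — a 1/f-like
#' baseline plus a Gaussian alpha peak near 10 Hz whose amplitude drifts
#' with age — with Gaussian log-residuals of constant SD.  Both mean
#' coefficients are exactly polynomial in `u`, so they sit inside the model
#' family the normative fitter assumes; the cohort mirrors the classical
#' normative study conditions (211 subjects, ages 5--87, eyes closed).
#'
#' @param n_subjects cohort size (default 211).
#' @param age_range ages drawn uniformly on this range (default `c(5, 87)`).
#' @param grid [frequency_grid] the spectra live on.
#' @param channel_labels location labels (default the 19-lead 10--20
#'   montage).
#' @param base_intercept,base_slope baseline log10-power: intercept and
#'   slope of the `-log10(f)` term at `u = 0` (power-law EEG background).
#' @param age_slope coefficient of `u` in the bin mean (global slowing
#'   with log-age; default -0.5).
#' @param peak_hz,peak_width_hz,peak_amp,peak_age_slope alpha-peak model:
#'   center (Hz), Gaussian width (Hz), amplitude at `u = 0` and its slope
#'   in `u` (log10-power units).
#' @param sigma_gen residual SD in log10-power units (default 0.2).
#' @param state recording state tag.
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_subjects = 211L, age_range = c(5, 87),
                        grid = build_frequency_grid(512, 200),
                        channel_labels = load_montage("10-20-19")$labels,
                        base_intercept = 1.5, base_slope = 1.0,
                        age_slope = -0.5,
                        peak_hz = 10.15, peak_width_hz = 1.5,
                        peak_amp = 0.3, peak_age_slope = 0.25,
                        sigma_gen = 0.2, state = "EC") {
  stopifnot(n_subjects >= 1, age_range[1] > 0, age_range[1] < age_range[2],
            sigma_gen >= 0)
  structure(list(n_subjects = as.integer(n_subjects), age_range = age_range,
                 grid = grid, channel_labels = channel_labels,
                 base_intercept = base_intercept, base_slope = base_slope,
                 age_slope = age_slope, peak_hz = peak_hz,
                 peak_width_hz = peak_width_hz, peak_amp = peak_amp,
                 peak_age_slope = peak_age_slope, sigma_gen = sigma_gen,
                 state = state),
            class = "cohort_spec")
}

#' Generator truth: normative mean surface of a cohort spec
#'
#' The exact log10-power mean `[channel x bin]` the generator uses at a
#' given age — the ground truth that a fitted [norm_model] should recover.
#'
#' @param spec a [cohort_spec].
#' @param age age in years.
#' @return Matrix `[channel x bin]` of log10 power.
#' @export
cohort_truth_mu <- function(spec, age) {
  u <- log10(age)
  f <- spec$grid$bin_hz
  peak <- exp(-((f - spec$peak_hz)^2) / (2 * spec$peak_width_hz^2))
  bin_mu <- spec$base_intercept - spec$base_slope * log10(f) +
    spec$age_slope * u + (spec$peak_amp + spec$peak_age_slope * u) * peak
  # small fixed per-channel offset (posterior channels get more alpha-band
  # weight), deterministic in the channel index
  C <- length(spec$channel_labels)
  choff <- 0.05 * sin(seq_len(C))
  outer(choff, rep(1, length(f))) + matrix(bin_mu, C, length(f), byrow = TRUE)
}

#' Draw a synthetic normative cohort
#'
#' Ages are uniform on the spec's range; each subject's log10 spectrum is
#' the generator mean at their age plus i.i.d. Gaussian noise of SD
#' `sigma_gen`.  With `realize = "epochs"` the spectra are additionally
#' realized as time-domain epochs by inverse-DFT spectral shaping with
#' per-epoch random phases (each bin a cosine of amplitude
#' `sqrt(2 * power)`), which reproduces the target periodogram exactly at
#' every retained bin, so the full pipeline — not just the norms stage —
#' can consume the cohort.  Identical spec and seed give an identical
#' cohort.
#'
#' @param spec a [cohort_spec].
#' @param seed integer seed.
#' @param realize `"spectra"` (default; fast) or `"epochs"`.
#' @param n_epochs,epoch_samples,fs epoch geometry when realizing epochs
#'   (defaults 24 epochs of 512 samples at 200 Hz).
#' @return A list with `ages` and either `spectra` (list of raw-power
#'   `[channel x bin]` matrices) or `epochs` (list of [eeg_epochs]).
#' @export
make_cohort <- function(spec, seed = 1L, realize = c("spectra", "epochs"),
                        n_epochs = 24L, epoch_samples = 512L, fs = 200) {
  stopifnot(inherits(spec, "cohort_spec"))
  realize <- match.arg(realize)
  set.seed(seed)
  ages <- stats::runif(spec$n_subjects, spec$age_range[1], spec$age_range[2])
  C <- length(spec$channel_labels)
  B <- spec$grid$n_bins
  spectra <- vector("list", spec$n_subjects)
  for (i in seq_len(spec$n_subjects)) {
    mu <- cohort_truth_mu(spec, ages[i])
    ly <- mu + spec$sigma_gen * matrix(stats::rnorm(C * B), C, B)
    spectra[[i]] <- 10^ly
  }
  out <- list(ages = ages, spec = spec)
  if (realize == "spectra") {
    out$spectra <- spectra
  } else {
    out$epochs <- lapply(seq_len(spec$n_subjects), function(i)
      epochs_from_spectrum(spectra[[i]], spec$grid, spec$channel_labels,
                           n_epochs, epoch_samples, fs,
                           age = ages[i], state = spec$state,
                           id = sprintf("synth%03d", i)))
  }
  out
}

# Spectral shaping: time-domain epochs whose periodogram at every retained
# bin equals `power` exactly (random phase per epoch and bin).
epochs_from_spectrum <- function(power, grid, labels, n_epochs,
                                 epoch_samples, fs, age, state, id) {
  stopifnot(abs(grid$resolution_hz - fs / epoch_samples) < 1e-9)
  C <- nrow(power); B <- grid$n_bins; N <- epoch_samples
  tt <- (seq_len(N) - 1) / fs
  arg <- 2 * pi * outer(tt, grid$bin_hz)          # [N x B]
  amp <- sqrt(2 * power)                          # periodogram A^2/2 = power
  data <- array(0, dim = c(n_epochs, N, C))
  for (ep in seq_len(n_epochs)) {
    ph <- matrix(stats::runif(C * B, 0, 2 * pi), C, B)
    for (c in seq_len(C))
      data[ep, , c] <- cos(sweep(arg, 2L, ph[c, ], "+")) %*% amp[c, ]
  }
  eeg_epochs(data, fs = fs, channel_labels = labels, reference = "AVG",
             age = age, state = state, id = id)
}

#' Build the subject-by-response matrix for the norms fitter
#'
#' Stacks a cohort's transformed (log10) spectra into the
#' `[subject x (location*bin)]` matrix [fit_norm_model()] consumes
#' (locations varying fastest, matching `as.vector` of a
#' `[location x bin]` matrix).
#'
#' @param cohort a [make_cohort()] result with `$spectra`.
#' @return Numeric matrix `[subject x (location*bin)]` of log10 power.
#' @export
cohort_response_matrix <- function(cohort) {
  stopifnot(!is.null(cohort$spectra))
  do.call(rbind, lapply(cohort$spectra, function(p) as.vector(transform_spectra(p))))
}

#' Specification of a single-dipole scalp simulation
#'
#' @param voxel index of the active voxel in the lead field.
#' @param orientation unit 3-vector dipole moment direction (free mode) or
#'   `"radial"`.
#' @param freq_hz oscillation frequency; must sit on the epoch's DFT grid.
#' @param snr_db target signal-to-noise ratio at the oscillation bin, in
#'   dB (signal bin power over noise bin power, channel-averaged).
#' @param n_epochs,epoch_samples,fs epoch geometry.
#' @param moment dipole moment amplitude (arbitrary units, default 1).
#' @return An object of class `dipole_sim_spec`.
#' @export
dipole_sim_spec <- function(voxel, orientation = "radial", freq_hz = 10.15625,
                            snr_db = 20, n_epochs = 50L, epoch_samples = 512L,
                            fs = 200, moment = 1) {
  stopifnot(is.finite(snr_db), freq_hz > 0, freq_hz < fs / 2)
  kk <- freq_hz * epoch_samples / fs
  if (abs(kk - round(kk)) > 1e-6)
    stop("oscillation frequency must lie on the DFT grid (a multiple of fs/N)",
         call. = FALSE)
  structure(list(voxel = as.integer(voxel), orientation = orientation,
                 freq_hz = freq_hz, snr_db = snr_db,
                 n_epochs = as.integer(n_epochs),
                 epoch_samples = as.integer(epoch_samples), fs = fs,
                 moment = moment),
            class = "dipole_sim_spec")
}

#' Simulate scalp epochs from a single oscillating dipole
#'
#' Scalp data are the lead-field projection of a sinusoidal dipole moment
#' with a random phase per epoch, plus white sensor noise scaled so the
#' channel-averaged periodogram power ratio at the oscillation bin matches
#' the requested SNR.  Identical spec, lead field and seed give identical
#' epochs.
#'
#' @param spec a [dipole_sim_spec].
#' @param lf a [lead_field].
#' @param seed integer seed.
#' @return An [eeg_epochs] of simulated scalp data.
#' @export
simulate_dipole_epochs <- function(spec, lf, seed = 1L) {
  stopifnot(inherits(spec, "dipole_sim_spec"), inherits(lf, "lead_field"))
  nv <- nrow(lf$voxel_xyz)
  if (spec$voxel < 1 || spec$voxel > nv)
    stop("voxel index out of range", call. = FALSE)
  set.seed(seed)
  ncomp <- if (lf$orientation_mode == "free") 3L else 1L
  cols <- ((spec$voxel - 1L) * ncomp + 1L):(spec$voxel * ncomp)
  if (identical(spec$orientation, "radial")) {
    b <- lf$voxel_xyz[spec$voxel, ]
    f0 <- sqrt(sum(b^2))
    ori <- if (f0 > 1e-12) b / f0 else c(0, 0, 1)
  } else {
    ori <- spec$orientation / sqrt(sum(spec$orientation^2))
  }
  gain <- if (ncomp == 3L) as.vector(lf$k[, cols] %*% ori) else lf$k[, cols]

  N <- spec$epoch_samples; C <- nrow(lf$k); E <- spec$n_epochs
  tt <- (seq_len(N) - 1) / spec$fs
  A <- spec$moment
  # per-channel signal bin power A_c^2 / 2 with A_c = gain_c * A
  sig_bin <- mean((gain * A)^2 / 2)
  # white noise of variance v has expected one-sided bin power 2 v / N
  noise_var <- sig_bin / 10^(spec$snr_db / 10) * N / 2
  data <- array(0, dim = c(E, N, C))
  for (ep in seq_len(E)) {
    ph <- stats::runif(1, 0, 2 * pi)
    src <- A * sin(2 * pi * spec$freq_hz * tt + ph)
    data[ep, , ] <- outer(src, gain) +
      matrix(stats::rnorm(N * C, sd = sqrt(noise_var)), N, C)
  }
  eeg_epochs(data, fs = spec$fs, channel_labels = lf$channel_labels,
             reference = "AVG", age = 30, state = "EC", id = "dipole-sim")
}
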