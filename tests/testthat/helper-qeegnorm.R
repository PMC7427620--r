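# shared fixtures and independent oracles, built in code at test time

# epochs containing bin-aligned sinusoids: freqs k0/N*fs per channel
sinusoid_epochs <- function(k0, amp = 1, phase = 0, N = 512, fs = 200,
                            n_epochs = 1, labels = NULL) {
  C <- length(k0)
  amp <- rep_len(amp, C); phase <- rep_len(phase, C)
  tt <- (seq_len(N) - 1) / fs
  d <- array(0, dim = c(n_epochs, N, C))
  for (c in seq_len(C))
    for (ep in seq_len(n_epochs))
      d[ep, , c] <- amp[c] * sin(2 * pi * k0[c] * fs / N * tt + phase[c])
  eeg_epochs(d, fs, labels %||% paste0("ch", seq_len(C)))
}

noise_epochs <- function(E, N, C, fs = 200, seed = 1, labels = NULL) {
  set.seed(seed)
  eeg_epochs(array(stats::rnorm(E * N * C), dim = c(E, N, C)), fs,
             labels %||% paste0("ch", seq_len(C)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# brute-force O(N^2) DFT-sum cross-spectrum oracle, independent of the fft
# path: direct complex exponential sums, same normalization convention
oracle_cross_spectrum <- function(e, grid, taper = "none") {
  N <- dim(e$data)[2]; C <- dim(e$data)[3]; E <- dim(e$data)[1]
  w <- if (taper == "hann") 0.5 - 0.5 * cos(2 * pi * (seq_len(N) - 1) / N)
       else rep(1, N)
  U <- mean(w^2)
  s <- array(0 + 0i, dim = c(grid$n_bins, C, C))
  for (ep in seq_len(E)) {
    x <- matrix(e$data[ep, , ], N, C)
    x <- sweep(x, 2, colMeans(x))
    x <- x * w
    for (b in seq_along(grid$k)) {
      k <- grid$k[b]
      ex <- exp(-2i * pi * k * (seq_len(N) - 1) / N)
      v <- as.vector(t(x) %*% ex)          # direct DFT sum per channel
      s[b, , ] <- s[b, , ] + outer(Conj(v), v)
    }
  }
  s <- s * (2 / (N^2 * U * E))
  if (N %% 2 == 0 && any(grid$k == N %/% 2))
    s[which(grid$k == N %/% 2), , ] <- s[which(grid$k == N %/% 2), , ] / 2
  s
}

# small cached objects shared across files (built once per test run)
cached <- local({
  env <- new.env()
  function(name, builder) {
    if (is.null(env[[name]])) env[[name]] <- builder()
    env[[name]]
  }
})

test_montage <- function() cached("montage", function() load_montage("10-20-19"))
test_leadfield <- function()
  cached("leadfield", function() spherical_leadfield(test_montage()))
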