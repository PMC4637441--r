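# Shared fixtures and independent oracles.

# pure tone, unit amplitude
sinusoid <- function(freq_hz, n = 512, fs = 128, phase = 0) {
  sin(2 * pi * freq_hz * (seq_len(n) - 1L) / fs + phase)
}

# independent band-power oracle: fraction of total spectral energy
# inside [lo, hi) Hz, via the discrete Fourier transform
fft_band_fraction <- function(x, fs, lo, hi) {
  n <- length(x)
  p <- Mod(stats::fft(x))^2
  freqs <- (seq_len(n) - 1L) / n * fs
  # fold onto 0..fs/2
  freqs <- pmin(freqs, fs - freqs)
  sum(p[freqs >= lo & freqs < hi]) / sum(p)
}

signal_energy <- function(x) sum(x^2)

# small epoch with given per-channel generator (function of channel idx)
make_epoch <- function(n = 256, fs = 128, channel_fun = NULL,
                       tester = 1, event = 1, task = "online payment") {
  if (is.null(channel_fun)) {
    channel_fun <- function(ci) rnorm(n)
  }
  v <- vapply(1:8, channel_fun, numeric(n))
  eeg_epoch(tester, event, task, v, fs = fs)
}

# the published sample rows of the record layout (11 rows, tester 01,
# event 1), used for parsing and re-reference arithmetic checks
sample_record_lines <- function(delim = "\t") {
  header <- paste(c("Tester", "Event", "Minutes", "Seconds",
                    paste("Channel", 1:8), "Baseline"), collapse = delim)
  rows <- list(
    c("Number 01", 1, 3.511, 210.633, 33.925, 10.482, 36.855, -1.352,
      5.072, 7.101, 47.675, -135.587, -738.123),
    c("Number 01", 1, 3.511, 210.641, 25.359, 5.410, 41.251, 11.158,
      12.172, 17.921, 74.387, -129.163, -738.123),
    c("Number 01", 1, 3.511, 210.648, 35.954, 31.784, 50.719, 32.798,
      27.388, 29.417, 64.920, -93.322, -738.123),
    c("Number 01", 1, 3.511, 210.656, 6.875, 41.251, 32.798, 43.618,
      26.712, 36.179, 81.826, -66.610, -738.123),
    c("Number 01", 1, 3.511, 210.664, 53.085, 70.330, 78.445, 78.445,
      66.948, 59.848, 120.710, -34.827, -738.123),
    c("Number 01", 1, 3.511, 210.672, 63.342, 68.639, 74.049, 66.948,
      65.934, 61.877, 113.271, -3.381, -738.123),
    c("Number 01", 1, 3.511, 210.680, 84.869, 104.818, 130.178, 125.782,
      113.271, 113.948, 159.594, 29.079, -738.123),
    c("Number 01", 1, 3.511, 210.688, 168.385, 151.479, 197.802, 160.609,
      167.709, 138.292, 180.220, 51.395, -738.123),
    c("Number 01", 1, 3.512, 210.695, 194.759, 149.789, 201.860, 160.270,
      192.392, 152.494, 207.608, 104.480, -738.123),
    c("Number 01", 1, 3.512, 210.703, 257.875, 200.507, 253.593, 218.090,
      234.658, 196.788, 234.996, 143.026, -738.123),
    c("Number 01", 1, 3.512, 210.711, 238.377, 187.658, 207.270, 184.277,
      180.220, 170.752, 183.263, 123.415, -738.123))
  c(header, vapply(rows, paste, "", collapse = delim))
}

write_sample_records <- function(path = tempfile(fileext = ".tsv"),
                                 delim = "\t") {
  writeLines(sample_record_lines(delim), path)
  path
}

# tiny cohort for pipeline-level tests: fast but structurally complete
tiny_preset <- function(seed = 1, ...) {
  headline_preset(seed = seed, n_subjects = 2, n_trained = 1,
                  n_events = 4, epoch_duration_s = 2, ...)
}
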