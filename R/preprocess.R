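# Denoising: common average re-referencing followed by wavelet-subband
# removal of components above 30 Hz.

#' Common average reference
#'
#' Re-references every channel to the instantaneous mean across the 8
#' scalp channels: `out[t, c] = in[t, c] - mean_c(in[t, .])`. The
#' subtracted series is kept as `reference_series`. After CAR the
#' per-sample channel mean is identically zero, removing common-mode
#' signal (the stored baseline column plays no role here).
#'
#' @param epoch An [eeg_epoch()].
#' @return The epoch with class `referenced_epoch` prepended and an
#'   extra `reference_series` field; the input is not modified.
#' @export
common_average_reference <- function(epoch) {
  stopifnot(inherits(epoch, "eeg_epoch"))
  v <- epoch$voltages
  bad <- which(!is.finite(v))
  if (length(bad)) {
    stop("non-finite voltage at sample ",
         ((bad[1L] - 1L) %% nrow(v)) + 1L, call. = FALSE)
  }
  ref <- rowMeans(v)
  epoch$voltages <- v - ref
  epoch$reference_series <- ref
  if (!inherits(epoch, "referenced_epoch")) {
    class(epoch) <- c("referenced_epoch", class(epoch))
  }
  epoch
}

#' Wavelet low-pass below 30 Hz
#'
#' Removes the high-frequency content of a single-channel series by
#' zeroing, in a four-level db5 packet decomposition, every
#' frequency-ordered leaf lying entirely above 30 Hz (leaves 8-15, i.e.
#' 32 Hz and up at `fs = 128`), then reconstructing to the original
#' length. The 28-32 Hz leaf straddles the cut and is kept, because the
#' beta band is defined through the subband ending at 32 Hz.
#'
#' @param signal Numeric single-channel series in microvolts, length
#'   >= 16.
#' @param fs Sampling frequency in Hz (the subband arithmetic assumes
#'   128).
#' @param spec A [wavelet_spec()].
#' @return Filtered series, same length as the input.
#' @export
wavelet_lowpass_30 <- function(signal, fs = 128, spec = wavelet_spec()) {
  if (length(signal) < 2L^spec$levels) {
    stop("signal too short to low-pass filter (need >= ", 2L^spec$levels,
         " samples)", call. = FALSE)
  }
  tree <- wpt_decompose(signal, spec = spec, fs = fs)
  keep_freq <- 0:7   # leaves below 32 Hz
  wpt_reconstruct(tree, keep = natural_order(tree$levels, keep_freq))
}

#' Full epoch preprocessing
#'
#' Applies the two denoising steps in order: common average reference,
#' then the per-channel wavelet low-pass above 30 Hz.
#'
#' @param epoch An [eeg_epoch()].
#' @param spec A [wavelet_spec()].
#' @return A `referenced_epoch` with filtered voltages.
#' @export
preprocess_epoch <- function(epoch, spec = wavelet_spec()) {
  ref <- common_average_reference(epoch)
  ref$voltages <- apply(ref$voltages, 2, wavelet_lowpass_30,
                        fs = ref$fs, spec = spec)
  ref
}
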