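# Shared small fixtures: coarse binnings keep reconvolution fits fast.

bin64 <- time_binning(64)
bin128 <- time_binning(128)
bin256 <- time_binning(256)

irf256 <- make_gaussian_irf(fwhm_ps = 300, center_ns = 2, binning = bin256)
irf128 <- make_gaussian_irf(fwhm_ps = 400, center_ns = 3, binning = bin128)

# Direct O(N^2) circular convolution, the independent oracle for the FFT path.
convolve_direct <- function(signal, kernel) {
  n <- length(signal)
  out <- numeric(n)
  for (j in seq_len(n)) {
    idx <- ((j - seq_len(n)) %% n) + 1L
    out[j] <- sum(signal * kernel[idx])
  }
  out
}

# A noiseless histogram: rounded expected counts at a large amplitude, so
# quantization is negligible relative to the signal.
noiseless_histogram <- function(params, irf) {
  decay_histogram(round(forward_model(params, irf)), irf$binning)
}
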