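# Common generator configurations used across tests.

clean_params <- function(n_strides = 10, seed = 1, ...) {
  gait_params(stride_time_cv = 0, waveform_noise_sd = 0,
              within_cycle_shape_jitter = 0,
              n_strides = n_strides, seed = seed, ...)
}

# A trimmed recording + segmentation pair ready for preprocessing.
prepared_recording <- function(params) {
  rec <- generate_recording(params)
  seg <- segment_strides(rec)
  trim_first_last(rec, seg)
}

# Split a recording channel into per-cycle matrices on the ground-truth
# boundaries, each cycle linearly resampled to n_out points (local helper,
# independent of segment_resample).
cycles_matrix <- function(rec, variable, n_out = 100) {
  b <- rec$true_boundaries
  x <- rec[[variable]]
  k <- length(b) - 1
  out <- matrix(NA_real_, nrow = k, ncol = n_out)
  for (i in seq_len(k)) {
    seg <- x[b[i]:(b[i + 1] - 1)]
    out[i, ] <- approx(seq(0, 1, length.out = length(seg)), seg,
                       seq(0, 1, length.out = n_out))$y
  }
  out
}
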