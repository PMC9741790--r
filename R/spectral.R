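#' One-sided power spectrum with a cumulative-power bandwidth summary
#'
#' Mean-removed periodogram of a series (rectangular window by default,
#' Hann optional), folded to one side and normalised so that the summed
#' power equals the population variance of the series (Parseval; exact for
#' the rectangular window). The summary frequency is the smallest frequency
#' below which a configurable fraction (default 99%) of the total power
#' lies — a conservative reading of "the highest frequencies present",
#' used to pick a biologically meaningful template length for the entropy
#' analysis.
#'
#' @param series Numeric series (length >= 16) or `processed_signal`.
#' @param sampling_rate Hz.
#' @param window `"rectangular"` (default) or `"hann"`.
#' @param cum_threshold Cumulative-power fraction defining
#'   `highest_relevant_frequency` (default 0.99).
#' @return An object of class `spectrum_summary`: list with `frequencies`
#'   (Hz, positive frequencies up to Nyquist), `power`, and
#'   `highest_relevant_frequency` (Hz).
#' @export
power_spectrum <- function(series, sampling_rate,
                           window = c("rectangular", "hann"),
                           cum_threshold = 0.99) {
  x <- if (inherits(series, "processed_signal")) series$values else series
  x <- as.numeric(x)
  window <- match.arg(window)
  n <- length(x)
  if (n < 16) {
    stop_gait("gaitsampen_length_error",
              "series must have at least 16 samples for a spectrum")
  }
  if (sampling_rate <= 0) {
    stop_gait("gaitsampen_parameter_error", "'sampling_rate' must be > 0")
  }
  x <- x - mean(x)
  if (pop_sd(x) == 0) {
    stop_gait("gaitsampen_degenerate_signal",
              "constant series has no defined spectrum")
  }
  w <- if (window == "hann") {
    0.5 * (1 - cos(2 * pi * (seq_len(n) - 1) / (n - 1)))
  } else {
    rep(1, n)
  }
  xw <- x * w
  X <- fft(xw)
  # one-sided fold normalised so sum(power) = population variance
  # (exact by Parseval for the rectangular window; window-power corrected
  # otherwise)
  half <- floor(n / 2)
  k <- seq_len(half)                     # positive frequencies incl. Nyquist
  p <- Mod(X[k + 1])^2 / (n^2 * mean(w^2))
  double_it <- if (n %% 2 == 0) k < half else rep(TRUE, half)
  p[double_it] <- 2 * p[double_it]
  freqs <- k * sampling_rate / n
  cum <- cumsum(p) / sum(p)
  hi <- freqs[which(cum >= cum_threshold)[1]]
  structure(
    list(frequencies = freqs, power = p, highest_relevant_frequency = hi,
         cum_threshold = cum_threshold, window = window),
    class = "spectrum_summary"
  )
}

#' @export
print.spectrum_summary <- function(x, ...) {
  cat(sprintf(
    "<spectrum_summary> %d bins up to %.3g Hz; %.0f%% of power below %.3g Hz\n",
    length(x$frequencies), max(x$frequencies), 100 * x$cum_threshold,
    x$highest_relevant_frequency))
  invisible(x)
}

#' Shortest neuromotor-relevant time interval
#'
#' Given the highest frequency with meaningful power in a locomotion signal
#' (about 16 Hz for vertical force and fore-aft COP, about 24 Hz
#' medio-laterally), returns the period `1 / f` rounded (half up) to three
#' decimals: changes unfolding over intervals longer than this can reflect
#' a modification of the neuromotor or mechanical state rather than noise.
#'
#' @param max_frequency Hz, > 0.
#' @return Seconds, rounded to 3 decimals (e.g. 16 Hz -> 0.063 s).
#' @export
min_neuromotor_interval <- function(max_frequency) {
  if (!is.numeric(max_frequency) || length(max_frequency) != 1L ||
      max_frequency <= 0) {
    stop_gait("gaitsampen_parameter_error", "'max_frequency' must be > 0")
  }
  round_half_up(1 / max_frequency, 3)
}

#' Time span covered by an entropy template after resampling
#'
#' After each stride is resampled to `samples_per_cycle` points, an m-sample
#' template covers `m / samples_per_cycle` of a stride, i.e.
#' `m * mean_stride_time / samples_per_cycle` seconds. Comparing this span
#' with [min_neuromotor_interval()] justifies the template length: with
#' 100 points per cycle and a 1.06 s stride, m = 6 spans 0.064 s and m + 1
#' spans 0.074 s, just above the 0.063 s neuromotor threshold at 16 Hz.
#'
#' @param m Template length in samples.
#' @param mean_stride_time Seconds.
#' @param samples_per_cycle Points per resampled stride.
#' @return Seconds, rounded (half up) to 3 decimals.
#' @export
template_time_span <- function(m, mean_stride_time, samples_per_cycle) {
  if (any(c(m, mean_stride_time, samples_per_cycle) <= 0)) {
    stop_gait("gaitsampen_parameter_error", "all arguments must be > 0")
  }
  round_half_up(m * mean_stride_time / samples_per_cycle, 3)
}
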