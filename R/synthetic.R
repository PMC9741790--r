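#' Parameters for the synthetic treadmill-gait generator
#'
#' Bundles every knob of the synthetic recording generator into a validated
#' list. The defaults emulate treadmill walking at a comfortable speed:
#' strides of 1.06 s mean duration sampled at 100 Hz, a fore-aft
#' centre-of-pressure (COPap) excursion of about 60 mm per stride, a lateral
#' (COPml) oscillation of about 25 mm, and a resultant vertical ground
#' reaction force (vGRF) fluctuating around body weight with the familiar
#' double-peaked stance profile of each foot.
#'
#' @param sampling_rate Sampling rate in Hz.
#' @param mean_stride_time Mean stride duration in seconds.
#' @param stride_time_cv Coefficient of variation of stride duration
#'   (dimensionless, >= 0). Stride times are drawn from a normal
#'   distribution truncated at +/- 3 SD so no stride collapses to zero.
#' @param n_strides Number of strides to generate (>= 2).
#' @param copap_amplitude Peak fore-aft COP excursion per stride (mm).
#' @param copml_amplitude Peak lateral COP excursion (mm).
#' @param body_weight Mean level of the resultant vGRF (N).
#' @param waveform_noise_sd Standard deviation of additive white measurement
#'   noise, in each channel's own units. Length 1 (shared) or 3 (named
#'   `copap`, `copml`, `vgrf`).
#' @param drift_rate Linear positional drift applied to both COP channels,
#'   in mm per second.
#' @param within_cycle_shape_jitter Dimensionless magnitude of the smooth
#'   stride-to-stride deformation of the within-cycle waveform. Length 1 or
#'   3 as for `waveform_noise_sd`. 0 gives identical cycles.
#' @param seed Integer seed; the generator is fully deterministic given it.
#'
#' @return An object of class `gait_params`.
#' @seealso [generate_recording()]
#' @export
gait_params <- function(sampling_rate = 100,
                        mean_stride_time = 1.06,
                        stride_time_cv = 0.02,
                        n_strides = 30,
                        copap_amplitude = 60,
                        copml_amplitude = 25,
                        body_weight = 800,
                        waveform_noise_sd = c(copap = 0.5, copml = 0.5, vgrf = 4),
                        drift_rate = 0,
                        within_cycle_shape_jitter = 0.1,
                        seed = 1L) {
  check_scalar <- function(x, field, positive = TRUE, integer = FALSE) {
    if (!is.numeric(x) || length(x) != 1L || is.na(x)) {
      stop(sprintf("'%s' must be a single number", field), call. = FALSE)
    }
    if (positive && x <= 0) {
      stop(sprintf("'%s' must be > 0", field), call. = FALSE)
    }
    if (integer && x != round(x)) {
      stop(sprintf("'%s' must be a whole number", field), call. = FALSE)
    }
    invisible(x)
  }
  check_scalar(sampling_rate, "sampling_rate")
  check_scalar(mean_stride_time, "mean_stride_time")
  check_scalar(stride_time_cv, "stride_time_cv", positive = FALSE)
  if (stride_time_cv < 0) stop("'stride_time_cv' must be >= 0", call. = FALSE)
  check_scalar(n_strides, "n_strides", integer = TRUE)
  if (n_strides < 2) stop("'n_strides' must be >= 2", call. = FALSE)
  check_scalar(copap_amplitude, "copap_amplitude")
  check_scalar(copml_amplitude, "copml_amplitude")
  check_scalar(body_weight, "body_weight")
  check_scalar(drift_rate, "drift_rate", positive = FALSE)
  check_scalar(seed, "seed", positive = FALSE, integer = TRUE)
  waveform_noise_sd <- expand_channel_param(waveform_noise_sd, "waveform_noise_sd")
  if (any(waveform_noise_sd < 0)) {
    stop("'waveform_noise_sd' must be >= 0", call. = FALSE)
  }
  within_cycle_shape_jitter <-
    expand_channel_param(within_cycle_shape_jitter, "within_cycle_shape_jitter")
  if (any(within_cycle_shape_jitter < 0)) {
    stop("'within_cycle_shape_jitter' must be >= 0", call. = FALSE)
  }
  structure(
    list(
      sampling_rate = sampling_rate,
      mean_stride_time = mean_stride_time,
      stride_time_cv = stride_time_cv,
      n_strides = as.integer(n_strides),
      copap_amplitude = copap_amplitude,
      copml_amplitude = copml_amplitude,
      body_weight = body_weight,
      waveform_noise_sd = waveform_noise_sd,
      drift_rate = drift_rate,
      within_cycle_shape_jitter = within_cycle_shape_jitter,
      seed = as.integer(seed)
    ),
    class = "gait_params"
  )
}

#' @export
print.gait_params <- function(x, ...) {
  cat("<gait_params>\n")
  cat(sprintf("  %d strides, mean %.3f s (CV %.3f) at %g Hz, seed %d\n",
              x$n_strides, x$mean_stride_time, x$stride_time_cv,
              x$sampling_rate, x$seed))
  cat(sprintf("  amplitudes: COPap %g, COPml %g, vGRF ~%g\n",
              x$copap_amplitude, x$copml_amplitude, x$body_weight))
  cat(sprintf("  jitter: %s; noise SD: %s; drift %g/s\n",
              paste(signif(x$within_cycle_shape_jitter, 3), collapse = "/"),
              paste(signif(x$waveform_noise_sd, 3), collapse = "/"),
              x$drift_rate))
  invisible(x)
}

# --- within-cycle templates -------------------------------------------------
# phi is the within-stride phase in [0, 1). Stride phase 0 is anchored at the
# midstance (single-support valley) of the anchor foot, so the resultant
# force has a clean per-stride minimum exactly at each stride boundary.

# Fore-aft COP: asymmetric excursion made of two half-sine lobes with the
# peak at 60% of the stride.
copap_template <- function(phi, peak_at = 0.6) {
  up <- phi < peak_at
  out <- numeric(length(phi))
  out[up] <- sin(pi * phi[up] / (2 * peak_at))
  out[!up] <- sin(pi * (1 - phi[!up]) / (2 * (1 - peak_at)))
  out
}

# Lateral COP: one full oscillation per stride.
copml_template <- function(phi) sin(2 * pi * phi)

# Per-foot stance profile: M-shaped double bump over stance time u in [0,1];
# beta sets the depth of the midstance valley. The two feet get slightly
# different valley depths (a mild, realistic asymmetry) which makes the
# anchor leg identifiable from the resultant force.
foot_profile <- function(u, beta) sin(pi * u) + beta * sin(3 * pi * u)

# 0.7 keeps the resultant of the two offset stance profiles free of spurious
# valleys at the stance transitions: its only per-stride minima are the two
# midstance valleys. Slow treadmill walking does spend a large fraction of
# the stride in double support.
.stance_fraction <- 0.7
.beta_anchor <- 0.30
.beta_other <- 0.24

# Resultant vGRF template (unit scale): anchor foot stance centred on phase
# 0 (spanning [-0.3, 0.3) wrapped), other foot offset by half a stride.
vgrf_template <- function(phi) {
  sf <- .stance_fraction
  u_a <- ((phi + sf / 2) %% 1) / sf
  in_a <- u_a < 1 & ((phi %% 1) >= 1 - sf / 2 | (phi %% 1) < sf / 2)
  u_b <- (phi - (0.5 - sf / 2)) / sf
  in_b <- u_b >= 0 & u_b < 1
  out <- numeric(length(phi))
  out[in_a] <- out[in_a] + foot_profile(u_a[in_a], .beta_anchor)
  out[in_b] <- out[in_b] + foot_profile(u_b[in_b], .beta_other)
  out
}

# Scale so that the stride-average of the resultant template is 1.
vgrf_template_mean <- function() {
  mean_f <- function(beta) 2 / pi + beta * 2 / (3 * pi)
  .stance_fraction * (mean_f(.beta_anchor) + mean_f(.beta_other))
}

# Smooth per-stride shape deformation: a random low-order sine series that
# vanishes at both cycle ends, so concatenated strides stay continuous.
shape_jitter <- function(phi, coefs) {
  out <- numeric(length(phi))
  for (h in seq_along(coefs)) {
    out <- out + coefs[h] / h * sin(pi * h * phi)
  }
  out
}

#' Generate a synthetic treadmill-gait recording
#'
#' Synthesises one subject-by-condition recording with the structure the
#' downstream analysis assumes: quasi-periodic strides whose durations are
#' drawn from a truncated normal distribution, smooth within-cycle waveform
#' templates for COPap (asymmetric fore-aft excursion), COPml (one lateral
#' oscillation per stride) and vGRF (sum of two M-shaped per-foot stance
#' profiles offset by half a stride), a smooth stride-to-stride shape
#' deformation controlled by `within_cycle_shape_jitter`, additive white
#' Gaussian measurement noise, and a linear positional drift on the COP
#' channels. The vGRF channel is clipped at zero after noise. Stride phase 0
#' (the recorded ground-truth boundary) coincides with the anchor foot's
#' midstance valley of the resultant force.
#'
#' The generator is fully deterministic given `params$seed`.
#'
#' @param params A [gait_params()] object.
#' @return An object of class `gait_recording`: a list with `sampling_rate`,
#'   numeric vectors `copap`, `copml`, `vgrf` (equal length), and
#'   `true_boundaries`, the exact 1-based stride-onset sample indices
#'   (ground truth, available only for synthetic data).
#' @export
generate_recording <- function(params) {
  if (!inherits(params, "gait_params")) {
    stop("'params' must be a gait_params object", call. = FALSE)
  }
  withr::with_seed(params$seed, generate_recording_impl(params))
}

generate_recording_impl <- function(params) {
  rate <- params$sampling_rate
  n_str <- params$n_strides
  cv <- params$stride_time_cv
  mu <- params$mean_stride_time

  # stride durations: truncated normal at +/- 3 SD (exact mean when cv = 0)
  durations <- if (cv == 0) {
    rep(mu, n_str)
  } else {
    lo <- mu * (1 - 3 * cv)
    hi <- mu * (1 + 3 * cv)
    vapply(seq_len(n_str), function(i) {
      repeat {
        d <- rnorm(1, mu, cv * mu)
        if (d >= lo && d <= hi) return(d)
      }
    }, numeric(1))
  }
  n_samples <- pmax(2L, as.integer(round(durations * rate)))
  boundaries <- cumsum(c(1L, n_samples[-n_str]))
  total_n <- sum(n_samples)

  jit <- params$within_cycle_shape_jitter
  n_harm <- 3L
  vgrf_scale <- params$body_weight / vgrf_template_mean()

  copap <- numeric(total_n)
  copml <- numeric(total_n)
  vgrf <- numeric(total_n)
  for (k in seq_len(n_str)) {
    nk <- n_samples[k]
    phi <- (seq_len(nk) - 1) / nk
    idx <- boundaries[k]:(boundaries[k] + nk - 1L)
    # jitter coefficients drawn in fixed channel order for determinism
    c_ap <- if (jit[["copap"]] > 0) rnorm(n_harm) else numeric(n_harm)
    c_ml <- if (jit[["copml"]] > 0) rnorm(n_harm) else numeric(n_harm)
    c_vg <- if (jit[["vgrf"]] > 0) rnorm(n_harm) else numeric(n_harm)
    copap[idx] <- params$copap_amplitude *
      (copap_template(phi) + jit[["copap"]] * shape_jitter(phi, c_ap))
    copml[idx] <- params$copml_amplitude *
      (copml_template(phi) + jit[["copml"]] * shape_jitter(phi, c_ml))
    vgrf[idx] <- vgrf_scale *
      (vgrf_template(phi) + jit[["vgrf"]] * shape_jitter(phi, c_vg))
  }

  noise <- params$waveform_noise_sd
  if (noise[["copap"]] > 0) copap <- copap + rnorm(total_n, 0, noise[["copap"]])
  if (noise[["copml"]] > 0) copml <- copml + rnorm(total_n, 0, noise[["copml"]])
  if (noise[["vgrf"]] > 0) vgrf <- vgrf + rnorm(total_n, 0, noise[["vgrf"]])

  if (params$drift_rate != 0) {
    t_sec <- (seq_len(total_n) - 1) / rate
    copap <- copap + params$drift_rate * t_sec
    copml <- copml + params$drift_rate * t_sec
  }
  vgrf <- pmax(vgrf, 0)

  new_gait_recording(rate, copap, copml, vgrf, boundaries)
}

#' Construct a gait recording from raw channel vectors
#'
#' Builds a `gait_recording` from already-loaded series, e.g. when the data
#' come from an acquisition system rather than [generate_recording()] or
#' [read_recording()]. All three channels must have the same length and the
#' vGRF must be non-negative.
#'
#' @param sampling_rate Hz.
#' @param copap,copml,vgrf Equal-length numeric vectors.
#' @param true_boundaries Optional known stride-onset indices (1-based).
#' @return A `gait_recording`.
#' @export
gait_recording <- function(sampling_rate, copap, copml, vgrf,
                           true_boundaries = NULL) {
  new_gait_recording(sampling_rate, copap, copml, vgrf, true_boundaries)
}

new_gait_recording <- function(sampling_rate, copap, copml, vgrf,
                               true_boundaries = NULL) {
  n <- length(copap)
  stopifnot(length(copml) == n, length(vgrf) == n, n >= 1)
  if (any(vgrf < 0)) stop("vGRF samples must be >= 0", call. = FALSE)
  if (!is.null(true_boundaries)) {
    stopifnot(all(diff(true_boundaries) > 0),
              all(true_boundaries >= 1), all(true_boundaries <= n))
  }
  structure(
    list(sampling_rate = sampling_rate, copap = copap, copml = copml,
         vgrf = vgrf, true_boundaries = true_boundaries),
    class = "gait_recording"
  )
}

#' @export
print.gait_recording <- function(x, ...) {
  n <- length(x$copap)
  cat(sprintf("<gait_recording> %d samples (%.2f s at %g Hz)\n",
              n, n / x$sampling_rate, x$sampling_rate))
  if (!is.null(x$true_boundaries)) {
    cat(sprintf("  synthetic ground truth: %d stride onsets\n",
                length(x$true_boundaries)))
  }
  invisible(x)
}

#' Number of samples in a recording
#' @param recording A `gait_recording`.
#' @return Integer sample count.
#' @export
recording_length <- function(recording) length(recording$copap)

#' Extract one channel of a recording
#' @param recording A `gait_recording`.
#' @param variable One of `"copap"`, `"copml"`, `"vgrf"`.
#' @return Numeric vector.
#' @export
recording_channel <- function(recording, variable) {
  variable <- match.arg(variable, .gait_channels)
  recording[[variable]]
}

#' Generate a matched pair of recordings for two walking conditions
#'
#' Produces the preferred-speed (Vpref) and maximum-speed (Vmax) recordings
#' of one subject. The pair shares a subject-level seed: the Vpref
#' recording uses `params_pref$seed` and the Vmax recording `seed + 1`, so
#' paired experiments are reproducible from a single integer. The speed
#' manipulation is expressed entirely through the parameter sets (typically
#' a shorter mean stride time and altered per-channel shape jitter for
#' Vmax).
#'
#' @param params_pref,params_max [gait_params()] for the two conditions.
#' @return A named list with elements `vpref` and `vmax`, each a
#'   `gait_recording`.
#' @export
generate_condition_pair <- function(params_pref, params_max) {
  if (!inherits(params_pref, "gait_params") ||
      !inherits(params_max, "gait_params")) {
    stop("both parameter sets must be gait_params objects", call. = FALSE)
  }
  params_max$seed <- params_pref$seed + 1L
  list(vpref = generate_recording(params_pref),
       vmax = generate_recording(params_max))
}
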