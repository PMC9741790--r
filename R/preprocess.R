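#' Processed-signal container
#'
#' A 1-D series tagged with how it was prepared. Four preparations are
#' analysed:
#' * `WHOLE` — the raw series, truncated to a common length, no amplitude or
#'   time-base change;
#' * `SEGM`  — stride-segmented and each cycle resampled to a fixed number
#'   of points;
#' * `NORM`  — `SEGM` plus a per-cycle spatial rescale of the COP excursion
#'   to the unit interval;
#' * `ZERO`  — `SEGM` plus translation of every cycle so it starts at the
#'   coordinate (0, 0), removing slow positional drift while keeping all
#'   within-cycle point-to-point distances.
#'
#' @param values Numeric series.
#' @param type_tag One of `"WHOLE"`, `"SEGM"`, `"NORM"`, `"ZERO"`.
#' @param variable One of `"copap"`, `"copml"`, `"vgrf"`.
#' @param samples_per_cycle,n_cycles Cycle structure (`NULL` for WHOLE).
#' @param units `"original"` or `"normalized"`.
#' @return An object of class `processed_signal`.
#' @export
processed_signal <- function(values, type_tag, variable,
                             samples_per_cycle = NULL, n_cycles = NULL,
                             units = "original") {
  type_tag <- match.arg(type_tag, c("WHOLE", "SEGM", "NORM", "ZERO"))
  variable <- match.arg(variable, .gait_channels)
  if (type_tag != "WHOLE") {
    stopifnot(length(values) == samples_per_cycle * n_cycles)
  }
  structure(
    list(values = as.numeric(values), type_tag = type_tag,
         variable = variable,
         samples_per_cycle = samples_per_cycle, n_cycles = n_cycles,
         units = units),
    class = "processed_signal"
  )
}

#' @export
print.processed_signal <- function(x, ...) {
  cyc <- if (is.null(x$n_cycles)) "" else {
    sprintf(" (%d cycles x %d samples)", x$n_cycles, x$samples_per_cycle)
  }
  cat(sprintf("<processed_signal> %s %s, %d samples%s, units %s\n",
              x$type_tag, x$variable, length(x$values), cyc, x$units))
  invisible(x)
}

#' Raw series of a fixed common length (WHOLE)
#'
#' Takes the first `n_points` samples of one channel of a (trimmed)
#' recording, with no amplitude or time-base change. Trials are cut to a
#' common length so every subject contributes the same number of points to
#' the entropy analysis; 2200 points (22 s at 100 Hz) is the conventional
#' default for half-minute treadmill trials.
#'
#' @param recording A `gait_recording`, normally after [trim_first_last()].
#' @param variable Channel name.
#' @param n_points Number of samples to keep.
#' @return A `processed_signal` with `type_tag = "WHOLE"`.
#' @export
make_whole <- function(recording, variable, n_points = 2200) {
  stopifnot(inherits(recording, "gait_recording"))
  if (n_points < 1) {
    stop_gait("gaitsampen_length_error",
              "'n_points' must be >= 1; an empty WHOLE signal is not allowed")
  }
  n <- recording_length(recording)
  if (n < n_points) {
    stop_gait("gaitsampen_length_error",
              sprintf("recording has %d samples but %d were requested",
                      n, n_points))
  }
  x <- recording_channel(recording, variable)
  processed_signal(x[seq_len(n_points)], "WHOLE", variable)
}

#' Stride-segmented, time-resampled series (SEGM)
#'
#' Cuts one channel into cycles at the segmentation boundaries (half-open
#' `[b_i, b_{i+1})`), resamples every cycle independently to
#' `samples_per_cycle` points by piecewise-linear interpolation on a uniform
#' grid including both cycle endpoints, and concatenates the first
#' `n_cycles` cycles. This removes stride-duration differences so subjects
#' and conditions contribute comparable time bases.
#'
#' @param recording A `gait_recording`.
#' @param segmentation A `stride_segmentation` for this recording.
#' @param variable Channel name.
#' @param samples_per_cycle Target points per cycle (default 100).
#' @param n_cycles Number of cycles to keep; default all complete cycles.
#' @return A `processed_signal` with `type_tag = "SEGM"`.
#' @export
segment_resample <- function(recording, segmentation, variable,
                             samples_per_cycle = 100, n_cycles = NULL) {
  stopifnot(inherits(recording, "gait_recording"),
            inherits(segmentation, "stride_segmentation"))
  available <- length(segmentation$boundaries) - 1L
  if (is.null(n_cycles)) n_cycles <- available
  if (available < n_cycles) {
    stop_gait("gaitsampen_too_few_cycles",
              sprintf("%d cycles requested but only %d available",
                      n_cycles, available))
  }
  if (samples_per_cycle < 2) {
    stop_gait("gaitsampen_parameter_error", "'samples_per_cycle' must be >= 2")
  }
  x <- recording_channel(recording, variable)
  b <- segmentation$boundaries
  out <- vector("list", n_cycles)
  for (k in seq_len(n_cycles)) {
    seg <- x[b[k]:(b[k + 1L] - 1L)]
    out[[k]] <- resample_cycle(seg, samples_per_cycle)
  }
  processed_signal(unlist(out), "SEGM", variable,
                   samples_per_cycle = as.integer(samples_per_cycle),
                   n_cycles = as.integer(n_cycles))
}

resample_cycle <- function(seg, n_out) {
  n_in <- length(seg)
  if (n_in == n_out) return(seg)
  if (n_in == 1L) return(rep(seg, n_out))
  approx(x = seq(0, 1, length.out = n_in), y = seg,
         xout = seq(0, 1, length.out = n_out))$y
}

#' Per-cycle spatial normalisation of a COP signal (NORM)
#'
#' Rescales every cycle of a SEGM signal affinely so that it spans exactly
#' `[0, 1]` — the COPap excursion as a fraction of that stride's fore-aft
#' range ("stride length"), the COPml excursion as a fraction of its lateral
#' range ("stride width"). Applies to COP channels only; the vGRF is never
#' spatially normalised.
#'
#' @param segm_signal A `processed_signal` with `type_tag = "SEGM"`.
#' @return A `processed_signal` with `type_tag = "NORM"`, unit interval.
#' @export
normalize_spatial <- function(segm_signal) {
  stopifnot(inherits(segm_signal, "processed_signal"))
  if (segm_signal$type_tag != "SEGM") {
    stop_gait("gaitsampen_parameter_error",
              "spatial normalisation expects a SEGM signal")
  }
  if (segm_signal$variable == "vgrf") {
    stop_gait("gaitsampen_parameter_error",
              "the vGRF is never spatially normalised; COP channels only")
  }
  spc <- segm_signal$samples_per_cycle
  vals <- segm_signal$values
  for (k in seq_len(segm_signal$n_cycles)) {
    idx <- ((k - 1L) * spc + 1L):(k * spc)
    rng <- range(vals[idx])
    if (rng[2] - rng[1] <= 0) {
      stop_gait("gaitsampen_degenerate_cycle",
                sprintf("cycle %d has zero spatial range; cannot normalise", k))
    }
    vals[idx] <- (vals[idx] - rng[1]) / (rng[2] - rng[1])
  }
  processed_signal(vals, "NORM", segm_signal$variable,
                   samples_per_cycle = spc, n_cycles = segm_signal$n_cycles,
                   units = "normalized")
}

#' Per-cycle zeroing of the COP trajectory (ZERO)
#'
#' Translates every cycle of the paired COPap/COPml SEGM signals so it
#' starts at the coordinate (0, 0) — as if the subject began each stride
#' from the same point. Within-cycle point-to-point vector differences are
#' untouched, so absolute distances between data points are preserved; only
#' the slow positional drift across strides is removed. Applies to COP
#' channels only.
#'
#' @param segm_signal_ap,segm_signal_ml SEGM `processed_signal`s for COPap
#'   and COPml with identical cycle structure.
#' @return A named list `list(copap =, copml =)` of `processed_signal`s with
#'   `type_tag = "ZERO"`.
#' @export
zero_cycles <- function(segm_signal_ap, segm_signal_ml) {
  stopifnot(inherits(segm_signal_ap, "processed_signal"),
            inherits(segm_signal_ml, "processed_signal"))
  if (segm_signal_ap$type_tag != "SEGM" || segm_signal_ml$type_tag != "SEGM") {
    stop_gait("gaitsampen_parameter_error", "zeroing expects SEGM signals")
  }
  if (segm_signal_ap$variable != "copap" || segm_signal_ml$variable != "copml") {
    stop_gait("gaitsampen_parameter_error",
              "zeroing applies to the (COPap, COPml) pair only")
  }
  if (!identical(segm_signal_ap$samples_per_cycle,
                 segm_signal_ml$samples_per_cycle) ||
      !identical(segm_signal_ap$n_cycles, segm_signal_ml$n_cycles)) {
    stop_gait("gaitsampen_structure_error",
              "COPap and COPml signals have mismatched cycle structure")
  }
  list(copap = zero_one(segm_signal_ap), copml = zero_one(segm_signal_ml))
}

zero_one <- function(sig) {
  spc <- sig$samples_per_cycle
  vals <- sig$values
  for (k in seq_len(sig$n_cycles)) {
    idx <- ((k - 1L) * spc + 1L):(k * spc)
    vals[idx] <- vals[idx] - vals[idx[1]]
  }
  processed_signal(vals, "ZERO", sig$variable,
                   samples_per_cycle = spc, n_cycles = sig$n_cycles)
}
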