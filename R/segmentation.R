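#' Detect stride boundaries from the vertical ground reaction force
#'
#' Segments a recording into gait cycles using only the vGRF channel. The
#' resultant force of double-bump (M-shaped) stance profiles has a stable
#' valley at each foot's midstance; these valleys are phase-stable
#' landmarks. The detector (i) smooths the vGRF with a short moving average,
#' (ii) finds its local minima, (iii) enforces a refractory separation of
#' 0.4 times the median landmark spacing (keeping the deeper of two close
#' minima), and (iv) keeps every second landmark so that consecutive
#' boundaries span one full stride of the same leg. Of the two alternating
#' landmark series, the one with the lower mean force is taken as the
#' anchor leg (ties fall back to the first landmark).
#'
#' The identical boundaries are applied to COPap, COPml and vGRF downstream,
#' so segmentation is by construction invariant to anything that happens on
#' the COP channels.
#'
#' @param recording A `gait_recording`.
#' @param smooth_window Moving-average window in samples; default
#'   `sampling_rate / 20` (5 samples at 100 Hz), forced odd.
#' @param min_separation_factor Refractory separation as a fraction of the
#'   median landmark spacing. Default 0.4.
#' @return An object of class `stride_segmentation`: list with `boundaries`
#'   (1-based stride-onset sample indices, strictly increasing),
#'   `stride_durations` (seconds, one per complete cycle) and `source_rate`.
#' @export
segment_strides <- function(recording,
                            smooth_window = NULL,
                            min_separation_factor = 0.4) {
  stopifnot(inherits(recording, "gait_recording"))
  v <- recording$vgrf
  rate <- recording$sampling_rate
  if (length(unique(v)) == 1L || sd(v) < 1e-12 * max(abs(v), 1)) {
    stop_gait("gaitsampen_signal_quality",
              "vGRF channel is flat; cannot detect gait events")
  }
  if (is.null(smooth_window)) smooth_window <- round(rate / 20)
  w <- max(3L, as.integer(smooth_window))
  if (w %% 2L == 0L) w <- w + 1L
  vs <- moving_average(v, w)

  cand <- local_minima(vs)
  if (length(cand) >= 3) {
    cand <- enforce_separation(cand, vs, min_separation_factor)
  }
  if (length(cand) < 3) {
    stop_gait("gaitsampen_segmentation_failure",
              sprintf("only %d gait events detected; need at least 3",
                      length(cand)))
  }

  # refine each valley to the vertex of a local least-squares parabola;
  # averaging over the neighbourhood localises far better than the raw
  # argmin under measurement noise
  cand <- vapply(cand, refine_minimum, integer(1),
                 y = vs, half = max(3L, as.integer(round(rate / 10))))
  cand <- sort(unique(cand))

  # split alternating landmarks into the two legs; anchor = deeper valleys
  set_a <- cand[seq(1L, length(cand), by = 2L)]
  set_b <- cand[seq(2L, length(cand), by = 2L)]
  boundaries <- if (length(set_b) && mean(vs[set_b]) < mean(vs[set_a])) {
    set_b
  } else {
    set_a
  }
  if (length(boundaries) < 2) {
    stop_gait("gaitsampen_segmentation_failure",
              "fewer than 2 same-leg landmarks detected")
  }
  new_stride_segmentation(as.integer(boundaries), rate)
}

#' Construct a segmentation from known boundaries
#'
#' Wraps externally determined stride-onset indices (for instance the
#' ground truth of a synthetic recording, or events from a kinematic
#' system) in a `stride_segmentation` so they can drive the preprocessing
#' stage in place of [segment_strides()].
#'
#' @param boundaries Strictly increasing 1-based sample indices.
#' @param source_rate Hz.
#' @return A `stride_segmentation`.
#' @export
stride_segmentation <- function(boundaries, source_rate) {
  new_stride_segmentation(as.integer(boundaries), source_rate)
}

new_stride_segmentation <- function(boundaries, source_rate) {
  stopifnot(all(diff(boundaries) > 0))
  structure(
    list(boundaries = boundaries,
         stride_durations = diff(boundaries) / source_rate,
         source_rate = source_rate),
    class = "stride_segmentation"
  )
}

#' @export
print.stride_segmentation <- function(x, ...) {
  cat(sprintf("<stride_segmentation> %d cycles, mean stride %.3f s (SD %.3f)\n",
              length(x$stride_durations), mean(x$stride_durations),
              sd(x$stride_durations)))
  invisible(x)
}

#' Number of complete cycles in a segmentation
#' @param segmentation A `stride_segmentation`.
#' @return Integer cycle count.
#' @export
n_cycles <- function(segmentation) length(segmentation$boundaries) - 1L

moving_average <- function(x, w) {
  half <- (w - 1L) %/% 2L
  # pad by edge replication so landmarks near the ends keep their phase
  xp <- c(rep(x[1], half), x, rep(x[length(x)], half))
  as.numeric(stats::filter(xp, rep(1 / w, w), sides = 2))[
    (half + 1L):(half + length(x))]
}

local_minima <- function(x) {
  d <- diff(x)
  s <- sign(d)
  # collapse plateaus: carry the last non-zero slope forward
  nz <- s != 0
  if (!any(nz)) return(integer(0))
  s_f <- s
  last <- 0
  for (i in seq_along(s_f)) {
    if (s_f[i] == 0) s_f[i] <- last else last <- s_f[i]
  }
  which(diff(s_f) > 0) + 1L
}

refine_minimum <- function(idx, y, half) {
  lo <- max(1L, idx - half)
  hi <- min(length(y), idx + half)
  xs <- lo:hi
  fit <- stats::lm.fit(cbind(1, xs - idx, (xs - idx)^2), y[xs])
  a <- fit$coefficients[3]
  b <- fit$coefficients[2]
  if (!is.finite(a) || a <= 0) return(idx)
  vertex <- -b / (2 * a)
  if (abs(vertex) > half) return(idx)
  min(length(y), max(1L, idx + as.integer(round(vertex))))
}

enforce_separation <- function(cand, vs, factor) {
  spacing <- median(diff(cand))
  min_sep <- factor * spacing
  keep <- cand[1]
  for (c in cand[-1]) {
    if (c - keep[length(keep)] < min_sep) {
      # too close: keep the deeper of the two
      if (vs[c] < vs[keep[length(keep)]]) keep[length(keep)] <- c
    } else {
      keep <- c(keep, c)
    }
  }
  keep
}

#' Remove the first and last detected cycles
#'
#' Drops the first and last complete cycles from the analysis window, the
#' usual precaution against transient steps at the start and end of a trial.
#' The recording is cut to the remaining window and boundary indices are
#' re-based to it. Each call removes one cycle from each end (the operation
#' is deliberately not idempotent).
#'
#' @param recording A `gait_recording`.
#' @param segmentation Its `stride_segmentation`.
#' @return List with elements `recording` and `segmentation`, both trimmed.
#' @export
trim_first_last <- function(recording, segmentation) {
  stopifnot(inherits(recording, "gait_recording"),
            inherits(segmentation, "stride_segmentation"))
  b <- segmentation$boundaries
  if (n_cycles(segmentation) <= 2) {
    stop_gait("gaitsampen_too_few_cycles",
              sprintf("cannot trim first and last cycle: only %d cycles",
                      n_cycles(segmentation)))
  }
  start <- b[2]
  end <- b[length(b) - 1L]  # window is [start, end)
  idx <- start:(end - 1L)
  trimmed <- new_gait_recording(
    recording$sampling_rate,
    recording$copap[idx], recording$copml[idx], recording$vgrf[idx],
    true_boundaries = rebase_boundaries(recording$true_boundaries, start, end)
  )
  new_b <- b[2:(length(b) - 1L)] - start + 1L
  list(recording = trimmed,
       segmentation = new_stride_segmentation(new_b, segmentation$source_rate))
}

rebase_boundaries <- function(tb, start, end) {
  if (is.null(tb)) return(NULL)
  tb <- tb[tb >= start & tb < end]
  if (!length(tb)) NULL else tb - start + 1L
}

stop_gait <- function(class, message) {
  stop(structure(
    class = c(class, "gaitsampen_error", "error", "condition"),
    list(message = message, call = NULL)
  ))
}
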