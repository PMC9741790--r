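#' Effective tolerance from the series spread
#'
#' The matching tolerance `r` is conventionally expressed as a multiple of
#' the standard deviation of the analysed series (0.2 by convention for gait
#' signals). The SD uses the population convention (denominator N); at
#' typical series lengths the difference from the sample convention is
#' negligible, but a fixed convention keeps results exactly reproducible.
#' Optionally the SD can be averaged over cycles instead of taken over the
#' full series (`per_cycle = TRUE` with the cycle structure of a segmented
#' signal).
#'
#' @param series Numeric series (length >= 2).
#' @param r_factor Positive multiplier of the SD (default 0.2).
#' @param samples_per_cycle If not `NULL`, average per-cycle SDs over
#'   consecutive blocks of this length instead of using the full-series SD.
#' @return The effective tolerance, in signal units.
#' @export
compute_r <- function(series, r_factor = 0.2, samples_per_cycle = NULL) {
  if (length(series) < 2) {
    stop_gait("gaitsampen_length_error", "series must have at least 2 samples")
  }
  if (!is.numeric(r_factor) || length(r_factor) != 1L || r_factor <= 0) {
    stop_gait("gaitsampen_parameter_error", "'r_factor' must be > 0")
  }
  s <- if (is.null(samples_per_cycle)) {
    pop_sd(series)
  } else {
    k <- length(series) %/% samples_per_cycle
    mean(vapply(seq_len(k), function(i) {
      pop_sd(series[((i - 1) * samples_per_cycle + 1):(i * samples_per_cycle)])
    }, numeric(1)))
  }
  if (s <= 0) {
    stop_gait("gaitsampen_zero_tolerance",
              "series is constant (SD = 0); tolerance would be zero")
  }
  r_factor * s
}

pop_sd <- function(x) sqrt(mean((x - mean(x))^2))

#' Sample Entropy of a series
#'
#' Computes `SampEn(m, r, N) = -ln(A / B)` where `B` counts pairs of
#' m-length templates within Chebyshev distance `r` and `A` counts pairs of
#' (m+1)-length templates within `r`, both over template start indices
#' `1..N-m` with self-matches excluded (the Richman-Moorman pairing, which
#' guarantees `A <= B` and hence a non-negative value). Low values indicate
#' a regular, repetitive series; an uncorrelated random series drives the
#' value up without bound.
#'
#' Exactly one of `r` (absolute, in signal units) or `r_factor` (multiple of
#' the series SD, see [compute_r()]) must be given.
#'
#' @param series Numeric series, or a `processed_signal`.
#' @param m Template length in samples (>= 1).
#' @param r Absolute tolerance in signal units.
#' @param r_factor Tolerance as a multiple of the series SD.
#' @param samples_per_cycle Passed to [compute_r()] when `r_factor` is used.
#' @return An object of class `sampen_result`: list with `value` (nats),
#'   match counts `A` and `B` (unordered pairs), `m`, `effective_r`, `N`.
#'   If no template pair matches at length m (`B = 0`) or none extends to
#'   m+1 (`A = 0`), the entropy is undefined and a classed error is raised
#'   (`gaitsampen_no_m_matches` / `gaitsampen_no_m1_matches`);
#'   [sampen_grid()] converts these into missing cells with reason codes.
#' @export
sample_entropy <- function(series, m, r = NULL, r_factor = NULL,
                           samples_per_cycle = NULL) {
  x <- if (inherits(series, "processed_signal")) series$values else series
  x <- as.numeric(x)
  if (!is.numeric(m) || length(m) != 1L || m < 1 || m != round(m)) {
    stop_gait("gaitsampen_parameter_error", "'m' must be a whole number >= 1")
  }
  m <- as.integer(m)
  n <- length(x)
  if (n <= m + 1) {
    stop_gait("gaitsampen_length_error",
              sprintf("series length %d must exceed m + 1 = %d", n, m + 1))
  }
  if (is.null(r) == is.null(r_factor)) {
    stop_gait("gaitsampen_parameter_error",
              "supply exactly one of 'r' or 'r_factor'")
  }
  effective_r <- if (!is.null(r)) {
    if (r <= 0) stop_gait("gaitsampen_parameter_error", "'r' must be > 0")
    r
  } else {
    compute_r(x, r_factor, samples_per_cycle)
  }
  counts <- sampen_counts_cpp(x, m, effective_r)
  new_sampen_result(counts$A[m], counts$B[m], m, effective_r, n)
}

new_sampen_result <- function(A, B, m, effective_r, n) {
  if (B == 0) {
    stop_gait("gaitsampen_no_m_matches",
              sprintf("no template pairs match at m = %d; entropy undefined", m))
  }
  if (A == 0) {
    stop_gait("gaitsampen_no_m1_matches",
              sprintf("no template pairs extend to m + 1 = %d; entropy undefined",
                      m + 1))
  }
  value <- -log(A / B)
  if (value == 0) value <- 0  # normalise -0 from A == B
  structure(
    list(value = value, A = A, B = B, m = m,
         effective_r = effective_r, N = n),
    class = "sampen_result"
  )
}

#' @export
print.sampen_result <- function(x, ...) {
  cat(sprintf("SampEn(m = %d, r = %.4g, N = %d) = %.4f  [A = %.0f, B = %.0f]\n",
              x$m, x$effective_r, x$N, x$value, x$A, x$B))
  invisible(x)
}

#' Reference brute-force Sample Entropy
#'
#' Direct O(N^2 m) enumeration of every template pair in plain R, kept as a
#' transparent reference for the optimised counting kernel. Identical
#' contract to [sample_entropy()] with an absolute tolerance.
#'
#' @inheritParams sample_entropy
#' @return A `sampen_result`.
#' @export
sample_entropy_brute <- function(series, m, r) {
  x <- if (inherits(series, "processed_signal")) series$values else series
  n <- length(x)
  if (n <= m + 1) {
    stop_gait("gaitsampen_length_error", "series too short for this m")
  }
  n_t <- n - m  # templates start at 1..n-m for both lengths
  A <- 0L
  B <- 0L
  for (i in seq_len(n_t - 1L)) {
    for (j in (i + 1L):n_t) {
      if (max(abs(x[i:(i + m - 1L)] - x[j:(j + m - 1L)])) <= r) {
        B <- B + 1L
        if (abs(x[i + m] - x[j + m]) <= r) A <- A + 1L
      }
    }
  }
  new_sampen_result(A, B, as.integer(m), r, n)
}

#' Sample Entropy over a grid of template lengths and tolerances
#'
#' Evaluates SampEn for every combination of `m_list` and `r_factor_list`
#' on one signal. The effective tolerance is recomputed per signal (not per
#' cycle) from its SD. Cells whose entropy is undefined (no matches at m or
#' no extensions to m+1) are reported as missing with a reason code rather
#' than failing the run.
#'
#' @param signal A `processed_signal` or numeric series.
#' @param m_list Template lengths (conventional grid: 2, 4, 6, 8, 10).
#' @param r_factor_list SD multipliers (default 0.2; sweeps often use
#'   0.1-0.3).
#' @param samples_per_cycle Optional per-cycle SD averaging, see
#'   [compute_r()].
#' @return A tibble with one row per (m, r_factor): columns `m`, `r_factor`,
#'   `effective_r`, `A`, `B`, `value`, `reason` (`NA` for valid cells,
#'   `"no m matches"` / `"no (m+1) matches"` otherwise).
#' @export
sampen_grid <- function(signal, m_list = c(2, 4, 6, 8, 10),
                        r_factor_list = 0.2, samples_per_cycle = NULL) {
  x <- if (inherits(signal, "processed_signal")) signal$values else signal
  x <- as.numeric(x)
  if (!length(m_list)) {
    return(tibble::tibble(m = integer(), r_factor = numeric(),
                          effective_r = numeric(), A = numeric(),
                          B = numeric(), value = numeric(),
                          reason = character()))
  }
  m_list <- as.integer(sort(unique(m_list)))
  m_max <- max(m_list)
  if (length(x) <= m_max + 1) {
    stop_gait("gaitsampen_length_error",
              sprintf("series length %d too short for m = %d", length(x), m_max))
  }
  rows <- lapply(r_factor_list, function(rf) {
    eff_r <- compute_r(x, rf, samples_per_cycle)
    counts <- sampen_counts_cpp(x, m_max, eff_r)
    lapply(m_list, function(m) {
      A <- counts$A[m]
      B <- counts$B[m]
      if (B == 0) {
        val <- NA_real_; reason <- "no m matches"
      } else if (A == 0) {
        val <- NA_real_; reason <- "no (m+1) matches"
      } else {
        val <- -log(A / B); reason <- NA_character_
      }
      tibble::tibble(m = m, r_factor = rf, effective_r = eff_r,
                     A = A, B = B, value = val, reason = reason)
    })
  })
  dplyr::bind_rows(unlist(rows, recursive = FALSE))
}
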