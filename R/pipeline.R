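#' Configuration for a full sensitivity experiment
#'
#' Bundles everything [run_experiment()] needs. In `"synthetic"` mode each
#' subject gets a matched pair of recordings from the two condition
#' parameter sets, with per-subject seeds derived from the run seed. The
#' default condition parameterisation emulates the speed manipulation of a
#' treadmill protocol: preferred walking (Vpref) with 1.06 s strides, and
#' maximum tolerated speed (Vmax) with shorter (0.85 s) strides, a tighter
#' within-cycle waveform on COPap and vGRF, and a looser one on COPml.
#' In `"files"` mode, `files` must be a data frame with columns
#' `subject_id`, `condition` (`Vpref`/`Vmax`) and `path` pointing at CSVs
#' readable by [read_recording()].
#'
#' @param mode `"synthetic"` or `"files"`.
#' @param params_pref,params_max [gait_params()] for the two conditions
#'   (synthetic mode); per-subject seeds are overwritten from `seed`.
#' @param n_subjects Number of subjects (synthetic mode).
#' @param m_list Template lengths for the SampEn grid.
#' @param r_factor_list Tolerance factors for the grid.
#' @param samples_per_cycle Points per resampled stride.
#' @param whole_n_points Common raw-series length; lowered automatically to
#'   the shortest trimmed recording in the run ("lowest number achieved").
#' @param variables Channels to analyse (vGRF only admits WHOLE and SEGM).
#' @param anova_m Template length for the velocity comparison (default 6).
#' @param anova_r Tolerance factor entering the ANOVAs (default 0.2).
#' @param seed Run seed; all randomness derives from it.
#' @param files File manifest for `"files"` mode.
#' @return An object of class `run_config`.
#' @export
run_config <- function(mode = c("synthetic", "files"),
                       params_pref = NULL,
                       params_max = NULL,
                       n_subjects = 23,
                       m_list = c(2, 4, 6, 8, 10),
                       r_factor_list = 0.2,
                       samples_per_cycle = 100,
                       whole_n_points = 2200,
                       variables = c("copap", "copml", "vgrf"),
                       anova_m = 6,
                       anova_r = 0.2,
                       seed = 1L,
                       files = NULL) {
  mode <- match.arg(mode)
  if (is.null(params_pref)) {
    params_pref <- gait_params(
      mean_stride_time = 1.06, n_strides = 30,
      within_cycle_shape_jitter = c(copap = 0.15, copml = 0.10, vgrf = 0.10),
      drift_rate = 1
    )
  }
  if (is.null(params_max)) {
    params_max <- gait_params(
      mean_stride_time = 0.85, n_strides = 37,
      within_cycle_shape_jitter = c(copap = 0.05, copml = 0.20, vgrf = 0.04),
      drift_rate = 1
    )
  }
  if (!length(m_list)) {
    stop_gait("gaitsampen_parameter_error", "'m_list' must be non-empty")
  }
  variables <- match.arg(variables, .gait_channels, several.ok = TRUE)
  if (mode == "files" &&
      (is.null(files) ||
       !all(c("subject_id", "condition", "path") %in% names(files)))) {
    stop_gait("gaitsampen_parameter_error",
              "'files' must have columns subject_id, condition, path")
  }
  structure(
    list(mode = mode, params_pref = params_pref, params_max = params_max,
         n_subjects = as.integer(n_subjects), m_list = m_list,
         r_factor_list = r_factor_list,
         samples_per_cycle = as.integer(samples_per_cycle),
         whole_n_points = as.integer(whole_n_points),
         variables = variables, anova_m = anova_m, anova_r = anova_r,
         seed = as.integer(seed), files = files),
    class = "run_config"
  )
}

# Which processing types apply to which channel: the vGRF is analysed only
# raw and segmented; it is never spatially normalised or zeroed.
types_for_variable <- function(variable) {
  if (variable == "vgrf") c("WHOLE", "SEGM") else c("WHOLE", "SEGM", "NORM", "ZERO")
}

#' Run the full sensitivity and speed-discrimination experiment
#'
#' Orchestrates every stage: recording synthesis (or loading), stride
#' segmentation from the vGRF, first/last-cycle trimming, the four signal
#' preparations per channel, the SampEn grid over template lengths and
#' tolerances, assembly of the long-form sensitivity table, the per-condition
#' two-way ANOVAs (type x m), the mixed velocity ANOVA at the chosen
#' template length, and the velocity-comparison summary. Deterministic given
#' `config$seed`. The number of cycles entering the segmented preparations
#' and the common raw-series length are the minima achieved across the run,
#' so every subject contributes equally to every analysis.
#'
#' Undefined-entropy cells are kept as missing rows in the sensitivity
#' table (with reason codes); any subject contributing a missing cell to an
#' ANOVA is dropped from that ANOVA (with a logged diagnostic) so the design
#' stays balanced.
#'
#' @param config A [run_config()].
#' @param out_dir If not `NULL`, write `sensitivity.csv`,
#'   `summary_tables.csv`, `anova_<condition>_<variable>.json`,
#'   `velocity_comparison.csv` and `run_meta.json` there.
#' @return An object of class `gait_experiment`: list with `sensitivity`
#'   (tibble), `summary` (mean and 0.95 t-based CI per condition x variable
#'   x type x m), `anova_two_way` (named list of `anova_result`),
#'   `anova_mixed` (named list), `velocity_comparison` (tibble at
#'   `anova_m`), `n_cycles_used`, `whole_n_used`, `diagnostics` (character),
#'   `config`.
#' @export
run_experiment <- function(config, out_dir = NULL) {
  stopifnot(inherits(config, "run_config"))
  diagnostics <- character()

  recordings <- gather_recordings(config)
  subjects <- names(recordings)

  # segment + trim every recording; stage failures abort with identifiers
  prepared <- lapply(subjects, function(sid) {
    lapply(names(recordings[[sid]]), function(cond) {
      rec <- recordings[[sid]][[cond]]
      res <- tryCatch({
        seg <- segment_strides(rec)
        trim_first_last(rec, seg)
      }, gaitsampen_error = function(e) {
        stop(sprintf("stage 'segmentation' failed for subject %s, %s: %s",
                     sid, cond, conditionMessage(e)), call. = FALSE)
      })
      res
    }) |> stats::setNames(names(recordings[[sid]]))
  }) |> stats::setNames(subjects)

  n_cyc <- min(vapply(prepared, function(p) {
    min(vapply(p, function(x) n_cycles(x$segmentation), integer(1)))
  }, integer(1)))
  min_len <- min(vapply(prepared, function(p) {
    min(vapply(p, function(x) recording_length(x$recording), integer(1)))
  }, integer(1)))
  whole_n <- min(config$whole_n_points, min_len)
  if (whole_n < config$whole_n_points) {
    diagnostics <- c(diagnostics, sprintf(
      "whole_n_points lowered from %d to %d (shortest trimmed recording)",
      config$whole_n_points, whole_n))
  }

  rows <- list()
  for (sid in subjects) {
    for (cond in names(prepared[[sid]])) {
      p <- prepared[[sid]][[cond]]
      sigs <- build_signals(p$recording, p$segmentation, config, whole_n, n_cyc)
      for (sig in sigs) {
        grid <- sampen_grid(sig, config$m_list, config$r_factor_list)
        rows[[length(rows) + 1L]] <- tibble::tibble(
          subject_id = sid, condition = cond, variable = sig$variable,
          type_tag = sig$type_tag, m = grid$m, r_factor = grid$r_factor,
          sampen_value = grid$value, reason = grid$reason
        )
      }
    }
  }
  sensitivity <- dplyr::bind_rows(rows)

  n_missing <- sum(!is.na(sensitivity$reason))
  if (n_missing > 0) {
    diagnostics <- c(diagnostics,
                     sprintf("%d undefined-entropy cells in the grid",
                             n_missing))
  }

  summary_tbl <- summarise_sensitivity(sensitivity)

  anova_two_way <- list()
  anova_mixed <- list()
  velocity_comparison <- NULL
  if (length(subjects) < 2) {
    diagnostics <- c(diagnostics,
                     "statistics skipped: fewer than 2 subjects")
  } else {
    at_r <- dplyr::filter(sensitivity, .data$r_factor == config$anova_r)
    for (cond in unique(at_r$condition)) {
      for (v in unique(at_r$variable)) {
        sub <- dplyr::filter(at_r, .data$condition == cond, .data$variable == v)
        sub <- drop_incomplete_subjects(sub, "two-way", cond, v)
        diagnostics <- c(diagnostics, attr(sub, "dropped"))
        if (length(unique(sub$subject_id)) >= 2) {
          res <- tryCatch(two_way_anova(sub), gaitsampen_error = function(e) {
            diagnostics <<- c(diagnostics, sprintf(
              "two-way ANOVA (%s, %s) skipped: %s", cond, v,
              conditionMessage(e)))
            NULL
          })
          if (!is.null(res)) anova_two_way[[paste(cond, v, sep = "_")]] <- res
        }
      }
    }
    at_m <- dplyr::filter(at_r, .data$m == config$anova_m)
    for (v in unique(at_m$variable)) {
      sub <- dplyr::filter(at_m, .data$variable == v)
      sub <- drop_incomplete_subjects(sub, "mixed", "both", v)
      diagnostics <- c(diagnostics, attr(sub, "dropped"))
      if (length(unique(sub$subject_id)) >= 2) {
        res <- tryCatch(mixed_anova(sub), gaitsampen_error = function(e) {
          diagnostics <<- c(diagnostics, sprintf(
            "mixed ANOVA (%s) skipped: %s", v, conditionMessage(e)))
          NULL
        })
        if (!is.null(res)) anova_mixed[[v]] <- res
      }
    }
    velocity_comparison <- at_m |>
      dplyr::group_by(.data$variable, .data$type_tag, .data$condition) |>
      dplyr::summarise(mean_sampen = mean(.data$sampen_value, na.rm = TRUE),
                       .groups = "drop") |>
      tidyr::pivot_wider(names_from = "condition", values_from = "mean_sampen") |>
      dplyr::mutate(delta = .data$Vmax - .data$Vpref,
                    direction = ifelse(.data$delta < 0,
                                       "more regular in Vmax",
                                       "less regular in Vmax"))
  }

  out <- structure(
    list(sensitivity = sensitivity, summary = summary_tbl,
         anova_two_way = anova_two_way, anova_mixed = anova_mixed,
         velocity_comparison = velocity_comparison,
         n_cycles_used = n_cyc, whole_n_used = whole_n,
         diagnostics = diagnostics, config = config),
    class = "gait_experiment"
  )
  if (!is.null(out_dir)) write_experiment(out, out_dir)
  out
}

gather_recordings <- function(config) {
  if (config$mode == "synthetic") {
    subjects <- sprintf("S%02d", seq_len(config$n_subjects))
    recs <- lapply(seq_len(config$n_subjects), function(i) {
      pp <- config$params_pref
      pm <- config$params_max
      pp$seed <- config$seed + (i - 1L) * 2L
      pair <- generate_condition_pair(pp, pm)
      list(Vpref = pair$vpref, Vmax = pair$vmax)
    })
    stats::setNames(recs, subjects)
  } else {
    manifest <- as.data.frame(config$files)
    subjects <- unique(manifest$subject_id)
    recs <- lapply(subjects, function(sid) {
      rows <- manifest[manifest$subject_id == sid, ]
      if (!all(c("Vpref", "Vmax") %in% rows$condition)) {
        stop_gait("gaitsampen_pairing_error",
                  sprintf("subject %s is missing a condition", sid))
      }
      list(Vpref = read_recording(rows$path[rows$condition == "Vpref"][1]),
           Vmax = read_recording(rows$path[rows$condition == "Vmax"][1]))
    })
    stats::setNames(recs, as.character(subjects))
  }
}

build_signals <- function(recording, segmentation, config, whole_n, n_cyc) {
  sigs <- list()
  segm <- list()
  for (v in config$variables) {
    types <- types_for_variable(v)
    if ("WHOLE" %in% types) {
      sigs[[paste0(v, "_WHOLE")]] <- make_whole(recording, v, whole_n)
    }
    segm[[v]] <- segment_resample(recording, segmentation, v,
                                  config$samples_per_cycle, n_cyc)
    sigs[[paste0(v, "_SEGM")]] <- segm[[v]]
    if ("NORM" %in% types) {
      sigs[[paste0(v, "_NORM")]] <- normalize_spatial(segm[[v]])
    }
  }
  if (all(c("copap", "copml") %in% config$variables)) {
    z <- zero_cycles(segm[["copap"]], segm[["copml"]])
    sigs[["copap_ZERO"]] <- z$copap
    sigs[["copml_ZERO"]] <- z$copml
  }
  sigs
}

# Drop subjects with any missing SampEn cell from one ANOVA's input so the
# design stays balanced; report who was dropped.
drop_incomplete_subjects <- function(sub, which_anova, cond, variable) {
  bad <- unique(sub$subject_id[is.na(sub$sampen_value)])
  out <- dplyr::filter(sub, !(.data$subject_id %in% bad))
  attr(out, "dropped") <- if (length(bad)) {
    sprintf("%s ANOVA (%s, %s): dropped %s for undefined entropy cells",
            which_anova, cond, variable, paste(bad, collapse = ", "))
  } else {
    character()
  }
  out
}

summarise_sensitivity <- function(sensitivity) {
  sensitivity |>
    dplyr::filter(!is.na(.data$sampen_value)) |>
    dplyr::group_by(.data$condition, .data$variable, .data$type_tag,
                    .data$m, .data$r_factor) |>
    dplyr::summarise(
      n = dplyr::n(),
      mean_sampen = mean(.data$sampen_value),
      sd_sampen = sd(.data$sampen_value),
      ci_lo = .data$mean_sampen - ci_halfwidth(.data$sd_sampen, .data$n),
      ci_hi = .data$mean_sampen + ci_halfwidth(.data$sd_sampen, .data$n),
      .groups = "drop"
    )
}

# 0.95 t-based half-width over subjects (NA for a single subject)
ci_halfwidth <- function(s, n) {
  ifelse(n > 1, qt(0.975, n - 1) * s / sqrt(n), NA_real_)
}

#' @export
print.gait_experiment <- function(x, ...) {
  cat("<gait_experiment>\n")
  cat(sprintf("  %d sensitivity rows (%d subjects), %d cycles x %d samples, WHOLE n = %d\n",
              nrow(x$sensitivity), length(unique(x$sensitivity$subject_id)),
              x$n_cycles_used, x$config$samples_per_cycle, x$whole_n_used))
  cat(sprintf("  %d two-way ANOVAs, %d mixed ANOVAs\n",
              length(x$anova_two_way), length(x$anova_mixed)))
  for (d in x$diagnostics) cat("  note:", d, "\n")
  invisible(x)
}

write_experiment <- function(x, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(x$sensitivity, file.path(out_dir, "sensitivity.csv"),
                   row.names = FALSE)
  utils::write.csv(x$summary, file.path(out_dir, "summary_tables.csv"),
                   row.names = FALSE)
  for (nm in names(x$anova_two_way)) {
    jsonlite::write_json(anova_as_list(x$anova_two_way[[nm]]),
                         file.path(out_dir, sprintf("anova_%s.json", nm)),
                         auto_unbox = TRUE, digits = NA)
  }
  for (nm in names(x$anova_mixed)) {
    jsonlite::write_json(anova_as_list(x$anova_mixed[[nm]]),
                         file.path(out_dir, sprintf("anova_mixed_%s.json", nm)),
                         auto_unbox = TRUE, digits = NA)
  }
  if (!is.null(x$velocity_comparison)) {
    utils::write.csv(x$velocity_comparison,
                     file.path(out_dir, "velocity_comparison.csv"),
                     row.names = FALSE)
  }
  meta <- list(seed = x$config$seed, mode = x$config$mode,
               n_subjects = x$config$n_subjects,
               m_list = x$config$m_list,
               r_factor_list = x$config$r_factor_list,
               samples_per_cycle = x$config$samples_per_cycle,
               whole_n_used = x$whole_n_used,
               n_cycles_used = x$n_cycles_used,
               package_version = as.character(utils::packageVersion("gaitsampen")),
               diagnostics = x$diagnostics)
  jsonlite::write_json(meta, file.path(out_dir, "run_meta.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(out_dir)
}

anova_as_list <- function(a) {
  lapply(seq_len(nrow(a)), function(i) {
    list(effect = a$effect[i], F = a$statistic[i],
         df1 = a$df1[i], df2 = a$df2[i], p = a$p_value[i], ss = a$ss[i])
  })
}
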