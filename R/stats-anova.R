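#' Two-way fixed-effects ANOVA over processing type and template length
#'
#' For one walking condition and one variable, tests the effect of the
#' preprocessing type (WHOLE/SEGM/NORM/ZERO, or WHOLE/SEGM for the vGRF)
#' and of the template length m on the SampEn values, subjects acting as
#' replicates. The design must be balanced and complete (the F-test's
#' robustness argument relies on equal cell counts); with 4 types, 5 m
#' levels and 23 subjects the error degrees of freedom are 440 and the
#' effect dfs are 3 (type), 4 (m) and 12 (interaction).
#'
#' @param table Long-form data (tibble/data.frame) with columns
#'   `subject_id`, `type_tag`, `m`, `sampen_value`, already restricted to a
#'   single condition, variable and tolerance.
#' @return An `anova_result`: tibble with one row per effect (`type`, `m`,
#'   `type:m`, `residuals`) and columns `effect`, `df`, `ss`, `statistic`,
#'   `df1`, `df2`, `p_value`.
#' @export
two_way_anova <- function(table) {
  table <- as.data.frame(table)
  need <- c("subject_id", "type_tag", "m", "sampen_value")
  if (!all(need %in% names(table))) {
    stop_gait("gaitsampen_parameter_error",
              paste("table must have columns", paste(need, collapse = ", ")))
  }
  f_type <- factor(table$type_tag)
  f_m <- factor(table$m)
  if (nlevels(f_type) < 2 || nlevels(f_m) < 2) {
    stop_gait("gaitsampen_parameter_error",
              "two_way_anova needs at least 2 levels of both type and m")
  }
  counts <- table(f_type, f_m)
  if (length(unique(as.vector(counts))) != 1L || any(counts < 2)) {
    bad <- which(counts != max(counts) | counts < 2, arr.ind = TRUE)
    stop_gait("gaitsampen_unbalanced_design",
              paste0("unbalanced or underfilled cells (type x m): ",
                     paste(sprintf("%s:%s", rownames(counts)[bad[, 1]],
                                   colnames(counts)[bad[, 2]]),
                           collapse = ", ")))
  }
  fit <- aov(sampen_value ~ f_type * f_m,
             data = data.frame(sampen_value = table$sampen_value,
                               f_type = f_type, f_m = f_m))
  tab <- summary(fit)[[1]]
  effects <- c("type", "m", "type:m", "residuals")
  build_anova_result(tab, effects,
                     design = sprintf("%d types x %d m-levels x %d replicates",
                                      nlevels(f_type), nlevels(f_m),
                                      max(counts)))
}

#' Two-way mixed ANOVA: walking condition within, processing type between
#'
#' Split-plot design testing the effect of walking velocity on signal
#' regularity at a fixed template length: walking condition (Vpref/Vmax) is
#' the within-subjects factor and processing type the between-subjects
#' factor, each subject-by-type series forming one experimental unit
#' measured in both conditions. With 4 types and 23 subjects both error
#' strata have 88 degrees of freedom, giving the familiar F(3,88) for type
#' and F(1,88) for velocity.
#'
#' Note the design caveat: all processing types derive from the same
#' subjects, yet type is analysed as a between-subjects factor; this is the
#' conventional layout for this sensitivity analysis and is reproduced
#' as such.
#'
#' @param table Long-form data with columns `subject_id`, `condition`,
#'   `type_tag`, `sampen_value`, restricted to a single variable, tolerance
#'   and template length; every subject must appear in both conditions for
#'   every type.
#' @return An `anova_result` with rows `type` (between-units),
#'   `residuals_between`, `velocity`, `velocity:type`, `residuals_within`.
#' @export
mixed_anova <- function(table) {
  table <- as.data.frame(table)
  need <- c("subject_id", "condition", "type_tag", "sampen_value")
  if (!all(need %in% names(table))) {
    stop_gait("gaitsampen_parameter_error",
              paste("table must have columns", paste(need, collapse = ", ")))
  }
  if ("m" %in% names(table) && length(unique(table$m)) > 1L) {
    stop_gait("gaitsampen_parameter_error",
              "mixed_anova expects a single template length m")
  }
  f_cond <- factor(table$condition)
  if (nlevels(f_cond) != 2L) {
    stop_gait("gaitsampen_parameter_error",
              "exactly two walking conditions are required")
  }
  unit <- interaction(table$subject_id, table$type_tag, drop = TRUE)
  pairing <- table(unit, f_cond)
  if (any(pairing != 1L)) {
    bad <- rownames(pairing)[rowSums(pairing != 1L) > 0]
    stop_gait("gaitsampen_pairing_error",
              paste0("each subject x type unit needs exactly one value per ",
                     "condition; offending units: ",
                     paste(utils::head(bad, 5), collapse = ", ")))
  }
  f_type <- factor(table$type_tag)
  grp <- table(f_type) / 2
  if (length(unique(as.vector(grp))) != 1L) {
    stop_gait("gaitsampen_unbalanced_design",
              "between-subject groups (types) are unbalanced")
  }
  d <- data.frame(sampen_value = table$sampen_value, f_type = f_type,
                  f_cond = f_cond, unit = unit)
  fit <- aov(sampen_value ~ f_type * f_cond + Error(unit), data = d)
  s <- summary(fit)
  tab_b <- s[["Error: unit"]][[1]]
  tab_w <- s[["Error: Within"]][[1]]
  total_ss <- sum((d$sampen_value - mean(d$sampen_value))^2)
  between <- build_anova_result(tab_b, c("type", "residuals_between"),
                                total_ss = total_ss)
  within <- build_anova_result(tab_w,
                               c("velocity", "velocity:type",
                                 "residuals_within"),
                               total_ss = total_ss)
  out <- dplyr::bind_rows(between, within)
  attr(out, "design") <- sprintf(
    "%d types (between) x 2 conditions (within) x %d subjects",
    nlevels(f_type), max(grp))
  class(out) <- c("anova_result", class(tibble::as_tibble(out)))
  out
}

# Map an aov summary table onto a tidy effect table. `effects` names the
# rows in order, the last one being the residual stratum.
build_anova_result <- function(tab, effects, design = NULL, total_ss = NULL) {
  stopifnot(nrow(tab) == length(effects))
  df <- tab[["Df"]]
  ss <- tab[["Sum Sq"]]
  fval <- tab[["F value"]]
  pval <- tab[["Pr(>F)"]]
  res_df <- df[length(effects)]
  # an effect with (numerically) zero between-group variance carries no
  # evidence: report F = 0, p = 1 rather than aov's 0/0 (the threshold is
  # relative to the grand total SS of the data)
  if (is.null(total_ss)) total_ss <- sum(ss)
  zero <- seq_along(effects) < length(effects) & ss <= 1e-12 * total_ss
  fval[zero] <- 0
  pval[zero] <- 1
  out <- tibble::tibble(
    effect = effects,
    df = as.integer(df),
    ss = ss,
    statistic = fval,
    df1 = ifelse(seq_along(effects) < length(effects), as.integer(df), NA_integer_),
    df2 = ifelse(seq_along(effects) < length(effects), as.integer(res_df), NA_integer_),
    p_value = pval
  )
  if (!is.null(design)) attr(out, "design") <- design
  class(out) <- c("anova_result", class(out))
  out
}

#' @export
print.anova_result <- function(x, ...) {
  design <- attr(x, "design")
  if (!is.null(design)) cat("Design:", design, "\n")
  for (i in seq_len(nrow(x))) {
    if (is.na(x$statistic[i])) {
      cat(sprintf("  %-18s df = %d, SS = %.4g\n", x$effect[i], x$df[i], x$ss[i]))
    } else {
      cat(sprintf("  %-18s F(%d,%d) = %.2f, p = %.3g\n",
                  x$effect[i], x$df1[i], x$df2[i], x$statistic[i],
                  x$p_value[i]))
    }
  }
  invisible(x)
}
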