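# Independent oracles, kept deliberately separate from the package's own
# algorithms.

# Sample-entropy match counts by full pairwise enumeration: every template
# pair is materialised via embed() and compared with base R's Chebyshev
# distance. Both template lengths use start indices 1..N-m (the pairing
# that makes A/B a conditional probability).
oracle_sampen_counts <- function(x, m, r) {
  n <- length(x)
  stopifnot(n > m + 1)
  t_m <- embed(x, m)[seq_len(n - m), , drop = FALSE]
  t_m1 <- embed(x, m + 1)
  B <- sum(as.matrix(dist(t_m, method = "maximum"))[upper.tri(diag(n - m))] <= r)
  A <- sum(as.matrix(dist(t_m1, method = "maximum"))[upper.tri(diag(n - m))] <= r)
  list(A = A, B = B)
}

# Textbook sums-of-squares decomposition for a balanced two-factor
# fixed-effects design with replicates.
oracle_two_way <- function(y, fa, fb) {
  fa <- factor(fa); fb <- factor(fb)
  n_rep <- length(y) / (nlevels(fa) * nlevels(fb))
  g <- mean(y)
  mean_a <- tapply(y, fa, mean)
  mean_b <- tapply(y, fb, mean)
  mean_ab <- tapply(y, interaction(fa, fb), mean)
  ss_a <- n_rep * nlevels(fb) * sum((mean_a - g)^2)
  ss_b <- n_rep * nlevels(fa) * sum((mean_b - g)^2)
  cell <- tapply(y, list(fa, fb), mean)
  ss_ab <- n_rep * sum((sweep(sweep(cell, 1, mean_a), 2, mean_b) + g)^2)
  ss_tot <- sum((y - g)^2)
  ss_err <- ss_tot - ss_a - ss_b - ss_ab
  df_a <- nlevels(fa) - 1
  df_b <- nlevels(fb) - 1
  df_ab <- df_a * df_b
  df_err <- length(y) - nlevels(fa) * nlevels(fb)
  f <- c(a = (ss_a / df_a) / (ss_err / df_err),
         b = (ss_b / df_b) / (ss_err / df_err),
         ab = (ss_ab / df_ab) / (ss_err / df_err))
  p <- pf(f, c(df_a, df_b, df_ab), df_err, lower.tail = FALSE)
  list(ss = c(a = ss_a, b = ss_b, ab = ss_ab, err = ss_err, tot = ss_tot),
       df = c(a = df_a, b = df_b, ab = df_ab, err = df_err),
       F = f, p = p)
}

# Split-plot sums of squares: `unit` (subject x group) measured in both
# within-factor levels, `grp` constant within unit.
oracle_split_plot <- function(y, grp, within, unit) {
  grp <- factor(grp); within <- factor(within); unit <- factor(unit)
  g <- mean(y)
  n_per_level <- length(y) / nlevels(within)
  unit_means <- tapply(y, unit, mean)
  ss_between <- nlevels(within) * sum((unit_means - g)^2)
  grp_means <- tapply(y, grp, mean)
  ss_grp <- (length(y) / nlevels(grp)) * sum((grp_means - g)^2)
  ss_err_b <- ss_between - ss_grp
  w_means <- tapply(y, within, mean)
  ss_w <- n_per_level * sum((w_means - g)^2)
  cell <- tapply(y, list(grp, within), mean)
  ss_int <- (length(y) / (nlevels(grp) * nlevels(within))) *
    sum((sweep(sweep(cell, 1, grp_means), 2, w_means) + g)^2)
  ss_tot <- sum((y - g)^2)
  ss_err_w <- ss_tot - ss_between - ss_w - ss_int
  df_grp <- nlevels(grp) - 1
  df_err_b <- nlevels(unit) - nlevels(grp)
  df_w <- nlevels(within) - 1
  df_int <- df_grp * df_w
  df_err_w <- (nlevels(unit) - nlevels(grp)) * df_w
  list(
    F = c(grp = (ss_grp / df_grp) / (ss_err_b / df_err_b),
          within = (ss_w / df_w) / (ss_err_w / df_err_w),
          int = (ss_int / df_int) / (ss_err_w / df_err_w)),
    df = c(grp = df_grp, err_b = df_err_b, within = df_w, int = df_int,
           err_w = df_err_w),
    ss = c(grp = ss_grp, err_b = ss_err_b, within = ss_w, int = ss_int,
           err_w = ss_err_w, tot = ss_tot)
  )
}
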