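make_two_way_table <- function(n_subj, types, ms, f = function(n) rnorm(n)) {
  grid <- expand.grid(subject_id = sprintf("S%02d", seq_len(n_subj)),
                      type_tag = types, m = ms,
                      stringsAsFactors = FALSE)
  grid$sampen_value <- f(nrow(grid))
  grid
}

test_that("the full design reproduces the expected degrees of freedom", {
  set.seed(1)
  tab <- make_two_way_table(23, c("WHOLE", "SEGM", "NORM", "ZERO"),
                            c(2, 4, 6, 8, 10))
  res <- two_way_anova(tab)
  expect_identical(res$df1[res$effect == "type"], 3L)
  expect_identical(res$df1[res$effect == "m"], 4L)
  expect_identical(res$df1[res$effect == "type:m"], 12L)
  expect_identical(unique(res$df2[1:3]), 440L)
  # decomposition identity
  expect_equal(sum(res$ss), sum((tab$sampen_value - mean(tab$sampen_value))^2),
               tolerance = 1e-8)
})

test_that("F statistics match the textbook sums-of-squares oracle", {
  set.seed(2)
  for (i in 1:5) {
    tab <- make_two_way_table(5, c("A", "B"), c(1, 2))
    res <- two_way_anova(tab)
    orc <- oracle_two_way(tab$sampen_value, tab$type_tag, tab$m)
    expect_equal(res$statistic[1:3], unname(orc$F), tolerance = 1e-8)
    expect_equal(res$p_value[1:3], unname(orc$p), tolerance = 1e-8)
    expect_equal(res$ss[4], unname(orc$ss["err"]), tolerance = 1e-8)
  }
})

test_that("a constant table yields zero F for every effect", {
  tab <- make_two_way_table(4, c("A", "B"), c(1, 2), f = function(n) rep(2, n))
  res <- two_way_anova(tab)
  expect_identical(res$statistic[1:3], rep(0, 3))
  expect_identical(res$p_value[1:3], rep(1, 3))
})

test_that("adding a constant to every observation changes no F value", {
  set.seed(3)
  tab <- make_two_way_table(6, c("A", "B", "C"), c(1, 2, 3))
  res1 <- two_way_anova(tab)
  tab$sampen_value <- tab$sampen_value + 123.4
  res2 <- two_way_anova(tab)
  expect_equal(res1$statistic, res2$statistic, tolerance = 1e-8)
})

test_that("unbalanced two-way tables are rejected with the offending cells", {
  set.seed(4)
  tab <- make_two_way_table(5, c("A", "B"), c(1, 2))
  tab <- tab[-1, ]
  expect_error(two_way_anova(tab), class = "gaitsampen_unbalanced_design")
})

make_mixed_table <- function(n_subj, types, f = function(n) rnorm(n)) {
  grid <- expand.grid(subject_id = sprintf("S%02d", seq_len(n_subj)),
                      type_tag = types, condition = c("Vpref", "Vmax"),
                      stringsAsFactors = FALSE)
  grid$sampen_value <- f(nrow(grid))
  grid
}

test_that("the mixed design reproduces the split-plot degrees of freedom", {
  set.seed(5)
  tab <- make_mixed_table(23, c("WHOLE", "SEGM", "NORM", "ZERO"))
  res <- mixed_anova(tab)
  expect_identical(res$df1[res$effect == "type"], 3L)
  expect_identical(res$df2[res$effect == "type"], 88L)
  expect_identical(res$df1[res$effect == "velocity"], 1L)
  expect_identical(res$df2[res$effect == "velocity"], 88L)
  expect_identical(res$df1[res$effect == "velocity:type"], 3L)
  expect_equal(sum(res$ss), sum((tab$sampen_value - mean(tab$sampen_value))^2),
               tolerance = 1e-8)
})

test_that("mixed-model F statistics match the split-plot oracle", {
  set.seed(6)
  for (i in 1:5) {
    tab <- make_mixed_table(7, c("A", "B", "C"))
    res <- mixed_anova(tab)
    orc <- oracle_split_plot(tab$sampen_value, tab$type_tag, tab$condition,
                             interaction(tab$subject_id, tab$type_tag))
    expect_equal(res$statistic[res$effect == "type"], unname(orc$F["grp"]),
                 tolerance = 1e-8)
    expect_equal(res$statistic[res$effect == "velocity"],
                 unname(orc$F["within"]), tolerance = 1e-8)
    expect_equal(res$statistic[res$effect == "velocity:type"],
                 unname(orc$F["int"]), tolerance = 1e-8)
  }
})

test_that("identical condition values per subject give zero velocity F", {
  set.seed(7)
  half <- expand.grid(subject_id = sprintf("S%02d", 1:6),
                      type_tag = c("A", "B"), condition = "Vpref",
                      stringsAsFactors = FALSE)
  half$sampen_value <- rnorm(nrow(half))
  other <- half
  other$condition <- "Vmax"
  tab <- rbind(half, other)
  res <- mixed_anova(tab)
  expect_identical(res$statistic[res$effect == "velocity"], 0)
})

test_that("a subject missing one condition is a pairing error", {
  set.seed(8)
  tab <- make_mixed_table(5, c("A", "B"))
  tab <- tab[!(tab$subject_id == "S01" & tab$condition == "Vmax" &
                 tab$type_tag == "A"), ]
  expect_error(mixed_anova(tab), class = "gaitsampen_pairing_error")
})

test_that("an injected velocity effect is detected with high power", {
  detect <- function(seed) {
    set.seed(seed)
    tab <- make_mixed_table(8, c("A", "B"))
    shift <- ifelse(tab$condition == "Vmax", 1.5, 0)
    tab$sampen_value <- rnorm(nrow(tab)) + shift
    res <- mixed_anova(tab)
    res$p_value[res$effect == "velocity"] < 0.05
  }
  hits <- sum(vapply(1:100, detect, logical(1)))
  expect_gte(hits, 90)
})
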