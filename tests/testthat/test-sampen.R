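test_that("the tolerance is a fixed fraction of the population SD", {
  x <- c(0, 10, 0, 10)  # population SD exactly 5
  expect_equal(compute_r(x, 0.2), 1.0)
  expect_error(compute_r(rep(3, 50), 0.2), class = "gaitsampen_zero_tolerance")
  # per-cycle averaging variant
  y <- c(rep(c(0, 10), 5), rep(c(0, 2), 5))   # cycle SDs 5 and 1
  expect_equal(compute_r(y, 0.2, samples_per_cycle = 10), 0.2 * 3)
})

test_that("an exactly periodic series has zero sample entropy", {
  x <- rep(c(0, 1, 2, 1), 50)
  res <- sample_entropy(x, m = 2, r = 0.5)
  expect_identical(res$value, 0)
  expect_identical(res$A, res$B)
  expect_gt(res$B, 0)
})

test_that("fast counts equal full enumeration on fixed and random series", {
  x <- c(1, 2, 3, 2, 1, 2, 3, 2, 1)
  res <- sample_entropy(x, m = 2, r = 0.5)
  orc <- oracle_sampen_counts(x, 2, 0.5)
  expect_identical(res$A, as.numeric(orc$A))
  expect_identical(res$B, as.numeric(orc$B))
  expect_equal(res$value, -log(orc$A / orc$B))

  set.seed(123)
  for (i in 1:40) {
    n <- sample(30:200, 1)
    m <- sample(1:10, 1)
    y <- rnorm(n)
    r <- runif(1, 0.1, 0.6)
    orc <- oracle_sampen_counts(y, m, r)
    got <- tryCatch(sample_entropy(y, m, r = r),
                    gaitsampen_error = function(e) e)
    if (inherits(got, "sampen_result")) {
      expect_identical(got$A, as.numeric(orc$A))
      expect_identical(got$B, as.numeric(orc$B))
      expect_true(got$A <= got$B)
      expect_gte(got$value, 0)
    } else {
      expect_true(orc$A == 0 || orc$B == 0)
    }
  }
})

test_that("sample entropy is translation-invariant and scale-covariant", {
  set.seed(7)
  x <- rnorm(150)
  base <- sample_entropy(x, 3, r = 0.4)
  shifted <- sample_entropy(x + 57.3, 3, r = 0.4)
  expect_identical(shifted$value, base$value)
  expect_identical(shifted$A, base$A)
  # with the SD-relative convention, positive scaling cancels exactly
  base_rf <- sample_entropy(x, 3, r_factor = 0.2)
  scaled_rf <- sample_entropy(4 * x, 3, r_factor = 0.2)
  expect_identical(scaled_rf$A, base_rf$A)
  expect_identical(scaled_rf$B, base_rf$B)
})

test_that("i.i.d. noise is consistently less regular than a sine", {
  n <- 2200
  t <- seq_len(n)
  for (s in 1:20) {
    set.seed(s)
    noise <- runif(n)
    sine <- sin(2 * pi * t / 100)
    e_noise <- sample_entropy(noise, 2, r_factor = 0.2)$value
    e_sine <- sample_entropy(sine, 2, r_factor = 0.2)$value
    expect_gt(e_noise, e_sine)
  }
})

test_that("undefined entropies distinguish missing m-matches from missing extensions", {
  # strictly increasing with huge steps: no m-matches at all
  x_no_b <- cumsum(rep(10, 30))
  expect_error(sample_entropy(x_no_b, 2, r = 0.5),
               class = "gaitsampen_no_m_matches")
  # zeros match at m = 1 but every continuation differs
  x_no_a <- as.numeric(rbind(0, 2^(1:10)))
  expect_error(sample_entropy(x_no_a, 1, r = 0.1),
               class = "gaitsampen_no_m1_matches")
  expect_error(sample_entropy(1:5, 10, r = 0.5),
               class = "gaitsampen_length_error")
})

test_that("the grid reports one row per combination and missing cells carry reasons", {
  set.seed(11)
  x <- rnorm(300)
  g <- sampen_grid(x, m_list = c(2, 4, 6, 8, 10), r_factor_list = 0.2)
  expect_identical(nrow(g), 5L)
  expect_true(all(is.na(g$reason) | g$reason != ""))
  g2 <- sampen_grid(x, m_list = c(2, 4), r_factor_list = c(0.1, 0.2, 0.3))
  expect_identical(nrow(g2), 6L)
  expect_identical(sampen_grid(x, m_list = integer(0)) |> nrow(), 0L)
  # a cell with matches at m but none extending: reason code, not an error
  x_no_a <- as.numeric(rbind(0, 2^(1:10)))
  g3 <- sampen_grid(x_no_a, m_list = 1, r_factor_list = 0.01 / sd(x_no_a))
  expect_true(is.na(g3$value[1]))
  expect_match(g3$reason[1], "no \\(m\\+1\\) matches")
})
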