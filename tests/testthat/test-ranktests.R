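test_that("degenerate and separated samples give their exact p-values", {
  r <- rank_sum_test(5, 5)
  expect_equal(r$p_value, 1)
  expect_equal(r$eta_squared, 0)
  expect_false(r$significant)

  # complete separation of 6 vs 6 distinct values: 2 of the C(12,6)
  # equally likely rank assignments are as extreme
  r <- rank_sum_test(1:6, 7:12, alpha = 0.05)
  expect_equal(r$p_value, 2 / 924, tolerance = 1e-12)
  expect_true(r$significant)
  expect_equal(r$method, "exact enumeration")
  # rank eta-squared of that configuration: SS_between/SS_total = 108/143
  expect_equal(r$eta_squared, 108 / 143, tolerance = 1e-12)
})

test_that("exact enumeration agrees with wilcox.test without ties", {
  set.seed(19)
  for (i in 1:20) {
    a <- stats::rnorm(sample(3:7, 1))
    b <- stats::rnorm(sample(3:8, 1), mean = stats::runif(1, 0, 2))
    ours <- rank_sum_test(a, b)
    ref <- stats::wilcox.test(a, b, exact = TRUE, correct = FALSE)
    expect_equal(ours$p_value, ref$p.value, tolerance = 1e-10)
  }
})

test_that("the normal approximation converges but the exact path is needed", {
  set.seed(29)
  # untied samples of moderate size: approximation within 0.02
  worst_cont <- 0
  for (i in 1:40) {
    a <- stats::rnorm(sample(6:8, 1))
    b <- stats::rnorm(sample(6:8, 1), mean = 0.8)
    exact <- rank_sum_test(a, b)
    approx <- rank_sum_test(a, b, max_enum = 0)
    expect_equal(exact$method, "exact enumeration")
    expect_equal(approx$method, "normal approximation")
    worst_cont <- max(worst_cont, abs(exact$p_value - approx$p_value))
  }
  expect_lt(worst_cont, 0.02)
  # heavily tied tiny samples break the approximation, which is why
  # enumeration handles them (and matches wilcox.test's approximation
  # when forced off)
  a <- c(1.5, 0.5, 1.5); b <- c(2.5, 1.5, 1.5)
  approx <- rank_sum_test(a, b, max_enum = 0)
  ref <- stats::wilcox.test(a, b, exact = FALSE, correct = TRUE)
  expect_equal(approx$p_value, ref$p.value, tolerance = 1e-12)
  expect_gt(abs(rank_sum_test(a, b)$p_value - approx$p_value), 0.02)
})

test_that("rank eta-squared equals direct sums of squares and H/(n-1)", {
  set.seed(41)
  for (i in 1:25) {
    a <- stats::rnorm(sample(5:30, 1))
    b <- stats::rnorm(sample(5:30, 1), mean = 0.5)
    e <- eta_squared_ranks(a, b)
    r <- rank(c(a, b)); g <- rep(1:2, c(length(a), length(b)))
    ssb <- sum(tapply(r, g, function(v) length(v) * (mean(v) - mean(r))^2))
    expect_lt(abs(e - ssb / sum((r - mean(r))^2)), 1e-12)
    # Kruskal-Wallis cross-check: eta^2 on ranks = H / (n - 1)
    H <- unname(stats::kruskal.test(c(a, b), g)$statistic)
    expect_lt(abs(e - H / (length(r) - 1)), 1e-10)
  }
})

test_that("rank statistics are invariant under monotone transforms", {
  set.seed(61)
  a <- stats::rgamma(12, 2); b <- stats::rgamma(15, 3)
  r1 <- rank_sum_test(a, b)
  r2 <- rank_sum_test(exp(a), exp(b))
  r3 <- rank_sum_test(log(a), log(b))
  expect_equal(r1$p_value, r2$p_value, tolerance = 1e-12)
  expect_equal(r1$p_value, r3$p_value, tolerance = 1e-12)
  expect_equal(r1$eta_squared, r2$eta_squared, tolerance = 1e-12)
  expect_equal(r1$eta_squared, r3$eta_squared, tolerance = 1e-12)
})
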