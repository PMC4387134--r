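test_that("HQI ratios are exact quotients with guarded input", {
  expect_equal(hqi_ratio(1882, 2155), 1882 / 2155)
  expect_equal(round(hqi_ratio(1882, 2155), 2), 0.87)
  expect_equal(round(hqi_ratio(4, 267), 3), 0.015)
  expect_equal(hqi_ratio(0, 100), 0)
  expect_error(hqi_ratio(0, 0), "at least one")
  expect_error(hqi_ratio(5, 4))
})

test_that("SumDiff and pwStd match their closed forms on tiny streams", {
  # constant stream: both zero
  a <- array(1.1, c(3, 4, 5))
  expect_true(all(sum_diff(a) == 0))
  expect_true(all(pw_std(a) == 0))
  # two frames differing at one pixel by 0.005
  b <- array(1.2, c(3, 4, 2)); b[2, 3, 2] <- 1.205
  sd2 <- sum_diff(b)
  expect_equal(sd2[2, 3], 0.005)
  expect_equal(sum(sd2), 0.005)
  # two-point sample standard deviation is d/sqrt(2)
  expect_equal(pw_std(b)[2, 3], 0.005 / sqrt(2))
  expect_error(sum_diff(array(1, c(2, 2, 1))), "two frames")
  expect_error(pw_std(array(1, c(2, 2, 1))), "two frames")
})

test_that("criteria equal brute-force loops on a random 7-frame stream", {
  set.seed(21)
  fr <- array(stats::rnorm(6 * 5 * 7, 1.2, 0.01), c(6, 5, 7))
  sd_fast <- sum_diff(fr)
  std_fast <- pw_std(fr)
  for (r in 1:6) for (cc in 1:5) {
    v <- fr[r, cc, ]
    expect_lt(abs(sd_fast[r, cc] - sum(abs(diff(v))) / 6), 1e-12)
    expect_lt(abs(std_fast[r, cc] - stats::sd(v)), 1e-12)
  }
})

test_that("pwStd is permutation-invariant; SumDiff only for two frames", {
  set.seed(8)
  fr <- array(stats::rnorm(4 * 4 * 6), c(4, 4, 6))
  perm <- fr[, , sample(6)]
  expect_equal(pw_std(perm), pw_std(fr), tolerance = 1e-12)
  two <- fr[, , 1:2]
  expect_equal(sum_diff(two[, , 2:1]), sum_diff(two), tolerance = 1e-12)
})

test_that("RpV follows its defining quotient", {
  expect_equal(rpv(c(70, 72, 73, 75)), 5 / 4)
  expect_equal(rpv(rep(71, 10)), 0)
  expect_true(is.na(rpv(numeric(0))))
  # hand-loop oracle on simulated-like coordinate lists
  set.seed(3)
  for (i in 1:20) {
    xs <- sample(60:80, sample(2:40, 1), replace = TRUE)
    expect_equal(rpv(xs), (max(xs) - min(xs)) / length(xs))
  }
})

test_that("region medians match a sorting oracle", {
  m <- matrix(0.004, 9, 9)
  p <- partition_regions(matrix(TRUE, 9, 9))
  tab <- medians_by_region(m, p)
  expect_true(all(tab$median == 0.004))

  set.seed(14)
  mask <- random_blob_mask(20, 18)
  vals <- matrix(stats::runif(20 * 18), 20, 18)
  p <- partition_regions(mask)
  tab <- medians_by_region(vals, p)
  expect_equal(tab$median[tab$label == "interior"],
               stats::median(sort(vals[p$interior])))
  expect_equal(tab$median[tab$label == "boundary"],
               stats::median(sort(vals[p$boundary])))
  expect_equal(tab$n[tab$label == "boundary"], sum(p$boundary))
})
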