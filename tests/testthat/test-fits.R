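test_that("quadratic fits recover exact polynomials and obey conventions", {
  f <- fit_quadratic(c(1, 4, 9, 16), 1:4)
  expect_equal(unname(f$coefficients), c(1, 0, 0), tolerance = 1e-10)
  expect_equal(f$rmsd, 0, tolerance = 1e-7)
  expect_equal(f$r_squared, 1, tolerance = 1e-12)
  expect_equal(f$dof, 1)
  expect_error(fit_quadratic(c(1, 2, 3)), "at least 4")
})

test_that("quadratic coefficients match the normal-equations oracle", {
  set.seed(33)
  x <- 1:4
  X <- cbind(1, x, x^2)
  for (i in 1:100) {
    y <- stats::rnorm(4)
    f <- fit_quadratic(y, x)
    beta <- solve(t(X) %*% X, t(X) %*% y)
    expect_lt(abs(f$coefficients["alpha"] - beta[3]), 1e-9)
    expect_lt(abs(f$coefficients["beta"] - beta[2]), 1e-9)
    expect_lt(abs(f$coefficients["gamma"] - beta[1]), 1e-9)
    # orthogonal-polynomial identity for equally spaced abscissae
    expect_lt(abs(f$coefficients["alpha"] - (y[1] - y[2] - y[3] + y[4]) / 4),
              1e-12)
  }
})

test_that("gaussian-exponential fit is self-consistent and near-global", {
  x <- 1:4
  y <- 2 * exp(-((x - 0) / 1.5)^2)
  f <- fit_gaussian_exp(y, x)
  expect_lt(f$rmsd, 1e-6)
  expect_equal(unname(f$coefficients["K"]), 2, tolerance = 1e-4)
  expect_equal(unname(f$coefficients["L"]), 0, tolerance = 1e-3)
  expect_equal(unname(f$coefficients["M"]), 1.5, tolerance = 1e-3)

  # grid-search oracle: the fitted SSE is no worse than the best point
  # of a dense parameter grid
  yf <- hqi_ratio(c(2138, 141, 21, 4), c(2138, 411, 356, 267))
  f2 <- fit_gaussian_exp(yf, x)
  grid <- expand.grid(K = seq(0.5, 3, length.out = 100),
                      L = seq(-3, 3, length.out = 100),
                      M = seq(0.3, 6, length.out = 100))
  sse <- rep(0, nrow(grid))
  for (xi in x) {
    yi <- yf[xi]
    sse <- sse + (yi - grid$K * exp(-((xi - grid$L) / grid$M)^2))^2
  }
  expect_lte(f2$sse, min(sse) + 1e-12)
})

test_that("restarting the fur-ratio fit always reaches the same minimum", {
  x <- 1:4
  yf <- hqi_ratio(c(2138, 141, 21, 4), c(2138, 411, 356, 267))
  base <- fit_gaussian_exp(yf, x)
  set.seed(55)
  for (i in 1:20) {
    init <- c(stats::runif(1, 0.2, 5), stats::runif(1, -4, 4),
              stats::runif(1, 0.2, 8))
    f <- fit_gaussian_exp(yf, x, init = init)
    expect_lt(abs(f$sse - base$sse), 1e-6)
  }
})

test_that("half-away rounding follows the tabulation convention", {
  expect_equal(round_half_away(-0.005, 2), -0.01)
  expect_equal(round_half_away(0.0368, 3), 0.037)
  expect_equal(round_half_away(0.015, 2), 0.02)
  expect_equal(round_half_away(2.4, 0), 2)
  expect_equal(round_half_away(-2.5, 0), -3)
})
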