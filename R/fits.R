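#' Quadratic least-squares fit with the study's goodness-of-fit conventions
#'
#' Fits `alpha*x^2 + beta*x + gamma` by ordinary least squares. The four
#' velocities 0, 10, 20, 30 cm/s enter as the ordinal abscissae
#' x = 1, 2, 3, 4 (not the cm/s values): evaluating the reported
#' coefficients at x = 1 must return the standstill value. Goodness of
#' fit follows the curve-fitting convention `RMSD = sqrt(SSE / dof)` with
#' `dof = n - 3` (a single degree of freedom for four points) and
#' `R^2 = 1 - SSE/SST`. For equally spaced x the quadratic coefficient
#' satisfies the orthogonal-polynomial identity
#' `alpha = (y1 - y2 - y3 + y4) / 4`.
#'
#' @param y Numeric vector of at least 4 finite values.
#' @param x Abscissae; defaults to `1:length(y)`.
#' @return Object of class `fit_result`: `kind`, `coefficients`
#'   (`alpha`, `beta`, `gamma`), `sse`, `rmsd`, `r_squared`, `dof`,
#'   `fitted`, `converged`.
#' @export
fit_quadratic <- function(y, x = seq_along(y)) {
  if (length(y) < 4) stop("quadratic fit needs at least 4 points")
  if (!all(is.finite(y))) stop("y must be finite")
  fit <- stats::lm(y ~ x + I(x^2))
  co <- stats::coef(fit)
  coefficients <- c(alpha = unname(co[3]), beta = unname(co[2]),
                    gamma = unname(co[1]))
  fit_result("quadratic", coefficients, y, stats::fitted(fit),
             n_par = 3, converged = TRUE)
}

#' Gaussian-exponential least-squares fit
#'
#' Fits `K * exp(-((x - L) / M)^2)` by nonlinear least squares with a
#' deterministic multi-start (default initialisation `K = max(y)`,
#' `L = argmax abscissa`, `M = grid span`; log-quadratic and log-linear
#' ridge starts; a small deterministic perturbation set), each polished
#' with Nelder-Mead and BFGS, keeping the global SSE minimum. Note the
#' negative sign in the exponent: only this form decays and reproduces
#' the decreasing frame-quality ratios. Monotone log-convex data makes
#' the model degenerate (the optimum runs along a ridge of growing `|L|`,
#' `M` toward a pure exponential); the multi-start follows the ridge far
#' enough that the SSE is at its limiting value, and `converged` reports
#' whether the best start terminated cleanly.
#'
#' @param y Numeric vector (>= 4 values, positive `K` expected).
#' @param x Abscissae; defaults to `1:length(y)`.
#' @param init Optional `c(K, L, M)` start, tried in addition.
#' @return Object of class `fit_result` with coefficients `K`, `L`, `M`.
#' @export
fit_gaussian_exp <- function(y, x = seq_along(y), init = NULL) {
  if (length(y) < 4) stop("Gaussian-exponential fit needs at least 4 points")
  if (!all(is.finite(y))) stop("y must be finite")
  model <- function(p, x) p[1] * exp(-((x - p[2]) / p[3])^2)
  sse_fun <- function(p) {
    r <- y - model(p, x)
    sum(r * r)
  }
  span <- diff(range(x))
  starts <- list(c(max(y), x[which.max(y)], span))
  if (!is.null(init)) starts <- c(starts, list(init))
  # log-quadratic start: exact when the data lie on the model
  ypos <- pmax(y, 1e-12)
  lq <- stats::coef(stats::lm(log(ypos) ~ x + I(x^2)))
  if (is.finite(lq[3]) && lq[3] < -1e-12) {
    M0 <- sqrt(-1 / lq[3]); L0 <- lq[2] * M0^2 / 2
    starts <- c(starts, list(c(exp(lq[1] + L0^2 / M0^2), L0, M0)))
  }
  # log-linear ridge starts for monotone data the model can only reach in
  # the large-M limit
  ll <- stats::coef(stats::lm(log(ypos) ~ x))
  for (M0 in c(5, 30, 150, 1000)) {
    L0 <- ll[2] * M0^2 / 2
    K0 <- exp(min(ll[1] + L0^2 / M0^2, 700))
    starts <- c(starts, list(c(K0, L0, M0)))
  }
  starts <- c(starts, list(c(max(y), min(x) - span, span),
                           c(mean(y), mean(x), span / 2)))
  best <- NULL
  for (s in starts) {
    if (!all(is.finite(s))) next
    o <- tryCatch({
      nm <- stats::optim(s, sse_fun, method = "Nelder-Mead",
                         control = list(maxit = 20000, reltol = 1e-15))
      stats::optim(nm$par, sse_fun, method = "BFGS",
                   control = list(maxit = 2000, reltol = 1e-15))
    }, error = function(e) NULL)
    if (is.null(o) || !is.finite(o$value)) next
    if (is.null(best) || o$value < best$value) best <- o
  }
  if (is.null(best)) {
    out <- fit_result("gaussian_exp", c(K = NA_real_, L = NA_real_,
                                        M = NA_real_), y, rep(NA_real_,
                                                              length(y)),
                      n_par = 3, converged = FALSE)
    return(out)
  }
  coefficients <- c(K = unname(best$par[1]), L = unname(best$par[2]),
                    M = abs(unname(best$par[3])))
  fit_result("gaussian_exp", coefficients, y, model(best$par, x),
             n_par = 3, converged = best$convergence == 0)
}

fit_result <- function(kind, coefficients, y, fitted, n_par, converged) {
  sse <- sum((y - fitted)^2)
  dof <- length(y) - n_par
  sst <- sum((y - mean(y))^2)
  out <- list(kind = kind, coefficients = coefficients, sse = sse,
              rmsd = sqrt(sse / dof), r_squared = 1 - sse / sst,
              dof = dof, fitted = fitted, converged = converged)
  class(out) <- "fit_result"
  out
}

#' @export
print.fit_result <- function(x, ...) {
  cat(sprintf("%s fit: %s\n  SSE %.6g, RMSD %.4f, R^2 %.4f, dof %d%s\n",
              x$kind,
              paste(sprintf("%s = %.4g", names(x$coefficients),
                            x$coefficients), collapse = ", "),
              x$sse, x$rmsd, x$r_squared, x$dof,
              if (x$converged) "" else " (not converged)"))
  invisible(x)
}

#' Round half away from zero
#'
#' The tabulation convention used for reported coefficients: halves round
#' away from zero (`-0.005` prints as `-0.01` at two decimals), unlike
#' R's banker's rounding.
#'
#' @param value Numeric vector.
#' @param decimals Number of decimal places.
#' @return Rounded values.
#' @export
round_half_away <- function(value, decimals = 0) {
  p <- 10^decimals
  # the 1e-9 guard keeps decimal halves (0.015 * 100 = 1.4999...98 in
  # binary) on the away-from-zero side
  sign(value) * floor(abs(value) * p + 0.5 + 1e-9) / p
}
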