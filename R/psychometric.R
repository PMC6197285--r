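#' Cumulative normal function
#'
#' The standard-normal cumulative distribution function `H(z)`, the link of
#' the psychometric model `P(delta_c) = H((delta_c + b)/sigma)`. A thin,
#' vectorised wrapper around [stats::pnorm()].
#'
#' @param z Numeric vector.
#' @return `P(Z <= z)` for standard normal `Z`.
#' @export
cumulative_normal <- function(z) {
  stats::pnorm(z)
}

#' Maximum psychometric slope from internal noise
#'
#' Converts the noise SD `sigma` of a cumulative-Gaussian psychometric curve
#' into its maximum slope, `S = 1/sqrt(2 * pi * sigma^2)` — the sensitivity
#' measure. Strictly decreasing in `sigma`.
#'
#' @param sigma Positive noise SD (contrast units). Vectorised.
#' @return Sensitivity `S` in 1/contrast units.
#' @export
#' @examples
#' slope_from_sigma(1)            # 1/sqrt(2*pi)
#' slope_from_sigma(1 / sqrt(2 * pi))  # 1
slope_from_sigma <- function(sigma) {
  if (any(!is.finite(sigma)) || any(sigma <= 0)) {
    stop("parameter error: sigma must be positive")
  }
  1 / sqrt(2 * pi * sigma^2)
}

#' Predicted probability of a "second interval" report
#'
#' Evaluates the psychometric curve `H((delta_c + b)/sigma)` of a fitted or
#' hand-specified model.
#'
#' @param fit A [fit_psychometric()] result, or any list with elements `b`
#'   and `sigma`.
#' @param delta_c Numeric vector of signed contrast differences.
#' @return Probabilities of choosing interval 2.
#' @export
predict_prob <- function(fit, delta_c) {
  if (!is.finite(fit$sigma) || fit$sigma <= 0) {
    stop("parameter error: sigma must be positive")
  }
  cumulative_normal((delta_c + fit$b) / fit$sigma)
}

# Binomial log-likelihood of a probit model with linear predictor
# beta0 + beta1 * delta_c; probabilities clamped away from 0/1 so that
# boundary grid points stay finite.
probit_loglik <- function(beta0, beta1, delta_c, y) {
  p <- stats::pnorm(beta0 + beta1 * delta_c)
  p <- pmin(pmax(p, 1e-12), 1 - 1e-12)
  sum(y * log(p) + (1 - y) * log(1 - p))
}

new_psychometric_fit <- function(beta0, beta1, n, loglik, converged,
                                 method = "mle") {
  if (beta1 != 0) {
    sigma <- 1 / abs(beta1)
    b <- beta0 / beta1
  } else {
    sigma <- Inf
    b <- NA_real_
  }
  structure(
    list(
      b = b,
      sigma = sigma,
      slope_coef = beta1,
      intercept_coef = beta0,
      S_signed = beta1 / sqrt(2 * pi),
      n_trials = as.integer(n),
      loglik = loglik,
      converged = converged,
      method = method
    ),
    class = "psychometric_fit"
  )
}

#' @export
print.psychometric_fit <- function(x, ...) {
  cat(sprintf(
    "probit psychometric fit (%s, n = %d): b = %.4f, sigma = %.4f, S = %.4f\n",
    x$method, x$n_trials, x$b, x$sigma, x$S_signed
  ))
  cat(sprintf(
    "coefficients: intercept %.4f, slope %.4f; loglik %.4f; converged: %s\n",
    x$intercept_coef, x$slope_coef, x$loglik, x$converged
  ))
  invisible(x)
}

#' Fit the cumulative-Gaussian psychometric model
#'
#' Maximum-likelihood probit regression of the binary response "reported the
#' target in the second display" on the signed contrast difference `delta_c`,
#' with an intercept, via [stats::glm()] with a probit link. The
#' coefficients `(beta0, beta1)` are mapped to the psychometric
#' parameterisation `P(delta_c) = H((delta_c + b)/sigma)` by `sigma = 1/|beta1|`
#' and `b = beta0/beta1`, and to the signed maximum slope
#' `S_signed = beta1/sqrt(2*pi)`. A negative fitted slope ("negative
#' sensitivity") means responses anti-correlated with the stimulus; its sign
#' is preserved so the exclusion rule can act on it.
#'
#' @param delta_c Numeric vector of signed contrast differences; at least two
#'   distinct values are required.
#' @param chose_second Logical (or 0/1) vector: chose interval 2? Both
#'   response categories must occur.
#' @param epsilon Convergence tolerance on the IRLS deviance.
#' @param maxit Maximum IRLS iterations.
#' @return An object of class `psychometric_fit` with elements `b`, `sigma`,
#'   `slope_coef`, `intercept_coef`, `S_signed`, `n_trials`, `loglik`,
#'   `converged`.
#' @export
#' @examples
#' set.seed(1)
#' dc <- sample(c(-0.15, -0.075, 0.075, 0.15), 500, replace = TRUE)
#' y <- runif(500) < pnorm(dc / 0.2)
#' fit_psychometric(dc, y)
fit_psychometric <- function(delta_c, chose_second, epsilon = 1e-8, maxit = 200L) {
  y <- as.integer(as.logical(chose_second))
  if (length(y) != length(delta_c)) {
    stop("data error: delta_c and chose_second lengths differ")
  }
  if (anyNA(y) || anyNA(delta_c)) {
    stop("data error: missing values in psychometric data")
  }
  if (length(unique(delta_c)) < 2L) {
    stop("data error: need at least 2 distinct delta_c values")
  }
  if (all(y == 1L) || all(y == 0L)) {
    stop(sprintf(
      "degenerate data: all %d responses identical (%s); the probit slope is unbounded",
      length(y), if (y[1L] == 1L) "interval 2" else "interval 1"
    ))
  }
  fit <- suppressWarnings(stats::glm(
    y ~ delta_c,
    family = stats::binomial(link = "probit"),
    control = stats::glm.control(epsilon = epsilon, maxit = maxit)
  ))
  cf <- stats::coef(fit)
  new_psychometric_fit(
    beta0 = unname(cf[1L]), beta1 = unname(cf[2L]),
    n = length(y),
    loglik = as.numeric(stats::logLik(fit)),
    converged = isTRUE(fit$converged)
  )
}

#' Brute-force grid search fit of the probit psychometric model
#'
#' Evaluates the binomial log-likelihood of the probit model on an explicit
#' `(beta0, beta1)` grid and returns the grid argmax. Intended as an
#' exhaustive, optimiser-free cross-check of [fit_psychometric()]: refining
#' the grid around its argmax converges to the maximum-likelihood estimate.
#'
#' @param delta_c,chose_second As in [fit_psychometric()].
#' @param beta0_grid,beta1_grid Finite numeric grids of intercept and slope
#'   values.
#' @return A `psychometric_fit` whose coefficients are the grid argmax
#'   (`method = "grid"`).
#' @export
fit_psychometric_grid <- function(delta_c, chose_second, beta0_grid, beta1_grid) {
  if (length(beta0_grid) == 0L || length(beta1_grid) == 0L) {
    stop("configuration error: empty parameter grid")
  }
  if (any(!is.finite(beta0_grid)) || any(!is.finite(beta1_grid))) {
    stop("configuration error: grids must be finite")
  }
  y <- as.integer(as.logical(chose_second))
  best <- c(ll = -Inf, b0 = NA_real_, b1 = NA_real_)
  for (b1 in beta1_grid) {
    for (b0 in beta0_grid) {
      ll <- probit_loglik(b0, b1, delta_c, y)
      if (ll > best[["ll"]]) best <- c(ll = ll, b0 = b0, b1 = b1)
    }
  }
  new_psychometric_fit(
    beta0 = best[["b0"]], beta1 = best[["b1"]],
    n = length(y), loglik = best[["ll"]],
    converged = TRUE, method = "grid"
  )
}
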