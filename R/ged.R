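# Symmetric generalized Gaussian (generalized error) distribution:
# f(x) = beta / (2 alpha Gamma(1/beta)) * exp(-(|x - mu| / alpha)^beta).
# beta = 2 recovers the normal (variance alpha^2 / 2), beta = 1 the
# Laplace distribution.

#' Density of the generalized error distribution
#'
#' @param x quantiles
#' @param mu location
#' @param alpha scale (> 0)
#' @param beta shape (> 0); 2 = Gaussian, 1 = Laplace
#' @param log return log-density
#' @export
dged <- function(x, mu = 0, alpha = 1, beta = 2, log = FALSE) {
  stopifnot(alpha > 0, beta > 0)
  ld <- log(beta) - log(2 * alpha) - lgamma(1 / beta) -
    (abs(x - mu) / alpha)^beta
  if (log) ld else exp(ld)
}

#' Random draws from the generalized error distribution
#'
#' Uses the gamma representation: `|X - mu|^beta / alpha^beta` is
#' Gamma(1/beta, 1) with a random sign.
#'
#' @param n number of draws
#' @inheritParams dged
#' @export
rged <- function(n, mu = 0, alpha = 1, beta = 2) {
  stopifnot(alpha > 0, beta > 0)
  g <- stats::rgamma(n, shape = 1 / beta, scale = 1)
  s <- sample(c(-1, 1), n, replace = TRUE)
  mu + alpha * s * g^(1 / beta)
}

#' Fit the generalized error distribution to residuals
#'
#' Maximum-likelihood fit over (mu, log alpha, log beta), started from
#' moment matching (mean, the beta = 2 variance relation
#' `alpha^2 = 2 var`, beta = 2). The log parameterization keeps the
#' scale and shape positive without boundary constraints; Nelder-Mead
#' handles the non-smooth |x - mu| term.
#'
#' @param residuals numeric vector (at least 10 values with nonzero spread)
#' @return list with `mu`, `alpha`, `beta`, `loglik` and `convergence`
#' @export
fit_ged <- function(residuals) {
  residuals <- residuals[is.finite(residuals)]
  if (length(residuals) < 10L) {
    stop("need at least 10 residuals to fit the error distribution",
         call. = FALSE)
  }
  s2 <- stats::var(residuals)
  if (s2 <= .Machine$double.eps) {
    stop("degenerate residuals (zero spread): scale parameter would be 0",
         call. = FALSE)
  }
  start <- c(mu = mean(residuals), la = 0.5 * log(2 * s2), lb = log(2))
  nll <- function(p) {
    -sum(dged(residuals, p[1], exp(p[2]), exp(p[3]), log = TRUE))
  }
  opt <- stats::optim(start, nll, method = "Nelder-Mead",
                      control = list(maxit = 5000, reltol = 1e-10))
  if (opt$convergence != 0) {
    stop(sprintf(
      "error-distribution fit did not converge (start mu=%.4g alpha=%.4g beta=2)",
      start[1], exp(start[2])), call. = FALSE)
  }
  list(mu = unname(opt$par[1]), alpha = unname(exp(opt$par[2])),
       beta = unname(exp(opt$par[3])), loglik = -opt$value,
       convergence = opt$convergence)
}
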