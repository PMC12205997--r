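# Distribution families for the normative trajectory models.
#
# A family bundles: the number of modelled distribution parameters, link
# inverses from the linear predictors, per-observation log-likelihood,
# CDF, quantile function and random generator. Parameters are always
# carried as a list(mu, sigma, nu, tau) on the natural scale.

family_spec <- function(name) {
  switch(name,
    gaussian = family_gaussian(),
    bcpe = family_bcpe(),
    cs_stop(sprintf("unknown family '%s'", name), "cs_validation_error"))
}

family_gaussian <- function() {
  list(
    name = "gaussian",
    npar = 2L,
    par_names = c("mu", "sigma"),
    links = c(mu = "identity", sigma = "log"),
    linkinv = function(eta) list(mu = eta[, 1], sigma = exp(eta[, 2])),
    loglik = function(y, par) dnorm(y, par$mu, par$sigma, log = TRUE),
    cdf = function(y, par) pnorm(y, par$mu, par$sigma),
    quantile = function(p, par) qnorm(p, par$mu, par$sigma),
    rand = function(n, par) rnorm(n, par$mu, par$sigma))
}

# Box-Cox power exponential: y > 0, mu > 0, sigma > 0, nu real (skew /
# transformation power), tau > 0 (kurtosis; tau = 2 is Box-Cox normal).
# The usual centile-estimation convention of neglecting the truncation
# correction for z > -1/(sigma nu) is followed.
bcpe_recycle <- function(...) {
  args <- list(...)
  n <- max(vapply(args, length, integer(1)))
  lapply(args, rep_len, n)
}

bcpe_z <- function(y, mu, sigma, nu) {
  a <- bcpe_recycle(y, mu, sigma, nu)
  r <- a[[1]] / a[[2]]
  z <- numeric(length(r))
  small <- abs(a[[4]]) <= 1e-10
  z[small] <- log(r[small]) / a[[3]][small]
  z[!small] <- (r[!small]^a[[4]][!small] - 1) /
    (a[[3]][!small] * a[[4]][!small])
  z
}

bcpe_log_c <- function(tau) {
  0.5 * (-(2 / tau) * log(2) + lgamma(1 / tau) - lgamma(3 / tau))
}

#' Box-Cox power exponential distribution
#'
#' Density, distribution function, quantile function and random
#' generation for the four-parameter Box-Cox power exponential
#' distribution used by the normative trajectory models. `mu` is the
#' (approximate) median scale, `sigma` the relative dispersion, `nu` the
#' Box-Cox transformation power controlling skew, and `tau` the power
#' exponential exponent controlling tail weight (`tau = 2` recovers the
#' Box-Cox normal).
#'
#' @param x,q,p vectors of values / probabilities.
#' @param n number of draws.
#' @param mu,sigma,nu,tau distribution parameters (recycled).
#' @param log return log-density.
#' @name bcpe
#' @export
dbcpe <- function(x, mu = 1, sigma = 0.1, nu = 1, tau = 2, log = FALSE) {
  z <- bcpe_z(x, mu, sigma, nu)
  logc <- bcpe_log_c(tau)
  ll <- (nu - 1) * base::log(x) - nu * base::log(mu) - base::log(sigma) +
    base::log(tau) - logc - (1 + 1 / tau) * base::log(2) - lgamma(1 / tau) -
    0.5 * (abs(z) / exp(logc))^tau
  ll[x <= 0] <- -Inf
  if (log) ll else exp(ll)
}

#' @rdname bcpe
#' @export
pbcpe <- function(q, mu = 1, sigma = 0.1, nu = 1, tau = 2) {
  z <- bcpe_z(pmax(q, .Machine$double.xmin), mu, sigma, nu)
  cc <- exp(bcpe_log_c(tau))
  p <- 0.5 * (1 + sign(z) * pgamma(0.5 * (abs(z) / cc)^tau, 1 / tau))
  p[q <= 0] <- 0
  p
}

#' @rdname bcpe
#' @export
qbcpe <- function(p, mu = 1, sigma = 0.1, nu = 1, tau = 2) {
  a <- bcpe_recycle(p, mu, sigma, nu, tau)
  p <- a[[1]]; mu <- a[[2]]; sigma <- a[[3]]; nu <- a[[4]]; tau <- a[[5]]
  u <- 2 * p - 1
  g <- qgamma(abs(u), 1 / tau)
  cc <- exp(bcpe_log_c(tau))
  z <- sign(u) * cc * (2 * g)^(1 / tau)
  out <- numeric(length(z))
  small <- abs(nu) <= 1e-10
  out[small] <- mu[small] * exp(sigma[small] * z[small])
  ns <- !small
  out[ns] <- mu[ns] *
    pmax(1 + sigma[ns] * nu[ns] * z[ns], 1e-12)^(1 / nu[ns])
  out
}

#' @rdname bcpe
#' @export
rbcpe <- function(n, mu = 1, sigma = 0.1, nu = 1, tau = 2) {
  qbcpe(runif(n), mu, sigma, nu, tau)
}

family_bcpe <- function() {
  list(
    name = "bcpe",
    npar = 4L,
    par_names = c("mu", "sigma", "nu", "tau"),
    links = c(mu = "log", sigma = "log", nu = "identity", tau = "log"),
    linkinv = function(eta) list(mu = exp(eta[, 1]), sigma = exp(eta[, 2]),
                                 nu = eta[, 3], tau = exp(eta[, 4])),
    loglik = function(y, par)
      dbcpe(y, par$mu, par$sigma, par$nu, par$tau, log = TRUE),
    cdf = function(y, par) pbcpe(y, par$mu, par$sigma, par$nu, par$tau),
    quantile = function(p, par) qbcpe(p, par$mu, par$sigma, par$nu, par$tau),
    rand = function(n, par) rbcpe(n, par$mu, par$sigma, par$nu, par$tau))
}
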