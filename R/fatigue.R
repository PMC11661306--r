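#' Hill fatigue parameters
#'
#' The three-parameter Hill dose-response function used to model reporting
#' fatigue maps the repeat count r to a log-scale reduction
#' `rho(r) = -gamma * e^zeta r^eta / (1 + e^zeta r^eta)`, i.e. a logistic
#' function of `zeta + eta * log(r)` scaled by `-gamma`. `gamma` sets the
#' asymptotic effect size at large r, while `zeta` and `eta` jointly
#' control how quickly the asymptote is approached.
#'
#' @param gamma scale parameter (> 0)
#' @param zeta log half-saturation parameter (real)
#' @param eta shape parameter (> 0)
#' @return an object of class `cf_hill`
#' @export
hill_params <- function(gamma, zeta, eta) {
  if (!all(is.finite(c(gamma, zeta, eta)))) stop("Hill parameters must be finite")
  if (gamma <= 0 || eta <= 0) stop("gamma and eta must be strictly positive")
  structure(list(gamma = gamma, zeta = zeta, eta = eta), class = "cf_hill")
}

#' Hill reporting-fatigue effect
#'
#' Evaluates `rho(r) = -gamma * e^zeta r^eta / (1 + e^zeta r^eta)` on the
#' log-intensity scale. By construction `rho(0) = 0` (first-time
#' participation carries no fatigue), `rho` is non-increasing in r, and
#' `rho(r) -> -gamma` as r grows.
#'
#' @param r non-negative repeat counts
#' @param params a `cf_hill` (or list with `gamma`, `zeta`, `eta`)
#' @return numeric vector of log-scale effects
#' @export
hill_effect <- function(r, params) {
  if (!all(is.finite(c(params$gamma, params$zeta, params$eta))))
    stop("Hill parameters must be finite")
  stopifnot(all(r >= 0))
  out <- -params$gamma * stats::plogis(params$zeta + params$eta * log(r))
  out[r == 0] <- 0
  out
}

#' Percent change in contact intensity implied by a log-scale effect
#'
#' Converts a (typically non-positive) log-scale fatigue effect into a
#' percent change, `100 * (exp(rho) - 1)`; at the Hill asymptote this is
#' the maximum percent reduction `100 * (exp(-gamma) - 1)`.
#'
#' @param rho log-scale effect
#' @return percent change
#' @export
percent_reduction <- function(rho) 100 * (exp(rho) - 1)

#' Matern-3/2 covariance function
#'
#' `k(t, t') = sigma * (1 + sqrt(3) d / l) * exp(-sqrt(3) d / l)` with
#' `d = |t - t'|`. The amplitude `sigma` acts as the variance at zero
#' distance.
#'
#' @param t,t2 numeric vectors of inputs (recycled)
#' @param params list with `sigma` (> 0) and `lengthscale` (> 0)
#' @return covariance values
#' @export
matern32 <- function(t, t2, params) {
  stopifnot(params$sigma > 0, params$lengthscale > 0)
  d <- sqrt(3) * abs(t - t2) / params$lengthscale
  params$sigma * (1 + d) * exp(-d)
}

#' Matern-3/2 Gram matrix over a set of inputs
#'
#' @param x numeric vector of inputs
#' @param params list with `sigma` and `lengthscale`
#' @param jitter value added to the diagonal for numerical stability
#' @return a `length(x)` square covariance matrix
#' @export
matern32_cov <- function(x, params, jitter = 1e-9) {
  d <- sqrt(3) * abs(outer(x, x, "-")) / params$lengthscale
  params$sigma * (1 + d) * exp(-d) + diag(jitter, length(x))
}

# Squared-exponential covariance, sigma acting as variance at distance 0.
se_cov <- function(x, params, jitter = 1e-9) {
  d2 <- outer(x, x, "-")^2
  params$sigma * exp(-d2 / (2 * params$lengthscale^2)) + diag(jitter, length(x))
}

#' Standardize repeat counts
#'
#' Rescales repeat counts to zero mean and unit standard deviation before
#' they enter the repeat-count Gaussian process. Uses the sample (n - 1)
#' standard deviation by default.
#'
#' @param r_values integer repeat counts (at least two distinct values)
#' @param population_sd use the population (n) convention instead
#' @return standardized values
#' @export
standardize_repeats <- function(r_values, population_sd = FALSE) {
  if (length(unique(r_values)) < 2)
    stop("cannot standardize a constant set of repeat counts")
  s <- stats::sd(r_values)
  if (population_sd) s <- s * sqrt((length(r_values) - 1) / length(r_values))
  (r_values - mean(r_values)) / s
}
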