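#' Hilbert-space approximate Gaussian process (HSGP) configuration
#'
#' The HSGP represents a stationary GP on a compact interval by `m`
#' Laplacian eigenfunctions scaled by the square root of the kernel's
#' spectral density. It is used for the smooth age effect in the
#' de-biasing model and for the calendar-time trend in the longitudinal
#' model.
#'
#' @param m number of basis functions (>= 10)
#' @param boundary_factor domain half-width as a multiple of the largest
#'   absolute standardized input (> 1)
#' @param kernel `"se"` (squared exponential) or `"matern32"`
#' @return an object of class `cf_hsgp_config`
#' @export
hsgp_config <- function(m = 30L, boundary_factor = 1.5, kernel = "se") {
  stopifnot(m >= 10, boundary_factor > 1)
  kernel <- match.arg(kernel, c("se", "matern32"))
  structure(list(m = m, boundary_factor = boundary_factor, kernel = kernel),
            class = "cf_hsgp_config")
}

#' HSGP eigenfunction basis
#'
#' Builds the sine eigenfunction matrix `phi_j(x) = L^{-1/2} sin(omega_j
#' (x + L))` with `omega_j = pi j / (2 L)` on the domain `[-L, L]`, where
#' `x` are the centred/scaled inputs and `L = boundary_factor * max(|x|)`.
#'
#' @param x numeric inputs (already centred and scaled)
#' @param m number of basis functions
#' @param L domain half-width (must cover the inputs)
#' @return list with `PHI` (length(x) x m), `omega` (frequencies), `L`
#' @export
hsgp_basis <- function(x, m, L) {
  stopifnot(L >= max(abs(x)))
  j <- seq_len(m)
  omega <- pi * j / (2 * L)
  PHI <- sqrt(1 / L) * sin(outer(x + L, omega))
  list(PHI = PHI, omega = omega, L = L)
}

#' Spectral densities of the supported kernels
#'
#' One-dimensional spectral densities evaluated at frequencies `omega`,
#' under the convention that `sigma` is the kernel value at distance zero.
#'
#' @param omega frequencies
#' @param sigma kernel amplitude (variance at distance 0)
#' @param lengthscale kernel lengthscale
#' @return spectral density values
#' @export
spd_se <- function(omega, sigma, lengthscale) {
  sigma * lengthscale * sqrt(2 * pi) * exp(-0.5 * (lengthscale * omega)^2)
}

#' @rdname spd_se
#' @export
spd_matern32 <- function(omega, sigma, lengthscale) {
  sigma * 4 * 3^1.5 / lengthscale^3 / (3 / lengthscale^2 + omega^2)^2
}

hsgp_spd <- function(kernel) {
  switch(kernel, se = spd_se, matern32 = spd_matern32,
         stop("unknown kernel: ", kernel))
}

# Standardize inputs and build the basis over their range; returns the
# pieces needed to evaluate f(x) = PHI %*% (sqrt(spd(omega)) * z) inside a
# log-posterior, plus an `expand` closure for new inputs on the raw scale.
hsgp_setup <- function(x_raw, config) {
  mu <- mean(x_raw)
  sdv <- stats::sd(x_raw)
  if (!is.finite(sdv) || sdv == 0) sdv <- 1
  x <- (x_raw - mu) / sdv
  L <- config$boundary_factor * max(abs(x), 1e-9)
  b <- hsgp_basis(x, config$m, L)
  spd <- hsgp_spd(config$kernel)
  list(
    PHI = b$PHI, omega = b$omega, L = L, mu = mu, sd = sdv,
    spd = spd, m = config$m,
    expand = function(x_new) {
      xs <- (x_new - mu) / sdv
      xs <- pmin(pmax(xs, -L), L)
      sqrt(1 / L) * sin(outer(xs + L, b$omega))
    }
  )
}

#' Exact GP regression posterior mean (reference implementation)
#'
#' Conjugate Gaussian-noise GP regression with fixed hyperparameters,
#' computed from the exact covariance matrix. Serves as the reference
#' against which the HSGP basis approximation is validated.
#'
#' @param x,y training inputs and responses
#' @param x_new prediction inputs
#' @param params list with `sigma` and `lengthscale`
#' @param noise_var Gaussian noise variance
#' @param kernel `"se"` or `"matern32"`
#' @return posterior mean at `x_new`
#' @export
gp_posterior_mean_exact <- function(x, y, x_new, params, noise_var = 1,
                                    kernel = "se") {
  covfun <- switch(kernel, se = se_cov, matern32 = matern32_cov)
  K <- covfun(x, params)
  a <- solve(K + diag(noise_var, length(x)), y - mean(y))
  d <- outer(x_new, x, "-")
  Ks <- if (kernel == "se") {
    params$sigma * exp(-d^2 / (2 * params$lengthscale^2))
  } else {
    dd <- sqrt(3) * abs(d) / params$lengthscale
    params$sigma * (1 + dd) * exp(-dd)
  }
  mean(y) + as.vector(Ks %*% a)
}

#' HSGP regression posterior mean (basis approximation)
#'
#' The basis-approximation counterpart of [gp_posterior_mean_exact()]:
#' Bayesian linear regression on the scaled eigenfunctions.
#'
#' @inheritParams gp_posterior_mean_exact
#' @param config a `cf_hsgp_config`
#' @return posterior mean at `x_new`
#' @export
gp_posterior_mean_hsgp <- function(x, y, x_new, params, noise_var = 1,
                                   config = hsgp_config()) {
  setup <- hsgp_setup(x, config)
  s <- sqrt(setup$spd(setup$omega, params$sigma,
                      params$lengthscale / setup$sd))
  B <- sweep(setup$PHI, 2, s, "*")
  A <- crossprod(B) / noise_var + diag(setup$m)
  w <- solve(A, crossprod(B, y - mean(y)) / noise_var)
  Bn <- sweep(setup$expand(x_new), 2, s, "*")
  mean(y) + as.vector(Bn %*% w)
}
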