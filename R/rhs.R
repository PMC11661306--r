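#' Regularized horseshoe (RHS) prior configuration
#'
#' Hyperparameters of the regularized horseshoe prior used for variable
#' selection: local scales with half-t(nu1) priors, a slab whose squared
#' scale has an inverse-gamma(nu2/2, nu2 s2/2) prior, and a global scale
#' with a half-t(nu3) prior scaled by `rhs_epsilon0()`. `p0` encodes the
#' prior guess of the number of non-zero coefficients and defaults to half
#' the number of tested coefficients at fit time.
#'
#' @param nu1,nu2,nu3 degrees of freedom (defaults 3, 2, 4)
#' @param s2 slab scale squared (default 2)
#' @param p0 prior guess of non-zero coefficients (default `K/2`)
#' @return an object of class `cf_rhs_config`
#' @export
rhs_config <- function(nu1 = 3, nu2 = 2, nu3 = 4, s2 = 2, p0 = NULL) {
  stopifnot(nu1 > 0, nu2 > 0, nu3 > 0, s2 > 0)
  structure(list(nu1 = nu1, nu2 = nu2, nu3 = nu3, s2 = s2, p0 = p0),
            class = "cf_rhs_config")
}

#' Global scale of the regularized horseshoe prior
#'
#' `epsilon0 = p0 / (P - p0) * n^(-1/2)`, the reference scaling of the
#' global shrinkage parameter for a count regression with `P` tested
#' coefficients, `p0` of which are expected to be non-zero, and `n`
#' observations.
#'
#' @param p0 prior guess of non-zero coefficients (0 < p0 < P)
#' @param P number of tested coefficients
#' @param n sample size
#' @return the global scale
#' @export
rhs_epsilon0 <- function(p0, P, n) {
  if (!(p0 > 0 && p0 < P)) stop("p0 must satisfy 0 < p0 < P")
  if (any(n <= 0)) stop("n must be positive")
  p0 / (P - p0) / sqrt(n)
}

#' Scale of the sign-constrained (negative half-normal) RHS component
#'
#' The fatigue coefficients are constrained to the negative reals by
#' replacing the normal RHS kernel with a negative half-normal whose scale
#' carries the variance-matching factor `(1 - 2/pi)^(-1/2)`, so that the
#' prior variance of the constrained coefficient equals `eps^2 *
#' zeta_tilde^2`, the variance of the unconstrained version.
#'
#' @param eps global scale (> 0)
#' @param zeta_tilde regularized local scale (> 0)
#' @return the half-normal scale (standard deviation parameter)
#' @export
half_rhs_scale <- function(eps, zeta_tilde) {
  stopifnot(all(eps > 0), all(zeta_tilde > 0))
  eps * zeta_tilde / sqrt(1 - 2 / pi)
}

# Regularized local scale: zeta_tilde^2 = c2 zeta^2 / (c2 + eps^2 zeta^2).
rhs_zeta_tilde2 <- function(zeta, eps, c2) {
  c2 * zeta^2 / (c2 + eps^2 * zeta^2)
}

# Gauss-Legendre nodes/weights on (0, 1) via the Golub-Welsch eigenvalue
# construction.
gauss_legendre01 <- function(n) {
  j <- seq_len(n - 1)
  b <- j / sqrt(4 * j^2 - 1)
  J <- diag(0, n)
  J[cbind(j, j + 1)] <- b
  J[cbind(j + 1, j)] <- b
  e <- eigen(J, symmetric = TRUE)
  list(x = (e$values + 1) / 2, w = e$vectors[1, ]^2)
}

# Log marginal RHS prior density of a coefficient vector given the global
# scale and slab, with the half-t local scales integrated out numerically
# (substitution zeta = s / (1 - s), Gauss-Legendre on (0, 1)). Sampling
# this marginal instead of the local scales removes the horseshoe funnel;
# the prior over the coefficients is unchanged. `half = TRUE` gives the
# negative half-normal kernel with the variance-matching adjustment
# (coefficients must already satisfy the sign constraint).
rhs_marginal_lp <- function(beta, eps, c2, nu1, gl, half = FALSE) {
  z <- gl$x / (1 - gl$x)
  zt2 <- rhs_zeta_tilde2(z, eps, c2)
  sdv <- pmax(eps * sqrt(zt2), SD_FLOOR)
  if (half) sdv <- sdv / sqrt(1 - 2 / pi)
  dens <- 2 * stats::dt(z, nu1) * gl$w / (1 - gl$x)^2
  m <- as.vector(outer(beta, sdv, function(b, s) stats::dnorm(b, 0, s)) %*% dens)
  if (half) m <- 2 * m
  sum(log(m))
}

# Hyperprior terms of an RHS block on the unconstrained scale
# (le = log eps, lc = log c2), with Jacobians.
rhs_hyper_lp <- function(le, lc, cfg, eps0) {
  ld_half_t(exp(le), cfg$nu3, eps0) + le +
    ld_inv_gamma(exp(lc), cfg$nu2 / 2, cfg$nu2 * cfg$s2 / 2) + lc
}

#' Fit the contact-intensity variable-selection model
#'
#' Poisson regression for first-time participants' contact counts:
#' `log lambda = beta0 + u' alpha + v' beta`, with a diffuse normal prior
#' on the baseline `beta0`, hierarchical normal priors (half-Cauchy scale)
#' on the always-in coefficients `alpha`, and the regularized horseshoe
#' prior on the tested coefficients `beta` so that weak associations are
#' shrunk toward zero. The RHS local scales are integrated out of the
#' sampled posterior by quadrature; the global scale and slab are sampled.
#'
#' @param data a `cf_wave`; only records with repeat count 0 are used
#' @param config a `cf_rhs_config`
#' @param seed integer seed
#' @param chains,n_iter,n_warmup sampler settings
#' @return a `cf_fit` with natural-scale parameters named `beta0`, the
#'   always-in design column names (alpha), the tested design column names
#'   (beta), `sigma_alpha`, `eps`, `c2`
#' @export
fit_intensity_selection_model <- function(data, config = rhs_config(),
                                          seed = 1L, chains = 2,
                                          n_iter = 2500, n_warmup = 2500) {
  keep <- data$records$repeat_count == 0
  if (!any(keep)) stop("no first-time participants in data")
  y <- data$records$contact_count[keep]
  U <- data$U[keep, estimable_columns(data$schema, "always_in"), drop = FALSE]
  V <- data$V[keep, estimable_columns(data$schema, "tested"), drop = FALSE]
  J <- ncol(U); K <- ncol(V); n <- length(y)
  p0 <- config$p0 %||% (K / 2)
  eps0 <- rhs_epsilon0(p0, K, n)
  X <- cbind(1, U, V)
  gl <- gauss_legendre01(48)

  i_b0 <- 1L
  i_alpha <- 1L + seq_len(J)
  i_beta <- 1L + J + seq_len(K)
  i_lsa <- 2L + J + K
  i_le <- i_lsa + 1L
  i_lc <- i_lsa + 2L
  n_par <- i_lc

  lp_lik <- function(th) {
    eta <- as.vector(X %*% th[1:(1 + J + K)])
    if (any(eta > 30)) return(-Inf)
    sum(stats::dpois(y, exp(eta), log = TRUE))
  }
  lp_prior <- function(th) {
    sa <- pmax(exp(th[i_lsa]), SD_FLOOR)
    stats::dnorm(th[i_b0], 0, 100, log = TRUE) +
      sum(stats::dnorm(th[i_alpha], 0, sa, log = TRUE)) +
      ld_half_cauchy(exp(th[i_lsa])) + th[i_lsa] +
      rhs_marginal_lp(th[i_beta], exp(th[i_le]), exp(th[i_lc]),
                      config$nu1, gl) +
      rhs_hyper_lp(th[i_le], th[i_lc], config, eps0)
  }
  cond_lsa <- function(th, j, x) {
    if (abs(x) > LOG_SCALE_BOUND) return(-Inf)
    sa <- pmax(exp(x), SD_FLOOR)
    sum(stats::dnorm(th[i_alpha], 0, sa, log = TRUE)) +
      ld_half_cauchy(exp(x)) + x
  }
  cond_le <- function(th, j, x) {
    if (abs(x) > LOG_SCALE_BOUND) return(-Inf)
    rhs_marginal_lp(th[i_beta], exp(x), exp(th[i_lc]), config$nu1, gl) +
      ld_half_t(exp(x), config$nu3, eps0) + x
  }
  cond_lc <- function(th, j, x) {
    if (abs(x) > LOG_SCALE_BOUND) return(-Inf)
    rhs_marginal_lp(th[i_beta], exp(th[i_le]), exp(x), config$nu1, gl) +
      ld_inv_gamma(exp(x), config$nu2 / 2, config$nu2 * config$s2 / 2) + x
  }

  prior1 <- function(th, j, x) {
    if (j == i_b0) return(stats::dnorm(x, 0, 100, log = TRUE))
    if (j %in% i_alpha) {
      sa <- pmax(exp(th[i_lsa]), SD_FLOOR)
      return(stats::dnorm(x, 0, sa, log = TRUE))
    }
    rhs_marginal_lp(x, exp(th[i_le]), exp(th[i_lc]), config$nu1, gl)
  }
  model <- list(
    n_par = n_par, lp_lik = lp_lik, lp_prior = lp_prior,
    lik_idx = 1:(1 + J + K),
    blocks = list(
      poisson_coord_block(X, y, 1:(1 + J + K), prior1, w = 0.3),
      list(type = "slice", idx = i_lsa, lp_cond = cond_lsa, w = 1),
      list(type = "slice", idx = i_le, lp_cond = cond_le, w = 1.5,
           repeats = 2L),
      list(type = "slice", idx = i_lc, lp_cond = cond_lc, w = 1)
    ),
    init = function(ch) {
      th <- numeric(n_par)
      cf <- glm_init(X, y)
      th[1:(1 + J + K)] <- cf + stats::rnorm(1 + J + K, 0, 0.02)
      # start tested coefficients shrunk: true signals are released
      # quickly, while a spurious maximum-likelihood start would bias
      # early draws away from the prior's sparse solutions
      th[i_beta] <- th[i_beta] * 0.3
      th[i_lsa] <- log(0.3) + stats::rnorm(1, 0, 0.2)
      th[i_le] <- log(eps0) + stats::rnorm(1, 0, 0.2)
      th[i_lc] <- log(config$s2) + stats::rnorm(1, 0, 0.2)
      th
    },
    report = function(draws) {
      nat <- cbind(
        draws[, 1:(1 + J + K), drop = FALSE],
        exp(draws[, c(i_lsa, i_le, i_lc), drop = FALSE])
      )
      colnames(nat) <- c("beta0", colnames(U), colnames(V),
                         "sigma_alpha", "eps", "c2")
      nat
    }
  )
  raw <- run_mcmc(model, n_iter = n_iter, n_warmup = n_warmup,
                  chains = chains, seed = seed)
  finish_fit(model, raw, meta = list(
    model = "intensity_selection", features = colnames(V),
    always_in = colnames(U), n = n, config = config, eps0 = eps0
  ))
}

#' Refit the intensity model with standard-normal priors on selected
#' features
#'
#' After selection, the intensity model is refitted with independent
#' standard-normal priors on the selected tested features (in place of the
#' RHS prior); its posterior medians provide the plug-in values that the
#' fatigue selection model conditions on.
#'
#' @param data a `cf_wave`; only first-time participants are used
#' @param selected character vector of selected tested design columns
#' @inheritParams fit_intensity_selection_model
#' @return a `cf_fit`
#' @export
refit_intensity_normal <- function(data, selected, seed = 1L, chains = 2,
                                   n_iter = 1500, n_warmup = 1500) {
  keep <- data$records$repeat_count == 0
  if (!any(keep)) stop("no first-time participants in data")
  y <- data$records$contact_count[keep]
  U <- data$U[keep, estimable_columns(data$schema, "always_in"), drop = FALSE]
  V <- data$V[keep, selected, drop = FALSE]
  J <- ncol(U); K <- ncol(V)
  X <- cbind(1, U, V)
  i_lsa <- 2L + J + K
  lp_lik <- function(th) {
    eta <- as.vector(X %*% th[1:(1 + J + K)])
    if (any(eta > 30)) return(-Inf)
    sum(stats::dpois(y, exp(eta), log = TRUE))
  }
  lp_prior <- function(th) {
    sa <- pmax(exp(th[i_lsa]), SD_FLOOR)
    stats::dnorm(th[1], 0, 100, log = TRUE) +
      sum(stats::dnorm(th[1 + seq_len(J)], 0, sa, log = TRUE)) +
      ld_half_cauchy(exp(th[i_lsa])) + th[i_lsa] +
      (if (K > 0) sum(stats::dnorm(th[1 + J + seq_len(K)], 0, 1, log = TRUE)) else 0)
  }
  cond_lsa <- function(th, j, x) {
    if (abs(x) > LOG_SCALE_BOUND) return(-Inf)
    sa <- pmax(exp(x), SD_FLOOR)
    sum(stats::dnorm(th[1 + seq_len(J)], 0, sa, log = TRUE)) +
      ld_half_cauchy(exp(x)) + x
  }
  prior1 <- function(th, j, x) {
    if (j == 1) return(stats::dnorm(x, 0, 100, log = TRUE))
    if (j <= 1 + J) {
      sa <- pmax(exp(th[i_lsa]), SD_FLOOR)
      return(stats::dnorm(x, 0, sa, log = TRUE))
    }
    stats::dnorm(x, 0, 1, log = TRUE)
  }
  model <- list(
    n_par = i_lsa, lp_lik = lp_lik, lp_prior = lp_prior,
    lik_idx = 1:(1 + J + K),
    blocks = list(
      poisson_coord_block(X, y, 1:(1 + J + K), prior1, w = 0.3),
      list(type = "slice", idx = i_lsa, lp_cond = cond_lsa, w = 1)
    ),
    init = function(ch) {
      th <- numeric(i_lsa)
      th[1:(1 + J + K)] <- glm_init(X, y) +
        stats::rnorm(1 + J + K, 0, 0.02)
      th[i_lsa] <- log(0.3) + stats::rnorm(1, 0, 0.2)
      th
    },
    report = function(draws) {
      nat <- cbind(draws[, 1:(1 + J + K), drop = FALSE],
                   exp(draws[, i_lsa, drop = FALSE]))
      colnames(nat) <- c("beta0", colnames(U), selected, "sigma_alpha")
      nat
    }
  )
  raw <- run_mcmc(model, n_iter = n_iter, n_warmup = n_warmup,
                  chains = chains, seed = seed)
  finish_fit(model, raw, meta = list(
    model = "intensity_refit", features = selected,
    always_in = colnames(U), n = length(y)
  ))
}

#' Extract plug-in posterior medians from an intensity refit
#'
#' @param fit a `cf_fit` from [refit_intensity_normal()]
#' @return list with `beta0`, named `alpha`, named `beta`
#' @export
plugin_from_fit <- function(fit) {
  s <- fit$summary
  med <- stats::setNames(s$median, s$parameter)
  list(
    beta0 = med[["beta0"]],
    alpha = med[fit$always_in],
    beta = if (length(fit$features)) med[fit$features] else
      stats::setNames(numeric(0), character(0))
  )
}

#' Fit the reporting-fatigue variable-selection model
#'
#' Poisson regression for repeating participants that conditions on the
#' plug-in posterior medians of the first-time intensity model and adds a
#' fatigue term `w' gamma` over the 33 fatigue-candidate features. Each
#' `gamma` is constrained to the negative reals through the
#' sign-constrained RHS prior (negative half-normal kernel with the
#' `(1 - 2/pi)^(-1)` variance-matching adjustment); as in the intensity
#' model, the local scales are integrated out by quadrature.
#'
#' @param data a `cf_wave` containing repeating participants
#' @param plugin plug-in values from [plugin_from_fit()]
#' @param config a `cf_rhs_config`
#' @inheritParams fit_intensity_selection_model
#' @return a `cf_fit` with parameters named by the fatigue design columns
#'   (gamma), plus `eps` and `c2`
#' @export
fit_fatigue_selection_model <- function(data, plugin, config = rhs_config(),
                                        seed = 1L, chains = 2,
                                        n_iter = 2500, n_warmup = 2500) {
  keep <- data$records$repeat_count > 0
  if (!any(keep)) stop("no repeating participants in data")
  y <- data$records$contact_count[keep]
  U <- data$U[keep, estimable_columns(data$schema, "always_in"), drop = FALSE]
  W <- data$W[keep, , drop = FALSE]
  offset <- plugin$beta0 + as.vector(U %*% plugin$alpha)
  if (length(plugin$beta)) {
    V <- data$V[keep, names(plugin$beta), drop = FALSE]
    offset <- offset + as.vector(V %*% plugin$beta)
  }
  L <- ncol(W); n <- length(y)
  p0 <- config$p0 %||% (L / 2)
  eps0 <- rhs_epsilon0(p0, L, n)
  gl <- gauss_legendre01(48)

  i_g <- seq_len(L)
  i_le <- L + 1L
  i_lc <- L + 2L
  n_par <- i_lc

  lp_lik <- function(th) {
    eta <- offset + as.vector(W %*% th[i_g])
    if (any(eta > 30)) return(-Inf)
    sum(stats::dpois(y, exp(eta), log = TRUE))
  }
  lp_prior <- function(th) {
    g <- th[i_g]
    if (any(g > 0)) return(-Inf)
    rhs_marginal_lp(g, exp(th[i_le]), exp(th[i_lc]), config$nu1, gl,
                    half = TRUE) +
      rhs_hyper_lp(th[i_le], th[i_lc], config, eps0)
  }
  cond_le <- function(th, j, x) {
    if (abs(x) > LOG_SCALE_BOUND) return(-Inf)
    rhs_marginal_lp(th[i_g], exp(x), exp(th[i_lc]), config$nu1, gl,
                    half = TRUE) +
      ld_half_t(exp(x), config$nu3, eps0) + x
  }
  cond_lc <- function(th, j, x) {
    if (abs(x) > LOG_SCALE_BOUND) return(-Inf)
    rhs_marginal_lp(th[i_g], exp(th[i_le]), exp(x), config$nu1, gl,
                    half = TRUE) +
      ld_inv_gamma(exp(x), config$nu2 / 2, config$nu2 * config$s2 / 2) + x
  }
  prior1 <- function(th, j, x) {
    if (x > 0) return(-Inf)
    rhs_marginal_lp(x, exp(th[i_le]), exp(th[i_lc]), config$nu1, gl,
                    half = TRUE)
  }
  model <- list(
    n_par = n_par, lp_lik = lp_lik, lp_prior = lp_prior, lik_idx = i_g,
    blocks = list(
      poisson_coord_block(W, y, i_g, prior1, w = 0.3, offset = offset),
      list(type = "slice", idx = i_le, lp_cond = cond_le, w = 1.5,
           repeats = 2L),
      list(type = "slice", idx = i_lc, lp_cond = cond_lc, w = 1)
    ),
    init = function(ch) {
      th <- numeric(n_par)
      th[i_g] <- -0.01 - abs(stats::rnorm(L, 0, 0.02))
      th[i_le] <- log(eps0) + stats::rnorm(1, 0, 0.2)
      th[i_lc] <- log(config$s2) + stats::rnorm(1, 0, 0.2)
      th
    },
    report = function(draws) {
      nat <- cbind(draws[, i_g, drop = FALSE],
                   exp(draws[, c(i_le, i_lc), drop = FALSE]))
      colnames(nat) <- c(colnames(W), "eps", "c2")
      nat
    }
  )
  raw <- run_mcmc(model, n_iter = n_iter, n_warmup = n_warmup,
                  chains = chains, seed = seed)
  finish_fit(model, raw, meta = list(
    model = "fatigue_selection", features = colnames(W), n = n,
    config = config, eps0 = eps0
  ))
}

#' Select contact-intensity features from a fitted selection model
#'
#' A tested feature is selected when its posterior median effect lies
#' strictly outside `(lower, upper)`; the defaults `log(0.95)` and
#' `log(1.05)` correspond to a +/-5% change from the baseline intensity.
#'
#' @param fit a `cf_fit` from [fit_intensity_selection_model()] (or a
#'   posterior summary data.frame together with `features`)
#' @param lower,upper selection thresholds on the log scale
#' @param features tested feature names (defaults to those stored in the
#'   fit)
#' @return an object of class `cf_selection`: list with `selected`,
#'   `table` (feature, median, percent change), `thresholds`, `universe`
#' @export
select_features <- function(fit, lower = log(0.95), upper = log(1.05),
                            features = NULL) {
  s <- if (inherits(fit, "cf_fit")) fit$summary else fit
  features <- features %||% fit$features
  med <- stats::setNames(s$median, s$parameter)[features]
  sel <- features[med < lower | med > upper]
  structure(
    list(
      selected = sel,
      table = data.frame(
        feature = features, median = unname(med),
        pct_change = percent_reduction(unname(med)),
        selected = features %in% sel,
        stringsAsFactors = FALSE
      ),
      thresholds = c(lower = lower, upper = upper),
      universe = features
    ),
    class = "cf_selection"
  )
}

#' Select reporting-fatigue features
#'
#' A fatigue feature is selected when its posterior median reduction of
#' contact intensity exceeds 5%, i.e. when the median of gamma is below
#' `log(0.95)`.
#'
#' @param fit a `cf_fit` from [fit_fatigue_selection_model()]
#' @param threshold selection threshold on the log scale
#' @return a `cf_selection`
#' @export
select_fatigue_features <- function(fit, threshold = log(0.95)) {
  s <- if (inherits(fit, "cf_fit")) fit$summary else fit
  features <- fit$features
  med <- stats::setNames(s$median, s$parameter)[features]
  sel <- features[med < threshold]
  structure(
    list(
      selected = sel,
      table = data.frame(
        feature = features, median = unname(med),
        pct_change = percent_reduction(unname(med)),
        selected = features %in% sel,
        stringsAsFactors = FALSE
      ),
      thresholds = c(lower = threshold, upper = Inf),
      universe = features
    ),
    class = "cf_selection"
  )
}

#' Union of per-wave selection results
#'
#' The final feature set is the union of the features selected in each
#' analysed wave. Per-wave provenance is retained, and the reported
#' per-feature median is the strongest (largest absolute) across waves.
#'
#' @param results list of `cf_selection` sharing a feature universe
#' @return a `cf_selection`
#' @export
union_across_waves <- function(results) {
  stopifnot(length(results) >= 1)
  uni <- results[[1]]$universe
  for (r in results) {
    if (!setequal(r$universe, uni))
      stop("selection results do not share a feature universe")
  }
  sel <- sort(unique(unlist(lapply(results, `[[`, "selected"))))
  meds <- sapply(results, function(r) {
    stats::setNames(r$table$median, r$table$feature)[uni]
  })
  meds <- matrix(meds, nrow = length(uni))
  strongest <- vapply(seq_along(uni), function(i) {
    row <- meds[i, ]
    row[which.max(abs(row))]
  }, numeric(1))
  structure(
    list(
      selected = sel,
      table = data.frame(
        feature = uni, median = strongest,
        pct_change = percent_reduction(strongest),
        selected = uni %in% sel, stringsAsFactors = FALSE
      ),
      thresholds = results[[1]]$thresholds,
      universe = uni,
      provenance = lapply(results, `[[`, "selected")
    ),
    class = "cf_selection"
  )
}

#' @export
print.cf_selection <- function(x, ...) {
  cat("<cf_selection> ", length(x$selected), " of ", length(x$universe),
      " features selected\n", sep = "")
  if (length(x$selected)) cat(paste(" -", x$selected, collapse = "\n"), "\n")
  invisible(x)
}
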