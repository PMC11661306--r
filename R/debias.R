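#' Hill prior configurations for the de-biasing model
#'
#' `default_hill_priors()` gives the weakly informative priors
#' gamma ~ half-Normal(0, 1), zeta ~ Normal(0, 1), eta ~ Exponential(1).
#' `informative_hill_priors()` centres the priors at posterior medians
#' from a fitted longitudinal Hill model, with the default scales 0.5
#' (gamma), 0.1 (zeta) and 0.1 (eta); the same constructor with scales
#' `c(0.3, 0.1, 0.1)` and posterior-mean centres implements the
#' wave-to-wave prior propagation of [sequential_fit()].
#'
#' @param gamma_hat,zeta_hat,eta_hat centres (posterior medians or means
#'   of a previous fit); `gamma_hat` and `eta_hat` must be positive
#' @param scales numeric length-3 vector of prior scales for (gamma,
#'   zeta, eta)
#' @return an object of class `cf_hill_priors`
#' @export
informative_hill_priors <- function(gamma_hat, zeta_hat, eta_hat,
                                    scales = c(0.5, 0.1, 0.1)) {
  if (!(gamma_hat > 0)) stop("gamma_hat must be positive")
  if (!(eta_hat > 0)) stop("eta_hat must be positive")
  structure(
    list(type = "informative",
         gamma = c(location = gamma_hat, scale = scales[1]),
         zeta = c(location = zeta_hat, scale = scales[2]),
         eta = c(location = eta_hat, scale = scales[3])),
    class = "cf_hill_priors"
  )
}

#' @rdname informative_hill_priors
#' @export
default_hill_priors <- function() {
  structure(
    list(type = "default",
         gamma = c(location = 0, scale = 1),
         zeta = c(location = 0, scale = 1),
         eta = c(location = NA, scale = 1)),
    class = "cf_hill_priors"
  )
}

hill_prior_lp <- function(g, z, e, pr, lg, le) {
  # g, z, e natural; lg, le the unconstrained log-params (Jacobians)
  if (pr$type == "default") {
    stats::dnorm(g, 0, 1, log = TRUE) + log(2) + lg +
      stats::dnorm(z, 0, 1, log = TRUE) +
      stats::dexp(e, 1, log = TRUE) + le
  } else {
    ld_half_normal_pos(g, pr$gamma["location"], pr$gamma["scale"]) + lg +
      stats::dnorm(z, pr$zeta["location"], pr$zeta["scale"], log = TRUE) +
      ld_half_normal_pos(e, pr$eta["location"], pr$eta["scale"]) + le
  }
}

#' Fit the de-biasing negative-binomial additive model
#'
#' `Y ~ NegBinomial(lambda, phi)` with `log lambda = beta0 + u' beta +
#' f(age) + w' rho(r)`, where `f` is a smooth age effect represented by a
#' zero-mean Hilbert-space approximate Gaussian process with squared
#' exponential kernel, `u` collects sex and household size (plus any
#' requested tested features) and each selected fatigue feature carries
#' its own Hill function `rho_q(r)`. With `adjust = FALSE` the fatigue
#' term is omitted, giving the unadjusted comparator.
#'
#' Priors: `beta0 ~ Normal(0, 10)`, `beta_p ~ Normal(0, 1)` (or the
#' propagated priors supplied via `beta_prior`), `1/phi ~ Exponential(1)`,
#' inverse-gamma(5, 1) hyperpriors on the age-kernel amplitude and
#' lengthscale, and the Hill priors supplied via `hill_priors`.
#'
#' @param data a `cf_wave` with imputed ages
#' @param fatigue_features fatigue design columns receiving Hill
#'   adjustments (typically the final selection)
#' @param hsgp a `cf_hsgp_config` for the age effect
#' @param hill_priors a `cf_hill_priors`
#' @param adjust include the fatigue adjustment term?
#' @param features extra tested design columns to include in `u`
#' @param beta_prior optional list `list(location = named vector, scale =
#'   scalar)` overriding the Normal(0, 1) priors on `beta`
#' @param seed,chains,n_iter,n_warmup sampler settings
#' @return a `cf_fit` carrying the design pieces needed to reconstruct
#'   age curves and per-record intensities
#' @export
fit_debias_model <- function(data, fatigue_features = character(0),
                             hsgp = hsgp_config(30L, 1.5, "se"),
                             hill_priors = default_hill_priors(),
                             adjust = TRUE, features = NULL,
                             beta_prior = NULL, seed = 1L, chains = 2,
                             n_iter = 1500, n_warmup = 1500) {
  recs <- data$records
  if (anyNA(recs$age_years)) stop("ages must be imputed before fitting")
  y <- recs$contact_count
  r <- recs$repeat_count
  ages <- recs$age_years
  ucols <- grep("^(sex|hh_size)\\[",
                estimable_columns(data$schema, "always_in"), value = TRUE)
  X <- cbind(data$U[, ucols, drop = FALSE],
             if (length(features)) data$V[, features, drop = FALSE])
  P <- ncol(X)
  if (!adjust) fatigue_features <- character(0)
  Q <- length(fatigue_features)
  Wq <- data$W[, fatigue_features, drop = FALSE]
  n <- length(y)
  hs <- hsgp_setup(ages, hsgp)
  m <- hs$m
  # centre the age basis over the fitted records (zero-mean smooth)
  phi_center <- colMeans(hs$PHI)
  PHI_c <- sweep(hs$PHI, 2, phi_center)

  # hill_priors may be one cf_hill_priors applied i.i.d. to every feature,
  # or a named list with one cf_hill_priors per fatigue feature
  prior_of <- function(q) {
    if (inherits(hill_priors, "cf_hill_priors")) hill_priors
    else hill_priors[[fatigue_features[q]]]
  }
  bp_loc <- numeric(P)
  bp_scale <- rep(1, P)
  if (!is.null(beta_prior)) {
    loc <- beta_prior$location
    bp_loc <- unname(loc[colnames(X)])
    bp_loc[is.na(bp_loc)] <- 0
    bp_scale <- rep(beta_prior$scale %||% 1, P)
  }

  i_b0 <- 1L
  i_beta <- 1L + seq_len(P)
  i_zf <- 1L + P + seq_len(m)
  i_lsf <- 1L + P + m + 1L
  i_llf <- 1L + P + m + 2L
  i_hill <- if (Q > 0) i_llf + seq_len(3L * Q) else integer(0)
  i_lphi <- i_llf + 3L * Q + 1L
  n_par <- i_lphi

  f_at_records <- function(th) {
    s <- sqrt(hs$spd(hs$omega, exp(th[i_lsf]), exp(th[i_llf])))
    as.vector(PHI_c %*% (s * th[i_zf]))
  }
  fatigue_term <- function(th) {
    if (Q == 0) return(0)
    out <- 0
    for (q in seq_len(Q)) {
      tq <- th[i_hill[(3 * q - 2):(3 * q)]]
      rho <- -exp(tq[1]) * stats::plogis(tq[2] + exp(tq[3]) * log(pmax(r, 1)))
      rho[r == 0] <- 0
      out <- out + Wq[, q] * rho
    }
    out
  }
  nb_ll <- nb_loglik_fun(y)
  lp_lik <- function(th) {
    eta <- th[i_b0] + as.vector(X %*% th[i_beta]) + f_at_records(th) +
      fatigue_term(th)
    if (any(eta > 30)) return(-Inf)
    nb_ll(eta, 1 / exp(th[i_lphi]))
  }
  lp_prior <- function(th) {
    sf <- exp(th[i_lsf]); lf <- exp(th[i_llf]); invphi <- exp(th[i_lphi])
    out <- stats::dnorm(th[i_b0], 0, 10, log = TRUE) +
      sum(stats::dnorm(th[i_beta], bp_loc, bp_scale, log = TRUE)) +
      sum(stats::dnorm(th[i_zf], 0, 1, log = TRUE)) +
      ld_inv_gamma(sf, 5, 1) + th[i_lsf] +
      ld_inv_gamma(lf, 5, 1) + th[i_llf] +
      stats::dexp(invphi, 1, log = TRUE) + th[i_lphi]
    for (q in seq_len(Q)) {
      tq <- th[i_hill[(3 * q - 2):(3 * q)]]
      out <- out + hill_prior_lp(exp(tq[1]), tq[2], exp(tq[3]),
                                 prior_of(q), tq[1], tq[3])
    }
    out
  }
  init_hill <- function() {
    unlist(lapply(seq_len(Q), function(q) {
      pr <- prior_of(q)
      if (pr$type == "informative") {
        c(log(pr$gamma[["location"]]), pr$zeta[["location"]],
          log(pr$eta[["location"]]))
      } else c(log(0.5), 0, 0)
    }))
  }
  model <- list(
    n_par = n_par, lp_lik = lp_lik, lp_prior = lp_prior,
    lik_idx = seq_len(n_par),
    blocks = c(
      list(
        list(type = "rwm", idx = c(i_b0, i_beta)),
        # joint membership of beta0 handles the intercept / age-basis ridge
        list(type = "rwm", idx = c(i_b0, i_zf, i_lsf, i_llf), repeats = 2L)
      ),
      if (Q > 0) list(list(type = "rwm", idx = c(i_hill, i_lphi)))
      else list(list(type = "rwm", idx = i_lphi))
    ),
    init = function(ch) {
      th <- numeric(n_par)
      th[i_b0] <- log(mean(y) + 0.05) + stats::rnorm(1, 0, 0.05)
      th[i_beta] <- stats::rnorm(P, 0, 0.1)
      th[i_zf] <- stats::rnorm(m, 0, 0.1)
      th[i_lsf] <- log(0.25) + stats::rnorm(1, 0, 0.2)
      th[i_llf] <- log(0.5) + stats::rnorm(1, 0, 0.2)
      if (Q > 0) th[i_hill] <- init_hill()
      th[i_lphi] <- 0
      th
    },
    report = function(draws) {
      nat <- cbind(
        draws[, c(i_b0, i_beta), drop = FALSE],
        draws[, i_zf, drop = FALSE],
        exp(draws[, c(i_lsf, i_llf), drop = FALSE]),
        1 / exp(draws[, i_lphi, drop = FALSE]),
        if (Q > 0) {
          h <- draws[, i_hill, drop = FALSE]
          for (q in seq_len(Q)) {
            h[, 3 * q - 2] <- exp(h[, 3 * q - 2])
            h[, 3 * q] <- exp(h[, 3 * q])
          }
          h
        }
      )
      colnames(nat) <- c(
        "beta0", colnames(X), paste0("zf[", seq_len(m), "]"),
        "sigma_f", "ell_f", "phi",
        if (Q > 0) as.vector(vapply(fatigue_features, function(f) {
          paste0(c("gamma", "zeta", "eta"), "[", f, "]")
        }, character(3)))
      )
      nat
    }
  )
  raw <- run_mcmc(model, n_iter = n_iter, n_warmup = n_warmup,
                  chains = chains, seed = seed)
  finish_fit(model, raw, meta = list(
    model = "debias_gam", adjust = adjust, features = colnames(X),
    fatigue_features = fatigue_features, hsgp = hs, n = n,
    X = X, ages = ages, records = recs, hill_priors = hill_priors,
    m_age = m, phi_center = phi_center
  ))
}

# Per-draw smooth age effect evaluated at arbitrary ages: returns a
# length(ages) x n_draws matrix.
debias_f_draws <- function(fit, ages) {
  hs <- fit$hsgp
  PHI <- sweep(hs$expand(ages), 2, fit$phi_center)
  m <- fit$m_age
  z <- t(fit$draws[, paste0("zf[", seq_len(m), "]"), drop = FALSE])
  s <- vapply(seq_len(ncol(z)), function(d) {
    sqrt(hs$spd(hs$omega, fit$draws[d, "sigma_f"], fit$draws[d, "ell_f"]))
  }, numeric(m))
  PHI %*% (z * s)
}

#' Posterior age-intensity curve of a fitted de-biasing model
#'
#' Evaluates the fatigue-free contact intensity `exp(beta0 + u_bar' beta +
#' f(age))` over an age grid, where `u_bar` is the average covariate
#' profile of the fitted records, and summarises it by posterior median
#' and 95% credible interval.
#'
#' @param fit a `cf_fit` from [fit_debias_model()]
#' @param ages integer age grid (default 0:84)
#' @return data.frame with columns `age`, `median`, `lower`, `upper`; the
#'   draw-level matrix is attached as attribute `"draws"`
#' @export
age_curve <- function(fit, ages = 0:84) {
  fd <- debias_f_draws(fit, ages)
  ubar <- colMeans(fit$X)
  base <- fit$draws[, "beta0"] +
    as.vector(fit$draws[, fit$features, drop = FALSE] %*% ubar)
  lam <- exp(sweep(fd, 2, base, "+"))
  q <- t(apply(lam, 1, stats::quantile, probs = c(0.025, 0.5, 0.975),
               names = FALSE))
  out <- data.frame(age = ages, median = q[, 2], lower = q[, 1],
                    upper = q[, 3])
  attr(out, "draws") <- lam
  out
}

#' Mean absolute percentage error between two age curves
#'
#' `mean(100 * |estimate - baseline| / baseline)` over a shared age grid.
#'
#' @param baseline,estimate numeric vectors on identical grids; baseline
#'   strictly positive
#' @return MAPE in percent
#' @export
mape <- function(baseline, estimate) {
  if (length(baseline) != length(estimate))
    stop("curves must share the same age grid")
  if (any(baseline <= 0)) stop("baseline values must be strictly positive")
  mean(100 * abs(estimate - baseline) / baseline)
}

#' Proportion of a baseline curve covered by posterior intervals
#'
#' @param baseline numeric vector
#' @param intervals two-column matrix or data.frame of lower and upper
#'   bounds on the same grid
#' @return fraction of grid points whose baseline value lies inside the
#'   interval
#' @export
baseline_coverage <- function(baseline, intervals) {
  lo <- intervals[[1]]
  hi <- intervals[[2]]
  if (length(lo) != length(baseline))
    stop("intervals must match the baseline grid")
  mean(baseline >= lo & baseline <= hi)
}

#' Incremental-inclusion accuracy experiment
#'
#' Quantifies how well the Hill-adjusted model de-biases age-specific
#' contact intensity estimates as participants with increasingly many
#' repeats are added. A baseline model is fitted to first-time
#' participants only; then, for each repeat cap `c`, both the
#' fatigue-adjusted and the unadjusted model are fitted to records with
#' `r <= c`, and each arm's posterior median age curve is scored against
#' the baseline by MAPE and by the fraction of baseline points inside the
#' arm's 95% intervals. Cap 0 reuses the baseline fit for both arms.
#'
#' @param data a `cf_wave` containing first-time participants and
#'   repeaters
#' @param caps integer vector of repeat caps
#' @param fatigue_features fatigue design columns for the adjusted arm
#' @param hill_priors a `cf_hill_priors` (typically informative, centred
#'   at longitudinal-model medians)
#' @param ages age grid
#' @param ... further arguments passed to [fit_debias_model()]
#' @param seed integer seed
#' @return an object of class `cf_incremental`: list with `table`
#'   (cap, arm, mape, coverage) and `curves`
#' @export
incremental_inclusion_experiment <- function(data, caps,
                                             fatigue_features,
                                             hill_priors,
                                             ages = 0:84, seed = 1L, ...) {
  recs <- data$records
  if (!any(recs$repeat_count == 0))
    stop("experiment requires first-time participants for the baseline")
  subset_wave <- function(keep) {
    build_design(recs[keep, , drop = FALSE], data$schema)
  }
  baseline_fit <- fit_debias_model(
    subset_wave(recs$repeat_count == 0), adjust = FALSE, seed = seed, ...
  )
  base_curve <- age_curve(baseline_fit, ages)
  rows <- list(); curves <- list()
  for (cap in sort(caps)) {
    if (cap == 0) {
      rows[[length(rows) + 1]] <- data.frame(
        cap = 0, arm = c("adjusted", "unadjusted"), mape = 0, coverage = 1
      )
      curves[[paste0("cap0")]] <- list(adjusted = base_curve,
                                       unadjusted = base_curve)
      next
    }
    wv <- subset_wave(recs$repeat_count <= cap)
    fits <- list(
      adjusted = fit_debias_model(
        wv, fatigue_features = fatigue_features, hill_priors = hill_priors,
        adjust = TRUE, seed = seed + cap, ...
      ),
      unadjusted = fit_debias_model(
        wv, adjust = FALSE, seed = seed + cap, ...
      )
    )
    cv <- lapply(fits, age_curve, ages = ages)
    rows[[length(rows) + 1]] <- data.frame(
      cap = cap, arm = names(cv),
      mape = vapply(cv, function(cc) mape(base_curve$median, cc$median),
                    numeric(1)),
      coverage = vapply(cv, function(cc) {
        baseline_coverage(base_curve$median, cc[c("lower", "upper")])
      }, numeric(1))
    )
    curves[[paste0("cap", cap)]] <- cv
  }
  structure(
    list(table = do.call(rbind, rows), curves = curves,
         baseline = base_curve),
    class = "cf_incremental"
  )
}

#' Sequential fitting of the de-biasing model across all waves
#'
#' Fits the de-biasing model wave by wave. The first wave uses the
#' supplied priors; from the second wave onwards the priors for the
#' covariate effects and Hill parameters are centred at the previous
#' wave's posterior means with propagation scales 0.3 (beta), 0.3
#' (gamma), 0.1 (zeta) and 0.1 (eta). This partial pooling resolves the
#' non-identifiability between covariate effects and fatigue parameters
#' in waves with few or no first-time participants. The unadjusted
#' comparator, which has no such issue, is fitted independently per wave
#' when `comparator = TRUE`.
#'
#' @param data a multi-wave `cf_wave`; wave indices must be consecutive
#' @param fatigue_features fatigue design columns
#' @param hill_priors priors for the first wave
#' @param propagation_scales named numeric vector with entries `beta`,
#'   `gamma`, `zeta`, `eta`
#' @param comparator also fit the unadjusted model per wave?
#' @param seed integer seed
#' @param ... further arguments passed to [fit_debias_model()]
#' @return list with `adjusted` (per-wave fits), `unadjusted` (or NULL),
#'   and `scales`
#' @export
sequential_fit <- function(data, fatigue_features,
                           hill_priors = default_hill_priors(),
                           propagation_scales = c(beta = 0.3, gamma = 0.3,
                                                  zeta = 0.1, eta = 0.1),
                           comparator = FALSE, seed = 1L, ...) {
  recs <- data$records
  waves <- sort(unique(recs$wave_index))
  if (any(diff(waves) != 1))
    stop("waves must form a consecutive sequence; missing wave in panel")
  fits <- list(); unadj <- list()
  bp <- NULL
  hp <- hill_priors
  for (w in waves) {
    wv <- build_design(recs[recs$wave_index == w, , drop = FALSE],
                       data$schema)
    fit <- fit_debias_model(
      wv, fatigue_features = fatigue_features, hill_priors = hp,
      beta_prior = bp, adjust = TRUE, seed = seed + w, ...
    )
    fits[[as.character(w)]] <- fit
    if (comparator)
      unadj[[as.character(w)]] <- fit_debias_model(
        wv, adjust = FALSE, seed = seed + w, ...
      )
    pm <- stats::setNames(fit$summary$mean, fit$summary$parameter)
    bp <- list(location = pm[fit$features],
               scale = propagation_scales[["beta"]])
    if (length(fatigue_features)) {
      hp <- stats::setNames(lapply(fatigue_features, function(f) {
        informative_hill_priors(
          max(pm[[paste0("gamma[", f, "]")]], 1e-3),
          pm[[paste0("zeta[", f, "]")]],
          max(pm[[paste0("eta[", f, "]")]], 1e-3),
          scales = unname(propagation_scales[c("gamma", "zeta", "eta")])
        )
      }), fatigue_features)
    }
  }
  list(adjusted = fits, unadjusted = if (comparator) unadj,
       scales = propagation_scales)
}
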