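test_that("MAPE and coverage follow their definitions", {
  expect_equal(mape(c(2, 4), c(2, 4)), 0)
  expect_equal(mape(c(1, 2, 3), 1.1 * c(1, 2, 3)), 10)
  expect_equal(mape(c(2, 4), c(3, 3)), 37.5)
  expect_error(mape(c(0, 1), c(1, 1)), "strictly positive")
  expect_error(mape(c(1, 2), c(1, 2, 3)), "grid")
  # MAPE is invariant to joint positive rescaling
  b <- c(2, 3, 5); e <- c(2.5, 2.8, 5.4)
  expect_equal(mape(b, e), mape(10 * b, 10 * e))

  iv <- data.frame(lower = c(1, 2, 3), upper = c(2, 3, 4))
  expect_equal(baseline_coverage(c(1.5, 2.5, 3.5), iv), 1)
  expect_equal(baseline_coverage(c(5, 5, 5), iv), 0)
  expect_equal(baseline_coverage(c(1.5, 5, 3.5), iv), 2 / 3)
  expect_error(baseline_coverage(c(1, 2), iv), "grid")
})

test_that("informative Hill priors carry the printed centres and scales", {
  pr <- informative_hill_priors(0.88, -1.55, 0.94)
  expect_equal(unname(pr$gamma), c(0.88, 0.5))
  expect_equal(unname(pr$zeta), c(-1.55, 0.1))
  expect_equal(unname(pr$eta), c(0.94, 0.1))
  expect_error(informative_hill_priors(-0.1, 0, 1), "gamma_hat")
  expect_error(informative_hill_priors(0.5, 0, -1), "eta_hat")
  # half-normal support: truncated density is zero below the origin
  expect_equal(contactfatigue:::ld_half_normal_pos(0.9, 0.88, 0.5),
               dnorm(0.9, 0.88, 0.5, log = TRUE) -
                 pnorm(0, 0.88, 0.5, lower.tail = FALSE, log.p = TRUE))
})

test_that("the de-biasing model recovers a smooth age profile", {
  # pointwise coverage of the normalized profile, averaged over three
  # replicate cohorts: curves are compared shape-to-shape so that the
  # finite-sample fluctuation of a cohort's overall sample mean (which no
  # model can undo) does not enter the check
  cov_one <- function(seed) {
    cfg <- cohort_config(
      n_per_wave = 1000, n_waves = 1, seed = seed, phi = 4, balanced = TRUE,
      effects = stats::setNames(numeric(0), character(0)),
      age_effect = function(a) 0.3 * sin(a / 12),
      hill = NULL, trend = function(t) 0, band_children = FALSE
    )
    wv <- simulate_contacts(generate_wave_mixture(cfg, 1), cfg)
    ds <- build_design(preprocess_records(wv, seed = 2,
                                          recompute_repeats = FALSE))
    fit <- suppressWarnings(fit_debias_model(
      ds, adjust = FALSE, seed = 3, n_iter = 800, n_warmup = 1200
    ))
    cv <- age_curve(fit)
    truth <- 3 * exp(0.3 * sin(cv$age / 12))
    lam <- attr(cv, "draws")
    lam_n <- sweep(lam, 2, colMeans(lam), "/")
    qs <- apply(lam_n, 1, stats::quantile, probs = c(0.025, 0.975))
    truth_n <- truth / mean(truth)
    c(inside = mean(truth_n >= qs[1, ] & truth_n <= qs[2, ]),
      mape = mape(truth, cv$median))
  }
  res <- vapply(c(11, 42, 77), cov_one, numeric(2))
  expect_gte(mean(res["inside", ]), 0.9)
  # absolute curves stay within a few percent of the truth on average
  expect_lt(mean(res["mape", ]), 10)
})

test_that("unadjusted fits on fatigued data are biased low; adjustment helps", {
  cfg <- cohort_config(
    n_per_wave = 1500, n_waves = 1, seed = 81, phi = 4, balanced = TRUE,
    effects = stats::setNames(numeric(0), character(0)),
    hill = NULL,
    hill_features = list("sex[male]" = hill_params(0.7, 2, 1),
                         "sex[female]" = hill_params(0.7, 2, 1)),
    trend = function(t) 0, band_children = FALSE
  )
  wv <- simulate_contacts(
    generate_wave_mixture(cfg, rep(1, 8)), cfg
  )
  ds <- build_design(preprocess_records(wv, seed = 2,
                                        recompute_repeats = FALSE))
  un <- suppressWarnings(fit_debias_model(
    ds, adjust = FALSE, seed = 3, n_iter = 600, n_warmup = 600
  ))
  ad <- suppressWarnings(fit_debias_model(
    ds, fatigue_features = c("sex[male]", "sex[female]"),
    hill_priors = informative_hill_priors(0.7, 2, 1),
    adjust = TRUE, seed = 3, n_iter = 600, n_warmup = 600
  ))
  truth <- rep(3, 85)
  cu <- age_curve(un); ca <- age_curve(ad)
  # unadjusted is biased downward on average
  expect_lt(mean(cu$median - truth), 0)
  # adjusted is closer to the truth
  expect_lt(mean(abs(ca$median - truth)), mean(abs(cu$median - truth)))
})

test_that("the incremental experiment anchors cap 0 at the baseline", {
  ds <- tiny_wave(n = 700, seed = 91, phi = 6,
                  repeat_probs = c(0.6, 0.2, 0.2),
                  hill_features = list("sex[male]" = hill_params(0.6, 2, 1),
                                       "sex[female]" = hill_params(0.6, 2, 1)))
  res <- suppressWarnings(incremental_inclusion_experiment(
    ds, caps = c(0, 2), fatigue_features = c("sex[male]", "sex[female]"),
    hill_priors = informative_hill_priors(0.6, 2, 1),
    seed = 5, n_iter = 400, n_warmup = 400
  ))
  t0 <- res$table[res$table$cap == 0, ]
  expect_equal(t0$mape, c(0, 0))
  expect_equal(t0$coverage, c(1, 1))
  expect_true(all(c("adjusted", "unadjusted") %in% res$table$arm))
  # no first-timers: precondition error
  recs <- ds$records[ds$records$repeat_count > 0, ]
  ds2 <- build_design(recs, ds$schema)
  expect_error(
    incremental_inclusion_experiment(ds2, 0:1, "sex[male]",
                                     informative_hill_priors(0.6, 2, 1)),
    "first-time"
  )
})

test_that("sequential fitting propagates means with the stated scales", {
  cfg <- cohort_config(
    n_per_wave = 350, n_waves = 2, retention = 0.6, seed = 95, phi = 6,
    balanced = TRUE, effects = stats::setNames(numeric(0), character(0)),
    hill = NULL, trend = function(t) 0, band_children = FALSE
  )
  pan <- simulate_contacts(generate_panel(cfg), cfg)
  ds <- build_design(preprocess_records(pan, seed = 1))
  out <- suppressWarnings(sequential_fit(
    ds, fatigue_features = "sex[female]",
    hill_priors = default_hill_priors(),
    seed = 2, n_iter = 400, n_warmup = 400
  ))
  expect_length(out$adjusted, 2)
  expect_equal(unname(out$scales),
               c(0.3, 0.3, 0.1, 0.1))
  # two equal-sized waves from the same population: wave-2 covariate
  # posteriors stay near wave-1 means
  m1 <- stats::setNames(out$adjusted[[1]]$summary$mean,
                        out$adjusted[[1]]$summary$parameter)
  m2 <- stats::setNames(out$adjusted[[2]]$summary$mean,
                        out$adjusted[[2]]$summary$parameter)
  feats <- out$adjusted[[1]]$features
  expect_lt(max(abs(m1[feats] - m2[feats])), 0.35)
  # missing wave in the sequence is an ordering error
  recs <- ds$records[ds$records$wave_index != 1, ]
  recs$wave_index <- recs$wave_index + 1
  ds3 <- build_design(rbind(ds$records[ds$records$wave_index == 1, ], recs),
                      ds$schema)
  expect_error(sequential_fit(ds3, "sex[female]"), "missing wave")
})
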