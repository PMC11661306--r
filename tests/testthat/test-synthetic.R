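test_that("panel membership follows retention and recruitment rules", {
  # full retention, no dropout: everyone appears in all waves with r = w - 1
  cfg <- cohort_config(n_per_wave = 50, n_waves = 3, retention = 1,
                       seed = 2)
  pan <- generate_panel(cfg)
  expect_equal(nrow(pan), 150)
  for (w in 1:3) {
    expect_true(all(pan$repeat_count[pan$wave_index == w] == w - 1))
  }

  # full dropout: every wave is first-timers only
  cfg0 <- cohort_config(n_per_wave = 50, n_waves = 3, retention = 0,
                        seed = 2)
  pan0 <- generate_panel(cfg0)
  expect_true(all(pan0$repeat_count == 0))

  # infeasible configuration
  expect_error(
    cohort_config(n_per_wave = 10, n_waves = 3, retention = 0,
                  recruit = FALSE),
    "infeasible"
  )

  # empirical retention near the configured probability (binomial bound)
  cfgr <- cohort_config(n_per_wave = 500, n_waves = 10, retention = 0.7,
                        seed = 4)
  panr <- generate_panel(cfgr)
  kept <- vapply(1:9, function(w) {
    ids <- panr$participant_id[panr$wave_index == w]
    mean(ids %in% panr$participant_id[panr$wave_index == w + 1])
  }, numeric(1))
  se <- sqrt(0.7 * 0.3 / 500)
  expect_true(all(abs(kept - 0.7) < 3 * se + 1e-9))
})

test_that("simulated contacts follow the negative-binomial intensity model", {
  # all effects zero, fatigue off, near-Poisson: sample mean ~ exp(beta0)
  cfg <- cohort_config(
    n_per_wave = 20000, n_waves = 1, seed = 3, beta0 = log(3),
    effects = stats::setNames(numeric(0), character(0)),
    trend = function(t) 0, hill = NULL, phi = 1e9, truncate_cap = NULL
  )
  pan <- simulate_contacts(generate_panel(cfg), cfg)
  expect_lt(abs(mean(pan$contact_count) - 3), 3 * sqrt(3 / 20000))

  # variance contract V = mu + mu^2 / phi at lambda = 4, phi = 2
  cfgv <- cohort_config(
    n_per_wave = 50000, n_waves = 1, seed = 5, beta0 = log(4),
    effects = stats::setNames(numeric(0), character(0)),
    trend = function(t) 0, hill = NULL, phi = 2, truncate_cap = NULL
  )
  panv <- simulate_contacts(generate_panel(cfgv), cfgv)
  v <- var(panv$contact_count)
  expect_lt(abs(v - 12) / 12, 0.05)

  # saturated fatigue multiplies the mean by exp(-gamma)
  cfgf <- cohort_config(
    n_per_wave = 50000, n_waves = 1, seed = 7, beta0 = log(4),
    effects = stats::setNames(numeric(0), character(0)),
    trend = function(t) 0, hill = hill_params(0.9, 8, 1), phi = 1e9,
    truncate_cap = NULL
  )
  wv <- generate_wave_mixture(cfgf, repeat_probs = c(0.5, 0, 0, 0, 0.5))
  wv <- simulate_contacts(wv, cfgf)
  m0 <- mean(wv$contact_count[wv$repeat_count == 0])
  m4 <- mean(wv$contact_count[wv$repeat_count == 4])
  expect_lt(abs(m4 / m0 - exp(-0.9)), 0.03)
})

test_that("fatigue in the generator is monotone and anchored at r = 0", {
  cfg <- cohort_config(seed = 1)
  rho <- hill_effect(0:11, cfg$hill)
  expect_equal(rho[1], 0)
  expect_true(all(diff(rho) <= 0))
  # with fatigue disabled, expected counts do not depend on r
  cfg0 <- cohort_config(n_per_wave = 30000, n_waves = 1, seed = 9,
                        hill = NULL, trend = function(t) 0,
                        effects = stats::setNames(numeric(0), character(0)),
                        phi = 1e9, truncate_cap = NULL)
  wv <- simulate_contacts(
    generate_wave_mixture(cfg0, repeat_probs = c(0.5, 0.5)), cfg0
  )
  m <- tapply(wv$contact_count, wv$repeat_count, mean)
  expect_lt(abs(m[["1"]] - m[["0"]]), 4 * sqrt(2 * 3 / 15000))
})

test_that("generated panels pass the data-model validators", {
  cfg <- cohort_config(n_per_wave = 200, n_waves = 3, seed = 6)
  pan <- simulate_contacts(generate_panel(cfg), cfg)
  # exactly one of age / band present pre-imputation
  expect_true(all(xor(is.na(pan$age_years), is.na(pan$child_age_band))))
  recs <- preprocess_records(pan, seed = 1)
  expect_true(all(recs$contact_count <= 30))
  ds <- build_design(recs)
  expect_s3_class(ds, "cf_wave")
  expect_equal(ds$meta$n, nrow(recs))
})

test_that("population margins reflect sample shares and configured skew", {
  cfg <- cohort_config(n_per_wave = 500, n_waves = 1, seed = 10)
  recs <- preprocess_records(simulate_contacts(generate_panel(cfg), cfg),
                             seed = 2)
  m0 <- generate_margins(recs, total = 1e6, skew = 0)
  expect_equal(sum(m0$population), 1e6)
  ag <- age_group_of(recs$age_years, recs$attends_preschool)
  cell <- paste(ag, recs$sex, recs$hh_size)
  shares <- table(cell) / length(cell)
  mcell <- paste(m0$age_group, m0$sex, m0$hh_size)
  expect_equal(unname(m0$population[match(names(shares), mcell)] / 1e6),
               unname(as.numeric(shares)))
  m1 <- generate_margins(recs, total = 5e5, skew = 0.4, seed = 3)
  expect_equal(sum(m1$population), 5e5)
  expect_gt(sd(log(m1$population / m0$population * 2)), 0)
})

test_that("cohorts are written with a machine-readable truth file", {
  cfg <- cohort_config(n_per_wave = 60, n_waves = 2, seed = 12)
  pan <- simulate_contacts(generate_panel(cfg), cfg)
  d <- withr::local_tempdir()
  write_cohort(pan, cfg, d)
  expect_true(file.exists(file.path(d, "participants.csv")))
  truth <- jsonlite::read_json(file.path(d, "truth.json"))
  expect_equal(truth$hill$gamma, 0.88)
  expect_equal(truth$hill$zeta, -1.55)
  expect_equal(truth$phi, 2)
})
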