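test_that("the RHS global reference scale follows the sparsity formula", {
  expect_equal(rhs_epsilon0(8, 16, 400), 0.05)
  expect_equal(rhs_epsilon0(6, 12, 900), 1 / 30)  # p0 = P/2 gives 1/sqrt(n)
  n <- c(100, 400, 1600, 6400)
  expect_true(all(diff(rhs_epsilon0(4, 16, n)) < 0))
  expect_error(rhs_epsilon0(16, 16, 100), "p0")
  expect_error(rhs_epsilon0(0, 16, 100), "p0")
  expect_error(rhs_epsilon0(4, 16, 0), "n")
})

test_that("the half-RHS scale matches the variance-matching adjustment", {
  expect_equal(half_rhs_scale(1, 1), (1 - 2 / pi)^(-1 / 2))
  expect_equal(round(half_rhs_scale(1, 1), 4), 1.6589)
  # Monte-Carlo: variance of the negative half-normal with this scale
  # equals eps^2 * zeta_tilde^2
  set.seed(9)
  eps <- 0.4; zt <- 1.3
  draws <- -abs(rnorm(1e6, 0, half_rhs_scale(eps, zt)))
  v <- var(draws)
  se <- v * sqrt(2 / 1e6)  # approximate SE of a variance estimate
  expect_lt(abs(v - eps^2 * zt^2), 5 * se)
  expect_equal(half_rhs_scale(1e-9, 1), 1e-9 * (1 - 2 / pi)^(-0.5))
})

test_that("the marginalized RHS prior density matches direct integration", {
  gl <- contactfatigue:::gauss_legendre01(48)
  for (eps in c(0.015, 0.07, 0.3)) {
    for (b in c(0.005, 0.05, 0.2, 0.8)) {
      direct <- integrate(function(z) {
        zt2 <- 2 * z^2 / (2 + eps^2 * z^2)
        2 * dt(z, 3) * dnorm(b, 0, pmax(eps * sqrt(zt2), 1e-4))
      }, 0, Inf, rel.tol = 1e-10)$value
      quad <- exp(contactfatigue:::rhs_marginal_lp(b, eps, 2, 3, gl))
      expect_equal(quad, direct, tolerance = 1e-3)
    }
  }
})

test_that("selection thresholds implement the +/-5% rule strictly", {
  expect_equal(round(log(0.95), 4), -0.0513)
  expect_equal(round(log(1.05), 4), 0.0488)
  s <- data.frame(
    parameter = c("f1", "f2", "f3", "f4"),
    median = c(0.06, 0, log(1.05), -0.052),
    stringsAsFactors = FALSE
  )
  sel <- select_features(s, features = s$parameter)
  expect_setequal(sel$selected, c("f1", "f4"))  # exact boundary excluded
  # degenerate thresholds
  none <- select_features(s, lower = -Inf, upper = Inf,
                          features = s$parameter)
  expect_length(none$selected, 0)
  all_nz <- select_features(s, lower = -1e-12, upper = 1e-12,
                            features = s$parameter)
  expect_setequal(all_nz$selected, c("f1", "f3", "f4"))
})

test_that("fatigue selection uses the 5% median-reduction rule", {
  s <- data.frame(
    parameter = c("g1", "g2", "g3"),
    median = c(-0.10, -0.01, 0),
    stringsAsFactors = FALSE
  )
  fake <- list(summary = s, features = s$parameter)
  class(fake) <- "cf_fit"
  sel <- select_fatigue_features(fake)
  expect_equal(sel$selected, "g1")
  expect_equal(round(sel$table$pct_change[1], 1), -9.5)
  expect_equal(round(sel$table$pct_change[2], 1), -1.0)
})

test_that("selection unions across waves with provenance", {
  mk <- function(sel, uni = c("A", "B", "C")) {
    structure(list(
      selected = sel,
      table = data.frame(feature = uni, median = ifelse(uni %in% sel, 0.1, 0),
                         pct_change = 0, selected = uni %in% sel),
      thresholds = c(lower = log(0.95), upper = log(1.05)),
      universe = uni
    ), class = "cf_selection")
  }
  u <- union_across_waves(list(mk(c("A", "B")), mk(c("B", "C"))))
  expect_setequal(u$selected, c("A", "B", "C"))
  expect_length(u$provenance, 2)
  expect_setequal(union_across_waves(list(mk("A")))$selected, "A")
  expect_setequal(union_across_waves(list(mk(character(0)),
                                          mk("C")))$selected, "C")
  expect_error(
    union_across_waves(list(mk("A"), mk("A", uni = c("A", "B")))),
    "universe"
  )
})

test_that("RHS shrinks null coefficients harder than normal priors", {
  ds <- tiny_wave(n = 600, seed = 51)   # all tested effects are null
  rhs_fit <- suppressWarnings(fit_intensity_selection_model(
    ds, seed = 3, n_iter = 700, n_warmup = 700
  ))
  nrm_fit <- suppressWarnings(refit_intensity_normal(
    ds, selected = estimable_columns(ds$schema, "tested"),
    seed = 3, n_iter = 700, n_warmup = 700
  ))
  tested <- estimable_columns(ds$schema, "tested")
  med_rhs <- stats::setNames(rhs_fit$summary$median,
                             rhs_fit$summary$parameter)[tested]
  med_nrm <- stats::setNames(nrm_fit$summary$median,
                             nrm_fit$summary$parameter)[tested]
  expect_lt(mean(abs(med_rhs)), mean(abs(med_nrm)))
  # with all tested effects null, nothing is selected and the baseline
  # intensity is recovered
  expect_length(select_features(rhs_fit)$selected, 0)
  b0 <- rhs_fit$summary$median[rhs_fit$summary$parameter == "beta0"]
  expect_lt(abs(b0 - log(3)), 0.12)
})

test_that("selection is insensitive to the prior non-zero count p0", {
  # strong (p0 = 1), default (K/2) and weak (K - 1) shrinkage settings
  # agree on the selected set for a clearly planted effect
  ds <- tiny_wave(n = 1200, seed = 55,
                  effects = c("employment[student]" = log(1.35)))
  sets <- lapply(c(1, 6, 11), function(p0) {
    fit <- suppressWarnings(fit_intensity_selection_model(
      ds, config = rhs_config(p0 = p0), seed = 4,
      n_iter = 900, n_warmup = 900
    ))
    select_features(fit)$selected
  })
  expect_identical(sets[[1]], sets[[2]])
  expect_identical(sets[[2]], sets[[3]])
  expect_true("employment[student]" %in% sets[[2]])
})

test_that("fatigue selection requires repeaters and keeps gamma negative", {
  ds <- tiny_wave(n = 300, seed = 61)  # first-timers only
  plugin <- list(beta0 = log(3),
                 alpha = stats::setNames(
                   numeric(18), estimable_columns(ds$schema, "always_in")),
                 beta = stats::setNames(numeric(0), character(0)))
  expect_error(fit_fatigue_selection_model(ds, plugin),
               "no repeating participants")
  ds2 <- tiny_wave(n = 400, seed = 62, repeat_probs = c(0.4, 0.6))
  fit <- suppressWarnings(fit_fatigue_selection_model(
    ds2, plugin, seed = 1, n_iter = 300, n_warmup = 300
  ))
  gcols <- fit$features
  expect_true(all(fit$draws[, gcols] <= 0))
})
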