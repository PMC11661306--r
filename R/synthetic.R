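#' Configuration for the synthetic multi-wave cohort generator
#'
#' Defines the study conditions under which synthetic panels are generated:
#' a panel of `n_per_wave` participants per wave over `n_waves` waves, with
#' Bernoulli retention between consecutive waves and recruitment of new
#' participants up to the per-wave quota, covariate-driven log-linear
#' contact intensities, a smooth calendar-time trend, multiplicative
#' reporting fatigue that decays with repeat count toward an asymptote, and
#' negative-binomial observation noise.
#'
#' Defaults emulate the COVIMOD-style design analysed by the models: a
#' baseline intensity of 3 contacts/person/day, overdispersion `phi = 2`,
#' 70% wave-to-wave retention, waves 21 days apart each spanning 14 days,
#' and a global Hill fatigue term with parameters gamma = 0.88,
#' zeta = -1.55, eta = 0.94.
#'
#' @param n_per_wave participants per wave (the recruitment quota)
#' @param n_waves number of waves
#' @param retention probability a wave-w participant returns in wave w+1
#' @param recruit whether dropouts are replaced by newly recruited
#'   participants to fill the quota
#' @param beta0 true log baseline intensity
#' @param effects named numeric vector of true log-linear covariate
#'   effects, keyed by design-block column names (e.g.
#'   `"employment[student]"`); unnamed columns have effect 0
#' @param trend function mapping day index to the calendar-time effect on
#'   the log scale (default: sinusoid plus mild linear drift)
#' @param age_effect optional function mapping age in years to a smooth
#'   log-scale intensity effect (evaluated at true ages), for experiments
#'   targeting the smooth age profile of the de-biasing model
#' @param hill global Hill fatigue parameters as `hill_params()`, or `NULL`
#'   to disable global fatigue
#' @param hill_features named list of `hill_params()`, keyed by
#'   fatigue-block column names, for feature-specific fatigue
#' @param phi negative-binomial overdispersion (> 0); the observation
#'   variance is `mu + mu^2 / phi`. An infinite value gives the Poisson
#'   limit
#' @param truncate_cap truncation bound applied to simulated counts
#'   (`NULL` to disable)
#' @param band_children if `TRUE` (default), participants under 19 carry a
#'   child age band instead of an exact age, as in the real survey
#' @param wave_spacing_days,wave_span_days calendar layout of waves
#' @param balanced draw covariates with near-uniform category frequencies
#'   instead of the realistic skewed frequencies (used by
#'   operating-characteristics experiments)
#' @param seed integer seed
#' @return an object of class `cf_cohort_config`
#' @export
cohort_config <- function(n_per_wave = 2500, n_waves = 10, retention = 0.7,
                          recruit = TRUE, beta0 = log(3),
                          effects = default_true_effects(),
                          trend = default_trend(),
                          hill = hill_params(0.88, -1.55, 0.94),
                          age_effect = NULL,
                          hill_features = list(), phi = 2,
                          truncate_cap = 30L, band_children = TRUE,
                          wave_spacing_days = 21L, wave_span_days = 14L,
                          balanced = FALSE, seed = 1L) {
  stopifnot(phi > 0, retention >= 0, retention <= 1, n_per_wave >= 1,
            n_waves >= 1)
  if (retention == 0 && !recruit && n_waves > 1)
    stop("infeasible cohort: full dropout with no recruitment leaves later waves empty")
  cfg <- structure(
    list(
      n_per_wave = n_per_wave, n_waves = n_waves, retention = retention,
      recruit = recruit, beta0 = beta0, effects = effects, trend = trend,
      hill = hill, age_effect = age_effect,
      hill_features = hill_features, phi = phi,
      truncate_cap = truncate_cap, band_children = band_children,
      wave_spacing_days = wave_spacing_days, wave_span_days = wave_span_days,
      balanced = balanced, seed = seed
    ),
    class = "cf_cohort_config"
  )
  schema <- contact_schema()
  cols <- design_colnames(schema)
  bad <- setdiff(names(effects), cols$all)
  if (length(bad))
    stop("true effect keys not in schema design columns: ",
         paste(bad, collapse = ", "))
  bad <- setdiff(names(hill_features), cols$fatigue)
  if (length(bad))
    stop("hill_features keys not in fatigue design columns: ",
         paste(bad, collapse = ", "))
  cfg
}

design_colnames <- function(schema) {
  lab <- function(f) paste0(f, "[", schema$factors[[f]], "]")
  always <- unlist(lapply(schema$always_in, lab))
  tested <- unlist(lapply(schema$tested, lab))
  fatigue <- unlist(lapply(schema$fatigue, lab))
  list(always = always, tested = tested, fatigue = fatigue,
       all = c(always, tested))
}

#' Default true covariate effects used by the generator
#'
#' A modest, realistic profile: school-age children and students have
#' higher contact intensities, weekend reporting raises counts, retired
#' and symptomatic individuals report fewer contacts, and larger
#' households more.
#' @return named numeric vector of log-scale effects
#' @export
default_true_effects <- function() {
  c(
    "age_group[0-5 preschool]" = 0.20, "age_group[6-9]" = 0.30,
    "age_group[10-14]" = 0.30, "age_group[15-19]" = 0.25,
    "age_group[65-69]" = -0.15, "age_group[70-74]" = -0.20,
    "age_group[75-79]" = -0.25, "age_group[80-84]" = -0.30,
    "sex[female]" = -0.05,
    "hh_size[1]" = -0.15, "hh_size[4]" = 0.10, "hh_size[5+]" = 0.15,
    "employment[student]" = 0.26, "employment[retired]" = -0.15,
    "symptoms[yes]" = -0.10, "day_type[weekend]" = 0.10
  )
}

#' Default calendar-time trend (log scale)
#'
#' A smooth sinusoid of amplitude `amp` with period `period` days plus a
#' mild linear drift, giving the calendar-time Gaussian process stage a
#' signal to recover.
#' @param amp amplitude of the sinusoid
#' @param period period in days
#' @param drift linear drift per 100 days
#' @return function day index -> log-scale effect
#' @export
default_trend <- function(amp = 0.15, period = 120, drift = -0.05) {
  function(t) amp * sin(2 * pi * t / period) + drift * t / 100
}

sample_covariates <- function(n, ids, balanced = FALSE) {
  if (balanced) {
    # balanced design: near-uniform cell frequencies, used for
    # operating-characteristics experiments where tiny cells would
    # dominate the noise budget
    grp <- sample(1:14, n, replace = TRUE)
    lo <- c(0, 0, 6, 10, 15, 20, 25, 35, 45, 55, 65, 70, 75, 80)
    hi <- c(5, 5, 9, 14, 19, 24, 34, 44, 54, 64, 69, 74, 79, 84)
    age <- lo[grp] + floor(stats::runif(n) * (hi[grp] - lo[grp] + 1))
    preschool <- ifelse(age <= 5, grp == 1, NA)
    hh <- sample(c("1", "2", "3", "4", "5+"), n, replace = TRUE)
    urban <- sample(c("rural", "intermediate", "urban"), n, replace = TRUE)
  } else {
    age <- sample(0:84, n, replace = TRUE,
                  prob = c(rep(0.8, 19), rep(1.2, 46), rep(0.9, 16), rep(0.5, 4)))
    preschool <- ifelse(age <= 5, stats::runif(n) < 0.75, NA)
    hh <- sample(c("1", "2", "3", "4", "5+"), n, replace = TRUE,
                 prob = c(0.25, 0.35, 0.2, 0.13, 0.07))
    urban <- sample(c("rural", "intermediate", "urban"), n, replace = TRUE,
                    prob = c(0.2, 0.35, 0.45))
  }
  sex <- sample(c("male", "female"), n, replace = TRUE)
  emp <- rep(NA_character_, n)
  adult <- age >= 15
  young_adult <- adult & age < 65
  emp_levels <- c(
    "full-time employed", "part-time employed", "self-employed", "student",
    "retired", "long-term sick", "unemployed (seeking)",
    "unemployed (not seeking)", "stay-at-home parent"
  )
  emp[young_adult] <- sample(
    emp_levels, sum(young_adult), replace = TRUE,
    prob = if (balanced) rep(1 / 9, 9) else
      c(0.38, 0.15, 0.06, 0.15, 0.05, 0.03, 0.08, 0.04, 0.06)
  )
  emp[adult & age >= 65] <- if (balanced) {
    sample(emp_levels, sum(adult & age >= 65), replace = TRUE)
  } else {
    sample(c("retired", "full-time employed", "part-time employed"),
           sum(adult & age >= 65), replace = TRUE, prob = c(0.9, 0.05, 0.05))
  }
  data.frame(
    participant_id = ids, true_age = age, sex = sex, hh_size = hh,
    employment = emp,
    attends_preschool = preschool,
    urban_type = urban, stringsAsFactors = FALSE
  )
}

#' Generate a synthetic multi-wave panel (covariates only)
#'
#' Participants persist across waves with Bernoulli retention; dropouts
#' are replaced by newly recruited participants up to the per-wave quota.
#' Fixed covariates (age, sex, household size, employment, urban type) are
#' drawn once per participant; report dates and day-varying covariates
#' (symptoms, day type) are drawn per record. Repeat counts are consistent
#' with each participant's appearance history.
#'
#' @param config a `cf_cohort_config`
#' @return participant records without contact counts (use
#'   [simulate_contacts()] to fill them)
#' @export
generate_panel <- function(config) {
  set.seed(config$seed)
  pool <- sample_covariates(config$n_per_wave,
                            sprintf("P%06d", seq_len(config$n_per_wave)),
                            balanced = config$balanced)
  n_created <- config$n_per_wave
  current <- pool$participant_id
  waves <- vector("list", config$n_waves)
  for (w in seq_len(config$n_waves)) {
    if (w > 1) {
      kept <- current[stats::runif(length(current)) < config$retention]
      n_new <- if (config$recruit) max(0L, config$n_per_wave - length(kept)) else 0L
      if (n_new > 0) {
        new_ids <- sprintf("P%06d", n_created + seq_len(n_new))
        pool <- rbind(pool, sample_covariates(n_new, new_ids,
                                              balanced = config$balanced))
        n_created <- n_created + n_new
        current <- c(kept, new_ids)
      } else current <- kept
      if (!length(current))
        stop("infeasible cohort: wave ", w, " has no participants")
    }
    i <- match(current, pool$participant_id)
    n <- length(current)
    day0 <- (w - 1L) * config$wave_spacing_days
    waves[[w]] <- data.frame(
      wave_index = w,
      participant_id = current,
      repeat_count = NA_integer_,
      age_years = pool$true_age[i],
      child_age_band = NA_character_,
      attends_preschool = pool$attends_preschool[i],
      sex = pool$sex[i],
      hh_size = pool$hh_size[i],
      employment = pool$employment[i],
      symptoms = sample(c("no", "yes"), n, replace = TRUE, prob = c(0.8, 0.2)),
      day_type = NA_character_,
      urban_type = pool$urban_type[i],
      contact_count = NA_integer_,
      report_date = day0 + sample.int(config$wave_span_days, n, replace = TRUE),
      stringsAsFactors = FALSE
    )
  }
  records <- do.call(rbind, waves)
  records$day_type <- ifelse(records$report_date %% 7 %in% c(0, 6),
                             "weekend", "weekday")
  records <- compute_repeat_counts(records)
  if (config$band_children) {
    child <- records$age_years <= 18
    band <- cut(records$age_years, c(-1, 4, 9, 14, 18),
                labels = names(CHILD_BANDS))
    records$child_age_band[child] <- as.character(band[child])
    records$true_age <- records$age_years
    records$age_years[child] <- NA_integer_
  } else {
    records$true_age <- records$age_years
  }
  records
}

#' Generate a single synthetic wave with a mixed repeat-count composition
#'
#' Produces a cross-sectional wave in which each participant's repeat
#' count is drawn from a specified distribution, emulating a late survey
#' wave that contains both many first-time participants and participants
#' with a long participation history. Used by the de-biasing accuracy
#' experiment.
#'
#' @param config a `cf_cohort_config`
#' @param repeat_probs numeric vector of weights for repeat counts
#'   `0:(length(repeat_probs) - 1)`
#' @param wave_index nominal wave index of the generated wave
#' @return participant records for one wave, with `repeat_count` assigned
#' @export
generate_wave_mixture <- function(config, repeat_probs, wave_index = 21L) {
  stopifnot(length(repeat_probs) >= 1, all(repeat_probs >= 0))
  set.seed(config$seed)
  n <- config$n_per_wave
  pool <- sample_covariates(n, sprintf("P%06d", seq_len(n)),
                            balanced = config$balanced)
  day0 <- (wave_index - 1L) * config$wave_spacing_days
  rec <- data.frame(
    wave_index = wave_index,
    participant_id = pool$participant_id,
    repeat_count = sample(seq_along(repeat_probs) - 1L, n, replace = TRUE,
                          prob = repeat_probs),
    age_years = pool$true_age,
    child_age_band = NA_character_,
    attends_preschool = pool$attends_preschool,
    sex = pool$sex,
    hh_size = pool$hh_size,
    employment = pool$employment,
    symptoms = sample(c("no", "yes"), n, replace = TRUE, prob = c(0.8, 0.2)),
    day_type = NA_character_,
    urban_type = pool$urban_type,
    contact_count = NA_integer_,
    report_date = day0 + sample.int(config$wave_span_days, n, replace = TRUE),
    stringsAsFactors = FALSE
  )
  rec$day_type <- ifelse(rec$report_date %% 7 %in% c(0, 6),
                         "weekend", "weekday")
  rec$true_age <- rec$age_years
  rec
}

#' Simulate contact counts for a panel
#'
#' Counts are drawn from a negative binomial with log-mean
#' `beta0 + x' beta + trend(t) + fatigue(r)`, where the fatigue term is
#' the global Hill effect plus any feature-specific Hill effects, and then
#' truncated if the configuration requests it. The generator uses true
#' ages (before any banding), so the planted intensity surface is exact.
#'
#' @param panel records from [generate_panel()] or [generate_wave_mixture()]
#' @param config the `cf_cohort_config` used to generate the panel
#' @return the panel with `contact_count` filled
#' @export
simulate_contacts <- function(panel, config) {
  schema <- contact_schema()
  tmp <- panel
  tmp$age_years <- panel$true_age %||% panel$age_years
  ds <- build_design(tmp, schema)
  X <- cbind(ds$U, ds$V)
  beta <- stats::setNames(numeric(ncol(X)), colnames(X))
  beta[names(config$effects)] <- config$effects
  eta <- config$beta0 + as.vector(X %*% beta) + config$trend(panel$report_date)
  if (!is.null(config$age_effect)) eta <- eta + config$age_effect(tmp$age_years)
  r <- panel$repeat_count
  if (!is.null(config$hill)) eta <- eta + hill_effect(r, config$hill)
  for (feat in names(config$hill_features)) {
    eta <- eta + ds$W[, feat] * hill_effect(r, config$hill_features[[feat]])
  }
  set.seed(config$seed + 7919L)
  y <- if (is.finite(config$phi)) {
    stats::rnbinom(length(eta), size = config$phi, mu = exp(eta))
  } else {
    stats::rpois(length(eta), exp(eta))
  }
  if (!is.null(config$truncate_cap)) y <- truncate_contacts(y, config$truncate_cap)
  panel$contact_count <- y
  panel
}

#' Generate population margins for post-stratification
#'
#' Builds census-style cell counts over age group x sex x household size.
#' With `skew = 0` the margins are proportional to the sample composition;
#' positive skew multiplies cell populations by lognormal factors so that
#' weighting becomes non-trivial.
#'
#' @param records participant records defining the sample composition
#'   (ages must be imputed)
#' @param total total population size
#' @param skew standard deviation of the log cell-perturbation
#' @param seed integer seed
#' @return data.frame with columns `age_group`, `sex`, `hh_size`,
#'   `population`; class `cf_margins`
#' @export
generate_margins <- function(records, total = 83e6, skew = 0, seed = 1L) {
  ag <- age_group_of(records$age_years, records$attends_preschool %||% TRUE)
  cells <- stats::aggregate(
    list(n = seq_len(nrow(records))),
    by = list(age_group = ag, sex = records$sex, hh_size = records$hh_size),
    FUN = length
  )
  set.seed(seed)
  fac <- exp(stats::rnorm(nrow(cells), 0, skew))
  share <- cells$n * fac / sum(cells$n * fac)
  out <- data.frame(
    age_group = cells$age_group, sex = cells$sex, hh_size = cells$hh_size,
    population = total * share, stringsAsFactors = FALSE
  )
  class(out) <- c("cf_margins", "data.frame")
  out
}

#' Write a synthetic cohort to disk
#'
#' Emits `participants.csv` and `contacts.csv` in the survey long format,
#' `margins.csv`, and `truth.json` holding every generative parameter for
#' later recovery tests.
#'
#' @param panel records with contact counts
#' @param config the generating `cf_cohort_config`
#' @param dir output directory (created if needed)
#' @param margins optional `cf_margins` to write
#' @return `dir`, invisibly
#' @export
write_cohort <- function(panel, config, dir, margins = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_survey_tables(panel,
                      file.path(dir, "participants.csv"),
                      file.path(dir, "contacts.csv"))
  truth <- list(
    beta0 = config$beta0, effects = as.list(config$effects),
    phi = config$phi,
    hill = if (!is.null(config$hill)) unclass(config$hill),
    hill_features = lapply(config$hill_features, unclass),
    retention = config$retention, n_per_wave = config$n_per_wave,
    n_waves = config$n_waves, seed = config$seed
  )
  jsonlite::write_json(truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  if (!is.null(margins))
    utils::write.csv(margins, file.path(dir, "margins.csv"), row.names = FALSE)
  invisible(dir)
}
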