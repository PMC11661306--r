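# Small in-code fixtures shared across test files.

# A minimal, fully explicit record table (no randomness).
tiny_records <- function() {
  data.frame(
    wave_index = c(1L, 1L, 1L, 2L, 2L),
    participant_id = c("a", "b", "c", "a", "d"),
    repeat_count = NA_integer_,
    age_years = c(30L, NA, 70L, 30L, 8L),
    child_age_band = c(NA, "10-14", NA, NA, "5-9"),
    attends_preschool = NA,
    sex = c("male", "female", "female", "male", "male"),
    hh_size = c("2", "3", "1", "2", "4"),
    employment = c("full-time employed", NA, "retired",
                   "full-time employed", NA),
    symptoms = c("no", "no", "yes", "no", "no"),
    day_type = c("weekday", "weekend", "weekday", "weekday", "weekday"),
    urban_type = c("urban", "rural", "intermediate", "urban", "urban"),
    contact_count = c(4L, 45L, 0L, 3L, 7L),
    report_date = c(1L, 3L, 5L, 22L, 25L),
    stringsAsFactors = FALSE
  )
}

# A small simulated single-wave cohort for fast model smoke tests.
tiny_wave <- function(n = 400, seed = 5, phi = Inf, effects = NULL,
                      hill_features = list(), repeat_probs = 1) {
  cfg <- cohort_config(
    n_per_wave = n, n_waves = 1, seed = seed, phi = phi, balanced = TRUE,
    effects = effects %||% stats::setNames(numeric(0), character(0)),
    hill = NULL, hill_features = hill_features, trend = function(t) 0
  )
  wv <- generate_wave_mixture(cfg, repeat_probs = repeat_probs)
  wv <- simulate_contacts(wv, cfg)
  build_design(preprocess_records(wv, seed = seed + 1,
                                  recompute_repeats = FALSE))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
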