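test_that("survey tables are read, aggregated and round-tripped", {
  pdir <- withr::local_tempdir()
  parts <- data.frame(
    part_id = c("p1", "p2", "p3"), wave = 1, date = "2020-06-11",
    age = c(30, 41, 25), sex = "male", hh_size = "2",
    employment = "full-time employed", symptoms = "no",
    urban_type = "urban"
  )
  conts <- data.frame(part_id = rep("p1", 5), wave = 1)
  pf <- file.path(pdir, "participants.csv")
  cf <- file.path(pdir, "contacts.csv")
  write.csv(parts, pf, row.names = FALSE)
  write.csv(conts, cf, row.names = FALSE)
  recs <- read_survey_tables(pf, cf)
  expect_equal(recs$contact_count, c(5L, 0L, 0L))

  # empty contact file: all counts zero
  write.csv(conts[0, ], cf, row.names = FALSE)
  expect_equal(read_survey_tables(pf, cf)$contact_count, rep(0L, 3))

  # aggregate totals add to itemised rows
  conts2 <- data.frame(part_id = c("p1", "p1", "p1"), wave = 1,
                       n_contacts = c(NA, NA, 4))
  write.csv(conts2, cf, row.names = FALSE)
  expect_equal(read_survey_tables(pf, cf)$contact_count[1], 6L)

  # schema errors name the missing column; duplicates are integrity errors
  write.csv(parts[, setdiff(names(parts), "sex")], pf, row.names = FALSE)
  expect_error(read_survey_tables(pf, cf), "sex")
  write.csv(rbind(parts, parts[1, ]), pf, row.names = FALSE)
  expect_error(read_survey_tables(pf, cf), "duplicate")

  # round trip through write_survey_tables on preprocessed records
  recs <- preprocess_records(tiny_records(), seed = 3)
  write_survey_tables(recs, pf, cf)
  back <- compute_repeat_counts(read_survey_tables(pf, cf))
  ord <- order(back$participant_id, back$wave_index)
  ord0 <- order(recs$participant_id, recs$wave_index)
  expect_equal(back$contact_count[ord], recs$contact_count[ord0])
  expect_equal(back$age_years[ord], recs$age_years[ord0])
  expect_equal(back$repeat_count[ord], recs$repeat_count[ord0])
})

test_that("records lacking age or sex are dropped", {
  recs <- tiny_records()
  recs$sex[1] <- NA
  expect_message(out <- filter_missing_demographics(recs), "1 record")
  expect_equal(nrow(out), 4)
  expect_silent(filter_missing_demographics(tiny_records()))
  recs2 <- tiny_records()
  recs2$age_years[] <- NA
  recs2$child_age_band[] <- NA
  recs2$child_age_band[c(2, 5)] <- "5-9"
  expect_equal(nrow(suppressMessages(filter_missing_demographics(recs2))), 2)
})

test_that("child age imputation is uniform within the band and seeded", {
  expect_true(impute_child_age("10-14", 1) %in% 10:14)
  expect_identical(impute_child_age("10-14", 7), impute_child_age("10-14", 7))
  expect_error(impute_child_age("9-12", 1), "unknown child age band")

  # frequencies of 10,000 draws from a 5-wide band are binomial-consistent
  draws <- vapply(1:10000, function(s) impute_child_age("5-9", s), integer(1))
  tol <- 3 * sqrt(10000 * 0.2 * 0.8)
  expect_true(all(abs(table(draws) - 2000) <= tol))
  expect_setequal(unique(draws), 5:9)

  # panel-level imputation: one age per participant, reproducible
  recs <- tiny_records()
  a1 <- impute_ages(recs, seed = 11)
  a2 <- impute_ages(recs, seed = 11)
  expect_identical(a1$age_years, a2$age_years)
  expect_true(a1$age_years[2] %in% 10:14)
  expect_true(a1$age_years[5] %in% 5:9)
})

test_that("contact truncation is capped, idempotent and monotone", {
  expect_equal(truncate_contacts(45L), 30L)
  expect_equal(truncate_contacts(30L), 30L)
  expect_equal(truncate_contacts(3L), 3L)
  expect_error(truncate_contacts(-1L), "non-negative")
  y <- c(0L, 5L, 29L, 30L, 31L, 100L)
  expect_identical(truncate_contacts(truncate_contacts(y)),
                   truncate_contacts(y))
  expect_true(all(diff(truncate_contacts(sort(y))) >= 0))
})

test_that("repeat counts equal the number of earlier appearances", {
  recs <- data.frame(
    wave_index = c(3L, 4L, 7L, 2L),
    participant_id = c("x", "x", "x", "solo"),
    stringsAsFactors = FALSE
  )
  out <- compute_repeat_counts(recs)
  expect_equal(out$repeat_count[out$participant_id == "x"], 0:2)
  expect_equal(out$repeat_count[out$participant_id == "solo"], 0L)

  # staggered panel matches a brute-force scan, and r increases with wave
  set.seed(8)
  panel <- data.frame(
    wave_index = sample(1:4, 40, replace = TRUE),
    participant_id = sample(letters[1:5], 40, replace = TRUE)
  )
  panel <- panel[!duplicated(panel[c("wave_index", "participant_id")]), ]
  out <- compute_repeat_counts(panel)
  brute <- mapply(function(w, id) {
    sum(panel$wave_index < w & panel$participant_id == id)
  }, panel$wave_index, panel$participant_id)
  expect_equal(out$repeat_count, unname(brute))
  for (id in unique(out$participant_id)) {
    sub <- out[out$participant_id == id, ]
    expect_true(all(diff(sub$repeat_count[order(sub$wave_index)]) > 0))
  }
})

test_that("design blocks have schema widths and correct one-hot rows", {
  recs <- preprocess_records(tiny_records(), seed = 3)
  ds <- build_design(recs)
  expect_equal(ncol(ds$U), 21)
  expect_equal(ncol(ds$V), 16)
  expect_equal(ncol(ds$W), 33)
  expect_true(all(rowSums(ds$U[, 1:14]) == 1))  # one age group per record
  expect_true(all(rowSums(ds$V) <= 4))

  # a record with all-reference categories has zeros on non-reference
  # tested columns; employment/student and weekend give exactly 2 ones
  base <- recs[1, ]
  base$employment <- "student"; base$day_type <- "weekend"
  row <- build_design(base)$V[1, ]
  expect_equal(sum(row[c("employment[student]", "day_type[weekend]")]), 2)
  expect_equal(sum(row), 4)  # the two above plus symptoms[no], urban[urban]

  # unknown category names the record and field
  bad <- recs
  bad$employment[2] <- "astronaut"
  expect_error(build_design(bad), "employment")
  expect_error(build_design(bad), "astronaut")

  # estimable columns drop exactly one reference level per factor
  sch <- contact_schema()
  expect_length(estimable_columns(sch, "always_in"), 18)
  expect_length(estimable_columns(sch, "tested"), 12)
  expect_false("age_group[25-34]" %in% estimable_columns(sch, "always_in"))
})

test_that("schema configuration honours reference overrides", {
  sch <- contact_schema(reference = c(sex = "female"))
  expect_equal(unname(sch$reference["sex"]), "female")
  expect_error(contact_schema(reference = c(sex = "other")), "not a category")
  f <- withr::local_tempfile(fileext = ".yaml")
  writeLines("reference:\n  hh_size: '3'\n", f)
  expect_equal(unname(read_schema_config(f)$reference["hh_size"]), "3")
})
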