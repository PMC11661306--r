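#' @title Survey table ingestion and preprocessing
#' @description Readers for long-format participant and contact tables
#'   (socialmixr-style), plus the preprocessing rules applied before any
#'   model fit: dropping records without age or sex, imputing child ages
#'   from reported age bands, truncating contact totals at 30, and deriving
#'   per-participant repeat counts.
#' @name preprocess
NULL

CHILD_BANDS <- list(
  "0-4" = c(0L, 4L), "5-9" = c(5L, 9L),
  "10-14" = c(10L, 14L), "15-18" = c(15L, 18L)
)

record_columns <- c(
  "wave_index", "participant_id", "repeat_count", "age_years",
  "child_age_band", "attends_preschool", "sex", "hh_size", "employment",
  "symptoms", "day_type", "urban_type", "contact_count", "report_date"
)

#' Read participant and contact tables into participant records
#'
#' The participant table must contain columns `part_id`, `wave`, `date`,
#' `sex`, `hh_size`, and at least one of `age` / `age_band`; optional
#' columns are `employment`, `symptoms`, `day_type`, `urban_type` and
#' `attends_preschool`. The contact table lists one row per itemised
#' contact, keyed by `part_id` and `wave`; an optional `n_contacts` column
#' carries reported aggregate totals (available from wave 3 of the survey
#' onwards). A participant's contact count is the number of itemised rows
#' plus the sum of any aggregate totals; participants with no contact rows
#' have a count of zero.
#'
#' @param participant_path CSV path for the participant table
#' @param contact_path CSV path for the contact table
#' @return a data.frame of participant records (one row per
#'   participant-wave) with `repeat_count` left `NA` until
#'   [compute_repeat_counts()] is applied
#' @export
read_survey_tables <- function(participant_path, contact_path) {
  parts <- utils::read.csv(participant_path, stringsAsFactors = FALSE)
  conts <- utils::read.csv(contact_path, stringsAsFactors = FALSE)

  needed <- c("part_id", "wave", "date", "sex", "hh_size")
  missing_cols <- setdiff(needed, names(parts))
  if (length(missing_cols))
    stop(
      "participant table is missing mandatory column(s): ",
      paste(missing_cols, collapse = ", ")
    )
  if (!any(c("age", "age_band") %in% names(parts)))
    stop("participant table is missing mandatory column(s): age or age_band")
  if (!"part_id" %in% names(conts))
    stop("contact table is missing mandatory column(s): part_id")

  key <- paste(parts$wave, parts$part_id)
  if (anyDuplicated(key))
    stop(
      "duplicate (wave, participant) rows in participant table: ",
      key[duplicated(key)][1]
    )

  if ("wave" %in% names(conts)) {
    ckey <- paste(conts$wave, conts$part_id)
  } else {
    ckey <- as.character(conts$part_id)
    key <- as.character(parts$part_id)
  }
  itemised <- tapply(
    rep(1L, nrow(conts)) * is.na(conts$n_contacts %||% rep(NA, nrow(conts))),
    ckey, sum
  )
  totals <- tapply(
    {
      n <- conts$n_contacts %||% rep(NA_real_, nrow(conts))
      ifelse(is.na(n), 0, n)
    },
    ckey, sum
  )
  y <- integer(nrow(parts))
  hit <- match(key, names(itemised))
  y[!is.na(hit)] <- as.integer(itemised[hit[!is.na(hit)]] + totals[hit[!is.na(hit)]])

  dates <- suppressWarnings(as.Date(parts$date))
  day_idx <- if (all(is.na(dates))) as.integer(parts$date) else
    as.integer(dates - min(dates, na.rm = TRUE)) + 1L
  day_type <- parts$day_type %||% ifelse(
    format(dates, "%u") %in% c("6", "7"), "weekend", "weekday"
  )

  opt <- function(col) parts[[col]] %||% rep(NA_character_, nrow(parts))
  data.frame(
    wave_index = as.integer(parts$wave),
    participant_id = as.character(parts$part_id),
    repeat_count = NA_integer_,
    age_years = as.integer(parts$age %||% rep(NA_integer_, nrow(parts))),
    child_age_band = as.character(opt("age_band")),
    attends_preschool = as.logical(
      parts$attends_preschool %||% rep(NA, nrow(parts))
    ),
    sex = as.character(parts$sex),
    hh_size = as.character(parts$hh_size),
    employment = as.character(opt("employment")),
    symptoms = as.character(opt("symptoms")),
    day_type = as.character(day_type),
    urban_type = as.character(opt("urban_type")),
    contact_count = y,
    report_date = day_idx,
    stringsAsFactors = FALSE
  )
}

#' Write participant records back to the participant/contact CSV pair
#'
#' Inverse of [read_survey_tables()] on preprocessed records: contact rows
#' are emitted as one aggregate `n_contacts` entry per participant-wave.
#'
#' @param records participant records
#' @param participant_path,contact_path output CSV paths
#' @export
write_survey_tables <- function(records, participant_path, contact_path) {
  parts <- data.frame(
    part_id = records$participant_id,
    wave = records$wave_index,
    date = records$report_date,
    age = records$age_years,
    age_band = records$child_age_band,
    attends_preschool = records$attends_preschool,
    sex = records$sex,
    hh_size = records$hh_size,
    employment = records$employment,
    symptoms = records$symptoms,
    day_type = records$day_type,
    urban_type = records$urban_type
  )
  utils::write.csv(parts, participant_path, row.names = FALSE)
  conts <- data.frame(
    part_id = records$participant_id,
    wave = records$wave_index,
    n_contacts = records$contact_count
  )
  utils::write.csv(conts[conts$n_contacts > 0, ], contact_path, row.names = FALSE)
}

#' Drop records with undisclosed age or sex
#'
#' Age (in years or as a child age band) and sex are required by every
#' model in the package; records lacking either are removed, and the number
#' dropped is reported.
#'
#' @param records participant records
#' @return the retained records
#' @export
filter_missing_demographics <- function(records) {
  keep <- !is.na(records$sex) &
    (!is.na(records$age_years) | !is.na(records$child_age_band))
  dropped <- sum(!keep)
  if (dropped > 0)
    message("dropped ", dropped, " record(s) with missing age or sex")
  records[keep, , drop = FALSE]
}

#' Impute a child's age from a reported age band
#'
#' Children's ages are reported in the bands 0-4, 5-9, 10-14 and 15-18
#' years; an exact age is drawn from a discrete uniform distribution over
#' the band (endpoints inclusive).
#'
#' @param band one of `"0-4"`, `"5-9"`, `"10-14"`, `"15-18"`
#' @param rng_seed integer seed making the draw reproducible
#' @return an integer age within the band
#' @export
impute_child_age <- function(band, rng_seed) {
  bounds <- CHILD_BANDS[[band]]
  if (is.null(bounds)) stop("unknown child age band: '", band, "'")
  set.seed(rng_seed)
  sample(seq.int(bounds[1], bounds[2]), 1L)
}

#' Impute ages for all banded records in a panel
#'
#' One age is drawn per participant (not per record), so a child keeps the
#' same imputed age across waves and reruns with the same seed reproduce
#' the same ages.
#'
#' @param records participant records
#' @param seed integer seed
#' @return records with `age_years` filled
#' @export
impute_ages <- function(records, seed = 1L) {
  need <- is.na(records$age_years) & !is.na(records$child_age_band)
  if (!any(need)) return(records)
  ids <- sort(unique(records$participant_id[need]))
  set.seed(seed)
  drawn <- vapply(ids, function(id) {
    band <- records$child_age_band[need & records$participant_id == id][1]
    bounds <- CHILD_BANDS[[band]]
    if (is.null(bounds)) stop("unknown child age band: '", band, "'")
    sample(seq.int(bounds[1], bounds[2]), 1L)
  }, integer(1))
  records$age_years[need] <- drawn[match(records$participant_id[need], ids)]
  records
}

#' Truncate reported contact totals
#'
#' Contact totals are truncated (default cap 30) to limit the influence of
#' extreme outliers on the count models.
#'
#' @param y integer vector of non-negative contact totals
#' @param cap truncation bound
#' @return `pmin(y, cap)`
#' @export
truncate_contacts <- function(y, cap = 30L) {
  if (any(y < 0, na.rm = TRUE)) stop("contact counts must be non-negative")
  pmin(y, cap)
}

#' Derive per-participant repeat counts
#'
#' A record's repeat count r is the number of earlier waves in which the
#' same participant id appears; first-time participation has r = 0.
#'
#' @param records participant records spanning one or more waves
#' @return records with `repeat_count` filled
#' @export
compute_repeat_counts <- function(records) {
  ord <- order(records$participant_id, records$wave_index)
  r <- integer(nrow(records))
  id <- records$participant_id[ord]
  first <- !duplicated(id)
  r[ord] <- sequence(rle(id)$lengths) - 1L
  records$repeat_count <- r
  records
}

#' Apply the full preprocessing pipeline
#'
#' Filters records with missing demographics, imputes child ages, truncates
#' contact totals and computes repeat counts, in that order.
#'
#' @param records raw participant records
#' @param seed seed for child-age imputation
#' @param cap truncation bound for contact totals
#' @param recompute_repeats recompute repeat counts from the appearance
#'   history (set to `FALSE` for cross-sectional tables that carry an
#'   externally assigned repeat count)
#' @return preprocessed records
#' @export
preprocess_records <- function(records, seed = 1L, cap = 30L,
                               recompute_repeats = TRUE) {
  records <- filter_missing_demographics(records)
  records <- impute_ages(records, seed = seed)
  records$contact_count <- truncate_contacts(records$contact_count, cap = cap)
  if (recompute_repeats) records <- compute_repeat_counts(records)
  records
}
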