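#' Covariate schema for contact-survey models
#'
#' Declares the categorical covariates used throughout the package, split
#' into the block that is always included in intensity models (age group,
#' sex, household size), the block of tested candidate determinants
#' (employment, symptoms, day of week, urban-rural typology), and the block
#' of candidate reporting-fatigue determinants (age group, sex, household
#' size, employment, urban-rural typology).
#'
#' Age groups follow the survey convention of 14 levels, with children aged
#' 0-5 split by whether they attend preschool or are raised at home. The
#' one-hot design blocks built from this schema have widths 21 (= 14 + 2 +
#' 5), 16 (= 9 + 2 + 2 + 3) and 33 (= 14 + 2 + 5 + 9 + 3).
#'
#' @param reference named character vector overriding the default reference
#'   level of each factor. References are metadata: design blocks are full
#'   one-hot encodings (shrinkage priors keep the models identifiable), but
#'   the reference levels are retained so that effects can be reported
#'   relative to a fixed profile.
#' @return an object of class `cf_schema`: a list with elements `factors`
#'   (named list of category levels), `always_in`, `tested`, `fatigue`
#'   (character vectors of factor names) and `reference`.
#' @export
contact_schema <- function(reference = NULL) {
  factors <- list(
    age_group = c(
      "0-5 preschool", "0-5 home", "6-9", "10-14", "15-19", "20-24",
      "25-34", "35-44", "45-54", "55-64", "65-69", "70-74", "75-79", "80-84"
    ),
    sex = c("male", "female"),
    hh_size = c("1", "2", "3", "4", "5+"),
    employment = c(
      "full-time employed", "part-time employed", "self-employed",
      "student", "retired", "long-term sick", "unemployed (seeking)",
      "unemployed (not seeking)", "stay-at-home parent"
    ),
    symptoms = c("no", "yes"),
    day_type = c("weekday", "weekend"),
    urban_type = c("rural", "intermediate", "urban")
  )
  ref <- c(
    age_group = "25-34", sex = "male", hh_size = "2",
    employment = "full-time employed", symptoms = "no",
    day_type = "weekday", urban_type = "urban"
  )
  if (!is.null(reference)) {
    bad <- setdiff(names(reference), names(factors))
    if (length(bad)) stop("unknown factor in reference: ", paste(bad, collapse = ", "))
    for (f in names(reference)) {
      if (!reference[[f]] %in% factors[[f]])
        stop("reference level '", reference[[f]], "' not a category of ", f)
      ref[[f]] <- reference[[f]]
    }
  }
  structure(
    list(
      factors = factors,
      always_in = c("age_group", "sex", "hh_size"),
      tested = c("employment", "symptoms", "day_type", "urban_type"),
      fatigue = c("age_group", "sex", "hh_size", "employment", "urban_type"),
      reference = ref
    ),
    class = "cf_schema"
  )
}

#' Read a covariate schema from a YAML configuration file
#'
#' The file may declare `reference:` (a map factor -> level). Categories
#' themselves are fixed by the survey instrument and are not configurable.
#'
#' @param path path to a YAML file
#' @return a `cf_schema`
#' @export
read_schema_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  contact_schema(reference = unlist(cfg$reference))
}

block_width <- function(schema, block) {
  sum(lengths(schema$factors[schema[[block]]]))
}

#' Map age in years to the schema age group
#'
#' Children aged 0-5 are split into the preschool / raised-at-home groups
#' using the `attends_preschool` flag (defaults to preschool when unknown,
#' the more common situation in the survey samples).
#'
#' @param age_years integer vector of ages 0-84
#' @param attends_preschool logical vector (recycled); only used for ages 0-5
#' @return character vector of age-group labels
#' @export
age_group_of <- function(age_years, attends_preschool = TRUE) {
  stopifnot(all(is.na(age_years) | (age_years >= 0 & age_years <= 84)))
  attends_preschool <- rep_len(attends_preschool, length(age_years))
  attends_preschool[is.na(attends_preschool)] <- TRUE
  breaks <- c(6, 10, 15, 20, 25, 35, 45, 55, 65, 70, 75, 80, 85)
  labels <- c(
    "6-9", "10-14", "15-19", "20-24", "25-34", "35-44", "45-54",
    "55-64", "65-69", "70-74", "75-79", "80-84"
  )
  out <- rep(NA_character_, length(age_years))
  young <- !is.na(age_years) & age_years <= 5
  out[young] <- ifelse(attends_preschool[young], "0-5 preschool", "0-5 home")
  old <- !is.na(age_years) & age_years > 5
  out[old] <- labels[findInterval(age_years[old], breaks)]
  out
}

# One-hot encode a character vector over declared levels. NA rows become
# all-zero (used for factors that do not apply, e.g. employment of young
# children). Unknown categories raise an error naming the offending rows.
one_hot <- function(x, levels, factor_name) {
  known <- is.na(x) | x %in% levels
  if (!all(known)) {
    bad <- which(!known)[1]
    stop(
      "record ", bad, ": category '", x[bad], "' not in schema for field '",
      factor_name, "'"
    )
  }
  m <- matrix(0, nrow = length(x), ncol = length(levels))
  colnames(m) <- paste0(factor_name, "[", levels, "]")
  hit <- !is.na(x)
  m[cbind(which(hit), match(x[hit], levels))] <- 1
  m
}

design_block <- function(records, schema, block) {
  cols <- lapply(schema[[block]], function(f) {
    vals <- if (f == "age_group") {
      age_group_of(records$age_years, records$attends_preschool %||% TRUE)
    } else {
      as.character(records[[f]])
    }
    one_hot(vals, schema$factors[[f]], f)
  })
  do.call(cbind, cols)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Build model design blocks for one wave (or panel) of records
#'
#' Produces the three one-hot design blocks used by the models: the
#' always-in block `U` (age group, sex, household size; 21 columns), the
#' tested block `V` (employment, symptoms, day type, urban type; 16
#' columns) and the fatigue-candidate block `W` (33 columns). Blocks are
#' full one-hot encodings; reference levels are carried as metadata.
#'
#' @param records preprocessed participant records (ages imputed)
#' @param schema a `cf_schema`
#' @return an object of class `cf_wave`: list with `records`, `U`, `V`,
#'   `W`, `schema`, and `meta` (wave sizes, first-time vs repeating counts)
#' @export
build_design <- function(records, schema = contact_schema()) {
  stopifnot(is.data.frame(records))
  if (anyNA(records$age_years))
    stop("records contain missing age_years; impute child ages first")
  U <- design_block(records, schema, "always_in")
  V <- design_block(records, schema, "tested")
  W <- design_block(records, schema, "fatigue")
  stopifnot(
    ncol(U) == block_width(schema, "always_in"),
    ncol(V) == block_width(schema, "tested"),
    ncol(W) == block_width(schema, "fatigue")
  )
  r <- records$repeat_count
  structure(
    list(
      records = records, U = U, V = V, W = W, schema = schema,
      meta = list(
        n = nrow(records),
        waves = sort(unique(records$wave_index)),
        n_first_time = sum(r == 0, na.rm = TRUE),
        n_repeating = sum(r > 0, na.rm = TRUE)
      )
    ),
    class = "cf_wave"
  )
}

#' @export
print.cf_wave <- function(x, ...) {
  cat(
    "<cf_wave> ", x$meta$n, " records, waves ",
    paste(range(x$meta$waves), collapse = "-"),
    " (", x$meta$n_first_time, " first-time, ",
    x$meta$n_repeating, " repeating)\n",
    sep = ""
  )
  invisible(x)
}

#' Estimable (non-reference) design columns of a block
#'
#' Intercept-carrying models estimate only the non-reference columns of
#' the one-hot blocks; the reference levels define the baseline profile
#' absorbed by the intercept.
#'
#' @param schema a `cf_schema`
#' @param block one of `"always_in"`, `"tested"`, `"fatigue"`
#' @return character vector of design column names
#' @export
estimable_columns <- function(schema, block = c("always_in", "tested",
                                                "fatigue")) {
  block <- match.arg(block)
  unlist(lapply(schema[[block]], function(f) {
    lv <- setdiff(schema$factors[[f]], schema$reference[[f]])
    paste0(f, "[", lv, "]")
  }))
}
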