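#' Post-stratification weights from population margins
#'
#' Computes per-record weights proportional to the ratio of the
#' population cell share to the sample cell share over the age group x
#' sex x household size cells, normalized to mean 1. Margin cells with no
#' sampled counterpart trigger a warning and are collapsed: their
#' population mass is dropped and the remaining cell shares renormalized.
#'
#' @param records participant records (ages imputed)
#' @param margins a `cf_margins` data.frame with columns `age_group`,
#'   `sex`, `hh_size`, `population`
#' @return numeric vector of strictly positive weights with mean 1
#' @export
poststrat_weights <- function(records, margins) {
  ag <- age_group_of(records$age_years, records$attends_preschool %||% TRUE)
  cell <- paste(ag, records$sex, records$hh_size, sep = "|")
  mcell <- paste(margins$age_group, margins$sex, margins$hh_size, sep = "|")
  samp <- table(cell)
  observed <- mcell %in% names(samp)
  if (!all(observed)) {
    warning(sum(!observed),
            " margin cell(s) have no sampled records; collapsing them",
            call. = FALSE)
  }
  pop <- margins$population[observed]
  mcell <- mcell[observed]
  missing_margin <- setdiff(names(samp), mcell)
  if (length(missing_margin))
    stop("sample cell(s) missing from margins: ",
         paste(utils::head(missing_margin, 3), collapse = ", "))
  pop_share <- pop / sum(pop)
  samp_share <- as.numeric(samp[mcell]) / sum(samp)
  w_cell <- stats::setNames(pop_share / samp_share, mcell)
  w <- as.numeric(w_cell[cell])
  w / mean(w)
}

new_weighted_estimate <- function(point, lower, upper, wave, subgroup,
                                  method) {
  data.frame(
    wave = wave, subgroup = subgroup, method = method,
    point = point, lower = lower, upper = upper,
    stringsAsFactors = FALSE
  )
}

# Draws x 1 weighted mean of fatigue-free per-record intensities from a
# fitted de-biasing model: lambda_i = exp(beta0 + u_i' beta + f(age_i)),
# i.e. the model evaluated at repeat count 0.
debias_population_draws <- function(fit, weights) {
  fd <- debias_f_draws(fit, fit$ages)
  eta <- fit$draws[, "beta0"] +
    tcrossprod(fit$draws[, fit$features, drop = FALSE], fit$X)
  lam <- exp(t(eta) + fd)
  as.vector(crossprod(lam, weights / sum(weights)))
}

#' Post-stratified population-level contact intensity
#'
#' For each posterior draw of a fitted de-biasing model, computes the
#' weighted mean of the fatigue-free per-record intensities (the fatigue
#' term evaluated at repeat count 0, which is exactly zero), and
#' summarises the draws by posterior median and 95% credible interval.
#'
#' @param fit a `cf_fit` from [fit_debias_model()]
#' @param weights per-record post-stratification weights (default:
#'   uniform)
#' @param wave wave label for the output row
#' @param method method tag for the output row
#' @return a one-row data.frame (`wave`, `subgroup`, `method`, `point`,
#'   `lower`, `upper`)
#' @export
population_mean_intensity <- function(fit, weights = NULL, wave = NA,
                                      method = if (isTRUE(fit$adjust))
                                        "adjusted" else "unadjusted") {
  weights <- weights %||% rep(1, fit$n)
  stopifnot(length(weights) == fit$n)
  mu <- debias_population_draws(fit, weights)
  q <- stats::quantile(mu, c(0.025, 0.5, 0.975), names = FALSE)
  new_weighted_estimate(q[2], q[1], q[3], wave, "population", method)
}

#' Simple bootstrap estimate of the mean contact intensity
#'
#' Participant-level resampling with replacement from first-time
#' participants: each of `B` resamples yields a weighted mean contact
#' count; the point estimate is the mean of the resample means and the
#' interval the 2.5/97.5 percentiles.
#'
#' @param records first-time participant records (repeat count 0)
#' @param B number of bootstrap resamples
#' @param seed integer seed
#' @param weights optional post-stratification weights
#' @param wave wave label
#' @return a one-row data.frame as in [population_mean_intensity()]
#' @export
bootstrap_mean <- function(records, B = 1000L, seed = 1L, weights = NULL,
                           wave = NA) {
  if (any(records$repeat_count != 0, na.rm = TRUE))
    stop("bootstrap comparator uses first-time participants only")
  if (B < 100) warning("B < 100 bootstrap resamples", call. = FALSE)
  y <- records$contact_count
  n <- length(y)
  weights <- weights %||% rep(1, n)
  set.seed(seed)
  means <- vapply(seq_len(B), function(b) {
    i <- sample.int(n, n, replace = TRUE)
    stats::weighted.mean(y[i], weights[i])
  }, numeric(1))
  q <- stats::quantile(means, c(0.025, 0.975), names = FALSE)
  new_weighted_estimate(mean(means), q[1], q[2], wave, "population",
                        "bootstrap")
}

#' Subgroup contact intensity estimates
#'
#' Computes weighted posterior intensities for population subgroups
#' defined by covariate constraints, e.g. `list(sex = "male", hh_size =
#' "3", age_range = c(45, 54))`. Fields other than `age_range` must name
#' record columns; `age_range` is an inclusive bound on age in years.
#'
#' @param fit a `cf_fit` from [fit_debias_model()]
#' @param subgroups named list of subgroup definitions
#' @param weights per-record weights (default uniform)
#' @param wave wave label
#' @return data.frame with one row per subgroup
#' @export
subgroup_estimates <- function(fit, subgroups, weights = NULL, wave = NA) {
  weights <- weights %||% rep(1, fit$n)
  recs <- fit$records
  rows <- lapply(names(subgroups), function(nm) {
    def <- subgroups[[nm]]
    keep <- rep(TRUE, nrow(recs))
    for (f in names(def)) {
      if (f == "age_range") {
        keep <- keep & recs$age_years >= def[[f]][1] &
          recs$age_years <= def[[f]][2]
      } else {
        if (!f %in% names(recs)) stop("unknown subgroup field: ", f)
        if (!all(def[[f]] %in% recs[[f]]))
          stop("unknown category in subgroup definition: ",
               paste(setdiff(def[[f]], recs[[f]]), collapse = ", "))
        keep <- keep & recs[[f]] %in% def[[f]]
      }
    }
    if (!any(keep)) stop("subgroup '", nm, "' matches no records")
    fd <- debias_f_draws(fit, fit$ages[keep])
    eta <- fit$draws[, "beta0"] +
      tcrossprod(fit$draws[, fit$features, drop = FALSE],
                 fit$X[keep, , drop = FALSE])
    lam <- exp(t(eta) + fd)
    wk <- weights[keep]
    mu <- as.vector(crossprod(lam, wk / sum(wk)))
    q <- stats::quantile(mu, c(0.025, 0.5, 0.975), names = FALSE)
    new_weighted_estimate(q[2], q[1], q[3], wave, nm,
                          if (isTRUE(fit$adjust)) "adjusted" else "unadjusted")
  })
  do.call(rbind, rows)
}

#' Write estimate tables to disk
#'
#' Writes a tidy CSV of weighted estimates (columns `wave`, `subgroup`,
#' `method`, `point`, `lower`, `upper`). If a stringency table (columns
#' `date`, `index`) and a wave-to-date mapping are supplied, a
#' `stringency` column is appended for plotting overlays.
#'
#' @param results data.frame of weighted estimates
#' @param out_dir output directory
#' @param file output file name
#' @param stringency optional data.frame with columns `date`, `index`
#' @param wave_dates optional data.frame with columns `wave`, `date`
#' @return the output path, invisibly
#' @export
write_report <- function(results, out_dir, file = "estimates.csv",
                         stringency = NULL, wave_dates = NULL) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  cols <- c("wave", "subgroup", "method", "point", "lower", "upper")
  if (is.null(results) || nrow(results) == 0) {
    results <- stats::setNames(
      data.frame(matrix(ncol = length(cols), nrow = 0)), cols
    )
  }
  results <- results[, cols, drop = FALSE]
  if (!is.null(stringency) && !is.null(wave_dates)) {
    idx <- stats::setNames(stringency$index, stringency$date)
    results$stringency <-
      as.numeric(idx[as.character(wave_dates$date[
        match(results$wave, wave_dates$wave)])])
  }
  path <- file.path(out_dir, file)
  utils::write.csv(results, path, row.names = FALSE)
  invisible(path)
}
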