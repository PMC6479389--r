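# Time-staggered birth cohorts aggregated into calendar-year population
# snapshots.

#' Construct a set of birth cohorts
#'
#' Each cohort enters the model in age band 0-4 during its 5-year birth
#' period and is propagated with the transition table of its `vintage`.
#' By convention cohorts born before 1980 may use vintage-specific
#' initiation/cessation tables while later cohorts share a constant table;
#' the default vintage labels follow that convention (`"<birth year>"`
#' before 1980, `"constant"` from 1980 on), but any labels matching the
#' names of the supplied table list are accepted.
#'
#' @param df data.frame with columns `birth_period_start` (multiples of 5,
#'   non-overlapping and contiguous), `initial_size` (persons, `>= 0`) and
#'   optionally `vintage`.
#' @return Object of class `birth_cohorts`.
#' @export
birth_cohorts <- function(df) {
  df <- as.data.frame(df, stringsAsFactors = FALSE)
  if (!all(c("birth_period_start", "initial_size") %in% names(df)))
    stop("need columns birth_period_start, initial_size")
  if (any(df$initial_size < 0)) stop("initial_size must be >= 0")
  if (anyDuplicated(df$birth_period_start))
    stop("overlapping birth periods")
  df <- df[order(df$birth_period_start), ]
  if (nrow(df) > 1 && any(diff(df$birth_period_start) != 5))
    stop("birth periods must be contiguous 5-year quinquennia")
  if (is.null(df$vintage))
    df$vintage <- ifelse(df$birth_period_start < 1980,
                         as.character(df$birth_period_start), "constant")
  rownames(df) <- NULL
  class(df) <- c("birth_cohorts", "data.frame")
  df
}

#' Run a time-staggered multi-cohort population
#'
#' Propagates every birth cohort independently from age 0 with its vintage's
#' transition table, then assembles calendar-year snapshots by aligning each
#' cohort's age to the calendar: a cohort born in `[y, y + 5)` occupies age
#' band `[a, a + 5)` during calendar years `[y + a, y + a + 5)`. When a
#' `modified_table` and `switch_year` are given, each cohort switches to the
#' modified rates at the age it reaches in the switch year, so a scenario
#' beginning mid-history affects only the years after it.
#'
#' @param cohorts a [birth_cohorts()] object.
#' @param tables named list of [transition_table()]s, one per vintage used.
#' @param models a [mortality_models()] bundle.
#' @param err an [err_params()] object.
#' @param horizon_year last calendar year to report.
#' @param modified_table optional [transition_table()] applied from
#'   `switch_year` on (all vintages).
#' @param switch_year calendar year at which the modified rates take effect.
#' @param max_age oldest reported band start (100 reports bands 0-4 through
#'   100-104); must be a multiple of 5. Ages beyond the oldest modelled
#'   cohort are reported as zero.
#' @param ... passed to [run_cohort()].
#' @return Object of class `population_snapshots`: data.frame `year`,
#'   `age`, `count` for every 5-year calendar mark from the first birth
#'   period to `horizon_year`.
#' @export
run_population <- function(cohorts, tables, models, err = err_params(),
                           horizon_year, modified_table = NULL,
                           switch_year = NULL, max_age = 100, ...) {
  stopifnot(inherits(cohorts, "birth_cohorts"))
  if (inherits(tables, "transition_table")) tables <- list(constant = tables)
  missing_v <- setdiff(unique(cohorts$vintage), names(tables))
  if (length(missing_v))
    stop("no transition table for vintage(s): ",
         paste(missing_v, collapse = ", "))
  if (!is.null(modified_table) && is.null(switch_year))
    stop("modified_table given without switch_year")

  per_cohort <- vector("list", nrow(cohorts))
  for (i in seq_len(nrow(cohorts))) {
    y <- cohorts$birth_period_start[i]
    size <- cohorts$initial_size[i]
    if (size == 0) next
    ages_needed <- horizon_year - y           # age reached at the horizon
    if (ages_needed <= 0) next
    end_age <- min(max_age, ceiling(ages_needed / 5) * 5)
    cfg <- cohort_config(initial_size = size, start_age = 0,
                         end_age = max(5, end_age))
    sw_age <- NULL
    if (!is.null(switch_year) && switch_year > y &&
        switch_year < y + cfg$end_age) sw_age <- switch_year - y
    use_mod_all <- !is.null(switch_year) && switch_year <= y
    res <- run_cohort(cfg,
                      table = if (use_mod_all) modified_table
                              else tables[[cohorts$vintage[i]]],
                      models = models, err = err,
                      switch_age = if (!is.null(sw_age) && !use_mod_all)
                        sw_age,
                      switch_table = if (!is.null(sw_age) && !use_mod_all)
                        modified_table,
                      keep_occupancy = FALSE, ...)
    per_cohort[[i]] <- data.frame(birth = y, age = res$ages, lx = res$lx)
  }
  traj <- do.call(rbind, per_cohort)

  years <- seq(min(cohorts$birth_period_start), horizon_year, by = 5)
  snaps <- do.call(rbind, lapply(years, function(Y) {
    ages <- seq(0, max_age, by = 5)
    cnt <- vapply(ages, function(a) {
      j <- which(traj$birth == Y - a & traj$age == a)
      if (length(j) == 1L) traj$lx[j] else 0
    }, numeric(1))
    data.frame(year = Y, age = ages, count = cnt)
  }))
  rownames(snaps) <- NULL
  class(snaps) <- c("population_snapshots", "data.frame")
  snaps
}

#' Total premature deaths prevented between two snapshot series
#'
#' Per-age-group difference (modified minus base) in a given calendar year,
#' and its total over an age range (conventionally ages 0-84).
#'
#' @param base_snapshots,modified_snapshots [run_population()] results (or
#'   data.frames with `year`, `age`, `count`) sharing year and age
#'   structure.
#' @param year calendar year to evaluate.
#' @param age_range inclusive band-start range to total over.
#' @return List with `total` and `by_age` (data.frame `age`, `base`,
#'   `modified`, `diff`).
#' @export
total_deaths_prevented <- function(base_snapshots, modified_snapshots, year,
                                   age_range = c(0, 84)) {
  b <- base_snapshots[base_snapshots$year == year, ]
  m <- modified_snapshots[modified_snapshots$year == year, ]
  if (nrow(b) == 0L) stop("year ", year, " not in snapshots")
  b <- b[order(b$age), ]; m <- m[order(m$age), ]
  if (nrow(b) != nrow(m) || any(b$age != m$age))
    stop("mismatched age structures between scenarios")
  by_age <- data.frame(age = b$age, base = b$count, modified = m$count,
                       diff = m$count - b$count)
  sel <- by_age$age >= age_range[1] & by_age$age <= age_range[2]
  list(total = sum(by_age$diff[sel]), by_age = by_age)
}

#' Percent difference between a model total and a reference total
#'
#' `100 * (model - reference) / reference`; the multicohort validation
#' statistic against census-style counts. Vectorised, so per-band
#' comparisons work too.
#'
#' @param model_total modelled count(s).
#' @param reference_total reference count(s), non-zero.
#' @return Percent difference(s).
#' @export
validate_against_reference <- function(model_total, reference_total) {
  if (any(reference_total == 0)) stop("reference total must be non-zero")
  100 * (model_total - reference_total) / reference_total
}
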