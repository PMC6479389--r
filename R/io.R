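# Plain-CSV input/output, scenario configuration and run manifests.
#
# External files carry an explicit unit tag in the rate column name
# (`rate_fraction` or `rate_percent`) to prevent the 1.4-vs-0.014 ambiguity;
# a bare `rate` column is read as a fraction.

#' Read or write a transition table as CSV
#'
#' Columns `age_group,from_category,to_category,rate_fraction` (written
#' form). Readers also accept `rate` (fraction) or `rate_percent`, and an
#' optional `class` column.
#'
#' @param path file path.
#' @param table a [transition_table()] (for writing).
#' @param percent write rates as percent (`rate_percent` column).
#' @return `read_transition_table()` returns a [transition_table()].
#' @export
read_transition_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  names(df)[names(df) == "age_group"] <- "age"
  names(df)[names(df) == "from_category"] <- "from"
  names(df)[names(df) == "to_category"] <- "to"
  if ("rate_percent" %in% names(df)) {
    df$rate <- df$rate_percent / 100
    df$rate_percent <- NULL
  } else if ("rate_fraction" %in% names(df)) {
    df$rate <- df$rate_fraction
    df$rate_fraction <- NULL
  } else if (!"rate" %in% names(df)) {
    stop(path, ": no rate, rate_fraction or rate_percent column")
  }
  transition_table(df)
}

#' @rdname read_transition_table
#' @export
write_transition_table <- function(table, path, percent = FALSE) {
  out <- data.frame(age_group = table$age, from_category = table$from,
                    to_category = table$to)
  if (percent) out$rate_percent <- table$rate * 100
  else out$rate_fraction <- table$rate
  out$class <- table$class
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read or write mortality records as CSV
#'
#' Columns `age,ysm,yqsm,person_years,deaths,group`.
#'
#' @param path file path.
#' @param records mortality records (for writing).
#' @return `read_mortality_records()` returns validated records.
#' @export
read_mortality_records <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  validate_mortality_records(df)
  df
}

#' @rdname read_mortality_records
#' @export
write_mortality_records <- function(records, path) {
  validate_mortality_records(records)
  utils::write.csv(
    records[, c("age", "ysm", "yqsm", "person_years", "deaths", "group")],
    path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read or write behavioural-intention summaries as CSV
#'
#' Columns `behavior,from_category,to_category,control_pre,control_post,
#' test_pre,test_post`, proportions as percent.
#'
#' @param path file path.
#' @param intentions the summary data.frame (for writing).
#' @return `read_intentions()` returns the summary data.frame.
#' @export
read_intentions <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  names(df)[names(df) == "from_category"] <- "from"
  names(df)[names(df) == "to_category"] <- "to"
  need <- c("from", "to", "control_pre", "control_post",
            "test_pre", "test_post")
  if (!all(need %in% names(df)))
    stop(path, ": intentions file needs columns ",
         paste(need, collapse = ", "))
  df
}

#' @rdname read_intentions
#' @export
write_intentions <- function(intentions, path) {
  out <- intentions
  names(out)[names(out) == "from"] <- "from_category"
  names(out)[names(out) == "to"] <- "to_category"
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read or write birth-cohort sizes as CSV
#'
#' Columns `birth_period_start,initial_size` and optionally `vintage`.
#'
#' @param path file path.
#' @param cohorts a [birth_cohorts()] object (for writing).
#' @return `read_cohort_sizes()` returns a [birth_cohorts()] object.
#' @export
read_cohort_sizes <- function(path) {
  birth_cohorts(utils::read.csv(path, stringsAsFactors = FALSE))
}

#' @rdname read_cohort_sizes
#' @export
write_cohort_sizes <- function(cohorts, path) {
  utils::write.csv(as.data.frame(cohorts), path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

#' Write population snapshots as CSV
#'
#' Columns `year,age_group,count`.
#'
#' @param snapshots a [run_population()] result.
#' @param path file path.
#' @export
write_snapshots <- function(snapshots, path) {
  out <- data.frame(year = snapshots$year, age_group = snapshots$age,
                    count = snapshots$count)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a scenario comparison as CSV
#'
#' Columns `age_group,base,modified,deaths_prevented_mean,ci_low,ci_high`
#' (uncertainty columns when draws were run).
#'
#' @param comparison a [compare_scenarios()] result.
#' @param path file path.
#' @export
write_comparison <- function(comparison, path) {
  s <- comparison$summary
  out <- data.frame(age_group = s$age, base = s$base, modified = s$modified,
                    deaths_prevented = s$diff)
  if (!is.null(s$diff_mean)) {
    out$deaths_prevented_mean <- s$diff_mean
    out$deaths_prevented_sd <- s$diff_sd
    out$ci_low <- s$ci_low
    out$ci_high <- s$ci_high
  }
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a scenario configuration
#'
#' A JSON file naming the input CSVs and run settings. Recognised fields
#' (all optional, with spec-matching defaults): `base_table`,
#' `mortality_records`, `intentions`, `cohort_sizes` (paths);
#' `initial_size`, `start_age`, `end_age`; `err_current`, `err_former`;
#' `would_be_smoker`, `would_be_quitter`; `n_draws`, `seed`, `rate_sd`;
#' `use_rounded_deltas`, `hazard_timing`, `ax_fraction`.
#'
#' @param path JSON file path.
#' @return A named list of settings with defaults filled in; referenced
#'   files are checked for existence.
#' @export
read_scenario_config <- function(path) {
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  defaults <- list(initial_size = 1e6, start_age = 13, end_age = 103,
                   err_current = 0.09, err_former = 0.04,
                   would_be_smoker = 0.01, would_be_quitter = 0.05,
                   n_draws = 10000L, seed = 1L, rate_sd = 0.02,
                   use_rounded_deltas = FALSE,
                   hazard_timing = "destination", ax_fraction = 0.5)
  for (k in names(defaults)) if (is.null(cfg[[k]])) cfg[[k]] <- defaults[[k]]
  for (k in c("base_table", "mortality_records", "intentions",
              "cohort_sizes")) {
    if (!is.null(cfg[[k]]) && !file.exists(cfg[[k]]))
      stop("configured file does not exist: ", k, " = ", cfg[[k]])
  }
  cfg
}

#' Write a run manifest
#'
#' Records what produced a set of outputs: the configuration echo, the seed,
#' package and R versions, and MD5 checksums of the input files, so any
#' output is reproducible from its manifest alone.
#'
#' @param path JSON file path for the manifest.
#' @param config the configuration list used.
#' @param inputs character vector of input file paths to checksum.
#' @param seed the seed used.
#' @export
write_manifest <- function(path, config = list(), inputs = character(),
                           seed = NULL) {
  man <- list(
    package = "mstcohort",
    package_version = as.character(utils::packageVersion("mstcohort")),
    r_version = R.version.string,
    timestamp = format(Sys.time(), tz = "UTC", usetz = TRUE),
    seed = seed,
    config = config,
    input_md5 = as.list(tools::md5sum(inputs[file.exists(inputs)]))
  )
  jsonlite::write_json(man, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
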