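# Expected-value mass-flow propagation of a closed cohort, scenario
# comparison with Monte-Carlo parameter uncertainty, and single-transition
# attribution.

#' Cohort configuration
#'
#' A closed cohort of never-users followed in 5-year steps from `start_age`
#' to `end_age` (the final age group is treated as open-ended by the life
#' table). The conventional setting is 1,000,000 males followed from age 13
#' to 103.
#'
#' @param initial_size persons at `start_age`.
#' @param start_age,end_age band boundaries in years; `end_age - start_age`
#'   must be a multiple of the 5-year step.
#' @param init_category category of the whole cohort at `start_age`.
#' @return Object of class `cohort_config`.
#' @export
cohort_config <- function(initial_size = 1e6, start_age = 13,
                          end_age = 103, init_category = "NEVER") {
  if (initial_size <= 0) stop("initial_size must be positive")
  if (start_age >= end_age) stop("start_age must be below end_age")
  if ((end_age - start_age) %% 5 != 0)
    stop("end_age - start_age must be a multiple of 5")
  if (!init_category %in% .CATEGORIES) stop("unknown init_category")
  structure(list(initial_size = initial_size, start_age = start_age,
                 end_age = end_age, step = 5, init_category = init_category),
            class = "cohort_config")
}

#' Propagate a cohort through transitions and survival
#'
#' Deterministic expected-value propagation: at each 5-year step the state
#' mass is redistributed along the transition edges for the current age
#' band, durations advance according to the category occupied during the
#' interval, and a 5-year survival probability is applied. By default the
#' hazard of the destination state applies over the interval
#' (`hazard_timing = "destination"`); `"source"` applies the pre-transition
#' state's hazard instead. Mass is conserved exactly: survivors plus
#' cumulative deaths equal the initial size at every age.
#'
#' @param cfg a [cohort_config()].
#' @param table a [transition_table()] covering all simulated age bands.
#' @param models a [mortality_models()] bundle.
#' @param err an [err_params()] object.
#' @param hazard_timing `"destination"` (default) or `"source"`.
#' @param max_bins duration-counter cap in 5-year bins; hazards saturate
#'   once a counter reaches the cap, keeping covariates inside the fitted
#'   range.
#' @param switch_age,switch_table optionally switch to a second table for
#'   bands starting at or after `switch_age` (used by the multicohort
#'   runner when a scenario begins mid-life).
#' @param keep_occupancy retain the full state-by-age occupancy history.
#' @return Object of class `scenario_result`: `ages` (band starts plus
#'   final age), `lx` (survivors at each age), `deaths` per band,
#'   `occupancy` (a data.table of age, category, durations, mass when
#'   `keep_occupancy`), and the configuration.
#' @export
run_cohort <- function(cfg, table, models, err = err_params(),
                       hazard_timing = c("destination", "source"),
                       max_bins = 12L,
                       switch_age = NULL, switch_table = NULL,
                       keep_occupancy = TRUE) {
  hazard_timing <- match.arg(hazard_timing)
  stopifnot(inherits(cfg, "cohort_config"),
            inherits(table, "transition_table"),
            inherits(models, "mortality_models"))
  if (!is.null(switch_age) && is.null(switch_table))
    stop("switch_age given without switch_table")

  band_starts <- seq(cfg$start_age, cfg$end_age - cfg$step, by = cfg$step)
  states <- data.table::data.table(
    cat = cfg$init_category, ysm = 0L, yqsm = 0L, mst = 0L, yqmst = 0L,
    mass = as.numeric(cfg$initial_size))

  n <- length(band_starts)
  lx <- numeric(n + 1L); lx[1L] <- cfg$initial_size
  deaths <- numeric(n)
  occupancy <- if (keep_occupancy) vector("list", n + 1L)
  if (keep_occupancy)
    occupancy[[1L]] <- cbind(age = band_starts[1L], data.table::copy(states))

  for (s in seq_len(n)) {
    a <- band_starts[s]
    tab <- if (!is.null(switch_age) && a >= switch_age) switch_table else table
    r <- data.table::as.data.table(.rates_for_band(tab, a))

    if (nrow(r) > 0L) {
      out_by_src <- r[, list(p_out = sum(rate)), by = "from"]
      moved <- merge(states, r, by.x = "cat", by.y = "from",
                     allow.cartesian = TRUE)
      moved[, "mass" := moved$mass * moved$rate]
      moved[, "rate" := NULL]
      stay <- merge(states, out_by_src, by.x = "cat", by.y = "from",
                    all.x = TRUE)
      stay[is.na(stay$p_out), "p_out" := 0]
      stay[, "mass" := stay$mass * (1 - stay$p_out)]
      stay[, "p_out" := NULL]
      stay[, "to" := stay$cat]
      flows <- rbind(moved, stay, use.names = TRUE)
    } else {
      flows <- data.table::copy(states)
      flows[, "to" := flows$cat]
    }

    # durations accrue per the SOURCE category occupied during the interval
    d <- .advance_durations(flows$cat, flows$ysm, flows$yqsm, flows$mst,
                            flows$yqmst, max_bins)

    if (hazard_timing == "source") {
      h <- .hazard_vec(flows$cat, d$ysm * 5, d$yqsm * 5, d$mst * 5,
                       d$yqmst * 5, a + cfg$step / 2, models, err)
      flows[, "mass" := flows$mass * survival_5y(h)]
    }

    nxt <- data.table::data.table(cat = flows$to,
                                  ysm = as.integer(d$ysm),
                                  yqsm = as.integer(d$yqsm),
                                  mst = as.integer(d$mst),
                                  yqmst = as.integer(d$yqmst),
                                  mass = flows$mass)
    states <- nxt[, list(mass = sum(mass)),
                  by = c("cat", "ysm", "yqsm", "mst", "yqmst")]

    if (hazard_timing == "destination") {
      h <- .hazard_vec(states$cat, states$ysm * 5, states$yqsm * 5,
                       states$mst * 5, states$yqmst * 5,
                       a + cfg$step / 2, models, err)
      surv <- survival_5y(h)
      deaths[s] <- sum(states$mass * (1 - surv))
      states[, "mass" := states$mass * surv]
    } else {
      deaths[s] <- lx[s] - sum(states$mass)
    }
    states <- states[states$mass > 0]
    lx[s + 1L] <- sum(states$mass)
    if (keep_occupancy)
      occupancy[[s + 1L]] <- cbind(age = a + cfg$step,
                                   data.table::copy(states))
  }

  structure(list(config = cfg,
                 ages = c(band_starts, cfg$end_age),
                 lx = lx,
                 deaths = deaths,
                 total_deaths = sum(deaths),
                 occupancy = if (keep_occupancy)
                   data.table::rbindlist(occupancy)),
            class = "scenario_result")
}

#' @export
print.scenario_result <- function(x, ...) {
  cat(sprintf(
    "Cohort of %s from age %d to %d: %s survivors (%s deaths)\n",
    format(x$config$initial_size, big.mark = ","),
    x$config$start_age, x$config$end_age,
    format(round(x$lx[length(x$lx)]), big.mark = ","),
    format(round(x$total_deaths), big.mark = ",")))
  invisible(x)
}

#' Survivors at a given age
#'
#' @param result a [run_cohort()] result.
#' @param age a band boundary present in `result$ages`.
#' @return Number of survivors at the start of that age.
#' @export
survivors_at <- function(result, age) {
  i <- match(age, result$ages)
  if (is.na(i)) stop("age ", age, " is not a simulated band boundary")
  result$lx[i]
}

# shared-quantile table over the union of drawable rows of both tables
.shared_quantiles <- function(base, modified, classes) {
  rows <- unique(rbind(
    base[base$class %in% classes, c("age", "from", "to")],
    modified[modified$class %in% classes, c("age", "from", "to")]))
  rows$u <- stats::runif(nrow(rows))
  rows
}

#' Compare Base-Case and Modified-Case scenarios
#'
#' Runs both scenarios and reports, per age, the difference in survivors
#' (premature deaths prevented). With `n_draws > 0`, transition rates are
#' drawn from truncated normals ([draw_rates()]) and mortality coefficients
#' from their asymptotic posterior, with draws SHARED between the two
#' scenarios (common random numbers), so identical tables give exactly zero
#' differences. Reports the mean, SD and an equal-tailed 95% credible
#' interval of each age's difference across draws.
#'
#' @param cfg a [cohort_config()].
#' @param base_table,modified_table [transition_table()]s.
#' @param models a [mortality_models()] bundle (coefficient draws need a
#'   covariance, e.g. from [fit_mortality_model()]).
#' @param err an [err_params()] object.
#' @param n_draws posterior-predictive replicates (0 = deterministic only;
#'   the conventional full analysis uses 10,000).
#' @param seed integer seed for all randomness.
#' @param rate_sd truncated-normal SD of rate draws (probability points).
#' @param draw_classes edge classes subject to rate uncertainty.
#' @param draw_coefficients also draw mortality coefficients.
#' @param keep_draws retain the per-draw survivor-difference matrix.
#' @param ... passed to [run_cohort()] (e.g. `hazard_timing`, `max_bins`).
#' @return Object of class `scenario_comparison` with a `summary`
#'   data.frame (`age`, `base`, `modified`, `diff`, and with draws
#'   `diff_mean`, `diff_sd`, `ci_low`, `ci_high`).
#' @export
compare_scenarios <- function(cfg, base_table, modified_table, models,
                              err = err_params(), n_draws = 10000L,
                              seed = 1L, rate_sd = 0.02,
                              draw_classes = c("initiation", "cessation"),
                              draw_coefficients = TRUE,
                              keep_draws = FALSE, ...) {
  if (n_draws == 1L)
    stop("n_draws must be 0 (deterministic) or at least 2")
  run <- function(tab, mods)
    run_cohort(cfg, tab, mods, err, keep_occupancy = FALSE, ...)

  b0 <- run(base_table, models)
  m0 <- run(modified_table, models)
  ages <- b0$ages
  out <- data.frame(age = ages, base = b0$lx, modified = m0$lx,
                    diff = m0$lx - b0$lx)

  draws <- NULL
  if (n_draws > 0L) {
    set.seed(seed)
    draws <- matrix(NA_real_, nrow = n_draws, ncol = length(ages))
    for (d in seq_len(n_draws)) {
      q <- .shared_quantiles(base_table, modified_table, draw_classes)
      bt <- draw_rates(base_table, sd = rate_sd, classes = draw_classes,
                       quantiles = q)
      mt <- draw_rates(modified_table, sd = rate_sd, classes = draw_classes,
                       quantiles = q)
      mods <- if (draw_coefficients) .draw_models(models) else models
      draws[d, ] <- run(mt, mods)$lx - run(bt, mods)$lx
    }
    out$diff_mean <- colMeans(draws)
    out$diff_sd <- apply(draws, 2, stats::sd)
    out$ci_low <- apply(draws, 2, stats::quantile, probs = 0.025)
    out$ci_high <- apply(draws, 2, stats::quantile, probs = 0.975)
  }

  structure(list(summary = out, n_draws = n_draws, seed = seed,
                 draws = if (keep_draws) draws),
            class = "scenario_comparison")
}

#' @export
print.scenario_comparison <- function(x, ...) {
  cat("Scenario comparison (", x$n_draws, " draws)\n", sep = "")
  print(x$summary, row.names = FALSE)
  invisible(x)
}

#' Attribute deaths prevented to single transitions
#'
#' Applies the Modified-Case adjustment to one transition at a time, keeping
#' every other rate at its Base-Case value, and reports the survivors gained
#' at `at_age` for each, sorted in ascending order of benefit. The sum of
#' single-edge attributions need not equal the joint effect (transitions
#' interact through the shared state space).
#'
#' @param cfg a [cohort_config()].
#' @param base_table a [transition_table()].
#' @param delta a [scenario_delta()] with at least one component.
#' @param models,err as in [compare_scenarios()].
#' @param at_age age at which survivors are compared (default: final age).
#' @param ... passed to [run_cohort()].
#' @return data.frame with `label`, `from`, `to`, `deaths_prevented`,
#'   ascending.
#' @export
attribute_transitions <- function(cfg, base_table, delta, models,
                                  err = err_params(), at_age = NULL, ...) {
  stopifnot(inherits(delta, "scenario_delta"))
  n_edges <- nrow(delta$deltas)
  if (n_edges == 0 && delta$would_be_smoker == 0 &&
      delta$would_be_quitter == 0)
    stop("delta has no components to attribute")
  if (is.null(at_age)) at_age <- cfg$end_age

  base_run <- run_cohort(cfg, base_table, models, err,
                         keep_occupancy = FALSE, ...)
  base_l <- survivors_at(base_run, at_age)

  one <- function(d, label, from, to) {
    mod <- derive_modified_table(base_table, d)
    r <- run_cohort(cfg, mod, models, err, keep_occupancy = FALSE, ...)
    data.frame(label = label, from = from, to = to,
               deaths_prevented = survivors_at(r, at_age) - base_l,
               stringsAsFactors = FALSE)
  }

  res <- list()
  for (i in seq_len(n_edges)) {
    e <- delta$deltas[i, ]
    d <- scenario_delta(e, would_be_smoker = 0, would_be_quitter = 0)
    res[[length(res) + 1L]] <-
      one(d, paste0(e$from, "->", e$to), e$from, e$to)
  }
  if (delta$would_be_smoker > 0)
    res[[length(res) + 1L]] <- one(
      scenario_delta(NULL, would_be_smoker = delta$would_be_smoker,
                     would_be_quitter = 0),
      "would_be_smoker", "NEVER", "CUR_MST")
  if (delta$would_be_quitter > 0)
    res[[length(res) + 1L]] <- one(
      scenario_delta(NULL, would_be_smoker = 0,
                     would_be_quitter = delta$would_be_quitter),
      "would_be_quitter", "CUR_CIG", "CUR_MST")

  out <- do.call(rbind, res)
  out <- out[order(out$deaths_prevented), ]
  rownames(out) <- NULL
  out
}
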