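# Seeded generators for every input shape the pipeline reads: mortality
# person-year tables, transition tables, behavioural-intention summaries and
# birth-cohort sizes, with known ground truth for recovery tests.

#' Ground-truth mortality coefficients for the synthetic generator
#'
#' Gompertz-like (log-linear in age with mild curvature) never-user
#' mortality resembling a male life table, a smoking excess that grows with
#' years smoked and fades slightly with age, and a quitting benefit that
#' decays with age. On this truth, long-term smokers carry a relative risk
#' of roughly 2-2.7 versus never-users, and former smokers sit between
#' never and current users.
#'
#' @return Named list of coefficient vectors (`never`, `current`, `former`)
#'   in the canonical order used by [mortality_model_from_coef()].
#' @export
default_beta_truth <- function() {
  list(
    never = c(b0 = 3.55, b1_age = 0.0483, b2_age2 = 2e-4),
    current = c(b0 = 3.55, b1_age = 0.0483, b2_age2 = 2e-4,
                b3_ysm = 0.025, b4_ysm_age = -1e-4),
    former = c(b0 = 3.55, b1_age = 0.0483, b2_age2 = 2e-4,
               b3_ysm = 0.025, b4_yqsm = -0.012,
               b5_ysm_age = -1e-4, b6_yqsm_age = 1e-4)
  )
}

#' Ground-truth models from coefficient truth
#'
#' @param beta a [default_beta_truth()]-shaped list.
#' @return A [mortality_models()] bundle (no covariance: exact truth).
#' @export
truth_models <- function(beta = default_beta_truth()) {
  mortality_models(
    mortality_model_from_coef("never", beta$never),
    mortality_model_from_coef("current", beta$current),
    mortality_model_from_coef("former", beta$former))
}

#' Generate a synthetic person-years mortality dataset
#'
#' Emulates an insurance-cohort-style table of person-years and all-cause
#' deaths by age band, years smoked and years since quitting, for the three
#' user groups. Deaths are Poisson draws with mean
#' `person_years * rate(truth) / 100000` over a factorial grid respecting
#' the group constraints (never: no durations; current: no quit time).
#'
#' @param seed integer seed.
#' @param exposure person-years per never-user cell; current and former
#'   cells get half and a quarter of it, mimicking group sizes.
#' @param beta ground-truth coefficients, see [default_beta_truth()].
#' @param ages age-band midpoints.
#' @return Mortality records (see [validate_mortality_records()]) with the
#'   truth attached as attribute `"beta_truth"`.
#' @export
gen_mortality <- function(seed = 1L, exposure = 5e5,
                          beta = default_beta_truth(),
                          ages = seq(17.5, 92.5, by = 5)) {
  if (exposure <= 0) stop("exposure must be positive")
  set.seed(seed)
  models <- truth_models(beta)

  grids <- list()
  grids$never <- data.frame(age = ages, ysm = 0, yqsm = 0, group = "never",
                            person_years = exposure)
  cur <- do.call(rbind, lapply(ages[ages >= 20], function(a) {
    ysm <- seq(5, min(a - 15, 60), by = 5)
    data.frame(age = a, ysm = ysm, yqsm = 0, group = "current",
               person_years = exposure / 2)
  }))
  grids$current <- cur
  fmr <- do.call(rbind, lapply(ages[ages >= 25], function(a) {
    g <- expand.grid(ysm = seq(5, 55, by = 10), yqsm = seq(5, 55, by = 10))
    g <- g[g$ysm + g$yqsm <= a - 15, , drop = FALSE]
    if (nrow(g) == 0) return(NULL)
    data.frame(age = a, ysm = g$ysm, yqsm = g$yqsm, group = "former",
               person_years = exposure / 4)
  }))
  grids$former <- fmr

  rec <- do.call(rbind, grids)
  lam <- numeric(nrow(rec))
  for (g in .GROUPS) {
    i <- rec$group == g
    lam[i] <- predict_rate(models[[g]], rec$age[i], rec$ysm[i], rec$yqsm[i])
  }
  rec$deaths <- stats::rpois(nrow(rec), rec$person_years * lam / 1e5)
  rownames(rec) <- NULL
  rec <- rec[, c("age", "ysm", "yqsm", "person_years", "deaths", "group")]
  validate_mortality_records(rec)
  attr(rec, "beta_truth") <- beta
  rec
}

#' Fit the three mortality models to a synthetic dataset
#'
#' @param records output of [gen_mortality()] (or any valid records
#'   containing all three groups).
#' @return A [mortality_models()] bundle.
#' @export
fit_all_mortality_models <- function(records) {
  mortality_models(
    fit_mortality_model(records[records$group == "never", ], "never"),
    fit_mortality_model(records[records$group == "current", ], "current"),
    fit_mortality_model(records[records$group == "former", ], "former"))
}

#' Generate a transition table
#'
#' The `"paper-like"` preset encodes a two-product Base Case on a 0-100 age
#' grid: cigarette initiation concentrated at ages 10-30, MST initiation
#' 1.6% over the same window, switching from cigarettes to MST at 1.4%,
#' dual uptake 2%, resolution of dual use to exclusive MST at 17.4%,
#' age-increasing cigarette cessation, and zero relapse. With
#' `jitter_sd > 0`, rates are perturbed by seeded truncated-normal noise
#' (row sums re-validated), giving distinct but valid tables for property
#' tests.
#'
#' @param preset currently `"paper-like"`.
#' @param seed seed for the jitter.
#' @param jitter_sd SD of the optional rate perturbation.
#' @return A [transition_table()].
#' @export
gen_transitions <- function(preset = "paper-like", seed = 1L,
                            jitter_sd = 0) {
  preset <- match.arg(preset, "paper-like")
  ages <- seq(0, 100, by = 5)
  young <- ages >= 10 & ages <= 30
  adult <- ages >= 10

  edge_rows <- function(from, to, rate) {
    # full 0-100 coverage (zero rates below the initiation window) so the
    # same table serves cohorts started at any age
    data.frame(age = ages, from = from, to = to, rate = rate,
               stringsAsFactors = FALSE)
  }
  step_up <- function(breaks, values) {
    # values[i] applies from breaks[i] (0 before breaks[1])
    j <- findInterval(ages, breaks)
    ifelse(j == 0, 0, values[pmax(j, 1)])
  }

  tab <- rbind(
    edge_rows("NEVER", "CUR_CIG",
              step_up(c(10, 15, 20, 25, 30, 35), c(0.06, 0.10, 0.06, 0.02,
                                                   0.005, 0))),
    edge_rows("NEVER", "CUR_MST", ifelse(young, 0.016, 0)),
    edge_rows("CUR_CIG", "CUR_MST", ifelse(adult, 0.014, 0)),
    edge_rows("CUR_CIG", "DUAL", ifelse(adult, 0.020, 0)),
    edge_rows("CUR_CIG", "FORMER_CIG",
              step_up(c(10, 35, 60), c(0.08, 0.14, 0.22))),
    edge_rows("CUR_MST", "DUAL", ifelse(adult, 0.030, 0)),
    edge_rows("CUR_MST", "FORMER_MST", ifelse(adult, 0.10, 0)),
    edge_rows("DUAL", "CUR_MST", ifelse(adult, 0.174, 0)),
    edge_rows("DUAL", "CUR_CIG", ifelse(adult, 0.15, 0)),
    edge_rows("DUAL", "FORMER_ALL", ifelse(adult, 0.06, 0)),
    edge_rows("FORMER_CIG", "CUR_CIG", rep(0, length(ages))),
    edge_rows("FORMER_MST", "CUR_MST", rep(0, length(ages))),
    edge_rows("FORMER_ALL", "CUR_CIG", rep(0, length(ages))),
    edge_rows("FORMER_ALL", "CUR_MST", rep(0, length(ages)))
  )
  out <- transition_table(tab)
  if (jitter_sd > 0) {
    out <- draw_rates(out, sd = jitter_sd,
                      classes = unique(out$class), seed = seed)
  }
  out
}

#' Generate behavioural-intention summaries
#'
#' The `"paper-like"` preset carries the four published pre/post likelihood
#' proportions (percent) for the key transitions affected by a modified
#' risk claim: never-user MST initiation, smoker switching, smoker dual
#' uptake, and dual users moving to exclusive MST.
#'
#' @param preset currently `"paper-like"`.
#' @return data.frame with `behavior`, `from`, `to`, `control_pre`,
#'   `control_post`, `test_pre`, `test_post` (percent).
#' @export
gen_intentions <- function(preset = "paper-like") {
  preset <- match.arg(preset, "paper-like")
  data.frame(
    behavior = c("initiation", "switching", "dual_uptake", "dual_to_mst"),
    from = c("NEVER", "CUR_CIG", "CUR_CIG", "DUAL"),
    to = c("CUR_MST", "CUR_MST", "DUAL", "CUR_MST"),
    control_pre = c(3.06, 17.73, 24.04, 34.14),
    control_post = c(2.42, 15.87, 19.90, 32.38),
    test_pre = c(4.85, 13.99, 17.86, 35.48),
    test_post = c(3.65, 15.13, 18.33, 35.57),
    stringsAsFactors = FALSE
  )
}

#' Generate census-style birth-cohort sizes
#'
#' Quinquennial male birth-cohort sizes from 1910 to 2010, shaped like the
#' U.S. native-born series (interwar dip, post-war boom, late-century
#' recovery), in persons per 5-year period. With `jitter_sd > 0` a seeded
#' lognormal perturbation is applied.
#'
#' @param seed seed for the jitter.
#' @param jitter_sd SD of `log`-scale noise (0 = deterministic preset).
#' @return A [birth_cohorts()] object.
#' @export
gen_cohort_sizes <- function(seed = 1L, jitter_sd = 0) {
  sizes <- c(4.9, 5.2, 5.6, 5.3, 5.0, 5.7, 7.0, 8.7, 10.3, 9.6, 8.9,
             9.3, 9.7, 10.2, 9.8, 9.6, 10.1, 10.6, 10.9, 11.2, 11.5) * 1e6
  periods <- seq(1910, 2010, by = 5)
  if (jitter_sd > 0) {
    set.seed(seed)
    sizes <- sizes * exp(stats::rnorm(length(sizes), 0, jitter_sd))
  }
  birth_cohorts(data.frame(birth_period_start = periods,
                           initial_size = sizes,
                           vintage = "constant"))
}

#' Bundle the paper-like scenario world
#'
#' Everything a worked example needs: the Base-Case transition table, the
#' Modified-Case table derived from the bundled intention summaries (with
#' 1%/5% diversions), ERR ratios 0.09/0.04, ground-truth coefficients, and
#' mortality models fitted to one synthetic dataset.
#'
#' @param seed seed for the synthetic mortality dataset.
#' @param exposure person-years per never-user cell of that dataset.
#' @param use_rounded round intention-derived relative changes to whole
#'   percents before applying them.
#' @return List with `base_table`, `modified_table`, `delta`, `intentions`,
#'   `err`, `models` (fitted), `truth` (exact-coefficient models), and
#'   `catalogue`.
#' @export
preset_scenario <- function(seed = 1L, exposure = 5e5, use_rounded = FALSE) {
  intentions <- gen_intentions("paper-like")
  delta <- scenario_delta_from_intentions(intentions,
                                          would_be_smoker = 0.01,
                                          would_be_quitter = 0.05,
                                          use_rounded = use_rounded)
  base <- gen_transitions("paper-like")
  records <- gen_mortality(seed = seed, exposure = exposure)
  list(base_table = base,
       modified_table = derive_modified_table(base, delta),
       delta = delta,
       intentions = intentions,
       err = err_params(0.09, 0.04),
       models = fit_all_mortality_models(records),
       truth = truth_models(),
       catalogue = default_edge_catalogue())
}
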