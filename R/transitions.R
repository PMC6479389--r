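# Age-specific transition tables, behavioural-intention deltas, and
# truncated-normal rate uncertainty.

#' Construct a transition table
#'
#' Age-specific per-5-year transition probabilities on the edges of a use
#' catalogue. `age` is the start of a 5-year age band; a simulation step
#' beginning at age `a` uses the row with the largest tabulated `age <= a`,
#' so a table on the 0, 5, 10, ... grid serves cohorts started at any age.
#' For every `(age, from)` the outgoing rates must sum to at most 1; the
#' residual is the probability of staying.
#'
#' @param df data.frame with columns `age`, `from`, `to`, `rate` and
#'   optionally `class` (edge class, used by [draw_rates()]); missing
#'   classes are filled from the default catalogue.
#' @return The validated table, class `transition_table`.
#' @export
transition_table <- function(df) {
  df <- as.data.frame(df, stringsAsFactors = FALSE)
  need <- c("age", "from", "to", "rate")
  if (!all(need %in% names(df)))
    stop("transition table needs columns: ", paste(need, collapse = ", "))
  if (is.null(df$class)) {
    cat0 <- default_edge_catalogue()
    key <- paste(cat0$from, cat0$to)
    idx <- match(paste(df$from, df$to), key[cat0$class != "diversion"])
    df$class <- ifelse(is.na(idx), "other",
                       cat0$class[cat0$class != "diversion"][idx])
  }
  if (any(df$rate < 0 | df$rate > 1))
    stop("transition rates must lie in [0, 1]")
  if (any(df$from == df$to))
    stop("self-loops are implicit; remove explicit stay rows")
  if (anyDuplicated(df[, c("age", "from", "to")]))
    stop("duplicated (age, from, to) rows")
  sums <- stats::aggregate(rate ~ age + from, data = df, FUN = sum)
  bad <- sums$rate > 1 + 1e-9
  if (any(bad))
    stop("outgoing rates exceed 1 for (age, source): ",
         paste(sprintf("(%s, %s)", sums$age[bad], sums$from[bad]),
               collapse = ", "))
  df <- df[order(df$age, df$from, df$to),
           c("age", "from", "to", "rate", "class")]
  rownames(df) <- NULL
  class(df) <- c("transition_table", "data.frame")
  df
}

# rows applying to the band starting at `band_age` (positive rates only)
.rates_for_band <- function(table, band_age) {
  ages <- sort(unique(table$age))
  if (band_age < ages[1L])
    stop("transition table has no age band covering age ", band_age)
  a <- ages[findInterval(band_age, ages)]
  table[table$age == a & table$rate > 0, c("from", "to", "rate"), drop = FALSE]
}

#' Relative percent change between test and control pre/post proportions
#'
#' The effect of exposure to a modified-risk claim on a behavioural
#' intention is summarised as the relative difference between the test
#' condition's pre-to-post ratio and the control condition's:
#' `((test_post/test_pre) - (control_post/control_pre)) /
#' (control_post/control_pre)`. The result is a dimensionless relative
#' change (e.g. +0.21 for a 21 percent increase); it is invariant to the
#' scale of the proportions, so percent and fraction inputs give the same
#' answer.
#'
#' @param control_pre,control_post,test_pre,test_post strictly positive
#'   proportions (vectorised).
#' @return Numeric vector of relative changes.
#' @seealso [whole_percent()] for Table-style whole-percent reporting.
#' @export
relative_percent_change <- function(control_pre, control_post,
                                    test_pre, test_post) {
  vals <- cbind(control_pre, control_post, test_pre, test_post)
  if (any(vals <= 0))
    stop("all four proportions must be strictly positive (ratios are taken)")
  ctrl <- control_post / control_pre
  test <- test_post / test_pre
  (test - ctrl) / ctrl
}

#' Round a relative change to a whole percent
#'
#' Reporting helper: 0.20824 becomes 21. Internal propagation keeps the
#' unrounded value unless the rounded dialect is requested explicitly.
#'
#' @param delta relative change(s), dimensionless.
#' @return Integer percent value(s).
#' @export
whole_percent <- function(delta) round(100 * delta)

#' Apply a relative change to a transition rate
#'
#' Returns `rate * (1 + delta)`, clipped to the unit interval (with a
#' warning when clipping occurs). A delta of +0.21 turns a 1.4% rate into
#' 1.7% (one-decimal reporting); a delta of +1 doubles the rate.
#'
#' @param rate probability (or vector) in `[0, 1]`.
#' @param delta relative change `>= -1`.
#' @return Adjusted probability, in `[0, 1]`.
#' @export
apply_relative_change <- function(rate, delta) {
  if (any(rate < 0 | rate > 1)) stop("rate must lie in [0, 1]")
  if (any(delta < -1)) stop("delta must be >= -1")
  out <- rate * (1 + delta)
  if (any(out > 1)) {
    warning("adjusted rate capped at 1")
    out <- pmin(out, 1)
  }
  pmax(out, 0)
}

#' Scenario delta: edge-wise relative changes plus diversion fractions
#'
#' Bundles the Modified-Case adjustments: relative changes on named edges
#' (typically derived from a behavioural-intention study) and the two
#' hypothetical diversion fractions. `would_be_smoker` is the fraction of
#' the never-to-cigarette initiation flow diverted to MST initiation;
#' `would_be_quitter` is the fraction of the cigarette-cessation flow
#' diverted to switching. Defaults are the conventional 1% and 5%.
#'
#' @param deltas data.frame with columns `from`, `to`, `delta`
#'   (relative change `>= -1`), or `NULL` for none.
#' @param would_be_smoker,would_be_quitter diversion fractions in `[0, 1]`.
#' @return Object of class `scenario_delta`.
#' @export
scenario_delta <- function(deltas = NULL, would_be_smoker = 0.01,
                           would_be_quitter = 0.05) {
  if (is.null(deltas)) {
    deltas <- data.frame(from = character(), to = character(),
                         delta = numeric(), stringsAsFactors = FALSE)
  }
  deltas <- as.data.frame(deltas, stringsAsFactors = FALSE)
  if (!all(c("from", "to", "delta") %in% names(deltas)))
    stop("deltas needs columns from, to, delta")
  if (any(deltas$delta < -1)) stop("relative changes must be >= -1")
  if (would_be_smoker < 0 || would_be_smoker > 1 ||
      would_be_quitter < 0 || would_be_quitter > 1)
    stop("diversion fractions must lie in [0, 1]")
  structure(list(deltas = deltas,
                 would_be_smoker = would_be_smoker,
                 would_be_quitter = would_be_quitter),
            class = "scenario_delta")
}

#' Build a scenario delta from behavioural-intention summaries
#'
#' Applies [relative_percent_change()] to each row of an intention summary
#' (see [gen_intentions()] for the expected shape) and attaches the
#' diversion fractions.
#'
#' @param intentions data.frame with columns `from`, `to`, `control_pre`,
#'   `control_post`, `test_pre`, `test_post` (proportions, any scale).
#' @param use_rounded if `TRUE`, round each derived relative change to a
#'   whole percent before use, reproducing published whole-percent dialects;
#'   the default propagates unrounded values.
#' @inheritParams scenario_delta
#' @return Object of class `scenario_delta`.
#' @export
scenario_delta_from_intentions <- function(intentions,
                                           would_be_smoker = 0.01,
                                           would_be_quitter = 0.05,
                                           use_rounded = FALSE) {
  d <- relative_percent_change(intentions$control_pre, intentions$control_post,
                               intentions$test_pre, intentions$test_post)
  if (use_rounded) d <- whole_percent(d) / 100
  scenario_delta(data.frame(from = intentions$from, to = intentions$to,
                            delta = d, stringsAsFactors = FALSE),
                 would_be_smoker = would_be_smoker,
                 would_be_quitter = would_be_quitter)
}

#' Derive a Modified-Case transition table
#'
#' Scales the listed edges of a Base-Case table by their relative changes
#' and reroutes the two diversion flows: a `would_be_smoker` fraction of the
#' base never-to-cigarette initiation rate moves onto never-to-MST
#' initiation, and a `would_be_quitter` fraction of the base cigarette
#' cessation rate moves onto cigarette-to-MST switching. Diversions reroute
#' flow, so when only diversions are applied the outgoing probability mass
#' of each source category is conserved. Unlisted edges are unchanged and
#' row sums are re-validated.
#'
#' @param base a [transition_table()].
#' @param delta a [scenario_delta()].
#' @return A new `transition_table`.
#' @export
derive_modified_table <- function(base, delta) {
  stopifnot(inherits(base, "transition_table"),
            inherits(delta, "scenario_delta"))
  mod <- as.data.frame(base)
  key <- paste(mod$from, mod$to)
  for (i in seq_len(nrow(delta$deltas))) {
    e <- delta$deltas[i, ]
    hit <- key == paste(e$from, e$to)
    if (!any(hit))
      stop("delta edge (", e$from, ", ", e$to, ") not present in base table")
    mod$rate[hit] <- apply_relative_change(mod$rate[hit], e$delta)
  }

  divert <- function(tab, src_from, src_to, dst_to, frac) {
    if (frac == 0) return(tab)
    src <- tab$from == src_from & tab$to == src_to
    for (a in tab$age[src]) {
      take <- frac * base$rate[base$age == a & base$from == src_from &
                                 base$to == src_to]
      if (length(take) == 0 || take == 0) next
      j <- which(tab$age == a & tab$from == src_from & tab$to == src_to)
      tab$rate[j] <- tab$rate[j] - take
      if (tab$rate[j] < 0)
        stop("diversion exceeds available (", src_from, ", ", src_to,
             ") flow at age ", a)
      k <- which(tab$age == a & tab$from == src_from & tab$to == dst_to)
      if (length(k) == 1L) {
        tab$rate[k] <- tab$rate[k] + take
      } else {
        tab <- rbind(tab, data.frame(age = a, from = src_from, to = dst_to,
                                     rate = take,
                                     class = tab$class[j],
                                     stringsAsFactors = FALSE))
      }
    }
    tab
  }
  mod <- divert(mod, "NEVER", "CUR_CIG", "CUR_MST", delta$would_be_smoker)
  mod <- divert(mod, "CUR_CIG", "FORMER_CIG", "CUR_MST", delta$would_be_quitter)
  transition_table(mod)
}

# inverse-CDF draw from Normal(mean, sd) truncated to [lower, upper];
# u are Uniform(0,1) quantiles
.qtruncnorm <- function(u, mean, sd, lower = 0, upper = 1) {
  plo <- stats::pnorm(lower, mean, sd)
  phi <- stats::pnorm(upper, mean, sd)
  stats::qnorm(plo + u * (phi - plo), mean, sd)
}

#' Draw uncertain transition rates
#'
#' Replaces each initiation and cessation rate (by default) with a draw
#' from a normal distribution centred on the tabulated rate, truncated to
#' `[0, 1]`, with standard deviation `sd` (default 2 percentage points).
#' Rows of a source category whose drawn outgoing rates would exceed 1 are
#' redrawn. Supplying `quantiles` (a data.frame `age, from, to, u`) instead
#' of a seed makes draws shareable across scenarios (common random
#' numbers): identical tables then produce identical draws.
#'
#' @param table a [transition_table()].
#' @param sd standard deviation of the draw, probability points; `0`
#'   returns the means unchanged.
#' @param classes edge classes subject to uncertainty.
#' @param seed integer seed (ignored when `quantiles` is given).
#' @param quantiles optional pre-drawn uniforms keyed by `(age, from, to)`.
#' @param max_tries redraw attempts for the row-sum constraint.
#' @return A new `transition_table` of drawn rates.
#' @export
draw_rates <- function(table, sd = 0.02,
                       classes = c("initiation", "cessation"),
                       seed = NULL, quantiles = NULL, max_tries = 100L) {
  stopifnot(inherits(table, "transition_table"))
  if (sd < 0) stop("sd must be >= 0")
  if (sd == 0) return(table)
  out <- as.data.frame(table)
  idx <- which(out$class %in% classes)
  if (length(idx) == 0L) return(table)
  if (!is.null(quantiles)) {
    m <- match(paste(out$age[idx], out$from[idx], out$to[idx]),
               paste(quantiles$age, quantiles$from, quantiles$to))
    if (anyNA(m))
      stop("quantiles missing for some (age, from, to) rows")
    u <- quantiles$u[m]
  } else {
    if (!is.null(seed)) set.seed(seed)
    u <- stats::runif(length(idx))
  }
  uu <- u
  out$rate[idx] <- .qtruncnorm(uu, table$rate[idx], sd)

  # enforce the row-sum invariant by redrawing offending source rows; with
  # supplied quantiles the redraw sequence is a deterministic function of u
  # so common-random-number runs stay shared
  for (try in seq_len(max_tries)) {
    sums <- stats::aggregate(rate ~ age + from, data = out, FUN = sum)
    bad <- sums[sums$rate > 1, , drop = FALSE]
    if (nrow(bad) == 0L) break
    if (try == max_tries)
      stop("row-sum constraint unsatisfiable after ", max_tries, " redraws")
    redo_i <- paste(out$age[idx], out$from[idx]) %in% paste(bad$age, bad$from)
    if (!is.null(quantiles)) {
      uu[redo_i] <- (uu[redo_i] + 0.6180339887498949) %% 1
    } else {
      uu[redo_i] <- stats::runif(sum(redo_i))
    }
    out$rate[idx[redo_i]] <- .qtruncnorm(uu[redo_i], table$rate[idx[redo_i]], sd)
  }
  transition_table(out)
}
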