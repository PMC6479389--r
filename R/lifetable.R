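# Abridged life tables from survivor series, and scenario differences in
# survivors and remaining person-years.

#' Build an abridged life table
#'
#' From survivors `l_x` at the start of each 5-year band, computes
#' person-years lived in the band `L_x = 5 * (a * l_x + (1 - a) * l_{x+5})`
#' with `a = ax_fraction` (0.5 is the trapezoid: deaths uniform within the
#' band), cumulative remaining person-years `T_x` by backward summation, and
#' expectation of remaining life `e_x = T_x / l_x`. When the final band is
#' open-ended, its person-years are `l_final / h_final` (constant-hazard
#' closure) with `h_final` the per-person-year hazard, either supplied,
#' derived from `final_e` (`L = l * e`), or estimated from the mortality of
#' the last closed band.
#'
#' @param age band-start ages (increasing, 5 years apart).
#' @param lx survivors at each band start (non-increasing, positive at
#'   start). The last entry is the survivors entering the open-ended band.
#' @param open_final treat the last age as an open-ended band.
#' @param ax_fraction within-band person-year weighting toward the band
#'   start (0.5 = uniform deaths).
#' @param final_hazard per person-year hazard closing the open band.
#' @param final_e expectation of remaining life in the open band.
#' @return Object of class `life_table`: data.frame `age`, `lx`, `Lx`,
#'   `Tx`, `ex`.
#' @export
build_life_table <- function(age, lx, open_final = TRUE, ax_fraction = 0.5,
                             final_hazard = NULL, final_e = NULL) {
  n <- length(age)
  stopifnot(length(lx) == n, n >= 2)
  if (any(diff(age) != 5)) stop("age bands must be 5 years apart")
  if (lx[1] <= 0) stop("survivors must be positive at the first age")
  if (any(diff(lx) > 1e-9 * lx[1]))
    stop("survivor series must be non-increasing")
  if (ax_fraction < 0 || ax_fraction > 1) stop("ax_fraction must be in [0,1]")

  Lx <- numeric(n)
  Lx[-n] <- 5 * (ax_fraction * lx[-n] + (1 - ax_fraction) * lx[-1])
  if (open_final) {
    if (is.null(final_e)) {
      if (is.null(final_hazard)) {
        # constant-hazard estimate from the last closed band
        if (lx[n] <= 0 || lx[n - 1] <= 0) {
          final_hazard <- Inf
        } else {
          final_hazard <- -log(lx[n] / lx[n - 1]) / 5
        }
        if (final_hazard <= 0)
          stop("cannot derive a final-band hazard from a flat survivor tail; ",
               "supply final_hazard or final_e")
      }
      final_e <- 1 / final_hazard
    }
    Lx[n] <- lx[n] * final_e
  } else {
    Lx[n] <- 0
  }
  Tx <- rev(cumsum(rev(Lx)))
  ex <- ifelse(lx > 0, Tx / lx, 0)
  structure(data.frame(age = age, lx = lx, Lx = Lx, Tx = Tx, ex = ex),
            class = c("life_table", "data.frame"))
}

#' Life table from a cohort run
#'
#' Convenience wrapper: builds the life table from a [run_cohort()] result,
#' closing the open-ended final band with the hazard of the never-user model
#' at the final age unless told otherwise.
#'
#' @param result a [run_cohort()] result.
#' @param models optional [mortality_models()]; when given and no explicit
#'   closure is supplied, the never-user rate at the final age closes the
#'   open band.
#' @param ... passed to [build_life_table()].
#' @return A `life_table`.
#' @export
life_table_from_run <- function(result, models = NULL, ...) {
  dots <- list(...)
  if (is.null(dots$final_hazard) && is.null(dots$final_e) &&
      !is.null(models)) {
    dots$final_hazard <-
      predict_rate(models$never, result$ages[length(result$ages)]) / 1e5
  }
  do.call(build_life_table,
          c(list(age = result$ages, lx = result$lx), dots))
}

#' Wrap printed life-table columns
#'
#' Builds a minimal `life_table` from already-computed `l_x` and `T_x`
#' columns (e.g. a published table) so they can be differenced with
#' [additional_expected_years()].
#'
#' @param age band-start ages.
#' @param lx,Tx survivors and cumulative remaining person-years.
#' @return A `life_table` (with `Lx`/`ex` derived where possible).
#' @export
as_life_table <- function(age, lx, Tx) {
  stopifnot(length(age) == length(lx), length(lx) == length(Tx))
  if (any(diff(lx) > 0)) stop("survivor series must be non-increasing")
  structure(data.frame(age = age, lx = lx,
                       Lx = c(-diff(Tx), Tx[length(Tx)]),
                       Tx = Tx, ex = ifelse(lx > 0, Tx / lx, 0)),
            class = c("life_table", "data.frame"))
}

#' Additional survivors and years of expected life between scenarios
#'
#' Per-band differences `l_x(modified) - l_x(base)` and
#' `T_x(modified) - T_x(base)`: the additional survivors and the additional
#' cumulative years of life lived in the modified scenario.
#'
#' @param lt_modified,lt_base `life_table` objects on the same age bands.
#' @return data.frame `age`, `l_diff`, `T_diff`.
#' @export
additional_expected_years <- function(lt_modified, lt_base) {
  if (nrow(lt_modified) != nrow(lt_base) ||
      any(lt_modified$age != lt_base$age))
    stop("life tables have mismatched age bands")
  data.frame(age = lt_base$age,
             l_diff = lt_modified$lx - lt_base$lx,
             T_diff = lt_modified$Tx - lt_base$Tx)
}

#' Write a scenario life-table comparison as CSV
#'
#' Columns `age,l_m,T_m,l_b,T_b,l_diff,T_diff`.
#'
#' @param lt_modified,lt_base `life_table` objects on the same bands.
#' @param path file path.
#' @export
write_life_table_comparison <- function(lt_modified, lt_base, path) {
  d <- additional_expected_years(lt_modified, lt_base)
  out <- data.frame(age = d$age,
                    l_m = lt_modified$lx, T_m = lt_modified$Tx,
                    l_b = lt_base$lx, T_b = lt_base$Tx,
                    l_diff = d$l_diff, T_diff = d$T_diff)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
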