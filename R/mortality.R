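# Poisson mortality models with person-year offsets, excess-relative-risk
# scaling of smokeless-product hazards, and survival curves.

.GROUPS <- c("never", "current", "former")

# canonical coefficient names per group, in the order beta0, beta1, ...
.coef_names <- function(group) {
  switch(group,
         never = c("b0", "b1_age", "b2_age2"),
         current = c("b0", "b1_age", "b2_age2", "b3_ysm", "b4_ysm_age"),
         former = c("b0", "b1_age", "b2_age2", "b3_ysm", "b4_yqsm",
                    "b5_ysm_age", "b6_yqsm_age"),
         stop("unknown group: ", group))
}

# design matrix matching .coef_names(group)
.design <- function(group, age, ysm = 0, yqsm = 0) {
  n <- max(length(age), length(ysm), length(yqsm))
  age <- rep_len(age, n); ysm <- rep_len(ysm, n); yqsm <- rep_len(yqsm, n)
  switch(group,
         never = cbind(1, age, age^2),
         current = cbind(1, age, age^2, ysm, ysm * age),
         former = cbind(1, age, age^2, ysm, yqsm, ysm * age, yqsm * age))
}

#' Validate mortality records
#'
#' A mortality dataset holds one row per exposure cell: age-band midpoint,
#' years smoked (`ysm`), years since quitting (`yqsm`), person-years at
#' risk, all-cause deaths, and the user group (`never`, `current`,
#' `former`). Never-users must have `ysm = yqsm = 0`; current smokers must
#' have `yqsm = 0`.
#'
#' @param records data.frame with columns `age`, `ysm`, `yqsm`,
#'   `person_years`, `deaths`, `group`.
#' @return The records, invisibly, after validation.
#' @export
validate_mortality_records <- function(records) {
  need <- c("age", "ysm", "yqsm", "person_years", "deaths", "group")
  if (!all(need %in% names(records)))
    stop("mortality records need columns: ", paste(need, collapse = ", "))
  if (any(records$person_years <= 0)) stop("person_years must be positive")
  if (any(records$deaths < 0)) stop("deaths must be non-negative")
  if (!all(records$group %in% .GROUPS))
    stop("group must be one of: ", paste(.GROUPS, collapse = ", "))
  nv <- records$group == "never"
  if (any(records$ysm[nv] != 0 | records$yqsm[nv] != 0))
    stop("never-user records must have ysm = yqsm = 0")
  cu <- records$group == "current"
  if (any(records$yqsm[cu] != 0))
    stop("current-smoker records must have yqsm = 0")
  invisible(records)
}

#' Fit a Poisson mortality model
#'
#' Maximum-likelihood Poisson regression of death counts on the group's
#' design -- never-users: age and age squared; current smokers: plus years
#' smoked and its age interaction; former smokers: plus years since
#' quitting and its age interaction -- with `log(person_years / 100000)` as
#' exposure offset, so the linear predictor is the log mortality rate per
#' 100,000 person-years.
#'
#' @param records mortality records of a single group
#'   (see [validate_mortality_records()]).
#' @param group the group to fit; defaults to the records' group.
#' @return Object of class `mortality_model`: coefficients in canonical
#'   order, their covariance, and fit summaries.
#' @export
fit_mortality_model <- function(records, group = unique(records$group)) {
  if (length(group) != 1L) stop("records must belong to a single group")
  records <- records[records$group == group, , drop = FALSE]
  validate_mortality_records(records)
  if (nrow(records) == 0L) stop("no records for group ", group)
  if (sum(records$deaths) == 0)
    stop("degenerate likelihood: no deaths observed in group ", group)

  X <- .design(group, records$age, records$ysm, records$yqsm)
  if (qr(X)$rank < ncol(X))
    stop("singular design for group ", group, ": rank ", qr(X)$rank,
         " < ", ncol(X), " columns (", paste(.coef_names(group),
                                             collapse = ", "), ")")
  if (nrow(records) < ncol(X))
    stop("fewer records than coefficients for group ", group)

  dat <- data.frame(deaths = records$deaths, age = records$age,
                    ysm = records$ysm, yqsm = records$yqsm,
                    off = log(records$person_years / 1e5))
  form <- switch(group,
                 never = deaths ~ age + I(age^2),
                 current = deaths ~ age + I(age^2) + ysm + age:ysm,
                 former = deaths ~ age + I(age^2) + ysm + yqsm +
                   age:ysm + age:yqsm)
  fit <- stats::glm(form, family = stats::poisson(link = "log"),
                    data = dat, offset = off)
  if (!fit$converged) stop("Poisson fit did not converge for group ", group)
  if (anyNA(stats::coef(fit)))
    stop("aliased coefficients in group ", group, " fit")

  # reorder glm terms into the canonical beta order
  glm_names <- switch(group,
                      never = c("(Intercept)", "age", "I(age^2)"),
                      current = c("(Intercept)", "age", "I(age^2)", "ysm",
                                  "age:ysm"),
                      former = c("(Intercept)", "age", "I(age^2)", "ysm",
                                 "yqsm", "age:ysm", "age:yqsm"))
  beta <- stats::coef(fit)[glm_names]
  V <- stats::vcov(fit)[glm_names, glm_names]
  names(beta) <- .coef_names(group)
  dimnames(V) <- list(names(beta), names(beta))
  structure(list(group = group, coef = beta, vcov = V,
                 n = nrow(records),
                 deaths = sum(records$deaths),
                 fitted_deaths = sum(stats::fitted(fit)),
                 deviance = stats::deviance(fit)),
            class = "mortality_model")
}

#' @export
print.mortality_model <- function(x, ...) {
  cat("Poisson mortality model (", x$group, "), ", x$n, " cells, ",
      x$deaths, " deaths\n", sep = "")
  print(round(x$coef, 6))
  invisible(x)
}

#' Predicted mortality rate per 100,000 person-years
#'
#' @param model a [fit_mortality_model()] result (or a model built by
#'   [mortality_model_from_coef()]).
#' @param age age in years (vectorised).
#' @param ysm,yqsm duration covariates in years.
#' @return Rates per 100,000 person-years.
#' @export
predict_rate <- function(model, age, ysm = 0, yqsm = 0) {
  X <- .design(model$group, age, ysm, yqsm)
  r <- exp(drop(X %*% model$coef))
  if (any(!is.finite(r)))
    stop("non-finite mortality rate (extrapolation outside the fitted range?)")
  r
}

#' Build a mortality model from known coefficients
#'
#' Used for synthetic ground truth and for posterior coefficient draws.
#'
#' @param group one of `never`, `current`, `former`.
#' @param coef coefficient vector in canonical order
#'   (intercept, age, age^2, then group-specific terms).
#' @param vcov optional covariance matrix.
#' @return Object of class `mortality_model`.
#' @export
mortality_model_from_coef <- function(group, coef, vcov = NULL) {
  nm <- .coef_names(group)
  if (length(coef) != length(nm))
    stop("group ", group, " needs ", length(nm), " coefficients")
  coef <- stats::setNames(as.numeric(coef), nm)
  structure(list(group = group, coef = coef, vcov = vcov),
            class = "mortality_model")
}

#' Bundle the three group models
#'
#' @param never,current,former `mortality_model` objects of the matching
#'   groups.
#' @return Object of class `mortality_models`.
#' @export
mortality_models <- function(never, current, former) {
  stopifnot(inherits(never, "mortality_model"), never$group == "never",
            inherits(current, "mortality_model"), current$group == "current",
            inherits(former, "mortality_model"), former$group == "former")
  structure(list(never = never, current = current, former = former),
            class = "mortality_models")
}

# one draw of each model's coefficients from the asymptotic normal
# approximation to the posterior (flat prior); models without a covariance
# are returned unchanged
.draw_models <- function(models) {
  draw1 <- function(m) {
    if (is.null(m$vcov)) return(m)
    L <- chol(m$vcov)
    z <- stats::rnorm(length(m$coef))
    mortality_model_from_coef(m$group, m$coef + drop(crossprod(L, z)), m$vcov)
  }
  mortality_models(draw1(models$never), draw1(models$current),
                   draw1(models$former))
}

#' Excess relative risk ratio
#'
#' `(rr_product - 1) / (rr_cig - 1)`: the excess all-cause mortality risk of
#' a smokeless product relative to the excess risk of cigarette smoking,
#' both measured against never-users. 0 means no excess risk, 1 means
#' cigarette-equivalent risk.
#'
#' @param rr_product relative risk of the product vs never-users.
#' @param rr_cig relative risk of cigarette smoking vs never-users
#'   (must exceed 1).
#' @return The dimensionless ERR ratio.
#' @export
err_ratio <- function(rr_product, rr_cig) {
  if (any(rr_cig <= 1))
    stop("rr_cig must exceed 1 (cigarette smoking must carry excess risk)")
  (rr_product - 1) / (rr_cig - 1)
}

#' ERR parameters
#'
#' Excess-relative-risk ratios scaling smokeless-product hazards against
#' cigarette hazards: `err_current` for current MST use vs current smoking
#' (default 0.09, i.e. 91% less excess risk) and `err_former` for former
#' MST use vs former smoking (default 0.04). Values outside `[0, 1]` are
#' allowed with a warning.
#'
#' @param err_current,err_former dimensionless ERR ratios.
#' @return Object of class `err_params`.
#' @export
err_params <- function(err_current = 0.09, err_former = 0.04) {
  if (err_current < 0 || err_current > 1 || err_former < 0 || err_former > 1)
    warning("ERR ratios outside the conventional [0, 1] reference scale")
  structure(list(err_current = err_current, err_former = err_former),
            class = "err_params")
}

# Vectorised pathway hazard (per 100,000 person-years). Duration arguments
# are in YEARS. The hazard is the never-user rate times a smoking-history
# multiplier and an MST multiplier:
#   - current smokers and dual users: current-smoker RR(age, ysm); dual use
#     carries cigarette-level risk, so no MST term is added on top;
#   - anyone else with a smoking past: former-smoker RR(age, ysm, yqsm);
#   - current MST use: 1 + err_current * (current-smoker RR(age, MST
#     duration) - 1), MST years standing in on the YSM axis;
#   - former MST use: 1 + err_former * (former-smoker RR(age, MST duration,
#     years since quitting MST) - 1).
.hazard_vec <- function(cat, ysm, yqsm, mst, yqmst, age, models, err) {
  n <- length(cat)
  age <- rep_len(age, n)
  lam0 <- predict_rate(models$never, age)

  rr_smoke <- rep(1, n)
  i <- cat %in% .SMOKING_CATS
  if (any(i))
    rr_smoke[i] <- predict_rate(models$current, age[i], ysm = ysm[i]) / lam0[i]
  j <- !(cat %in% .SMOKING_CATS) & ysm > 0
  if (any(j))
    rr_smoke[j] <- predict_rate(models$former, age[j], ysm = ysm[j],
                                yqsm = yqsm[j]) / lam0[j]

  rr_mst <- rep(1, n)
  k <- cat == "CUR_MST"
  if (any(k)) {
    rr <- predict_rate(models$current, age[k], ysm = mst[k]) / lam0[k]
    rr_mst[k] <- 1 + err$err_current * (rr - 1)
  }
  l <- !(cat %in% c(.SMOKING_CATS, "CUR_MST")) & mst > 0
  if (any(l)) {
    rr <- predict_rate(models$former, age[l], ysm = mst[l],
                       yqsm = yqmst[l]) / lam0[l]
    rr_mst[l] <- 1 + err$err_former * (rr - 1)
  }

  h <- lam0 * pmax(rr_smoke, 0) * pmax(rr_mst, 0)
  if (any(!is.finite(h))) stop("non-finite pathway hazard")
  h
}

#' Pathway-specific mortality hazard
#'
#' All-cause mortality rate (per 100,000 person-years) for a cohort member
#' in a given expanded state at a given age, composed as the never-user
#' background rate times relative-risk multipliers for the member's smoking
#' history and smokeless-product use. MST multipliers are ERR-scaled
#' cigarette relative risks; dual use carries cigarette-level risk.
#'
#' @param state an [expanded_state()] (duration bins are 5 years each).
#' @param age age in years at which to evaluate (band midpoint in the
#'   engine).
#' @param models a [mortality_models()] bundle.
#' @param err an [err_params()] object.
#' @return Hazard per 100,000 person-years.
#' @export
pathway_hazard <- function(state, age, models, err = err_params()) {
  stopifnot(inherits(state, "expanded_state"))
  .hazard_vec(state$category, state$ysm * 5, state$yqsm * 5,
              state$mst * 5, state$yqmst * 5, age, models, err)
}

#' Five-year survival probability from a hazard
#'
#' Constant hazard within the interval: `exp(-5 * hazard / 100000)`.
#'
#' @param hazard rate per 100,000 person-years (vectorised, `>= 0`).
#' @return Survival probability over one 5-year interval.
#' @export
survival_5y <- function(hazard) {
  if (any(hazard < 0)) stop("hazard must be non-negative")
  exp(-5 * hazard / 1e5)
}

#' Cumulative survival curve along a use pathway
#'
#' Given the category occupied during each successive 5-year interval from
#' `start_age`, accrues durations with the state-machine bookkeeping and
#' returns the cumulative product of 5-year survival probabilities, each
#' interval evaluated at its age midpoint with end-of-interval durations.
#'
#' @param pathway character vector: category occupied during interval
#'   `i` (ages `start_age + 5 * (i - 1)` to `start_age + 5 * i`).
#' @param start_age age at the start of the first interval.
#' @param models a [mortality_models()] bundle.
#' @param err an [err_params()] object.
#' @param max_bins duration cap in 5-year bins.
#' @return data.frame with `age` (interval end), `hazard`, and cumulative
#'   `survival`.
#' @export
survival_curve <- function(pathway, start_age, models, err = err_params(),
                           max_bins = 12L) {
  if (!all(pathway %in% .CATEGORIES))
    stop("unknown category in pathway")
  # a pathway must be realisable: durations imply consistency, e.g. a
  # FORMER_CIG interval requires a prior smoking interval
  ysm <- 0L; yqsm <- 0L; mst <- 0L; yqmst <- 0L
  haz <- numeric(length(pathway))
  for (i in seq_along(pathway)) {
    cat_i <- pathway[i]
    ok <- switch(cat_i,
                 FORMER_CIG = ysm > 0L,
                 FORMER_MST = mst > 0L,
                 FORMER_DUAL = ,
                 FORMER_ALL = ysm > 0L || mst > 0L,
                 TRUE)
    if (!ok)
      stop("inconsistent pathway: ", cat_i, " at interval ", i,
           " without prior use history")
    d <- .advance_durations(cat_i, ysm, yqsm, mst, yqmst, max_bins)
    ysm <- d$ysm; yqsm <- d$yqsm; mst <- d$mst; yqmst <- d$yqmst
    haz[i] <- .hazard_vec(cat_i, ysm * 5, yqsm * 5, mst * 5, yqmst * 5,
                          start_age + 5 * (i - 1) + 2.5, models, err)
  }
  data.frame(age = start_age + 5 * seq_along(pathway),
             hazard = haz,
             survival = cumprod(survival_5y(haz)))
}

#' Read or write fitted mortality models as JSON
#'
#' @param models a [mortality_models()] bundle.
#' @param path file path.
#' @return `read_mortality_models()` returns a [mortality_models()] bundle.
#' @export
write_mortality_models <- function(models, path) {
  ser <- lapply(models[c("never", "current", "former")], function(m)
    list(group = m$group, coef = as.list(m$coef),
         vcov = if (!is.null(m$vcov)) unclass(m$vcov)))
  jsonlite::write_json(ser, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_mortality_models
#' @export
read_mortality_models <- function(path) {
  ser <- jsonlite::read_json(path, simplifyVector = TRUE)
  mk <- function(s) {
    v <- if (!is.null(s$vcov)) as.matrix(s$vcov)
    mortality_model_from_coef(s$group, unlist(s$coef), v)
  }
  mortality_models(mk(ser$never), mk(ser$current), mk(ser$former))
}
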