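test_that("a single cohort's snapshots equal the single-cohort run re-indexed", {
  w <- get_world()
  cohorts <- birth_cohorts(data.frame(birth_period_start = 1950,
                                      initial_size = 1e6,
                                      vintage = "constant"))
  snaps <- run_population(cohorts, list(constant = w$base_table),
                          w$models, w$err, horizon_year = 2030)
  single <- run_cohort(cohort_config(initial_size = 1e6, start_age = 0,
                                     end_age = 80),
                       w$base_table, w$models, w$err)
  for (a in seq(0, 80, by = 5)) {
    got <- snaps$count[snaps$year == 1950 + a & snaps$age == a]
    expect_equal(got, survivors_at(single, a), tolerance = 1e-12)
  }
  # ages beyond the modelled cohort are zero
  expect_equal(snaps$count[snaps$year == 1950 & snaps$age == 50], 0)
})

test_that("pure aging and linearity hold for multiple cohorts", {
  zero_tab <- transition_table(data.frame(age = 0, from = "NEVER",
                                          to = "CUR_CIG", rate = 0))
  cohorts <- birth_cohorts(data.frame(
    birth_period_start = c(1950, 1955), initial_size = c(2e5, 3e5),
    vintage = "constant"))
  snaps <- run_population(cohorts, list(constant = zero_tab),
                          zero_models(), horizon_year = 1990)
  # with no mortality and no transitions, counts are initial sizes
  # shifted along the age axis
  expect_equal(snaps$count[snaps$year == 1990 & snaps$age == 40], 2e5)
  expect_equal(snaps$count[snaps$year == 1990 & snaps$age == 35], 3e5)
  expect_equal(sum(snaps$count[snaps$year == 1990]), 5e5)

  # doubling the initial sizes doubles every snapshot count
  w <- get_world()
  small <- birth_cohorts(data.frame(birth_period_start = c(1950, 1955),
                                    initial_size = c(1e5, 2e5),
                                    vintage = "constant"))
  big <- birth_cohorts(data.frame(birth_period_start = c(1950, 1955),
                                  initial_size = 2 * c(1e5, 2e5),
                                  vintage = "constant"))
  s1 <- run_population(small, list(constant = w$base_table), w$models,
                       w$err, horizon_year = 1990)
  s2 <- run_population(big, list(constant = w$base_table), w$models,
                       w$err, horizon_year = 1990)
  expect_equal(s2$count, 2 * s1$count, tolerance = 1e-12)

  # a missing vintage is rejected by name
  odd <- birth_cohorts(data.frame(birth_period_start = 1950,
                                  initial_size = 1, vintage = "v1950"))
  expect_error(run_population(odd, list(constant = zero_tab), zero_models(),
                              horizon_year = 1990), "v1950")
})

test_that("aggregation sums printed per-age survivor differences exactly", {
  # published 60-year multicohort comparison, ages 0-84
  ages <- seq(0, 80, by = 5)
  base <- c(11659500, 11503227, 11343808, 11384863, 11210354, 10975342,
            10691192, 10397394, 10099412, 9783564, 9348637, 8747530,
            8038615, 7676364, 6873894, 5759539, 4749605)
  modified <- c(11659500, 11503227, 11343808, 11384863, 11210354, 10975495,
                10691665, 10398367, 10101332, 9787295, 9355425, 8757301,
                8050922, 7691177, 6889508, 5774009, 4761915)
  bsnap <- data.frame(year = 2075, age = ages, count = base)
  msnap <- data.frame(year = 2075, age = ages, count = modified)
  out <- total_deaths_prevented(bsnap, msnap, year = 2075,
                                age_range = c(0, 84))
  expect_identical(out$total, 93323)
  # no benefit below the first affected age band
  expect_identical(out$by_age$diff[out$by_age$age <= 20], rep(0, 5))
  # reversing the scenarios negates every difference
  rev <- total_deaths_prevented(msnap, bsnap, year = 2075)
  expect_identical(rev$by_age$diff, -out$by_age$diff)
  expect_identical(rev$total, -93323)
  expect_error(total_deaths_prevented(bsnap, msnap[-1, ], 2075),
               "mismatched")
})

test_that("reference validation reproduces the printed census comparison", {
  expect_equal(round(validate_against_reference(140297321, 137187000), 2),
               2.27)
  expect_equal(validate_against_reference(5, 5), 0)
  expect_equal(validate_against_reference(50, 100), -50)
  expect_error(validate_against_reference(1, 0), "non-zero")
})

test_that("a mid-history scenario switch only affects later years", {
  w <- get_world()
  cohorts <- birth_cohorts(data.frame(birth_period_start = c(1950, 1955),
                                      initial_size = c(5e5, 5e5),
                                      vintage = "constant"))
  base <- run_population(cohorts, list(constant = w$base_table), w$models,
                         w$err, horizon_year = 2010)
  mod <- run_population(cohorts, list(constant = w$base_table), w$models,
                        w$err, horizon_year = 2010,
                        modified_table = w$modified_table,
                        switch_year = 1990)
  expect_equal(mod$count[mod$year <= 1990], base$count[base$year <= 1990],
               tolerance = 1e-12)
  expect_gt(sum(mod$count[mod$year == 2010]),
            sum(base$count[base$year == 2010]))

  # cohort-size generator output feeds the runner directly
  sizes <- gen_cohort_sizes()
  expect_s3_class(sizes, "birth_cohorts")
  expect_true(all(sizes$initial_size > 0))
  expect_identical(gen_cohort_sizes(seed = 2, jitter_sd = 0.05),
                   gen_cohort_sizes(seed = 2, jitter_sd = 0.05))
})
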