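test_that("relative percent change reproduces the published worked rows", {
  intents <- gen_intentions("paper-like")
  rpc <- relative_percent_change(intents$control_pre, intents$control_post,
                                 intents$test_pre, intents$test_post)
  expect_identical(whole_percent(rpc), c(-5, 21, 24, 6))
  # unrounded switching value, frozen from the closed-form ratio arithmetic
  expect_equal(rpc[2], 0.2082395, tolerance = 1e-6)

  # identical pre-post change in both arms is a zero effect
  expect_equal(relative_percent_change(10, 8, 20, 16), 0)
  # scale invariance: percent and fraction inputs agree
  expect_equal(rpc, relative_percent_change(
    intents$control_pre / 100, intents$control_post / 100,
    intents$test_pre / 100, intents$test_post / 100))
  expect_error(relative_percent_change(0, 1, 1, 1), "strictly positive")
})

test_that("apply_relative_change matches worked examples and is monotone", {
  expect_equal(round(100 * apply_relative_change(0.014, 0.21), 1), 1.7)
  expect_equal(apply_relative_change(0.016, 1.0), 0.032)
  r <- c(0, 0.2, 0.9)
  expect_equal(apply_relative_change(r, 0), r)        # identity
  expect_equal(apply_relative_change(r, -1), c(0, 0, 0))
  deltas <- seq(-1, 1, by = 0.25)
  out <- vapply(deltas, function(d) apply_relative_change(0.3, d), numeric(1))
  expect_true(all(diff(out) >= 0))                    # monotone in delta
  expect_warning(out1 <- apply_relative_change(0.9, 1), "capped")
  expect_identical(out1, 1)
  expect_error(apply_relative_change(1.2, 0), "\\[0, 1\\]")
  expect_error(apply_relative_change(0.5, -2), ">= -1")
})

test_that("derive_modified_table scales edges and reroutes diversions", {
  base <- gen_transitions("paper-like")

  # no changes at all: Modified equals Base
  same <- derive_modified_table(base, scenario_delta(NULL, 0, 0))
  expect_equal(as.data.frame(same), as.data.frame(base))

  # the 21% switching delta turns 1.4% into 1.694% (diversions off)
  d <- scenario_delta(data.frame(from = "CUR_CIG", to = "CUR_MST",
                                 delta = 0.21),
                      would_be_smoker = 0, would_be_quitter = 0)
  mod <- derive_modified_table(base, d)
  sw <- mod$rate[mod$from == "CUR_CIG" & mod$to == "CUR_MST" & mod$age == 20]
  expect_equal(sw, 0.01694)

  # full would-be-smoker diversion reroutes the whole cigarette initiation
  d2 <- scenario_delta(NULL, would_be_smoker = 1, would_be_quitter = 0)
  mod2 <- derive_modified_table(base, d2)
  expect_equal(mod2$rate[mod2$from == "NEVER" & mod2$to == "CUR_CIG"],
               rep(0, sum(mod2$from == "NEVER" & mod2$to == "CUR_CIG")))
  expect_equal(
    mod2$rate[mod2$from == "NEVER" & mod2$to == "CUR_MST" & mod2$age == 15],
    0.016 + 0.10)

  # diversions alone conserve each source's outgoing probability mass
  d3 <- scenario_delta(NULL, would_be_smoker = 0.01, would_be_quitter = 0.05)
  mod3 <- derive_modified_table(base, d3)
  out_base <- aggregate(rate ~ age + from, as.data.frame(base), sum)
  out_mod <- aggregate(rate ~ age + from, as.data.frame(mod3), sum)
  m <- merge(out_base, out_mod, by = c("age", "from"))
  expect_equal(m$rate.x, m$rate.y, tolerance = 1e-12)

  # unknown edges and row-sum violations are rejected with names
  expect_error(derive_modified_table(
    base, scenario_delta(data.frame(from = "NEVER", to = "DUAL",
                                    delta = 0.5), 0, 0)),
    "not present")
  crowded <- transition_table(data.frame(
    age = 0, from = "CUR_CIG", to = c("CUR_MST", "FORMER_CIG"),
    rate = c(0.5, 0.45)))
  expect_error(
    suppressWarnings(derive_modified_table(
      crowded, scenario_delta(data.frame(from = "CUR_CIG", to = "CUR_MST",
                                         delta = 0.2), 0, 0))),
    "CUR_CIG")
})

test_that("rounded-delta dialect reproduces whole-percent arithmetic", {
  intents <- gen_intentions("paper-like")
  d <- scenario_delta_from_intentions(intents, 0, 0, use_rounded = TRUE)
  expect_equal(d$deltas$delta, c(-0.05, 0.21, 0.24, 0.06))
})

test_that("truncated-normal rate draws are centred, bounded and reproducible", {
  base <- gen_transitions("paper-like")

  # sd = 0 degenerates to the means
  expect_identical(draw_rates(base, sd = 0), base)

  # a rate of 0.5 far from the bounds keeps its mean under truncation
  # (10,000 independent age rows drawn in one vectorised call)
  tab <- transition_table(data.frame(age = seq_len(10000), from = "CUR_CIG",
                                     to = "FORMER_CIG", rate = 0.5))
  draws <- draw_rates(tab, sd = 0.02, seed = 99)$rate
  expect_lt(abs(mean(draws) - 0.5), 0.001)
  expect_true(all(draws >= 0 & draws <= 1))

  # determinism under a fixed seed
  a <- draw_rates(base, sd = 0.02, seed = 5)
  b <- draw_rates(base, sd = 0.02, seed = 5)
  expect_identical(a, b)
  # only initiation/cessation rates move by default
  moved <- a$rate != base$rate
  expect_true(all(a$class[moved] %in% c("initiation", "cessation")))
  # row sums still valid after drawing
  sums <- aggregate(rate ~ age + from, as.data.frame(a), sum)
  expect_true(all(sums$rate <= 1 + 1e-9))
})

test_that("transition tables validate rates and round-trip through CSV", {
  expect_error(transition_table(data.frame(age = 0, from = "NEVER",
                                           to = "CUR_CIG", rate = 1.2)),
               "\\[0, 1\\]")
  expect_error(transition_table(data.frame(
    age = 0, from = "DUAL", to = c("CUR_CIG", "CUR_MST"),
    rate = c(0.6, 0.6))), "exceed 1")

  base <- gen_transitions("paper-like")
  f <- withr::local_tempfile(fileext = ".csv")
  write_transition_table(base, f)
  expect_equal(as.data.frame(read_transition_table(f)),
               as.data.frame(base))
  # percent dialect reads back to the same fractions
  write_transition_table(base, f, percent = TRUE)
  expect_equal(read_transition_table(f)$rate, base$rate, tolerance = 1e-12)
})
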