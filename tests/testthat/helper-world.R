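# Shared fixtures: one cached paper-like scenario world (synthetic mortality
# data fitted once), toy catalogues, and an independent exhaustive-pathway
# oracle for the mass-flow engine.

.world_cache <- new.env(parent = emptyenv())

get_world <- function() {
  if (is.null(.world_cache$w))
    .world_cache$w <- preset_scenario(seed = 7, exposure = 2e5)
  .world_cache$w
}

# models under which nobody dies
zero_models <- function() {
  mortality_models(
    mortality_model_from_coef("never", c(-1e6, 0, 0)),
    mortality_model_from_coef("current", c(-1e6, 0, 0, 0, 0)),
    mortality_model_from_coef("former", c(-1e6, 0, 0, 0, 0, 0, 0)))
}

# a 4-category toy table (NEVER, CUR_CIG, CUR_MST, FORMER_CIG) on a single
# age row, for exhaustive-pathway comparisons
toy_table <- function(p_init = 0.3, p_switch = 0.2, p_quit = 0.3,
                      p_quit_mst = 0.1) {
  transition_table(data.frame(
    age = 0,
    from = c("NEVER", "CUR_CIG", "CUR_CIG", "CUR_MST"),
    to = c("CUR_CIG", "CUR_MST", "FORMER_CIG", "FORMER_MST"),
    rate = c(p_init, p_switch, p_quit, p_quit_mst)))
}

# Exhaustive pathway enumeration: expected survivors by age as the sum over
# all category pathways of pathway probability times pathway survival, with
# scalar duration bookkeeping. Independent of the data.table engine.
oracle_lx <- function(cfg, table, models, err, max_bins = 12L) {
  n_steps <- (cfg$end_age - cfg$start_age) / 5
  lx <- numeric(n_steps + 1)
  lx[1] <- cfg$initial_size
  ages <- sort(unique(table$age))
  rates_at <- function(a, cat) {
    aa <- ages[findInterval(a, ages)]
    r <- table[table$age == aa & table$from == cat & table$rate > 0, ]
    r[, c("to", "rate")]
  }
  recurse <- function(step, cat, ysm, yqsm, mst, yqm, w) {
    if (step > n_steps || w == 0) return()
    a <- cfg$start_age + (step - 1) * 5
    r <- rates_at(a, cat)
    dests <- c(r$to, cat)
    probs <- c(r$rate, 1 - sum(r$rate))
    smoking <- cat %in% c("CUR_CIG", "DUAL")
    musing <- cat %in% c("CUR_MST", "DUAL")
    ysm2 <- min(ysm + smoking, max_bins)
    yqsm2 <- min(yqsm + (ysm > 0 && !smoking), max_bins)
    mst2 <- min(mst + musing, max_bins)
    yqm2 <- min(yqm + (mst > 0 && !musing), max_bins)
    for (i in seq_along(dests)) {
      if (probs[i] <= 0) next
      st <- expanded_state(dests[i], ysm2, yqsm2, mst2, yqm2)
      h <- pathway_hazard(st, a + 2.5, models, err)
      w2 <- w * probs[i] * survival_5y(h)
      lx[step + 1] <<- lx[step + 1] + w2
      recurse(step + 1, dests[i], ysm2, yqsm2, mst2, yqm2, w2)
    }
  }
  recurse(1, cfg$init_category, 0L, 0L, 0L, 0L, cfg$initial_size)
  lx
}
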