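fast_durations <- list(hunt = c(1, 0.3), seal = c(1, 0.3),
                       break_in = c(0.3, 0.1), clean = c(0.5, 0.2),
                       screen = c(1, 0.2))

test_that("all-success patch-walking runs reproduce the closed-form yield", {
  for (n in c(4, 10, 25)) {
    cfg <- sim_config(n_cells = n, success_prob = 1,
                      stage_durations = fast_durations)
    s <- summarize_log(simulate_experiment(cfg, seed = 11))
    expect_equal(s$pairs, n - 1)
    expect_equal(s$probed_connections, 2 * (n - 1))
    expect_equal(s$probed_connections, patchwalk_possible_connections(n, 2))
  }
})

test_that("all-success traditional runs match the grouped closed form", {
  for (n in c(4, 10, 25)) {
    cfg <- sim_config(n_cells = n, success_prob = 1, strategy = "traditional",
                      stage_durations = fast_durations)
    s <- summarize_log(simulate_experiment(cfg, seed = 11))
    expect_equal(s$probed_connections, traditional_possible_connections(n, 2))
  }
})

test_that("zero success probability yields no whole cells and no pairs", {
  cfg <- sim_config(n_cells = 6, success_prob = 0,
                    stage_durations = fast_durations)
  s <- summarize_log(simulate_experiment(cfg, seed = 5))
  expect_equal(s$whole_cells, 0)
  expect_equal(s$pairs, 0)
  expect_equal(s$attempts, 6)
})

test_that("the same seed reproduces bit-identical logs and summaries", {
  cfg <- sim_config(n_cells = 9)
  a <- simulate_experiment(cfg, seed = 42)
  b <- simulate_experiment(cfg, seed = 42)
  expect_identical(a$events, b$events)
  expect_identical(a$pairs, b$pairs)
  expect_identical(summarize_log(a), summarize_log(b))
  c_ <- simulate_experiment(cfg, seed = 43)
  expect_false(identical(a$events, c_$events))
})

test_that("stochastic runs respect the structural invariants", {
  for (seed in 1:8) {
    cfg <- sim_config(n_cells = 9, stage_durations = fast_durations)
    log <- simulate_experiment(cfg, seed = seed)
    s <- summarize_log(log)
    expect_equal(s$probed_connections, 2 * s$pairs)
    expect_equal(s$attempts, s$whole_cells + sum(log$events$kind == "fail"))
    expect_lte(s$pairs, patchwalk_possible_connections(9, 2) / 2)
    # the log-derived pairing agrees with the scheduler's own record
    expect_equal(nrow(pairs_from_log(log)), s$pairs)
  }
})

test_that("simulated connection draws track the distance-decay model", {
  # pool directed probes over replicates; found counts should sit within
  # 4 SD of the sum of per-probe probabilities (Poisson-binomial mean)
  q_sum <- 0
  q_var <- 0
  found <- 0
  for (seed in 1:30) {
    cfg <- sim_config(n_cells = 8, success_prob = 1,
                      stage_durations = fast_durations)
    log <- simulate_experiment(cfg, seed = seed)
    q <- connection_probability(rep(log$pairs$distance_um, each = 2))
    q_sum <- q_sum + sum(q)
    q_var <- q_var + sum(q * (1 - q))
    found <- found + summarize_log(log)$found_connections
  }
  expect_lt(abs(found - q_sum), 4 * sqrt(q_var))
})

test_that("success rates are reported as one-decimal percentages", {
  mk_log <- function(attempts, successes) {
    n_fail <- attempts - successes
    rows <- lapply(seq_len(attempts), function(i) {
      kind <- if (i <= successes) c("whole_cell", "release") else "fail"
      data.frame(t = 10 * i + seq_along(kind), pipette = "a",
                 cell = i, kind = kind, cell2 = NA_integer_, connected = NA)
    })
    do.call(rbind, rows)
  }
  expect_equal(summarize_log(mk_log(136, 71))$success_rate_pct, 52.2)
  expect_equal(summarize_log(mk_log(18, 8))$success_rate_pct, 44.4)
  empty <- mk_log(1, 0)[0, ]
  s0 <- summarize_log(empty)
  expect_equal(s0$attempts, 0)
  expect_equal(s0$pairs, 0)
})

test_that("strategy comparison recovers the closed-form improvement at success 1", {
  det <- list(hunt = c(1, 0), seal = c(1, 0), break_in = c(0.3, 0),
              clean = c(0.5, 0), screen = c(1, 0))
  cfg <- sim_config(n_cells = 10, success_prob = 1, stage_durations = det)
  cmp <- compare_strategies(cfg, n_reps = 3, seed = 2)
  expect_equal(cmp$improvement_fraction, improvement(10, 2))
  # stochastic regime: failures cannot increase pairs beyond the ideal
  cfg2 <- sim_config(n_cells = 10, stage_durations = fast_durations)
  cmp2 <- compare_strategies(cfg2, n_reps = 4, seed = 7)
  mean_pw <- cmp2$means$pairs[cmp2$means$strategy == "patchwalk"]
  expect_lte(mean_pw, 9)
})

test_that("invalid configurations fail before any event", {
  expect_error(sim_config(n_cells = 9, success_prob = 1.4), "probability")
  expect_error(sim_config(n_cells = 9, n_pipettes = 4), "two-pipette")
  expect_error(sim_config(n_cells = 9,
                          stage_durations = list(hunt = c(-1, 0))), "hunt")
  expect_error(simulate_experiment(sim_config(n_cells = 6)), "seed")
})
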