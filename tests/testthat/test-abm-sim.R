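test_that("rate-to-probability discretisation is exact and monotone", {
  expect_identical(rate_to_probability(0, 0.01), 0)
  expect_equal(rate_to_probability(4.4, 0.01), 1 - exp(-0.044))
  expect_lt(abs(rate_to_probability(4.4, 0.01) - 0.043046), 1e-5)
  expect_gt(rate_to_probability(1e6, 1), 1 - 1e-9)
  rates <- seq(0, 10, by = 0.5)
  expect_true(all(diff(rate_to_probability(rates, 0.02)) > 0))
  p <- rate_to_probability(rates, 0.02)
  expect_true(all(p >= 0 & p < 1))
  expect_error(rate_to_probability(-1, 0.01), "non-negative")
  expect_error(rate_to_probability(1, 0), "positive")
})

test_that("new agents start in the state their source produces", {
  expect_identical(decide_new_agent_state("THYMUS"), "NAIVE")
  expect_identical(decide_new_agent_state("PERIPHERAL_PROLIFERATION"),
                   "NAIVE_FROM_PROLIFERATION")
  expect_identical(decide_new_agent_state("ACTIVE_REVERSION"), "MEMORY")
  expect_error(decide_new_agent_state("SPLEEN"), "unknown")
})

test_that("a run with no events is constant and runs are seed-reproducible", {
  actives <- fixture_actives()
  cfg <- abm_config(dt = 0.05, n_runs = 1, t_end = 10)
  sc0 <- null_scenario()
  still <- simulate_abm_run(sc0, actives, cfg, run_seed = 1)
  expect_identical(still$N, rep(3673, 11))
  expect_identical(still$Np, rep(0, 11))
  expect_identical(still$M, rep(0, 11))

  a <- simulate_abm_run(2, actives, cfg, run_seed = 42)
  b <- simulate_abm_run(2, actives, cfg, run_seed = 42)
  d <- simulate_abm_run(2, actives, cfg, run_seed = 43)
  expect_identical(as.data.frame(a), as.data.frame(b))
  expect_false(identical(a$N, d$N))
})

test_that("per-step bookkeeping conserves agents by state", {
  actives <- fixture_actives()
  cfg <- abm_config(dt = 0.02, n_runs = 1, t_end = 20)
  for (id in c(1, 2)) {
    traj <- simulate_abm_run(id, actives, cfg, run_seed = 9,
                             instrument = TRUE)
    ev <- attr(traj, "events")
    last <- length(traj$times)
    expect_identical(traj$N[last],
                     3673 + ev[["thymic"]] - ev[["n_death"]] -
                       ev[["n_conv"]])
    expect_identical(traj$Np[last],
                     ev[["n_conv"]] + ev[["np_birth"]] - ev[["np_death"]] +
                       ev[["m_rev"]])
    expect_identical(traj$M[last],
                     ev[["mem_arrivals"]] - ev[["m_death"]] - ev[["m_rev"]])
  }
})

test_that("ensemble mean is the pointwise mean with derived seeds", {
  actives <- fixture_actives()
  one <- simulate_abm_ensemble(3, actives,
                               abm_config(n_runs = 1, seed = 5, t_end = 5,
                                          dt = 0.05))
  expect_identical(one$mean$N, one$per_run[[1]]$N)
  expect_identical(one$seeds, 6L)

  ens <- simulate_abm_ensemble(3, actives,
                               abm_config(n_runs = 4, seed = 5, t_end = 5,
                                          dt = 0.05))
  expect_identical(ens$seeds, 5L + 1:4)
  manual <- rowMeans(sapply(ens$per_run, function(r) r$total_naive))
  expect_equal(ens$mean$total_naive, manual)
  ens2 <- simulate_abm_ensemble(3, actives,
                                abm_config(n_runs = 4, seed = 5, t_end = 5,
                                           dt = 0.05))
  expect_identical(ens2$mean$N, ens$mean$N)
  expect_identical(ens$mean$simulator, "ABM_MEAN")
})

test_that("ensemble mean converges to the deterministic trajectory", {
  # law of large numbers at desk scale: 20-run mean within 5% of SD over
  # a 30-year window wherever the population is appreciable
  actives <- fixture_actives()
  sd <- simulate_sd(2, actives, t_end = 30, dt = 0.01)
  ens <- simulate_abm_ensemble(2, actives,
                               abm_config(n_runs = 20, seed = 77,
                                          t_end = 30, dt = 0.01))
  keep <- sd$total_naive > 500
  rel <- abs(ens$mean$total_naive[keep] - sd$total_naive[keep]) /
    sd$total_naive[keep]
  expect_lt(max(rel), 0.05)
})

test_that("demographic noise shrinks as populations are scaled up", {
  # run-to-run variance of the total naive pool falls roughly as
  # 1/population when the initial count and thymic source are scaled 10x
  actives <- fixture_actives()
  cfg <- abm_config(n_runs = 12, seed = 21, t_end = 10, dt = 0.02)
  sc <- scenario_parameters(2)
  small <- simulate_abm_ensemble(sc, actives, cfg)
  sc10 <- sc
  sc10$parameters$s0 <- sc$parameters$s0 * 10
  sc10$parameters$np_bar <- sc$parameters$np_bar * 10
  big <- simulate_abm_ensemble(sc10, actives, cfg,
                               init = c(N = 36730, Np = 0, M = 0))
  at <- 11  # age 10
  cv2 <- function(e) {
    v <- vapply(e$per_run, function(r) r$total_naive[at], numeric(1))
    stats::var(v) / mean(v)^2
  }
  ratio <- cv2(small) / cv2(big)
  # expect about 10x reduction in squared CV; allow wide stochastic slack
  expect_gt(ratio, 3)
})

test_that("binomial and per-agent modes are statistically indistinguishable", {
  actives <- fixture_actives()
  cfg <- abm_config(n_runs = 20, seed = 31, t_end = 10, dt = 0.02)
  bin <- simulate_abm_ensemble(2, actives, cfg, mode = "binomial")
  agt <- simulate_abm_ensemble(2, actives, cfg, mode = "agent")
  p <- rank_sum_test(bin$mean$total_naive, agt$mean$total_naive)$p_value
  expect_gt(p, 0.05)
})

test_that("configuration validation rejects bad settings", {
  expect_error(abm_config(dt = 0.2), "dt")
  expect_error(abm_config(dt = 0.03), "evenly")
  expect_error(abm_config(n_runs = 0), "n_runs")
  expect_error(abm_config(t_end = -1), "t_end")
})
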