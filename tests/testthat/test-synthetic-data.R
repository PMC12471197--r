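test_that("simulated consumption respects bottle constraints and the seed", {
  cfg <- simulation_config(attack_rate = 1.2, handling_time = 0.03,
                           seed = 5L)
  ts1 <- suppressWarnings(simulate_trials(cfg))
  ts2 <- suppressWarnings(simulate_trials(cfg))
  expect_identical(ts1, ts2)
  expect_true(all(ts1$trials$consumed >= 0))
  expect_true(all(ts1$trials$consumed <= ts1$trials$density))
  expect_equal(nrow(ts1$trials), 6 * 4)

  ts3 <- suppressWarnings(
    simulate_trials(simulation_config(attack_rate = 1.2,
                                      handling_time = 0.03, seed = 6L)))
  expect_false(identical(ts1$trials$consumed, ts3$trials$consumed))
})

test_that("density substreams are stable when the design grows", {
  base <- simulation_config(attack_rate = 0.8, handling_time = 0.05,
                            densities = c(10, 20, 30), seed = 3L)
  wider <- simulation_config(attack_rate = 0.8, handling_time = 0.05,
                             densities = c(10, 15, 20, 25, 30), seed = 3L)
  t_base <- simulate_trials(base)$trials
  t_wide <- simulate_trials(wider)$trials
  for (N in c(10, 20, 30)) {
    expect_identical(t_base$consumed[t_base$density == N],
                     t_wide$consumed[t_wide$density == N])
  }
})

test_that("noise-free generation reproduces the disc-equation expectation", {
  cfg <- simulation_config(attack_rate = 1.276, handling_time = 0.023,
                           densities = c(10, 20, 30), noise = "none",
                           seed = 1)
  exact <- simulate_trials(cfg, round_noise_free = FALSE)$trials
  mu10 <- 1.276 * 10 / (1 + 1.276 * 0.023 * 10)
  expect_equal(exact$consumed[exact$density == 10], rep(mu10, 4),
               tolerance = 1e-12)
  rounded <- simulate_trials(cfg)$trials
  expect_equal(rounded$consumed[rounded$density == 10],
               rep(round_half_up(mu10), 4))
})

test_that("saturating attack rates clamp consumption at the prey offered", {
  cfg <- simulation_config(attack_rate = 1e6, handling_time = 1e-6,
                           seed = 2L)
  w <- capture_warnings(ts <- simulate_trials(cfg))
  expect_match(w, "clamped", all = TRUE)
  expect_length(w, length(cfg$densities))  # one clamp warning per density
  expect_identical(ts$trials$consumed, as.integer(ts$trials$density))
})

test_that("replicate means converge to the clamped expectation", {
  cfg <- simulation_config(attack_rate = 0.9, handling_time = 0.04,
                           replicates = 4000L, seed = 9L)
  ts <- simulate_trials(cfg)
  for (N in cfg$densities) {
    mu <- min(N, 0.9 * N / (1 + 0.9 * 0.04 * N))
    obs <- ts$trials$consumed[ts$trials$density == N]
    se <- sd(obs) / sqrt(length(obs))
    expect_lt(abs(mean(obs) - mu), 4 * se + 1e-9)
  }
})

test_that("simulated detection tables hit boundary rates and binomial means", {
  taxa <- data.frame(species = c("never", "always", "half"),
                     n_detected = c(30L, 30L, 66L),
                     true_rate = c(0, 1, 0.4242))
  dt <- simulate_detection_table(detection_sim_config(taxa, seed = 4L))
  expect_identical(dt$n_positive[dt$species == "never"], 0L)
  expect_identical(dt$n_positive[dt$species == "always"], 30L)
  expect_identical(simulate_detection_table(detection_sim_config(taxa, 4L)),
                   dt)
  expect_error(detection_sim_config(
    data.frame(species = "x", n_detected = 5, true_rate = 1.4)), "\\[0, 1\\]")

  # Monte-Carlo mean of positives over many seeded draws
  draws <- vapply(1:10000, function(s) {
    tab <- simulate_detection_table(detection_sim_config(
      data.frame(species = "e", n_detected = 66L, true_rate = 0.4242),
      seed = s))
    tab$n_positive
  }, integer(1))
  se <- sd(draws) / sqrt(length(draws))
  expect_lt(abs(mean(draws) - 66 * 0.4242), 3 * se)
})

test_that("noise-free recovery experiment has near-zero bias", {
  cfg <- simulation_config(attack_rate = 1.276, handling_time = 0.023,
                           densities = c(10, 15, 20, 25, 30),
                           noise = "none", seed = 1)
  rep1 <- recovery_experiment(cfg, n_runs = 1)
  expect_lt(abs(rep1$bias[["attack_rate"]]) / 1.276, 1e-5)
  expect_lt(abs(rep1$bias[["handling_time"]]) / 0.023, 1e-5)
  expect_identical(rep1$n_failed, 0L)
})

test_that("estimation bias shrinks as replication grows", {
  small <- simulation_config(attack_rate = 1.0, handling_time = 0.04,
                             replicates = 4L, seed = 21L)
  large <- simulation_config(attack_rate = 1.0, handling_time = 0.04,
                             replicates = 100L, seed = 21L)
  r_small <- recovery_experiment(small, n_runs = 20)
  r_large <- recovery_experiment(large, n_runs = 20)
  expect_lt(r_large$rmse[["attack_rate"]], r_small$rmse[["attack_rate"]])
  expect_lt(r_large$rmse[["handling_time"]],
            r_small$rmse[["handling_time"]])
  # classification frequency on clear Type II truth at high replication
  expect_gte(r_large$type_frequency[match("II", r_large$type_levels)], 0.9)
})
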