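test_that("response type follows the sign of the linear coefficient", {
  expect_identical(classify_response(-0.008), "II")
  expect_identical(classify_response(-0.105), "II")
  expect_identical(classify_response(0.02), "III")
  expect_identical(classify_response(0), "indeterminate")
  expect_error(classify_response(NaN), "finite")
  expect_error(classify_response(Inf), "finite")
})

test_that("cubic fit recovers generating coefficients exactly on noise-free data", {
  truth <- c(0.9, -0.01, 2e-4, -1e-6)
  ts <- cubic_trials(truth[1], truth[2], truth[3], truth[4])
  # exact data: lm warns that the fit is perfect, which is the point here
  fit <- suppressWarnings(fit_polynomial_type(ts))
  expect_lt(max(abs(fit$coefficients - truth)), 1e-9)
  # cross-check against a direct normal-equations solve
  oracle <- cubic_ols_oracle(ts$trials$density,
                             ts$trials$consumed / ts$trials$density)
  expect_equal(unname(fit$coefficients), oracle, tolerance = 1e-9)
  expect_identical(fit$response_type, "II")
  expect_gte(fit$r_squared, 0)
  expect_lte(fit$r_squared, 1)
})

test_that("cubic fit handles constant ratios and degenerate inputs", {
  dens <- c(5, 10, 15, 20, 25, 30)
  ts <- trial_set(data.frame(density = dens, consumed = 0.5 * dens),
                  predator_id = "flat")
  fit <- suppressWarnings(fit_polynomial_type(ts))  # perfect-fit warning
  expect_equal(unname(fit$coefficients), c(0.5, 0, 0, 0), tolerance = 1e-9)
  expect_identical(fit$response_type, "indeterminate")

  ts3 <- trial_set(data.frame(density = c(5, 10, 15), consumed = c(2, 4, 6)),
                   predator_id = "few")
  expect_error(fit_polynomial_type(ts3), "underdetermined")

  ts0 <- trial_set(data.frame(density = dens, consumed = rep(0, 6)),
                   predator_id = "none")
  expect_error(fit_polynomial_type(ts0), "degenerate")
})

test_that("cubic fit on hyperbolic Type II expectations classifies Type II", {
  # noise-free proportion curve from a saturating fit in the regime where
  # expected consumption never exceeds the prey offered
  cfg <- simulation_config(attack_rate = 1.339, handling_time = 0.022,
                           densities = c(12, 15, 20, 25, 30),
                           noise = "none", seed = 1)
  ts <- simulate_trials(cfg, round_noise_free = FALSE)
  fit <- fit_polynomial_type(ts)
  expect_lt(fit$coefficients[["b"]], 0)
  expect_identical(fit$response_type, "II")
})

test_that("binomial-GLM classification variant agrees on clear-cut data", {
  cfg <- simulation_config(attack_rate = 1.067, handling_time = 0.045,
                           replicates = 50L, seed = 11L)
  ts <- simulate_trials(cfg)
  ols <- fit_polynomial_type(ts, method = "ols")
  glmfit <- fit_polynomial_type(ts, method = "glm")
  expect_identical(ols$response_type, "II")
  expect_identical(glmfit$response_type, "II")
  expect_gt(ols$se_b, 0)
})

test_that("disc-equation fit recovers generating parameters on noise-free data", {
  for (model in c("II", "III")) {
    truth <- if (model == "II") c(a = 1.276, th = 0.023) else
      c(a = 0.05, th = 0.03)
    dens <- if (model == "II") c(10, 15, 20, 25, 30) else
      c(5, 10, 15, 20, 25, 30)
    cfg <- simulation_config(model = model, attack_rate = truth[["a"]],
                             handling_time = truth[["th"]],
                             densities = dens, noise = "none", seed = 1)
    ts <- simulate_trials(cfg, round_noise_free = FALSE)
    fit <- fit_holling(ts, model = model)
    expect_lt(abs(fit$attack_rate - truth[["a"]]) / truth[["a"]], 1e-6)
    expect_lt(abs(fit$handling_time - truth[["th"]]) / truth[["th"]], 1e-6)
    expect_true(fit$converged)
    expect_false(fit$boundary)
    expect_gt(fit$r_squared, 0.999)
  }
})

test_that("disc-equation NLS attains the exhaustive grid-search minimum", {
  cfg <- simulation_config(attack_rate = 1.2, handling_time = 0.03, seed = 7L)
  ts <- suppressWarnings(simulate_trials(cfg))
  fit <- fit_holling(ts, "II")
  nls_sse <- sum((ts$trials$consumed -
                    predict_consumption(fit, ts$trials$density))^2)
  expect_lte(nls_sse, grid_min_sse(ts) * (1 + 1e-8))
})

test_that("unsaturating (linear) data drives handling time to the bound", {
  dens <- rep(c(5, 10, 15, 20, 25, 30), each = 2)
  ts <- trial_set(data.frame(density = dens, consumed = 0.8 * dens),
                  predator_id = "linear")
  expect_warning(fit <- fit_holling(ts, "II"), "positivity bound")
  expect_equal(fit$attack_rate, 0.8, tolerance = 1e-3)
  expect_true(fit$boundary)
})

test_that("all-zero consumption is rejected as unidentifiable", {
  ts <- trial_set(data.frame(density = c(5, 10, 15, 20), consumed = rep(0, 4)),
                  predator_id = "nil")
  expect_error(fit_holling(ts, "II"), "no predation")
})

test_that("predicted consumption is monotone, zero at zero, and saturates at T/Th", {
  fit <- holling_fit(1.276, 0.023)
  expect_identical(predict_consumption(fit, 0), 0)
  expect_equal(predict_consumption(fit, 10), 12.76 / (1 + 0.029348 * 10),
               tolerance = 1e-12)
  dens <- seq(0, 100, by = 5)
  expect_true(all(diff(predict_consumption(fit, dens)) > 0))
  asym <- fit$exposure_T / fit$handling_time
  expect_lt(abs(predict_consumption(fit, 1e6) - asym) / asym, 0.01)
  expect_true(all(predict_consumption(fit, dens) <= asym))
  expect_error(predict_consumption(fit, -1), "non-negative")
})

test_that("derived metrics are T/Th and a'/Th", {
  expect_equal(unname(derived_metrics(holling_fit(1, 1))), c(1, 1))
  dm <- derived_metrics(holling_fit(1.067, 0.045))
  expect_equal(round_half_up(unname(dm), 2), c(22.22, 23.71))
  # consistency identity at full precision
  f <- holling_fit(1.339, 0.022, exposure_T = 2)
  dm <- derived_metrics(f)
  expect_equal(dm[["daily_max_predation"]], 2 / 0.022, tolerance = 1e-12)
  expect_equal(dm[["theoretical_predation"]], 1.339 / 0.022,
               tolerance = 1e-12)
})

test_that("search efficiency equals a' at N = 0 and decreases strictly in N", {
  fit <- holling_fit(1.067, 0.045)
  sc <- search_efficiency(fit, c(0, 5))
  expect_equal(sc$efficiency[1], fit$attack_rate)
  expect_equal(round_half_up(sc$efficiency[2], 2), 0.86)
  expect_error(search_efficiency(fit, c(-1, 5)), "non-negative")

  # property: strict monotone decrease over random positive parameters
  set.seed(101)
  for (i in 1:25) {
    f <- holling_fit(runif(1, 0.1, 3), runif(1, 0.005, 0.2))
    s <- search_efficiency(f, sort(runif(8, 0, 60)))$efficiency
    expect_true(all(diff(s) < 0))
  }
})

test_that("predators rank by theoretical predation with documented tie-breaks", {
  fits <- published_fits()
  for (stage in c("nymph_4_5", "adult")) {
    sub <- Filter(function(f) f$prey_stage == stage, fits)
    ranked <- rank_predators(sub)
    expect_identical(attr(ranked, "ranking")$predator,
                     c("O. sertatus", "E. tricuspidata", "X. ephippiatus",
                       "H. graminicola"))
  }
  one <- rank_predators(fits[1])
  expect_identical(one[[1]]$predator_id, fits[[1]]$predator_id)
  expect_error(rank_predators(list()), "non-empty")

  # tie on theoretical predation broken by daily max, then label
  a <- holling_fit(2, 0.04, predator_id = "beta")   # a'/Th = 50, T/Th = 25
  b <- holling_fit(1, 0.02, predator_id = "alpha")  # a'/Th = 50, T/Th = 50
  expect_identical(attr(rank_predators(list(a, b)), "ranking")$predator,
                   c("alpha", "beta"))
  b2 <- holling_fit(2, 0.04, predator_id = "alpha")
  expect_identical(attr(rank_predators(list(a, b2)), "ranking")$predator,
                   c("alpha", "beta"))
})

test_that("fits_table mirrors the parameter-table layout with report rounding", {
  tab <- fits_table(published_fits())
  expect_identical(names(tab),
                   c("predator", "prey_stage", "model", "a_prime", "Th", "T",
                     "r_squared", "T_over_Th", "aprime_over_Th"))
  row <- tab[tab$predator == "O. sertatus" & tab$prey_stage == "nymph_4_5", ]
  expect_equal(row$T_over_Th, 45.45)
  expect_equal(row$aprime_over_Th, 60.86)
})
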