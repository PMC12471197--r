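# Shared fixtures built from the package's bundled plain-text data and a few
# hand-constructed trial sets.

published_fits <- function() {
  hp <- predfr_holling_params()
  lapply(seq_len(nrow(hp)), function(i) {
    holling_fit(attack_rate = hp$attack_rate[i],
                handling_time = hp$handling_time[i],
                exposure_T = hp$exposure_T[i],
                predator_id = hp$predator[i],
                prey_stage = hp$prey_stage[i],
                r_squared = hp$r_squared[i])
  })
}

# trial set whose ratios follow a known cubic exactly (no noise)
cubic_trials <- function(a = 0.9, b = -0.01, c = 2e-4, d = -1e-6,
                         densities = c(5, 10, 15, 20, 25, 30)) {
  ratio <- a + b * densities + c * densities^2 + d * densities^3
  stopifnot(all(ratio >= 0 & ratio <= 1))
  trial_set(data.frame(density = densities, consumed = ratio * densities),
            predator_id = "cubic_truth")
}

# independent OLS oracle: solve the cubic normal equations directly
cubic_ols_oracle <- function(N, ratio) {
  X <- cbind(1, N, N^2, N^3)
  as.numeric(solve(t(X) %*% X, t(X) %*% ratio))
}

# exhaustive grid SSE oracle for the Type II disc equation
grid_min_sse <- function(trials, exposure_T = 1,
                         a_grid = seq(0.5, 2.0, by = 1e-3),
                         th_grid = seq(0.005, 0.08, by = 1e-3)) {
  N <- trials$trials$density
  Na <- trials$trials$consumed
  best <- Inf
  for (th in th_grid) {
    # vectorised over the attack-rate axis
    sse <- vapply(a_grid, function(a) {
      mu <- a * exposure_T * N / (1 + a * th * N)
      sum((Na - mu)^2)
    }, numeric(1))
    best <- min(best, min(sse))
  }
  best
}
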