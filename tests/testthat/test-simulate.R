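# Synthetic-data generator: latent dynamics, Poisson spiking, VAR realizations
# and dataset assembly.

test_that("latent rates sit at the fixed point when coupling and noise vanish", {
  cfg <- sim_config(n_neurons = 4, n_components = 2, n_correct = 1,
                    n_error = 0, n_baseline = 0, component_drive = 0.2,
                    self_decay = 0.5, noise_sd = 0,
                    loading_matrix = matrix(1, 4, 2),
                    component_coupling = matrix(0, 2, 2),
                    coupling_peak_gain = 1, seed = 3)
  Z <- simulate_latent_rates(cfg, "correct")
  expect_true(all(abs(Z - 0.2 / (1 - 0.5)) < 1e-12))
})

test_that("gain 1 makes correct and error trials identical for a given seed", {
  cfg <- sim_config(n_neurons = 6, n_components = 3, coupling_peak_gain = 1,
                    n_correct = 1, n_error = 1, n_baseline = 0, seed = 11)
  zc <- simulate_latent_rates(cfg, "correct", seed = 99)
  ze <- simulate_latent_rates(cfg, "error", seed = 99)
  expect_identical(unclass(zc), unclass(ze))
})

test_that("two-component chain matches an independent scalar recursion", {
  C <- matrix(0, 2, 2); C[2, 1] <- 0.6
  cfg <- sim_config(n_neurons = 4, n_components = 2, trial_duration = 50,
                    rt_time = 25, n_correct = 0, n_error = 1, n_baseline = 0,
                    component_drive = 0.5, self_decay = 0.3, noise_sd = 0.5,
                    loading_matrix = matrix(1, 4, 2), component_coupling = C,
                    coupling_peak_gain = 1, sample_dt = 0.01, seed = 21)
  Z <- simulate_latent_rates(cfg, "error", seed = 5, burn_in = 0)
  n <- ncol(Z)
  # independent scalar recursion, same seed discipline
  set.seed(5)
  innov <- matrix(rnorm(2 * (n - 1), 0, 0.5), 2, n - 1)
  z1 <- z2 <- numeric(n)
  z0 <- solve(diag(1, 2) - (diag(0.3, 2) + C), c(0.5, 0.5))
  z1[1] <- z0[1]; z2[1] <- z0[2]
  for (k in 2:n) {
    z1[k] <- max(0, 0.5 + 0.3 * z1[k - 1] + innov[1, k - 1])
    z2[k] <- max(0, 0.5 + 0.3 * z2[k - 1] + 0.6 * z1[k - 1] + innov[2, k - 1])
  }
  cc_pkg <- cor(Z[2, -1], Z[1, -n])
  cc_ora <- cor(z2[-1], z1[-n])
  expect_lt(abs(cc_pkg - cc_ora), 0.05)
})

test_that("spike counts follow the Poisson mean under constant intensity", {
  # near-zero loadings leave only the constant baseline intensity
  lam <- 5; dur <- 2; n_trials <- 200
  cfg <- sim_config(n_neurons = 4, n_components = 2, trial_duration = dur,
                    rt_time = 1, n_correct = 0, n_error = 0,
                    n_baseline = n_trials, baseline_rate = lam,
                    component_drive = 0, self_decay = 0.5, noise_sd = 0,
                    loading_matrix = matrix(1e-9, 4, 2),
                    component_coupling = matrix(0, 2, 2),
                    coupling_peak_gain = 1, seed = 31)
  ds <- build_dataset(cfg)
  counts <- vapply(ds$trials, function(tr)
    mean(vapply(tr$trains, function(s) length(s$times), 1L)), 1)
  se <- sqrt(lam * dur / (n_trials * 4))
  expect_lt(abs(mean(counts) - lam * dur), 3 * se)

  # doubling the intensity doubles the mean count within sampling error
  cfg2 <- sim_config(n_neurons = 4, n_components = 2, trial_duration = dur,
                     rt_time = 1, n_correct = 0, n_error = 0,
                     n_baseline = n_trials, baseline_rate = 2 * lam,
                     component_drive = 0, self_decay = 0.5, noise_sd = 0,
                     loading_matrix = matrix(1e-9, 4, 2),
                     component_coupling = matrix(0, 2, 2),
                     coupling_peak_gain = 1, seed = 31)
  ds2 <- build_dataset(cfg2)
  counts2 <- vapply(ds2$trials, function(tr)
    mean(vapply(tr$trains, function(s) length(s$times), 1L)), 1)
  expect_lt(abs(mean(counts2) - 2 * lam * dur), 3 * sqrt(2 * lam * dur / (n_trials * 4)))
})

test_that("zero intensity produces empty spike trains", {
  cfg <- sim_config(n_neurons = 3, n_components = 2, n_correct = 0,
                    n_error = 1, n_baseline = 0, baseline_rate = 0,
                    component_drive = 0, self_decay = 0.5, noise_sd = 0,
                    loading_matrix = matrix(1e-9, 3, 2),
                    component_coupling = matrix(0, 2, 2),
                    coupling_peak_gain = 1, seed = 3)
  latent <- simulate_latent_rates(cfg, "error")
  trains <- simulate_spike_trains(latent * 0, cfg)
  expect_true(all(vapply(trains, function(s) length(s$times), 1L) == 0))
})

test_that("VAR realization matches white-noise and Lyapunov oracles", {
  # all-zero coefficients: i.i.d. series, lag-1 autocorrelation near 0
  X <- simulate_var_series(matrix(0, 2, 2), diag(2), 5000, seed = 88)
  n <- nrow(X)
  for (j in 1:2) {
    expect_lt(abs(cor(X[-1, j], X[-n, j])), 3 / sqrt(n))
  }
  # bivariate AR(1) x -> y: variance of y matches discrete-Lyapunov iteration
  A <- matrix(0, 2, 2); A[2, 1] <- 0.5
  Y <- simulate_var_series(A, diag(2), 20000, seed = 9)
  S <- lyapunov_cov(A, diag(2))
  expect_lt(abs(var(Y[, 2]) - S[2, 2]) / S[2, 2], 0.05)
  # determinism
  expect_identical(simulate_var_series(A, diag(2), 100, seed = 4),
                   simulate_var_series(A, diag(2), 100, seed = 4))
  # unstable coefficients rejected
  expect_error(simulate_var_series(diag(1.01, 2), diag(2), 100, seed = 1),
               "unstable")
})

test_that("unstable latent coupling is rejected with the offending gain", {
  C <- matrix(0.5, 3, 3); diag(C) <- 0
  expect_error(
    sim_config(n_neurons = 6, n_components = 3, component_coupling = C,
               self_decay = 0.9, coupling_peak_gain = 2, seed = 1),
    "gain")
})

test_that("dataset assembly is deterministic and respects bookkeeping", {
  cfg <- tiny_sim_config(n_correct = 2, n_error = 1, n_baseline = 1, seed = 13)
  ds <- build_dataset(cfg)
  expect_length(ds$trials, 4)
  ids <- vapply(ds$trials, `[[`, "", "trial_id")
  expect_false(anyDuplicated(ids) > 0)
  for (tr in ds$trials) {
    for (st in tr$trains) {
      if (length(st$times)) {
        expect_true(all(diff(st$times) > 0))
        expect_true(st$times[1] >= tr$t_start &&
                      st$times[length(st$times)] <= tr$t_end)
      }
    }
  }
  ds2 <- build_dataset(cfg)
  expect_identical(as_spike_table(ds), as_spike_table(ds2))
  # empty dataset is valid
  ds0 <- build_dataset(tiny_sim_config(0, 0, 0))
  expect_length(ds0$trials, 0)
})

test_that("raising the coupling gain does not weaken peak lagged coupling", {
  base <- list(n_neurons = 4, n_components = 2, n_correct = 1, n_error = 0,
               n_baseline = 0, component_drive = 0.3, self_decay = 0.7,
               noise_sd = 0.5, loading_matrix = matrix(1, 4, 2),
               component_coupling = {C <- matrix(0, 2, 2); C[2, 1] <- 0.15; C},
               sample_dt = 0.01, seed = 17)
  peak_xcor <- function(gain) {
    cfg <- do.call(sim_config, c(base, list(coupling_peak_gain = gain)))
    vals <- vapply(1:8, function(k) {
      Z <- simulate_latent_rates(cfg, "correct", seed = 100 + k)
      sel <- which(attr(Z, "times") >= cfg$rt_time - 0.5 &
                     attr(Z, "times") <= cfg$rt_time)
      suppressWarnings(cor(Z[2, sel[-1]], Z[1, sel[-length(sel)]]))
    }, 1)
    mean(vals, na.rm = TRUE)
  }
  expect_gte(peak_xcor(3) + 0.02, peak_xcor(1))
})

test_that("spike tables round-trip through the TSV writer", {
  cfg <- tiny_sim_config(n_correct = 1, n_error = 1, n_baseline = 0, seed = 23)
  ds <- build_dataset(cfg)
  dir <- tempfile("spikegc")
  paths <- write_spike_dataset(ds, dir)
  expect_true(all(file.exists(paths)))
  ds2 <- read_spike_dataset(paths["spikes"], paths["events"],
                            n_neurons = cfg$n_neurons)
  expect_equal(as_spike_table(ds2), as_spike_table(ds), tolerance = 1e-8)
  expect_equal(as_events_table(ds2), as_events_table(ds))
  unlink(dir, recursive = TRUE)
})
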