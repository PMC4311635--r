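# Synthetic working-memory spike data with known ground-truth coupling.
#
# The generator emulates the structure of multi-electrode prefrontal
# recordings during a maze task: a small number of shared non-negative latent
# components drive the firing of all neurons; directed coupling among the
# components ramps up to a peak shortly before the behavioural reference time
# (RT, the maze choice point) in correct trials and stays flat in error and
# baseline trials.

#' Simulation configuration for synthetic spike-train datasets
#'
#' Builds and validates the parameter set for the synthetic working-memory
#' dataset generator. Neurons fire as inhomogeneous Poisson processes whose
#' intensity is `baseline_rate + loading_matrix %*% latent(t)`, where the
#' latent components follow a rectified first-order autoregression with
#' directed cross-coupling. In `"correct"` trials the cross-coupling is
#' multiplied by a ramp rising linearly over \[rt_time − 0.75, rt_time − 0.25\] s
#' from 1 to `coupling_peak_gain` and decaying linearly back to 1 by
#' rt_time + 0.25 s; in `"error"` and `"baseline"` trials the multiplier stays
#' at 1.
#'
#' @param n_neurons number of recorded units per trial.
#' @param n_components true latent rank (number of shared components).
#' @param trial_duration trial length in seconds.
#' @param rt_time reference time (choice point) within the trial, seconds.
#' @param n_correct,n_error,n_baseline trial counts per condition.
#' @param baseline_rate condition-independent firing rate added to every
#'   neuron, spikes/s.
#' @param component_drive constant drive of the latent autoregression
#'   (scalar or length `n_components`).
#' @param self_decay lag-1 self coefficient of each latent component (scalar
#'   or length `n_components`); sets the latent autocorrelation timescale
#'   `sample_dt / (1 - self_decay)`.
#' @param loading_matrix `n_neurons x n_components` non-negative weights
#'   mapping latent components to firing intensity (spikes/s per latent unit).
#'   Every row must contain at least one nonzero entry. Default: exclusive
#'   assembly membership -- each neuron belongs to exactly one component
#'   (round-robin) with weight U(12, 20), drawn reproducibly from `seed`.
#' @param component_coupling `n_components x n_components` directed
#'   cross-coupling matrix, entry `[i, j]` the influence of component j on
#'   component i at lag 1 (diagonal must be zero; self dynamics are
#'   `self_decay`). Default: disjoint one-way pairs `1 -> 2`, `3 -> 4`, ...
#'   with coefficient 0.15, so ground-truth edges exist without cascading
#'   amplification along a chain.
#' @param coupling_peak_gain unitless multiplier applied to
#'   `component_coupling` at the ramp peak (rt_time − 0.25 s) in correct
#'   trials.
#' @param noise_sd standard deviation of the latent innovations; scalar or
#'   length `n_components` (driver components can be noisier than driven
#'   ones).
#' @param sample_dt latent/intensity sampling interval, seconds.
#' @param silence_prob per-trial probability that any given neuron is silent
#'   (its loadings and baseline set to zero for that trial); default 0.
#' @param seed integer seed; the dataset is a deterministic function of the
#'   full configuration including the seed.
#'
#' @return an object of class `sim_config` (a validated list).
#'
#' @details Stability requires the effective lag-1 matrix
#'   `self_decay * I + g * component_coupling` to have spectral radius < 1 for
#'   every gain `g` up to `coupling_peak_gain`; configurations violating this
#'   are rejected with the offending gain reported.
#'
#' @examples
#' cfg <- sim_config(n_neurons = 8, n_components = 3,
#'                   n_correct = 2, n_error = 2, n_baseline = 2, seed = 1)
#' ds <- build_dataset(cfg)
#' length(ds$trials)
#' @export
sim_config <- function(n_neurons = 32,
                       n_components = 5,
                       trial_duration = 2.0,
                       rt_time = 1.5,
                       n_correct = 40,
                       n_error = 40,
                       n_baseline = 40,
                       baseline_rate = 1,
                       component_drive = -0.25,
                       self_decay = rep_len(c(0.95, 0.7), n_components),
                       loading_matrix = NULL,
                       component_coupling = NULL,
                       coupling_peak_gain = 3,
                       noise_sd = rep_len(c(1.2, 0.15), n_components),
                       sample_dt = 0.025,
                       silence_prob = 0,
                       seed = 1L) {
  stop_if_not_scalar_pos(trial_duration, "trial_duration")
  stop_if_not_scalar_pos(sample_dt, "sample_dt")
  if (!(rt_time > 0 && rt_time < trial_duration)) {
    stop("`rt_time` must satisfy 0 < rt_time < trial_duration", call. = FALSE)
  }
  counts <- c(n_correct = n_correct, n_error = n_error, n_baseline = n_baseline)
  if (any(counts < 0) || any(counts != round(counts))) {
    stop("trial counts must be non-negative integers", call. = FALSE)
  }
  if (n_neurons < 1 || n_components < 1) {
    stop("`n_neurons` and `n_components` must be >= 1", call. = FALSE)
  }
  if (baseline_rate < 0 || any(noise_sd < 0)) {
    stop("`baseline_rate` and `noise_sd` must be non-negative", call. = FALSE)
  }
  if (silence_prob < 0 || silence_prob > 1) {
    stop("`silence_prob` must lie in [0, 1]", call. = FALSE)
  }

  if (is.null(loading_matrix)) {
    loading_matrix <- default_loadings(n_neurons, n_components, seed)
  }
  loading_matrix <- as.matrix(loading_matrix)
  if (!all(dim(loading_matrix) == c(n_neurons, n_components))) {
    stop("`loading_matrix` must be n_neurons x n_components", call. = FALSE)
  }
  if (any(loading_matrix < 0)) {
    stop("`loading_matrix` entries must be >= 0", call. = FALSE)
  }
  if (any(rowSums(loading_matrix) == 0)) {
    stop("every neuron must load on at least one component", call. = FALSE)
  }

  if (is.null(component_coupling)) {
    component_coupling <- pair_coupling(n_components, 0.15)
  }
  component_coupling <- as.matrix(component_coupling)
  if (!all(dim(component_coupling) == c(n_components, n_components))) {
    stop("`component_coupling` must be n_components x n_components",
         call. = FALSE)
  }
  if (any(diag(component_coupling) != 0)) {
    stop("`component_coupling` diagonal must be zero (self dynamics come from `self_decay`)",
         call. = FALSE)
  }
  if (coupling_peak_gain < 0) {
    stop("`coupling_peak_gain` must be >= 0", call. = FALSE)
  }
  check_latent_stability(self_decay, component_coupling, coupling_peak_gain)

  cfg <- list(
    n_neurons = as.integer(n_neurons),
    n_components = as.integer(n_components),
    trial_duration = trial_duration,
    rt_time = rt_time,
    n_correct = as.integer(n_correct),
    n_error = as.integer(n_error),
    n_baseline = as.integer(n_baseline),
    baseline_rate = baseline_rate,
    component_drive = rep_len(component_drive, n_components),
    self_decay = rep_len(self_decay, n_components),
    loading_matrix = loading_matrix,
    component_coupling = component_coupling,
    coupling_peak_gain = coupling_peak_gain,
    noise_sd = rep_len(noise_sd, n_components),
    sample_dt = sample_dt,
    silence_prob = silence_prob,
    seed = as.integer(seed)
  )
  class(cfg) <- "sim_config"
  cfg
}

# Default loadings: exclusive assembly membership (each neuron belongs to one
# latent component, round-robin) with weight U(12, 20) spikes/s per latent
# unit. Exclusive membership is the classical cell-assembly picture and keeps
# the factorization identifiable.
default_loadings <- function(m, r, seed) {
  with_seed(seed, {
    L <- matrix(0, m, r)
    grp <- rep(seq_len(r), length.out = m)
    for (i in seq_len(m)) {
      L[i, grp[i]] <- stats::runif(1L, 12, 20)
    }
    L
  })
}

# Disjoint one-way pair coupling 1 -> 2, 3 -> 4, ... Nilpotent (no loops, no
# cascades), so the latent dynamics stay stable at any coupling gain.
pair_coupling <- function(r, coef) {
  C <- matrix(0, r, r)
  if (r >= 2) {
    for (j in seq(1L, r - 1L, by = 2L)) C[j + 1L, j] <- coef
  }
  C
}

self_matrix <- function(self_decay, r) {
  diag(rep_len(self_decay, r), nrow = r)
}

check_latent_stability <- function(self_decay, coupling, gain) {
  r <- nrow(coupling)
  for (g in unique(c(1, gain))) {
    rho <- spectral_radius(self_matrix(self_decay, r) + g * coupling)
    if (rho >= 1) {
      stop(sprintf(
        "unstable latent dynamics: spectral radius %.3f >= 1 at coupling gain %.3f",
        rho, g), call. = FALSE)
    }
  }
  invisible(TRUE)
}

# Ramp multiplier for the cross-coupling: 1 far from RT, linear rise over
# [rt - 0.75, rt - 0.25], peak `gain` at rt - 0.25, linear fall to 1 at
# rt + 0.25. Vectorised over t.
coupling_ramp <- function(t, rt, gain, rise = 0.5, peak_offset = 0.25,
                          fall = 0.5) {
  peak <- rt - peak_offset
  up <- 1 + (gain - 1) * (t - (peak - rise)) / rise
  down <- gain - (gain - 1) * (t - peak) / fall
  out <- rep(1, length(t))
  out[t > peak - rise & t <= peak] <- up[t > peak - rise & t <= peak]
  out[t > peak & t < peak + fall] <- down[t > peak & t < peak + fall]
  out
}

#' Simulate latent component rates for one trial
#'
#' Latent components follow a rectified (non-negative) first-order
#' autoregression `z(t) = max(0, d + (self_decay I + s(t) C) z(t-1) + e(t))`
#' with Gaussian innovations, where `C` is the directed cross-coupling and
#' `s(t)` the correct-trial ramp (identically 1 for error/baseline trials).
#' A seeded burn-in of `burn_in` steps at gain 1 precedes the trial so every
#' trial starts from the stationary flat-state distribution (no shared onset
#' transient).
#'
#' @param config a [sim_config()].
#' @param trial_kind one of `"correct"`, `"error"`, `"baseline"`.
#' @param seed RNG seed for this trial (defaults to `config$seed`).
#' @param burn_in discarded stationary warm-up steps before the trial start.
#' @return `n_components x n_samples` non-negative matrix with attributes
#'   `t0`, `dt` and `times`.
#' @export
simulate_latent_rates <- function(config,
                                  trial_kind = c("correct", "error", "baseline"),
                                  seed = config$seed, burn_in = 200L) {
  stopifnot(inherits(config, "sim_config"))
  trial_kind <- match.arg(trial_kind)
  check_latent_stability(config$self_decay, config$component_coupling,
                         config$coupling_peak_gain)
  r <- config$n_components
  tt <- time_grid(0, config$trial_duration, config$sample_dt)
  n <- length(tt)
  d <- config$component_drive
  Cc <- config$component_coupling
  phi1 <- self_matrix(config$self_decay, r) + Cc
  z0 <- pmax(0, solve(diag(1, r) - phi1, d))

  gain <- if (trial_kind == "correct") config$coupling_peak_gain else 1
  s <- coupling_ramp(tt, config$rt_time, gain)

  Z <- matrix(0, r, n)
  with_seed(seed, {
    z <- z0
    if (burn_in > 0) {
      warm <- matrix(stats::rnorm(burn_in * r, 0, config$noise_sd), r, burn_in)
      for (k in seq_len(burn_in)) {
        z <- pmax(0, d + phi1 %*% z + warm[, k])
      }
    }
    Z[, 1] <- z
    innov <- matrix(stats::rnorm((n - 1L) * r, 0, config$noise_sd), r, n - 1L)
    for (k in 2:n) {
      phi <- self_matrix(config$self_decay, r) + s[k] * Cc
      Z[, k] <- pmax(0, d + phi %*% Z[, k - 1L] + innov[, k - 1L])
    }
  })
  attr(Z, "t0") <- 0
  attr(Z, "dt") <- config$sample_dt
  attr(Z, "times") <- tt
  Z
}

#' Simulate spike trains from latent rates
#'
#' Each neuron fires as an inhomogeneous Poisson process with intensity
#' `baseline_rate + loading_matrix[i, ] %*% latent(t)`, realised by thinning a
#' homogeneous process at the trial-maximum intensity. Intensity between grid
#' points is linearly interpolated.
#'
#' @param latent `n_components x n_samples` matrix from
#'   [simulate_latent_rates()].
#' @param config the [sim_config()] used to generate `latent`.
#' @param seed RNG seed (defaults to `config$seed`).
#' @param silenced optional integer vector of neuron indices with zero
#'   intensity for this trial.
#' @return list of [spike_train()] objects, one per neuron.
#' @export
simulate_spike_trains <- function(latent, config, seed = config$seed,
                                  silenced = integer(0)) {
  stopifnot(inherits(config, "sim_config"))
  if (any(latent < 0)) stop("latent rates must be non-negative", call. = FALSE)
  tt <- attr(latent, "times") %||% time_grid(0, config$trial_duration,
                                             config$sample_dt)
  dur <- config$trial_duration
  Lam <- config$baseline_rate + config$loading_matrix %*% latent
  if (length(silenced)) Lam[silenced, ] <- 0
  stopifnot(all(Lam >= -1e-9))  # impossible by construction
  Lam[Lam < 0] <- 0

  with_seed(seed, {
    lapply(seq_len(config$n_neurons), function(i) {
      lam <- Lam[i, ]
      lmax <- max(lam)
      if (lmax <= 0) {
        return(spike_train(numeric(0), 0, dur, neuron_id = i))
      }
      n_cand <- stats::rpois(1L, lmax * dur)
      u <- sort(stats::runif(n_cand, 0, dur))
      lam_u <- stats::approx(tt, lam, xout = u, rule = 2)$y
      keep <- stats::runif(n_cand) < lam_u / lmax
      times <- unique(u[keep])
      spike_train(times, 0, dur, neuron_id = i)
    })
  })
}

#' Simulate an exact Gaussian VAR(p) time series
#'
#' Generates a realisation of `X(t) = sum_l A(l) X(t-l) + E(t)` with Gaussian
#' innovations, discarding a burn-in of at least `10 * p` samples so the
#' retained segment is effectively stationary.
#'
#' @param coeffs a single `N x N` matrix (VAR(1)) or a list of `p` such
#'   matrices `A(1) ... A(p)`.
#' @param noise_cov `N x N` symmetric positive-definite innovation covariance.
#' @param n_samples number of retained samples.
#' @param seed integer RNG seed.
#' @param burn_in discarded initial samples; raised to `10 * p` if smaller.
#' @return `n_samples x N` matrix (time in rows).
#' @export
simulate_var_series <- function(coeffs, noise_cov, n_samples, seed,
                                burn_in = NULL) {
  if (is.matrix(coeffs)) coeffs <- list(coeffs)
  p <- length(coeffs)
  N <- nrow(coeffs[[1]])
  stopifnot(all(vapply(coeffs, function(A) all(dim(A) == c(N, N)), logical(1))))
  noise_cov <- as.matrix(noise_cov)
  if (!isSymmetric(noise_cov, tol = 1e-10)) {
    stop("`noise_cov` must be symmetric", call. = FALSE)
  }
  comp <- companion_matrix(coeffs)
  rho <- spectral_radius(comp)
  if (rho >= 1) {
    stop(sprintf("unstable VAR coefficients (companion spectral radius %.3f >= 1)",
                 rho), call. = FALSE)
  }
  Lchol <- t(chol(noise_cov))  # fails for non-PD input
  burn_in <- max(burn_in %||% 0L, 10L * p)
  total <- burn_in + n_samples

  X <- matrix(0, total + p, N)
  with_seed(seed, {
    E <- matrix(stats::rnorm(total * N), total, N) %*% t(Lchol)
    for (t in (p + 1):(total + p)) {
      x <- E[t - p, ]
      for (l in seq_len(p)) x <- x + coeffs[[l]] %*% X[t - l, ]
      X[t, ] <- x
    }
  })
  X[(p + burn_in + 1):(p + total), , drop = FALSE]
}

companion_matrix <- function(coeffs) {
  p <- length(coeffs)
  N <- nrow(coeffs[[1]])
  comp <- matrix(0, N * p, N * p)
  for (l in seq_len(p)) {
    comp[1:N, ((l - 1) * N + 1):(l * N)] <- coeffs[[l]]
  }
  if (p > 1) {
    comp[(N + 1):(N * p), 1:(N * (p - 1))] <- diag(1, N * (p - 1))
  }
  comp
}

#' Build a complete synthetic spike dataset
#'
#' Generates `n_correct + n_error + n_baseline` trials. Trial `i` (in the
#' order correct, error, baseline) draws its latent rates and spikes from a
#' dedicated RNG substream seeded with `config$seed + i`, so any single trial
#' is reproducible in isolation and the dataset is byte-identical on re-run.
#'
#' @param config a [sim_config()].
#' @return an object of class `spike_dataset`: a list with `trials` (each a
#'   list with `trial_id`, `label`, `t_start`, `t_end`, `rt`, `trains`,
#'   `latent`, `silenced`) and `config` (the ground-truth configuration).
#' @export
build_dataset <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  labels <- c(rep("correct", config$n_correct),
              rep("error", config$n_error),
              rep("baseline", config$n_baseline))
  trials <- vector("list", length(labels))
  counter <- c(correct = 0L, error = 0L, baseline = 0L)
  for (i in seq_along(labels)) {
    lab <- labels[i]
    counter[lab] <- counter[lab] + 1L
    trial_seed <- config$seed + i
    silenced <- integer(0)
    if (config$silence_prob > 0) {
      silenced <- with_seed(trial_seed * 2L + 1L, {
        which(stats::runif(config$n_neurons) < config$silence_prob)
      })
    }
    latent <- simulate_latent_rates(config, lab, seed = trial_seed)
    trains <- simulate_spike_trains(latent, config, seed = trial_seed + 1L,
                                    silenced = silenced)
    trials[[i]] <- list(
      trial_id = sprintf("%s_%03d", lab, counter[lab]),
      label = lab,
      t_start = 0,
      t_end = config$trial_duration,
      rt = config$rt_time,
      trains = trains,
      latent = latent,
      silenced = silenced
    )
  }
  structure(list(trials = trials, config = config), class = "spike_dataset")
}

#' @export
print.spike_dataset <- function(x, ...) {
  labs <- vapply(x$trials, `[[`, "", "label")
  cat(sprintf("<spike_dataset> %d trials (%s), %d neurons\n",
              length(x$trials),
              paste(sprintf("%s: %d", names(table(labs)), table(labs)),
                    collapse = ", "),
              x$config$n_neurons))
  invisible(x)
}

#' Flatten a spike dataset to spike and event tables
#'
#' @param dataset a `spike_dataset`.
#' @return `as_spike_table()`: data.frame with columns `trial_id`,
#'   `neuron_id`, `spike_time_s`. `as_events_table()`: data.frame with columns
#'   `trial_id`, `t_start_s`, `t_end_s`, `rt_s`, `label`.
#' @export
as_spike_table <- function(dataset) {
  stopifnot(inherits(dataset, "spike_dataset"))
  rows <- lapply(dataset$trials, function(tr) {
    per_neuron <- lapply(tr$trains, function(st) {
      if (length(st$times) == 0) return(NULL)
      data.frame(trial_id = tr$trial_id, neuron_id = st$neuron_id,
                 spike_time_s = st$times)
    })
    do.call(rbind, per_neuron)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(trial_id = character(0), neuron_id = integer(0),
                      spike_time_s = numeric(0))
  }
  rownames(out) <- NULL
  out
}

#' @rdname as_spike_table
#' @export
as_events_table <- function(dataset) {
  stopifnot(inherits(dataset, "spike_dataset"))
  out <- do.call(rbind, lapply(dataset$trials, function(tr) {
    data.frame(trial_id = tr$trial_id, t_start_s = tr$t_start,
               t_end_s = tr$t_end, rt_s = tr$rt, label = tr$label)
  }))
  rownames(out) <- NULL
  out
}

#' Write / read a spike dataset as plain-text tables
#'
#' `write_spike_dataset()` writes `spikes.tsv` (trial_id, neuron_id,
#' spike_time_s), `events.tsv` (trial_id, t_start_s, t_end_s, rt_s, label) and
#' a `ground_truth.json` sidecar with the generating configuration.
#' `read_spike_dataset()` reconstructs a `spike_dataset` from the two tables
#' (without ground truth).
#'
#' @param dataset a `spike_dataset`.
#' @param dir output directory (created if missing).
#' @return `write_spike_dataset()`: invisibly, the paths written.
#' @export
write_spike_dataset <- function(dataset, dir) {
  stopifnot(inherits(dataset, "spike_dataset"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  spikes_path <- file.path(dir, "spikes.tsv")
  events_path <- file.path(dir, "events.tsv")
  gt_path <- file.path(dir, "ground_truth.json")
  utils::write.table(as_spike_table(dataset), spikes_path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(as_events_table(dataset), events_path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  cfg <- unclass(dataset$config)
  cfg$loading_matrix <- as.data.frame(cfg$loading_matrix)
  cfg$component_coupling <- as.data.frame(cfg$component_coupling)
  jsonlite::write_json(cfg, gt_path, auto_unbox = TRUE, digits = NA)
  invisible(c(spikes = spikes_path, events = events_path, ground_truth = gt_path))
}

#' @rdname write_spike_dataset
#' @param spikes,events paths to the spike and event TSV files, or data.frames
#'   in the same layout.
#' @param n_neurons total neuron count; defaults to the largest neuron id seen.
#' @export
read_spike_dataset <- function(spikes, events, n_neurons = NULL) {
  sp <- if (is.character(spikes)) {
    utils::read.delim(spikes, stringsAsFactors = FALSE)
  } else {
    as.data.frame(spikes)
  }
  ev <- if (is.character(events)) {
    utils::read.delim(events, stringsAsFactors = FALSE)
  } else {
    as.data.frame(events)
  }
  n_neurons <- n_neurons %||% max(sp$neuron_id, 1L)
  trials <- lapply(seq_len(nrow(ev)), function(k) {
    row <- ev[k, ]
    sub <- sp[sp$trial_id == row$trial_id, , drop = FALSE]
    trains <- lapply(seq_len(n_neurons), function(i) {
      times <- sort(sub$spike_time_s[sub$neuron_id == i])
      spike_train(times, row$t_start_s, row$t_end_s, neuron_id = i)
    })
    list(trial_id = row$trial_id, label = row$label, t_start = row$t_start_s,
         t_end = row$t_end_s, rt = row$rt_s, trains = trains,
         latent = NULL, silenced = integer(0))
  })
  structure(list(trials = trials, config = NULL), class = "spike_dataset")
}
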