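# Independent oracles and small fixture builders used across the test files.

# Exhaustive-enumeration global efficiency for small directed weighted graphs.
# lengths: N x N matrix of edge lengths (Inf where no edge). Returns the mean
# over ordered pairs of 1 / (shortest path length), unreachable pairs
# contributing 0. Enumerates all simple paths recursively -- no shortest-path
# library involved.
enum_efficiency <- function(lengths) {
  N <- nrow(lengths)
  shortest <- function(from, to) {
    best <- Inf
    visit <- function(node, dist, seen) {
      if (dist >= best) return(invisible())
      if (node == to) {
        best <<- dist
        return(invisible())
      }
      for (nxt in seq_len(N)) {
        if (!seen[nxt] && is.finite(lengths[node, nxt])) {
          seen2 <- seen
          seen2[nxt] <- TRUE
          visit(nxt, dist + lengths[node, nxt], seen2)
        }
      }
    }
    seen <- rep(FALSE, N)
    seen[from] <- TRUE
    visit(from, 0, seen)
    best
  }
  acc <- 0
  for (i in seq_len(N)) {
    for (j in seq_len(N)[-i]) {
      d <- shortest(i, j)
      if (is.finite(d) && d > 0) acc <- acc + 1 / d
    }
  }
  acc / (N * (N - 1))
}

# Discrete-Lyapunov stationary covariance of a VAR(1): iterate
# S <- A S A' + Q to convergence.
lyapunov_cov <- function(A, Q, iters = 10000, tol = 1e-12) {
  S <- Q
  for (k in seq_len(iters)) {
    S2 <- A %*% S %*% t(A) + Q
    if (max(abs(S2 - S)) < tol) return(S2)
    S <- S2
  }
  S
}

# Build a pruned gc_network by hand for the metric tests. F[i, j] = j -> i.
make_net <- function(Fm, mask = Fm > 0) {
  N <- nrow(Fm)
  structure(list(node_ids = as.character(seq_len(N)),
                 F = ifelse(mask, Fm, 0), F_raw = Fm,
                 pvalues = matrix(0.5, N, N), fstat = matrix(1, N, N),
                 sig_mask = mask, p = 1L, df1 = 1L, df2 = 10L, T_eff = 50L,
                 floored_frac = 0, ridge_used = FALSE,
                 invalid_pairs = matrix(FALSE, N, N),
                 padj = matrix(0.5, N, N), alpha = 0.05,
                 window_center = 0, space_tag = "original"),
            class = "gc_network")
}

# Homogeneous Poisson spike train on [0, dur].
make_poisson_train <- function(rate, dur, seed, neuron_id = 1) {
  set.seed(seed)
  n <- rpois(1, rate * dur)
  spike_train(sort(runif(n, 0, dur)), 0, dur, neuron_id = neuron_id)
}

# Regular train with fixed ISI.
make_regular_train <- function(isi, dur, t0 = isi / 2, neuron_id = 1) {
  spike_train(seq(t0, dur, by = isi), 0, dur, neuron_id = neuron_id)
}

# Trapezoid quadrature of a rate_series over its grid.
trapz_rate <- function(rs) {
  v <- rs$values
  sum((v[-1] + v[-length(v)]) / 2) * rs$dt
}

# Small sim_config for fast pipeline tests (3 assemblies, 9 neurons).
tiny_sim_config <- function(n_correct = 3, n_error = 3, n_baseline = 3,
                            seed = 7, ...) {
  sim_config(n_neurons = 9, n_components = 3, trial_duration = 1.5,
             rt_time = 1.0, n_correct = n_correct, n_error = n_error,
             n_baseline = n_baseline, seed = seed, ...)
}
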