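# VAR fitting, order selection, conditional Granger causality and pruning.

test_that("an exact deterministic VAR(1) is recovered to numerical precision", {
  A <- matrix(c(0.9, 0.3, 0, 0.5), 2, 2, byrow = TRUE)
  X <- matrix(0, 15, 2)
  X[1, ] <- c(2, -1)
  for (t in 2:15) X[t, ] <- A %*% X[t - 1, ]
  fit <- fit_var(X, p = 1)
  expect_lt(max(abs(fit$coeffs[[1]] - A)), 1e-6)
  expect_false(fit$ridge_used)
})

test_that("white-noise coefficients shrink at the OLS rate", {
  set.seed(12)
  X <- matrix(rnorm(10000 * 3), ncol = 3)
  fit <- fit_var(X, p = 1)
  A <- fit$coeffs[[1]]
  expect_lt(max(abs(A[row(A) != col(A)])), 3 / sqrt(10000))
})

test_that("omitting a variable shrinks the model bookkeeping", {
  set.seed(13)
  X <- matrix(rnorm(500 * 4), ncol = 4)
  fit <- fit_var(X, p = 2, omit = 3)
  expect_equal(fit$n_vars, 3L)
  expect_equal(dim(fit$resid_cov), c(3L, 3L))
  expect_length(fit$coeffs, 2L)
  expect_equal(dim(fit$coeffs[[1]]), c(3L, 3L))
})

test_that("bivariate causality matches the closed form ln(1 + c^2)", {
  A <- matrix(0, 2, 2); A[2, 1] <- 0.5
  X <- simulate_var_series(A, diag(2), 20000, seed = 42)
  net <- conditional_gc(X, p = 1)
  expect_lt(abs(net$F[2, 1] - log(1.25)) / log(1.25), 0.10)
  expect_lt(net$F[1, 2], 0.01)
  pruned <- significance_filter(net, alpha = 0.05)
  expect_true(pruned$sig_mask[2, 1])
  expect_false(pruned$sig_mask[1, 2])
})

test_that("conditional GC on two variables equals an independent pairwise fit", {
  # oracle: residual variances from explicit lm() regressions
  A <- matrix(c(0.4, 0.2, 0.3, 0.1), 2, 2)
  X <- simulate_var_series(A, diag(2), 3000, seed = 17)
  net <- conditional_gc(X, p = 1)
  Xc <- scale(X, center = TRUE, scale = FALSE)
  n <- nrow(Xc)
  y2 <- Xc[2:n, 2]
  full <- lm(y2 ~ 0 + Xc[1:(n - 1), 1] + Xc[1:(n - 1), 2])
  restr <- lm(y2 ~ 0 + Xc[1:(n - 1), 2])
  f_oracle <- log(mean(residuals(restr)^2) / mean(residuals(full)^2))
  expect_equal(net$F[2, 1], f_oracle, tolerance = 1e-6)
})

test_that("BIC selects the generating order for VAR(1) data and white noise", {
  A <- matrix(c(0.5, 0.2, 0, 0, 0.4, 0.2, 0.1, 0, 0.3), 3, 3)
  hits <- 0L
  for (k in 1:20) {
    X <- simulate_var_series(A, diag(3), 5000, seed = 100 + k)
    if (as.integer(select_order(X, p_max = 3)) == 1L) hits <- hits + 1L
  }
  expect_gte(hits, 18L)  # >= 90% of runs
  hits_wn <- 0L
  for (k in 1:20) {
    set.seed(200 + k)
    X <- matrix(rnorm(1000 * 3), ncol = 3)
    if (as.integer(select_order(X, p_max = 3)) == 1L) hits_wn <- hits_wn + 1L
  }
  expect_gte(hits_wn, 18L)
  # p_max = 1 always yields 1
  expect_equal(as.integer(select_order(matrix(rnorm(300), ncol = 3), p_max = 1)), 1L)
  expect_error(select_order(matrix(rnorm(12), 4, 3), p_max = 3), "insufficient")
})

test_that("pruning zeroes what the FDR-corrected F-tests reject", {
  set.seed(19)
  X <- matrix(rnorm(400 * 3), ncol = 3)
  net <- conditional_gc(X, p = 1)
  net$pvalues[] <- 1
  pruned <- significance_filter(net, alpha = 0.05)
  expect_true(all(!pruned$sig_mask))
  expect_true(all(pruned$F == 0))
  # a strong edge among four nodes survives in nearly every run
  A <- matrix(0, 4, 4); A[2, 1] <- 0.9
  survived <- 0L
  for (k in 1:10) {
    Y <- simulate_var_series(A, diag(4), 5000, seed = 300 + k)
    pr <- significance_filter(conditional_gc(Y, p = 1), alpha = 0.05)
    if (pr$sig_mask[2, 1]) survived <- survived + 1L
  }
  expect_gte(survived, 9L)
})

test_that("window networks flag degenerate windows and keep bookkeeping", {
  # all-constant matrix: every window skipped, trial flagged
  Xc <- as_rate_matrix(matrix(5, 3, 201), t0 = 0, dt = 0.01)
  expect_warning(nets <- window_networks(sliding_windows(Xc, window_spec()),
                                         space_tag = "original"),
                 "unanalyzable")
  expect_true(all(vapply(nets, inherits, logical(1), "gc_window_skipped")))
  expect_true(isTRUE(attr(nets, "unanalyzable")))

  # well-behaved noise: one pruned network per window, centres preserved
  set.seed(23)
  Xn <- as_rate_matrix(matrix(abs(rnorm(3 * 201, 10)), 3, 201), t0 = 0, dt = 0.01)
  wins <- sliding_windows(Xn, window_spec(), rt = 1.5)
  nets2 <- window_networks(wins, space_tag = "nmf")
  expect_length(nets2, 13)
  expect_equal(vapply(nets2, `[[`, numeric(1), "window_center"),
               vapply(wins, `[[`, numeric(1), "center"))
  expect_true(all(vapply(nets2, function(nw) nw$space_tag == "nmf", logical(1))))
  # determinism: the whole stage is deterministic
  nets3 <- window_networks(wins, space_tag = "nmf")
  expect_identical(lapply(nets2, `[[`, "F"), lapply(nets3, `[[`, "F"))

  # a window with one silent neuron keeps the full node set with absent edges
  Xm <- Xn
  Xm[2, ] <- 3  # constant row
  netsm <- window_networks(sliding_windows(Xm, window_spec()),
                           space_tag = "original")
  nw <- netsm[[1]]
  expect_false(inherits(nw, "gc_window_skipped"))
  expect_length(nw$node_ids, 3)
  expect_true(all(is.na(nw$pvalues[2, c(1, 3)])))
  expect_true(all(nw$F[2, ] == 0) && all(nw$F[, 2] == 0))
})

test_that("negative causality estimates are floored and counted", {
  set.seed(29)
  X <- matrix(rnorm(120 * 3), ncol = 3)
  net <- conditional_gc(X, p = 1)
  expect_true(all(net$F >= 0))
  expect_true(net$floored_frac >= 0 && net$floored_frac <= 1)
})
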