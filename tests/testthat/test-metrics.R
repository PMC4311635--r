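# Causal density, global efficiency, metric time courses, peak-window
# summaries and group comparisons.

test_that("causal density matches its closed forms", {
  full <- make_net(matrix(1, 4, 4) - diag(4))
  expect_equal(causal_density(full), 1)
  empty <- make_net(matrix(0, 4, 4), mask = matrix(FALSE, 4, 4))
  expect_equal(causal_density(empty), 0)
  Fm <- matrix(0, 4, 4); Fm[2, 1] <- 0.5; Fm[3, 1] <- 0.2; Fm[1, 4] <- 0.1
  expect_equal(causal_density(make_net(Fm)), 3 / 12)
  unpruned <- make_net(Fm); unpruned$sig_mask <- NULL
  expect_error(causal_density(unpruned), "pruned")
})

test_that("global efficiency matches closed forms on canonical graphs", {
  # empty network
  empty <- make_net(matrix(0, 4, 4), mask = matrix(FALSE, 4, 4))
  expect_equal(global_efficiency(empty), 0)
  # complete network with uniform weight w: E = w
  for (w in c(0.5, 2)) {
    Fm <- matrix(w, 5, 5); diag(Fm) <- 0
    expect_equal(global_efficiency(make_net(Fm)), w)
  }
  # 3-node chain a->b (2), b->c (2): E = 5/6
  Fm <- matrix(0, 3, 3); Fm[2, 1] <- 2; Fm[3, 2] <- 2
  expect_equal(global_efficiency(make_net(Fm)), 5 / 6)
})

test_that("shortest-path efficiency agrees with exhaustive enumeration", {
  set.seed(31)
  for (k in 1:30) {
    N <- 5
    Fm <- matrix(0, N, N)
    edges <- matrix(runif(N * N) < 0.4, N, N)
    diag(edges) <- FALSE
    Fm[edges] <- runif(sum(edges), 0.1, 2)
    net <- make_net(Fm)
    lengths <- ifelse(Fm > 0, 1 / Fm, Inf)
    # enumeration works on the transposed orientation: lengths[j, i] is j -> i
    expect_equal(global_efficiency(net), enum_efficiency(t(lengths)),
                 tolerance = 1e-10)
  }
})

test_that("strengthening an edge never lowers efficiency or density", {
  set.seed(37)
  Fm <- matrix(0, 4, 4)
  Fm[2, 1] <- 0.5; Fm[3, 2] <- 1; Fm[4, 3] <- 0.2
  e0 <- global_efficiency(make_net(Fm))
  Fm2 <- Fm; Fm2[3, 2] <- 2
  expect_gte(global_efficiency(make_net(Fm2)), e0)
  # adding a surviving edge cannot lower Cd
  Fm3 <- Fm; Fm3[1, 4] <- 0.3
  expect_gte(causal_density(make_net(Fm3)), causal_density(make_net(Fm)))
})

test_that("metric time courses sort by time and keep gaps as gaps", {
  n1 <- make_net(matrix(c(0, 1, 1, 0), 2, 2)); n1$window_center <- 0.2
  n2 <- make_net(matrix(0, 2, 2), mask = matrix(FALSE, 2, 2))
  n2$window_center <- -0.3
  skip <- structure(list(window_center = -0.05, reason = "degenerate"),
                    class = "gc_window_skipped")
  tc <- metric_timecourse(list(n1, skip, n2), label = "correct", trial_id = "t1")
  expect_equal(tc$times, c(-0.3, -0.05, 0.2))
  expect_equal(tc$cd, c(0, NA, 1))
  expect_equal(tc$eff, c(0, NA, 1))
  # identical networks give a constant course
  tc2 <- metric_timecourse(list(n1, n1, n1))
  expect_equal(length(unique(tc2$cd)), 1L)
})

test_that("peak-window summaries average the windows around the peak", {
  tc <- structure(list(times = seq(-0.75, 0, by = 0.125),
                       cd = c(0.1, 0.1, 0.2, 0.3, 0.4, 0.3, 0.2),
                       eff = rep(0.5, 7), label = "correct", trial_id = "x",
                       space_tag = "nmf"),
                  class = "metric_timecourse")
  ps <- peak_window_stats(tc, "cd", pre = 0.25, post = 0.25)
  expect_equal(ps$peak_time, -0.25)
  # windows within [-0.5, 0]: values 0.2 0.3 0.4 0.3 0.2 -> mean by enumeration
  expect_equal(ps$mean, mean(c(0.2, 0.3, 0.4, 0.3, 0.2)))
  # constant course: mean equals the constant; tie broken to earliest window
  psc <- peak_window_stats(tc, "eff")
  expect_equal(psc$mean, 0.5)
  expect_equal(psc$peak_time, -0.75)
  # all-gap course is excluded with a warning
  tcg <- tc; tcg$cd <- rep(NA_real_, 7)
  expect_warning(psg <- peak_window_stats(tcg, "cd"), "excluded")
  expect_true(is.na(psg$mean))
})

test_that("group comparison handles degenerate and separated inputs", {
  same <- compare_groups(c(1, 1, 1), c(1, 1, 1))
  expect_equal(same$statistic, 0)
  expect_equal(same$pvalue, 1)
  set.seed(41)
  sep <- compare_groups(1 + rnorm(4, sd = 1e-6), rnorm(4, sd = 1e-6))
  expect_lt(sep$pvalue, 0.01)
  expect_equal(sep$effect_direction, "a>b")
  expect_error(compare_groups(1, c(1, 2)), "at least 2")
})

test_that("the Welch test is calibrated under the null", {
  set.seed(43)
  rejections <- 0L
  n_rep <- 1000L
  for (k in seq_len(n_rep)) {
    if (compare_groups(rnorm(12), rnorm(12))$pvalue < 0.05) {
      rejections <- rejections + 1L
    }
  }
  rate <- rejections / n_rep
  se <- sqrt(0.05 * 0.95 / n_rep)
  expect_lt(abs(rate - 0.05), 2 * se + 1e-9)
})
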