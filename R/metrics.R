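# Global network properties of pruned causality networks: causal density,
# global efficiency, reference-time-aligned metric time courses, peak-window
# summaries and group comparisons.

#' Causal density of a pruned network
#'
#' The fraction of ordered node pairs with a statistically significant causal
#' connection: `Cd = Num_sig / (N (N - 1))`, bounded in \[0, 1\].
#'
#' @param net a `gc_network` pruned by [significance_filter()].
#' @return scalar in \[0, 1\].
#' @export
causal_density <- function(net) {
  stopifnot(inherits(net, "gc_network"))
  if (is.null(net$sig_mask)) {
    stop("network must be pruned by significance_filter() first", call. = FALSE)
  }
  N <- length(net$node_ids)
  if (N < 2) stop("causal density undefined for N < 2", call. = FALSE)
  sum(net$sig_mask) / (N * (N - 1L))
}

#' Global efficiency of a pruned weighted network
#'
#' Mean inverse shortest-path length over ordered node pairs of the directed
#' graph of surviving edges, with edge length the inverse of connection
#' strength (`1/F`). Unreachable pairs contribute 0 (`1/Inf`). An edge
#' `j -> i` exists wherever `F[i, j] > 0` after pruning.
#'
#' @param net a pruned `gc_network`.
#' @param mode `"directed"` (the faithful reading for causality graphs) or
#'   `"undirected"` (sensitivity analysis; parallel edges collapse to the
#'   shorter length).
#' @param weights `"pruned"` uses the FDR-pruned strengths (default);
#'   `"raw"` uses the unpruned causality matrix.
#' @return scalar efficiency `>= 0`.
#' @export
global_efficiency <- function(net, mode = c("directed", "undirected"),
                              weights = c("pruned", "raw")) {
  stopifnot(inherits(net, "gc_network"))
  mode <- match.arg(mode)
  weights <- match.arg(weights)
  N <- length(net$node_ids)
  if (N < 2) stop("global efficiency undefined for N < 2", call. = FALSE)
  Fm <- if (weights == "pruned") {
    if (is.null(net$sig_mask)) {
      stop("network must be pruned by significance_filter() first", call. = FALSE)
    }
    net$F
  } else {
    net$F_raw
  }
  idx <- which(Fm > 0, arr.ind = TRUE)  # rows i (target), cols j (source)
  if (nrow(idx) == 0) return(0)
  g <- igraph::make_empty_graph(n = N, directed = (mode == "directed"))
  g <- igraph::add_edges(g, rbind(idx[, "col"], idx[, "row"]))
  len <- 1 / Fm[idx]
  d <- igraph::distances(g, mode = "out", weights = len)
  inv <- 1 / d
  diag(inv) <- 0
  sum(inv[is.finite(inv)]) / (N * (N - 1L))
}

#' Metric time course of one trial
#'
#' Computes causal density and global efficiency for every window network and
#' assembles them, sorted by window centre (RT-relative when the networks
#' carry RT-relative centres). Skipped windows appear as NA gaps, never as
#' interpolated values.
#'
#' @param networks list from [window_networks()].
#' @param label trial condition label (`"correct"`, `"error"`, `"baseline"`).
#' @param trial_id identifier.
#' @return object of class `metric_timecourse`: list with `times`, `cd`,
#'   `eff`, `label`, `trial_id`, `space_tag`.
#' @export
metric_timecourse <- function(networks, label = NA_character_,
                              trial_id = NA_character_) {
  if (!length(networks)) stop("need at least one window network", call. = FALSE)
  times <- vapply(networks, function(nw) nw$window_center %||% NA_real_,
                  numeric(1))
  cd <- rep(NA_real_, length(networks))
  eff <- rep(NA_real_, length(networks))
  tag <- NA_character_
  for (k in seq_along(networks)) {
    nw <- networks[[k]]
    if (inherits(nw, "gc_window_skipped")) next
    cd[k] <- causal_density(nw)
    eff[k] <- global_efficiency(nw)
    tag <- nw$space_tag
  }
  ord <- order(times)
  structure(list(times = times[ord], cd = cd[ord], eff = eff[ord],
                 label = label, trial_id = trial_id, space_tag = tag),
            class = "metric_timecourse")
}

#' Peak-window summary of a metric time course
#'
#' Locates the metric's peak window within the trial (ties broken toward the
#' earliest window) and averages the metric over all valid windows whose
#' centres fall within `[t_peak - pre, t_peak + post]`.
#'
#' @param tc a [metric_timecourse()].
#' @param metric `"cd"` or `"eff"`.
#' @param pre,post half-widths of the averaging interval around the peak,
#'   seconds (defaults 0.25 each).
#' @return list with `peak_time`, `peak_value`, `mean` (the peak-window
#'   average). All-gap time courses return NAs with a warning (trial to be
#'   excluded).
#' @export
peak_window_stats <- function(tc, metric = c("cd", "eff"), pre = 0.25,
                              post = 0.25) {
  stopifnot(inherits(tc, "metric_timecourse"))
  metric <- match.arg(metric)
  v <- tc[[metric]]
  t <- tc$times
  ok <- is.finite(v)
  if (!any(ok)) {
    warning(sprintf("trial %s: all windows are gaps; excluded", tc$trial_id),
            call. = FALSE)
    return(list(peak_time = NA_real_, peak_value = NA_real_, mean = NA_real_))
  }
  vi <- v
  vi[!ok] <- -Inf
  peak <- which.max(vi)  # earliest maximum
  sel <- ok & t >= t[peak] - pre - 1e-9 & t <= t[peak] + post + 1e-9
  list(peak_time = t[peak], peak_value = v[peak], mean = mean(v[sel]))
}

#' Two-sample comparison of per-trial metric values
#'
#' Welch (unequal-variance) two-sample t-test, two-sided. When both groups
#' have zero variance and equal means the p-value is 1 by convention.
#'
#' @param a,b numeric vectors of per-trial values (each length >= 2).
#' @return object of class `group_comparison`: list with `statistic`,
#'   `pvalue`, `effect_direction` (`"a>b"`, `"b>a"` or `"none"`), `mean_a`,
#'   `mean_b`, `n_a`, `n_b`.
#' @export
compare_groups <- function(a, b) {
  a <- a[is.finite(a)]
  b <- b[is.finite(b)]
  if (length(a) < 2 || length(b) < 2) {
    stop("each group needs at least 2 finite values", call. = FALSE)
  }
  if (stats::var(a) == 0 && stats::var(b) == 0) {
    if (mean(a) == mean(b)) {
      stat <- 0
      pval <- 1
    } else {
      stat <- sign(mean(a) - mean(b)) * Inf
      pval <- 0
    }
  } else {
    tt <- stats::t.test(a, b, var.equal = FALSE)
    stat <- unname(tt$statistic)
    pval <- tt$p.value
  }
  dir <- if (mean(a) > mean(b)) "a>b" else if (mean(b) > mean(a)) "b>a" else "none"
  structure(list(statistic = stat, pvalue = pval, effect_direction = dir,
                 mean_a = mean(a), mean_b = mean(b),
                 n_a = length(a), n_b = length(b)),
            class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("<group_comparison> t = %.3f, p = %.4g (%s); means %.4g vs %.4g (n = %d, %d)\n",
              x$statistic, x$pvalue, x$effect_direction,
              x$mean_a, x$mean_b, x$n_a, x$n_b))
  invisible(x)
}

#' Plot metric time courses of a trial group
#'
#' Group mean with a shaded standard-error band, aligned to the reference
#' time at 0.
#'
#' @param tcs list of [metric_timecourse()] objects on a common time grid.
#' @param metric `"cd"` or `"eff"`.
#' @param col line colour.
#' @param add overlay onto an existing plot.
#' @param ... passed to [graphics::plot()].
#' @return invisibly, a list with `times`, `mean`, `sem`.
#' @export
plot_metric_timecourse <- function(tcs, metric = c("cd", "eff"),
                                   col = "firebrick", add = FALSE, ...) {
  metric <- match.arg(metric)
  M <- do.call(rbind, lapply(tcs, `[[`, metric))
  times <- tcs[[1]]$times
  mu <- colMeans(M, na.rm = TRUE)
  sem <- apply(M, 2, function(z) stats::sd(z, na.rm = TRUE) / sqrt(sum(is.finite(z))))
  if (!add) {
    graphics::plot(times, mu, type = "n",
                   xlab = "time relative to RT (s)",
                   ylab = if (metric == "cd") "causal density" else "global efficiency",
                   ylim = range(c(mu - sem, mu + sem), finite = TRUE), ...)
    graphics::abline(v = 0, lty = 2, col = "grey40")
  }
  graphics::polygon(c(times, rev(times)), c(mu - sem, rev(mu + sem)),
                    border = NA, col = grDevices::adjustcolor(col, 0.25))
  graphics::lines(times, mu, col = col, lwd = 2)
  invisible(list(times = times, mean = mu, sem = sem))
}
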