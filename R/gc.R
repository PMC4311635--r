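# Conditional Granger causality networks from multivariate time series.
#
# embed_network() lifts a network fitted on the active subset of a window's
# series back onto the full node set: edges touching an inactive (silent)
# node are absent (F = 0) and untested (p = NA), so FDR correction runs only
# over the pairs actually tested.
#
# Each window's series is modelled by a VAR(p) fitted per equation by OLS
# (order p by BIC). The causality from series j to series i conditioned on
# all other series is ln(rho_ii / Sigma_ii), comparing x_i's residual
# variance in the model omitting x_j (rho) with the full model (Sigma).
# Per-edge significance comes from the nested-regression F-test on equation
# i's residual sum of squares, corrected across all ordered pairs of a window
# by Benjamini-Hochberg FDR; non-significant edges are set to zero.

#' Fit a vector autoregressive model by per-equation least squares
#'
#' Columns are mean-centred (equivalent to an intercept term); each equation
#' is regressed on the `p` lags of all included variables. When `omit` is
#' given, that variable is excluded from both predictors and targets
#' (the restricted model of conditional Granger causality). The residual
#' covariance uses the `1/(T - p)` normalisation. If the regressor matrix is
#' rank-deficient, or the parameter count exceeds half the sample
#' (`N*p + 1 > T/2`), the fit falls back to ridge regression with
#' `lambda = 1e-8 * trace(Z'Z)` and sets `ridge_used`.
#'
#' @param series `T x N` numeric matrix, time in rows.
#' @param p model order (lags), `p >= 1`.
#' @param omit optional index of the variable to omit.
#' @return object of class `var_model`: list with `p`, `coeffs` (list of
#'   `N x N` lag matrices), `residuals` (`(T-p) x N`), `rss` (per equation),
#'   `resid_cov`, `T_eff`, `n_vars`, `ridge_used`.
#' @export
fit_var <- function(series, p, omit = NULL) {
  series <- as.matrix(series)
  if (!is.null(omit)) series <- series[, -omit, drop = FALSE]
  Tn <- nrow(series)
  N <- ncol(series)
  if (p < 1) stop("`p` must be >= 1", call. = FALSE)
  T_eff <- Tn - p
  k <- N * p
  if (T_eff < k + 1L) {
    stop(sprintf("insufficient samples: need T - p >= N*p + 1 (have %d, need %d)",
                 T_eff, k + 1L), call. = FALSE)
  }
  Y <- series[(p + 1):Tn, , drop = FALSE]
  Z <- do.call(cbind, lapply(seq_len(p), function(l) {
    series[(p + 1 - l):(Tn - l), , drop = FALSE]
  }))
  # centre response and regressors (intercept equivalent)
  Y <- scale(Y, center = TRUE, scale = FALSE)
  Z <- scale(Z, center = TRUE, scale = FALSE)
  ridge_used <- (k + 1L) > Tn / 2
  B <- NULL
  if (!ridge_used) {
    qz <- qr(Z)
    if (qz$rank < k) ridge_used <- TRUE else B <- qr.coef(qz, Y)
  }
  if (ridge_used) {
    ZtZ <- crossprod(Z)
    lambda <- 1e-8 * sum(diag(ZtZ))
    B <- solve(ZtZ + diag(lambda, k), crossprod(Z, Y))
  }
  E <- Y - Z %*% B
  rss <- colSums(E^2)
  coeffs <- lapply(seq_len(p), function(l) {
    t(B[((l - 1L) * N + 1L):(l * N), , drop = FALSE])
  })
  structure(list(p = as.integer(p), coeffs = coeffs, residuals = E,
                 rss = rss, resid_cov = crossprod(E) / T_eff,
                 T_eff = T_eff, n_vars = N, ridge_used = ridge_used),
            class = "var_model")
}

#' Select the VAR order by the Bayesian information criterion
#'
#' Fits orders 1..`p_max` and returns the minimiser of
#' `ln det(Sigma_hat) + N^2 p ln(T_eff) / T_eff`, with `Sigma_hat` the
#' unrestricted residual covariance and `T_eff = T - p`.
#'
#' @inheritParams fit_var
#' @param p_max largest order considered.
#' @return integer order, with attribute `bic` (the criterion per order).
#' @export
select_order <- function(series, p_max = 3L) {
  series <- as.matrix(series)
  Tn <- nrow(series)
  N <- ncol(series)
  if (Tn <= N * p_max + 1L) {
    stop(sprintf("insufficient samples for p_max = %d: need T > N*p_max + 1 = %d, have %d",
                 p_max, N * p_max + 1L, Tn), call. = FALSE)
  }
  bic <- vapply(seq_len(p_max), function(p) {
    fit <- fit_var(series, p)
    ld <- determinant(fit$resid_cov, logarithm = TRUE)
    if (ld$sign <= 0) return(Inf)
    as.numeric(ld$modulus) + (N^2 * p) * log(fit$T_eff) / fit$T_eff
  }, numeric(1))
  structure(as.integer(which.min(bic)), bic = bic)
}

#' Conditional Granger causality matrix of a multivariate series
#'
#' For every ordered pair (i, j), i != j, computes
#' `F[i, j] = ln(rho_ii / Sigma_ii)`: the causality from variable j to
#' variable i conditioned on all remaining variables, where `rho_ii` is the
#' residual variance of equation i in the VAR omitting j and `Sigma_ii` the
#' same in the full VAR. Estimates below zero (possible in finite samples)
#' are floored at 0 and counted in `floored_frac`. Per-pair p-values come
#' from the nested F-test
#' `F = ((RSS_r - RSS_u)/p) / (RSS_u / (T_eff - N*p - 1))` with
#' `df = (p, T_eff - N*p - 1)`.
#'
#' Orientation convention: `F[i, j]` is the influence of node j (column) on
#' node i (row), i.e. the directed edge j -> i.
#'
#' @inheritParams fit_var
#' @param node_ids optional node labels.
#' @return object of class `gc_network` with fields `F` (identical to
#'   `F_raw` until pruned), `F_raw`, `pvalues`, `fstat`, `sig_mask` (NULL
#'   until [significance_filter()]), `node_ids`, `p`, `df1`, `df2`, `T_eff`,
#'   `floored_frac`, `ridge_used`, `invalid_pairs`, `window_center`,
#'   `space_tag`.
#' @export
conditional_gc <- function(series, p, node_ids = NULL) {
  series <- as.matrix(series)
  N <- ncol(series)
  if (N < 2) stop("need at least 2 series", call. = FALSE)
  full <- fit_var(series, p)
  df1 <- full$p
  df2 <- full$T_eff - N * full$p - 1L
  if (df2 <= 0) {
    stop(sprintf("non-positive F-test denominator df (T_eff - N*p - 1 = %d)", df2),
         call. = FALSE)
  }
  Fm <- matrix(0, N, N)
  pv <- matrix(NA_real_, N, N)
  fs <- matrix(NA_real_, N, N)
  invalid <- matrix(FALSE, N, N)
  floored <- 0L
  ridge_any <- full$ridge_used
  for (j in seq_len(N)) {
    restr <- fit_var(series, p, omit = j)
    ridge_any <- ridge_any || restr$ridge_used
    for (i in seq_len(N)[-j]) {
      ii <- i - (i > j)
      sig_ii <- full$resid_cov[i, i]
      rho_ii <- restr$resid_cov[ii, ii]
      if (!is.finite(sig_ii) || sig_ii <= 0) {
        invalid[i, j] <- TRUE
        next
      }
      f_val <- log(rho_ii / sig_ii)
      if (f_val < 0) {
        floored <- floored + 1L
        f_val <- 0
      }
      Fm[i, j] <- f_val
      num <- (restr$rss[ii] - full$rss[i]) / df1
      den <- full$rss[i] / df2
      stat <- max(0, num / den)
      fs[i, j] <- stat
      pv[i, j] <- stats::pf(stat, df1, df2, lower.tail = FALSE)
    }
  }
  structure(list(node_ids = node_ids %||% as.character(seq_len(N)),
                 F = Fm, F_raw = Fm, pvalues = pv, fstat = fs,
                 sig_mask = NULL, p = full$p, df1 = df1, df2 = df2,
                 T_eff = full$T_eff,
                 floored_frac = floored / (N * (N - 1L)),
                 ridge_used = ridge_any,
                 invalid_pairs = invalid,
                 window_center = NA_real_, space_tag = NA_character_),
            class = "gc_network")
}

#' @export
print.gc_network <- function(x, ...) {
  N <- length(x$node_ids)
  pruned <- !is.null(x$sig_mask)
  cat(sprintf("<gc_network> %d nodes (%s), VAR order %d%s\n",
              N, x$space_tag %||% "untagged", x$p,
              if (pruned) sprintf(", %d/%d significant edges",
                                  sum(x$sig_mask), N * (N - 1L))
              else " (unpruned)"))
  invisible(x)
}

embed_network <- function(net, active, ids) {
  N <- length(active)
  lift <- function(M, fill) {
    out <- matrix(fill, N, N)
    out[active, active] <- M
    out
  }
  net$F <- lift(net$F, 0)
  net$F_raw <- lift(net$F_raw, 0)
  net$pvalues <- lift(net$pvalues, NA_real_)
  net$fstat <- lift(net$fstat, NA_real_)
  net$invalid_pairs <- lift(net$invalid_pairs, FALSE) > 0
  net$node_ids <- ids
  net$active <- active
  net
}

#' Prune a causality network by FDR-corrected F-tests
#'
#' Applies the Benjamini-Hochberg correction to the `N(N-1)` per-edge F-test
#' p-values of one window and zeroes every connection whose adjusted p-value
#' is not below `alpha`. Pairs flagged invalid by [conditional_gc()] are
#' treated as non-significant.
#'
#' @param net an unpruned `gc_network`.
#' @param alpha significance level after FDR correction (default 0.05).
#' @return the network with `sig_mask` filled, `F` zeroed on non-significant
#'   edges (`F_raw` untouched), and `padj` stored.
#' @export
significance_filter <- function(net, alpha = 0.05) {
  stopifnot(inherits(net, "gc_network"))
  N <- length(net$node_ids)
  off <- !diag(TRUE, N)
  padj <- matrix(NA_real_, N, N)
  padj[off] <- stats::p.adjust(net$pvalues[off], method = "BH")
  mask <- !is.na(padj) & padj < alpha & !net$invalid_pairs
  Fm <- net$F_raw
  Fm[!mask] <- 0
  net$F <- Fm
  net$sig_mask <- mask
  net$padj <- padj
  net$alpha <- alpha
  net
}

#' Causality networks for every sliding window of a trial
#'
#' Runs order selection, conditional Granger causality and FDR pruning on
#' each window from [sliding_windows()]. The procedure is identical for
#' neuron-space rows (a `rate_matrix`) and component-space rows (`H` of an
#' NMF fit). Series that are (numerically) constant within a window -- e.g.
#' neurons silent for the whole window -- carry no dynamical information and
#' are excluded from the conditional set for that window; their incident
#' edges are recorded as absent (F = 0, p = 1). A window is flagged and
#' skipped when fewer than 2 series remain active or the window is too short
#' for a first-order model; if more than half of a trial's windows are
#' skipped the result carries the attribute `unanalyzable = TRUE`.
#'
#' @param windows list from [sliding_windows()].
#' @param p_max maximum VAR order offered to BIC (capped per window so the
#'   order-selection sample requirement holds).
#' @param alpha FDR level for [significance_filter()].
#' @param space_tag `"original"` or `"nmf"`, recorded on every network.
#' @param node_ids optional node labels.
#' @return list, one element per window: a pruned `gc_network` (with
#'   `window_center` set) or a list of class `gc_window_skipped` carrying the
#'   reason.
#' @export
window_networks <- function(windows, p_max = 3L, alpha = 0.05,
                            space_tag = c("original", "nmf"),
                            node_ids = NULL) {
  space_tag <- match.arg(space_tag)
  out <- lapply(windows, function(w) {
    X <- w$data
    series_full <- t(X)
    Tn <- nrow(series_full)
    N_full <- ncol(series_full)
    ids <- node_ids %||% as.character(seq_len(N_full))
    sds <- apply(series_full, 2, stats::sd)
    scale_ref <- pmax(abs(colMeans(series_full)), 1)
    active <- is.finite(sds) & sds > 1e-6 * scale_ref
    if (sum(active) < 2L) {
      return(structure(list(window_center = w$center,
                            reason = "fewer than 2 non-constant series in window"),
                       class = "gc_window_skipped"))
    }
    series <- series_full[, active, drop = FALSE]
    N <- ncol(series)
    # fit_var needs T - p >= N*p + 1, i.e. p <= (T - 1)/(N + 1)
    pm <- min(p_max, floor((Tn - 1L) / (N + 1L)))
    if (pm < 1L) {
      return(structure(list(window_center = w$center,
                            reason = "window too short for a first-order model"),
                       class = "gc_window_skipped"))
    }
    p <- as.integer(select_order(series, p_max = pm))
    net <- tryCatch(conditional_gc(series, p, node_ids = ids[active]),
                    error = function(e) {
                      structure(list(window_center = w$center,
                                     reason = conditionMessage(e)),
                                class = "gc_window_skipped")
                    })
    if (inherits(net, "gc_window_skipped")) return(net)
    if (any(!active)) net <- embed_network(net, active, ids)
    net <- significance_filter(net, alpha = alpha)
    net$window_center <- w$center
    net$space_tag <- space_tag
    net
  })
  n_skip <- sum(vapply(out, inherits, logical(1), "gc_window_skipped"))

  if (length(out) && n_skip > length(out) / 2) {
    warning(sprintf("%d of %d windows skipped; trial flagged unanalyzable",
                    n_skip, length(out)), call. = FALSE)
    attr(out, "unanalyzable") <- TRUE
  }
  out
}
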