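# Non-negative matrix factorization of trial rate matrices, with rank
# selection by variance accounted for (VAF) and rank harmonization across the
# trials of one animal.
#
# X (m x n, non-negative) ~ W (m x r) H (r x n), minimising the Frobenius
# residual by multiplicative updates (Lee-Seung). VAF = 1 - |X - WH|_F^2 /
# |X|_F^2; the selected rank is the smallest r with VAF > threshold, subject
# to the admissibility bound r < mn / (m + n).

#' Variance accounted for by a factorization
#'
#' `VAF = 1 - sum((X - WH)^2) / sum(X^2)`. Equals 1 for a perfect fit, 0 when
#' `WH = 0`, and can be negative for fits worse than the zero matrix.
#'
#' @param X non-negative data matrix (m x n).
#' @param W,H factors (m x r and r x n).
#' @return scalar VAF.
#' @export
nmf_vaf <- function(X, W, H) {
  X <- as.matrix(X)
  denom <- sum(X^2)
  if (denom == 0) stop("VAF undefined for an all-zero matrix", call. = FALSE)
  e <- X - W %*% H
  1 - sum(e^2) / denom
}

# Largest admissible rank: r must satisfy r < m n / (m + n).
rank_bound <- function(m, n) {
  b <- m * n / (m + n)
  r_max <- ceiling(b) - 1L
  if (r_max >= b) r_max <- r_max - 1L  # exact-integer boundary
  max(1L, as.integer(r_max))
}

nmf_single <- function(X, r, max_iter, tol, eps = 1e-12) {
  m <- nrow(X)
  n <- ncol(X)
  scale0 <- sqrt(mean(X) / r)
  W <- matrix(stats::runif(m * r), m, r) * scale0
  H <- matrix(stats::runif(r * n), r, n) * scale0
  obj <- numeric(max_iter)
  prev <- Inf
  it <- 0L
  for (it in seq_len(max_iter)) {
    H <- H * (crossprod(W, X)) / (crossprod(W) %*% H + eps)
    W <- W * (X %*% t(H)) / (W %*% tcrossprod(H) + eps)
    o <- sqrt(sum((X - W %*% H)^2))
    obj[it] <- o
    if (is.finite(prev) && prev > 0 && abs(prev - o) / prev < tol) break
    prev <- o
  }
  list(W = W, H = H, objective = obj[it], n_iter = it,
       objective_path = obj[seq_len(it)])
}

#' Non-negative matrix factorization at a fixed rank
#'
#' Multiplicative-update minimisation of the Frobenius objective
#' `|X - WH|_F`, run `n_restarts` times from seeded non-negative random
#' initialisations (uniform, scaled by `sqrt(mean(X)/r)`); the restart with
#' the lowest final objective is returned. Iterations stop when the relative
#' objective change drops below `tol` or after `max_iter` iterations. The
#' objective is non-increasing within a run.
#'
#' @param X non-negative m x n matrix (a `rate_matrix` or plain matrix);
#'   must not be all-zero.
#' @param r factorization rank, `1 <= r <= m`.
#' @param seed integer; restart k uses seed `seed + k - 1`.
#' @param n_restarts number of random restarts (default 10).
#' @param max_iter iteration cap per restart (default 500).
#' @param tol relative objective-change convergence threshold (default 1e-6).
#' @return object of class `nmf_result`: list with `W`, `H`, `rank`, `vaf`,
#'   `objective` (final Frobenius residual), `n_iter`, `objective_path` (of
#'   the winning restart), `seed_used`.
#' @export
nmf_factorize <- function(X, r, seed = 1L, n_restarts = 10L, max_iter = 500L,
                          tol = 1e-6) {
  Xm <- as.matrix(X)
  if (any(Xm < 0)) stop("`X` must be non-negative", call. = FALSE)
  if (sum(Xm) == 0) stop("`X` must not be all-zero", call. = FALSE)
  m <- nrow(Xm)
  if (r < 1 || r > m) stop("need 1 <= r <= nrow(X)", call. = FALSE)
  best <- NULL
  best_seed <- NA_integer_
  for (k in seq_len(n_restarts)) {
    sk <- as.integer(seed) + k - 1L
    fit <- with_seed(sk, nmf_single(Xm, r, max_iter, tol))
    if (is.null(best) || fit$objective < best$objective) {
      best <- fit
      best_seed <- sk
    }
  }
  structure(list(W = best$W, H = best$H, rank = as.integer(r),
                 vaf = nmf_vaf(Xm, best$W, best$H),
                 objective = best$objective, n_iter = best$n_iter,
                 objective_path = best$objective_path,
                 seed_used = best_seed),
            class = "nmf_result")
}

#' @export
print.nmf_result <- function(x, ...) {
  cat(sprintf("<nmf_result> rank %d, VAF %.4f, %d iterations (objective %.4g)\n",
              x$rank, x$vaf, x$n_iter, x$objective))
  invisible(x)
}

#' Select the factorization rank by the VAF criterion
#'
#' Fits ranks r = 1, 2, ... and returns the smallest rank whose VAF exceeds
#' `threshold`. The result must also satisfy the admissibility bound
#' \code{r < mn/(m+n)}; if the smallest sufficient rank violates it, the largest
#' admissible rank is returned with a warning.
#'
#' @inheritParams nmf_factorize
#' @param threshold VAF fraction the fit must exceed (default 0.9).
#' @return integer rank, with attributes `vaf` (at the selected rank) and
#'   `vaf_path` (VAF of each rank tried).
#' @export
select_rank <- function(X, threshold = 0.9, seed = 1L, n_restarts = 10L) {
  Xm <- as.matrix(X)
  m <- nrow(Xm)
  n <- ncol(Xm)
  r_adm <- min(m, rank_bound(m, n))
  vafs <- numeric(0)
  for (r in seq_len(m)) {
    fit <- nmf_factorize(Xm, r, seed = seed, n_restarts = n_restarts)
    vafs[r] <- fit$vaf
    if (fit$vaf > threshold) {
      if (r > r_adm) {
        warning(sprintf(
          "smallest rank with VAF > %.2f is %d but the admissibility bound r < mn/(m+n) caps it at %d",
          threshold, r, r_adm), call. = FALSE)
        r <- r_adm
      }
      return(structure(as.integer(r), vaf = vafs[min(r, length(vafs))],
                       vaf_path = vafs))
    }
    if (r >= r_adm) break
  }
  warning(sprintf("no admissible rank reaches VAF > %.2f; returning %d",
                  threshold, r_adm), call. = FALSE)
  structure(as.integer(r_adm), vaf = vafs[length(vafs)], vaf_path = vafs)
}

#' Harmonize the factorization rank across the trials of one animal
#'
#' Selects a rank per trial by [select_rank()], fixes the animal-level rank at
#' the maximum over trials, then refits every trial at that common rank and
#' records the recomputed VAF. Because the common rank is at least each
#' trial's own selected rank (and restarts keep the best fit), the recomputed
#' VAF stays above the threshold in practice; this is verified downstream,
#' not assumed.
#'
#' @param trials named list of non-negative rate matrices (one per trial).
#' @param threshold VAF threshold (default 0.9).
#' @param seed,n_restarts passed to the factorizations.
#' @return object of class `rank_selection`: list with `per_trial_rank`,
#'   `animal_rank`, `per_trial_vaf_at_animal_rank`, and `fits` (the
#'   `nmf_result` of every trial at the animal rank, for downstream use of
#'   the component time courses `H`).
#' @export
harmonize_rank <- function(trials, threshold = 0.9, seed = 1L,
                           n_restarts = 10L) {
  if (!length(trials)) stop("need at least one trial", call. = FALSE)
  if (is.null(names(trials))) names(trials) <- sprintf("trial_%03d", seq_along(trials))
  per_rank <- vapply(seq_along(trials), function(k) {
    as.integer(select_rank(trials[[k]], threshold = threshold,
                           seed = seed + 100L * k, n_restarts = n_restarts))
  }, integer(1))
  names(per_rank) <- names(trials)
  animal_rank <- max(per_rank)
  fits <- lapply(seq_along(trials), function(k) {
    nmf_factorize(trials[[k]], animal_rank, seed = seed + 100L * k,
                  n_restarts = n_restarts)
  })
  names(fits) <- names(trials)
  vafs <- vapply(fits, `[[`, numeric(1), "vaf")
  structure(list(per_trial_rank = per_rank,
                 animal_rank = as.integer(animal_rank),
                 per_trial_vaf_at_animal_rank = vafs,
                 threshold = threshold,
                 fits = fits),
            class = "rank_selection")
}

#' @export
print.rank_selection <- function(x, ...) {
  cat(sprintf("<rank_selection> animal rank %d (per-trial ranks %s); mean VAF at animal rank %.3f\n",
              x$animal_rank,
              paste(range(x$per_trial_rank), collapse = "-"),
              mean(x$per_trial_vaf_at_animal_rank)))
  invisible(x)
}
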