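# Pairwise robust normalization of one target sample against one
# reference sample.  The model on log2 counts is
#     r_i = alpha + beta * t_i + e_i
# fitted by least trimmed squares (LTS): minimize the sum of the h
# smallest squared residuals, n/2 < h <= n.  The retained h points are
# the empirical "undifferentiated" transcript set for the pair.  In the
# single-parameter (sp) form beta is fixed at 1 (pure scaling on the
# count scale); in the double-parameter (dp) form beta is free
# (a power law on the count scale).

# Run `code` with a temporarily seeded RNG, restoring the caller's
# RNG state afterwards.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    stats::runif(1)
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  force(code)
}

# Indices of the h smallest values of x, ties broken by index (stable).
smallest_h_idx <- function(x, h) {
  n <- length(x)
  if (h >= n) return(seq_len(n))
  thr <- sort.int(x, partial = h)[h]
  idx <- which(x < thr)
  ties <- which(x == thr)
  c(idx, ties[seq_len(h - length(idx))])
}

new_pairwise_fit <- function(alpha, beta, h, retained, objective, mode, n,
                             target_id = NA_character_, ref_id = NA_character_) {
  structure(list(target_id = target_id, ref_id = ref_id,
                 alpha = alpha, beta = beta, h = as.integer(h),
                 retained = as.integer(retained), objective = objective,
                 mode = mode, n = as.integer(n)),
            class = "pairwise_fit")
}

#' @export
print.pairwise_fit <- function(x, ...) {
  cat(sprintf("pairwise LTS fit (%s): alpha = %.4f, beta = %.4f, h = %d/%d, objective = %.4g\n",
              x$mode, x$alpha, x$beta, x$h, x$n, x$objective))
  invisible(x)
}

#' Log-transform a count matrix
#'
#' Elementwise `log2(count + c)`.  The offset `c` (default 1) keeps zero
#' counts at zero after transformation and shrinks fold changes of low
#' counts toward zero; e.g. with `c = 1` the log difference between
#' counts 4 and 0 is `log2(5) - log2(1) = 2.3`, whereas with
#' `c = 1e-4` it would explode to 15.3.
#'
#' @param m Non-negative numeric matrix (or vector) of counts.
#' @param c Positive offset added before taking log2.
#' @return `log2(m + c)`, with the offset stored in attribute
#'   `"offset"` so the inverse transform is well defined.
#' @seealso [inv_log_transform()]
#' @export
log_transform <- function(m, c = 1) {
  if (!is.numeric(c) || length(c) != 1L || c <= 0) stop("offset c must be a positive number")
  out <- log2(m + c)
  attr(out, "offset") <- c
  out
}

#' Invert the log-offset transform
#'
#' @param x Log-scale values from [log_transform()].
#' @param c Offset; defaults to the `"offset"` attribute of `x`.
#' @return Count-scale values `2^x - c`, clipped below at 0.
#' @export
inv_log_transform <- function(x, c = attr(x, "offset")) {
  if (is.null(c)) stop("offset c not supplied and not stored in x")
  out <- pmax(2^x - c, 0)
  attr(out, "offset") <- NULL
  out
}

# Exact LTS location fit of r - t (sp mode): the optimal h-subset is a
# contiguous window of the sorted residuals, so all n-h+1 windows are
# scanned with cumulative sums.  Concentration steps afterwards align
# the retained set with the h smallest absolute residuals at alpha-hat.
lts_sp <- function(t, r, h, n_csteps = 50L) {
  e <- r - t
  n <- length(e)
  o <- order(e)
  es <- e[o]
  cs <- cumsum(es)
  cs2 <- cumsum(es * es)
  k <- seq_len(n - h + 1L)
  wsum <- cs[k + h - 1L] - c(0, cs)[k]
  wss <- cs2[k + h - 1L] - c(0, cs2)[k]
  obj <- wss - wsum^2 / h
  kb <- which.min(obj)
  alpha <- wsum[kb] / h
  retained <- o[seq.int(kb, kb + h - 1L)]
  for (it in seq_len(n_csteps)) {
    e2 <- (e - alpha)^2
    ret <- smallest_h_idx(e2, h)
    ret <- sort.int(ret)
    if (identical(ret, sort.int(retained))) { retained <- ret; break }
    retained <- ret
    alpha <- mean(e[retained])
  }
  e2 <- (e - alpha)^2
  retained <- sort.int(smallest_h_idx(e2, h))
  list(alpha = alpha, beta = 1, retained = retained,
       objective = sum(e2[retained]))
}

ls_line <- function(t, r) {
  mt <- mean(t); mr <- mean(r)
  vt <- sum((t - mt)^2)
  if (vt < .Machine$double.eps * length(t)) return(NULL)
  beta <- sum((t - mt) * (r - mr)) / vt
  c(alpha = mr - beta * mt, beta = beta)
}

# One FAST-LTS trajectory: concentration steps (refit LS on the h
# smallest squared residuals) until the retained set is stable.
dp_csteps <- function(t, r, h, alpha, beta, n_csteps) {
  ret_prev <- integer(0)
  for (it in seq_len(n_csteps)) {
    e2 <- (r - alpha - beta * t)^2
    ret <- smallest_h_idx(e2, h)
    if (identical(sort.int(ret), ret_prev)) break
    ret_prev <- sort.int(ret)
    th <- ls_line(t[ret], r[ret])
    if (is.null(th)) break
    alpha <- th[[1L]]; beta <- th[[2L]]
  }
  e2 <- (r - alpha - beta * t)^2
  ret <- sort.int(smallest_h_idx(e2, h))
  list(alpha = alpha, beta = beta, retained = ret, objective = sum(e2[ret]))
}

#' Least trimmed squares fit of a target/reference pair
#'
#' Fits `r = alpha + beta * t + e` by LTS: the estimate minimizes the
#' sum of the `h` smallest squared residuals, which makes the fit
#' resistant to up to `n - h` differentially expressed transcripts
#' (breakdown point roughly `(n - h)/n`).
#'
#' In `sp` mode `beta` is fixed at 1 and the location problem is solved
#' exactly: the optimal retained set is a contiguous window of the
#' sorted differences `r - t`, so all windows are scanned.  In `dp`
#' mode the FAST-LTS heuristic is used: `n_starts` random two-point
#' elemental starts, each refined by concentration steps (refit least
#' squares on the current h best residuals) until the retained set is
#' stable, keeping the best objective.
#'
#' At the solution the retained-set least-squares refit implies that the
#' mean of the signed residuals over the retained set is zero, i.e. the
#' average log ratio of the empirical undifferentiated set vanishes
#' after normalization.
#'
#' @param t,r Numeric vectors of log2 target and reference counts.
#' @param h Trim size: number of retained observations, `n/2 < h <= n`.
#' @param mode `"sp"` (slope fixed at 1) or `"dp"` (free slope).
#' @param n_starts Number of random elemental starts (`dp` mode).
#' @param n_csteps Maximum concentration steps per start.
#' @param seed Integer seed for the random starts; the caller's RNG
#'   state is untouched.  Identical seeds give identical fits.
#' @param target_id,ref_id Optional sample identifiers stored in the fit.
#' @return An object of class `pairwise_fit`: list with elements
#'   `alpha`, `beta`, `h`, `retained` (indices of the h smallest squared
#'   residuals, ties broken by index), `objective`, `mode`, `n`.
#' @export
lts_fit <- function(t, r, h, mode = c("sp", "dp"), n_starts = 500L,
                    n_csteps = 50L, seed = NULL,
                    target_id = NA_character_, ref_id = NA_character_) {
  mode <- match.arg(mode)
  n <- length(t)
  if (length(r) != n) stop("t and r must have equal length")
  if (n < 4L) stop("need at least 4 observations")
  if (h <= n / 2 || h > n) stop("h must satisfy n/2 < h <= n")
  h <- as.integer(h)
  if (mode == "sp") {
    f <- lts_sp(t, r, h, n_csteps)
  } else {
    if (stats::var(t) == 0) stop("degenerate target: zero variance in dp mode")
    f <- with_seed(seed, {
      best <- NULL
      start_full <- ls_line(t, r)
      if (!is.null(start_full))
        best <- dp_csteps(t, r, h, start_full[[1L]], start_full[[2L]], n_csteps)
      for (s in seq_len(n_starts)) {
        idx <- sample.int(n, 2L)
        th <- ls_line(t[idx], r[idx])
        if (is.null(th)) next
        cand <- dp_csteps(t, r, h, th[[1L]], th[[2L]], n_csteps)
        if (is.null(best) || cand$objective < best$objective - 1e-12)
          best <- cand
      }
      best
    })
    if (is.null(f)) stop("all elemental starts degenerate")
  }
  new_pairwise_fit(f$alpha, f$beta, h, f$retained, f$objective, mode, n,
                   target_id, ref_id)
}

#' Exhaustive LTS oracle (small n)
#'
#' Global LTS minimizer by enumeration: every h-subset is fitted by
#' least squares (mean shift in `sp` mode) and the trimmed objective is
#' recomputed from the h smallest squared residuals over all n points
#' at that candidate.  Exact but combinatorial; intended as an
#' independent check of [lts_fit()] on small instances.
#'
#' @inheritParams lts_fit
#' @return A `pairwise_fit` attaining the global trimmed objective.
#' @export
lts_exhaustive_oracle <- function(t, r, h, mode = c("sp", "dp")) {
  mode <- match.arg(mode)
  n <- length(t)
  if (length(r) != n) stop("t and r must have equal length")
  if (n > 20L) stop("n too large for exhaustive enumeration (max 20)")
  if (h <= n / 2 || h > n) stop("h must satisfy n/2 < h <= n")
  subsets <- utils::combn(n, h)
  best <- NULL
  for (k in seq_len(ncol(subsets))) {
    idx <- subsets[, k]
    if (mode == "sp") {
      alpha <- mean(r[idx] - t[idx]); beta <- 1
    } else {
      th <- ls_line(t[idx], r[idx])
      if (is.null(th)) next
      alpha <- th[[1L]]; beta <- th[[2L]]
    }
    e2 <- (r - alpha - beta * t)^2
    ret <- sort.int(smallest_h_idx(e2, h))
    obj <- sum(e2[ret])
    if (is.null(best) || obj < best$objective - 1e-12)
      best <- list(alpha = alpha, beta = beta, retained = ret, objective = obj)
  }
  if (is.null(best)) stop("no non-degenerate subset found")
  new_pairwise_fit(best$alpha, best$beta, h, best$retained, best$objective,
                   mode, n)
}

#' Apply a pairwise fit to raw counts
#'
#' Back-transforms the fitted log-scale adjustment to the count scale:
#' the pre-normalized count is `2^alpha * (T + c)^beta - c`, clipped
#' below at 0.
#'
#' @param fit A `pairwise_fit`.
#' @param target_counts Non-negative raw counts of the target sample.
#' @param c Positive log offset (must match the one used for fitting).
#' @return Pre-normalized counts, same length as `target_counts`.
#' @export
apply_fit <- function(fit, target_counts, c = 1) {
  if (any(target_counts < 0)) stop("counts must be non-negative")
  if (c <= 0) stop("offset c must be positive")
  pmax(2^fit$alpha * (target_counts + c)^fit$beta - c, 0)
}
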