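# Integration of the I x J table of pairwise pre-normalized values
# (targets x references) under the additive two-factor model
#     x_ij = mu + a_i + b_j + e_ij,
# identifiable under median{a_i} = median{b_j} = 0, estimated by least
# absolute deviations.  The shipped estimator is Tukey's median polish;
# an exhaustive LAD oracle is provided for verification on small tables.

#' Median polish of a two-way table
#'
#' Alternating row/column median sweeps (rows first) until the L1
#' objective (sum of absolute residuals) improves by less than `tol` or
#' `max_iter` is reached.  After convergence the decomposition is
#' re-centered once so that `median(a) = median(b) = 0`, with the
#' compensating shifts folded into `mu`; the fitted values and residuals
#' are unchanged by the re-centering.
#'
#' `NA` entries are allowed (e.g. when self-pairs are excluded from the
#' integration design); medians ignore them and their residuals stay
#' `NA`.
#'
#' @param tbl Numeric I x J matrix.
#' @param tol Absolute improvement threshold on the L1 objective.
#' @param max_iter Maximum number of full row+column sweeps.
#' @return List of class `integration_result`: `mu` (grand term), `a`
#'   (target effects, length I, median 0), `b` (reference effects,
#'   length J, median 0), `residuals` (I x J), `objective_l1`,
#'   `iterations`.  `mu + a_i + b_j + residuals_ij` reconstructs each
#'   table entry exactly.
#' @export
median_polish <- function(tbl, tol = 1e-9, max_iter = 100L) {
  tbl <- as.matrix(tbl)
  if (!is.numeric(tbl)) stop("table must be numeric")
  if (any(is.nan(tbl)) || any(is.infinite(tbl)))
    stop("table entries must be finite or NA")
  I <- nrow(tbl); J <- ncol(tbl)
  R <- tbl
  mu <- 0
  a <- numeric(I)
  b <- numeric(J)
  obj <- sum(abs(R), na.rm = TRUE)
  it <- 0L
  while (it < max_iter) {
    it <- it + 1L
    rm_ <- apply(R, 1L, stats::median, na.rm = TRUE)
    rm_[is.na(rm_)] <- 0
    a <- a + rm_
    R <- R - rm_
    d <- stats::median(b)
    mu <- mu + d; b <- b - d
    cm_ <- apply(R, 2L, stats::median, na.rm = TRUE)
    cm_[is.na(cm_)] <- 0
    b <- b + cm_
    R <- R - rep(cm_, each = I)
    d <- stats::median(a)
    mu <- mu + d; a <- a - d
    newobj <- sum(abs(R), na.rm = TRUE)
    if (obj - newobj < tol) { obj <- newobj; break }
    obj <- newobj
  }
  ma <- stats::median(a); mb <- stats::median(b)
  mu <- mu + ma + mb
  a <- a - ma
  b <- b - mb
  names(a) <- rownames(tbl)
  names(b) <- colnames(tbl)
  structure(list(mu = mu, a = a, b = b, residuals = R,
                 objective_l1 = sum(abs(R), na.rm = TRUE), iterations = it),
            class = "integration_result")
}

#' @export
print.integration_result <- function(x, ...) {
  cat(sprintf("two-factor LAD fit (median polish): mu = %.4f, %d x %d, L1 objective = %.4g (%d sweeps)\n",
              x$mu, length(x$a), length(x$b), x$objective_l1, x$iterations))
  invisible(x)
}

#' Exhaustive LAD oracle for the two-factor model
#'
#' Exact minimum of `sum |x_ij - mu - a_i - b_j|` for small tables.  An
#' optimal basic solution of the underlying linear program interpolates
#' `I + J - 1` cells whose bipartite incidence graph spans all rows and
#' columns; the oracle enumerates all spanning-tree cell subsets, solves
#' each interpolation, and returns the best.  The median-zero
#' constraints do not change the objective (they only fix the
#' decomposition), so they are applied by re-centering afterwards.
#'
#' @param tbl Numeric I x J matrix (no `NA`); intended for small
#'   instances (enumeration capped at 500000 subsets).
#' @return List with `objective` (optimal L1 value), `mu`, `a`, `b`
#'   (median-centered optimal parameters).
#' @export
lad_lp_oracle <- function(tbl) {
  tbl <- as.matrix(tbl)
  if (anyNA(tbl) || any(!is.finite(tbl))) stop("table entries must be finite")
  I <- nrow(tbl); J <- ncol(tbl)
  m_edges <- I * J
  p <- I + J - 1L
  if (choose(m_edges, p) > 5e5) stop("instance too large for exhaustive LAD oracle")
  edge_i <- rep(seq_len(I), times = J)
  edge_j <- rep(seq_len(J), each = I)
  combos <- utils::combn(m_edges, p)
  best <- NULL
  for (k in seq_len(ncol(combos))) {
    ed <- combos[, k]
    ei <- edge_i[ed]; ej <- edge_j[ed]
    # solve u_i + b_j = x_ij on the chosen cells by propagation from row 1
    u <- rep(NA_real_, I); v <- rep(NA_real_, J)
    u[1L] <- 0
    repeat {
      changed <- FALSE
      for (e in seq_len(p)) {
        i <- ei[e]; j <- ej[e]
        if (!is.na(u[i]) && is.na(v[j])) { v[j] <- tbl[i, j] - u[i]; changed <- TRUE }
        else if (is.na(u[i]) && !is.na(v[j])) { u[i] <- tbl[i, j] - v[j]; changed <- TRUE }
      }
      if (!changed) break
    }
    if (anyNA(u) || anyNA(v)) next  # not spanning
    obj <- sum(abs(tbl - outer(u, v, "+")))
    if (is.null(best) || obj < best$objective - 1e-12)
      best <- list(objective = obj, u = u, v = v)
  }
  mu <- 0; a <- best$u; b <- best$v
  ma <- stats::median(a); mu <- mu + ma; a <- a - ma
  mb <- stats::median(b); mu <- mu + mb; b <- b - mb
  list(objective = best$objective, mu = mu, a = a, b = b)
}

#' Single-parameter integration (once-for-all shortcut)
#'
#' With all pairwise slopes fixed at 1, the pre-normalized log count of
#' every transcript is `t_i + alpha_ij`, so the per-transcript two-way
#' tables differ from the alpha table only by row constants.  Median
#' polish therefore needs to run once on the alpha table: the final log
#' count of gene g in sample i is `t_gi + mu + a_i`, identical to
#' polishing each transcript's own table.
#'
#' @param alpha I x J matrix of pairwise intercepts (targets x
#'   references); `NA` entries are tolerated (excluded designs).
#' @param logcounts Optional G x I matrix of log2 counts; if supplied,
#'   the shifted log counts are returned as well.
#' @param ... Passed to [median_polish()].
#' @return List with `shifts` (length I, `mu + a_i`; add to each
#'   sample's log counts), `integration` (the `integration_result`),
#'   and `log_counts` (shifted matrix, if `logcounts` given).
#' @export
integrate_sp <- function(alpha, logcounts = NULL, ...) {
  alpha <- as.matrix(alpha)
  pol <- median_polish(alpha, ...)
  shifts <- pol$mu + pol$a
  names(shifts) <- rownames(alpha)
  out <- list(shifts = shifts, integration = pol)
  if (!is.null(logcounts)) {
    if (ncol(logcounts) != nrow(alpha))
      stop("logcounts columns must match alpha rows (targets)")
    out$log_counts <- sweep(logcounts, 2L, shifts, "+")
  }
  out
}

#' Double-parameter integration
#'
#' Integrates pairwise intercepts and slopes across references.
#' Methods:
#' \describe{
#'   \item{`fast`}{median-polish the alpha and beta tables separately
#'     and apply the polished per-target effects
#'     `alpha'_i + beta'_i * t` to all transcripts (heuristic, one
#'     polish per table).}
#'   \item{`ls_average`}{the exact least-squares integration under mean
#'     constraints: per-target row means `mean_j(alpha_ij) +
#'     mean_j(beta_ij) * t`.}
#'   \item{`per_transcript`}{the full model: median-polish each gene's
#'     own I x J table `alpha_ij + beta_ij * t_gi` and read off
#'     `mu + a_i` (O(G) polishes).}
#' }
#'
#' @param alpha,beta I x J matrices of pairwise intercepts and slopes.
#' @param logcounts G x I matrix of log2 counts (targets in columns).
#' @param method Integration method, see Details.
#' @param ... Passed to [median_polish()].
#' @return G x I matrix of integrated (normalized) log2 counts.
#' @export
integrate_dp <- function(alpha, beta, logcounts,
                         method = c("fast", "per_transcript", "ls_average"),
                         ...) {
  method <- match.arg(method)
  alpha <- as.matrix(alpha); beta <- as.matrix(beta)
  if (!identical(dim(alpha), dim(beta))) stop("alpha and beta dimensions differ")
  I <- nrow(alpha)
  if (ncol(logcounts) != I) stop("logcounts columns must match alpha rows (targets)")
  out <- switch(method,
    fast = {
      pa <- median_polish(alpha, ...)
      pb <- median_polish(beta, ...)
      ai <- pa$mu + pa$a
      bi <- pb$mu + pb$a
      sweep(sweep(logcounts, 2L, bi, "*"), 2L, ai, "+")
    },
    ls_average = {
      ai <- rowMeans(alpha, na.rm = TRUE)
      bi <- rowMeans(beta, na.rm = TRUE)
      sweep(sweep(logcounts, 2L, bi, "*"), 2L, ai, "+")
    },
    per_transcript = {
      res <- logcounts
      for (g in seq_len(nrow(logcounts))) {
        tg <- logcounts[g, ]
        tblg <- alpha + beta * tg  # row i constant t_gi recycled down columns
        pol <- median_polish(tblg, ...)
        res[g, ] <- pol$mu + pol$a
      }
      res
    })
  dimnames(out) <- dimnames(logcounts)
  out
}
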