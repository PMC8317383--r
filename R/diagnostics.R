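# Normalization diagnostics: pairwise M/A values, the mode of the
# log-ratio density (a near-zero mode indicates appropriate
# normalization), the empirical skewness of the log ratios (a signature
# of asymmetric regulation that normalization should preserve), and the
# MA-vs-nominal evaluation for spike-in controls.

#' Pairwise M-value (log ratio)
#'
#' `log2(c1 + c) - log2(c2 + c)` per gene.  Antisymmetric in its
#' arguments.
#'
#' @param c1,c2 Non-negative count vectors of equal length.
#' @param c Positive log offset.
#' @return Numeric vector of log2 ratios.
#' @export
m_value <- function(c1, c2, c = 1) {
  if (length(c1) != length(c2)) stop("count vectors must have equal length")
  log2(c1 + c) - log2(c2 + c)
}

#' Pairwise A-value (log average)
#'
#' `(log2(c1 + c) + log2(c2 + c)) / 2` per gene.  Symmetric in its
#' arguments.
#'
#' @inheritParams m_value
#' @return Numeric vector of average log2 abundances.
#' @export
a_value <- function(c1, c2, c = 1) {
  if (length(c1) != length(c2)) stop("count vectors must have equal length")
  (log2(c1 + c) + log2(c2 + c)) / 2
}

#' Empirical skewness
#'
#' Population-moment skewness `S = mean(((x - mu)/sigma)^3)` with the
#' population standard deviation (variance divided by n).  No
#' small-sample bias correction is applied.
#'
#' @param x Numeric vector, length >= 3, non-degenerate.
#' @return The skewness.
#' @export
skewness <- function(x) {
  n <- length(x)
  if (n < 3L) stop("skewness needs at least 3 observations")
  mu <- mean(x)
  s2 <- mean((x - mu)^2)
  if (s2 == 0) stop("skewness undefined: zero variance")
  mean(((x - mu) / sqrt(s2))^3)
}

#' Mean absolute deviation index of skewness (MADSI)
#'
#' `mean(|S_i - S_i'|)` over the pairwise skewness values before
#' (`s_raw`) and after (`s_norm`) normalization.  Smaller values mean
#' the normalization changed the shape of the pairwise differentiation
#' less; 0 means every pairwise skewness is preserved exactly.
#'
#' @param s_raw,s_norm Numeric vectors of equal length (one entry per
#'   sample pair).
#' @return Non-negative scalar.
#' @export
madsi <- function(s_raw, s_norm) {
  if (length(s_raw) != length(s_norm)) stop("skewness vectors must have equal length")
  if (!length(s_raw)) stop("need at least one pair")
  mean(abs(s_raw - s_norm))
}

#' Mode of a kernel density estimate
#'
#' Gaussian-kernel density on a 512-point grid spanning
#' `[min - 3*bw, max + 3*bw]` (the default grid of [stats::density()]),
#' bandwidth by Silverman's rule of thumb.  Returns the grid point of
#' maximal density; ties go to the smallest grid value.
#'
#' @param x Numeric vector, length >= 10, non-degenerate.
#' @param bw Bandwidth rule or value, passed to [stats::density()].
#' @param n_grid Number of grid points.
#' @return The estimated mode.
#' @export
density_mode <- function(x, bw = "nrd0", n_grid = 512L) {
  if (length(x) < 10L) stop("density mode needs at least 10 observations")
  if (stats::sd(x) == 0) stop("density mode undefined: degenerate input")
  d <- stats::density(x, bw = bw, n = n_grid)
  d$x[which.max(d$y)]
}

#' Pairwise diagnostics of a normalization
#'
#' For every unordered sample pair, computes the mode of the log-ratio
#' density and the empirical skewness, before and after normalization,
#' plus the overall MADSI.
#'
#' @param raw,normalized Genes x samples count matrices with matching
#'   dimensions.
#' @param offset Positive log offset.
#' @return List with `pairs` (data frame: `sample1`, `sample2`,
#'   `mode_raw`, `mode_norm`, `skew_raw`, `skew_norm`) and `madsi`.
#' @export
diagnose_normalization <- function(raw, normalized, offset = 1) {
  if (!identical(dim(raw), dim(normalized)))
    stop("raw and normalized matrices must have identical dimensions")
  K <- ncol(raw)
  pr <- utils::combn(K, 2L)
  out <- data.frame(sample1 = colnames(raw)[pr[1L, ]],
                    sample2 = colnames(raw)[pr[2L, ]],
                    mode_raw = NA_real_, mode_norm = NA_real_,
                    skew_raw = NA_real_, skew_norm = NA_real_)
  for (k in seq_len(ncol(pr))) {
    i <- pr[1L, k]; j <- pr[2L, k]
    mr <- m_value(raw[, i], raw[, j], offset)
    mn <- m_value(normalized[, i], normalized[, j], offset)
    out$mode_raw[k] <- density_mode(mr)
    out$mode_norm[k] <- density_mode(mn)
    out$skew_raw[k] <- skewness(mr)
    out$skew_norm[k] <- skewness(mn)
  }
  list(pairs = out, madsi = madsi(out$skew_raw, out$skew_norm))
}

#' MA evaluation of spike-in ratio groups
#'
#' For spike-in controls with known abundance ratios between a
#' treatment and a control condition, computes per-sequence M and A
#' values from the condition means of the (normalized) counts, fits a
#' LOWESS curve of M against A within each ratio group, and compares
#' the mean fitted M with the nominal `log2(ratio)`.
#'
#' @param normalized Genes x samples count matrix containing the
#'   spike-in rows.
#' @param spike Data frame with columns `gene_id` and `ratio`
#'   (treatment:control), e.g. the `spike` element of a
#'   [simulate_dataset()] truth.
#' @param control_ids,treat_ids Sample IDs (or indices) of the two
#'   condition blocks.
#' @param offset Positive log offset.
#' @param span,iter LOWESS smoother span and robustifying iterations.
#' @param plot_file Optional PNG path; if given, an MA panel with the
#'   fitted and nominal lines is written.
#' @return Data frame with one row per ratio group: `ratio`, `n`,
#'   `mean_M`, `mean_fitted_M`, `nominal_M`.
#' @export
ma_panel <- function(normalized, spike, control_ids, treat_ids, offset = 1,
                     span = 2/3, iter = 3L, plot_file = NULL) {
  if (is.null(spike) || !nrow(spike)) stop("no spike-in sequences supplied")
  miss <- setdiff(spike$gene_id, rownames(normalized))
  if (length(miss)) stop("spike-in rows missing from matrix: ", miss[1L])
  ctrl <- rowMeans(normalized[spike$gene_id, control_ids, drop = FALSE])
  trt <- rowMeans(normalized[spike$gene_id, treat_ids, drop = FALSE])
  M <- m_value(trt, ctrl, offset)
  A <- a_value(trt, ctrl, offset)
  groups <- sort(unique(spike$ratio))
  res <- data.frame(ratio = groups, n = NA_integer_, mean_M = NA_real_,
                    mean_fitted_M = NA_real_, nominal_M = log2(groups))
  fits <- vector("list", length(groups))
  for (k in seq_along(groups)) {
    sel <- spike$ratio == groups[k]
    lo <- stats::lowess(A[sel], M[sel], f = span, iter = iter)
    res$n[k] <- sum(sel)
    res$mean_M[k] <- mean(M[sel])
    res$mean_fitted_M[k] <- mean(lo$y)
    fits[[k]] <- lo
  }
  if (!is.null(plot_file)) {
    grDevices::png(plot_file, width = 800, height = 600)
    on.exit(grDevices::dev.off())
    cols <- grDevices::hcl.colors(length(groups), "Dark 3")
    graphics::plot(A, M, pch = 16, cex = 0.7,
                   col = cols[match(spike$ratio, groups)],
                   xlab = "A (mean log2 abundance)", ylab = "M (log2 ratio)")
    for (k in seq_along(groups)) {
      graphics::lines(fits[[k]], col = cols[k], lty = 2, lwd = 2)
      graphics::abline(h = res$nominal_M[k], col = cols[k], lwd = 1.5)
    }
    graphics::legend("topright", legend = sprintf("%g : 1", groups),
                     col = cols, pch = 16, bty = "n")
  }
  res
}
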