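# Reference implementations of the standard comparator normalizers,
# following their published definitions.  Methods with a per-sample
# linear factor attach it as attribute "scaling_factors"; factors are
# rescaled to unit geometric mean so only their ratios matter, and the
# normalized counts are raw counts divided by the factor's reciprocal
# scale (counts_norm = counts * factor).

geomean <- function(x) exp(mean(log(x)))

# Normalize so factors multiply raw counts onto the common scale and
# have unit geometric mean.
apply_factors <- function(m, size) {
  if (any(!is.finite(size) | size <= 0)) stop("invalid library size/scale")
  f <- geomean(size) / size
  out <- sweep(m, 2L, f, "*")
  attr(out, "scaling_factors") <- stats::setNames(f, colnames(m))
  out
}

#' Baseline normalizers
#'
#' Standard between-sample normalizers used as comparators:
#' \describe{
#'   \item{`norm_cpm`}{counts per million: divide by the library size.}
#'   \item{`norm_tpm`}{transcripts per million: divide by transcript
#'     length, then scale each sample's length-normalized rates to sum
#'     to 1e6.}
#'   \item{`norm_uq`}{upper-quartile scaling on the nonzero counts.}
#'   \item{`norm_rle`}{relative log expression: per-sample median ratio
#'     to the per-gene geometric-mean pseudo-sample (genes with a zero
#'     are excluded from the pseudo-sample).}
#'   \item{`norm_tmm`}{trimmed mean of M-values: per-sample
#'     precision-weighted mean of the log ratios to a reference sample,
#'     doubly trimmed on M (30\%) and A (5\%); the reference is the
#'     sample whose upper quartile of library-scaled counts is closest
#'     to the mean upper quartile.}
#'   \item{`norm_quantile`}{force every sample onto the common
#'     distribution of rank-averaged counts; tied counts receive the
#'     mean of the averaged quantiles over their rank span.}
#' }
#' All but `norm_tpm` and `norm_quantile` are pure per-sample
#' rescalings; their factors (multiplying raw counts, unit geometric
#' mean) are attached as attribute `"scaling_factors"`.
#'
#' @param m Non-negative genes x samples count matrix.
#' @param lengths Named numeric vector of transcript lengths covering
#'   all genes (TPM only).
#' @param q Quantile used by the upper-quartile method.
#' @param trim_M,trim_A Two-sided trim fractions on M and A (TMM).
#' @param ref Reference column index for TMM; `NULL` = automatic.
#' @return Normalized count matrix (see Details for the attached
#'   factors).
#' @name baselines
NULL

#' @rdname baselines
#' @export
norm_cpm <- function(m) {
  m <- validate_counts(m)
  N <- colSums(m)
  if (any(N <= 0)) stop("zero library size")
  out <- sweep(m, 2L, N / 1e6, "/")
  attr(out, "scaling_factors") <- stats::setNames(1e6 / N, colnames(m))
  out
}

#' @rdname baselines
#' @export
norm_tpm <- function(m, lengths) {
  m <- validate_counts(m)
  if (is.null(lengths)) stop("tpm requires transcript lengths")
  len <- lengths[rownames(m)]
  if (anyNA(len) || any(len <= 0)) stop("missing or non-positive transcript length")
  rate <- m / len
  out <- sweep(rate, 2L, colSums(rate) / 1e6, "/")
  attr(out, "scaling_factors") <- NULL
  out
}

#' @rdname baselines
#' @export
norm_uq <- function(m, q = 0.75) {
  m <- validate_counts(m)
  size <- apply(m, 2L, function(v) {
    v <- v[v > 0]
    if (!length(v)) stop("all-zero sample")
    stats::quantile(v, q, names = FALSE)
  })
  apply_factors(m, size)
}

#' @rdname baselines
#' @export
norm_rle <- function(m) {
  m <- validate_counts(m)
  pos <- rowSums(m == 0) == 0L
  if (!any(pos)) stop("RLE undefined: no gene has nonzero counts in all samples")
  geo <- exp(rowMeans(log(m[pos, , drop = FALSE])))
  size <- apply(m[pos, , drop = FALSE], 2L, function(v) stats::median(v / geo))
  apply_factors(m, size)
}

#' @rdname baselines
#' @export
norm_tmm <- function(m, trim_M = 0.30, trim_A = 0.05, ref = NULL) {
  m <- validate_counts(m)
  N <- colSums(m)
  if (any(N <= 0)) stop("zero library size")
  f75 <- vapply(seq_len(ncol(m)),
                function(j) stats::quantile(m[, j] / N[j], 0.75, names = FALSE),
                numeric(1L))
  if (is.null(ref)) ref <- which.min(abs(f75 - mean(f75)))
  f <- vapply(seq_len(ncol(m)), function(j) {
    if (j == ref) return(1)
    keep <- m[, j] > 0 & m[, ref] > 0
    pj <- m[keep, j] / N[j]
    pr <- m[keep, ref] / N[ref]
    M <- log2(pj / pr)
    A <- (log2(pj) + log2(pr)) / 2
    # precision weights: delta-method variance of M
    w <- (N[j] - m[keep, j]) / (N[j] * m[keep, j]) +
         (N[ref] - m[keep, ref]) / (N[ref] * m[keep, ref])
    n <- length(M)
    loM <- floor(n * trim_M) + 1; hiM <- n + 1 - loM
    loA <- floor(n * trim_A) + 1; hiA <- n + 1 - loA
    keep2 <- rank(M) >= loM & rank(M) <= hiM & rank(A) >= loA & rank(A) <= hiA
    2^(sum(M[keep2] / w[keep2]) / sum(1 / w[keep2]))
  }, numeric(1L))
  f <- f / geomean(f)
  # effective library sizes N * f play the role of sizes
  apply_factors(m, N * f)
}

#' @rdname baselines
#' @export
norm_quantile <- function(m) {
  m <- validate_counts(m)
  ref <- rowMeans(apply(m, 2L, sort.int))
  out <- apply(m, 2L, function(v) {
    s <- ref[order(order(v))]     # rank-assigned quantiles (stable within ties)
    stats::ave(s, v, FUN = mean)  # tied counts get the mean over their rank span
  })
  dimnames(out) <- dimnames(m)
  attr(out, "scaling_factors") <- NULL
  out
}
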