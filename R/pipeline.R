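# Orchestration: reference selection, all target x reference LTS fits,
# integration, back-transform to the count scale, scaling-factor export.

#' Select reference samples
#'
#' Strategies: `"all"` takes every sample (sensible for small K);
#' `"random:k"` draws k distinct samples reproducibly from `seed`
#' (for large K); a character vector of sample IDs (or an integer
#' vector of column indices) selects them explicitly.
#'
#' @param m Count matrix (samples in columns).
#' @param strategy `"all"`, `"random:k"`, or explicit IDs/indices.
#' @param seed Integer seed used by the random strategy.
#' @return Integer vector of reference column indices.
#' @export
select_references <- function(m, strategy = "all", seed = 1L) {
  K <- ncol(m)
  ids <- colnames(m)
  if (is.numeric(strategy)) {
    idx <- as.integer(strategy)
    if (any(idx < 1L | idx > K)) stop("reference index out of range")
    return(idx)
  }
  if (length(strategy) == 1L && strategy == "all") return(seq_len(K))
  if (length(strategy) == 1L && grepl("^random:[0-9]+$", strategy)) {
    k <- as.integer(sub("^random:", "", strategy))
    if (k < 1L || k > K) stop("random reference count k must be in 1..K")
    return(sort.int(with_seed(seed, sample.int(K, k))))
  }
  idx <- match(strategy, ids)
  if (anyNA(idx))
    stop("unknown reference sample ID: ", strategy[is.na(idx)][1L])
  idx
}

# Fit one (target, reference) pair on the genes passing the pair filter.
fit_one_pair <- function(i, j_col, counts, L, mode, trim, min_count,
                         n_starts, n_csteps, seed) {
  ids <- colnames(counts)
  if (i == j_col)  # self-pair: exact identity fit
    return(new_pairwise_fit(0, 1, nrow(counts), seq_len(nrow(counts)), 0,
                            mode, nrow(counts), ids[i], ids[j_col]))
  keep <- counts[, i] >= min_count | counts[, j_col] >= min_count
  n <- sum(keep)
  if (n < 4L) stop("fewer than 4 genes pass the pair filter for samples ",
                   ids[i], " / ", ids[j_col])
  h <- min(max(floor(n / 2) + 1L, ceiling((1 - trim) * n)), n)
  lts_fit(L[keep, i], L[keep, j_col], h, mode = mode, n_starts = n_starts,
          n_csteps = n_csteps, seed = seed,
          target_id = ids[i], ref_id = ids[j_col])
}

#' Normalize a count matrix
#'
#' The multi-reference methods (`"mr-sp"`, `"mr-dp"`) run the full
#' workflow: log-offset transform, LTS fit of every target against
#' every reference (self-pairs fit the identity exactly and anchor the
#' design), integration of the pairwise coefficients by median polish,
#' and back-transform `2^v - c` clipped at 0.  The comparator methods
#' (`"cpm"`, `"tpm"`, `"uq"`, `"rle"`, `"tmm"`, `"quantile"`) apply the
#' standard normalizers from [baseline normalizers][norm_cpm].
#'
#' Pairwise fits are independent; with `workers > 1` they are run via
#' forked processes with per-pair derived seeds, so results are
#' identical for any worker count.
#'
#' @param counts Non-negative genes x samples matrix (K >= 2) with
#'   gene/sample identifiers as dimnames.
#' @param method Normalization method (see Details).
#' @param offset Positive log offset `c` (default 1).
#' @param trim Trimming proportion of the pairwise LTS fits, in
#'   (0, 0.5); the retained fraction is `1 - trim`.
#' @param refs Reference selection, see [select_references()].
#' @param seed Integer seed for random reference selection and the dp
#'   random starts.
#' @param dp_method Integration method in dp mode, see [integrate_dp()].
#' @param min_count Pair pre-filter: genes with count below this in
#'   *both* samples of a pair are dropped from that fit (they still
#'   receive normalized values).
#' @param include_self Include self-pairs in the integration design
#'   (default `TRUE`); if `FALSE` the diagonal of the coefficient
#'   tables is `NA` and medians skip it.
#' @param workers Number of parallel workers for the pairwise fits.
#' @param n_starts,n_csteps FAST-LTS parameters, see [lts_fit()].
#' @param lengths Named numeric vector of transcript lengths (only for
#'   `method = "tpm"`).
#' @return Object of class `norm_result`: list with `counts`
#'   (normalized, count scale), `log_counts`, `scaling_factors`
#'   (per-sample factors multiplying raw counts to the normalized
#'   scale; `NULL` for methods without a single per-sample factor),
#'   `method`, `offset`, and for the multi-reference methods `fits`
#'   (list of `pairwise_fit`), `alpha`/`beta` coefficient tables,
#'   `integration`, `refs`.
#' @examples
#' m <- cbind(s1 = c(100, 50, 10), s2 = c(400, 200, 40))
#' rownames(m) <- paste0("g", 1:3)
#' res <- normalize_counts(m, "mr-sp")
#' res$scaling_factors
#' @export
normalize_counts <- function(counts,
                             method = c("mr-sp", "mr-dp", "cpm", "tpm", "uq",
                                        "rle", "tmm", "quantile"),
                             offset = 1, trim = 0.25, refs = "all", seed = 1L,
                             dp_method = c("fast", "per_transcript", "ls_average"),
                             min_count = 1, include_self = TRUE, workers = 1L,
                             n_starts = 500L, n_csteps = 50L, lengths = NULL) {
  method <- match.arg(method)
  dp_method <- match.arg(dp_method)
  counts <- validate_counts(counts)
  if (ncol(counts) < 2L) stop("normalization needs at least 2 samples")
  if (trim <= 0 || trim >= 0.5) stop("trim must be in (0, 0.5)")

  if (!startsWith(method, "mr-")) {
    norm <- switch(method,
                   cpm = norm_cpm(counts),
                   tpm = norm_tpm(counts, lengths),
                   uq = norm_uq(counts),
                   rle = norm_rle(counts),
                   tmm = norm_tmm(counts),
                   quantile = norm_quantile(counts))
    sf <- attr(norm, "scaling_factors")
    attr(norm, "scaling_factors") <- NULL
    return(structure(list(counts = norm,
                          log_counts = log_transform(norm, offset),
                          scaling_factors = sf, method = method,
                          offset = offset), class = "norm_result"))
  }

  mode <- if (method == "mr-sp") "sp" else "dp"
  K <- ncol(counts)
  L <- log_transform(counts, offset)
  ref_idx <- select_references(counts, refs, seed)
  J <- length(ref_idx)

  grid <- expand.grid(i = seq_len(K), j = seq_len(J))
  pair_seed <- function(k) (as.integer(seed) + 7919L * k) %% 2147483629L
  fit_k <- function(k) {
    i <- grid$i[k]; jc <- ref_idx[grid$j[k]]
    fit_one_pair(i, jc, counts, L, mode, trim, min_count,
                 n_starts, n_csteps, pair_seed(k))
  }
  fits <- if (workers > 1L) {
    parallel::mclapply(seq_len(nrow(grid)), fit_k, mc.cores = workers)
  } else {
    lapply(seq_len(nrow(grid)), fit_k)
  }
  alpha <- matrix(NA_real_, K, J,
                  dimnames = list(colnames(counts), colnames(counts)[ref_idx]))
  beta <- alpha
  for (k in seq_len(nrow(grid))) {
    alpha[grid$i[k], grid$j[k]] <- fits[[k]]$alpha
    beta[grid$i[k], grid$j[k]] <- fits[[k]]$beta
  }
  if (!include_self) {
    for (j in seq_len(J)) {
      i <- ref_idx[j]
      alpha[i, j] <- NA_real_
      beta[i, j] <- NA_real_
    }
    if (any(rowSums(!is.na(alpha)) == 0L))
      stop("excluding self-pairs left a target with no references")
  }

  if (mode == "sp") {
    integ <- integrate_sp(alpha, L)
    shifts <- integ$shifts
    log_norm <- sweep(L, 2L, shifts, "+")
    sf <- 2^shifts
    integration <- integ$integration
  } else {
    log_norm <- integrate_dp(alpha, beta, L, method = dp_method)
    sf <- NULL
    integration <- NULL
  }
  counts_norm <- inv_log_transform(log_norm, offset)
  dimnames(counts_norm) <- dimnames(counts)
  attr(log_norm, "offset") <- offset
  structure(list(counts = counts_norm, log_counts = log_norm,
                 scaling_factors = sf, method = method, offset = offset,
                 fits = fits, alpha = alpha, beta = beta,
                 integration = integration, refs = ref_idx,
                 dp_method = if (mode == "dp") dp_method else NULL),
            class = "norm_result")
}

#' @export
print.norm_result <- function(x, ...) {
  cat(sprintf("normalized counts (%s): %d genes x %d samples\n",
              x$method, nrow(x$counts), ncol(x$counts)))
  if (!is.null(x$scaling_factors)) {
    cat("scaling factors:\n")
    print(round(x$scaling_factors, 4))
  }
  invisible(x)
}

#' Export per-sample scaling factors
#'
#' Writes a two-column TSV (`sample_id`, `factor`) of the per-sample
#' scaling factors, usable as library-size/size-factor substitutes in
#' count-based differential expression tools.  The factors multiply raw
#' counts to the normalized scale.  Only defined for methods that
#' produce a single per-sample factor (e.g. `mr-sp`); the dp power-law
#' normalization has no such factor and is refused.
#'
#' @param res A `norm_result`.
#' @param path Output TSV path.
#' @return Invisibly, `path`.
#' @export
export_factors <- function(res, path) {
  if (!inherits(res, "norm_result")) stop("res must be a norm_result")
  sf <- res$scaling_factors
  if (is.null(sf))
    stop("scaling factors undefined for method '", res$method,
         "' (no single per-sample factor exists)")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# scaling factors (%s); geometric mean = %.8g",
                     res$method, exp(mean(log(sf)))), con)
  writeLines("sample_id\tfactor", con)
  writeLines(sprintf("%s\t%.10g", names(sf), sf), con)
  invisible(path)
}
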