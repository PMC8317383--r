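# Synthetic RNA-seq benchmark data with the structure the evaluation
# experiments assume: a majority-undifferentiated transcriptome with a
# tunable, possibly fully asymmetric DE fraction; per-sample scaling
# and power-law distortions; spike-in control groups at fixed nominal
# abundance ratios; a top-ratio truncation perturbation; and corrupted
# outlier samples.  Counts are negative binomial with variance
# mu + dispersion * mu^2 (Poisson when dispersion = 0).

#' Spike-in control design
#'
#' Groups of external control sequences at fixed nominal
#' treatment:control abundance ratios, mirroring ERCC-style mixes:
#' four ratio groups (1, 1.5, 2, 4), 23 sequences each, with baseline
#' abundances log-uniform over a wide range.
#'
#' @param group_ratios Positive treatment:control ratios, one per group.
#' @param seqs_per_group Sequences per ratio group.
#' @param abundance_range Log-uniform bounds for the baseline mean
#'   counts of the spike-in sequences.
#' @return List of class `spikein_design`.
#' @export
spikein_design <- function(group_ratios = c(1, 1.5, 2, 4),
                           seqs_per_group = 23L,
                           abundance_range = c(8, 32768)) {
  if (any(group_ratios <= 0)) stop("ratios must be positive")
  if (seqs_per_group < 1L) stop("seqs_per_group must be >= 1")
  structure(list(group_ratios = group_ratios,
                 seqs_per_group = as.integer(seqs_per_group),
                 abundance_range = abundance_range),
            class = "spikein_design")
}

rcounts <- function(n, mu, dispersion) {
  if (dispersion <= 0) stats::rpois(n, mu)
  else stats::rnbinom(n, mu = mu, size = 1 / dispersion)
}

#' Simulate a benchmark count dataset with known truth
#'
#' Two condition blocks (control = first `ceiling(K/2)` samples,
#' treatment = rest).  Baseline log2 mean abundances are log-normal; a
#' fraction `de_frac` of genes is differentially expressed between the
#' blocks, a share `asym` of them up-regulated, with log2 effect sizes
#' drawn log-normal.  Each sample k then distorts the mean counts as
#' `scale_k * mean^power_k` (a log-linear distortion: `power = 1`
#' everywhere is pure scaling), and counts are drawn negative binomial.
#' Optionally a [spikein_design()] appends control sequences whose
#' means follow the nominal group ratios between the blocks and that
#' are subject to the same per-sample distortions (with their own,
#' smaller, technical dispersion).
#'
#' @param G Number of genes (spike-ins come on top).
#' @param K Number of samples (>= 2).
#' @param de_frac Fraction of DE genes, in [0, 0.5): the majority of
#'   the transcriptome must stay undifferentiated.
#' @param asym Share of DE genes that are up-regulated (1 = fully
#'   asymmetric).
#' @param effect_meanlog,effect_sdlog Log-normal parameters of the
#'   log2 effect-size magnitudes.
#' @param base_log2_meanlog,base_log2_sdlog Log-normal parameters of
#'   the baseline log2 mean abundances.
#' @param scale_range Range of the per-sample scale distortion `2^alpha`
#'   (drawn log2-uniform).
#' @param power_range Range of the per-sample power distortion `beta`
#'   (uniform; `c(1, 1)` = none).
#' @param nb_dispersion Negative-binomial dispersion of the genes
#'   (variance `mu + disp * mu^2`); 0 gives Poisson counts.
#' @param spike A [spikein_design()] or `NULL`.
#' @param spike_dispersion Dispersion of the spike-in sequences
#'   (technical controls: smaller than the biological dispersion).
#' @param seed Integer seed; the dataset is fully reproducible from it.
#' @return List with `counts` (matrix, spike-ins appended as rows) and
#'   `truth`: list with `condition` (per sample), `sample_scale`,
#'   `sample_power`, `de` (data frame `gene_id`, `status` in
#'   none/up/down, `lfc` signed log2 effect), and `spike` (data frame
#'   `gene_id`, `ratio`, `group`, or `NULL`).
#' @export
simulate_dataset <- function(G = 2000L, K = 6L, de_frac = 0.2, asym = 0.5,
                             effect_meanlog = 0, effect_sdlog = 0.5,
                             base_log2_meanlog = 1.6, base_log2_sdlog = 0.45,
                             scale_range = c(0.25, 4), power_range = c(1, 1),
                             nb_dispersion = 0.1, spike = NULL,
                             spike_dispersion = 0.01, seed = 1L) {
  if (de_frac < 0 || de_frac >= 0.5)
    stop("de_frac must be in [0, 0.5): most of the transcriptome must be undifferentiated")
  if (K < 2L) stop("need at least 2 samples")
  with_seed(seed, {
    cond <- rep(c("control", "treatment"), c(ceiling(K / 2), floor(K / 2)))
    sample_ids <- sprintf("s%d", seq_len(K))
    sample_scale <- 2^stats::runif(K, log2(scale_range[1L]), log2(scale_range[2L]))
    sample_power <- stats::runif(K, power_range[1L], power_range[2L])

    base_mu <- 2^stats::rlnorm(G, base_log2_meanlog, base_log2_sdlog)
    n_de <- round(de_frac * G)
    de_idx <- if (n_de > 0) sort.int(sample.int(G, n_de)) else integer(0)
    status <- rep("none", G)
    lfc <- numeric(G)
    if (n_de > 0) {
      up <- stats::runif(n_de) < asym
      mag <- stats::rlnorm(n_de, effect_meanlog, effect_sdlog)
      lfc[de_idx] <- ifelse(up, mag, -mag)
      status[de_idx] <- ifelse(up, "up", "down")
    }
    mu <- outer(base_mu, rep(1, K))
    trt <- cond == "treatment"
    mu[, trt] <- mu[, trt] * 2^lfc
    mu_dist <- sweep(mu^rep(sample_power, each = G), 2L, sample_scale, "*")
    counts <- matrix(rcounts(G * K, as.vector(mu_dist), nb_dispersion), G, K)
    gene_ids <- sprintf("g%05d", seq_len(G))

    spike_truth <- NULL
    if (!is.null(spike)) {
      stopifnot(inherits(spike, "spikein_design"))
      S <- length(spike$group_ratios) * spike$seqs_per_group
      ratio <- rep(spike$group_ratios, each = spike$seqs_per_group)
      sbase <- 2^stats::runif(S, log2(spike$abundance_range[1L]),
                              log2(spike$abundance_range[2L]))
      smu <- outer(sbase, rep(1, K))
      smu[, trt] <- smu[, trt] * ratio
      smu_dist <- sweep(smu^rep(sample_power, each = S), 2L, sample_scale, "*")
      scounts <- matrix(rcounts(S * K, as.vector(smu_dist), spike_dispersion), S, K)
      sid <- sprintf("spike_%g_%02d", ratio,
                     unlist(lapply(spike$group_ratios,
                                   function(g) seq_len(spike$seqs_per_group))))
      counts <- rbind(counts, scounts)
      gene_ids <- c(gene_ids, sid)
      spike_truth <- data.frame(gene_id = sid, ratio = ratio,
                                group = match(ratio, sort(unique(ratio))))
    }
    dimnames(counts) <- list(gene_ids, sample_ids)
    list(counts = counts,
         truth = list(condition = stats::setNames(cond, sample_ids),
                      sample_scale = stats::setNames(sample_scale, sample_ids),
                      sample_power = stats::setNames(sample_power, sample_ids),
                      de = data.frame(gene_id = sprintf("g%05d", seq_len(G)),
                                      status = status, lfc = lfc),
                      spike = spike_truth))
  })
}

#' Truncate the top fraction of genes by treatment/control ratio
#'
#' Summarizes each gene by the median of the control columns and of the
#' treatment columns, ranks genes by the ratio
#' `(median_treat + 1) / (median_control + 1)`, and removes the top
#' `floor(frac * G)` genes from *all* samples.  Ties are broken by gene
#' index (stable ascending sort), so among equal ratios the
#' largest-index genes are removed.  This perturbation makes the
#' remaining transcriptome asymmetric and is used to stress-test
#' normalizers.
#'
#' @param m Genes x samples count matrix.
#' @param control_ids,treat_ids Sample IDs (or indices) of the two
#'   blocks; both non-empty.
#' @param frac Fraction to remove, in (0, 0.5) (0 allowed: identity).
#' @return The truncated count matrix.
#' @export
truncate_top <- function(m, control_ids, treat_ids, frac = 0.15) {
  if (!length(control_ids) || !length(treat_ids)) stop("both sample groups must be non-empty")
  if (frac < 0 || frac >= 0.5) stop("frac must be in [0, 0.5)")
  G <- nrow(m)
  n_drop <- floor(frac * G)
  if (n_drop == 0L) return(m)
  med_c <- apply(m[, control_ids, drop = FALSE], 1L, stats::median)
  med_t <- apply(m[, treat_ids, drop = FALSE], 1L, stats::median)
  ratio <- (med_t + 1) / (med_c + 1)
  ord <- order(ratio, seq_len(G))  # stable: ties removed at largest index
  drop <- ord[seq.int(G - n_drop + 1L, G)]
  m[-drop, , drop = FALSE]
}

#' Corrupt one sample with random count distortions
#'
#' Multiplies a seeded random subset (`floor(frac_genes * G)` genes) of
#' one sample's counts by `2^(+/- magnitude)` with random signs,
#' emulating a contaminated or otherwise faulty outlier sample.  Other
#' samples are untouched.
#'
#' @param m Genes x samples count matrix.
#' @param sample_id Sample ID (or column index) to corrupt.
#' @param frac_genes Fraction of genes to disturb, in [0, 1].
#' @param magnitude Absolute log2 distortion per disturbed gene.
#' @param seed Integer seed.
#' @return The corrupted count matrix.
#' @export
inject_outlier <- function(m, sample_id, frac_genes, magnitude, seed = 1L) {
  j <- if (is.numeric(sample_id)) as.integer(sample_id) else match(sample_id, colnames(m))
  if (is.na(j) || j < 1L || j > ncol(m)) stop("unknown sample: ", sample_id)
  G <- nrow(m)
  n_mod <- floor(frac_genes * G)
  if (n_mod == 0L) return(m)
  with_seed(seed, {
    idx <- sample.int(G, n_mod)
    sgn <- sample(c(-1, 1), n_mod, replace = TRUE)
    m[idx, j] <- m[idx, j] * 2^(sgn * magnitude)
  })
  m
}
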