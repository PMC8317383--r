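# mrnorm — robust multi-reference normalization of RNA-seq counts

`mrnorm` normalizes a genes × samples matrix of RNA-seq read counts by
pairwise robust regression against **multiple reference samples**,
instead of assuming a global housekeeping/invariant gene set (which
shrinks toward emptiness as sample collections grow, while an
undifferentiated set between any *pair* of samples remains well
defined).  It is aimed at anyone preparing count matrices for
differential expression or downstream quantitative analysis,
especially when differentiation may be **asymmetric** (unbalanced up-
vs down-regulation), where depth- and distribution-matching
normalizers go wrong.

## The model

Each target sample is fitted against each reference on offset log
counts, `t = log2(T + c)`, `r = log2(R + c)` with `c = 1`:

    r_i = α + β t_i + ε_i

by **least trimmed squares** (LTS): minimize the sum of the `h`
smallest squared residuals (`h = 0.75 n` by default).  The retained
transcripts are the pair's empirical undifferentiated set; up to
`n − h` differentially expressed transcripts cannot move the fit.
With `β = 1` (single-parameter mode, `mr-sp`) the correction is a pure
scaling `2^α`; with `β` free (`mr-dp`) it is a power law on the count
scale.  The I × J pairwise coefficients are then integrated under the
two-factor model

    t̂⁽ⁱʲ⁾ = μ + a⁽ⁱ⁾ + b⁽ʲ⁾ + ε⁽ⁱʲ⁾,  median{a⁽ⁱ⁾} = median{b⁽ʲ⁾} = 0

fitted by least absolute deviations via Tukey's **median polish**, so a
single corrupted reference cannot drag the result.  The normalized log
count of sample *i* is `t_i + μ + a⁽ⁱ⁾`; in sp mode `2^(μ + a⁽ⁱ⁾)` is a
per-sample scaling factor usable as a size-factor substitute in
edgeR/DESeq2-style tools.

The package also ships normalization diagnostics (log-ratio density
modes, skewness preservation / MADSI, spike-in MA panels), reference
implementations of the standard comparators (CPM, TPM, UQ, RLE, TMM,
quantile), and a synthetic-data generator with known ground truth.

## Worked example

```r
library(mrnorm)

sim <- simulate_dataset(G = 2000, K = 6, de_frac = 0.2, asym = 0.5,
                        base_log2_meanlog = 2.2, seed = 42)
res <- normalize_counts(sim$counts, method = "mr-sp")
res
#> normalized counts (mr-sp): 2000 genes x 6 samples
#> scaling factors:
#>     s1     s2     s3     s4     s5     s6
#> 0.6169 0.5792 3.4440 0.7814 1.2798 1.8521
```

The simulation distorted sample depths by known factors
(`sim$truth$sample_scale`, here 3.16, 3.36, 0.55, 2.50, 1.48, 1.05);
the estimated factors invert them: `log2` of factor × true scale,
centered at its median, is

```r
err <- log2(res$scaling_factors * sim$truth$sample_scale)
round(err - median(err), 4)
#>      s1      s2      s3      s4      s5      s6
#>  0.0010 -0.0010 -0.0328  0.0045 -0.0385  0.0042
```

i.e. every factor is recovered within 0.04 log2 (≈ 3%).  The
diagnostics show what normalization did and did not change:

```r
d <- diagnose_normalization(sim$counts, res$counts)
head(d$pairs[, 3:6], 3)
#>   mode_raw mode_norm skew_raw skew_norm
#> 1  -0.1788   -0.0877  -0.0100   -0.0100
#> 2   2.5360    0.0551   0.1163    0.1163
#> 3   0.2271   -0.1138   0.1001    0.1001
d$madsi
#> 2.65e-16
```

Modes of the pairwise log-ratio densities move to ≈ 0 (sample pair
s1–s3 started 2.54 log2 units apart), while the pairwise skewness —
the biological asymmetry signature — is untouched (MADSI ≈ 0; a pure
scaling cannot alter skewness, which is exactly the point).

A thin command-line wrapper is included:

```sh
Rscript inst/scripts/mrnorm.R simulate --genes 2000 --samples 6 --seed 1 --out sim
Rscript inst/scripts/mrnorm.R normalize --counts sim.counts.tsv --method mr-sp \
    --out sim.norm.tsv --factors sim.factors.tsv
Rscript inst/scripts/mrnorm.R diagnose --counts sim.counts.tsv \
    --normalized sim.norm.tsv --out-dir diag
```

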