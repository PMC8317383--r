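# Fixtures are built in code; no data files.

random_counts <- function(G = 20, K = 3, lambda = 50, seed = 1) {
  set.seed(seed)
  matrix(rpois(G * K, lambda), G, K,
         dimnames = list(sprintf("g%03d", seq_len(G)), paste0("s", seq_len(K))))
}

# A target/reference log-count pair with a fraction of one-sided DE.
de_pair <- function(n = 200, frac_de = 0.2, shift = 3, alpha = 1, seed = 1) {
  set.seed(seed)
  t <- rnorm(n, 8, 2)
  r <- alpha + t + rnorm(n, 0, 0.2)
  nde <- round(frac_de * n)
  de <- sample(n, nde)
  r[de] <- r[de] + shift
  list(t = t, r = r, de = sort(de))
}
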