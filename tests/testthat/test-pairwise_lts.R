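test_that("log-offset transform matches its closed form and inverts cleanly", {
  expect_equal(as.numeric(log_transform(4, 1) - log_transform(0, 1)), log2(5))
  expect_equal(round(as.numeric(log_transform(4, 1) - log_transform(0, 1)), 1), 2.3)
  expect_equal(round(as.numeric(log_transform(4, 1e-4) - log_transform(0, 1e-4)), 1), 15.3)
  expect_equal(as.numeric(log_transform(0, 1)), 0)  # zero count stays zero

  m <- random_counts(G = 30, K = 3, seed = 5) + 0.5
  lm_ <- log_transform(m, 1)
  expect_equal(inv_log_transform(lm_), m, tolerance = 1e-9,
               ignore_attr = TRUE)
  expect_error(log_transform(m, 0), "positive")
  expect_error(log_transform(m, -1), "positive")
})

test_that("identity pairs give a zero-objective identity fit in both modes", {
  set.seed(3)
  t <- rnorm(20, 8, 2)
  for (mode in c("sp", "dp")) {
    f <- lts_fit(t, t, 15, mode, seed = 1)
    expect_equal(f$alpha, 0, tolerance = 1e-12)
    expect_equal(f$beta, 1, tolerance = 1e-12)
    expect_equal(f$objective, 0, tolerance = 1e-12)
  }
})

test_that("sp fit recovers the majority shift and excludes outliers", {
  set.seed(4)
  t <- rnorm(20, 8, 2)
  r <- t + 2
  r[1:3] <- r[1:3] + 10
  f <- lts_fit(t, r, 15, "sp")
  expect_equal(f$alpha, 2, tolerance = 1e-12)
  expect_length(f$retained, 15)
  expect_false(any(1:3 %in% f$retained))
  expect_equal(f$objective, sum((r - t - f$alpha)[f$retained]^2),
               tolerance = 1e-9)
})

test_that("FAST-LTS attains the exhaustive-oracle objective on small instances", {
  n_ok <- 0L
  for (seed in 1:12) {
    set.seed(seed)
    t <- rnorm(12, 6, 2)
    r <- 0.5 + 1.2 * t + rnorm(12, 0, 0.5)
    r[sample(12, 3)] <- r[sample(12, 3)] + 6
    fo <- lts_exhaustive_oracle(t, r, 8, "dp")
    fh <- lts_fit(t, r, 8, "dp", n_starts = 500, seed = seed)
    expect_gte(fh$objective, fo$objective - 1e-9)
    if (fh$objective <= fo$objective + 1e-6) n_ok <- n_ok + 1L
  }
  expect_gte(n_ok, 11L)
})

test_that("untrimmed oracle (h = n) equals plain least squares", {
  set.seed(7)
  t <- rnorm(10, 5, 1.5)
  r <- 2 + 0.7 * t + rnorm(10, 0, 0.4)
  fo <- lts_exhaustive_oracle(t, r, 10, "dp")
  ls <- unname(coef(lm(r ~ t)))
  expect_equal(fo$alpha, ls[1], tolerance = 1e-9)
  expect_equal(fo$beta, ls[2], tolerance = 1e-9)
})

test_that("oracle recovers a clean line under contamination", {
  t <- seq(1, 8, length.out = 8)
  r <- 1 + 2 * t
  r[c(2, 5)] <- r[c(2, 5)] + 20
  fo <- lts_exhaustive_oracle(t, r, 6, "dp")
  expect_equal(fo$alpha, 1, tolerance = 1e-9)
  expect_equal(fo$beta, 2, tolerance = 1e-9)
  expect_equal(fo$objective, 0, tolerance = 1e-12)
})

test_that("signed residuals average to zero over the retained set", {
  for (seed in 1:10) {
    p <- de_pair(n = 150, seed = seed)
    for (mode in c("sp", "dp")) {
      f <- lts_fit(p$t, p$r, 112, mode, n_starts = 100, seed = seed)
      resid <- p$r - f$alpha - f$beta * p$t
      expect_lt(abs(mean(resid[f$retained])), 1e-8)
    }
  }
})

test_that("contamination below the breakdown point leaves an exact fit unmoved", {
  set.seed(11)
  t <- rnorm(20, 6, 2)
  r <- 1.5 + 1.1 * t          # exact line
  for (n_bad in c(1, 3, 5)) { # up to n - h = 5
    rb <- r
    rb[seq_len(n_bad)] <- rb[seq_len(n_bad)] + runif(n_bad, 10, 30)
    f <- lts_fit(t, rb, 15, "dp", n_starts = 300, seed = 1)
    expect_equal(f$alpha, 1.5, tolerance = 1e-6)
    expect_equal(f$beta, 1.1, tolerance = 1e-6)
  }
})

test_that("sp alpha is depth-equivariant for large counts", {
  set.seed(12)
  counts_t <- rpois(500, 5000)
  counts_r <- rpois(500, 5000)
  for (d in c(1, 2.5)) {
    f0 <- lts_fit(log2(counts_t + 1), log2(counts_r + 1), 375, "sp")
    f1 <- lts_fit(log2(counts_t * 2^d + 1), log2(counts_r + 1), 375, "sp")
    expect_equal(f1$alpha - f0$alpha, -d, tolerance = 0.01)
  }
})

test_that("identical seeds give identical dp fits", {
  p <- de_pair(n = 100, seed = 42)
  f1 <- lts_fit(p$t, p$r, 75, "dp", n_starts = 50, seed = 9)
  f2 <- lts_fit(p$t, p$r, 75, "dp", n_starts = 50, seed = 9)
  expect_identical(f1[c("alpha", "beta", "retained", "objective")],
                   f2[c("alpha", "beta", "retained", "objective")])
})

test_that("degenerate and out-of-range inputs error", {
  t <- rep(1, 10)
  expect_error(lts_fit(t, t + 1, 8, "dp"), "degenerate")
  expect_error(lts_fit(rnorm(10), rnorm(10), 5, "sp"), "h must")
  expect_error(lts_fit(rnorm(10), rnorm(10), 11, "sp"), "h must")
  expect_error(lts_fit(rnorm(3), rnorm(3), 3, "sp"), "at least 4")
})

test_that("apply_fit evaluates the count-scale back-transform with clipping", {
  id <- lts_fit(log2(1:20 + 1), log2(1:20 + 1), 15, "sp")
  x <- c(0, 4, 100)
  expect_equal(apply_fit(id, x, 1), x)
  f <- list(alpha = 1, beta = 1)
  expect_equal(apply_fit(f, 4, 1), 9)   # 2 * 5 - 1
  f2 <- list(alpha = -3, beta = 1)
  expect_equal(apply_fit(f2, 0, 1), 0)  # 2^-3 * 1 - 1 < 0, clipped
  expect_error(apply_fit(f, -1, 1), "non-negative")
})
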