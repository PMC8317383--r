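test_that("median polish solves constant and exactly additive tables", {
  p <- median_polish(matrix(5, 4, 3))
  expect_equal(p$mu, 5)
  expect_equal(unname(p$a), rep(0, 4))
  expect_equal(unname(p$b), rep(0, 3))
  expect_equal(max(abs(p$residuals)), 0)

  a <- c(-1, 0, 2); b <- c(-0.5, 0, 3)  # median-zero effects
  tbl <- outer(a, b, "+") + 7
  p2 <- median_polish(tbl)
  expect_equal(p2$mu, 7, tolerance = 1e-9)
  expect_equal(unname(p2$a), a, tolerance = 1e-9)
  expect_equal(unname(p2$b), b, tolerance = 1e-9)
  expect_equal(p2$objective_l1, 0, tolerance = 1e-9)
})

test_that("polish output always satisfies the model identities", {
  for (seed in 1:8) {
    set.seed(seed)
    I <- sample(2:6, 1); J <- sample(2:6, 1)
    tbl <- matrix(rnorm(I * J, sd = 3), I, J)
    p <- median_polish(tbl)
    expect_lt(abs(median(p$a)), 1e-9)
    expect_lt(abs(median(p$b)), 1e-9)
    recon <- p$mu + outer(p$a, p$b, "+") + p$residuals
    expect_equal(recon, tbl, tolerance = 1e-9, ignore_attr = TRUE)
    expect_equal(p$objective_l1, sum(abs(p$residuals)), tolerance = 1e-12)
  }
})

test_that("polish agrees with the stats::medpolish decomposition", {
  set.seed(30)
  tbl <- matrix(rnorm(20, sd = 2), 5, 4)
  ours <- median_polish(tbl)
  ref <- suppressWarnings(stats::medpolish(tbl, eps = 1e-12, maxiter = 100,
                                           trace.iter = FALSE))
  expect_equal(ours$objective_l1, sum(abs(ref$residuals)), tolerance = 1e-6)
})

test_that("the exhaustive LAD oracle is exact on known cases and bounds the polish", {
  a <- c(-1, 0, 1); b <- c(0, 0.5, 2)
  expect_equal(lad_lp_oracle(outer(a, b, "+") + 3)$objective, 0, tolerance = 1e-12)

  expect_equal(lad_lp_oracle(matrix(c(0, 1, 1, 0), 2))$objective, 2,
               tolerance = 1e-12)

  gaps <- numeric(0)
  for (seed in c(7, 1:5)) {
    set.seed(seed)
    tbl <- matrix(rnorm(9, sd = 2), 3, 3)
    opt <- lad_lp_oracle(tbl)$objective
    pol <- median_polish(tbl)$objective_l1
    expect_gte(pol, opt - 1e-9)  # optimality bound
    gaps <- c(gaps, pol - opt)
  }
  # the polish heuristic is near-optimal on these instances; record the gap
  expect_lt(max(gaps), 0.5)
})

test_that("oracle parameters satisfy the median constraints and reconstruct the optimum", {
  set.seed(13)
  tbl <- matrix(rnorm(12), 3, 4)
  o <- lad_lp_oracle(tbl)
  expect_lt(abs(median(o$a)), 1e-12)
  expect_lt(abs(median(o$b)), 1e-12)
  expect_equal(sum(abs(tbl - o$mu - outer(o$a, o$b, "+"))), o$objective,
               tolerance = 1e-9)
})

test_that("once-for-all sp integration equals per-transcript polish", {
  for (seed in 1:5) {
    set.seed(seed)
    I <- 4; J <- 3; G <- 20
    alpha <- matrix(rnorm(I * J), I, J)
    L <- matrix(rnorm(G * I, 8, 2), G, I)
    shifts <- integrate_sp(alpha)$shifts
    once <- sweep(L, 2L, shifts, "+")
    per <- L
    for (g in seq_len(G)) {
      p <- median_polish(outer(L[g, ], rep(0, J), "+") + alpha)
      per[g, ] <- p$mu + p$a
    }
    expect_equal(once, per, tolerance = 1e-9)
  }
})

test_that("degenerate alpha tables integrate to the expected shifts", {
  z <- integrate_sp(matrix(0, 3, 3), matrix(rnorm(15, 8), 5, 3))
  expect_equal(unname(z$shifts), rep(0, 3))       # counts remain as they were
  cc <- integrate_sp(matrix(1.7, 4, 2))
  expect_equal(unname(cc$shifts), rep(1.7, 4))
})

test_that("dp integration is consistent across its methods in reducible cases", {
  set.seed(17)
  I <- 4; J <- 3; G <- 12
  alpha <- matrix(rnorm(I * J), I, J)
  L <- matrix(rnorm(G * I, 8, 2), G, I)

  # all slopes 1: fast dp must reduce to the sp shifts
  beta1 <- matrix(1, I, J)
  sp_log <- sweep(L, 2L, integrate_sp(alpha)$shifts, "+")
  expect_equal(integrate_dp(alpha, beta1, L, "fast"), sp_log, tolerance = 1e-9)

  # single reference: every method is the exact pairwise transform
  a1 <- alpha[, 1, drop = FALSE]; b1 <- matrix(runif(I, 0.8, 1.2), I, 1)
  exact <- sweep(sweep(L, 2L, b1[, 1], "*"), 2L, a1[, 1], "+")
  for (meth in c("fast", "per_transcript", "ls_average"))
    expect_equal(integrate_dp(a1, b1, L, meth), exact, tolerance = 1e-9,
                 info = meth)
})

test_that("ls_average matches the two-factor least-squares fit per gene", {
  set.seed(11)
  I <- 3; J <- 2; G <- 10
  alpha <- matrix(rnorm(I * J), I, J)
  beta <- matrix(runif(I * J, 0.8, 1.2), I, J)
  L <- matrix(rnorm(G * I, 8, 2), G, I)
  got <- integrate_dp(alpha, beta, L, "ls_average")
  ti <- factor(rep(seq_len(I), J)); rj <- factor(rep(seq_len(J), each = I))
  for (g in seq_len(G)) {
    x <- as.vector(alpha + beta * L[g, ])
    fit <- lm(x ~ ti + rj, contrasts = list(ti = "contr.sum", rj = "contr.sum"))
    cf <- coef(fit)
    mu_a <- cf[1] + c(cf[2:I], -sum(cf[2:I]))  # grand + target effects
    expect_equal(unname(got[g, ]), unname(mu_a), tolerance = 1e-9)
  }
})

test_that("an odd reference panel absorbs one corrupted column without moving the shifts", {
  set.seed(23)
  I <- 5
  v <- rnorm(I, sd = 0.1)
  base <- cbind(v, v + rnorm(I, sd = 0.05), v)  # two identical reference columns
  s0 <- integrate_sp(base)$shifts
  bad <- base; bad[, 2] <- bad[, 2] + 10
  s1 <- integrate_sp(bad)$shifts
  expect_equal(s1, s0, tolerance = 1e-9)
})

test_that("non-finite tables are rejected", {
  expect_error(median_polish(matrix(c(1, Inf, 2, 3), 2)), "finite")
  expect_error(lad_lp_oracle(matrix(c(1, NA, 2, 3), 2)), "finite")
})
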