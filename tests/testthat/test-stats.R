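# Reliability, rank statistics and logistic modelling.

test_that("ICC is 1 for identical sets, ~0 for unrelated sets", {
  set.seed(1)
  x <- matrix(rnorm(60 * 3, c(10, 50, 200), c(2, 10, 40)), 60, 3, byrow = TRUE)
  expect_equal(as.numeric(icc_reliability(x, x)), rep(1, 3), tolerance = 1e-12)
  y <- matrix(rnorm(60 * 3, c(10, 50, 200), c(2, 10, 40)), 60, 3, byrow = TRUE)
  expect_true(all(abs(icc_reliability(x, y)) < 0.35))
  # degenerate: zero between-nodule variance is flagged, not mistaken for
  # agreement
  z <- matrix(5, 10, 1)
  r <- icc_reliability(z, z)
  expect_true(is.na(r[1]))
  expect_length(attr(r, "degenerate"), 1)
  expect_error(icc_reliability(x[1:3, ], x[1:3, ]), "at least 5")
})

test_that("ICC matches the two-way ANOVA mean-square formula on a hand case", {
  a <- c(9, 6, 8, 7, 10, 6)
  b <- c(2, 1, 4, 1, 5, 2)
  # independent computation from ANOVA sums of squares
  x <- cbind(a, b); n <- 6; k <- 2
  msr <- k * var(rowMeans(x))
  msc <- n * var(colMeans(x))
  mse <- (sum((x - mean(x))^2) - (n - 1) * msr - (k - 1) * msc) / ((n - 1) * (k - 1))
  exp_a1 <- (msr - mse) / (msr + (k - 1) * mse + k / n * (msc - mse))
  exp_c1 <- (msr - mse) / (msr + (k - 1) * mse)
  expect_equal(unname(icc_reliability(cbind(a), cbind(b), form = "A1"))[1], exp_a1)
  expect_equal(unname(icc_reliability(cbind(a), cbind(b), form = "C1"))[1], exp_c1)
  expect_gt(exp_c1, exp_a1)  # systematic rater shift hurts absolute agreement
})

test_that("Spearman correlation handles ties and matches cor.test", {
  x <- 1:10
  expect_equal(spearman(x, x)$rho, 1)
  expect_equal(spearman(x, -x)$rho, -1)
  expect_equal(spearman(x, x)$p, 0)
  # tie-heavy case against the brute rank formula and cor.test
  set.seed(3)
  a <- sample(1:4, 30, replace = TRUE)
  b <- a + sample(0:2, 30, replace = TRUE)
  s <- spearman(a, b)
  expect_equal(s$rho, cor(rank(a), rank(b)))
  ct <- suppressWarnings(cor.test(a, b, method = "spearman", exact = FALSE))
  expect_equal(s$rho, unname(ct$estimate))
  expect_equal(s$p, ct$p.value, tolerance = 1e-10)
  # infinite values rank at the top: usable for DT with stable nodules
  expect_equal(spearman(c(1, 2, 3, 4), c(5, 6, 7, Inf))$rho, 1)
})

test_that("Mann-Whitney U matches enumeration and wilcox.test", {
  # identical groups: p ~ 1
  expect_gt(mann_whitney(c(1, 2, 3), c(1, 2, 3))$p, 0.99)
  # full separation at n = 5/5: U = 0, exact p = 2/252
  mw <- mann_whitney(1:5, 6:10)
  expect_equal(mw$U, 0)
  expect_equal(mw$U_other, 25)
  expect_equal(mw$p, 2 / choose(10, 5))
  expect_match(mw$method, "exact")
  # tie-heavy small case: U equals the pair-counting oracle, p equals an
  # independent enumeration over assignments
  a <- c(1, 1, 2, 3, 3); b <- c(1, 2, 2, 2, 4)
  mw2 <- mann_whitney(a, b)
  expect_equal(mw2$U, u_pair_oracle(a, b))
  pooled <- c(a, b)
  combs <- combn(10, 5)
  u_all <- apply(combs, 2, function(idx)
    u_pair_oracle(pooled[idx], pooled[-idx]))
  p_oracle <- mean(abs(u_all - 12.5) >= abs(mw2$U - 12.5) - 1e-12)
  expect_equal(mw2$p, p_oracle)
  # large samples: agreement with wilcox.test's corrected normal approx
  set.seed(9)
  x <- rnorm(40); y <- rnorm(45, 0.4)
  mw3 <- mann_whitney(x, y)
  wt <- wilcox.test(x, y, exact = FALSE, correct = TRUE)
  expect_equal(mw3$U, unname(wt$statistic))
  expect_equal(mw3$p, wt$p.value, tolerance = 1e-10)
})

test_that("logistic regression recovers parameters and reports Wald stats", {
  set.seed(5)
  n <- 5000
  x <- rnorm(n)
  p <- plogis(-1 + 0.5 * x)
  y <- rbinom(n, 1, p)
  m <- logistic_fit(data.frame(x = x), y)
  expect_false(attr(m, "separated"))
  expect_lt(abs(m$beta[1] - (-1)), 3 * m$se[1])
  expect_lt(abs(m$beta[2] - 0.5), 3 * m$se[2])
  expect_equal(m$or, exp(m$beta))  # OR = e^beta to machine precision
  # outcome independent of x: beta ~ 0, OR ~ 1
  y0 <- rbinom(n, 1, 0.3)
  m0 <- logistic_fit(data.frame(x = x), y0)
  expect_lt(abs(m0$beta[2]), 3 * m0$se[2])
  expect_lt(abs(m0$or[2] - 1), 0.1)
})

test_that("complete separation is flagged, not silently reported", {
  x <- c(1, 2, 3, 4, 10, 11, 12, 13)
  y <- c(0, 0, 0, 0, 1, 1, 1, 1)
  m <- logistic_fit(data.frame(x = x), y)
  expect_true(attr(m, "separated"))
  expect_error(logistic_fit(data.frame(x = rep(1, 8)), y), "constant")
})

test_that("backward stepwise keeps true predictors and prunes noise", {
  # one true predictor among 8 noise columns
  kept_true <- 0; extras <- 0
  for (rep in 1:10) {
    set.seed(100 + rep)
    n <- 1000
    X <- as.data.frame(matrix(rnorm(n * 9), n, 9))
    names(X) <- c("signal", paste0("noise", 1:8))
    y <- rbinom(n, 1, plogis(-0.5 + 1.2 * X$signal))
    st <- backward_stepwise(X, y)
    kept_true <- kept_true + ("signal" %in% st$selected)
    extras <- extras + length(setdiff(st$selected, "signal"))
  }
  expect_gte(kept_true, 10 * 0.95)
  expect_lt(extras / 10, 1.5)
  # two strong independent predictors (skewness/LMD-like): both retained
  set.seed(77)
  n <- 1500
  X2 <- data.frame(skew_like = rnorm(n), lmd_like = rnorm(n),
                   junk1 = rnorm(n), junk2 = rnorm(n))
  y2 <- rbinom(n, 1, plogis(-1 + 1 * X2$skew_like + 0.8 * X2$lmd_like))
  st2 <- backward_stepwise(X2, y2)
  expect_true(all(c("skew_like", "lmd_like") %in% st2$selected))
  expect_false(is.null(st2$trace))
})

test_that("an all-noise design almost always yields a near-empty model", {
  n_sel <- integer(10)
  for (rep in 1:10) {
    set.seed(200 + rep)
    n <- 500
    X <- as.data.frame(matrix(rnorm(n * 8), n, 8))
    y <- rbinom(n, 1, 0.3)
    st <- backward_stepwise(X, y)
    n_sel[rep] <- length(st$selected)
  }
  # with 8 candidates screened at p < 0.05, ~0.4 false entries are expected;
  # at most 2 spurious predictors in >= 90% of runs
  expect_gte(mean(n_sel <= 2), 0.9)
})
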