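test_that("pearson_r handles exact, hand-derived and degenerate cases", {
  expect_equal(pearson_r(c(1, 2, 3), c(2, 4, 6)), 1)
  expect_equal(pearson_r(c(1, 2, 3), c(6, 4, 2)), -1)
  # hand evaluation: cov-sum 4, variance-sums 5 and 5 -> r = 4/5
  expect_equal(pearson_r(c(1, 2, 3, 4), c(1, 3, 2, 4)), 0.8)
  expect_true(is.na(pearson_r(c(1, 2, 3), c(5, 5, 5))))
  expect_error(pearson_r(1:3, 1:4), "equal length")
  expect_error(pearson_r(1:2, 1:2), "at least 3")
  expect_error(pearson_r(c(1, NA, 3), 1:3), "missing")
})

test_that("pearson_r matches the definitional formula and affine invariance", {
  set.seed(101)
  for (i in 1:200) {
    n <- sample(3:30, 1)
    x <- rnorm(n)
    y <- rnorm(n)
    r <- pearson_r(x, y)
    expect_equal(r, pearson_oracle(x, y), tolerance = 1e-12)
    a <- runif(1, 0.1, 5)
    b <- rnorm(1)
    expect_equal(pearson_r(a * x + b, y), r, tolerance = 1e-12)
    expect_equal(pearson_r(-a * x + b, y), -r, tolerance = 1e-12)
  }
})

test_that("bh_adjust matches its step-up definition and examples", {
  expect_equal(bh_adjust(0.5), 0.5)
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(c(1, 1)), c(1, 1))
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
  set.seed(7)
  for (i in 1:300) {
    p <- runif(sample(1:40, 1))
    q <- bh_adjust(p)
    expect_equal(q, bh_oracle(p), tolerance = 1e-12)
    # monotone nondecreasing when re-sorted by input p
    expect_true(all(diff(q[order(p)]) >= -1e-15))
  }
})

test_that("enrich_p equals hypergeometric enumeration and Fisher's exact test", {
  expect_equal(enrich_p(0, 3, 4, 10), 1)
  expect_equal(enrich_p(5, 5, 5, 10), 1 / choose(10, 5))
  expect_equal(enrich_p(1, 1, 1, 2), 0.5)
  expect_error(enrich_p(6, 5, 5, 10), "overlap_k")
  expect_error(enrich_p(1, 11, 5, 10), "universe")
  # full enumeration for all small universes
  for (N in 3:25) {
    K <- sample(1:N, 1)
    n <- sample(1:N, 1)
    for (k in 0:min(K, n)) {
      if (k < max(0, n - (N - K))) next
      expect_equal(enrich_p(k, K, n, N), hyper_oracle(k, K, n, N),
                   tolerance = 1e-12)
    }
  }
  # one-sided Fisher exact of the 2x2 table is the same quantity
  ft <- fisher.test(matrix(c(4, 1, 2, 13), 2, 2), alternative = "greater")
  expect_equal(enrich_p(4, 5, 6, 20), ft$p.value, tolerance = 1e-10)
})

test_that("pooled t matches the closed form and stats::t.test", {
  r <- pooled_t_test(c(1, 2), c(1, 2))
  expect_equal(r$effect, 0)
  expect_equal(r$p, 1)

  r <- pooled_t_test(c(0, 1, 2), c(3, 4, 5))
  expect_equal(r$t_stat, -3 / sqrt(2 / 3), tolerance = 1e-12) # s2=1, se=sqrt(2/3)
  expect_equal(r$df, 4)
  expect_equal(r$p, 0.0213, tolerance = 1e-3)
  tt <- t.test(c(0, 1, 2), c(3, 4, 5), var.equal = TRUE)
  expect_equal(r$p, tt$p.value, tolerance = 1e-12)

  r <- pooled_t_test(c(5, 5), c(5, 5))
  expect_equal(r$t_stat, 0)
  expect_equal(r$p, 1)
  r <- pooled_t_test(c(5, 5), c(7, 7))
  expect_true(r$degenerate)
  expect_equal(r$p, .Machine$double.xmin)
})

test_that("eb_shrink_variances recovers a known prior and its limits", {
  # identical variances -> complete shrinkage; the prior variance follows the
  # log-scale moment formula exp(mean(e)) with the finite-df bias correction
  fit <- eb_shrink_variances(rep(2.5, 50), df = 7)
  expect_true(is.infinite(fit$d0))
  expect_equal(fit$s0_sq, exp(log(2.5) - digamma(7 / 2) + log(7 / 2)),
               tolerance = 1e-10)

  # simulation with known generating prior d0 = 4
  set.seed(42)
  d0t <- 4; s0t <- 2; df <- 7
  sigma2 <- d0t * s0t / rchisq(10000, d0t)
  s2 <- sigma2 * rchisq(10000, df) / df
  fit <- eb_shrink_variances(s2, df)
  expect_lt(abs(fit$d0 - d0t) / d0t, 0.20)
  expect_lt(abs(fit$s0_sq - s0t) / s0t, 0.20)

  # two very different variances -> finite d0, checked against a grid oracle
  s2 <- c(0.01, 100)
  fit <- eb_shrink_variances(s2, df = 7)
  expect_true(is.finite(fit$d0) && fit$d0 > 0)
  e <- log(s2) - digamma(7 / 2) + log(7 / 2)
  target <- var(e) - trigamma(7 / 2)
  grid <- seq(fit$d0 * 0.5, fit$d0 * 2, length.out = 20001)
  best <- grid[which.min(abs(trigamma(grid / 2) - target))]
  expect_equal(fit$d0, best, tolerance = 1e-3)

  expect_error(eb_shrink_variances(c(0, 0, 1), df = 7), "at least 2")
})

test_that("moderated t equals pooled t at d0 = 0 and obeys its limits", {
  set.seed(5)
  for (i in 1:50) {
    xA <- rnorm(4); xB <- rnorm(5)
    m <- moderated_t_test(xA, xB, d0 = 0, s0_sq = runif(1))
    p <- pooled_t_test(xA, xB)
    expect_identical(m$t_stat, p$t_stat)
    expect_identical(m$p, p$p)
  }
  # complete shrinkage: s~2 = s0^2, normal reference
  m <- moderated_t_test(c(0, 1, 2), c(3, 4, 5), d0 = Inf, s0_sq = 1)
  expect_equal(m$t_stat, -3 / sqrt(2 / 3), tolerance = 1e-12)
  expect_equal(m$p, 2 * pnorm(-abs(m$t_stat)), tolerance = 1e-12)
  # hand evaluation: s2 = 1 pooled, d0 = 4, s0^2 = 1 -> posterior 1, df 8
  m <- moderated_t_test(c(0, 1, 2), c(3, 4, 5), d0 = 4, s0_sq = 1)
  expect_equal(m$t_stat, -3 / sqrt(2 / 3), tolerance = 1e-12)
  expect_equal(m$df, 8)
  expect_equal(m$p, 2 * pt(-abs(m$t_stat), 8), tolerance = 1e-12)
})

test_that("moderated t is continuous in d0", {
  xA <- c(0.2, 1.4, 0.9, 2.2)
  xB <- c(1.1, 0.3, 0.8, 1.9, 1.4)
  d0s <- c(0, 1e-6, 1e-3, 0.1, 1, 10, 1e4)
  ps <- vapply(d0s, function(d) moderated_t_test(xA, xB, d, 0.7)$p, numeric(1))
  expect_lt(abs(ps[2] - ps[1]), 1e-6)
  expect_true(all(is.finite(ps)))
  p_inf <- moderated_t_test(xA, xB, Inf, 0.7)$p
  expect_lt(abs(ps[length(ps)] - p_inf), 1e-3)
})

test_that("moderated machinery agrees with limma on a heteroskedastic panel", {
  skip_if_not_installed("limma")
  set.seed(99)
  n <- 800
  sigma2 <- 0.5 * 4 / rchisq(n, 4) # scaled inverse chi-square spread
  mat <- t(sapply(seq_len(n), function(i) rnorm(9, sd = sqrt(sigma2[i]))))
  dimnames(mat) <- list(paste0("f", 1:n), paste0("s", 1:9))
  is_case <- c(rep(TRUE, 4), rep(FALSE, 5))
  st <- coexmeth:::.row_two_group_stats(mat, is_case)
  pr <- eb_shrink_variances(st$s2, st$df)
  mod <- coexmeth:::.row_moderated_p(st, pr$d0, pr$s0_sq)
  fit <- limma::eBayes(limma::lmFit(mat, cbind(1, as.numeric(is_case))))
  expect_lt(abs(pr$d0 - fit$df.prior) / fit$df.prior, 0.10)
  expect_lt(abs(pr$s0_sq - fit$s2.prior) / fit$s2.prior, 0.10)
  expect_gt(cor(mod$p, fit$p.value[, 2]), 0.999)
})
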