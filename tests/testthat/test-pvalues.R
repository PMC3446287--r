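# Independent oracles: direct Poisson pmf summation and full hypergeometric
# enumeration over all 2x2 tables with fixed margins.
pois_tail_oracle <- function(k, mean) {
  if (k <= 0) return(1)
  1 - sum(exp(-mean) * mean^(0:(k - 1)) / factorial(0:(k - 1)))
}

fisher_oracle <- function(k, n, E, N) {
  K <- k + E
  x <- max(0, K - N):min(n, K)
  p <- exp(lchoose(n, x) + lchoose(N, K - x) - lchoose(n + N, K))
  sum(p[x >= k])
}

test_that("Poisson tail matches brute-force pmf summation", {
  expect_equal(poisson_pvalue(0, 30, 0.001), 1)
  expect_equal(poisson_pvalue(3, 30, 0.001), 4.39995494e-06,
               tolerance = 1e-8)                      # frozen from the oracle
  expect_equal(poisson_pvalue(1, 100, 0.01), 1 - exp(-1), tolerance = 1e-12)
  set.seed(7)
  for (i in 1:50) {
    n <- sample(1:5000, 1)
    lam <- runif(1, 1e-5, 50 / n)
    k <- sample(0:min(n, 200), 1)
    # absolute agreement: the subtraction oracle loses relative precision in
    # the far tail, but the absolute error stays below 1e-12
    expect_lt(abs(poisson_pvalue(k, n, lam) - pois_tail_oracle(k, n * lam)),
              1e-12)
  }
  expect_error(poisson_pvalue(1, 10, 0), "lambda")
  expect_error(poisson_pvalue(11, 10, 0.1), "exceed")
})

test_that("one-sided Fisher matches hypergeometric enumeration and fisher.test", {
  expect_equal(fisher_pvalue(0, 30, 5, 1000), 1)
  expect_equal(fisher_pvalue(3, 30, 1, 1000), 8.766833446e-05,
               tolerance = 1e-10)                     # frozen from the oracle
  set.seed(8)
  for (i in 1:40) {
    n <- sample(1:200, 1); N <- sample(1:200, 1)
    k <- sample(0:n, 1);   E <- sample(0:N, 1)
    p <- fisher_pvalue(k, n, E, N)
    expect_equal(p, fisher_oracle(k, n, E, N), tolerance = 1e-10)
    ft <- fisher.test(matrix(c(k, n - k, E, N - E), 2, byrow = TRUE),
                      alternative = "greater")
    expect_equal(p, ft$p.value, tolerance = 1e-8)
  }
  # equal rates at large counts: no enrichment signal
  expect_gte(fisher_pvalue(10, 1000, 10, 1000), 0.5)
})

test_that("empirical rank P-value follows the rank formula", {
  expect_equal(empirical_pvalue(5, 30, rep(0, 63)), 1 / 64)
  expect_equal(empirical_pvalue(0, 30, runif(20)), 1)       # all references >= 0
  freqs <- c(0.001, 0.002, 0.003, 0.004, 0.005)
  expect_equal(empirical_pvalue(3, 1000, freqs), (1 + 3) / 6)  # obs = 0.003 ties
  expect_error(empirical_pvalue(1, 30, numeric(0)), "degraded")
  expect_error(empirical_pvalue(1, 0, c(0.1)), "covered")
})

test_that("P-values are non-increasing in the minor count", {
  ks <- 0:40
  pp <- poisson_pvalue(ks, 50, 0.01)
  pf <- fisher_pvalue(ks, 50, 10, 2000)
  expect_true(all(diff(pp) <= 0))
  expect_true(all(diff(pf) <= 0))
  pe <- vapply(ks, function(k) empirical_pvalue(k, 50, c(0, 0.02, 0.1, 0.5)), 0)
  expect_true(all(diff(pe) <= 1e-15))
})

test_that("strand statistic: mean of per-bin Phred terms with caps", {
  cfg <- caller_config()
  # all bins at P = 1 contribute nothing
  bt <- data.frame(n = rep(30, 8), p = rep(1, 8))
  expect_equal(strand_bias_statistic(bt, "poisson", cfg)$Q, 0)
  # saturated bins hit the overall cap of 60
  bt$p <- rep(1e-9, 8)
  expect_equal(strand_bias_statistic(bt, "poisson", cfg)$Q, 60)
  expect_equal(strand_bias_statistic(bt, "fisher", cfg)$Q, 60)
  # one extreme bin out of six covered scores 60/6 = 10 per strand
  bt1 <- data.frame(n = c(rep(20, 6), 0, 0), p = c(1e-9, rep(1, 5), NA, NA))
  expect_equal(strand_bias_statistic(bt1, "poisson", cfg)$Q, 10)
  # empirical: mean of rank scores; frozen from the rank arithmetic
  bte <- data.frame(n = rep(25, 6), p = c(1 / 64, rep(0.5, 5)))
  expect_equal(strand_bias_statistic(bte, "empirical", cfg)$Q, 5.5188833,
               tolerance = 1e-6)
  # uncovered strand has no quality
  expect_true(is.na(strand_bias_statistic(data.frame(n = 0, p = NA),
                                          "poisson", cfg)$Q))
  # sum rule with per-bin cap reproduces the additive variant
  cfg2 <- caller_config(combine = "sum", per_bin_cap = 30)
  expect_equal(strand_bias_statistic(bt, "poisson", cfg2)$Q, 60)  # 8*30 capped
  expect_equal(strand_bias_statistic(bt1, "poisson", cfg2)$Q, 30)
})

test_that("strand quality is monotone in any single bin's count", {
  cfg <- caller_config()
  lam <- 0.004; n <- 40
  base_k <- c(1, 0, 2, 0, 1, 0, 0, 0)
  q_of <- function(kv) {
    bt <- data.frame(n = rep(n, 8), p = poisson_pvalue(kv, n, lam))
    strand_bias_statistic(bt, "poisson", cfg)$Q
  }
  q0 <- q_of(base_k)
  for (b in 1:8) {
    k2 <- base_k; k2[b] <- k2[b] + 3
    expect_gte(q_of(k2), q0)
  }
})
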