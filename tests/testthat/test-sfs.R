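test_that("EM degenerates correctly on monomorphic data", {
  m <- pool_model(40, 0)
  fit <- estimate_sfs_em(rep(0L, 50), rep(30L, 50), m)
  ## the EM stops at max |delta phi| < 1e-8, so allow that residual
  expect_equal(unname(fit$phi[1]), 1, tolerance = 1e-7)
  expect_lt(fit$p_polymorphic, 1e-7)
  expect_error(estimate_sfs_em(integer(0), integer(0), m), "no sites")
})

test_that("one EM step from a uniform prior matches the hand-computed posterior", {
  ## single site, n = 4 (classes 0, 1, 2), k = 1 of r = 2, eps = 0.1
  n <- 4L; eps <- 0.1; k <- 1L; r <- 2L
  q <- (1 - eps) * (0:2) / n + eps * (1 - (0:2) / n)      # per-read P(derived)
  like_unfolded <- function(kk, qq) choose(r, kk) * qq^kk * (1 - qq)^(r - kk)
  ## folded class f averages polarities f and n - f
  qf <- (1 - eps) * (4 - (0:2)) / n + eps * ((0:2) / n)
  A <- choose(r, k) * 0.5 * (q^k * (1 - q)^(r - k) + qf^k * (1 - qf)^(r - k))
  expected <- A / sum(A)   # uniform prior -> posterior are the new weights
  fit <- estimate_sfs_em(k, r, pool_model(n, eps), max_iter = 1L)
  expect_equal(unname(fit$phi), expected, tolerance = 1e-12)
})

test_that("EM log likelihood never decreases", {
  set.seed(21)
  m <- pool_model(20, 0.01)
  truth <- c(0.8, 0.1, 0.04, 0.02, 0.015, 0.009, 0.006, 0.004, 0.003,
             0.002, 0.001)
  y <- sample(0:10, 400, replace = TRUE, prob = truth)
  y <- ifelse(runif(400) < 0.5, y, 20 - y)
  r <- rpois(400, 60) + 1L
  k <- rbinom(400, r, (1 - 0.01) * y / 20 + 0.01 * (1 - y / 20))
  fit <- estimate_sfs_em(k, r, m, max_iter = 200L)
  expect_true(all(diff(fit$loglik) >= -1e-8))
  expect_equal(sum(fit$phi), 1, tolerance = 1e-9)
})

test_that("EM recovers a known folded spectrum from deep pooled data", {
  set.seed(31)
  n <- 40L; eps <- 0.001
  truth <- c(0.92, 0.045, 0.012, 0.007, 0.004, 0.003, rep(0.0015, 6),
             rep(0.001, 9))
  truth <- truth / sum(truth)
  S <- 20000L
  f <- sample(0:20, S, replace = TRUE, prob = truth)
  y <- ifelse(runif(S) < 0.5, f, n - f)   # random polarity, same folded class
  r <- rep(100L, S)
  k <- rbinom(S, r, (1 - eps) * y / n + eps * (1 - y / n))
  fit <- estimate_sfs_em(k, r, pool_model(n, eps))
  tv <- sum(abs(fit$phi - truth)) / 2
  expect_lt(tv, 0.05)
})

test_that("nucleotide diversity applies the small-sample correction", {
  expect_equal(nucleotide_diversity(numeric(0), 40, 1000), 0)
  expect_equal(nucleotide_diversity(0.5, 40, 1000),
               (40 / 39) * 2 * 0.25 / 1000)
  p <- c(0.1, 0.25, 0.8)
  expect_equal(nucleotide_diversity(p, 40, 100),
               nucleotide_diversity(1 - p, 40, 100))
  ## folded SFS input: per-site expectation over all classes
  sfs <- folded_sfs(c(0.9, 0.08, 0.02), 4)
  expect_equal(nucleotide_diversity(sfs),
               0.08 * (4 / 3) * 2 * 0.25 * 0.75 + 0.02 * (4 / 3) * 2 * 0.25)
  expect_error(nucleotide_diversity(c(0.1, 0.2), 40, 1), "at least")
})

test_that("Tajima's D matches its definition and an independent oracle", {
  expect_true(is.na(tajimas_d(rep(0, 9), 10)))
  ## neutral expectation xi_i = theta / i gives D = 0 identically
  n <- 10; theta <- 10
  xi <- theta / (1:(n - 1))
  expect_equal(tajimas_d(xi, n), 0, tolerance = 1e-9)
  ## small unfolded spectrum against the independently written constants
  expect_equal(tajimas_d(c(3, 1, 1), 4), oracle_tajimas_d(c(3, 1, 1), 4),
               tolerance = 1e-12)
  set.seed(5)
  for (i in 1:20) {
    n <- sample(4:30, 1)
    xi <- rpois(n - 1, 3)
    if (sum(xi) == 0) xi[1] <- 1
    expect_equal(tajimas_d(xi, n), oracle_tajimas_d(xi, n),
                 tolerance = 1e-12)
  }
  ## folded input gives the same value as its unfolded equivalent
  xi <- c(5, 3, 2, 1, 1, 0, 0, 0, 0)
  folded <- xi[1:5] + c(rev(xi[6:9]), 0)
  expect_equal(tajimas_d(folded, 10), tajimas_d(xi, 10), tolerance = 1e-12)
})

test_that("profiling the EM likelihood recovers the simulated error rate", {
  set.seed(61)
  n <- 40L; eps_true <- 0.003
  truth <- c(0.9, 0.05, 0.02, 0.01, rep(0.02 / 17, 17))
  f <- sample(0:20, 30000, replace = TRUE, prob = truth)
  y <- ifelse(runif(30000) < 0.5, f, n - f)
  k <- rbinom(30000, 100L, (1 - eps_true) * y / n + eps_true * (1 - y / n))
  prof <- estimate_epsilon_profile(k, rep(100L, 30000), n,
                                   grid = c(3e-4, 1e-3, 3e-3, 1e-2),
                                   max_iter = 150L)
  expect_equal(prof$epsilon, 3e-3)
  expect_equal(which.max(prof$loglik), 3L)
})

test_that("posterior polymorphism calls separate clear cases", {
  m <- pool_model(40, 0.001)
  sfs <- folded_sfs(c(0.9, rep(0.1 / 20, 20)), 40)
  ## 30 of 60 focal reads: clearly polymorphic; 0 of 60: clearly not
  calls <- call_polymorphic_sites(c(30L, 0L), c(60L, 60L), m, sfs)
  expect_identical(calls, c(TRUE, FALSE))
})
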