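test_that("per-site statistics match their closed forms", {
  expect_equal(site_pi_within(0, 40), 0)
  expect_equal(site_pi_within(0.5, 40), 40 / 39 * 0.5)  # 0.51282
  p <- c(0.1, 0.4, 0.77)
  expect_equal(site_pi_within(p, 40), site_pi_within(1 - p, 40))
  expect_error(site_pi_within(0.5, 1), ">= 2")

  expect_equal(site_pi_between(0, 1), 1)
  expect_equal(site_pi_between(0, 0), 0)
  expect_equal(site_pi_between(0.2, 0.8), 0.68)
  expect_equal(site_pi_between(0.2, 0.8), site_pi_between(0.8, 0.2))

  expect_equal(fst_value(0.3, 0.3), 0)
  expect_equal(fst_value(0, 0.2), 1)
  expect_equal(fst_value(0.32, 0.68), 1 - 0.32 / 0.68)  # 0.52941
  expect_true(is.na(fst_value(0, 0)))
  expect_lt(fst_value(0.4, 0.3), 0)  # negative values retained
})

mk_scan_table <- function(pos, k1, k2, r = 100L, size = 30000L) {
  genome_table(data.frame(chrom = "chr1", pos = pos, k1 = k1, r1 = r,
                          k2 = k2, r2 = r),
               chrom_sizes = c(chr1 = size))
}

test_that("window tiling follows the 10-kb/5-kb sliding rule", {
  pos <- seq(50L, 29950L, by = 100L)
  tab <- mk_scan_table(pos, k1 = 50L, k2 = 50L)
  w <- scan_windows(tab, pool_model(40, 0))
  expect_equal(w$start, c(0L, 5000L, 10000L, 15000L, 20000L))
  expect_equal(w$end - w$start, rep(10000L, 5))
  expect_error(scan_windows(tab, pool_model(40, 0), window = 10000,
                            step = 3000), "multiple")
})

test_that("windows of identical frequencies are slightly negative, fixed differences give F_ST 1", {
  pos <- seq(50L, 29950L, by = 100L)
  same <- mk_scan_table(pos, k1 = 30L, k2 = 30L)
  w <- scan_windows(same, pool_model(40, 0))
  ## p1 = p2 at every site: F_ST = 1 - n/(n-1) = -1/39 exactly
  expect_true(all(abs(w$fst - (-1 / 39)) < 1e-12))
  expect_true(all(w$fst < 0))

  fixed <- mk_scan_table(pos, k1 = 100L, k2 = 0L)
  wf <- scan_windows(fixed, pool_model(40, 0))
  expect_true(all(wf$pi_w == 0))
  expect_true(all(wf$fst == 1))
})

test_that("coverage gating drops windows and counts covered sites", {
  pos <- seq(50L, 29950L, by = 100L)
  r <- rep(100L, length(pos))
  r[pos < 12000] <- 10L      # first windows mostly below 20x
  tab <- genome_table(data.frame(chrom = "chr1", pos = pos,
                                 k1 = pmin(20L, r), r1 = r, k2 = 20L,
                                 r2 = 100L),
                      chrom_sizes = c(chr1 = 30000))
  w <- scan_windows(tab, pool_model(40, 0), min_cov = 20L,
                    min_cov_fraction = 0.5)
  expect_false(0L %in% w$start)      # 0% covered
  expect_false(5000L %in% w$start)   # 0% covered
  expect_true(15000L %in% w$start)
  expect_equal(w$n_sites[w$start == 10000L], 80L)  # sites at 12000-20000
})

test_that("coverage-binned F_ST summarises mean and sample SD", {
  out <- fst_by_coverage_bins(c(0.1, 0.3), c(42, 41), c(45, 49),
                              breaks = c(40, 50, 60))
  expect_equal(out$mean, 0.2)
  expect_equal(out$sd, sd(c(0.1, 0.3)))  # 0.14142
  expect_equal(out$n, 2L)

  same <- fst_by_coverage_bins(rep(0.25, 10), rep(55, 10), rep(58, 10),
                               breaks = c(40, 50, 60))
  expect_equal(same$sd, 0)
  expect_equal(same$bin_lo, 50)

  empty <- fst_by_coverage_bins(numeric(0), numeric(0), numeric(0))
  expect_equal(nrow(empty), 0L)

  ## binning uses the smaller of the two coverages
  out2 <- fst_by_coverage_bins(0.1, 190, 45, breaks = seq(40, 200, 10))
  expect_equal(out2$bin_lo, 40)
})

test_that("species labels can be swapped without changing F_ST", {
  set.seed(17)
  pos <- sort(sample(1:29999, 250))
  k1 <- rbinom(250, 60, 0.3); k2 <- rbinom(250, 60, 0.35)
  tab <- genome_table(data.frame(chrom = "chr1", pos = pos, k1 = k1,
                                 r1 = 60L, k2 = k2, r2 = 60L),
                      chrom_sizes = c(chr1 = 30000))
  swapped <- genome_table(data.frame(chrom = "chr1", pos = pos, k1 = k2,
                                     r1 = 60L, k2 = k1, r2 = 60L),
                          chrom_sizes = c(chr1 = 30000))
  m <- pool_model(40, 0.001)
  expect_equal(scan_windows(tab, m)$fst, scan_windows(swapped, m)$fst)
})

test_that("window F_ST under a two-deme island model matches the closed form", {
  ## 4Nm = 25 (per-lineage rate in 4N units), constant size:
  ## F_ST = 1/(1 + 2M) on the ratio-of-means scale
  set.seed(23)
  M <- 25
  sim <- poolscan:::cpp_coal_counts(40L, 40L, 2000L, 20, 1, TRUE, M,
                                    0, 1, Inf)
  p1 <- sim$c1 / 40; p2 <- sim$c2 / 40
  pw <- (site_pi_within(p1, 40) + site_pi_within(p2, 40)) / 2
  pb <- site_pi_between(p1, p2)
  wpw <- rowsum(pw, sim$window); wpb <- rowsum(pb, sim$window)
  global <- 1 - sum(wpw) / sum(wpb)
  theory <- 1 / (1 + 2 * M)
  ## jackknife-over-windows SE of the global ratio estimator
  n <- length(wpw)
  loo <- 1 - (sum(wpw) - wpw) / (sum(wpb) - wpb)
  se <- sqrt((n - 1) / n * sum((loo - mean(loo))^2))
  expect_lt(abs(global - theory), 3 * se)
  ## the mean of per-window ratios is close but biased; loose check only
  expect_lt(abs(mean(1 - wpw / wpb) - theory), 0.02)
})
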