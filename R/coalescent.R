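#' Demography for the coalescent simulators
#'
#' Either a constant-size population or a population that expanded from
#' `N_ancestral` to `N_current` at `t_expansion` generations before the
#' present, instantaneously or exponentially.  Internally time is scaled
#' in units of `4 N_current` generations and sizes relative to
#' `N_current`; an exponential-growth phase is discretised into a
#' 20-step piecewise-constant staircase.
#'
#' Defaults are the package's stand-in for a strong post-colonisation
#' expansion: `N_ancestral = 2e4`, `N_current = 1e6`, 7500 generations.
#'
#' @param mode `"constant"` or `"expansion"`.
#' @param N_current,N_ancestral Effective sizes.
#' @param t_expansion Generations before present of the expansion.
#' @param growth `"instantaneous"` or `"exponential"`.
#' @return An object of class `demography_model`.
#' @export
demography_model <- function(mode = c("expansion", "constant"),
                             N_current = 1e6, N_ancestral = 2e4,
                             t_expansion = 7500,
                             growth = c("instantaneous", "exponential")) {
  mode <- match.arg(mode)
  growth <- match.arg(growth)
  stopifnot(N_current > 0, N_ancestral > 0, t_expansion >= 0)
  structure(list(mode = mode, N_current = N_current,
                 N_ancestral = N_ancestral, t_expansion = t_expansion,
                 growth = growth),
            class = "demography_model")
}

#' @export
print.demography_model <- function(x, ...) {
  if (x$mode == "constant") {
    cat(sprintf("Constant demography, N = %g\n", x$N_current))
  } else {
    cat(sprintf("Expansion (%s): N %g -> %g at %g generations ago\n",
                x$growth, x$N_ancestral, x$N_current, x$t_expansion))
  }
  invisible(x)
}

## piecewise-constant epochs in units of 4*N_current generations
.demography_epochs <- function(demography) {
  stopifnot(inherits(demography, "demography_model"))
  if (demography$mode == "constant" || demography$t_expansion == 0)
    return(list(starts = 0, sizes = 1))
  te <- demography$t_expansion / (4 * demography$N_current)
  ratio <- demography$N_ancestral / demography$N_current
  if (demography$growth == "instantaneous")
    return(list(starts = c(0, te), sizes = c(1, ratio)))
  nstep <- 20L
  ts <- seq(0, te, length.out = nstep + 1L)
  mid <- (ts[-1L] + ts[-(nstep + 1L)]) / 2
  beta <- log(1 / ratio) / te
  list(starts = c(ts[-(nstep + 1L)], te),
       sizes = c(exp(-beta * mid), ratio))
}

#' Simulate a panmictic coalescent sample
#'
#' Hudson-style coalescent without recombination under a
#' [demography_model()], with infinite-sites mutation at population-scaled
#' rate `theta` (`4 N_current mu` over the whole region of length `L`).
#' Returns the haplotypes as a binary matrix (rows = chromosomes,
#' columns = segregating sites).
#'
#' @param n Number of sampled chromosomes.
#' @param L Region length in bp; mutation positions are uniform on
#'   `[0, L)`.
#' @param theta Population-scaled mutation rate of the region.
#' @param demography A [demography_model()].
#' @param rho Recombination rate; only `rho = 0` (the no-recombination
#'   null the neutrality test uses) is supported.
#' @param seed Optional integer seed.
#' @return An object of class `haplotype_sample`: `n`, `L`, sorted
#'   `positions` and the 0/1 `haplotypes` matrix.
#' @export
simulate_panmictic_sample <- function(n = 80L, L = 10000, theta,
                                      demography = demography_model(),
                                      rho = 0, seed = NULL) {
  stopifnot(theta >= 0, n >= 2L)
  if (rho != 0) stop("only the rho = 0 (no recombination) null is supported")
  if (!is.null(seed)) set.seed(seed)
  ep <- .demography_epochs(demography)

  leafsets <- as.list(seq_len(n))
  tb <- numeric(n)
  t <- 0
  b_len <- numeric(0)
  b_leaves <- list()
  while (length(leafsets) > 1L) {
    k <- length(leafsets)
    i_ep <- findInterval(t, ep$starts)
    sigma <- ep$sizes[i_ep]
    rate <- k * (k - 1) / sigma
    dt <- stats::rexp(1L) / rate
    bnd <- if (i_ep < length(ep$starts)) ep$starts[i_ep + 1L] else Inf
    if (t + dt >= bnd) { t <- bnd; next }
    t <- t + dt
    pair <- sample.int(k, 2L)
    for (j in pair) {
      b_len <- c(b_len, t - tb[j])
      b_leaves[[length(b_leaves) + 1L]] <- leafsets[[j]]
    }
    merged <- c(leafsets[[pair[1L]]], leafsets[[pair[2L]]])
    keep <- setdiff(seq_len(k), pair)
    leafsets <- c(leafsets[keep], list(merged))
    tb <- c(tb[keep], t)
  }

  Ltot <- sum(b_len)
  nm <- stats::rpois(1L, theta * Ltot)
  pos <- sort(stats::runif(nm, 0, L))
  mat <- matrix(0L, nrow = n, ncol = nm)
  if (nm > 0) {
    br <- sample.int(length(b_len), nm, replace = TRUE, prob = b_len)
    for (j in seq_len(nm)) mat[b_leaves[[br[j]]], j] <- 1L
  }
  structure(list(n = n, L = L, positions = pos, haplotypes = mat),
            class = "haplotype_sample")
}

#' @export
print.haplotype_sample <- function(x, ...) {
  cat(sprintf("Haplotype sample: %d chromosomes, %d segregating sites on %g bp\n",
              x$n, length(x$positions), x$L))
  invisible(x)
}

#' Randomly split a sample into two pseudo-populations
#'
#' Uniform random partition of the chromosomes without replacement —
#' the panmixia null's "split 80 into two 40s" step.
#'
#' @param sample A `haplotype_sample`.
#' @param sizes Two subsample sizes summing to `sample$n`.
#' @param seed Optional integer seed.
#' @return List with `sample1`, `sample2` (both `haplotype_sample`s over
#'   the same positions) and the `assignment` index vector.
#' @export
split_panmictic <- function(sample, sizes = c(40L, 40L), seed = NULL) {
  stopifnot(inherits(sample, "haplotype_sample"), length(sizes) == 2L)
  if (sum(sizes) != sample$n) stop("sizes must sum to the sample size")
  if (!is.null(seed)) set.seed(seed)
  perm <- sample.int(sample$n)
  i1 <- perm[seq_len(sizes[1L])]
  i2 <- perm[sizes[1L] + seq_len(sizes[2L])]
  mk <- function(idx, m) structure(
    list(n = length(idx), L = sample$L, positions = sample$positions,
         haplotypes = sample$haplotypes[idx, , drop = FALSE]),
    class = "haplotype_sample")
  list(sample1 = mk(i1), sample2 = mk(i2), assignment = perm)
}

#' Simulate pooled reads from a haplotype pool
#'
#' At each site every read samples one chromosome uniformly with
#' replacement and reports its allele, miscalled with probability
#' `epsilon` — equivalently, the derived-read count is binomial with
#' success probability `(1 - epsilon) p + epsilon (1 - p)` where `p` is
#' the pool allele frequency, which is how it is drawn.
#'
#' @param sample A `haplotype_sample` (the pool).
#' @param coverage Mean (Poisson) or fixed coverage per site.
#' @param coverage_model `"fixed"` or `"poisson"`.
#' @param epsilon Per-read error probability.
#' @param seed Optional integer seed.
#' @return Data frame with `pos`, `k` (derived reads), `r` (coverage).
#' @export
poolseq_reads_from_pool <- function(sample, coverage = 34,
                                    coverage_model = c("fixed", "poisson"),
                                    epsilon = 0.001, seed = NULL) {
  stopifnot(inherits(sample, "haplotype_sample"))
  coverage_model <- match.arg(coverage_model)
  if (!is.null(seed)) set.seed(seed)
  S <- length(sample$positions)
  p <- if (S) colMeans(sample$haplotypes) else numeric(0)
  r <- switch(coverage_model,
              fixed = rep(as.integer(coverage), S),
              poisson = stats::rpois(S, coverage))
  k <- stats::rbinom(S, r, (1 - epsilon) * p + epsilon * (1 - p))
  data.frame(pos = sample$positions, k = k, r = r)
}

## shared pipeline: pooled counts -> ML frequencies -> per-site pi's.
## c1, c2 are true derived counts out of n1, n2; coverage vectors r1, r2.
.pool_estimate_site_pis <- function(c1, c2, n1, n2, r1, r2, epsilon) {
  p1t <- (1 - epsilon) * c1 / n1 + epsilon * (1 - c1 / n1)
  p2t <- (1 - epsilon) * c2 / n2 + epsilon * (1 - c2 / n2)
  k1 <- stats::rbinom(length(c1), r1, p1t)
  k2 <- stats::rbinom(length(c2), r2, p2t)
  m1 <- pool_model(n1, epsilon)
  m2 <- pool_model(n2, epsilon)
  f1 <- ml_site_frequency(k1, r1, m1)$freq
  f2 <- ml_site_frequency(k2, r2, m2)$freq
  list(pi_w = (site_pi_within(f1, n1) + site_pi_within(f2, n2)) / 2,
       pi_b = site_pi_between(f1, f2), f1 = f1, f2 = f2)
}

#' Null distribution of window F_ST under panmixia
#'
#' The neutrality-test null: simulate a panmictic coalescent sample of
#' `n1 + n2` chromosomes over a `window`-bp non-recombining region,
#' randomly split it into two pseudo-pools, simulate pooled reads at
#' fixed coverage in both, estimate per-site allele frequencies by ML,
#' and compute each replicate's window F_ST from the summed pi's.
#'
#' @param reps Number of window replicates.
#' @param coverage Fixed per-species coverage (the variance-maximising
#'   20x by default).
#' @param window Window length in bp.
#' @param theta Population-scaled mutation rate per window.
#' @param demography A [demography_model()].
#' @param n1,n2 Pseudo-pool sizes.
#' @param epsilon Sequencing error rate.
#' @param seed Optional integer seed.
#' @return Sorted numeric vector of null window F_ST values (windows
#'   with no usable site are dropped).
#' @export
null_fst_distribution <- function(reps = 100000L, coverage = 20L,
                                  window = 10000L, theta = 1000,
                                  demography = demography_model(),
                                  n1 = 40L, n2 = 40L, epsilon = 0.001,
                                  seed = NULL) {
  stopifnot(reps >= 1)
  if (!is.null(seed)) set.seed(seed)
  ep <- .demography_epochs(demography)
  sim <- cpp_coal_counts(n1, n2, as.integer(reps), theta, window,
                         FALSE, 0, ep$starts, ep$sizes, Inf)
  if (length(sim$window) == 0L) return(numeric(0))
  S <- length(sim$window)
  est <- .pool_estimate_site_pis(sim$c1, sim$c2, n1, n2,
                                 rep(as.integer(coverage), S),
                                 rep(as.integer(coverage), S), epsilon)
  sw <- rowsum_by_bin(est$pi_w, sim$window, reps)
  sb <- rowsum_by_bin(est$pi_b, sim$window, reps)
  sort(fst_value(sw[sb > 0], sb[sb > 0]))
}

#' Per-site F_ST under panmixia, with coverages
#'
#' Simulates segregating sites under the panmictic null (coalescent
#' sample of `n1 + n2`, random split, pooled reads with error) until at
#' least `n_sites` sites have been produced, drawing each species'
#' coverage uniformly from `coverage_range`, then estimates per-site
#' allele frequencies and F_ST.  The result feeds
#' [fst_by_coverage_bins()] — the coverage-resolved panmixia diagnostic.
#'
#' The default estimator is the posterior mean under an SFS prior fitted
#' to the simulated counts by EM ([posterior_site_frequency()]); the raw
#' per-site ML frequency carries a read-noise bias of order `1/r` in
#' per-site F_ST (about +0.025 at 20-30x), which the prior shrinkage
#' removes — only the shrunk estimator reproduces the near-zero,
#' slightly negative panmixia bin means.
#'
#' @param n_sites Minimum number of segregating sites.
#' @param coverage_range Integer range of per-species coverages.
#' @param theta Scaled mutation rate per simulated region.
#' @param L Region length in bp.
#' @param demography A [demography_model()].
#' @param n1,n2 Pseudo-pool sizes.
#' @param epsilon Sequencing error rate.
#' @param estimator `"posterior"` (default; SFS-prior posterior mean) or
#'   `"ml"` (raw maximum likelihood).
#' @param seed Optional integer seed.
#' @return Data frame with per-site `fst`, `cov1`, `cov2`.
#' @export
simulate_panmixia_sitefst <- function(n_sites = 100000L,
                                      coverage_range = c(20L, 50L),
                                      theta = 1000, L = 10000,
                                      demography = demography_model(),
                                      n1 = 40L, n2 = 40L, epsilon = 0.001,
                                      estimator = c("posterior", "ml"),
                                      seed = NULL) {
  estimator <- match.arg(estimator)
  if (!is.null(seed)) set.seed(seed)
  ep <- .demography_epochs(demography)
  covs <- seq(as.integer(coverage_range[1L]), as.integer(coverage_range[2L]))
  got <- 0L
  counts <- list()
  while (got < n_sites) {
    nw <- max(16L, ceiling((n_sites - got) / max(theta / 3, 1)))
    sim <- cpp_coal_counts(n1, n2, nw, theta, L, FALSE, 0,
                           ep$starts, ep$sizes, Inf)
    S <- length(sim$window)
    if (S == 0L) next
    counts[[length(counts) + 1L]] <- data.frame(c1 = sim$c1, c2 = sim$c2)
    got <- got + S
  }
  cc <- do.call(rbind, counts)
  S <- nrow(cc)
  r1 <- sample(covs, S, replace = TRUE)
  r2 <- sample(covs, S, replace = TRUE)
  p1t <- (1 - epsilon) * cc$c1 / n1 + epsilon * (1 - cc$c1 / n1)
  p2t <- (1 - epsilon) * cc$c2 / n2 + epsilon * (1 - cc$c2 / n2)
  k1 <- stats::rbinom(S, r1, p1t)
  k2 <- stats::rbinom(S, r2, p2t)
  m1 <- pool_model(n1, epsilon)
  m2 <- pool_model(n2, epsilon)
  if (estimator == "posterior") {
    sub <- if (S > 300000L) sample.int(S, 300000L) else seq_len(S)
    if (n1 == n2) {
      sfs1 <- sfs2 <- estimate_sfs_em(c(k1[sub], k2[sub]),
                                      c(r1[sub], r2[sub]), m1)
    } else {
      sfs1 <- estimate_sfs_em(k1[sub], r1[sub], m1)
      sfs2 <- estimate_sfs_em(k2[sub], r2[sub], m2)
    }
    f1 <- posterior_site_frequency(k1, r1, m1, sfs1)
    f2 <- posterior_site_frequency(k2, r2, m2, sfs2)
  } else {
    f1 <- ml_site_frequency(k1, r1, m1)$freq
    f2 <- ml_site_frequency(k2, r2, m2)$freq
  }
  pw <- (site_pi_within(f1, n1) + site_pi_within(f2, n2)) / 2
  pb <- site_pi_between(f1, f2)
  out <- data.frame(fst = fst_value(pw, pb), cov1 = r1, cov2 = r2)
  rownames(out) <- NULL
  out
}

#' Power to detect genome-wide differentiation
#'
#' Simulates `n_loci` independent two-deme loci with symmetric migration
#' tuned so the expected F_ST equals `true_fst_target` (island-model
#' closed form `F_ST = 1/(1 + 8 N m)`), pushes them through the Pool-seq
#' pipeline (pooled reads, ML frequencies), and computes the
#' genome-average F_ST (ratio of summed pi's).  Power is the fraction of
#' replicates exceeding the `1 - alpha` quantile of the matched panmixia
#' null.  A target of 0 is simulated as true panmixia, so power
#' calibrates to `alpha` by construction.
#'
#' @param true_fst_target Expected F_ST in `[0, 1)`.
#' @param n_per_pop Chromosomes per pool.
#' @param coverage Fixed per-species coverage.
#' @param n_loci Independent loci per replicate.
#' @param reps Alternative replicates.
#' @param null_reps Null replicates for the rejection threshold.
#' @param alpha Test size.
#' @param theta Scaled mutation rate per locus.
#' @param epsilon Sequencing error rate.
#' @param seed Optional integer seed.
#' @return Estimated power, with the simulated statistics in
#'   `attr(, "stats")` and `attr(, "null_stats")`.
#' @export
detection_power <- function(true_fst_target, n_per_pop = 40L, coverage = 34L,
                            n_loci = 300L, reps = 200L, null_reps = 400L,
                            alpha = 0.05, theta = 10, epsilon = 0.001,
                            seed = NULL) {
  stopifnot(true_fst_target >= 0, true_fst_target < 1)
  if (!is.null(seed)) set.seed(seed)

  one_stat <- function(mig) {
    sim <- cpp_coal_counts(n_per_pop, n_per_pop, n_loci, theta, 1,
                           mig > 0, mig, 0, 1, Inf)
    S <- length(sim$window)
    if (S == 0L) return(NA_real_)
    est <- .pool_estimate_site_pis(sim$c1, sim$c2, n_per_pop, n_per_pop,
                                   rep(as.integer(coverage), S),
                                   rep(as.integer(coverage), S), epsilon)
    fst_value(sum(est$pi_w), sum(est$pi_b))
  }

  ## per-lineage migration rate (units of 4N): F = 1/(1 + 2M)
  mig <- if (true_fst_target == 0) 0
         else (1 / true_fst_target - 1) / 2
  null_stats <- vapply(seq_len(null_reps), function(i) one_stat(0), 0)
  stats_alt <- vapply(seq_len(reps), function(i) one_stat(mig), 0)
  crit <- stats::quantile(null_stats, 1 - alpha, na.rm = TRUE, names = FALSE)
  power <- mean(stats_alt > crit, na.rm = TRUE)
  attr(power, "stats") <- stats_alt
  attr(power, "null_stats") <- null_stats
  attr(power, "critical_value") <- crit
  power
}
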