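#' Folded site frequency spectrum
#'
#' A probability vector over folded allele-count classes `0..floor(n/2)`
#' for a pool of `n` chromosomes.  Class 0 is the monomorphic class, so
#' `1 - phi[0]` is the implied proportion of polymorphic sites.
#'
#' @param phi Non-negative weights over classes `0..floor(n/2)`;
#'   normalised to sum to 1.
#' @param n Haploid sample size.
#' @return An object of class `folded_sfs`.
#' @export
folded_sfs <- function(phi, n) {
  n <- as.integer(n)
  stopifnot(n >= 2L, length(phi) == n %/% 2 + 1L, all(phi >= 0),
            sum(phi) > 0)
  phi <- phi / sum(phi)
  structure(list(n = n, phi = stats::setNames(phi, 0:(n %/% 2))),
            class = "folded_sfs")
}

#' @export
print.folded_sfs <- function(x, ...) {
  cat(sprintf("Folded SFS, n = %d chromosomes\n", x$n))
  cat(sprintf("  P(polymorphic) = %.4g\n", 1 - x$phi[[1]]))
  if (!is.null(x$n_iter))
    cat(sprintf("  EM: %d iterations, converged = %s\n",
                x$n_iter, x$converged))
  seg <- x$phi[-1]
  if (sum(seg) > 0)
    cat(sprintf("  singleton share among segregating classes = %.3f\n",
                seg[[1]] / sum(seg)))
  invisible(x)
}

#' Estimate the folded SFS from pooled read counts by EM
#'
#' Fits mixture weights `phi` over folded allele-count classes
#' `f = 0..floor(n/2)` to per-site read counts, with the folded pooled
#' read likelihood as the class-conditional density:
#' `P(k, r) = sum_f phi_f choose(r, k) P_f(k | f)`.
#' The E-step computes each site's posterior over classes, the M-step
#' replaces `phi` by the posterior mean; iteration stops when
#' `max |delta phi| < tol`.  Sites with identical `(k, r)` are aggregated
#' first, which leaves the algorithm unchanged.
#'
#' @param k,r Focal-allele read counts and coverages, one entry per site.
#' @param model A [pool_model()].
#' @param tol Convergence tolerance on `max |delta phi|`.
#' @param max_iter Iteration cap.
#' @return A `folded_sfs` with extra fields: `loglik` (trace of the
#'   observed-data log likelihood, non-decreasing), `n_iter`, `converged`,
#'   `p_polymorphic` and `n_sites`.
#' @export
estimate_sfs_em <- function(k, r, model, tol = 1e-8, max_iter = 1000L) {
  stopifnot(inherits(model, "pool_model"))
  if (length(k) == 0L) stop("no sites supplied")
  stopifnot(length(k) == length(r), all(k >= 0), all(k <= r), all(r >= 1))
  n <- model$n
  classes <- 0:(n %/% 2)

  grp <- paste(k, r)
  ug <- !duplicated(grp)
  ku <- k[ug]; ru <- r[ug]
  w <- as.vector(table(factor(grp, levels = grp[ug])))

  ## class-conditional likelihoods, groups x classes
  A <- vapply(classes, function(f) {
    lchoose(ru, ku) + log(folded_site_likelihood(ku, ru, f, model))
  }, numeric(length(ku)))
  A <- matrix(A, nrow = length(ku))

  phi <- rep(1 / length(classes), length(classes))
  ll_trace <- numeric(0)
  converged <- FALSE
  it <- 0L
  for (it in seq_len(max_iter)) {
    B <- sweep(A, 2L, log(phi), "+")
    mx <- apply(B, 1L, max)
    P <- exp(B - mx)
    rs <- rowSums(P)
    ll_trace <- c(ll_trace, sum(w * (log(rs) + mx)))
    phi_new <- colSums(w * P / rs)
    phi_new <- phi_new / sum(phi_new)
    delta <- max(abs(phi_new - phi))
    phi <- phi_new
    if (delta < tol) { converged <- TRUE; break }
  }

  out <- folded_sfs(phi, n)
  out$loglik <- ll_trace
  out$n_iter <- it
  out$converged <- converged
  out$p_polymorphic <- 1 - out$phi[[1]]
  out$n_sites <- length(k)
  out
}

#' Nucleotide diversity from allele frequencies or a folded SFS
#'
#' Average pairwise heterozygosity with the `n/(n-1)` small-sample
#' correction.  For a frequency vector `p` over polymorphic sites,
#' `pi = sum n/(n-1) * 2 p (1-p) / L`, where `L` is the total number of
#' sites screened (monomorphic included).  For a `folded_sfs`, whose
#' classes already include the monomorphic class, the per-site expectation
#' `sum_f phi_f * n/(n-1) * 2 (f/n) (1 - f/n)` is returned and `L` is not
#' needed.
#'
#' @param x Numeric vector of per-site frequency estimates, or a
#'   `folded_sfs`.
#' @param n Haploid sample size (taken from `x` when it is a `folded_sfs`).
#' @param L Total number of sites the frequencies were screened from.
#' @return Diversity per site.
#' @export
nucleotide_diversity <- function(x, n = NULL, L = NULL) {
  if (inherits(x, "folded_sfs")) {
    n <- x$n
    f <- as.numeric(names(x$phi))
    return(sum(x$phi * n / (n - 1) * 2 * (f / n) * (1 - f / n)))
  }
  stopifnot(is.numeric(x), all(x >= 0 & x <= 1), !is.null(n), !is.null(L))
  if (n < 2) stop("n must be >= 2")
  if (L < length(x)) stop("L must be at least the number of sites")
  if (length(x) == 0L) return(0)
  sum(n / (n - 1) * 2 * x * (1 - x)) / L
}

#' Tajima's D from a site frequency spectrum
#'
#' Standard Tajima (1989) statistic contrasting mean pairwise diversity
#' with the scaled number of segregating sites.  `counts` are SFS counts
#' of segregating sites: either unfolded (`xi_1 .. xi_{n-1}`) or folded
#' (`eta_1 .. eta_{floor(n/2)}`); both give identical `pi` because the
#' pairwise-difference weight `2 i (n - i) / (n (n - 1))` is fold-symmetric.
#'
#' @param counts SFS counts of segregating classes (no monomorphic class).
#' @param n Haploid sample size.
#' @return Tajima's D, or `NA_real_` when there are no segregating sites.
#' @export
tajimas_d <- function(counts, n) {
  stopifnot(n >= 4, all(counts >= 0))
  lc <- length(counts)
  if (lc == n - 1L) {
    i <- seq_len(n - 1L)
  } else if (lc == n %/% 2) {
    i <- seq_len(n %/% 2)
  } else {
    stop("counts must have length n-1 (unfolded) or floor(n/2) (folded)")
  }
  S <- sum(counts)
  if (S == 0) return(NA_real_)
  pi_hat <- sum(counts * 2 * i * (n - i)) / (n * (n - 1))

  a1 <- sum(1 / seq_len(n - 1))
  a2 <- sum(1 / seq_len(n - 1)^2)
  b1 <- (n + 1) / (3 * (n - 1))
  b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  e1 <- c1 / a1
  e2 <- c2 / (a1^2 + a2)
  (pi_hat - S / a1) / sqrt(e1 * S + e2 * S * (S - 1))
}

#' Posterior allele-frequency estimate under an SFS prior
#'
#' Posterior mean of the allele count `Y` given pooled reads, with the
#' folded SFS as prior (its mass symmetrised over the two polarities of
#' each folded class) and the pooled read likelihood.  Shrinking noisy
#' low-coverage read fractions toward the spectrum removes the upward
#' read-noise bias that plagues per-site F_ST from raw ML frequencies,
#' which is what the coverage-binned panmixia diagnostic needs.
#'
#' @param k,r Focal-allele read counts and coverages (vectorised).
#' @param model A [pool_model()].
#' @param sfs A [folded_sfs()] prior for the pool (e.g. from
#'   [estimate_sfs_em()]).
#' @param chunk Sites per internal block (memory control).
#' @return Numeric vector of posterior-mean frequencies in `[0, 1]`.
#' @export
posterior_site_frequency <- function(k, r, model, sfs, chunk = 200000L) {
  stopifnot(inherits(model, "pool_model"), inherits(sfs, "folded_sfs"),
            model$n == sfs$n, length(k) == length(r))
  n <- model$n
  phi <- as.numeric(sfs$phi)
  prior <- numeric(n + 1L)
  for (f in 0:(n %/% 2)) {
    if (f == n - f) prior[f + 1L] <- phi[f + 1L]
    else {
      prior[f + 1L] <- prior[f + 1L] + phi[f + 1L] / 2
      prior[n - f + 1L] <- prior[n - f + 1L] + phi[f + 1L] / 2
    }
  }
  lp <- log(prior)
  out <- numeric(length(k))
  for (off in seq(1L, length(k), by = chunk)) {
    idx <- off:min(off + chunk - 1L, length(k))
    ll <- vapply(0:n, function(y)
      pool_read_likelihood(k[idx], r[idx], y, model, log = TRUE) +
        lp[y + 1L],
      numeric(length(idx)))
    ll <- matrix(ll, ncol = n + 1L)
    w <- exp(ll - apply(ll, 1L, max))
    out[idx] <- as.numeric((w %*% (0:n / n)) / rowSums(w))
  }
  out
}

#' Profile the sequencing error rate over the EM likelihood
#'
#' The error rate enters the pooled read likelihood directly, so it can
#' be estimated by profiling: fit the folded SFS by EM at each candidate
#' `epsilon` and keep the value with the highest fitted log likelihood.
#'
#' @param k,r Focal-allele read counts and coverages.
#' @param n Haploid pool size.
#' @param grid Candidate error rates (default a log grid over
#'   `1e-4 .. 1e-2`).
#' @param ... Passed to [estimate_sfs_em()].
#' @return A list with `epsilon` (the profile maximiser), `loglik` (one
#'   value per grid point) and `fits` (the EM fit at each point).
#' @export
estimate_epsilon_profile <- function(k, r, n = 40L,
                                     grid = 10^seq(-4, -2, length.out = 9),
                                     ...) {
  stopifnot(length(grid) >= 1, all(grid >= 0 & grid < 0.5))
  fits <- lapply(grid, function(e)
    estimate_sfs_em(k, r, pool_model(n, e), ...))
  ll <- vapply(fits, function(f) f$loglik[length(f$loglik)], 0)
  list(epsilon = grid[which.max(ll)], loglik = ll, fits = fits)
}

#' Call sites polymorphic from their class posterior
#'
#' A site is called polymorphic when its posterior mass off the
#' monomorphic folded class, under the fitted SFS prior, exceeds `cut`
#' (default 0.5) — the per-site counterpart of the mixture-level
#' polymorphic proportion `1 - phi[0]`.
#'
#' @param k,r Focal-allele read counts and coverages.
#' @param model A [pool_model()].
#' @param sfs A fitted [folded_sfs()].
#' @param cut Posterior-mass threshold.
#' @return Logical vector, one entry per site.
#' @export
call_polymorphic_sites <- function(k, r, model, sfs, cut = 0.5) {
  stopifnot(inherits(model, "pool_model"), inherits(sfs, "folded_sfs"),
            model$n == sfs$n)
  n <- model$n
  classes <- 0:(n %/% 2)
  ll <- vapply(classes, function(f)
    log(folded_site_likelihood(k, r, f, model)) + log(sfs$phi[[f + 1L]]),
    numeric(length(k)))
  ll <- matrix(ll, ncol = length(classes))
  w <- exp(ll - apply(ll, 1L, max))
  1 - w[, 1L] / rowSums(w) > cut
}
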