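#' Pooled-sequencing sampling model
#'
#' Bundles the two quantities every Pool-seq likelihood needs: the haploid
#' pool size `n` (number of chromosomes in the pool, e.g. 40 for 20 diploid
#' individuals) and the per-read sequencing error probability `epsilon`.
#'
#' @param n Haploid pool size (chromosomes); must be >= 2.
#' @param epsilon Per-read error probability, in `[0, 0.5)`.
#' @return An object of class `pool_model`.
#' @examples
#' pool_model(40, 0.001)
#' @export
pool_model <- function(n = 40L, epsilon = 0.001) {
  n <- as.integer(n)
  stopifnot(length(n) == 1L, !is.na(n), n >= 2L,
            length(epsilon) == 1L, is.finite(epsilon),
            epsilon >= 0, epsilon < 0.5)
  structure(list(n = n, epsilon = epsilon), class = "pool_model")
}

#' @export
print.pool_model <- function(x, ...) {
  cat(sprintf("Pool-seq model: n = %d chromosomes, epsilon = %g\n",
              x$n, x$epsilon))
  invisible(x)
}

## probability that one read shows the derived allele, given pool allele
## count y out of n and error rate e
.read_prob <- function(y, n, e) (1 - e) * y / n + e * (1 - y / n)

#' Pooled read likelihood of an allele count
#'
#' Probability of observing a given ordered set of reads at one site:
#' `k` reads carry the focal allele and `r-k` do not, when the pool of `n`
#' chromosomes carries the focal allele `y` times and each read is drawn
#' uniformly from the pool and miscalled with probability `epsilon`.  No
#' binomial coefficient is included (the reads are treated as an ordered,
#' exchangeable sequence); multiply by `choose(r, k)` to get the
#' distribution over `k`.
#'
#' All arguments are vectorised and recycled.
#'
#' @param k Number of reads carrying the focal allele, `0 <= k <= r`.
#' @param r Coverage (total reads), `r>=0`.
#' @param y Allele count in the pool, `0 <= y <= n`.
#' @param model A [pool_model()].
#' @param log If `TRUE`, return the log probability.
#' @return Probability (or log probability) of the read configuration.
#' @examples
#' m <- pool_model(40, 0.01)
#' pool_read_likelihood(2, 4, 10, m)  # 0.255^2 * 0.745^2
#' @export
pool_read_likelihood <- function(k, r, y, model, log = FALSE) {
  stopifnot(inherits(model, "pool_model"))
  if (any(k < 0 | r < 0 | k > r, na.rm = TRUE))
    stop("need 0 <= k <= r")
  if (any(y < 0 | y > model$n, na.rm = TRUE))
    stop("need 0 <= y <= n")
  q <- .read_prob(y, model$n, model$epsilon)
  ## 0 * log(0) is a legitimate 0 contribution here
  t1 <- ifelse(k == 0, 0, k * log(q))
  t2 <- ifelse(r - k == 0, 0, (r - k) * log1p(-q))
  ll <- t1 + t2
  if (log) ll else exp(ll)
}

#' Folded pooled read likelihood
#'
#' When the ancestral state is unknown the spectrum is folded:
#' `P_f(k | y) = (P(k | y) + P(r - k | y)) / 2`.  Equivalently, the second
#' term is the likelihood under the mirrored allele count `n - y`.
#'
#' @inheritParams pool_read_likelihood
#' @return Folded likelihood of the read configuration.
#' @export
folded_site_likelihood <- function(k, r, y, model) {
  (pool_read_likelihood(k, r, y, model) +
     pool_read_likelihood(r - k, r, y, model)) / 2
}

#' Maximum-likelihood allele count from pooled reads
#'
#' Maximises the pooled read likelihood over the integer allele count
#' `y in 0..n`.  The likelihood is concave in the per-read probability,
#' which is affine in `y`, so the integer optimum brackets the continuous
#' optimum `n * (k/r - epsilon) / (1 - 2 epsilon)`; only the two bracketing
#' candidates need to be evaluated.  Exact ties are broken toward the
#' boundary (0 or `n`) nearer to `k / r`.
#'
#' @param k,r Focal-allele read counts and coverages (vectorised).
#' @param model A [pool_model()].
#' @return A data frame with columns `y_hat` (ML allele count), `freq`
#'   (`y_hat / n`), `loglik` and `coverage`.
#' @examples
#' ml_site_frequency(5, 10, pool_model(40, 0))  # y_hat = 20
#' @export
ml_site_frequency <- function(k, r, model) {
  stopifnot(inherits(model, "pool_model"))
  if (any(r < 1, na.rm = TRUE)) stop("coverage must be >= 1")
  if (any(k < 0 | k > r, na.rm = TRUE)) stop("need 0 <= k <= r")
  n <- model$n
  e <- model$epsilon
  ystar <- n * (k / r - e) / (1 - 2 * e)
  lo <- pmin(pmax(floor(ystar), 0), n)
  hi <- pmin(pmax(ceiling(ystar), 0), n)
  ll_lo <- pool_read_likelihood(k, r, lo, model, log = TRUE)
  ll_hi <- pool_read_likelihood(k, r, hi, model, log = TRUE)
  y <- ifelse(ll_hi > ll_lo, hi, lo)
  ## ties: pick the candidate nearer the boundary that k/r is nearer to
  tie <- ll_hi == ll_lo & lo != hi
  y[tie] <- ifelse(k[tie] / r[tie] <= 0.5, lo[tie], hi[tie])
  data.frame(y_hat = as.integer(y), freq = y / n,
             loglik = pmax(ll_lo, ll_hi), coverage = as.integer(r))
}
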