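# Independent oracles used across the suite.  These deliberately do not
# share code paths with the package internals they check.

# Brute-force pooled read likelihood: enumerate every per-read
# configuration (which chromosome state the read sampled, and whether it
# was miscalled) and sum the probability of configurations consistent
# with observing k derived reads out of r, in observation order
# (derived reads first -- the model is exchangeable so order is moot).
brute_read_likelihood <- function(k, r, y, n, eps) {
  obs <- c(rep(1L, k), rep(0L, r - k))
  ## per read: (true allele a in {1, 0}) x (error e in {TRUE, FALSE})
  states <- expand.grid(a = c(1L, 0L), e = c(TRUE, FALSE))
  states$p <- ifelse(states$a == 1L, y / n, 1 - y / n) *
    ifelse(states$e, eps, 1 - eps)
  states$seen <- ifelse(states$e, 1L - states$a, states$a)
  total <- 0
  idx <- rep(1L, r)
  repeat {
    p <- 1
    okconf <- TRUE
    for (j in seq_len(r)) {
      st <- states[idx[j], ]
      if (st$seen != obs[j]) { okconf <- FALSE; break }
      p <- p * st$p
    }
    if (okconf) total <- total + p
    ## odometer over 4^r configurations
    j <- 1L
    while (j <= r && idx[j] == 4L) { idx[j] <- 1L; j <- j + 1L }
    if (j > r) break
    idx[j] <- idx[j] + 1L
  }
  total
}

# Brute-force integer ML allele count (full grid search, tie toward the
# boundary nearer k/r).
brute_ml_count <- function(k, r, n, eps) {
  ll <- vapply(0:n, function(y) {
    q <- (1 - eps) * y / n + eps * (1 - y / n)
    t1 <- if (k == 0) 0 else k * log(q)
    t2 <- if (r - k == 0) 0 else (r - k) * log(1 - q)
    t1 + t2
  }, 0)
  best <- which(ll == max(ll)) - 1L
  if (length(best) == 1L) return(best)
  if (k / r <= 0.5) min(best) else max(best)
}

# Independently written Tajima's D (constants written out in full).
oracle_tajimas_d <- function(xi, n) {
  S <- sum(xi)
  i <- seq_along(xi)
  stopifnot(length(xi) == n - 1)
  pi_hat <- sum(2 * xi * i * (n - i)) / (n * (n - 1))
  a1 <- sum(1 / (1:(n - 1)))
  a2 <- sum(1 / (1:(n - 1))^2)
  e1 <- ((n + 1) / (3 * (n - 1)) - 1 / a1) / a1
  e2 <- (2 * (n^2 + n + 3) / (9 * n * (n - 1)) -
           (n + 2) / (n * a1) + a2 / a1^2) / (a1^2 + a2)
  (pi_hat - S / a1) / sqrt(e1 * S + e2 * S * (S - 1))
}

# small handmade site table
toy_table <- function(df, ...) genome_table(df, ...)

# fraction of truth regions recovered with >= 50% reciprocal overlap,
# and the number of calls not matching any truth region
score_recovery <- function(calls, truth) {
  matched <- rep(FALSE, nrow(calls))
  rec <- 0L
  for (i in seq_len(nrow(truth))) {
    if (nrow(calls) == 0L) break
    ov <- pmin(calls$end, truth$end[i]) - pmax(calls$start, truth$start[i])
    hit <- calls$chrom == truth$chrom[i] & ov > 0 &
      ov >= 0.5 * (truth$end[i] - truth$start[i]) &
      ov >= 0.5 * (calls$end - calls$start)
    if (any(hit)) {
      rec <- rec + 1L
      matched[hit] <- TRUE
    }
  }
  list(recovered = rec, false_calls = sum(!matched))
}
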