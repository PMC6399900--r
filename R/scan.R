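#' Per-site diversity and differentiation statistics
#'
#' `site_pi_within()` is the within-population heterozygosity with the
#' small-sample correction, `n/(n-1) * 2 p (1-p)`.  `site_pi_between()` is
#' the average pairwise divergence between populations,
#' `p1 (1-p2) + p2 (1-p1)` (frequencies must share folding polarity).
#' `fst_value()` is the Hudson-style ratio `1 - pi_w / pi_b`; it returns
#' `NA` when `pi_b = 0` and deliberately retains negative values (under
#' panmixia the correction makes it slightly negative on average).
#'
#' @param p,p1,p2 Allele frequencies in `[0, 1]` (vectorised).
#' @param n Haploid sample size (>= 2).
#' @param pi_w,pi_b Within-diversity and between-divergence.
#' @return Numeric vector of per-site statistics.
#' @export
site_pi_within <- function(p, n) {
  if (any(n < 2)) stop("n must be >= 2")
  stopifnot(all(p >= 0 & p <= 1, na.rm = TRUE))
  n / (n - 1) * 2 * p * (1 - p)
}

#' @rdname site_pi_within
#' @export
site_pi_between <- function(p1, p2) {
  stopifnot(all(p1 >= 0 & p1 <= 1, na.rm = TRUE),
            all(p2 >= 0 & p2 <= 1, na.rm = TRUE))
  p1 * (1 - p2) + p2 * (1 - p1)
}

#' @rdname site_pi_within
#' @export
fst_value <- function(pi_w, pi_b) {
  if (any(pi_b < 0, na.rm = TRUE)) stop("pi_b must be >= 0")
  ifelse(pi_b == 0, NA_real_, 1 - pi_w / pi_b)
}

## per-site estimates used by the scan and the DR caller
.site_estimates <- function(table, model1, model2) {
  f1 <- ml_site_frequency(table$k1, table$r1, model1)$freq
  f2 <- ml_site_frequency(table$k2, table$r2, model2)$freq
  pw <- (site_pi_within(f1, model1$n) + site_pi_within(f2, model2$n)) / 2
  pb <- site_pi_between(f1, f2)
  list(f1 = f1, f2 = f2, pi_w = pw, pi_b = pb)
}

#' Sliding-window pi and F_ST genome scan
#'
#' Estimates per-site allele frequencies by maximum likelihood, then
#' tiles each chromosome with windows of `window` bp advanced by `step`
#' bp (0-based half-open spans; the last window must fit entirely).  A
#' site is "covered" when both species reach `min_cov` reads; windows in
#' which fewer than `min_cov_fraction` of their sites are covered are
#' dropped.  Window `pi_w` and `pi_b` are per-covered-site means and the
#' window F_ST is computed from those sums (ratio of averages, the robust
#' choice for low-information sites), so `fst = 1 - sum(pi_w)/sum(pi_b)`.
#'
#' @param table A filtered [genome_table()].
#' @param model A [pool_model()] shared by both species (per-species
#'   models via `model2`).
#' @param model2 Optional second-species model (defaults to `model`).
#' @param window,step Window size and increment in bp.
#' @param min_cov_fraction Minimum fraction of covered sites per window.
#' @param min_cov Per-species coverage defining a covered site.
#' @return A data frame of class `window_stats` with columns `chrom`,
#'   `start`, `end`, `n_sites` (covered sites), `pi_w`, `pi_b`, `fst`.
#' @export
scan_windows <- function(table, model, model2 = model, window = 10000L,
                         step = 5000L, min_cov_fraction = 0.5,
                         min_cov = 20L) {
  stopifnot(inherits(table, "genome_table"), inherits(model, "pool_model"))
  window <- as.integer(window); step <- as.integer(step)
  if (window < step) warning("window smaller than step: tiling leaves gaps")
  if (window %% step != 0L)
    stop("window must be a multiple of step")
  nb <- window %/% step

  chrom_sizes <- attr(table, "chrom_sizes")
  chroms <- unique(table$chrom)
  if (is.null(chrom_sizes)) {
    chrom_sizes <- vapply(split(table$pos, table$chrom)[chroms], max, 0L)
  }

  covered <- table$r1 >= min_cov & table$r2 >= min_cov
  est <- .site_estimates(table[covered, , drop = FALSE], model, model2)

  out <- vector("list", length(chroms))
  for (ci in seq_along(chroms)) {
    ch <- chroms[ci]
    len <- chrom_sizes[[ch]]
    nwin <- (len - window) %/% step + 1L
    if (is.na(nwin) || nwin < 1L) next
    nbins <- (len - 1L) %/% step + 1L

    sel <- table$chrom == ch
    bin_all <- (table$pos[sel] - 1L) %/% step + 1L
    n_tot <- tabulate(bin_all, nbins)
    selc <- covered & table$chrom == ch
    bin_cov <- (table$pos[selc] - 1L) %/% step + 1L
    n_cov <- tabulate(bin_cov, nbins)
    ## est vectors are indexed over covered rows only
    cov_rows <- which(table$chrom[covered] == ch)
    s_pw <- rowsum_by_bin(est$pi_w[cov_rows], bin_cov, nbins)
    s_pb <- rowsum_by_bin(est$pi_b[cov_rows], bin_cov, nbins)

    wsum <- function(v) {
      cs <- cumsum(v)
      cs[seq(nb, by = 1L, length.out = nwin)] -
        c(0, cs)[seq(0L, by = 1L, length.out = nwin) + 1L]
    }
    w_tot <- wsum(n_tot); w_cov <- wsum(n_cov)
    w_pw <- wsum(s_pw); w_pb <- wsum(s_pb)

    keep <- w_tot > 0L & w_cov >= min_cov_fraction * w_tot
    starts <- (seq_len(nwin) - 1L) * step
    pi_w <- ifelse(w_cov > 0, w_pw / w_cov, NA_real_)
    pi_b <- ifelse(w_cov > 0, w_pb / w_cov, NA_real_)
    out[[ci]] <- data.frame(chrom = ch, start = starts[keep],
                            end = starts[keep] + window,
                            n_sites = w_cov[keep],
                            pi_w = pi_w[keep], pi_b = pi_b[keep],
                            fst = fst_value(w_pw[keep], w_pb[keep]))
  }
  res <- do.call(rbind, out)
  if (is.null(res))
    res <- data.frame(chrom = character(), start = integer(),
                      end = integer(), n_sites = integer(),
                      pi_w = numeric(), pi_b = numeric(), fst = numeric())
  rownames(res) <- NULL
  class(res) <- c("window_stats", "data.frame")
  attr(res, "window") <- window
  attr(res, "step") <- step
  res
}

## sum v by integer bin (1..nbins); fast dense tabulation
rowsum_by_bin <- function(v, bin, nbins) {
  out <- numeric(nbins)
  if (length(v)) {
    s <- rowsum(v, bin)
    b <- as.integer(rownames(s))
    ok <- b >= 1L & b <= nbins
    out[b[ok]] <- s[ok, 1L]
  }
  out
}

#' Mean per-site F_ST by coverage bin
#'
#' Bins per-site F_ST values by the smaller of the two species' coverages
#' and reports mean, sample SD and count per bin — the panmixia
#' diagnostic plotted against coverage.
#'
#' @param fst Per-site F_ST values (NAs dropped).
#' @param cov1,cov2 Per-site coverages of the two species.
#' @param breaks Bin edges (left-closed, right-open).
#' @return Data frame with `bin_lo`, `bin_hi`, `mean`, `sd`, `n`.
#' @export
fst_by_coverage_bins <- function(fst, cov1, cov2,
                                 breaks = seq(40, 200, by = 10)) {
  stopifnot(length(fst) == length(cov1), length(fst) == length(cov2))
  cov <- pmin(cov1, cov2)
  ok <- !is.na(fst) & cov >= breaks[1L] & cov < breaks[length(breaks)]
  if (!any(ok))
    return(data.frame(bin_lo = numeric(), bin_hi = numeric(),
                      mean = numeric(), sd = numeric(), n = integer()))
  b <- findInterval(cov[ok], breaks, rightmost.closed = FALSE)
  f <- fst[ok]
  agg <- function(fun) as.numeric(tapply(f, b, fun))
  lev <- sort(unique(b))
  data.frame(bin_lo = breaks[lev], bin_hi = breaks[lev + 1L],
             mean = agg(mean), sd = agg(stats::sd),
             n = as.integer(tapply(f, b, length)))
}
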