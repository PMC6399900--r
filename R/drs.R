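#' Top-quantile F_ST screening threshold
#'
#' Empirical `1 - q` quantile (inverse-ECDF, type 1) of the window F_ST
#' values; windows are selected by *strict* inequality, so when all values
#' are tied nothing is selected, and `q = 0` yields `Inf`.
#'
#' @param window_fsts Window F_ST values (NAs dropped).
#' @param q Upper tail fraction to screen (default 0.001, the top 0.1%).
#' @return The screening threshold.
#' @export
fst_threshold_top_quantile <- function(window_fsts, q = 0.001) {
  x <- window_fsts[!is.na(window_fsts)]
  if (length(x) == 0L) stop("no window F_ST values")
  stopifnot(q >= 0, q < 1)
  if (q == 0) return(Inf)
  if (length(x) < 1 / q)
    warning(sprintf("only %d windows for a top-%g screen", length(x), q))
  unname(stats::quantile(x, probs = 1 - q, type = 1L, names = FALSE))
}

#' Find fixed nucleotide differences between the species
#'
#' A fixed difference is a site where the ML allele count is `n` in one
#' species and `0` in the other, using sites covered by at least
#' `min_cov` reads in both species.  Optionally a stricter posterior rule
#' is applied on top: the boundary class must carry posterior probability
#' above `posterior` under a uniform prior over allele counts.
#'
#' @param table A (filtered) [genome_table()].
#' @param model A [pool_model()] (second species via `model2`).
#' @param model2 Optional second-species model.
#' @param min_cov Minimum per-species coverage.
#' @param posterior Optional posterior-probability threshold in `(0, 1)`;
#'   `NULL` (default) uses the plain ML rule.
#' @return Data frame with `chrom`, `pos` (1-based) of fixed differences.
#' @export
find_fixed_differences <- function(table, model, model2 = model,
                                   min_cov = 20L, posterior = NULL) {
  stopifnot(inherits(table, "genome_table"))
  ok <- table$r1 >= min_cov & table$r2 >= min_cov
  t2 <- table[ok, , drop = FALSE]
  if (nrow(t2) == 0L)
    return(data.frame(chrom = character(), pos = integer()))
  y1 <- ml_site_frequency(t2$k1, t2$r1, model)$y_hat
  y2 <- ml_site_frequency(t2$k2, t2$r2, model2)$y_hat
  fixed <- (y1 == model$n & y2 == 0L) | (y1 == 0L & y2 == model2$n)
  if (!is.null(posterior)) {
    pp <- function(k, r, m, boundary) {
      ll <- vapply(0:m$n, function(y)
        pool_read_likelihood(k, r, y, m, log = TRUE), numeric(length(k)))
      ll <- matrix(ll, ncol = m$n + 1L)
      mx <- apply(ll, 1L, max)
      w <- exp(ll - mx)
      w[, boundary + 1L] / rowSums(w)
    }
    p1 <- ifelse(y1 == model$n, pp(t2$k1, t2$r1, model, model$n),
                 pp(t2$k1, t2$r1, model, 0L))
    p2 <- ifelse(y2 == model2$n, pp(t2$k2, t2$r2, model2, model2$n),
                 pp(t2$k2, t2$r2, model2, 0L))
    fixed <- fixed & p1 > posterior & p2 > posterior
  }
  out <- data.frame(chrom = t2$chrom[fixed], pos = t2$pos[fixed])
  rownames(out) <- NULL
  out
}

#' Call differentiated regions from screened windows
#'
#' Implements the outlier-region rule: (1) windows with F_ST strictly
#' above `threshold` are selected; (2) selected windows whose spans
#' overlap or abut are merged into candidate peaks; (3) a peak must look
#' like a peak — on each side of the merged span, F_ST must fall back
#' below the `background_quantile` of all window values within
#' `max_shoulder` non-intersecting windows (a genuine outlier region has
#' shoulders, so the immediately adjacent windows are allowed to be
#' elevated, but the elevation must be short-ranged; chromosome ends
#' pass); (4) a peak must contain at least one fixed difference.  The
#' region span is the union of its member windows.
#'
#' @param windows A `window_stats` data frame from [scan_windows()].
#' @param threshold Screening threshold from
#'   [fst_threshold_top_quantile()].
#' @param fixed_diffs Data frame of fixed differences (`chrom`, 1-based
#'   `pos`) from [find_fixed_differences()].
#' @param background_quantile Quantile of all window F_ST values that
#'   the flanks must drop below (default 0.9).
#' @param max_shoulder Number of non-intersecting windows on each side
#'   within which F_ST must return below the background level
#'   (default 10, i.e. 50 kb of shoulder at the default 5-kb step).
#' @return A data frame of class `dr_calls` with `chrom`, `start`, `end`
#'   (0-based half-open), `n_windows`, `max_fst`, `n_fixed`, `p_value`,
#'   `fdr`; fixed-difference positions per region are in
#'   `attr(, "fixed_positions")`.
#' @export
call_differentiated_regions <- function(windows, threshold, fixed_diffs,
                                        background_quantile = 0.9,
                                        max_shoulder = 10L) {
  stopifnot(inherits(windows, "data.frame"), is.finite(background_quantile))
  bg <- stats::quantile(windows$fst, probs = background_quantile,
                        na.rm = TRUE, names = FALSE)
  empty <- data.frame(chrom = character(), start = integer(),
                      end = integer(), n_windows = integer(),
                      max_fst = numeric(), n_fixed = integer(),
                      p_value = numeric(), fdr = numeric())
  sel <- !is.na(windows$fst) & windows$fst > threshold
  if (!any(sel)) {
    class(empty) <- c("dr_calls", "data.frame")
    return(empty)
  }
  w <- windows[sel, , drop = FALSE]
  w <- w[order(w$chrom, w$start), ]

  regions <- list()
  fixed_pos <- list()
  for (ch in unique(w$chrom)) {
    d <- w[w$chrom == ch, , drop = FALSE]
    allw <- windows[windows$chrom == ch, , drop = FALSE]
    allw <- allw[order(allw$start), ]
    grp <- cumsum(c(1L, as.integer(d$start[-1L] > d$end[-nrow(d)])))
    for (g in unique(grp)) {
      m <- d[grp == g, , drop = FALSE]
      span <- c(min(m$start), max(m$end))
      ## F_ST must return to background within max_shoulder
      ## non-intersecting windows on each side
      left <- allw[allw$end <= span[1L], , drop = FALSE]
      right <- allw[allw$start >= span[2L], , drop = FALSE]
      returns_to_bg <- function(f) {
        length(f) == 0L || any(is.na(f)) || any(f < bg)
      }
      lf <- utils::tail(left$fst[order(left$start)], max_shoulder)
      rf <- utils::head(right$fst[order(right$start)], max_shoulder)
      if (!returns_to_bg(lf) || !returns_to_bg(rf)) next
      fd <- fixed_diffs[fixed_diffs$chrom == ch &
                          fixed_diffs$pos - 1L >= span[1L] &
                          fixed_diffs$pos - 1L < span[2L], , drop = FALSE]
      if (nrow(fd) == 0L) next
      regions[[length(regions) + 1L]] <-
        data.frame(chrom = ch, start = span[1L], end = span[2L],
                   n_windows = nrow(m), max_fst = max(m$fst),
                   n_fixed = nrow(fd), p_value = NA_real_, fdr = NA_real_)
      fixed_pos[[length(fixed_pos) + 1L]] <- fd$pos
    }
  }
  out <- if (length(regions)) do.call(rbind, regions) else empty
  rownames(out) <- NULL
  class(out) <- c("dr_calls", "data.frame")
  attr(out, "fixed_positions") <- fixed_pos
  attr(out, "threshold") <- threshold
  attr(out, "background_fst") <- bg
  out
}

#' @export
print.dr_calls <- function(x, ...) {
  cat(sprintf("Differentiated regions: %d called (screen F_ST > %.4g)\n",
              nrow(x), attr(x, "threshold")))
  if (nrow(x)) {
    df <- as.data.frame(x)
    df$length_kb <- (df$end - df$start) / 1000
    print.data.frame(df, digits = 4)
  }
  invisible(x)
}

#' Simulation-based neutrality p-value for a window
#'
#' Upper-tail p-value of an observed window F_ST against the simulated
#' panmixia null, with the add-one correction
#' `p = (1 + #{null >= observed}) / (1 + #null)` so that p is never
#' exactly zero.
#'
#' @param observed_fst Observed window F_ST.
#' @param null_fsts Simulated null window F_ST values.
#' @return The p-value.
#' @export
window_neutrality_pvalue <- function(observed_fst, null_fsts) {
  null_fsts <- null_fsts[!is.na(null_fsts)]
  if (length(null_fsts) == 0L) stop("empty null distribution")
  (1 + sum(null_fsts >= observed_fst)) / (1 + length(null_fsts))
}

#' Crude false-discovery-rate estimate for a screen
#'
#' Expected false positives over discoveries:
#' `min(1, p * n_windows_tested / n_selected)`.  An estimate of the FDR
#' of the screen, not a Benjamini-Hochberg adjustment.
#'
#' @param p_value Per-window neutrality p-value.
#' @param n_windows_tested Number of windows screened.
#' @param n_selected Number of windows (or regions) selected.
#' @return FDR estimate in `[0, 1]`.
#' @export
estimate_fdr <- function(p_value, n_windows_tested, n_selected) {
  if (n_selected < 1) stop("n_selected must be >= 1")
  stopifnot(p_value >= 0, p_value <= 1, n_windows_tested >= n_selected)
  min(1, p_value * n_windows_tested / n_selected)
}
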