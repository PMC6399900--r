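#' Two-locus haplotype state
#'
#' Haplotype frequencies of the two-locus, two-population model in the
#' order A-B, A-b, a-B, a-b; `x` is population 1 (where A is favoured)
#' and `y` population 2 (where a is favoured).
#'
#' @param x,y Length-4 frequency vectors, each summing to 1.
#' @return An object of class `two_locus_state`.
#' @export
two_locus_state <- function(x, y) {
  stopifnot(length(x) == 4L, length(y) == 4L, all(x >= 0), all(y >= 0),
            abs(sum(x) - 1) < 1e-12, abs(sum(y) - 1) < 1e-12)
  structure(list(x = as.numeric(x), y = as.numeric(y)),
            class = "two_locus_state")
}

#' @export
print.two_locus_state <- function(x, ...) {
  m <- rbind(pop1 = x$x, pop2 = x$y)
  colnames(m) <- c("A-B", "A-b", "a-B", "a-b")
  print(round(m, 6))
  cat(sprintf("D_x = %.6g, D_y = %.6g\n",
              x$x[1] * x$x[4] - x$x[2] * x$x[3],
              x$y[1] * x$y[4] - x$y[2] * x$y[3]))
  invisible(x)
}

#' Parameters of the divergent-selection simulator
#'
#' Population-scaled inputs are converted to per-generation rates:
#' mutation `mu = 4Nmu / (4N)` (symmetric, locus II only), recombination
#' `r=4Nr/(4N)`, migration `m = 4Nm / (4N)` per gamete, selection
#' `s = 4Ns / (4N)` (additive, opposite sign in the two populations).
#'
#' @param N Per-population size (default 1000).
#' @param four_Nmu,four_Nr,four_Nm,four_Ns Population-scaled rates.
#' @param init `"new_mutation"` (a enters population 2 at frequency
#'   1/2N at T = 0 with selection on), `"standing_variation"` (a drifts
#'   neutrally until it reaches `standing_threshold`, then selection
#'   switches on; reps losing a first are restarted) or `"neutral"` (a is
#'   never introduced).
#' @param standing_threshold Frequency that arms selection in
#'   standing-variation mode (default 0.2).
#' @param establishment_fraction In new-mutation mode, reps where a is
#'   lost before reaching this fraction of the deterministic equilibrium
#'   frequency are restarted (conditioning on establishment, which is
#'   what makes the post-sweep trajectory interpretable); 0 disables.
#' @param prerun Neutral burn-in generations for locus II
#'   (default `10 * N`: five times the 2N-generation relaxation time of
#'   heterozygosity).
#' @param T_max Generations simulated after selection onset
#'   (default `8 * N`).
#' @param reps Replicates.
#' @return An object of class `divsel_params`.
#' @export
divsel_params <- function(N = 1000L, four_Nmu = 0.01, four_Nr = 1,
                          four_Nm = 50, four_Ns = 400,
                          init = c("new_mutation", "standing_variation",
                                   "neutral"),
                          standing_threshold = 0.2,
                          establishment_fraction = 0.5,
                          prerun = 10L * N, T_max = 8L * N,
                          reps = 1000L) {
  init <- match.arg(init)
  N <- as.integer(N)
  rates <- c(mu = four_Nmu, r = four_Nr, m = four_Nm, s = four_Ns) / (4 * N)
  if (any(rates < 0 | rates > 0.5))
    stop("per-generation rates must lie in [0, 0.5]; reduce the scaled rates or raise N")
  stopifnot(N >= 2L, standing_threshold > 0, standing_threshold < 1,
            establishment_fraction >= 0, prerun >= 0, T_max >= 0, reps >= 1)
  structure(list(N = N, mu = rates[["mu"]], r = rates[["r"]],
                 m = rates[["m"]], s = rates[["s"]],
                 four_Nmu = four_Nmu, four_Nr = four_Nr,
                 four_Nm = four_Nm, four_Ns = four_Ns,
                 init = init, standing_threshold = standing_threshold,
                 establishment_fraction = establishment_fraction,
                 prerun = as.integer(prerun), T_max = as.integer(T_max),
                 reps = as.integer(reps)),
            class = "divsel_params")
}

#' @export
print.divsel_params <- function(x, ...) {
  cat(sprintf(
    "Divergent-selection model: N = %d, 4Nmu = %g, 4Nr = %g, 4Nm = %g, 4Ns = %g\n",
    x$N, x$four_Nmu, x$four_Nr, x$four_Nm, x$four_Ns))
  cat(sprintf("  init = %s, prerun = %d, T_max = %d, reps = %d\n",
              x$init, x$prerun, x$T_max, x$reps))
  invisible(x)
}

#' Migration-selection equilibrium frequency
#'
#' Frequency the favoured allele reaches immediately in an infinite
#' population under divergent selection `s` opposed by symmetric
#' migration `m`:
#' `p_hat = -m/s + 1/2 + sqrt((m/s)^2 + 1/4)`.
#'
#' @param m Migration rate per gamete per generation (>= 0).
#' @param s Selection coefficient (> 0).
#' @return The equilibrium frequency (1 when `m = 0`; -> 0.5 as
#'   `m/s -> Inf`).
#' @export
equilibrium_frequency <- function(m, s) {
  if (any(s <= 0)) stop("s must be > 0")
  stopifnot(all(m >= 0))
  cc <- m / s
  -cc + 0.5 + sqrt(cc^2 + 0.25)
}

#' One deterministic generation of the two-locus recursion
#'
#' Applies the expectation recursion — symmetric mutation at locus II,
#' recombination through the linkage disequilibria
#' `D_x = x1 x4 - x2 x3` (and `D_y`), symmetric migration, and additive
#' divergent selection with opposite sign in the two populations.  The
#' update conserves each population's frequency simplex exactly, and
#' commutes with the joint swap of populations and locus I alleles.
#'
#' @param state A [two_locus_state()].
#' @param params A [divsel_params()] (its per-generation `mu`, `r`, `m`,
#'   `s` are used).
#' @return The next [two_locus_state()].
#' @export
deterministic_step <- function(state, params) {
  stopifnot(inherits(state, "two_locus_state"),
            inherits(params, "divsel_params"))
  x <- state$x; y <- state$y
  mu <- params$mu; r <- params$r; m <- params$m; s <- params$s
  Dx <- x[1] * x[4] - x[2] * x[3]
  Dy <- y[1] * y[4] - y[2] * y[3]
  xA <- x[1] + x[2]; xa <- x[3] + x[4]
  yA <- y[1] + y[2]; ya <- y[3] + y[4]
  xn <- c((1 - mu) * x[1] + mu * x[2] - r * Dx - m * (x[1] - y[1]) + s * x[1] * xa,
          (1 - mu) * x[2] + mu * x[1] + r * Dx - m * (x[2] - y[2]) + s * x[2] * xa,
          (1 - mu) * x[3] + mu * x[4] + r * Dx - m * (x[3] - y[3]) - s * x[3] * xA,
          (1 - mu) * x[4] + mu * x[3] - r * Dx - m * (x[4] - y[4]) - s * x[4] * xA)
  yn <- c((1 - mu) * y[1] + mu * y[2] - r * Dy - m * (y[1] - x[1]) - s * y[1] * ya,
          (1 - mu) * y[2] + mu * y[1] + r * Dy - m * (y[2] - x[2]) - s * y[2] * ya,
          (1 - mu) * y[3] + mu * y[4] + r * Dy - m * (y[3] - x[3]) + s * y[3] * yA,
          (1 - mu) * y[4] + mu * y[3] - r * Dy - m * (y[4] - x[4]) + s * y[4] * yA)
  structure(list(x = xn, y = yn), class = "two_locus_state")
}

#' One stochastic (Wright-Fisher) generation
#'
#' Expected frequencies from [deterministic_step()], then independent
#' multinomial sampling of `2N` gametes in each population (tiny negative
#' expectations from the recursion are clamped to 0 before sampling).
#'
#' @inheritParams deterministic_step
#' @param seed Optional integer seed.
#' @return The next [two_locus_state()].
#' @export
stochastic_generation <- function(state, params, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  det <- deterministic_step(state, params)
  twoN <- 2L * params$N
  samp <- function(p) {
    p <- pmax(p, 0)
    as.numeric(stats::rmultinom(1L, twoN, p)) / twoN
  }
  structure(list(x = samp(det$x), y = samp(det$y)),
            class = "two_locus_state")
}

#' Run the divergent-selection simulator over a recombination grid
#'
#' For each population-scaled recombination distance in `four_Nr_grid`
#' (locus II's distance from the selected locus I), runs `params$reps`
#' replicates of: neutral pre-run of locus II, introduction of the a
#' allele per `params$init`, then `T_max` generations of
#' migration-selection-drift, recording heterozygosity within each
#' population and divergence between them at locus II at the requested
#' time points.
#'
#' @param params A [divsel_params()].
#' @param four_Nr_grid Population-scaled recombination distances.
#' @param time_points Recording times in generations since selection
#'   onset; default `c(0.01, 0.05, 0.1, 0.5, 1, 2, 4, 8) * N`.
#' @param seed Optional integer seed.
#' @return An object of class `divsel_runs` holding per-time sums and
#'   sums of squares for each grid value; summarise with
#'   [summarize_locus_stats()].
#' @export
run_divergent_selection <- function(params, four_Nr_grid = params$four_Nr,
                                    time_points = NULL, seed = NULL) {
  stopifnot(inherits(params, "divsel_params"))
  if (!is.null(seed)) set.seed(seed)
  if (is.null(time_points))
    time_points <- round(c(0.01, 0.05, 0.1, 0.5, 1, 2, 4, 8) * params$N)
  time_points <- sort(unique(as.integer(pmin(time_points, params$T_max))))
  init_code <- match(params$init,
                     c("neutral", "new_mutation", "standing_variation")) - 1L
  res <- vector("list", length(four_Nr_grid))
  for (i in seq_along(four_Nr_grid)) {
    r_gen <- four_Nr_grid[i] / (4 * params$N)
    if (r_gen > 0.5) stop("4Nr too large for per-generation rate <= 0.5")
    out <- cpp_divsel(params$N, params$mu, r_gen, params$m, params$s,
                      params$prerun, time_points, init_code,
                      params$standing_threshold,
                      params$establishment_fraction, params$reps, 100000L)
    res[[i]] <- out
  }
  structure(list(four_Nr = four_Nr_grid, times = time_points,
                 runs = res, params = params),
            class = "divsel_runs")
}

#' Summarise divergent-selection runs into a trajectory grid
#'
#' Means over replicates of pi_W in each population, pi_B, and the allele
#' frequencies at the two loci, for every (4Nr, time) cell, with
#' Monte-Carlo standard errors.  F_ST is computed from the mean pi's
#' (ratio of means), `fst = 1 - mean(pi_W) / mean(pi_B)`, with a
#' delta-method SE using the stored cross-moment.
#'
#' @param runs A `divsel_runs` object from [run_divergent_selection()].
#' @return A data frame of class `trajectory_grid` with columns
#'   `four_Nr`, `time`, `pi_w1`, `pi_w2`, `pi_b`, `fst`, `freq_a2`,
#'   `freq_A1`, `se_pi_w`, `se_pi_b`, `se_fst`, `reps`, `restarts`.
#' @export
summarize_locus_stats <- function(runs) {
  stopifnot(inherits(runs, "divsel_runs"))
  rows <- list()
  for (i in seq_along(runs$four_Nr)) {
    o <- runs$runs[[i]]
    R <- o$reps
    mean_ <- o$sums / R
    var_ <- pmax(o$sumsq / R - mean_^2, 0)     # population variance
    h1 <- mean_[, 1L]; h2 <- mean_[, 2L]; pb <- mean_[, 3L]
    pw <- (h1 + h2) / 2
    ## delta-method SE of the ratio pw/pb from per-rep moments
    ## Var(pw) = (Var h1 + Var h2 + 2 Cov(h1, h2)) / 4
    cov_h1h2 <- o$sums[, 7L] / R - h1 * h2
    var_pw <- pmax((var_[, 1L] + var_[, 2L] + 2 * cov_h1h2) / 4, 0)
    cov_pwpb <- o$sums[, 6L] / R - pw * pb
    ratio <- ifelse(pb > 0, pw / pb, NA_real_)
    var_ratio <- ifelse(pb > 0,
                        (var_pw + ratio^2 * var_[, 3L] -
                           2 * ratio * cov_pwpb) / (R * pb^2),
                        NA_real_)
    rows[[i]] <- data.frame(
      four_Nr = runs$four_Nr[i], time = runs$times,
      pi_w1 = h1, pi_w2 = h2, pi_b = pb,
      fst = 1 - ratio,
      freq_a2 = mean_[, 4L], freq_A1 = mean_[, 5L],
      se_pi_w = sqrt(var_pw / R), se_pi_b = sqrt(var_[, 3L] / R),
      se_fst = sqrt(pmax(var_ratio, 0)),
      reps = R, restarts = o$restarts)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("trajectory_grid", "data.frame")
  attr(out, "params") <- runs$params
  out
}

#' @export
print.trajectory_grid <- function(x, ...) {
  p <- attr(x, "params")
  if (!is.null(p))
    cat(sprintf("Divergent-selection trajectories (init = %s, reps = %d)\n",
                p$init, p$reps))
  print.data.frame(utils::head(as.data.frame(x), 12L), digits = 4)
  if (nrow(x) > 12L) cat(sprintf("  ... %d more rows\n", nrow(x) - 12L))
  invisible(x)
}
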