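test_that("the equilibrium frequency follows its closed form", {
  expect_equal(equilibrium_frequency(0, 0.1), 1)
  expect_equal(equilibrium_frequency(0.0125, 0.1), 0.890388,
               tolerance = 1e-6)
  ## m/s -> Inf approaches the symmetric limit 1/2
  expect_equal(equilibrium_frequency(1000, 0.001), 0.5, tolerance = 1e-3)
  expect_error(equilibrium_frequency(0.01, 0), "> 0")
})

## per-generation rates mu, r, m, s set through the scaled parameters
pars_pg <- function(mu = 0, r = 0, m = 0, s = 0, N = 1000L, ...) {
  divsel_params(N = N, four_Nmu = mu * 4 * N, four_Nr = r * 4 * N,
                four_Nm = m * 4 * N, four_Ns = s * 4 * N, ...)
}

test_that("the deterministic recursion reproduces hand-computed cases", {
  ## all rates zero: identity
  st <- two_locus_state(c(0.3, 0.2, 0.4, 0.1), c(0.25, 0.25, 0.25, 0.25))
  out <- deterministic_step(st, pars_pg())
  expect_equal(out$x, st$x, tolerance = 1e-15)
  expect_equal(out$y, st$y, tolerance = 1e-15)

  ## monomorphic A-B is a fixed point without mutation; with mutation
  ## the A-b class gains mu * x1
  mono <- two_locus_state(c(1, 0, 0, 0), c(1, 0, 0, 0))
  expect_equal(deterministic_step(mono, pars_pg(r = 0.1, m = 0.01,
                                                s = 0.1))$x,
               c(1, 0, 0, 0))
  withmu <- deterministic_step(mono, pars_pg(mu = 1e-3))
  expect_equal(withmu$x, c(1 - 1e-3, 1e-3, 0, 0))

  ## mirrored divergent state, hand evaluation with D = 0
  st2 <- two_locus_state(c(0.5, 0.5, 0, 0), c(0, 0, 0.5, 0.5))
  out2 <- deterministic_step(st2, pars_pg(r = 0.1, m = 0.01, s = 0.1))
  expect_equal(out2$x, c(0.495, 0.495, 0.005, 0.005), tolerance = 1e-12)
  expect_equal(out2$y, c(0.005, 0.005, 0.495, 0.495), tolerance = 1e-12)
})

test_that("the recursion conserves the simplex and commutes with label swapping", {
  set.seed(41)
  swap <- c(3L, 4L, 1L, 2L)  # A <-> a
  for (i in 1:400) {
    x <- as.numeric(rmultinom(1, 1000, runif(4))) / 1000
    y <- as.numeric(rmultinom(1, 1000, runif(4))) / 1000
    st <- two_locus_state(x, y)
    p <- pars_pg(mu = runif(1, 0, 0.5), r = runif(1, 0, 0.5),
                 m = runif(1, 0, 0.5), s = runif(1, 0, 0.5))
    out <- deterministic_step(st, p)
    expect_lt(abs(sum(out$x) - 1), 1e-12)
    expect_lt(abs(sum(out$y) - 1), 1e-12)
    ## swap populations and locus I alleles, step, swap back
    st_sw <- two_locus_state(y[swap], x[swap])
    out_sw <- deterministic_step(st_sw, p)
    expect_equal(out$x, out_sw$y[swap], tolerance = 1e-14)
    expect_equal(out$y, out_sw$x[swap], tolerance = 1e-14)
  }
})

test_that("the deterministic fixed point solves the equilibrium equation", {
  for (case in list(c(m = 0.0125, s = 0.1), c(m = 0.001, s = 0.05),
                    c(m = 0.02, s = 0.3))) {
    p <- pars_pg(m = case[["m"]], s = case[["s"]])
    st <- two_locus_state(c(0.6, 0, 0.4, 0), c(0.4, 0, 0.6, 0))
    for (i in 1:50000) {
      nx <- deterministic_step(st, p)
      if (max(abs(nx$x - st$x)) < 1e-15) break
      st <- nx
    }
    expect_equal(st$x[1] + st$x[2],
                 equilibrium_frequency(case[["m"]], case[["s"]]),
                 tolerance = 1e-8)
  }
})

test_that("drift sampling is multinomial around the deterministic step", {
  st <- two_locus_state(c(0.4, 0.3, 0.2, 0.1), c(0.25, 0.25, 0.25, 0.25))
  p <- pars_pg(mu = 1e-4, r = 0.01, m = 0.005, s = 0.02, N = 1000L)

  ## same seed, same trajectory
  a <- stochastic_generation(st, p, seed = 42)
  b <- stochastic_generation(st, p, seed = 42)
  expect_identical(a, b)
  expect_equal(sum(a$x), 1)
  expect_true(all(a$x * 2000 == round(a$x * 2000)))  # counts of 2N gametes

  ## monomorphic state stays monomorphic without mutation
  mono <- two_locus_state(c(0, 1, 0, 0), c(0, 1, 0, 0))
  expect_equal(stochastic_generation(mono, pars_pg(m = 0.01), seed = 1)$x,
               c(0, 1, 0, 0))

  ## large N: one generation is within O(1/sqrt(N)) of deterministic
  pbig <- pars_pg(mu = 1e-4, r = 0.01, m = 0.005, s = 0.02, N = 1000000L)
  det <- deterministic_step(st, pbig)
  sg <- stochastic_generation(st, pbig, seed = 43)
  expect_lt(max(abs(sg$x - det$x)), 5 / sqrt(1e6))
})

test_that("trajectory summaries are internally consistent", {
  pars <- divsel_params(four_Nm = 50, four_Ns = 400, reps = 40,
                        init = "new_mutation")
  runs <- run_divergent_selection(pars, four_Nr_grid = c(1, 100),
                                  time_points = c(100, 1000), seed = 44)
  tr <- summarize_locus_stats(runs)
  expect_equal(nrow(tr), 4L)
  ## stored F_ST equals 1 - mean(pi_w)/mean(pi_b) recomputed from pi's
  expect_equal(tr$fst, 1 - (tr$pi_w1 + tr$pi_w2) / 2 / tr$pi_b,
               tolerance = 1e-12)
  expect_true(all(tr$pi_b >= 0 & tr$pi_w1 >= 0))

  ## a single replicate is its own summary (no averaging artefacts)
  pars1 <- divsel_params(four_Nm = 50, four_Ns = 400, reps = 1,
                         init = "neutral", prerun = 200L)
  t1 <- summarize_locus_stats(
    run_divergent_selection(pars1, 1, time_points = 50, seed = 45))
  expect_equal(t1$se_pi_b, 0)
  expect_equal(t1$reps, 1)

  ## doubling replicates shrinks the Monte-Carlo SE by about sqrt(2)
  se_for <- function(reps, seed) {
    p <- divsel_params(four_Nm = 50, four_Ns = 0.004, reps = reps,
                       init = "neutral", prerun = 2000L)
    summarize_locus_stats(
      run_divergent_selection(p, 1, time_points = 2000, seed = seed))$se_pi_b
  }
  se1 <- mean(vapply(1:6, function(s) se_for(400, s), 0))
  se2 <- mean(vapply(7:12, function(s) se_for(800, s), 0))
  expect_equal(se1 / se2, sqrt(2), tolerance = 0.25)
})
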