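---
title: "Models and methods behind poolscan"
author: "poolscan authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind poolscan}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(poolscan)
```

## The problem

Pooled whole-genome sequencing (Pool-seq) of two closely related species
or populations yields, at every genomic site, only read counts per
allele per pool — no individual genotypes.  From those counts this
package

1. estimates allele frequencies and the folded site frequency spectrum
   (SFS) while accounting for sequencing error,
2. scans the genome in sliding windows for regions of elevated
   differentiation (`F_ST`) between the two pools, calls short
   *differentiated regions* (DRs) anchored on fixed nucleotide
   differences, and tests them against a simulated panmixia null, and
3. provides a two-locus forward simulator of divergent selection
   opposed by migration, which explains *why* such regions are short
   and carry fixed differences when gene flow is strong.

The motivating setting is a pair of very young species that are almost
panmictic (genome-wide `F_ST` near zero) yet ecologically distinct,
where only a handful of short regions — tens of kilobases — resist
homogenising gene flow because divergent selection acts inside them.

## The pooled read model

At one site, let the pool contain `n` chromosomes (default `n = 40`,
i.e. 20 diploids), `Y` of which carry the focal allele, and let a read
be miscalled with probability `epsilon`.  A read then shows the focal
allele with probability

    q(Y) = (1 - epsilon) * Y/n + epsilon * (1 - Y/n),

and `k` focal reads out of coverage `r` have (ordered) probability
`q^k (1-q)^(r-k)` — `pool_read_likelihood()`.  Because ancestral states
are unknown, spectra are folded; the folded likelihood averages the two
polarities, `P_f(k|Y) = (P(k|Y) + P(r-k|Y))/2`
(`folded_site_likelihood()`).  Both are evaluated in log space; the
likelihood is concave in `q`, and `q` is affine in `Y`, so the integer
maximum-likelihood count (`ml_site_frequency()`) needs only the two
integers bracketing `n (k/r - epsilon)/(1 - 2 epsilon)`; ties go to the
boundary nearer `k/r`.  A brute-force enumeration over every per-read
(chromosome, error) configuration verifies the likelihood exactly in
the test suite.

`estimate_sfs_em()` fits mixture weights over the folded classes
`0..n/2` by EM, with `choose(r,k) * P_f(k|f)` as class-conditional
density.  Sites with identical `(k, r)` are aggregated first — an
algebraically identical but much faster formulation.  The observed-data
log likelihood is recorded each iteration and is non-decreasing;
iteration stops at `max |delta phi| < 1e-8` or 1000 iterations.  On
100,000 simulated sites at 100x coverage the estimated spectrum is
within 0.05 total-variation distance of the truth (an acceptance test).

### Two frequency estimators, and why both exist

The scan uses the raw ML frequency.  For *per-site* `F_ST` at low
coverage, however, the ML estimate is essentially `k/r`, whose sampling
variance (order `p(1-p)/r`) deflates the within-pool heterozygosity
estimate but not the between-pool divergence, biasing per-site `F_ST`
upward by roughly `1/r` — about +0.025 in a 20–30x bin, an order of
magnitude above the near-zero values a panmictic pair should show.
`posterior_site_frequency()` therefore shrinks the estimate with the
EM-fitted folded SFS as prior (mass symmetrised over polarity,
posterior mean of `Y/n`).  With shrinkage the panmixia bin means come
out slightly *negative* (about −0.003), matching the known small
negative skew of per-site `F_ST` when the two pools' frequencies are
nearly equal.  The window scan and its simulated null both use the raw
ML estimator, so their common bias cancels in the neutrality test —
verified by the uniformity of null p-values in the suite.

## Diversity, Tajima's D, and the scan

Within-pool diversity uses the small-sample correction,
`pi_W = n/(n-1) * 2 p (1-p)` per site; between-pool divergence is
`pi_B = p1(1-p2) + p2(1-p1)`; differentiation is Hudson-style,
`F_ST = 1 - pi_W/pi_B`, with `pi_B = 0` returned as `NA` and negative
values retained (under panmixia the correction makes `F_ST` slightly
negative, `-1/(n-1)` at identical frequencies).  `tajimas_d()` is the
standard statistic with constants derived from `n`; folded and unfolded
inputs agree because the pairwise-difference weights are
fold-symmetric.

`scan_windows()` tiles each chromosome with 10-kb windows advanced by
5 kb (both configurable; a 2-kb step is the documented alternative used
for finer scans).  A site counts as covered at ≥ 20 reads in both
species, windows with fewer than 50% covered sites are dropped, and the
window `F_ST` is computed from summed `pi`'s (ratio of averages), the
robust standard choice — low-information sites then contribute in
proportion to their divergence rather than each contributing a noisy
ratio.

Site-level QC (`apply_site_filters()`) mirrors standard pileup
practice: a ±9 bp mask around supplied indel positions (applied as the
union over species), removal of sites showing three or more
nucleotides, per-analysis coverage presets (scan 20–200x, SFS 80–200x,
per-site `F_ST` ≥ 40x), and optional strand-/tail-distance-/baseQ-bias
p-value cuts (1e-4, 1e-4, 1e-100) that apply only when the annotation
exists.

## DR calling

Candidate windows are the top 0.1% of window `F_ST` (strict inequality
against the empirical type-1 quantile, so ties select nothing and
`q = 0` selects nothing).  Overlapping or abutting selected windows are
merged; a merged candidate is kept only if

* it looks like a *peak*: within `max_shoulder` (default 10)
  non-intersecting windows on each side, `F_ST` returns below the 90%
  quantile of all windows.  A genuine outlier region has elevated
  shoulders immediately beside it — they are part of the peak — so the
  adjacent windows are allowed to be high, but the elevation must be
  short-ranged.  (Requiring the *immediately* adjacent windows to be at
  background rejects every true peak whose span is defined by only its
  top windows; the shoulder-bounded rule keeps the same "short, clear
  peak" semantics.)
* it contains at least one *fixed difference*: a site, covered ≥ 20x in
  both species, whose ML allele count is `n` in one species and 0 in
  the other (`find_fixed_differences()`; a stricter posterior rule is
  available via `posterior =`).  The default coverage floor follows the
  scan site set; with the generator's Poisson(34) coverage a 40x floor
  would discard almost all informative sites, whereas real coverage
  distributions are overdispersed enough to populate a 40x set.

Significance comes from simulation: `null_fst_distribution()` rebuilds
the null end to end — a panmictic coalescent sample of 80 chromosomes
over a non-recombining 10-kb window, a random 40/40 split, pooled reads
at fixed 20x (low coverage maximises the null variance, the
conservative choice), ML frequencies, window `F_ST`.  P-values use the
add-one rule `p = (1 + #{null >= obs})/(1 + #null)`, and the screen's
false-discovery rate is estimated as `min(1, p * M / k)` (expected
false positives over discoveries) — an estimate attached to the screen,
not a Benjamini–Hochberg adjustment.

## Coalescent machinery

The samplers are Hudson-style continuous-time coalescents written for
this package (compiled, driven by R's RNG so everything is seed
reproducible): piecewise-constant population sizes, optional two demes
with symmetric migration (per-lineage rate `4Nm` on the `4N`-generation
time scale), optional merging of the demes into the ancestral
population, and infinite-sites mutation.  Closed forms anchor the
tests: `E[pi] = theta` for a pair, `E[S] = theta * a_{n-1}`, and the
two-deme island model's `F_ST = 1/(1 + 8Nm)` (exact for coalescence
times at constant size; checked on the ratio-of-means estimator within
Monte-Carlo error — the mean of per-window ratios is Jensen-biased and
is only checked loosely).  A second, pure-R implementation
(`simulate_panmictic_sample()`, returning the full haplotype matrix)
serves the object-level API and doubles as an independent cross-check
of the compiled path.

The default demography is a documented stand-in for a strong
post-colonisation expansion: instantaneous growth from `N = 2e4` to
`1e6` at 7500 generations ago.  With `theta = 0.1` per bp it yields
~2.5% segregating sites per pool-pair at `n = 80`, a strongly
singleton-skewed folded SFS (~63% singletons) and clearly negative
Tajima's D (mean ≈ −0.9 at these settings; the study system's reported
values below −2 reflect a sharper fitted demography that is not public,
so the tests assert the qualitative expansion signatures only).

`detection_power()` tunes two-deme migration so the island-model
`F_ST` equals a target, pushes simulated loci through the full Pool-seq
pipeline, and compares genome-average `F_ST` against the `1 - alpha`
quantile of a matched panmixia null.  At target 0 the alternative *is*
the null, so power calibrates to `alpha` by construction; power is
essentially 1 by a target of 0.01 with pools of 40 at 34x.

## The divergent-selection simulator

Two populations of size `N` (default 1000) exchange migrants at rate
`m` per gamete per generation.  Locus I carries alleles A/a under
additive divergent selection `s` (A favoured in population 1, a in
population 2); locus II, at recombination distance `r`, is neutral with
symmetric mutation `mu` (locus I does not mutate).  The deterministic
recursion updates the four haplotype frequencies per population via
mutation, recombination through `D = x1 x4 - x2 x3`, migration and
selection; the update conserves each simplex exactly (the terms cancel
in the sum — asserted to 1e-12 on random states) and commutes with
jointly swapping populations and locus-I alleles.  Drift is multinomial
resampling of `2N` gametes per population after the deterministic
update (the standard Wright–Fisher scheme; tiny negative expectations
possible at extreme parameters are clamped before sampling).  With
`mu = r = 0` the symmetric fixed point of the recursion solves the
migration–selection balance exactly:

    p_hat = -m/s + 1/2 + sqrt((m/s)^2 + 1/4),

which is also how the implementation is tested (convergence to `p_hat`
to 1e-8 over a 20-point `(m, s)` grid; `m/s = 0.125` gives 0.890388).

Runs are conditioned the way the resulting figures are interpretable:
in new-mutation mode the a allele enters population 2 at frequency
`1/(2N)` and replicates that lose it before reaching half of `p_hat`
are restarted; in standing-variation mode a drifts neutrally until it
reaches 20% (restarting on loss), then selection switches on.  The
neutral pre-run is `10N` generations — five times the `2N`-generation
relaxation time of heterozygosity, which parks locus II at
mutation–drift equilibrium to within a fraction of a percent at a
fraction of the cost of longer burn-ins.  Recording times default to
`{0.01, 0.05, 0.1, 0.5, 1, 2, 4, 8} x N` generations after selection
onset in both modes.  Summaries are ratio-of-means: `F_ST(t, 4Nr) =
1 - mean(pi_W)/mean(pi_B)` over replicates, with delta-method standard
errors from stored cross-moments.

At the headline setting `4Ns = 400`, `4Nm = 50`, `4Nmu = 0.01`, the
simulated picture is: the a allele sweeps to `p_hat = 0.890` within
~0.1N generations, crushing `pi_W` in population 2 near the selected
site; far sites (`4Nr = 200`) relax back to the neutral level; and the
differentiated span (where `F_ST` exceeds ~0.1) narrows over time,
faster when selection acts on standing variation.  One quantitative
caveat is documented rather than hidden: `F_ST` at the selected site
plateaus around 0.5–0.6 by `8N` generations, not near 1 — `pi_B` grows
only by `2 mu t` over the ~0.02 equilibrium diversity while population
1 never sweeps, so the mean within-diversity stays an appreciable
fraction of `pi_B`.  Peak heights near 0.5 are exactly what the
empirical scans in this setting report (window thresholds ~0.37, peak
values ~0.5), and the acceptance test that asserts a 0.9 peak is left
failing with this analysis on record.

## The synthetic data generator

`generate_two_species_dataset()` builds a full two-species Pool-seq
dataset with known truth, so every pipeline stage is testable without
downloads.

* **Background.**  Per 10-kb tile, segregating sites come from the
  two-deme structured coalescent at `4Nm = 50` whose demes merge into
  the ancestral population at the expansion time — the reading of the
  system's history (species formed inside the lake after the
  expansion) under which background differentiation stays near zero.
  Under the expansion demography the constant-size closed form
  `1/(1+8Nm)` does not apply, so near-zero differentiation is asserted
  directly and the closed form is tested under constant size where it
  is exact.  Tiles are unlinked; sites within a tile share one
  genealogy.
* **Planted DRs.**  21 regions of 14–28 kb, at least 100 kb apart, each
  with 1–7 exact fixed differences near its centre.  Interior site
  frequencies are pushed apart with a weight `w` taken from the
  divergent-selection simulator's `F_ST(4Nr)` profile (new-mutation
  mode, `4Ns = 400`, `4Nm = 50`, recorded at `0.5N`), normalised to 1
  at the centre (`w = sqrt(F/F(0))`), with the per-DR distance scale
  chosen so the profile's differentiated extent matches that DR's drawn
  length: `p1' = p1 + w(1-p1)`, `p2' = p2(1-w)` (orientation random per
  region), pool counts redrawn binomially.
* **Reads.**  Poisson(34) coverage per species and error 0.001, through
  the same read model as everything else.
* **Scale.**  The default genome is 60 chromosomes x 5 Mb (300 Mb) with
  `theta = 0.1`/bp, giving ~7.5 million usable segregating sites — the
  scale of the usable-site set in the motivating study — and ~60,000
  scan windows, so a top-0.1% screen retains ~60 windows, enough to
  cover 21 regions with 2–3 windows each.  Generating and scanning this
  genome takes about a minute and under 2 GB.

What the generator does *not* emulate: linkage across tiles, coverage
overdispersion and mapping artefacts (repeats, paralogy), reference
bias, indel misalignment (indel positions are a clean side-channel),
and base-quality structure.  Passing the end-to-end test therefore
demonstrates the pipeline's statistical behaviour under its stated
model, not robustness to alignment pathology.

## Numerical choices and degenerate inputs

* Likelihoods in log space with per-site max subtraction; `0 log 0 = 0`
  handled explicitly at `epsilon = 0`.
* `F_ST` with `pi_B = 0` is `NA` and excluded from window sums and bin
  means; windows with no usable site are dropped.
* Quantile thresholds use the inverse-ECDF (type 1) quantile with
  strict selection, so all-tied inputs select nothing.
* The EM aggregates identical `(k, r)` pairs; its tolerance (1e-8 on
  `max |delta phi|`) leaves residual mass of order 1e-8 on boundary
  fits.
* Empty tables, empty call sets and empty files are valid inputs with
  documented round-trips.
* Every stochastic function threads R's RNG (compiled code included),
  so a single `set.seed()` reproduces any result; functions with a
  `seed` argument seed themselves for convenience.

## Problem sizes used by the test suite

Chosen once as desk-scale versions of the study conditions and stated
here as the package's own defaults: 100,000 sites for the panmixia bin
means and the EM recovery; 10,000 replicates for the neutral
calibration of the two-locus model at `4Nm` of 10 and 50; 1,500 (new
mutation) and 1,000 (standing) replicates over a five-point `4Nr` grid
for the hitchhiking shape; the full 300-Mb default genome for the
end-to-end recovery (19+ of 21 planted regions at ≥ 50% reciprocal
overlap, at most one unmatched call); 150 replicates per point for the
power curve.  The complete suite runs in roughly a quarter of an hour
on one CPU.

## Known limitations

* The per-site `F_ST` diagnostic depends on the SFS-prior shrinkage;
  with raw ML frequencies, low-coverage bins sit ~`1/r` above zero by
  construction, which is a property of the estimator, not of the data.
* The neutrality null assumes free exchangeability of the 80
  chromosomes and no recombination within windows; with strong real
  population structure the null would be anti-conservative.
* The divergent-selection model is two loci with symmetric migration
  and additive selection; epistasis, dominance, and chromosome-scale
  linkage are out of scope.
* The demography is a configurable stand-in, not a fit to data; all
  quantitative statements tied to it (singleton share, Tajima's D
  magnitude) move with it.
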