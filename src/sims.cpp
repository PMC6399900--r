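#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Coalescent and forward-simulation engines.  All randomness comes from R's
// RNG (via Rcpp's RNGScope), so results are reproducible with set.seed().
//
// Time convention for the coalescent: units of 4*N_current generations.
//  - pair coalescence rate within a deme of relative size sigma: 2/sigma
//  - migration rate per lineage: M = 4*N_current*m
//  - mutation rate per branch per unit length: theta (= 4*N_current*mu per
//    simulated region), so E[S] = theta * a_{n-1} for a constant-size
//    panmictic sample of size n.

namespace {

struct Lineage {
  int deme;
  int cnt1;   // descendant leaves belonging to pool 1
  int cnt;    // total descendant leaves
  double tb;  // birth time of the branch above this node
};

inline double size_at(double t, const std::vector<double>& starts,
                      const std::vector<double>& sizes) {
  // piecewise-constant relative sizes; starts[0] == 0, ascending
  int i = (int)starts.size() - 1;
  while (i > 0 && t < starts[i]) --i;
  return sizes[i];
}

inline double next_boundary(double t, const std::vector<double>& starts,
                            double merge_time, bool merged) {
  double b = R_PosInf;
  for (size_t i = 0; i < starts.size(); ++i)
    if (starts[i] > t && starts[i] < b) b = starts[i];
  if (!merged && merge_time > t && merge_time < b) b = merge_time;
  return b;
}

} // namespace

// Simulate independent non-recombining genealogies ("windows") and drop
// infinite-sites mutations on them.  Returns one row per mutation with the
// derived-allele count in each pool.  For a panmictic model (two_deme =
// FALSE) the two "pools" are the first n1 and remaining n2 leaves, which by
// leaf exchangeability is a uniform random 40/40-style split.
// [[Rcpp::export]]
List cpp_coal_counts(int n1, int n2, int n_windows, double theta, double L,
                     bool two_deme, double mig,
                     NumericVector epoch_starts, NumericVector epoch_sizes,
                     double merge_time) {
  std::vector<double> starts(epoch_starts.begin(), epoch_starts.end());
  std::vector<double> sizes(epoch_sizes.begin(), epoch_sizes.end());
  if (starts.empty() || starts[0] != 0.0)
    stop("epoch_starts must begin at 0");
  if (starts.size() != sizes.size())
    stop("epoch_starts and epoch_sizes must have equal length");

  std::vector<int> out_win;
  std::vector<double> out_pos;
  std::vector<int> out_c1, out_c2;
  size_t guess = (size_t)std::max(16.0, theta * 6.0 * n_windows);
  out_win.reserve(guess); out_pos.reserve(guess);
  out_c1.reserve(guess); out_c2.reserve(guess);

  const int n = n1 + n2;
  std::vector<Lineage> lin;
  std::vector<double> blen; std::vector<int> bc1, bcn;

  for (int w = 0; w < n_windows; ++w) {
    lin.clear(); blen.clear(); bc1.clear(); bcn.clear();
    lin.reserve(n);
    for (int i = 0; i < n; ++i) {
      Lineage li;
      li.deme = (two_deme && i >= n1) ? 1 : 0;
      li.cnt1 = (i < n1) ? 1 : 0;
      li.cnt = 1;
      li.tb = 0.0;
      lin.push_back(li);
    }
    double t = 0.0;
    bool merged = !two_deme;

    while ((int)lin.size() > 1) {
      int k0 = 0, k1 = 0;
      for (size_t i = 0; i < lin.size(); ++i) (lin[i].deme == 0 ? k0 : k1)++;
      double sigma = size_at(t, starts, sizes);
      double crate = ((double)k0 * (k0 - 1) + (double)k1 * (k1 - 1)) / sigma;
      double mrate = merged ? 0.0 : mig * (k0 + k1);
      double total = crate + mrate;

      double bnd = next_boundary(t, starts, merge_time, merged);
      double dt = (total > 0) ? R::exp_rand() / total : R_PosInf;

      if (t + dt >= bnd) {
        t = bnd;
        if (!merged && bnd == merge_time) {
          for (size_t i = 0; i < lin.size(); ++i) lin[i].deme = 0;
          merged = true;
        }
        continue;
      }
      t += dt;

      if (unif_rand() * total < crate) {
        // coalescence: choose deme proportional to k_d*(k_d-1)
        double w0 = (double)k0 * (k0 - 1) / sigma;
        int deme = (unif_rand() * crate < w0) ? 0 : 1;
        // pick two distinct lineages in that deme
        int kd = (deme == 0) ? k0 : k1;
        int a = (int)std::floor(unif_rand() * kd);
        int b = (int)std::floor(unif_rand() * (kd - 1));
        if (b >= a) b += 1;
        // map within-deme indices to positions in lin
        int ia = -1, ib = -1, seen = 0;
        for (size_t i = 0; i < lin.size(); ++i) {
          if (lin[i].deme == deme) {
            if (seen == a) ia = (int)i;
            if (seen == b) ib = (int)i;
            ++seen;
          }
        }
        // record the two child branches
        blen.push_back(t - lin[ia].tb); bc1.push_back(lin[ia].cnt1); bcn.push_back(lin[ia].cnt);
        blen.push_back(t - lin[ib].tb); bc1.push_back(lin[ib].cnt1); bcn.push_back(lin[ib].cnt);
        Lineage par;
        par.deme = deme;
        par.cnt1 = lin[ia].cnt1 + lin[ib].cnt1;
        par.cnt = lin[ia].cnt + lin[ib].cnt;
        par.tb = t;
        if (ia < ib) std::swap(ia, ib); // erase larger index first
        lin.erase(lin.begin() + ia);
        lin.erase(lin.begin() + ib);
        lin.push_back(par);
      } else {
        int j = (int)std::floor(unif_rand() * lin.size());
        lin[j].deme = 1 - lin[j].deme;
      }
    }

    // mutations
    double Ltot = 0.0;
    for (size_t i = 0; i < blen.size(); ++i) Ltot += blen[i];
    int nm = (int)R::rpois(theta * Ltot);
    if (nm > 0) {
      std::vector<double> cum(blen.size());
      double acc = 0.0;
      for (size_t i = 0; i < blen.size(); ++i) { acc += blen[i]; cum[i] = acc; }
      for (int mft = 0; mft < nm; ++mft) {
        double u = unif_rand() * Ltot;
        size_t lo = 0, hi = cum.size() - 1;
        while (lo < hi) {
          size_t mid = (lo + hi) / 2;
          if (cum[mid] < u) lo = mid + 1; else hi = mid;
        }
        out_win.push_back(w + 1);
        out_pos.push_back(unif_rand() * L);
        out_c1.push_back(bc1[lo]);
        out_c2.push_back(bcn[lo] - bc1[lo]);
      }
    }
  }

  return List::create(_["window"] = wrap(out_win), _["pos"] = wrap(out_pos),
                      _["c1"] = wrap(out_c1), _["c2"] = wrap(out_c2));
}

namespace {

// one deterministic generation of the two-locus recursion; preserves the
// simplex sum exactly (the mutation/recombination/migration/selection terms
// cancel in the sum); sgn is +1 for the population where A is favoured.
inline void det_step(const double* x, const double* y, double mu, double r,
                     double m, double s, double* xo, double* yo) {
  double Dx = x[0] * x[3] - x[1] * x[2];
  double Dy = y[0] * y[3] - y[1] * y[2];
  double xA = x[0] + x[1], xa = x[2] + x[3];
  double yA = y[0] + y[1], ya = y[2] + y[3];
  xo[0] = (1 - mu) * x[0] + mu * x[1] - r * Dx - m * (x[0] - y[0]) + s * x[0] * xa;
  xo[1] = (1 - mu) * x[1] + mu * x[0] + r * Dx - m * (x[1] - y[1]) + s * x[1] * xa;
  xo[2] = (1 - mu) * x[2] + mu * x[3] + r * Dx - m * (x[2] - y[2]) - s * x[2] * xA;
  xo[3] = (1 - mu) * x[3] + mu * x[2] - r * Dx - m * (x[3] - y[3]) - s * x[3] * xA;
  yo[0] = (1 - mu) * y[0] + mu * y[1] - r * Dy - m * (y[0] - x[0]) - s * y[0] * ya;
  yo[1] = (1 - mu) * y[1] + mu * y[0] + r * Dy - m * (y[1] - x[1]) - s * y[1] * ya;
  yo[2] = (1 - mu) * y[2] + mu * y[3] + r * Dy - m * (y[2] - x[2]) + s * y[2] * yA;
  yo[3] = (1 - mu) * y[3] + mu * y[2] - r * Dy - m * (y[3] - x[3]) + s * y[3] * yA;
}

// multinomial sampling of 2N gametes by conditional binomials
inline void drift(double* p, int twoN) {
  double psum = 0.0;
  for (int i = 0; i < 4; ++i) { if (p[i] < 0) p[i] = 0; psum += p[i]; }
  int rem = twoN;
  double prem = psum;
  int cnt[4];
  for (int i = 0; i < 3; ++i) {
    double pr = (prem > 0) ? p[i] / prem : 0.0;
    if (pr > 1) pr = 1;
    cnt[i] = (rem > 0) ? (int)R::rbinom(rem, pr) : 0;
    rem -= cnt[i];
    prem -= p[i];
  }
  cnt[3] = rem;
  for (int i = 0; i < 4; ++i) p[i] = (double)cnt[i] / twoN;
}

} // namespace

// Two-locus two-population migration-selection-drift simulator.
// Haplotype order: A-B, A-b, a-B, a-b (x = population 1, y = population 2).
// init_mode: 0 = none (neutral; the a allele is never introduced),
//            1 = new mutation (frequency 1/2N in population 2 at T = 0),
//            2 = standing variation (neutral drift of a until it reaches
//                standing_threshold, then selection switches on; reps where
//                a is lost first are restarted).
// est_frac: in mode 1, restart attempts where a is lost before reaching
//           est_frac * p_hat (conditioning on establishment); 0 disables.
// record: generations since selection onset at which to record, ascending.
// Records sums and sums of squares (over reps) of: het(B) in pop1, het(B)
// in pop2, pi_B at locus II, freq(a) in pop2, freq(A) in pop1, plus the
// cross-products mean(het)*pi_B and het1*het2 needed for delta-method SEs.
// [[Rcpp::export]]
List cpp_divsel(int N, double mu, double r, double m, double s,
                int prerun, IntegerVector record, int init_mode,
                double standing_threshold, double est_frac, int reps,
                int max_restarts) {
  const int twoN = 2 * N;
  const int T = record.size();
  const int tmax = (T > 0) ? record[T - 1] : 0;
  NumericMatrix sums(T, 7), sumsq(T, 7);
  long long restarts = 0;

  double phat = 1.0;
  if (s > 0) {
    double c = m / s;
    phat = -c + 0.5 + std::sqrt(c * c + 0.25);
  }
  const double est_thr = est_frac * phat;

  double x[4], y[4], xn[4], yn[4];
  double sx[4], sy[4];
  std::vector<double> recbuf(7 * (size_t)std::max(T, 1));

  for (int rep = 0; rep < reps; ++rep) {
    // locus II starts fixed for B on the A background; neutral pre-run
    x[0] = 1; x[1] = 0; x[2] = 0; x[3] = 0;
    y[0] = 1; y[1] = 0; y[2] = 0; y[3] = 0;
    for (int g = 0; g < prerun; ++g) {
      det_step(x, y, mu, r, m, 0.0, xn, yn);
      for (int i = 0; i < 4; ++i) { x[i] = xn[i]; y[i] = yn[i]; }
      drift(x, twoN); drift(y, twoN);
    }
    for (int i = 0; i < 4; ++i) { sx[i] = x[i]; sy[i] = y[i]; }

    bool done = false;
    int tries = 0;
    while (!done) {
      if (++tries > max_restarts)
        stop("too many restarts while conditioning on establishment");
      for (int i = 0; i < 4; ++i) { x[i] = sx[i]; y[i] = sy[i]; }

      if (init_mode != 0) {
        // introduce one copy of a in population 2, keeping its locus II allele
        double yA = y[0] + y[1];
        int j = (yA <= 0 || unif_rand() < y[0] / yA) ? 0 : 1;
        double q = 1.0 / twoN;
        if (y[j] < q) j = 1 - j;
        y[j] -= q; y[j + 2] += q;
      }

      bool lost = false, established = (init_mode == 0);
      if (init_mode == 2) {
        // neutral phase until a reaches the standing threshold
        long long g = 0;
        while (true) {
          double fa = y[2] + y[3];
          if (fa + x[2] + x[3] <= 0) { lost = true; break; }
          if (fa >= standing_threshold) break;
          det_step(x, y, mu, r, m, 0.0, xn, yn);
          for (int i = 0; i < 4; ++i) { x[i] = xn[i]; y[i] = yn[i]; }
          drift(x, twoN); drift(y, twoN);
          if (++g > 4000LL * N) { lost = true; break; } // stuck; restart
        }
        if (lost) { ++restarts; continue; }
        established = true; // conditioning done at threshold crossing
      }

      // selection phase, recording at the requested generations
      int ri = 0;
      std::fill(recbuf.begin(), recbuf.end(), 0.0);
      for (int g = 0; g <= tmax && ri < T; ++g) {
        while (ri < T && record[ri] == g) {
          double fB1 = x[0] + x[2], fB2 = y[0] + y[2];
          double h1 = 2.0 * fB1 * (1.0 - fB1);
          double h2 = 2.0 * fB2 * (1.0 - fB2);
          double pb = fB1 * (1.0 - fB2) + fB2 * (1.0 - fB1);
          recbuf[ri * 7 + 0] = h1;
          recbuf[ri * 7 + 1] = h2;
          recbuf[ri * 7 + 2] = pb;
          recbuf[ri * 7 + 3] = y[2] + y[3];
          recbuf[ri * 7 + 4] = x[0] + x[1];
          recbuf[ri * 7 + 5] = 0.5 * (h1 + h2) * pb;
          recbuf[ri * 7 + 6] = h1 * h2;
          ++ri;
        }
        if (g == tmax) break;
        det_step(x, y, mu, r, m, (init_mode == 0) ? 0.0 : s, xn, yn);
        for (int i = 0; i < 4; ++i) { x[i] = xn[i]; y[i] = yn[i]; }
        drift(x, twoN); drift(y, twoN);
        if (init_mode == 1 && !established && est_frac > 0) {
          double fa = y[2] + y[3];
          if (fa >= est_thr) established = true;
          else if (fa + x[2] + x[3] <= 0) { lost = true; break; }
        }
      }
      if (lost && !established && est_frac > 0) { ++restarts; continue; }
      for (int ti = 0; ti < T; ++ti)
        for (int j = 0; j < 7; ++j) {
          double v = recbuf[ti * 7 + j];
          sums(ti, j) += v;
          sumsq(ti, j) += v * v;
        }
      done = true;
    }
    if (rep % 256 == 0) Rcpp::checkUserInterrupt();
  }

  return List::create(_["sums"] = sums, _["sumsq"] = sumsq,
                      _["reps"] = reps, _["restarts"] = (double)restarts);
}
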