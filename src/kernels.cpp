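#include <Rcpp.h>
#include <random>
#include <cmath>
#include <limits>
using namespace Rcpp;

// Sum of (rho^2 + delta^2)^-3 over a square lattice of spacing `spacing`
// restricted to rho <= cutoff.  The lattice is centred on the reporter's
// lateral position (a node at rho = 0); by lateral averaging of the mobile
// labels the choice of origin is immaterial at the spacings used.
// [[Rcpp::export]]
double lattice_sum_cpp(double delta, double spacing, double cutoff) {
  if (spacing <= 0.0) stop("lattice spacing must be positive");
  if (cutoff <= 0.0) stop("cutoff radius must be positive");
  const double d2 = delta * delta;
  const double c2 = cutoff * cutoff;
  const long nmax = (long)std::floor(cutoff / spacing);
  double total = 0.0;
  for (long i = -nmax; i <= nmax; ++i) {
    const double x = i * spacing;
    const double x2 = x * x;
    if (x2 > c2) continue;
    const long mmax = (long)std::floor(std::sqrt(c2 - x2) / spacing);
    double row = 0.0;
    for (long j = -mmax; j <= mmax; ++j) {
      const double y = j * spacing;
      const double r2 = x2 + y * y + d2;
      row += 1.0 / (r2 * r2 * r2);
    }
    total += row;
  }
  return total;
}

static inline double chi2_from_sum(const std::vector<double>& gsum, int N,
                                   const double* meas, const double* sig,
                                   double r2dia, double tdelay, int m) {
  double chi2 = 0.0;
  for (int j = 0; j < m; ++j) {
    const double g = gsum[j] / N;
    double ratio;
    if (std::isinf(g)) ratio = 0.0;
    else ratio = r2dia * std::exp(-g * tdelay) / (r2dia + g);
    const double resid = (ratio - meas[j]) / sig[j];
    chi2 += resid * resid;
  }
  return chi2;
}

// invert ratio = r2 exp(-g t) / (r2 + g) for g >= 0 (strictly decreasing)
static double invert_ratio(double r, double r2dia, double tdelay) {
  if (r >= 1.0) return 0.0;
  double lo = 0.0, hi = 1.0;
  auto f = [&](double g) { return r2dia * std::exp(-g * tdelay) / (r2dia + g); };
  int guard = 0;
  while (f(hi) > r && guard++ < 60) hi *= 2.0;
  for (int it = 0; it < 200; ++it) {
    const double mid = 0.5 * (lo + hi);
    if (f(mid) > r) lo = mid; else hi = mid;
  }
  return 0.5 * (lo + hi);
}

// Fixed-size multiset search minimising the weighted chi^2 between the
// fast-exchange ensemble ratio and the measured ratio profile.
//
// gamma2: n x m matrix (conformers x reporters) of back-calculated rates.
// method "sweep": exhaustive best-single-swap coordinate descent to a local
// minimum, restarted from random multisets (restart 0 uses a greedy forward
// construction).  method "proposals": random single-member replacement
// proposals accepted on strict decrease.
// Deterministic given `seed` (std::mt19937, raw draws only).
// [[Rcpp::export]]
List ensemble_search_cpp(NumericMatrix gamma2, NumericVector measured,
                         NumericVector sigma, int ensemble_size,
                         double r2dia, double tdelay,
                         int restarts, int iterations, int seed,
                         std::string method, double polish_threshold) {
  const int n = gamma2.nrow(), m = gamma2.ncol();
  if (n < 1) stop("empty conformer library");
  if (measured.size() != m || sigma.size() != m)
    stop("measured/sigma length must match response-matrix columns");
  if (ensemble_size < 1 || ensemble_size > n * 1000)
    stop("invalid ensemble size");
  const int N = ensemble_size;
  const double* meas = REAL(measured);
  const double* sig = REAL(sigma);
  // row-major copy for cache-friendly access
  std::vector<double> G((size_t)n * m);
  for (int i = 0; i < n; ++i)
    for (int j = 0; j < m; ++j) G[(size_t)i * m + j] = gamma2(i, j);

  std::mt19937 rng((unsigned)seed);
  auto rand_idx = [&](int k) { return (int)(rng() % (unsigned)k); };

  std::vector<int> best_members;
  double best_chi2 = std::numeric_limits<double>::infinity();

  std::vector<int> members(N);
  std::vector<double> gsum(m), gtry(m);

  // Pair-repair machinery (sweep method): target summed rates from the
  // measured ratios, deterministic scalar projection of every row, and the
  // projection order, so candidate replacement pairs whose summed rates
  // match a required vector can be short-listed by binary search (an exact
  // pair sum has an exactly matching projection).
  std::vector<double> target(m, 0.0), proj_w(m, 0.0);
  std::vector<char> has_target(m, 0);
  std::vector<double> s_proj(n);
  std::vector<int> s_order;
  if (method == "sweep") {
    unsigned w = 2463534242u;  // fixed xorshift stream: weights independent of seed
    for (int j = 0; j < m; ++j) {
      w ^= w << 13; w ^= w >> 17; w ^= w << 5;
      proj_w[j] = 0.5 + (double)(w % 1000003u) / 1000003.0;
      if (meas[j] > 0.0 && std::isfinite(meas[j])) {
        has_target[j] = 1;
        target[j] = N * invert_ratio(meas[j], r2dia, tdelay);
      }
    }
    for (int c = 0; c < n; ++c) {
      double s = 0.0;
      for (int j = 0; j < m; ++j)
        if (has_target[j]) s += proj_w[j] * G[(size_t)c * m + j];
      s_proj[c] = s;
    }
    s_order.resize(n);
    for (int c = 0; c < n; ++c) s_order[c] = c;
    std::sort(s_order.begin(), s_order.end(),
              [&](int a, int b) { return s_proj[a] < s_proj[b]; });
  }

  // one pass of pair repairs; returns true if chi2 improved
  auto pair_repair = [&](std::vector<int>& mem, std::vector<double>& gs,
                         double& chi2) {
    bool improved = false;
    std::vector<double> base(m);
    for (int p1 = 0; p1 < N - 1; ++p1) {
      for (int p2 = p1 + 1; p2 < N; ++p2) {
        const double* r1 = &G[(size_t)mem[p1] * m];
        const double* r2 = &G[(size_t)mem[p2] * m];
        double need_s = 0.0;
        for (int j = 0; j < m; ++j) {
          base[j] = gs[j] - r1[j] - r2[j];
          if (has_target[j]) need_s += proj_w[j] * (target[j] - base[j]);
        }
        int bc1 = -1, bc2 = -1;
        double bchi = chi2;
        for (int c1 = 0; c1 < n; ++c1) {
          if (!std::isfinite(s_proj[c1])) continue;
          const double want = need_s - s_proj[c1];
          // binary search the sorted projections for `want`
          int lo = 0, hi = n;
          while (lo < hi) {
            const int mid = (lo + hi) / 2;
            if (s_proj[s_order[mid]] < want) lo = mid + 1; else hi = mid;
          }
          const double* rowc1 = &G[(size_t)c1 * m];
          for (int k = lo - 8; k <= lo + 8; ++k) {
            if (k < 0 || k >= n) continue;
            const int c2 = s_order[k];
            const double* rowc2 = &G[(size_t)c2 * m];
            double c2v = 0.0;
            for (int j = 0; j < m; ++j) {
              const double g = (base[j] + rowc1[j] + rowc2[j]) / N;
              double ratio;
              if (std::isinf(g)) ratio = 0.0;
              else ratio = r2dia * std::exp(-g * tdelay) / (r2dia + g);
              const double resid = (ratio - meas[j]) / sig[j];
              c2v += resid * resid;
            }
            if (c2v < bchi - 1e-15) { bchi = c2v; bc1 = c1; bc2 = c2; }
          }
        }
        if (bc1 >= 0) {
          for (int j = 0; j < m; ++j)
            gs[j] = base[j] + G[(size_t)bc1 * m + j] + G[(size_t)bc2 * m + j];
          mem[p1] = bc1;
          mem[p2] = bc2;
          chi2 = bchi;
          improved = true;
        }
      }
    }
    return improved;
  };

  double chi2 = 0.0;
  const int max_sweeps = std::max(1, iterations);
  auto sweep_descent = [&]() {
    for (int sweep = 0; sweep < max_sweeps; ++sweep) {
      bool improved = false;
      for (int p = 0; p < N; ++p) {
        const double* cur = &G[(size_t)members[p] * m];
        for (int j = 0; j < m; ++j) gtry[j] = gsum[j] - cur[j];
        int arg = members[p]; double bestc = chi2;
        for (int c = 0; c < n; ++c) {
          const double* row = &G[(size_t)c * m];
          double c2 = 0.0;
          for (int j = 0; j < m; ++j) {
            const double g = (gtry[j] + row[j]) / N;
            double ratio;
            if (std::isinf(g)) ratio = 0.0;
            else ratio = r2dia * std::exp(-g * tdelay) / (r2dia + g);
            const double resid = (ratio - meas[j]) / sig[j];
            c2 += resid * resid;
          }
          if (c2 < bestc - 1e-15) { bestc = c2; arg = c; }
        }
        if (arg != members[p]) {
          const double* row = &G[(size_t)arg * m];
          for (int j = 0; j < m; ++j) gsum[j] = gtry[j] + row[j];
          members[p] = arg;
          chi2 = bestc;
          improved = true;
        }
      }
      if (!improved) break;
    }
  };

  for (int r = 0; r < restarts; ++r) {
    std::fill(gsum.begin(), gsum.end(), 0.0);
    if (r == 0 && method == "sweep") {
      // greedy forward construction: add the member minimising the chi^2 of
      // the mean over the members chosen so far
      for (int p = 0; p < N; ++p) {
        int arg = 0; double bestc = std::numeric_limits<double>::infinity();
        for (int c = 0; c < n; ++c) {
          const double* row = &G[(size_t)c * m];
          for (int j = 0; j < m; ++j) gtry[j] = gsum[j] + row[j];
          const double c2 = chi2_from_sum(gtry, p + 1, meas, sig, r2dia, tdelay, m);
          if (c2 < bestc) { bestc = c2; arg = c; }
        }
        members[p] = arg;
        const double* row = &G[(size_t)arg * m];
        for (int j = 0; j < m; ++j) gsum[j] += row[j];
      }
    } else {
      for (int p = 0; p < N; ++p) {
        members[p] = rand_idx(n);
        const double* row = &G[(size_t)members[p] * m];
        for (int j = 0; j < m; ++j) gsum[j] += row[j];
      }
    }
    chi2 = chi2_from_sum(gsum, N, meas, sig, r2dia, tdelay, m);

    if (method == "sweep") {
      sweep_descent();
    } else {  // proposals
      for (int it = 0; it < iterations; ++it) {
        const int p = rand_idx(N);
        const int c = rand_idx(n);
        if (c == members[p]) continue;
        const double* cur = &G[(size_t)members[p] * m];
        const double* row = &G[(size_t)c * m];
        for (int j = 0; j < m; ++j) gtry[j] = gsum[j] - cur[j] + row[j];
        const double c2 = chi2_from_sum(gtry, N, meas, sig, r2dia, tdelay, m);
        if (c2 < chi2 - 1e-15) {
          gsum = gtry;
          members[p] = c;
          chi2 = c2;
        }
      }
    }

    if (chi2 < best_chi2) {
      best_chi2 = chi2;
      best_members = members;
    }
  }

  // Polish phase, entered only when the restart search already sits near an
  // exact representation (chi^2 per datum below `polish_threshold`, the
  // noise-free regime; under measurement noise the optimum is far from zero
  // and polishing cannot change it materially).  Ensembles of this kind
  // concentrate on few distinct conformations, so candidate solutions
  // supported on 1-3 distinct members are enumerated exactly (support 3 via
  // the projection shortlist), then pair repairs alternate with single-swap
  // descent until neither improves.
  if (method == "sweep" && std::isfinite(best_chi2) &&
      best_chi2 < polish_threshold * m) {
    std::vector<double> T16(m, 0.0);
    double projT = 0.0;
    for (int j = 0; j < m; ++j) {
      if (has_target[j]) { T16[j] = target[j]; projT += proj_w[j] * target[j]; }
    }
    std::vector<double> gs_buf(m);
    auto try_weighted = [&](int c1, int k1, int c2k, int k2, int c3, int k3) {
      const double* r1 = &G[(size_t)c1 * m];
      const double* r2 = &G[(size_t)c2k * m];
      const double* r3 = (k3 > 0) ? &G[(size_t)c3 * m] : r1;
      double c2v = 0.0;
      for (int j = 0; j < m; ++j) {
        double g = k1 * r1[j] + k2 * r2[j];
        if (k3 > 0) g += k3 * r3[j];
        g /= N;
        double ratio;
        if (std::isinf(g)) ratio = 0.0;
        else ratio = r2dia * std::exp(-g * tdelay) / (r2dia + g);
        const double resid = (ratio - meas[j]) / sig[j];
        c2v += resid * resid;
        if (c2v >= best_chi2) return;
      }
      if (c2v < best_chi2 - 1e-18) {
        best_chi2 = c2v;
        best_members.clear();
        best_members.insert(best_members.end(), k1, c1);
        best_members.insert(best_members.end(), k2, c2k);
        if (k3 > 0) best_members.insert(best_members.end(), k3, c3);
      }
    };
    // support 1
    for (int c = 0; c < n; ++c) try_weighted(c, N, c, 0, c, 0);
    // support 2, exhaustive over pairs and multiplicity splits
    if (N >= 2) {
      for (int c1 = 0; c1 < n; ++c1)
        for (int c2 = c1 + 1; c2 < n; ++c2)
          for (int k1 = 1; k1 < N; ++k1)
            try_weighted(c1, k1, c2, N - k1, c1, 0);
    }
    // support 3: third member located by exact projection matching; for
    // fixed (c1, k1, k2) the required third projection is monotone in the
    // second member's projection, so a two-pointer merge over the sorted
    // projections finds all near-exact triples in linear time
    if (N >= 3) {
      std::vector<double> s_sorted(n);
      for (int i = 0; i < n; ++i) s_sorted[i] = s_proj[s_order[i]];
      const int n_fin = [&]{
        int k = 0;
        while (k < n && std::isfinite(s_sorted[k])) ++k;
        return k;
      }();
      for (int c1 = 0; c1 < n; ++c1) {
        if (!std::isfinite(s_proj[c1])) continue;
        for (int k1 = 1; k1 <= N - 2; ++k1) {
          const double rem1 = projT - k1 * s_proj[c1];
          for (int k2 = 1; k2 <= N - k1 - 1; ++k2) {
            const int k3 = N - k1 - k2;
            int ptr = n_fin - 1;
            for (int i2 = 0; i2 < n_fin; ++i2) {
              const int c2 = s_order[i2];
              const double t2 = k2 * s_sorted[i2];
              const double want = (rem1 - t2) / k3;
              while (ptr > 0 && s_sorted[ptr] > want) --ptr;
              // tolerance at the floating cancellation scale of the sum
              const double tol =
                1e-9 * (std::fabs(rem1) + std::fabs(t2) + std::fabs(projT)) / k3;
              for (int k = ptr; k <= ptr + 1 && k < n_fin; ++k) {
                if (std::fabs(s_sorted[k] - want) > tol) continue;
                try_weighted(c1, k1, c2, k2, s_order[k], k3);
              }
            }
          }
        }
      }
    }
    // pair repairs alternating with sweeps from the overall best
    members = best_members;
    std::fill(gsum.begin(), gsum.end(), 0.0);
    for (int p = 0; p < N; ++p) {
      const double* row = &G[(size_t)members[p] * m];
      for (int j = 0; j < m; ++j) gsum[j] += row[j];
    }
    chi2 = best_chi2;
    for (int round = 0; round < 10 && chi2 > 1e-20; ++round) {
      if (!pair_repair(members, gsum, chi2)) break;
      sweep_descent();
    }
    if (chi2 < best_chi2) {
      best_chi2 = chi2;
      best_members = members;
    }
  }

  IntegerVector out(best_members.size());
  for (size_t i = 0; i < best_members.size(); ++i) out[i] = best_members[i] + 1;
  return List::create(_["members"] = out, _["chi2"] = best_chi2);
}
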