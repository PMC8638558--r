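// Partition-function folding over a simplified pair-wise energy model.
//
// Structures are nested sets of pairs drawn from {GC, AU, GU}; the energy of
// a structure is the sum of its pair energies plus, for every paired
// nucleotide, a SHAPE pseudo-energy term.  Boltzmann weights exp(-E/kT).
// Inside-outside dynamic programming gives exact pair probabilities in
// O(n^3); the minimum-energy structure is recovered by a deterministic
// traceback.  Per-position rescaling keeps the partition function in double
// range for window-sized inputs.

#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// base codes: A=0 C=1 G=2 U=3 N=4
static inline double pair_energy(int a, int b, double eGC, double eAU,
                                 double eGU) {
  if ((a == 2 && b == 1) || (a == 1 && b == 2)) return eGC;
  if ((a == 0 && b == 3) || (a == 3 && b == 0)) return eAU;
  if ((a == 2 && b == 3) || (a == 3 && b == 2)) return eGU;
  return NA_REAL;
}

// [[Rcpp::export(name = ".fold_engine_cpp")]]
List fold_engine_cpp(IntegerVector seq, NumericVector pseudo, double eGC,
                     double eAU, double eGU, int min_hairpin, double kT,
                     bool want_bpp, bool want_pmat) {
  const int n = seq.size();
  // ---- MFE pass (also used to pick the partition-function scale) ----
  // E[i][j]: minimum energy on [i, j], 1-based, E = 0 on empty segments.
  std::vector<std::vector<double>> E(n + 2, std::vector<double>(n + 2, 0.0));
  std::vector<std::vector<int>> choice(n + 2, std::vector<int>(n + 2, 0));
  const double INF = std::numeric_limits<double>::infinity();

  for (int len = 2; len <= n; ++len) {
    for (int i = 1; i + len - 1 <= n; ++i) {
      int j = i + len - 1;
      double best = E[i + 1][j];  // i unpaired (preferred on ties)
      int bestk = 0;
      for (int k = i + min_hairpin + 1; k <= j; ++k) {
        double ep = pair_energy(seq[i - 1], seq[k - 1], eGC, eAU, eGU);
        if (ISNA(ep)) continue;
        double cand = ep + pseudo[i - 1] + pseudo[k - 1] + E[i + 1][k - 1] +
                      E[k + 1][j];
        if (cand < best - 1e-12) {  // strict improvement; ties keep earlier
          best = cand;
          bestk = k;
        }
      }
      E[i][j] = best;
      choice[i][j] = bestk;
    }
  }
  double mfe = (n >= 2) ? E[1][n] : 0.0;

  // deterministic traceback
  IntegerVector partner(n, 0);  // 1-based partner, 0 = unpaired
  std::vector<std::pair<int, int>> stack;
  if (n >= 2) stack.push_back({1, n});
  while (!stack.empty()) {
    auto seg = stack.back();
    stack.pop_back();
    int i = seg.first, j = seg.second;
    if (i >= j) continue;
    int k = choice[i][j];
    if (k == 0) {
      stack.push_back({i + 1, j});
    } else {
      partner[i - 1] = k;
      partner[k - 1] = i;
      stack.push_back({i + 1, k - 1});
      stack.push_back({k + 1, j});
    }
  }

  NumericVector bpp(n, 0.0);
  double logZ = 0.0;
  NumericMatrix pmat(want_pmat ? n : 1, want_pmat ? n : 1);

  if (want_bpp && n >= 2) {
    // scale chosen from the MFE energy density, with head-room for entropy
    double safety = 1.5;
    bool ok = false;
    for (int attempt = 0; attempt < 4 && !ok; ++attempt) {
      double s = std::exp(-mfe / (kT * n)) * safety;
      std::vector<std::vector<double>> Z(n + 2,
                                         std::vector<double>(n + 2, 1.0));
      // Z[i][j] scaled by s^(j-i+1); empty segments (j < i) = 1
      for (int i = 1; i <= n; ++i) Z[i][i] = 1.0 / s;
      ok = true;
      for (int len = 2; len <= n && ok; ++len) {
        for (int i = 1; i + len - 1 <= n; ++i) {
          int j = i + len - 1;
          double z = Z[i + 1][j] / s;
          for (int k = i + min_hairpin + 1; k <= j; ++k) {
            double ep = pair_energy(seq[i - 1], seq[k - 1], eGC, eAU, eGU);
            if (ISNA(ep)) continue;
            double w = std::exp(-(ep + pseudo[i - 1] + pseudo[k - 1]) / kT) /
                       (s * s);
            z += w * Z[i + 1][k - 1] * Z[k + 1][j];
          }
          if (!std::isfinite(z) || z <= 0.0) {
            ok = false;
            break;
          }
          Z[i][j] = z;
        }
      }
      if (!ok) {
        safety *= 4.0;
        continue;
      }
      logZ = std::log(Z[1][n]) + n * std::log(s);

      // ---- outside pass ----
      // O[i][j] scaled by s^(n - (j-i+1)); defined for pairable (i, j).
      // A[i][l] = sum_{k < i} Wscaled(k,l) * O[k][l] * Z[k+1][i-1]
      std::vector<std::vector<double>> O(n + 2,
                                         std::vector<double>(n + 2, 0.0));
      std::vector<double> Arow(n + 2, 0.0);
      std::vector<std::vector<double>> A(n + 2,
                                         std::vector<double>(n + 2, 0.0));
      std::fill(bpp.begin(), bpp.end(), 0.0);
      for (int i = 1; i <= n && ok; ++i) {
        // A[i][l] for all l
        for (int l = 1; l <= n; ++l) {
          double a = 0.0;
          for (int k = 1; k < i; ++k) {
            if (O[k][l] == 0.0) continue;
            double ep = pair_energy(seq[k - 1], seq[l - 1], eGC, eAU, eGU);
            if (ISNA(ep)) continue;
            double w = std::exp(-(ep + pseudo[k - 1] + pseudo[l - 1]) / kT) /
                       (s * s);
            a += w * O[k][l] * Z[k + 1][i - 1];
          }
          A[i][l] = a;
        }
        for (int j = i + min_hairpin + 1; j <= n; ++j) {
          double ep = pair_energy(seq[i - 1], seq[j - 1], eGC, eAU, eGU);
          if (ISNA(ep)) continue;
          double o = Z[1][i - 1] * Z[j + 1][n];
          for (int l = j + 1; l <= n; ++l) {
            if (A[i][l] == 0.0) continue;
            o += A[i][l] * Z[j + 1][l - 1];
          }
          if (!std::isfinite(o)) {
            ok = false;
            break;
          }
          O[i][j] = o;
          double w = std::exp(-(ep + pseudo[i - 1] + pseudo[j - 1]) / kT) /
                     (s * s);
          double p = w * Z[i + 1][j - 1] * o / Z[1][n];
          if (p < 0) p = 0;
          if (p > 1) p = 1;
          bpp[i - 1] += p;
          bpp[j - 1] += p;
          if (want_pmat) {
            pmat(i - 1, j - 1) = p;
            pmat(j - 1, i - 1) = p;
          }
        }
      }
      if (!ok) safety *= 4.0;
    }
    if (!ok) stop("partition function did not converge numerically");
    for (int i = 0; i < n; ++i) {
      if (bpp[i] > 1.0) bpp[i] = 1.0;
    }
  }

  return List::create(_["mfe"] = mfe, _["partner"] = partner,
                      _["logZ"] = logZ, _["bpp"] = bpp,
                      _["pmat"] = want_pmat ? (SEXP)pmat : R_NilValue);
}
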