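// Global pairwise alignment with affine gap costs (Gotoh three-state DP).
// A gap run of length L costs gap_open + gap_ext * L.  Traceback is fully
// deterministic: on ties the diagonal (match/mismatch) state wins over a gap
// in the second sequence ("up"), which wins over a gap in the first ("left").

#include <Rcpp.h>
#include <vector>
#include <limits>
using namespace Rcpp;

// [[Rcpp::export(name = ".nw_align_cpp")]]
List nw_align_cpp(IntegerVector a, IntegerVector b, double match,
                  double mismatch, double gap_open, double gap_ext) {
  const int n = a.size(), m = b.size();
  const double NEG = -std::numeric_limits<double>::infinity();
  auto idx = [m](int i, int j) { return i * (m + 1) + j; };
  std::vector<double> M((n + 1) * (m + 1), NEG), X((n + 1) * (m + 1), NEG),
      Y((n + 1) * (m + 1), NEG);
  // traceback pointers: which state the max came from (0=M, 1=X, 2=Y)
  std::vector<signed char> pM((n + 1) * (m + 1), -1),
      pX((n + 1) * (m + 1), -1), pY((n + 1) * (m + 1), -1);

  M[idx(0, 0)] = 0.0;
  for (int i = 1; i <= n; ++i) {
    X[idx(i, 0)] = gap_open + gap_ext * i;
    pX[idx(i, 0)] = (i == 1) ? 0 : 1;
  }
  for (int j = 1; j <= m; ++j) {
    Y[idx(0, j)] = gap_open + gap_ext * j;
    pY[idx(0, j)] = (j == 1) ? 0 : 2;
  }

  // priority M > X > Y on ties
  auto pick3 = [](double vM, double vX, double vY, signed char &ptr) {
    double best = vM;
    ptr = 0;
    if (vX > best) {
      best = vX;
      ptr = 1;
    }
    if (vY > best) {
      best = vY;
      ptr = 2;
    }
    return best;
  };

  for (int i = 1; i <= n; ++i) {
    for (int j = 1; j <= m; ++j) {
      double s = (a[i - 1] == b[j - 1]) ? match : mismatch;
      signed char ptr;
      double best = pick3(M[idx(i - 1, j - 1)], X[idx(i - 1, j - 1)],
                          Y[idx(i - 1, j - 1)], ptr);
      M[idx(i, j)] = s + best;
      pM[idx(i, j)] = ptr;

      best = pick3(M[idx(i - 1, j)] + gap_open + gap_ext,
                   X[idx(i - 1, j)] + gap_ext,
                   Y[idx(i - 1, j)] + gap_open + gap_ext, ptr);
      X[idx(i, j)] = best;
      pX[idx(i, j)] = ptr;

      best = pick3(M[idx(i, j - 1)] + gap_open + gap_ext,
                   X[idx(i, j - 1)] + gap_open + gap_ext,
                   Y[idx(i, j - 1)] + gap_ext, ptr);
      Y[idx(i, j)] = best;
      pY[idx(i, j)] = ptr;
    }
  }

  signed char state;
  double score =
      pick3(M[idx(n, m)], X[idx(n, m)], Y[idx(n, m)], state);

  // traceback
  std::vector<int> ra, rb;  // 0-based indices, -1 = gap
  int i = n, j = m;
  while (i > 0 || j > 0) {
    signed char prev;
    if (state == 0) {
      prev = pM[idx(i, j)];
      ra.push_back(i - 1);
      rb.push_back(j - 1);
      --i;
      --j;
    } else if (state == 1) {
      prev = pX[idx(i, j)];
      ra.push_back(i - 1);
      rb.push_back(-1);
      --i;
    } else {
      prev = pY[idx(i, j)];
      ra.push_back(-1);
      rb.push_back(j - 1);
      --j;
    }
    state = prev;
  }
  std::reverse(ra.begin(), ra.end());
  std::reverse(rb.begin(), rb.end());
  return List::create(_["score"] = score, _["a_idx"] = wrap(ra),
                      _["b_idx"] = wrap(rb));
}
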