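#include <Rcpp.h>
#include <string>
#include <vector>
#include <limits>

using namespace Rcpp;

// Global pairwise alignment with affine gap penalties (Gotoh).
// A gap of length k costs gap_open + k * gap_extend (both <= 0 by
// convention). Tie-breaking is deterministic: at every choice the
// preference order is diagonal (match/mismatch), then gap in B (a column
// consuming A only), then gap in A.
//
// States: 0 = M (diagonal), 1 = X (gap in B, consumes A), 2 = Y (gap in A,
// consumes B). Traceback matrices store the predecessor state.

// [[Rcpp::export(name = ".align_global_cpp")]]
List align_global_cpp(std::string a, std::string b,
                      double match, double mismatch,
                      double gap_open, double gap_extend) {
  const int n = a.size(), m = b.size();
  const double NEG = -std::numeric_limits<double>::infinity();
  const size_t sz = (size_t)(n + 1) * (size_t)(m + 1);

  std::vector<double> M(sz, NEG), X(sz, NEG), Y(sz, NEG);
  std::vector<unsigned char> tbM(sz, 0), tbX(sz, 0), tbY(sz, 0);
  auto at = [m](int i, int j) { return (size_t)i * (size_t)(m + 1) + j; };

  M[at(0, 0)] = 0.0;
  for (int i = 1; i <= n; ++i) {
    X[at(i, 0)] = gap_open + i * gap_extend;
    tbX[at(i, 0)] = (i == 1) ? 0 : 1;
  }
  for (int j = 1; j <= m; ++j) {
    Y[at(0, j)] = gap_open + j * gap_extend;
    tbY[at(0, j)] = (j == 1) ? 0 : 2;
  }

  // best of (M, X, Y) with preference M > X > Y on ties
  auto best3 = [](double vm, double vx, double vy, unsigned char &state) {
    double v = vm; state = 0;
    if (vx > v) { v = vx; state = 1; }
    if (vy > v) { v = vy; state = 2; }
    return v;
  };

  for (int i = 1; i <= n; ++i) {
    for (int j = 1; j <= m; ++j) {
      const size_t cur = at(i, j), di = at(i - 1, j - 1),
                   up = at(i - 1, j), lf = at(i, j - 1);
      unsigned char s;
      const double sub = (a[i - 1] == b[j - 1]) ? match : mismatch;
      M[cur] = sub + best3(M[di], X[di], Y[di], s);
      tbM[cur] = s;
      X[cur] = best3(M[up] + gap_open + gap_extend,
                     X[up] + gap_extend,
                     Y[up] + gap_open + gap_extend, s);
      tbX[cur] = s;
      Y[cur] = best3(M[lf] + gap_open + gap_extend,
                     X[lf] + gap_open + gap_extend,
                     Y[lf] + gap_extend, s);
      tbY[cur] = s;
    }
  }

  unsigned char state;
  const double score = best3(M[at(n, m)], X[at(n, m)], Y[at(n, m)], state);

  std::string ga, gb;
  ga.reserve(n + m); gb.reserve(n + m);
  int i = n, j = m;
  while (i > 0 || j > 0) {
    if (state == 0) {
      const unsigned char prev = tbM[at(i, j)];
      ga.push_back(a[i - 1]); gb.push_back(b[j - 1]);
      --i; --j; state = prev;
    } else if (state == 1) {
      const unsigned char prev = tbX[at(i, j)];
      ga.push_back(a[i - 1]); gb.push_back('-');
      --i; state = prev;
    } else {
      const unsigned char prev = tbY[at(i, j)];
      ga.push_back('-'); gb.push_back(b[j - 1]);
      --j; state = prev;
    }
  }
  std::reverse(ga.begin(), ga.end());
  std::reverse(gb.begin(), gb.end());

  return List::create(_["gappedA"] = ga, _["gappedB"] = gb,
                      _["score"] = score);
}
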