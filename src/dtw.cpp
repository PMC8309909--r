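#include <Rcpp.h>
using namespace Rcpp;

// Cumulative-cost fill and backtracking for dynamic time warping.
// D(x,y) = (s1[x] - s2[y])^2; C by the standard three-neighbour recurrence.
// Backtracking starts at (m,n) and moves to the adjacent predecessor of
// lowest accumulated cost; ties prefer the diagonal, then the vertical
// (row-decreasing) step.

// [[Rcpp::export(name = ".dtw_core")]]
List dtw_core(NumericVector s1, NumericVector s2) {
  const int m = s1.size(), n = s2.size();
  NumericMatrix C(m, n);

  for (int i = 0; i < m; ++i) {
    for (int j = 0; j < n; ++j) {
      double d = s1[i] - s2[j];
      d *= d;
      if (i == 0 && j == 0) {
        C(i, j) = d;
      } else if (i == 0) {
        C(i, j) = d + C(i, j - 1);
      } else if (j == 0) {
        C(i, j) = d + C(i - 1, j);
      } else {
        double best = C(i - 1, j - 1);
        if (C(i - 1, j) < best) best = C(i - 1, j);
        if (C(i, j - 1) < best) best = C(i, j - 1);
        C(i, j) = d + best;
      }
    }
  }

  // Backtrack; path length is at most m + n - 1.
  std::vector<int> px, py;
  px.reserve(m + n);
  py.reserve(m + n);
  int i = m - 1, j = n - 1;
  px.push_back(i + 1);
  py.push_back(j + 1);
  while (i > 0 || j > 0) {
    if (i == 0) {
      --j;
    } else if (j == 0) {
      --i;
    } else {
      const double diag = C(i - 1, j - 1);
      const double vert = C(i - 1, j);
      const double horz = C(i, j - 1);
      if (diag <= vert && diag <= horz) {
        --i; --j;
      } else if (vert <= horz) {
        --i;
      } else {
        --j;
      }
    }
    px.push_back(i + 1);
    py.push_back(j + 1);
  }
  std::reverse(px.begin(), px.end());
  std::reverse(py.begin(), py.end());

  return List::create(_["cost"] = C,
                      _["path_x"] = wrap(px),
                      _["path_y"] = wrap(py));
}
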