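#include <Rcpp.h>
#include <vector>
#include <string>
#include <algorithm>
using namespace Rcpp;

// Global (Needleman-Wunsch) alignment with linear gap penalty, optionally
// restricted to a diagonal band.  Cells (i, j) with lo <= j - i <= hi are
// computed; everything else is unreachable.  Passing lo <= -(la + 1) and
// hi >= lb + 1 yields the full table.
//
// Backtrace tie order is fixed: diagonal, then up (gap in b), then left
// (gap in a), so outputs are bit-reproducible.  `touched` reports whether
// the backtraced path visited a cell on the band boundary (j - i == lo or
// hi), the signal used by the band-doubling escape.
//
// [[Rcpp::export(name = ".nw_core")]]
List nw_core(std::string a, std::string b,
             double match, double mismatch, double gap,
             int lo, int hi) {
  const int la = (int)a.size(), lb = (int)b.size();
  const double NEG = -1e18;
  std::vector<double> H((size_t)(la + 1) * (lb + 1), NEG);
  const int W = lb + 1;

  for (int i = 0; i <= la; ++i) {
    int jmin = std::max(0, i + lo), jmax = std::min(lb, i + hi);
    for (int j = jmin; j <= jmax; ++j) {
      if (i == 0 && j == 0) { H[0] = 0.0; continue; }
      double best = NEG;
      if (i > 0 && j > 0) {
        double d = H[(size_t)(i - 1) * W + (j - 1)];
        if (d > NEG / 2)
          best = d + (a[i - 1] == b[j - 1] ? match : mismatch);
      }
      if (i > 0) {
        double u = H[(size_t)(i - 1) * W + j];
        if (u > NEG / 2 && u + gap > best) best = u + gap;
      }
      if (j > 0) {
        double l = H[(size_t)i * W + (j - 1)];
        if (l > NEG / 2 && l + gap > best) best = l + gap;
      }
      H[(size_t)i * W + j] = best;
    }
  }

  int i = la, j = lb;
  bool touched = false;
  std::string ra, rb;
  ra.reserve(la + lb); rb.reserve(la + lb);
  while (i > 0 || j > 0) {
    if (j - i == lo || j - i == hi) touched = true;
    double cur = H[(size_t)i * W + j];
    bool stepped = false;
    if (i > 0 && j > 0) {
      double d = H[(size_t)(i - 1) * W + (j - 1)];
      if (d > NEG / 2 &&
          cur == d + (a[i - 1] == b[j - 1] ? match : mismatch)) {
        ra.push_back(a[i - 1]); rb.push_back(b[j - 1]);
        --i; --j; stepped = true;
      }
    }
    if (!stepped && i > 0) {
      double u = H[(size_t)(i - 1) * W + j];
      if (u > NEG / 2 && cur == u + gap) {
        ra.push_back(a[i - 1]); rb.push_back('-');
        --i; stepped = true;
      }
    }
    if (!stepped && j > 0) {
      double l = H[(size_t)i * W + (j - 1)];
      if (l > NEG / 2 && cur == l + gap) {
        ra.push_back('-'); rb.push_back(b[j - 1]);
        --j; stepped = true;
      }
    }
    if (!stepped) stop("internal error: broken backtrace");
  }
  std::reverse(ra.begin(), ra.end());
  std::reverse(rb.begin(), rb.end());

  return List::create(_["row_a"] = ra, _["row_b"] = rb,
                      _["score"] = H[(size_t)la * W + lb],
                      _["touched"] = touched);
}
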