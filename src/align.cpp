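#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <string>
using namespace Rcpp;

// Affine-gap Smith-Waterman with a fully specified tie-break so that
// score, identity and coverage are reproducible across platforms.
//
// Gap of length L costs gap_open + L * gap_ext (BLAST-style: the first
// gapped residue costs gap_open + gap_ext). Three states:
//   M — residue pair (the only state an alignment may start or end in),
//   X — gap in the subject (consumes a query residue),
//   Y — gap in the query  (consumes a subject residue).
// Best cell: highest M value; ties resolved to the smallest (row, col).
// Traceback preference at equal score: M, then X, then Y, then a fresh
// local start.

static inline bool feq(double a, double b) { return std::fabs(a - b) < 1e-9; }

// [[Rcpp::export]]
List sw_align_cpp(IntegerVector qa, IntegerVector sa, NumericMatrix S,
                  double gap_open, double gap_ext) {
  const int n = qa.size(), m = sa.size();
  const double NEG = -1e18;
  const double oe = gap_open + gap_ext;
  std::vector<double> M((size_t)(n + 1) * (m + 1), NEG);
  std::vector<double> X((size_t)(n + 1) * (m + 1), NEG);
  std::vector<double> Y((size_t)(n + 1) * (m + 1), NEG);
  const int W = m + 1;
  double best = 0.0;
  int bi = 0, bj = 0;
  for (int i = 1; i <= n; ++i) {
    for (int j = 1; j <= m; ++j) {
      double diag = 0.0;
      double pm = M[(size_t)(i - 1) * W + (j - 1)];
      double px = X[(size_t)(i - 1) * W + (j - 1)];
      double py = Y[(size_t)(i - 1) * W + (j - 1)];
      if (pm > diag) diag = pm;
      if (px > diag) diag = px;
      if (py > diag) diag = py;
      M[(size_t)i * W + j] = S(qa[i - 1] - 1, sa[j - 1] - 1) + diag;
      double xm = M[(size_t)(i - 1) * W + j] - oe;
      double xx = X[(size_t)(i - 1) * W + j] - gap_ext;
      double xy = Y[(size_t)(i - 1) * W + j] - oe;
      X[(size_t)i * W + j] = std::max(xm, std::max(xx, xy));
      double ym = M[(size_t)i * W + (j - 1)] - oe;
      double yx = X[(size_t)i * W + (j - 1)] - oe;
      double yy = Y[(size_t)i * W + (j - 1)] - gap_ext;
      Y[(size_t)i * W + j] = std::max(ym, std::max(yx, yy));
      if (M[(size_t)i * W + j] > best) {
        best = M[(size_t)i * W + j];
        bi = i; bj = j;
      }
    }
  }

  if (best <= 0.0) {
    return List::create(
      _["score"] = 0.0, _["nmatch"] = 0, _["ncol"] = 0,
      _["qstart"] = 0, _["qend"] = 0, _["sstart"] = 0, _["send"] = 0,
      _["qpath"] = IntegerVector(0), _["spath"] = IntegerVector(0));
  }

  // traceback; qpath/spath record the consumed positions (0 for a gap)
  std::vector<int> qpath, spath;
  int i = bi, j = bj, nmatch = 0;
  char st = 'M';
  while (true) {
    if (st == 'M') {
      qpath.push_back(i);
      spath.push_back(j);
      if (qa[i - 1] == sa[j - 1]) ++nmatch;
      double need = M[(size_t)i * W + j] - S(qa[i - 1] - 1, sa[j - 1] - 1);
      double pm = M[(size_t)(i - 1) * W + (j - 1)];
      double px = X[(size_t)(i - 1) * W + (j - 1)];
      double py = Y[(size_t)(i - 1) * W + (j - 1)];
      --i; --j;
      if (feq(pm, need)) st = 'M';
      else if (feq(px, need)) st = 'X';
      else if (feq(py, need)) st = 'Y';
      else break;  // local start (need == 0)
    } else if (st == 'X') {
      qpath.push_back(i);
      spath.push_back(0);
      double v = X[(size_t)i * W + j];
      double pm = M[(size_t)(i - 1) * W + j];
      double px = X[(size_t)(i - 1) * W + j];
      --i;
      if (feq(pm - oe, v)) st = 'M';
      else if (feq(px - gap_ext, v)) st = 'X';
      else st = 'Y';
    } else {  // Y
      qpath.push_back(0);
      spath.push_back(j);
      double v = Y[(size_t)i * W + j];
      double pm = M[(size_t)i * W + (j - 1)];
      double px = X[(size_t)i * W + (j - 1)];
      --j;
      if (feq(pm - oe, v)) st = 'M';
      else if (feq(px - oe, v)) st = 'X';
      else st = 'Y';
    }
  }
  std::reverse(qpath.begin(), qpath.end());
  std::reverse(spath.begin(), spath.end());
  return List::create(
    _["score"] = best, _["nmatch"] = nmatch, _["ncol"] = (int)qpath.size(),
    _["qstart"] = i + 1, _["qend"] = bi, _["sstart"] = j + 1, _["send"] = bj,
    _["qpath"] = wrap(qpath), _["spath"] = wrap(spath));
}
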