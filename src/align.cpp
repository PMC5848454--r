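#include <Rcpp.h>
using namespace Rcpp;

// Global (Needleman-Wunsch) alignment with affine gap penalties (Gotoh).
// Sequences arrive as 1-based integer indices into the substitution matrix.
// A gap of length g costs open + g * ext; terminal gaps are charged like any
// other. Identity = identical aligned columns / total alignment length
// (gap columns included in the denominator).

static const double NEG_INF = -1e30;

struct AlnCounts {
  double score;
  int matches;
  int length;
};

static AlnCounts gotoh_align(const IntegerVector& a, const IntegerVector& b,
                             const NumericMatrix& sub, double open, double ext) {
  const int n = a.size(), m = b.size();
  // DP layers: M diagonal, X gap in b (a consumes), Y gap in a (b consumes)
  NumericMatrix M(n + 1, m + 1), X(n + 1, m + 1), Y(n + 1, m + 1);
  // traceback: which layer each cell came from (0=M,1=X,2=Y)
  IntegerMatrix tM(n + 1, m + 1), tX(n + 1, m + 1), tY(n + 1, m + 1);

  M(0, 0) = 0.0;
  X(0, 0) = Y(0, 0) = NEG_INF;
  for (int i = 1; i <= n; ++i) {
    M(i, 0) = Y(i, 0) = NEG_INF;
    X(i, 0) = -(open + i * ext);
    tX(i, 0) = 1;
  }
  for (int j = 1; j <= m; ++j) {
    M(0, j) = X(0, j) = NEG_INF;
    Y(0, j) = -(open + j * ext);
    tY(0, j) = 2;
  }

  for (int i = 1; i <= n; ++i) {
    for (int j = 1; j <= m; ++j) {
      const double s = sub(a[i - 1] - 1, b[j - 1] - 1);
      // M: prefer diagonal continuation on ties (deterministic traceback)
      double best = M(i - 1, j - 1);
      int from = 0;
      if (X(i - 1, j - 1) > best) { best = X(i - 1, j - 1); from = 1; }
      if (Y(i - 1, j - 1) > best) { best = Y(i - 1, j - 1); from = 2; }
      M(i, j) = best + s;
      tM(i, j) = from;
      // X: gap in b
      double xo = M(i - 1, j) - (open + ext);
      double xe = X(i - 1, j) - ext;
      if (xo >= xe) { X(i, j) = xo; tX(i, j) = 0; }
      else          { X(i, j) = xe; tX(i, j) = 1; }
      // Y: gap in a
      double yo = M(i, j - 1) - (open + ext);
      double ye = Y(i, j - 1) - ext;
      if (yo >= ye) { Y(i, j) = yo; tY(i, j) = 0; }
      else          { Y(i, j) = ye; tY(i, j) = 2; }
    }
  }

  int layer = 0;
  double best = M(n, m);
  if (X(n, m) > best) { best = X(n, m); layer = 1; }
  if (Y(n, m) > best) { best = Y(n, m); layer = 2; }

  AlnCounts out;
  out.score = best;
  out.matches = 0;
  out.length = 0;
  int i = n, j = m;
  while (i > 0 || j > 0) {
    ++out.length;
    if (layer == 0) {
      int from = tM(i, j);
      if (a[i - 1] == b[j - 1]) ++out.matches;
      --i; --j;
      layer = from;
    } else if (layer == 1) {
      int from = tX(i, j);
      --i;
      layer = from;
    } else {
      int from = tY(i, j);
      --j;
      layer = from;
    }
  }
  return out;
}

// [[Rcpp::export]]
List nw_align_cpp(IntegerVector a, IntegerVector b, NumericMatrix sub,
                  double gap_open, double gap_ext) {
  AlnCounts r = gotoh_align(a, b, sub, gap_open, gap_ext);
  return List::create(_["score"] = r.score,
                      _["matches"] = r.matches,
                      _["length"] = r.length,
                      _["identity"] = (double)r.matches / (double)r.length);
}

// [[Rcpp::export]]
double nw_identity_cpp(IntegerVector a, IntegerVector b, NumericMatrix sub,
                       double gap_open, double gap_ext) {
  AlnCounts r = gotoh_align(a, b, sub, gap_open, gap_ext);
  return (double)r.matches / (double)r.length;
}
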