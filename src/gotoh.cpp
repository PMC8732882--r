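#include <Rcpp.h>
using namespace Rcpp;

// Global affine-gap (Gotoh) alignment over a precomputed column-score matrix
// S (m x n): S(i,j) = score of aligning column i of profile X with column j
// of profile Y. Gap of length L costs gap_open + (L-1)*gap_extend.
// End gaps are penalized. Score values use rolling rows; traceback uses three
// byte matrices, so memory is O(m*n) bytes, not doubles.
//
// Traceback tie-break (deterministic): prefer the match/mismatch state, then
// a gap in X (column consumed from Y only), then a gap in Y.
//
// Returns the alignment path as operation codes: 0 = column from both,
// 1 = gap in X (Y column only), 2 = gap in Y (X column only), in order.

// [[Rcpp::export(name = ".gotoh_align")]]
List gotoh_align(NumericMatrix S, double gap_open, double gap_extend) {
  const int m = S.nrow(), n = S.ncol();
  const double NEG = -1e30;

  // rolling score rows, indexed 0..n
  std::vector<double> Mprev(n + 1), Xprev(n + 1), Yprev(n + 1);
  std::vector<double> Mcur(n + 1), Xcur(n + 1), Ycur(n + 1);
  // traceback: which predecessor state fed each cell (0=M, 1=X, 2=Y, 3=none)
  RawMatrix tbM(m + 1, n + 1), tbX(m + 1, n + 1), tbY(m + 1, n + 1);

  Mprev[0] = 0.0;
  Xprev[0] = NEG;
  Yprev[0] = NEG;
  tbM(0, 0) = 3;
  for (int j = 1; j <= n; ++j) {
    Mprev[j] = NEG;
    Xprev[j] = gap_open + (j - 1) * gap_extend;
    Yprev[j] = NEG;
    tbX(0, j) = (j == 1) ? 0 : 1;
  }

  for (int i = 1; i <= m; ++i) {
    Mcur[0] = NEG;
    Xcur[0] = NEG;
    Ycur[0] = gap_open + (i - 1) * gap_extend;
    tbY(i, 0) = (i == 1) ? 0 : 2;
    for (int j = 1; j <= n; ++j) {
      // M: diagonal move, from any state at (i-1, j-1)
      double best = Mprev[j - 1];
      unsigned char who = 0;
      if (Xprev[j - 1] > best) { best = Xprev[j - 1]; who = 1; }
      if (Yprev[j - 1] > best) { best = Yprev[j - 1]; who = 2; }
      Mcur[j] = best + S(i - 1, j - 1);
      tbM(i, j) = who;

      // X: gap in X, consume Y column j, from (i, j-1)
      double xo = Mcur[j - 1] + gap_open;
      double xe = Xcur[j - 1] + gap_extend;
      double xy = Ycur[j - 1] + gap_open;
      if (xo >= xe && xo >= xy) { Xcur[j] = xo; tbX(i, j) = 0; }
      else if (xe >= xy)        { Xcur[j] = xe; tbX(i, j) = 1; }
      else                      { Xcur[j] = xy; tbX(i, j) = 2; }

      // Y: gap in Y, consume X column i, from (i-1, j)
      double yo = Mprev[j] + gap_open;
      double ye = Yprev[j] + gap_extend;
      double yx = Xprev[j] + gap_open;
      if (yo >= ye && yo >= yx) { Ycur[j] = yo; tbY(i, j) = 0; }
      else if (ye >= yx)        { Ycur[j] = ye; tbY(i, j) = 1; }
      else                      { Ycur[j] = yx; tbY(i, j) = 2; }
    }
    std::swap(Mprev, Mcur);
    std::swap(Xprev, Xcur);
    std::swap(Yprev, Ycur);
  }

  double score = Mprev[n];
  int state = 0;
  if (Xprev[n] > score) { score = Xprev[n]; state = 1; }
  if (Yprev[n] > score) { score = Yprev[n]; state = 2; }

  std::vector<int> ops;
  ops.reserve(m + n);
  int i = m, j = n;
  while (i > 0 || j > 0) {
    if (state == 0) {
      ops.push_back(0);
      state = tbM(i, j);
      --i; --j;
    } else if (state == 1) {
      ops.push_back(1);
      state = tbX(i, j);
      --j;
    } else {
      ops.push_back(2);
      state = tbY(i, j);
      --i;
    }
  }
  std::reverse(ops.begin(), ops.end());
  return List::create(_["score"] = score,
                      _["ops"] = IntegerVector(ops.begin(), ops.end()));
}
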