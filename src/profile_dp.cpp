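#include <Rcpp.h>
#include <vector>
#include <cstdint>
using namespace Rcpp;

// Banded global alignment of two alignment profiles with affine gaps.
//
// f1, f2: 5 x W frequency matrices (rows A,C,G,T,gap; columns sum to 1).
// Substitution score between columns i and j uses residue frequencies only:
//   s(i,j) = match * dot + mismatch * (nz1*nz2 - dot),
//   dot = sum_a f1(a,i) f2(a,j),  nz = residue (non-gap) frequency mass.
// Consuming a column against a gap is penalized by open/ext scaled by the
// consumed column's non-gap mass (a mostly-gap column is cheap to skip).
// A single sequence is the special case of a 1-row profile.
//
// Band: cell (i,j) is computed iff |j - i - off| <= k.  The caller must
// ensure k >= max(|off|, |W2 - W1 - off|) so both DP corners lie in band.
// With k >= max(W1, W2) the band covers the full matrix and the result is
// the unbanded optimum.
//
// Returns score, ops (1 = both columns, 2 = column of f1 only, i.e. gap
// inserted in profile 2; 3 = column of f2 only), and edge_hit (whether the
// optimal path touched the band boundary, used by the doubling schedule).
// [[Rcpp::export]]
List profile_pair_dp_cpp(NumericMatrix f1, NumericMatrix f2,
                         int k, int off,
                         double match, double mismatch,
                         double gap_open, double gap_ext) {
  const int W1 = f1.ncol(), W2 = f2.ncol();
  if (k < 1) k = 1;
  const double NEG = -1e30;
  // non-gap mass per column
  std::vector<double> nz1(W1 + 1, 0.0), nz2(W2 + 1, 0.0);
  for (int i = 1; i <= W1; ++i)
    nz1[i] = f1(0, i - 1) + f1(1, i - 1) + f1(2, i - 1) + f1(3, i - 1);
  for (int j = 1; j <= W2; ++j)
    nz2[j] = f2(0, j - 1) + f2(1, j - 1) + f2(2, j - 1) + f2(3, j - 1);

  const int B = 2 * k + 3;  // banded traceback row width, with sentinels
  std::vector<uint8_t> tb((size_t)(W1 + 1) * B, 0);
  auto tbi = [&](int i, int j) -> uint8_t& {
    return tb[(size_t)i * B + (j - (i + off - k) + 1)];
  };

  std::vector<double> H(W2 + 1, NEG), Hprev(W2 + 1, NEG);
  std::vector<double> Fcol(W2 + 1, NEG);

  // row 0
  {
    int jhi = std::min(W2, off + k);
    if (off - k > 0) stop("band does not contain the DP origin");
    H[0] = 0.0;
    double E = NEG;
    for (int j = 1; j <= jhi; ++j) {
      double e_open = H[j - 1] - (gap_open + gap_ext) * nz2[j];
      double e_ext = E - gap_ext * nz2[j];
      uint8_t bits = 0;
      if (e_ext > e_open) { E = e_ext; bits |= 4; } else E = e_open;
      H[j] = E;
      tbi(0, j) = bits | 2;  // from E
    }
  }
  int prev_jhi = std::min(W2, off + k);
  for (int i = 1; i <= W1; ++i) {
    std::swap(H, Hprev);
    int jlo = std::max(0, i + off - k);
    int jhi = std::min(W2, i + off + k);
    if (jlo > jhi) stop("empty band row");
    // cells entering the band on this row carry stale state
    for (int j = prev_jhi + 1; j <= jhi; ++j) { Hprev[j] = NEG; Fcol[j] = NEG; }
    double E = NEG;
    double Hleft = NEG;
    if (jlo == 0) {
      // column 0: gap consuming column i of profile 1
      double f_open = Hprev[0] - (gap_open + gap_ext) * nz1[i];
      double f_ext = Fcol[0] - gap_ext * nz1[i];
      uint8_t bits = 0;
      if (f_ext > f_open) { Fcol[0] = f_ext; bits |= 8; } else Fcol[0] = f_open;
      H[0] = Fcol[0];
      tbi(i, 0) = bits | 3;
      Hleft = H[0];
    } else {
      H[jlo - 1] = NEG;
      Hleft = NEG;
    }
    for (int j = std::max(1, jlo); j <= jhi; ++j) {
      uint8_t bits = 0;
      double e_open = Hleft - (gap_open + gap_ext) * nz2[j];
      double e_ext = E - gap_ext * nz2[j];
      if (e_ext > e_open) { E = e_ext; bits |= 4; } else E = e_open;
      double f_open = Hprev[j] - (gap_open + gap_ext) * nz1[i];
      double f_ext = Fcol[j] - gap_ext * nz1[i];
      if (f_ext > f_open) { Fcol[j] = f_ext; bits |= 8; } else Fcol[j] = f_open;
      double dot = f1(0, i - 1) * f2(0, j - 1) + f1(1, i - 1) * f2(1, j - 1) +
                   f1(2, i - 1) * f2(2, j - 1) + f1(3, i - 1) * f2(3, j - 1);
      double sub = match * dot + mismatch * (nz1[i] * nz2[j] - dot);
      double diag = Hprev[j - 1] + sub;
      double h = diag; uint8_t dir = 1;
      if (E > h) { h = E; dir = 2; }
      if (Fcol[j] > h) { h = Fcol[j]; dir = 3; }
      H[j] = h;
      tbi(i, j) = bits | dir;
      Hleft = h;
    }
    prev_jhi = jhi;
  }
  if (W2 > W1 + off + k || W2 < W1 + off - k)
    stop("band does not contain the DP terminus");
  double score = H[W2];

  // traceback
  std::vector<int> ops;
  int i = W1, j = W2, state = 0;
  bool edge = false;
  while (i > 0 || j > 0) {
    if (j - i - off == k || j - i - off == -k) edge = true;
    uint8_t b = (i >= 0) ? tbi(i, j) : 0;
    if (state == 0) {
      uint8_t dir = b & 3;
      if (dir == 1) { ops.push_back(1); --i; --j; }
      else if (dir == 2) state = 2;
      else if (dir == 3) state = 3;
      else stop("corrupt traceback");
    } else if (state == 2) {
      ops.push_back(3);  // column of f2 consumed against gap in 1
      if (!(b & 4)) state = 0;
      --j;
    } else {
      ops.push_back(2);  // column of f1 consumed against gap in 2
      if (!(b & 8)) state = 0;
      --i;
    }
  }
  std::reverse(ops.begin(), ops.end());
  return List::create(_["score"] = score,
                      _["ops"] = IntegerVector(ops.begin(), ops.end()),
                      _["edge_hit"] = edge);
}
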