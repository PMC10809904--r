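#include <Rcpp.h>
#include <vector>
#include <cstdint>
using namespace Rcpp;

// Affine-gap Smith-Waterman with full traceback.
// codes: 1..4 = A,C,G,T; 0 = masked position, scored as a mismatch against
// everything (including another masked position).
// A gap of length g costs gap_open + g * gap_ext.
// Tie-break on the optimum cell: smallest target end, then smallest query end.
// [[Rcpp::export]]
List sw_align_cpp(IntegerVector q, IntegerVector t,
                  double match, double mismatch,
                  double gap_open, double gap_ext) {
  const int L = q.size(), W = t.size();
  if (L == 0 || W == 0) stop("empty input to local alignment");
  const double big = (double)(L + 1) * (double)(W + 1);
  if (big > 4e8) stop("local alignment problem too large");
  const double NEG = -1e30;
  std::vector<double> H(W + 1, 0.0), E(W + 1, NEG);
  // traceback bytes: bits 0-1 H-dir (0 stop, 1 diag, 2 fromE, 3 fromF),
  // bit 2: E extends E, bit 3: F extends F
  std::vector<uint8_t> tb((size_t)(L + 1) * (W + 1), 0);
  double best = 0.0;
  int bi = 0, bj = 0;
  std::vector<double> Hprev(W + 1, 0.0), Fcol(W + 1, NEG);
  for (int i = 1; i <= L; ++i) {
    Hprev = H;
    H[0] = 0.0;
    double Erow = NEG;
    for (int j = 1; j <= W; ++j) {
      uint8_t bits = 0;
      // E: gap in query (consume target char j)
      double e_open = H[j - 1] - gap_open - gap_ext;
      double e_ext = Erow - gap_ext;
      if (e_ext > e_open) { Erow = e_ext; bits |= 4; } else Erow = e_open;
      // F: gap in target (consume query char i)
      double f_open = Hprev[j] - gap_open - gap_ext;
      double f_ext = Fcol[j] - gap_ext;
      if (f_ext > f_open) { Fcol[j] = f_ext; bits |= 8; } else Fcol[j] = f_open;
      double s = (q[i - 1] != 0 && q[i - 1] == t[j - 1]) ? match : mismatch;
      double diag = Hprev[j - 1] + s;
      double h = 0.0; uint8_t dir = 0;
      if (diag > h) { h = diag; dir = 1; }
      if (Erow > h) { h = Erow; dir = 2; }
      if (Fcol[j] > h) { h = Fcol[j]; dir = 3; }
      H[j] = h;
      tb[(size_t)i * (W + 1) + j] = bits | dir;
      if (h > best + 1e-12 ||
          (h > best - 1e-12 && (j < bj || (j == bj && i < bi)))) {
        best = h; bi = i; bj = j;
      }
    }
  }
  if (best <= 0.0 || bi == 0) {
    return List::create(_["score"] = 0.0, _["q_start"] = NA_INTEGER,
                        _["q_end"] = NA_INTEGER, _["t_start"] = NA_INTEGER,
                        _["t_end"] = NA_INTEGER, _["ops"] = IntegerVector(0),
                        _["n_match"] = 0, _["n_cols"] = 0, _["n_gap_cols"] = 0);
  }
  // traceback; ops: 1 = diag, 2 = gap in query (target consumed),
  // 3 = gap in target (query consumed)
  std::vector<int> ops;
  int i = bi, j = bj, nmatch = 0, ngap = 0;
  int state = 0;  // 0 = in H, 2 = in E, 3 = in F
  while (i > 0 || j > 0) {
    uint8_t b = tb[(size_t)i * (W + 1) + j];
    if (state == 0) {
      uint8_t dir = b & 3;
      if (dir == 0) break;
      if (dir == 1) {
        ops.push_back(1);
        if (q[i - 1] != 0 && q[i - 1] == t[j - 1]) ++nmatch;
        --i; --j;
      } else {
        state = dir;  // enter E (2) or F (3)
      }
    } else if (state == 2) {
      ops.push_back(2); ++ngap;
      if (!(b & 4)) state = 0;
      --j;
    } else {
      ops.push_back(3); ++ngap;
      if (!(b & 8)) state = 0;
      --i;
    }
  }
  std::reverse(ops.begin(), ops.end());
  return List::create(_["score"] = best,
                      _["q_start"] = i + 1, _["q_end"] = bi,
                      _["t_start"] = j + 1, _["t_end"] = bj,
                      _["ops"] = IntegerVector(ops.begin(), ops.end()),
                      _["n_match"] = nmatch,
                      _["n_cols"] = (int)ops.size(),
                      _["n_gap_cols"] = ngap);
}
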