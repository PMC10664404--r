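#include <Rcpp.h>
#include <vector>
#include <cstdint>
using namespace Rcpp;

// Needleman-Wunsch global alignment with affine gaps (Gotoh), EMBOSS-needle
// scoring for DNA: match +5, mismatch -4, gap open 10, gap extend 0.5.
// Identity is matches / alignment columns, end-gap columns included.
// Scores are doubled internally so the half-point gap extension stays
// integral; matches and columns along one optimal path are carried through
// the DP (rolling rows, no traceback), ties resolved in a fixed state order
// for determinism.

namespace {

const int NEG = -1000000000;

struct Cell { int sc; int mt; int co; };

struct NWStats { int matches, columns; double score; };

inline void upd(Cell& dst, const Cell& src, int dsc, int dmt) {
  if (src.sc == NEG) return;
  int s = src.sc + dsc;
  if (s > dst.sc) { dst.sc = s; dst.mt = src.mt + dmt; dst.co = src.co + 1; }
}

NWStats nw_core(const std::string& a, const std::string& b,
                int match2, int mismatch2, int go2, int ge2) {
  int n = (int)a.size(), m = (int)b.size();
  int open_first = go2 + ge2;
  // rows indexed by j over b; three states: M (diag), X (gap in b), Y (gap in a)
  std::vector<Cell> Mp(m + 1), Xp(m + 1), Yp(m + 1), Mc(m + 1), Xc(m + 1), Yc(m + 1);
  const Cell none = {NEG, 0, 0};
  for (int j = 0; j <= m; ++j) Mp[j] = Xp[j] = Yp[j] = none;
  Mp[0].sc = 0;
  for (int j = 1; j <= m; ++j)
    Yp[j] = {-(open_first + (j - 1) * ge2), 0, j};
  for (int i = 1; i <= n; ++i) {
    char ca = a[i - 1];
    Mc[0] = Yc[0] = none;
    Xc[0] = {-(open_first + (i - 1) * ge2), 0, i};
    for (int j = 1; j <= m; ++j) {
      char cb = b[j - 1];
      bool eq = (ca == cb && ca != 'N');
      int sub = eq ? match2 : mismatch2;
      Cell mcell = none;
      upd(mcell, Mp[j - 1], sub, eq);
      upd(mcell, Xp[j - 1], sub, eq);
      upd(mcell, Yp[j - 1], sub, eq);
      Mc[j] = mcell;
      Cell xcell = none;
      upd(xcell, Mp[j], -open_first, 0);
      upd(xcell, Xp[j], -ge2, 0);
      Xc[j] = xcell;
      Cell ycell = none;
      upd(ycell, Mc[j - 1], -open_first, 0);
      upd(ycell, Yc[j - 1], -ge2, 0);
      Yc[j] = ycell;
    }
    std::swap(Mp, Mc); std::swap(Xp, Xc); std::swap(Yp, Yc);
  }
  Cell best = Mp[m];
  if (Xp[m].sc > best.sc) best = Xp[m];
  if (Yp[m].sc > best.sc) best = Yp[m];
  NWStats s;
  s.matches = best.mt;
  s.columns = best.co;
  s.score = best.sc / 2.0;
  return s;
}

}  // namespace

// [[Rcpp::export(name = ".nw_stats_cpp")]]
NumericVector nw_stats_cpp(std::string a, std::string b,
                           double match = 5, double mismatch = -4,
                           double gap_open = 10, double gap_ext = 0.5) {
  NWStats s = nw_core(a, b, (int)(2 * match), (int)(2 * mismatch),
                      (int)(2 * gap_open), (int)(2 * gap_ext));
  return NumericVector::create(
      _["identity_pct"] = 100.0 * s.matches / s.columns,
      _["matches"] = s.matches, _["columns"] = s.columns, _["score"] = s.score);
}

// [[Rcpp::export(name = ".nw_identity_matrix_cpp")]]
NumericMatrix nw_identity_matrix_cpp(CharacterVector seqs,
                                     double match = 5, double mismatch = -4,
                                     double gap_open = 10, double gap_ext = 0.5) {
  int n = seqs.size();
  NumericMatrix out(n, n);
  std::vector<std::string> ss(n);
  for (int i = 0; i < n; ++i) ss[i] = as<std::string>(seqs[i]);
  for (int i = 0; i < n; ++i) {
    out(i, i) = 100.0;
    for (int j = i + 1; j < n; ++j) {
      NWStats s = nw_core(ss[i], ss[j], (int)(2 * match), (int)(2 * mismatch),
                          (int)(2 * gap_open), (int)(2 * gap_ext));
      double id = 100.0 * s.matches / s.columns;
      out(i, j) = id; out(j, i) = id;
    }
    if (i % 64 == 0) Rcpp::checkUserInterrupt();
  }
  return out;
}

// [[Rcpp::export(name = ".nw_identity_many_cpp")]]
NumericMatrix nw_identity_many_cpp(CharacterVector seqs, CharacterVector refs,
                                   double match = 5, double mismatch = -4,
                                   double gap_open = 10, double gap_ext = 0.5) {
  int n = seqs.size(), m = refs.size();
  NumericMatrix out(n, m);
  for (int j = 0; j < m; ++j) {
    std::string r = as<std::string>(refs[j]);
    for (int i = 0; i < n; ++i) {
      NWStats s = nw_core(as<std::string>(seqs[i]), r, (int)(2 * match),
                          (int)(2 * mismatch), (int)(2 * gap_open), (int)(2 * gap_ext));
      out(i, j) = 100.0 * s.matches / s.columns;
    }
    Rcpp::checkUserInterrupt();
  }
  return out;
}
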