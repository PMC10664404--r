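#include <Rcpp.h>
#include <unordered_map>
#include <vector>
#include <cstdint>
using namespace Rcpp;

// Genome self-alignment by exact-word seeding and ungapped X-drop extension.
// Seeds are exact matches of length `word` (2-bit packed, so word <= 15);
// each seed not already covered by an extension on its diagonal is extended
// left and right with match/mismatch scores until the running score drops
// more than `xdrop` below the best.  Hits are scored with Karlin-Altschul
// ungapped nucleotide statistics to obtain a BLASTN-comparable E-value.

namespace {

const double KA_LAMBDA = 1.33;  // ungapped, reward +1 / penalty -2
const double KA_K = 0.621;

inline int base2code(char c) {
  switch (c) {
    case 'A': case 'a': return 0;
    case 'C': case 'c': return 1;
    case 'G': case 'g': return 2;
    case 'T': case 't': return 3;
    default: return 4;  // N and anything else: mismatches everything
  }
}

struct Hit {
  int qs, qe, ss, se;   // 0-based half-open
  bool minus;
  int matches, len;
  double score;
};

// ungapped X-drop extension of an exact seed a[qa,qa+word) == b[qb,qb+word)
Hit extend_seed(const std::vector<int8_t>& a, const std::vector<int8_t>& b,
                int qa, int qb, int word, int match, int mismatch, int xdrop) {
  int n = (int)a.size(), m = (int)b.size();
  double sc = (double)word * match, best = sc;
  int br = 0;  // best right offset (positions beyond seed end)
  int i = qa + word, j = qb + word, off = 0;
  while (i < n && j < m) {
    sc += (a[i] == b[j] && a[i] < 4) ? match : mismatch;
    ++off;
    if (sc > best) { best = sc; br = off; }
    if (best - sc > xdrop) break;
    ++i; ++j;
  }
  sc = best;
  int bl = 0;
  i = qa - 1; j = qb - 1; off = 0;
  while (i >= 0 && j >= 0) {
    sc += (a[i] == b[j] && a[i] < 4) ? match : mismatch;
    ++off;
    if (sc > best) { best = sc; bl = off; }
    if (best - sc > xdrop) break;
    --i; --j;
  }
  Hit h;
  h.qs = qa - bl; h.qe = qa + word + br;
  h.ss = qb - bl; h.se = qb + word + br;
  h.minus = false;
  h.len = h.qe - h.qs;
  h.matches = 0;
  for (int k = 0; k < h.len; ++k)
    if (a[h.qs + k] == b[h.ss + k] && a[h.qs + k] < 4) ++h.matches;
  h.score = best;
  return h;
}

// kmer -> positions index (exact words only, no N)
std::unordered_map<uint32_t, std::vector<int>> kmer_index(
    const std::vector<int8_t>& s, int word) {
  std::unordered_map<uint32_t, std::vector<int>> idx;
  int n = (int)s.size();
  uint32_t key = 0, mask = (word < 16) ? ((1u << (2 * word)) - 1u) : 0xffffffffu;
  int run = 0;  // valid bases in current window
  for (int i = 0; i < n; ++i) {
    if (s[i] > 3) { run = 0; key = 0; continue; }
    key = ((key << 2) | (uint32_t)s[i]) & mask;
    if (++run >= word) idx[key].push_back(i - word + 1);
  }
  return idx;
}

}  // namespace

// [[Rcpp::export(name = ".self_align_cpp")]]
DataFrame self_align_cpp(std::string seq, int word = 12, double evalue_max = 1e-10,
                         int match = 1, int mismatch = -2, int xdrop = 100) {
  int L = (int)seq.size();
  std::vector<int8_t> fwd(L), rc(L);
  for (int i = 0; i < L; ++i) fwd[i] = (int8_t)base2code(seq[i]);
  for (int i = 0; i < L; ++i) {
    int8_t c = fwd[L - 1 - i];
    rc[i] = (c < 4) ? (int8_t)(3 - c) : (int8_t)4;
  }

  std::vector<Hit> hits;
  double logKmn = std::log(KA_K) + 2.0 * std::log((double)L);
  double min_score = (logKmn - std::log(evalue_max)) / KA_LAMBDA;

  {  // plus strand: pairs of occurrences of the same word, i < j
    auto idx = kmer_index(fwd, word);
    std::unordered_map<int64_t, std::pair<int, int>> seen;  // diag -> [qs,qe)
    for (auto& kv : idx) {
      const std::vector<int>& pos = kv.second;
      size_t m = pos.size();
      if (m < 2) continue;
      for (size_t a = 0; a + 1 < m; ++a) {
        for (size_t b = a + 1; b < m; ++b) {
          int qa = pos[a], qb = pos[b];
          int64_t diag = (int64_t)qb - qa;  // > 0, trivial self-diagonal never formed
          auto it = seen.find(diag);
          if (it != seen.end() && qa >= it->second.first && qa + word <= it->second.second)
            continue;
          Hit h = extend_seed(fwd, fwd, qa, qb, word, match, mismatch, xdrop);
          seen[diag] = std::make_pair(h.qs, h.qe);
          if (h.score >= min_score) hits.push_back(h);
        }
      }
    }
  }

  {  // minus strand: words of fwd vs words of reverse complement
    auto fidx = kmer_index(fwd, word);
    auto ridx = kmer_index(rc, word);
    std::unordered_map<int64_t, std::pair<int, int>> seen;
    for (auto& kv : fidx) {
      auto rit = ridx.find(kv.first);
      if (rit == ridx.end()) continue;
      for (int qa : kv.second) {
        for (int qr : rit->second) {
          int64_t diag = (int64_t)qr - qa;
          auto it = seen.find(diag);
          if (it != seen.end() && qa >= it->second.first && qa + word <= it->second.second)
            continue;
          Hit h = extend_seed(fwd, rc, qa, qr, word, match, mismatch, xdrop);
          seen[diag] = std::make_pair(h.qs, h.qe);
          if (h.score < min_score) continue;
          // map subject interval from rc coordinates back to the genome
          int ss = L - h.se, se = L - h.ss;
          h.ss = ss; h.se = se; h.minus = true;
          if (h.qs < h.ss || (h.qs == h.ss && h.qe <= h.se))  // canonical q <= s
            hits.push_back(h);
        }
      }
    }
  }

  // Chain co-diagonal hits separated by at most chain_gap nt into one hit
  // (X-drop trimming at score maxima otherwise fragments alignments of
  // palindromic elements whose diverged internal sequence scores poorly),
  // which also removes duplicate and nested hits on a diagonal.
  const int chain_gap = 50;
  std::sort(hits.begin(), hits.end(), [](const Hit& x, const Hit& y) {
    int64_t dx = x.minus ? (int64_t)x.qs + x.se : (int64_t)x.ss - x.qs;
    int64_t dy = y.minus ? (int64_t)y.qs + y.se : (int64_t)y.ss - y.qs;
    if (x.minus != y.minus) return !x.minus;
    if (dx != dy) return dx < dy;
    return x.qs < y.qs;
  });
  std::vector<Hit> out;
  out.reserve(hits.size());
  for (const Hit& h : hits) {
    if (!out.empty()) {
      Hit& c = out.back();
      int64_t dc = c.minus ? (int64_t)c.qs + c.se : (int64_t)c.ss - c.qs;
      int64_t dh = h.minus ? (int64_t)h.qs + h.se : (int64_t)h.ss - h.qs;
      if (c.minus == h.minus && dc == dh && h.qs <= c.qe + chain_gap) {
        if (h.qe > c.qe) {
          c.qe = h.qe;
          if (c.minus) c.ss = (int)(dc - c.qe); else c.se = (int)(c.qe + dc);
        }
        continue;
      }
    }
    out.push_back(h);
  }
  // recompute stats over the merged spans
  for (Hit& h : out) {
    h.len = h.qe - h.qs;
    h.matches = 0;
    double sc = 0;
    for (int k = 0; k < h.len; ++k) {
      int8_t aa = fwd[h.qs + k];
      int8_t bb = h.minus ? rc[(L - h.se) + k] : fwd[h.ss + k];
      bool eq = (aa == bb && aa < 4);
      if (eq) ++h.matches;
      sc += eq ? match : mismatch;
    }
    h.score = sc;
  }
  out.erase(std::remove_if(out.begin(), out.end(), [&](const Hit& h) {
    return h.score < min_score;
  }), out.end());

  int n = (int)out.size();
  IntegerVector qs(n), qe(n), ss(n), se(n);
  CharacterVector strand(n);
  NumericVector ident(n), ev(n), bits(n);
  for (int i = 0; i < n; ++i) {
    const Hit& h = out[i];
    qs[i] = h.qs; qe[i] = h.qe; ss[i] = h.ss; se[i] = h.se;
    strand[i] = h.minus ? "-" : "+";
    ident[i] = 100.0 * h.matches / h.len;
    double bit = (KA_LAMBDA * h.score - std::log(KA_K)) / std::log(2.0);
    bits[i] = bit;
    ev[i] = std::exp(logKmn - KA_LAMBDA * h.score);
  }
  return DataFrame::create(
      _["q_start"] = qs, _["q_end"] = qe, _["s_start"] = ss, _["s_end"] = se,
      _["strand"] = strand, _["identity_pct"] = ident, _["evalue"] = ev,
      _["bitscore"] = bits, _["stringsAsFactors"] = false);
}

// [[Rcpp::export(name = ".coverage_cpp")]]
IntegerVector coverage_cpp(IntegerVector q_start, IntegerVector q_end,
                           IntegerVector s_start, IntegerVector s_end, int L) {
  IntegerVector y(L);
  int n = q_start.size();
  for (int i = 0; i < n; ++i) {
    if (q_start[i] < 0 || q_end[i] > L || s_start[i] < 0 || s_end[i] > L)
      stop("alignment interval outside genome at hit %d", i + 1);
    for (int p = q_start[i]; p < q_end[i]; ++p) ++y[p];
    for (int p = s_start[i]; p < s_end[i]; ++p) ++y[p];
  }
  return y;
}
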