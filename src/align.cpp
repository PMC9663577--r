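#include <Rcpp.h>
#include <vector>
#include <string>
#include <cstdint>
using namespace Rcpp;

// Gotoh affine-gap alignment. Gap of length L costs gap_open + L * gap_ext,
// matching the Biostrings convention so scores cross-check directly.

static const int NEG_INF = -1000000000;

struct TraceResult {
  int score;
  int p_start, p_end, s_start, s_end; // 1-based inclusive
  std::string ap, as;                  // aligned strings with '-'
};

static inline int max3(int a, int b, int c) {
  int m = a > b ? a : b;
  return m > c ? m : c;
}

// Score-only local (Smith-Waterman) alignment; linear memory.
// [[Rcpp::export(name = ".sw_score")]]
int sw_score_cpp(std::string pattern, std::string subject,
                 int match, int mismatch, int gap_open, int gap_ext) {
  const int m = (int) pattern.size(), n = (int) subject.size();
  if (m == 0 || n == 0) return 0;
  std::vector<int> Hv(n + 1, 0), Ev(n + 1, NEG_INF);
  int *H = Hv.data(), *E = Ev.data();
  const char *sub = subject.data();
  int best = 0;
  const int go = gap_open + gap_ext, ge = gap_ext;
  for (int i = 1; i <= m; ++i) {
    int Hdiag = 0, Hleft = 0, F = NEG_INF;
    const char pc = pattern[i - 1];
    for (int j = 1; j <= n; ++j) {
      int e = E[j] - ge, e2 = H[j] - go;
      e = e > e2 ? e : e2;
      E[j] = e;
      int f1 = F - ge, f2 = Hleft - go;
      F = f1 > f2 ? f1 : f2;
      int h = Hdiag + (pc == sub[j - 1] ? match : -mismatch);
      if (e > h) h = e;
      if (F > h) h = F;
      if (h < 0) h = 0;
      Hdiag = H[j];
      H[j] = h;
      Hleft = h;
      if (h > best) best = h;
    }
  }
  return best;
}

// Do the two sequences share an exact k-mer (2-bit packed, k <= 15)?
// Non-ACGT characters break k-mer runs on both sides.
// [[Rcpp::export(name = ".shared_kmer")]]
bool shared_kmer_cpp(std::string a, std::string b, int k) {
  if ((int) a.size() < k || (int) b.size() < k) return false;
  auto code = [](char c) -> int {
    switch (c) {
      case 'A': case 'a': return 0;
      case 'C': case 'c': return 1;
      case 'G': case 'g': return 2;
      case 'T': case 't': return 3;
      default: return -1;
    }
  };
  const uint32_t mask = (k == 16) ? 0xFFFFFFFFu : ((1u << (2 * k)) - 1u);
  std::vector<bool> seen(mask + 1u, false);
  uint32_t kmer = 0; int run = 0;
  for (char c : a) {
    int v = code(c);
    if (v < 0) { run = 0; kmer = 0; continue; }
    kmer = ((kmer << 2) | (uint32_t) v) & mask;
    if (++run >= k) seen[kmer] = true;
  }
  kmer = 0; run = 0;
  for (char c : b) {
    int v = code(c);
    if (v < 0) { run = 0; kmer = 0; continue; }
    kmer = ((kmer << 2) | (uint32_t) v) & mask;
    if (++run >= k && seen[kmer]) return true;
  }
  return false;
}

// Full alignment with traceback. mode: 0 = local, 1 = global.
static TraceResult align_full(const std::string& pattern, const std::string& subject,
                              int match, int mismatch, int gap_open, int gap_ext,
                              int mode) {
  const int m = (int) pattern.size(), n = (int) subject.size();
  const int go = gap_open + gap_ext;
  const bool local = (mode == 0);
  // traceback codes per cell: 2 bits for H (0 stop,1 diag,2 up(E:gap in subject cols? ),3 left)
  // plus 1 bit each for E/F extension origin.
  std::vector<uint8_t> tb((size_t)(m + 1) * (n + 1), 0);
  std::vector<int> H(n + 1), E(n + 1);
  // row 0
  H[0] = 0; E[0] = NEG_INF;
  for (int j = 1; j <= n; ++j) {
    H[j] = local ? 0 : -(go + (j - 1) * gap_ext);
    E[j] = NEG_INF;
    if (!local) tb[(size_t)j] = 3; // left
  }
  int best = 0, bi = 0, bj = 0;
  for (int i = 1; i <= m; ++i) {
    int Hdiag = H[0];
    H[0] = local ? 0 : -(go + (i - 1) * gap_ext);
    int Hleft = H[0];
    int F = NEG_INF;
    if (!local) tb[(size_t)i * (n + 1)] = 2; // up
    const char pc = pattern[i - 1];
    for (int j = 1; j <= n; ++j) {
      size_t idx = (size_t)i * (n + 1) + j;
      uint8_t code = 0;
      // E: gap in pattern = move up (consume pattern char, gap in subject column)
      int e1 = E[j] - gap_ext, e2 = H[j] - go;
      if (e1 > e2) { E[j] = e1; code |= 4; } else { E[j] = e2; }
      // F: gap in subject = move left
      int f1 = F - gap_ext, f2 = Hleft - go;
      if (f1 > f2) { F = f1; code |= 8; } else { F = f2; }
      int diag = Hdiag + (pc == subject[j - 1] ? match : -mismatch);
      int h = diag; uint8_t dir = 1;
      if (E[j] > h) { h = E[j]; dir = 2; }
      if (F > h) { h = F; dir = 3; }
      if (local && h <= 0) { h = 0; dir = 0; }
      code |= dir;
      tb[idx] = code;
      Hdiag = H[j];
      H[j] = h; Hleft = h;
      if (local && h > best) { best = h; bi = i; bj = j; }
    }
  }
  TraceResult res;
  int ei, ej;
  if (local) {
    res.score = best; ei = bi; ej = bj;
    if (best == 0) { res.p_start = res.p_end = res.s_start = res.s_end = 0; return res; }
  } else {
    res.score = H[n]; ei = m; ej = n;
  }
  std::string ap, as;
  int i = ei, j = ej;
  while (i > 0 || j > 0) {
    uint8_t code = tb[(size_t)i * (n + 1) + j];
    uint8_t dir = code & 3;
    if (local && dir == 0) break;
    if (!local && i == 0) dir = 3;
    if (!local && j == 0) dir = 2;
    if (dir == 1) {
      ap.push_back(pattern[i - 1]); as.push_back(subject[j - 1]); --i; --j;
    } else if (dir == 2) {
      // gap run consuming pattern
      while (true) {
        uint8_t c2 = tb[(size_t)i * (n + 1) + j];
        ap.push_back(pattern[i - 1]); as.push_back('-'); --i;
        if (!(c2 & 4)) break;           // E came from H: run opened here
        if (i == 0) break;
      }
    } else if (dir == 3) {
      while (true) {
        uint8_t c2 = tb[(size_t)i * (n + 1) + j];
        ap.push_back('-'); as.push_back(subject[j - 1]); --j;
        if (!(c2 & 8)) break;
        if (j == 0) break;
      }
    } else break;
    if (local) {
      uint8_t nxt = tb[(size_t)i * (n + 1) + j];
      if ((nxt & 3) == 0) break;
    }
  }
  std::reverse(ap.begin(), ap.end());
  std::reverse(as.begin(), as.end());
  res.ap = ap; res.as = as;
  res.p_start = i + 1; res.p_end = ei;
  res.s_start = j + 1; res.s_end = ej;
  if (!local) { res.p_start = 1; res.s_start = 1; }
  return res;
}

static List trace_to_list(const TraceResult& r) {
  int cols = (int) r.ap.size();
  int matches = 0, mismatches = 0, gaps = 0;
  for (int k = 0; k < cols; ++k) {
    if (r.ap[k] == '-' || r.as[k] == '-') ++gaps;
    else if (r.ap[k] == r.as[k]) ++matches;
    else ++mismatches;
  }
  return List::create(
    _["score"] = r.score,
    _["pattern_start"] = r.p_start, _["pattern_end"] = r.p_end,
    _["subject_start"] = r.s_start, _["subject_end"] = r.s_end,
    _["aligned_pattern"] = r.ap, _["aligned_subject"] = r.as,
    _["length"] = cols, _["matches"] = matches,
    _["mismatches"] = mismatches, _["gaps"] = gaps);
}

// [[Rcpp::export(name = ".sw_align")]]
List sw_align_cpp(std::string pattern, std::string subject,
                  int match, int mismatch, int gap_open, int gap_ext) {
  TraceResult r = align_full(pattern, subject, match, mismatch, gap_open, gap_ext, 0);
  return trace_to_list(r);
}

// [[Rcpp::export(name = ".nw_align")]]
List nw_align_cpp(std::string pattern, std::string subject,
                  int match, int mismatch, int gap_open, int gap_ext) {
  TraceResult r = align_full(pattern, subject, match, mismatch, gap_open, gap_ext, 1);
  return trace_to_list(r);
}
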