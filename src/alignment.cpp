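#include <Rcpp.h>
#include <unordered_map>
#include <vector>
#include <cstdint>
using namespace Rcpp;

// Base encoding: A=0 C=1 G=2 T=3, N=4, anything else (incl. mask char '#')=5.
static inline int enc(char c) {
  switch (c) {
  case 'A': case 'a': return 0;
  case 'C': case 'c': return 1;
  case 'G': case 'g': return 2;
  case 'T': case 't': return 3;
  case 'N': case 'n': return 4;
  default: return 5;
  }
}

// N never counts as a match; mask characters forbid alignment across them.
static inline int subscore(int a, int b, int match, int mismatch) {
  if (a == 5 || b == 5) return -100000;
  if (a == b && a < 4) return match;
  return mismatch;
}

// Exact k-mer anchors between query and subject (forward orientation only;
// strand handling is done by the caller on the reverse-complemented query).
// K-mers containing non-ACGT are skipped. Returns 0-based start positions.
// [[Rcpp::export(name = ".kmer_seeds_cpp")]]
List kmer_seeds_cpp(std::string query, std::string subject, int k) {
  int m = query.size(), n = subject.size();
  std::vector<int> qpos, spos;
  if (k < 1 || k > 31 || m < k || n < k)
    return List::create(_["qpos"] = IntegerVector(0), _["spos"] = IntegerVector(0));
  std::unordered_map<uint64_t, std::vector<int> > idx;
  uint64_t key = 0, maskbits = (k == 32) ? ~0ULL : ((1ULL << (2 * k)) - 1);
  int run = 0;
  for (int i = 0; i < m; ++i) {
    int c = enc(query[i]);
    if (c > 3) { run = 0; key = 0; continue; }
    key = ((key << 2) | (uint64_t)c) & maskbits;
    if (++run >= k) idx[key].push_back(i - k + 1);
  }
  key = 0; run = 0;
  for (int j = 0; j < n; ++j) {
    int c = enc(subject[j]);
    if (c > 3) { run = 0; key = 0; continue; }
    key = ((key << 2) | (uint64_t)c) & maskbits;
    if (++run >= k) {
      std::unordered_map<uint64_t, std::vector<int> >::iterator it = idx.find(key);
      if (it != idx.end()) {
        for (size_t t = 0; t < it->second.size(); ++t) {
          qpos.push_back(it->second[t]);
          spos.push_back(j - k + 1);
        }
      }
    }
  }
  return List::create(_["qpos"] = wrap(qpos), _["spos"] = wrap(spos));
}

// Banded affine-gap Smith-Waterman with traceback. The band is expressed in
// diagonals d = j - i (subject index minus query index), dmin <= d <= dmax.
// A gap of length L costs gap_open + L * gap_ext (Biostrings convention).
// Returns the single best local alignment within the band; ties in the best
// score keep the cell first reached scanning rows then diagonals, and the
// traceback prefers diagonal moves, so the result is deterministic.
// [[Rcpp::export(name = ".sw_banded_cpp")]]
List sw_banded_cpp(std::string q, std::string s, int dmin, int dmax,
                   int match, int mismatch, int gap_open, int gap_ext) {
  const int NEG = -1000000000 / 2;
  int m = q.size(), n = s.size();
  if (m == 0 || n == 0) stop("empty sequence in alignment");
  if (dmin > dmax) stop("invalid band");
  if (dmin < -m) dmin = -m;
  if (dmax > n) dmax = n;
  long long W = (long long)dmax - dmin + 1;
  if ((long long)(m + 1) * W > 400000000LL) stop("alignment band too large");
  int Wi = (int)W;

  std::vector<int> qe(m), se(n);
  for (int i = 0; i < m; ++i) qe[i] = enc(q[i]);
  for (int j = 0; j < n; ++j) se[j] = enc(s[j]);

  // rolling rows for H, E, F; full byte matrix for traceback
  std::vector<int> Hprev(Wi, 0), Hcur(Wi, 0), Eprev(Wi, NEG), Ecur(Wi, NEG),
      Fprev(Wi, NEG), Fcur(Wi, NEG);
  // trace byte: bits 0-1 H origin (0 stop, 1 diag, 2 E, 3 F);
  // bit 2: E extends E; bit 3: F extends F
  std::vector<uint8_t> tr((size_t)(m + 1) * Wi, 0);

  int best = 0, bi = 0, bb = 0;
  // row i corresponds to having consumed i query chars (i = 1..m uses q[i-1])
  for (int b = 0; b < Wi; ++b) { Hprev[b] = 0; Eprev[b] = NEG; Fprev[b] = NEG; }
  for (int i = 1; i <= m; ++i) {
    for (int b = 0; b < Wi; ++b) { Hcur[b] = 0; Ecur[b] = NEG; Fcur[b] = NEG; }
    for (int b = 0; b < Wi; ++b) {
      int j = i + dmin + b;          // subject column (1-based consumed count)
      if (j < 1 || j > n) continue;
      // E: gap consuming subject (move j-1 -> j at same i)
      int e = NEG; uint8_t eext = 0;
      if (b >= 1) {
        int open = Hcur[b - 1] - gap_open - gap_ext;
        int ext  = Ecur[b - 1] - gap_ext;
        if (ext > open) { e = ext; eext = 4; } else e = open;
      }
      // F: gap consuming query (move i-1 -> i at same j => band col b+1 of prev row)
      int f = NEG; uint8_t fext = 0;
      if (b + 1 < Wi) {
        int open = Hprev[b + 1] - gap_open - gap_ext;
        int ext  = Fprev[b + 1] - gap_ext;
        if (ext > open) { f = ext; fext = 8; } else f = open;
      }
      int diag = Hprev[b] + subscore(qe[i - 1], se[j - 1], match, mismatch);
      int h = 0; uint8_t dir = 0;
      if (diag >= h) { h = diag; dir = 1; }
      if (e > h) { h = e; dir = 2; }
      if (f > h) { h = f; dir = 3; }
      if (h <= 0) { h = 0; dir = 0; }
      Hcur[b] = h; Ecur[b] = e; Fcur[b] = f;
      tr[(size_t)i * Wi + b] = (uint8_t)(dir | eext | fext);
      if (h > best) { best = h; bi = i; bb = b; }
    }
    std::swap(Hprev, Hcur); std::swap(Eprev, Ecur); std::swap(Fprev, Fcur);
  }

  if (best <= 0)
    return List::create(_["score"] = 0);

  // traceback
  int i = bi, b = bb;
  int j = i + dmin + b;
  int q1 = i, s1 = j;           // end (exclusive, since i,j are consumed counts)
  int matches = 0, cols = 0;
  int state = 0;                // 0 = in H, 1 = in E, 2 = in F
  while (i > 0 && j >= 0) {
    uint8_t t = tr[(size_t)i * Wi + b];
    if (state == 0) {
      int dir = t & 3;
      if (dir == 0) break;
      if (dir == 1) {
        ++cols;
        if (qe[i - 1] == se[j - 1] && qe[i - 1] < 4) ++matches;
        --i; --j;               // b unchanged on the diagonal
      } else if (dir == 2) state = 1;
      else state = 2;
    } else if (state == 1) {    // E: consumed subject char j
      ++cols; --j; --b;
      state = (t & 4) ? 1 : 0;
    } else {                    // F: consumed query char i
      ++cols; --i; ++b;
      state = (t & 8) ? 2 : 0;
    }
  }
  int q0 = i, s0 = j;
  return List::create(
    _["score"] = best, _["q0"] = q0, _["q1"] = q1, _["s0"] = s0, _["s1"] = s1,
    _["matches"] = matches, _["aln_len"] = cols);
}
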