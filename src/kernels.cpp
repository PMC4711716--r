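#include <Rcpp.h>
#include <algorithm>
#include <array>
#include <cstring>
#include <set>
#include <string>
#include <vector>

using namespace Rcpp;

// An 'N' (ambiguous base) never matches anything, not even another 'N'.
static inline bool base_match(char a, char b) {
  return a == b && a != 'N' && a != 'n';
}

// ---------------------------------------------------------------------------
// Suffix array
// ---------------------------------------------------------------------------

// Suffix array of s plus the empty (sentinel) suffix: a permutation of
// 0..n where n = nchar(s).  Plain comparison sort; genomes handled here are
// desk-scale so the O(n^2 log n) worst case is never approached in practice.
// [[Rcpp::export]]
IntegerVector sa_build_cpp(std::string s) {
  int n = (int)s.size();
  std::vector<int> idx(n + 1);
  for (int i = 0; i <= n; ++i) idx[i] = i;
  const char *p = s.c_str();
  std::sort(idx.begin(), idx.end(),
            [&](int a, int b) { return std::strcmp(p + a, p + b) < 0; });
  return IntegerVector(idx.begin(), idx.end());
}

// first/last suffix-array slot whose suffix starts with pat: [lo, hi)
static std::pair<int, int> sa_range_(const std::string &s,
                                     const IntegerVector &sa,
                                     const std::string &pat) {
  int n = sa.size();
  size_t m = pat.size();
  int lo = 0, hi = n;
  while (lo < hi) {
    int mid = (lo + hi) / 2;
    if (s.compare(sa[mid], m, pat) < 0) lo = mid + 1; else hi = mid;
  }
  int start = lo;
  hi = n;
  while (lo < hi) {
    int mid = (lo + hi) / 2;
    if (s.compare(sa[mid], m, pat) <= 0) lo = mid + 1; else hi = mid;
  }
  return std::make_pair(start, lo);
}

// All start positions of pat in s (exact, ascending).
// [[Rcpp::export]]
IntegerVector sa_find_cpp(std::string s, IntegerVector sa, std::string pat) {
  std::pair<int, int> r = sa_range_(s, sa, pat);
  std::vector<int> out;
  out.reserve(r.second - r.first);
  for (int t = r.first; t < r.second; ++t) out.push_back(sa[t]);
  std::sort(out.begin(), out.end());
  return IntegerVector(out.begin(), out.end());
}

// [[Rcpp::export]]
int count_occ_cpp(std::string s, IntegerVector sa, std::string pat) {
  std::pair<int, int> r = sa_range_(s, sa, pat);
  return r.second - r.first;
}

// ---------------------------------------------------------------------------
// Seed enumeration
// ---------------------------------------------------------------------------

// Every maximal exact match (read vs genome, this orientation only) of
// length >= min_len.  Anchored on read k-mers at every offset (scan_k <=
// min_len guarantees completeness: any match of length >= min_len contains
// a scan_k-mer at its first position), then extended maximally both ways.
// Columns: read_offset, genome_pos, length (all 0-based).
// [[Rcpp::export]]
IntegerMatrix mem_seeds_cpp(std::string g, IntegerVector sa, std::string read,
                            int min_len, int scan_k) {
  int rl = (int)read.size(), gl = (int)g.size();
  std::set<std::array<int, 3> > seen;
  for (int i = 0; i + scan_k <= rl; ++i) {
    std::string kmer = read.substr(i, scan_k);
    if (kmer.find('N') != std::string::npos) continue;
    std::pair<int, int> rg = sa_range_(g, sa, kmer);
    for (int t = rg.first; t < rg.second; ++t) {
      int p = sa[t];
      int ls = i, gs = p;
      while (ls > 0 && gs > 0 && base_match(read[ls - 1], g[gs - 1])) {
        --ls; --gs;
      }
      int le = i + scan_k, ge = p + scan_k;
      while (le < rl && ge < gl && base_match(read[le], g[ge])) {
        ++le; ++ge;
      }
      int len = le - ls;
      if (len >= min_len) {
        std::array<int, 3> m = {{ls, gs, len}};
        seen.insert(m);
      }
    }
  }
  IntegerMatrix out((int)seen.size(), 3);
  int r = 0;
  for (std::set<std::array<int, 3> >::const_iterator it = seen.begin();
       it != seen.end(); ++it, ++r) {
    out(r, 0) = (*it)[0]; out(r, 1) = (*it)[1]; out(r, 2) = (*it)[2];
  }
  return out;
}

// Exact occurrences of read k-mers sampled at stride k (non-overlapping).
// Columns: read_offset, genome_pos, length (== k).
// [[Rcpp::export]]
IntegerMatrix kmer_seeds_cpp(std::string g, IntegerVector sa, std::string read,
                             int k) {
  int rl = (int)read.size();
  std::vector<std::array<int, 3> > rows;
  for (int i = 0; i + k <= rl; i += k) {
    std::string kmer = read.substr(i, k);
    if (kmer.find('N') != std::string::npos) continue;
    std::pair<int, int> rg = sa_range_(g, sa, kmer);
    std::vector<int> pos;
    for (int t = rg.first; t < rg.second; ++t) pos.push_back(sa[t]);
    std::sort(pos.begin(), pos.end());
    for (size_t q = 0; q < pos.size(); ++q) {
      std::array<int, 3> m = {{i, pos[q], k}};
      rows.push_back(m);
    }
  }
  IntegerMatrix out((int)rows.size(), 3);
  for (int r = 0; r < (int)rows.size(); ++r) {
    out(r, 0) = rows[r][0]; out(r, 1) = rows[r][1]; out(r, 2) = rows[r][2];
  }
  return out;
}

// [[Rcpp::export]]
std::string revcomp_cpp(std::string s) {
  std::string out(s.rbegin(), s.rend());
  for (size_t i = 0; i < out.size(); ++i) {
    switch (out[i]) {
      case 'A': out[i] = 'T'; break;
      case 'C': out[i] = 'G'; break;
      case 'G': out[i] = 'C'; break;
      case 'T': out[i] = 'A'; break;
      case 'a': out[i] = 't'; break;
      case 'c': out[i] = 'g'; break;
      case 'g': out[i] = 'c'; break;
      case 't': out[i] = 'a'; break;
      default: out[i] = 'N';
    }
  }
  return out;
}

// ---------------------------------------------------------------------------
// Dynamic programming
// ---------------------------------------------------------------------------

static std::string rle_cigar(int lead_clip, const std::vector<char> &ops,
                             int tail_clip) {
  std::string cig;
  char buf[32];
  if (lead_clip > 0) {
    snprintf(buf, sizeof(buf), "%dS", lead_clip);
    cig += buf;
  }
  size_t i = 0;
  while (i < ops.size()) {
    size_t j = i;
    while (j < ops.size() && ops[j] == ops[i]) ++j;
    snprintf(buf, sizeof(buf), "%d%c", (int)(j - i), ops[i]);
    cig += buf;
    i = j;
  }
  if (tail_clip > 0) {
    snprintf(buf, sizeof(buf), "%dS", tail_clip);
    cig += buf;
  }
  return cig;
}

// Banded Smith-Waterman, affine gaps (a gap of length L costs
// gap_open + L * gap_extend; gap_open and gap_extend are negative).
// The band admits cells (i read chars, j ref chars) with
// band_lo <= j - i <= band_hi.  Traceback preference is diagonal, then
// gap-in-read (D), then gap-in-ref (I), making results deterministic.
// [[Rcpp::export]]
List local_align_cpp(std::string read, std::string ref, int match, int mismatch,
                     int gap_open, int gap_extend, int band_lo, int band_hi) {
  const int NEG = -(1 << 28);
  int L = (int)read.size(), W = (int)ref.size();
  std::vector<int> H((L + 1) * (W + 1), NEG);
  std::vector<int> E((L + 1) * (W + 1), NEG);
  std::vector<int> F((L + 1) * (W + 1), NEG);
  int stride = W + 1;
#define AT(i, j) ((i) * stride + (j))
  int best = 0, bi = -1, bj = -1;
  for (int j = 0; j <= W; ++j)
    if (j >= band_lo && j <= band_hi) H[AT(0, j)] = 0;
  for (int i = 1; i <= L; ++i) {
    int jlo = std::max(0, band_lo + i), jhi = std::min(W, band_hi + i);
    if (band_lo + i <= 0 && 0 <= band_hi + i) H[AT(i, 0)] = 0;
    for (int j = std::max(1, jlo); j <= jhi; ++j) {
      int e = NEG, f = NEG;
      if (j - 1 - i >= band_lo) {  // (i, j-1) in band
        int ho = H[AT(i, j - 1)], eo = E[AT(i, j - 1)];
        if (ho > NEG) e = ho + gap_open + gap_extend;
        if (eo > NEG && eo + gap_extend > e) e = eo + gap_extend;
      }
      if (j - (i - 1) <= band_hi) {  // (i-1, j) in band
        int ho = H[AT(i - 1, j)], fo = F[AT(i - 1, j)];
        if (ho > NEG) f = ho + gap_open + gap_extend;
        if (fo > NEG && fo + gap_extend > f) f = fo + gap_extend;
      }
      int diag = NEG;
      int hd = H[AT(i - 1, j - 1)];
      if (hd > NEG)
        diag = hd + (base_match(read[i - 1], ref[j - 1]) ? match : mismatch);
      int h = 0;
      if (diag > h) h = diag;
      if (e > h) h = e;
      if (f > h) h = f;
      E[AT(i, j)] = e;
      F[AT(i, j)] = f;
      H[AT(i, j)] = h;
      if (h > best) { best = h; bi = i; bj = j; }
    }
  }
  std::string cigar;
  int ref_start = -1, read_start = -1, read_end = -1, ref_end = -1;
  int n_m = 0, matches = 0, edits = 0;
  if (best > 0) {
    std::vector<char> ops;
    int i = bi, j = bj;
    char state = 'H';
    while (true) {
      if (state == 'H') {
        int h = H[AT(i, j)];
        if (h == 0) break;
        int diag = NEG;
        if (i > 0 && j > 0 && H[AT(i - 1, j - 1)] > NEG)
          diag = H[AT(i - 1, j - 1)] +
                 (base_match(read[i - 1], ref[j - 1]) ? match : mismatch);
        if (diag == h) {
          ops.push_back('M');
          ++n_m;
          if (base_match(read[i - 1], ref[j - 1])) ++matches; else ++edits;
          --i; --j;
        } else if (E[AT(i, j)] == h) {
          state = 'E';
        } else {
          state = 'F';
        }
      } else if (state == 'E') {
        ops.push_back('D');
        ++edits;
        int cur = E[AT(i, j)];
        int eo = (j > 1) ? E[AT(i, j - 1)] : NEG;
        --j;
        state = (eo > NEG && cur == eo + gap_extend) ? 'E' : 'H';
      } else {
        ops.push_back('I');
        ++edits;
        int cur = F[AT(i, j)];
        int fo = (i > 1) ? F[AT(i - 1, j)] : NEG;
        --i;
        state = (fo > NEG && cur == fo + gap_extend) ? 'F' : 'H';
      }
    }
    ref_start = j;
    read_start = i;
    read_end = bi;
    ref_end = bj;
    std::reverse(ops.begin(), ops.end());
    cigar = rle_cigar(i, ops, L - bi);
  }
#undef AT
  return List::create(
      _["score"] = best, _["ref_start"] = ref_start, _["ref_end"] = ref_end,
      _["read_start"] = read_start, _["read_end"] = read_end,
      _["cigar"] = cigar, _["aligned"] = n_m, _["matches"] = matches,
      _["edits"] = edits);
}

// Banded semi-global ("infix") alignment: the whole read is aligned
// end-to-end, the reference window contributes free leading/trailing gaps.
// The objective is the unit-cost edit distance; the affine score of the
// resulting alignment is reported alongside for record keeping.
// [[Rcpp::export]]
List semiglobal_align_cpp(std::string read, std::string ref, int band_lo,
                          int band_hi, int match, int mismatch, int gap_open,
                          int gap_extend) {
  const int INF = 1 << 28;
  int L = (int)read.size(), W = (int)ref.size();
  std::vector<int> D((L + 1) * (W + 1), INF);
  int stride = W + 1;
#define AT(i, j) ((i) * stride + (j))
  for (int j = 0; j <= W; ++j)
    if (j >= band_lo && j <= band_hi) D[AT(0, j)] = 0;
  for (int i = 1; i <= L; ++i) {
    int jlo = std::max(0, band_lo + i), jhi = std::min(W, band_hi + i);
    for (int j = jlo; j <= jhi; ++j) {
      int v = INF;
      if (j > 0 && D[AT(i - 1, j - 1)] < INF) {
        int c = D[AT(i - 1, j - 1)] +
                (base_match(read[i - 1], ref[j - 1]) ? 0 : 1);
        if (c < v) v = c;
      }
      if (D[AT(i - 1, j)] < INF && D[AT(i - 1, j)] + 1 < v)
        v = D[AT(i - 1, j)] + 1;  // read char vs gap (I)
      if (j > 0 && D[AT(i, j - 1)] < INF && D[AT(i, j - 1)] + 1 < v)
        v = D[AT(i, j - 1)] + 1;  // ref char vs gap (D)
      D[AT(i, j)] = v;
    }
  }
  int bestj = -1, beste = INF;
  for (int j = 0; j <= W; ++j) {
    if (D[AT(L, j)] < beste) { beste = D[AT(L, j)]; bestj = j; }
  }
  if (beste >= INF) {
    return List::create(_["score"] = NA_INTEGER, _["ref_start"] = -1,
                        _["ref_end"] = -1, _["cigar"] = "",
                        _["edits"] = NA_INTEGER, _["matches"] = 0);
  }
  // traceback: diagonal preferred, then read-gap, then ref-gap
  std::vector<char> ops;
  int i = L, j = bestj, matches = 0, mism = 0;
  while (i > 0) {
    int cur = D[AT(i, j)];
    int diag = (j > 0 && D[AT(i - 1, j - 1)] < INF)
                   ? D[AT(i - 1, j - 1)] +
                         (base_match(read[i - 1], ref[j - 1]) ? 0 : 1)
                   : INF;
    if (diag == cur) {
      ops.push_back('M');
      if (base_match(read[i - 1], ref[j - 1])) ++matches; else ++mism;
      --i; --j;
    } else if (D[AT(i - 1, j)] < INF && D[AT(i - 1, j)] + 1 == cur) {
      ops.push_back('I');
      --i;
    } else {
      ops.push_back('D');
      --j;
    }
  }
  int ref_start = j;
  std::reverse(ops.begin(), ops.end());
  // affine score of this alignment under the supplied scoring scheme
  int score = matches * match + mism * mismatch;
  size_t q = 0;
  while (q < ops.size()) {
    size_t r = q;
    while (r < ops.size() && ops[r] == ops[q]) ++r;
    if (ops[q] == 'I' || ops[q] == 'D')
      score += gap_open + (int)(r - q) * gap_extend;
    q = r;
  }
  std::string cigar = rle_cigar(0, ops, 0);
#undef AT
  return List::create(_["score"] = score, _["ref_start"] = ref_start,
                      _["ref_end"] = bestj, _["cigar"] = cigar,
                      _["edits"] = beste, _["matches"] = matches);
}
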