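#include <Rcpp.h>
#include <algorithm>
#include <cstdint>
#include <string>
#include <vector>

using namespace Rcpp;

namespace {

inline bool in_set(char c, const std::string& set) {
  return set.find(c) != std::string::npos;
}

struct Hit {
  int idx;    // subpattern index, 0-based
  int start;  // 0-based inclusive
  int end;    // 0-based exclusive
  int edits;
};

// Semi-global edit-distance scan of one pattern over a text.
//
// d(i, 0) = 0 (a match may start anywhere), d(0, j) = j (pattern characters
// matched against nothing each cost one edit), and the usual unit-cost
// insertion / deletion / substitution transition; adjacent transpositions
// cost one edit when `osa` is set (restricted Damerau-Levenshtein: each
// character takes part in at most one transposition).  For every text end
// position i with d(i, |P|) <= k one hit is emitted whose start index is
// recovered by carrying alignment start points forward with move preference
// diagonal > vertical (consume text) > horizontal (consume pattern) >
// transposition, which selects the longest text span among minimal-edit
// alignments.
//
// With `cutoff`, Ukkonen's cutoff restricts each column to the rows that can
// still be within budget k; results are identical to the full DP because
// every cell with value <= k (and every cell on a reported traceback path)
// is still computed.  Rows skipped by the cutoff are stored as a sentinel
// larger than any reachable distance.
//
// Overlap flags let pattern characters hang past a text boundary at zero
// cost, keeping at least `min_ov` pattern characters inside the text.
//
// `anchored` constrains every alignment to start at text position 0
// (d(i, 0) = i instead of 0): used when a pattern's start is pinned by the
// greedy line matcher.  Reported starts are then always 0.
void edit_scan(const std::string& P, const std::string& T, int k, bool osa,
               bool ov_start, bool ov_end, int min_ov,
               const std::string& wild, bool cutoff, bool anchored, int idx,
               std::vector<Hit>& hits) {
  const int m = static_cast<int>(P.size());
  const int n = static_cast<int>(T.size());
  const int BIG = m + n + 5;

  std::vector<int> dp2(m + 1, BIG), dp(m + 1), dc(m + 1, BIG);
  std::vector<int> sp2(m + 1, 0), sp(m + 1), sc(m + 1, 0);

  // column i = 0
  for (int j = 0; j <= m; ++j) {
    int v = j;
    if (ov_start && (m - j) >= min_ov) v = 0;
    dp[j] = v;
    sp[j] = 0;
  }
  {
    int ed = dp[m], st = sp[m];
    if (ov_end && n == 0) {
      for (int j = m - 1; j >= min_ov; --j)
        if (dp[j] < ed) { ed = dp[j]; st = sp[j]; }
    }
    if (ed <= k) hits.push_back(Hit{idx, st, 0, ed});
  }

  int lact = m;
  if (cutoff) {
    lact = 0;
    for (int j = m; j >= 0; --j)
      if (dp[j] <= k) { lact = j; break; }
  }

  for (int i = 1; i <= n; ++i) {
    const char tc = T[i - 1];
    const bool tw = in_set(tc, wild);
    const int jmax = cutoff ? std::min(m, lact + (osa ? 2 : 1)) : m;

    dc[0] = anchored ? i : 0;
    sc[0] = anchored ? 0 : i;
    for (int j = 1; j <= jmax; ++j) {
      const char pc = P[j - 1];
      const bool mt = (pc == tc) || tw || in_set(pc, wild);
      int best = dp[j - 1] + (mt ? 0 : 1);  // diagonal
      int bs = sp[j - 1];
      const int vert = dp[j] + 1;           // consume text
      if (vert < best) { best = vert; bs = sp[j]; }
      const int horiz = dc[j - 1] + 1;      // consume pattern
      if (horiz < best) { best = horiz; bs = sc[j - 1]; }
      if (osa && i >= 2 && j >= 2) {
        const char pc2 = P[j - 2];
        const char tc2 = T[i - 2];
        const bool tw2 = in_set(tc2, wild);
        const bool cross = ((pc == tc2) || tw2 || in_set(pc, wild)) &&
                           ((pc2 == tc) || tw || in_set(pc2, wild));
        if (cross) {
          const int tr = dp2[j - 2] + 1;
          if (tr < best) { best = tr; bs = sp2[j - 2]; }
        }
      }
      dc[j] = best;
      sc[j] = bs;
    }
    for (int j = jmax + 1; j <= m; ++j) dc[j] = BIG;

    if (cutoff) {
      int nl = jmax;
      while (nl > 0 && dc[nl] > k) --nl;
      lact = nl;
      // anchored + no transpositions: once a whole column is over budget
      // every later column is too (diagonal monotonicity), so stop early
      if (anchored && !osa && nl == 0 && dc[0] > k) break;
    }

    int ed = dc[m], st = sc[m];
    if (ov_end && i == n) {
      for (int j = m - 1; j >= min_ov; --j)
        if (dc[j] < ed) { ed = dc[j]; st = sc[j]; }
    }
    if (ed <= k) hits.push_back(Hit{idx, st, i, ed});

    dp2.swap(dp);
    dp.swap(dc);
    sp2.swap(sp);
    sp.swap(sc);
  }
}

// Bit-parallel Hamming scan (Bitap with k+1 state vectors, shift-and
// orientation).  Masks are split into ceil(|P| / word_width) machine words;
// bit j of state vector R_d is set after consuming text position i iff
// P[0..j] aligns against T[i-j..i] with at most d mismatches.  Wildcard
// characters (in pattern or text) match for free.
void bitap_scan(const std::string& P, const std::string& T, int k,
                int width, const std::string& wild, int idx,
                std::vector<Hit>& hits) {
  const int m = static_cast<int>(P.size());
  const int n = static_cast<int>(T.size());
  const int W = (m + width - 1) / width;
  const uint64_t WMASK =
      (width == 64) ? ~0ULL : ((1ULL << width) - 1ULL);

  std::vector<uint64_t> mask(256ULL * W, 0ULL);
  std::vector<uint64_t> ones(W, 0ULL);
  for (int j = 0; j < m; ++j) {
    const int w = j / width;
    const uint64_t b = 1ULL << (j % width);
    ones[w] |= b;
    if (in_set(P[j], wild)) {
      for (int c = 0; c < 256; ++c) mask[static_cast<size_t>(c) * W + w] |= b;
    } else {
      const unsigned char c = static_cast<unsigned char>(P[j]);
      mask[static_cast<size_t>(c) * W + w] |= b;
    }
  }

  std::vector<uint64_t> R(static_cast<size_t>(k + 1) * W, 0ULL);
  std::vector<uint64_t> Rn(R.size());
  const int mb_w = (m - 1) / width;
  const uint64_t mb_bit = 1ULL << ((m - 1) % width);

  for (int i = 1; i <= n; ++i) {
    const unsigned char c = static_cast<unsigned char>(T[i - 1]);
    const uint64_t* mc =
        in_set(T[i - 1], wild) ? ones.data() : &mask[static_cast<size_t>(c) * W];
    for (int d = 0; d <= k; ++d) {
      uint64_t carry = 1ULL;
      for (int w = 0; w < W; ++w) {
        const uint64_t x = R[static_cast<size_t>(d) * W + w];
        Rn[static_cast<size_t>(d) * W + w] = (((x << 1) | carry) & WMASK) & mc[w];
        carry = (x >> (width - 1)) & 1ULL;
      }
      if (d > 0) {
        uint64_t carry2 = 1ULL;
        for (int w = 0; w < W; ++w) {
          const uint64_t x = R[static_cast<size_t>(d - 1) * W + w];
          Rn[static_cast<size_t>(d) * W + w] |= ((x << 1) | carry2) & WMASK;
          carry2 = (x >> (width - 1)) & 1ULL;
        }
      }
    }
    R.swap(Rn);
    for (int d = 0; d <= k; ++d) {
      if (R[static_cast<size_t>(d) * W + mb_w] & mb_bit) {
        hits.push_back(Hit{idx, i - m, i, d});
        break;
      }
    }
  }
}

// n-gram elimination.  A subpattern may be dropped only when the q-gram
// argument applies: |P| > (k+1)(n-1)+k, neither the subpattern nor the text
// contains a wildcard character, and none of the subpattern's n-grams occurs
// in the text.  Everything else survives.
std::vector<bool> ngram_keep(const std::vector<std::string>& pats,
                             const std::string& text, int k, int n,
                             const std::string& wild) {
  bool text_wild = false;
  for (char c : text)
    if (in_set(c, wild)) { text_wild = true; break; }

  std::vector<bool> keep(pats.size(), true);
  if (n < 1 || text_wild) return keep;

  for (size_t p = 0; p < pats.size(); ++p) {
    const std::string& P = pats[p];
    const int m = static_cast<int>(P.size());
    if (m <= (k + 1) * (n - 1) + k) continue;
    bool pat_wild = false;
    for (char c : P)
      if (in_set(c, wild)) { pat_wild = true; break; }
    if (pat_wild) continue;
    bool found = false;
    for (int a = 0; a + n <= m && !found; ++a)
      if (text.find(P.substr(a, n)) != std::string::npos) found = true;
    keep[p] = found;
  }
  return keep;
}

IntegerMatrix hits_matrix(const std::vector<Hit>& hits, bool with_idx) {
  const int nr = static_cast<int>(hits.size());
  IntegerMatrix out(nr, with_idx ? 4 : 3);
  for (int r = 0; r < nr; ++r) {
    int c = 0;
    if (with_idx) out(r, c++) = hits[r].idx;
    out(r, c++) = hits[r].start;
    out(r, c++) = hits[r].end;
    out(r, c) = hits[r].edits;
  }
  colnames(out) = with_idx
      ? CharacterVector::create("idx", "start", "end", "edits")
      : CharacterVector::create("start", "end", "edits");
  return out;
}

}  // namespace

// [[Rcpp::export]]
IntegerMatrix cpp_edit_search(std::string pattern, std::string text, int k,
                              bool transpositions, bool overlap_start,
                              bool overlap_end, int min_overlap,
                              std::string wildcards, bool cutoff,
                              bool anchored = false) {
  std::vector<Hit> hits;
  edit_scan(pattern, text, k, transpositions, overlap_start, overlap_end,
            min_overlap, wildcards, cutoff, anchored, 0, hits);
  return hits_matrix(hits, false);
}

// [[Rcpp::export]]
IntegerMatrix cpp_bitap_search(std::string pattern, std::string text, int k,
                               int word_width, std::string wildcards) {
  std::vector<Hit> hits;
  bitap_scan(pattern, text, k, word_width, wildcards, 0, hits);
  return hits_matrix(hits, false);
}

// [[Rcpp::export]]
LogicalVector cpp_ngram_survivors(std::vector<std::string> patterns,
                                  std::string text, int k, int n,
                                  std::string wildcards) {
  std::vector<bool> keep = ngram_keep(patterns, text, k, n, wildcards);
  return LogicalVector(keep.begin(), keep.end());
}

// Search every surviving subpattern of a fuzzy pattern in one call.
// metric: 0 = hamming (Bitap), 1 = levenshtein, 2 = damerau (restricted).
// ngram_n = 0 disables the elimination filter.  Rows are ordered by
// ascending end, then ascending edits, then ascending subpattern index.
// [[Rcpp::export]]
IntegerMatrix cpp_multi_search(std::vector<std::string> patterns,
                               std::string text, int k, int metric,
                               int ngram_n, bool overlap_start,
                               bool overlap_end, int min_overlap,
                               int word_width, std::string wildcards,
                               bool cutoff, bool anchored = false) {
  std::vector<bool> keep =
      ngram_keep(patterns, text, k, ngram_n, wildcards);
  std::vector<Hit> hits;
  for (size_t p = 0; p < patterns.size(); ++p) {
    if (!keep[p]) continue;
    if (metric == 0) {
      if (anchored) {
        // the only window starting at 0 is T[0..|P|)
        const std::string& P = patterns[p];
        const int m = static_cast<int>(P.size());
        if (m <= static_cast<int>(text.size())) {
          int mm = 0;
          for (int j = 0; j < m && mm <= k; ++j) {
            if (P[j] != text[j] && !in_set(P[j], wildcards) &&
                !in_set(text[j], wildcards)) ++mm;
          }
          if (mm <= k) hits.push_back(Hit{static_cast<int>(p), 0, m, mm});
        }
      } else {
        bitap_scan(patterns[p], text, k, word_width, wildcards,
                   static_cast<int>(p), hits);
      }
    } else {
      edit_scan(patterns[p], text, k, metric == 2, overlap_start,
                overlap_end, min_overlap, wildcards, cutoff, anchored,
                static_cast<int>(p), hits);
    }
  }
  std::sort(hits.begin(), hits.end(), [](const Hit& a, const Hit& b) {
    if (a.end != b.end) return a.end < b.end;
    if (a.edits != b.edits) return a.edits < b.edits;
    return a.idx < b.idx;
  });
  return hits_matrix(hits, true);
}
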