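#include <Rcpp.h>
#include <vector>
#include <string>
#include <unordered_map>
#include <algorithm>
#include <cstdint>
#include <cstring>
#include <functional>

using namespace Rcpp;

// Banded global Needleman-Wunsch with linear gap penalty.
// band < 0 runs the full matrix. With band >= 0 the search is restricted to
// |j - i| in [-band, (m - n) + band] (after ensuring n <= m), which is exact
// whenever the optimal path stays inside the band -- guaranteed here only
// for the near-diagonal, high-identity comparisons the callers use it for.
// Traceback ties break diagonal > up > left for reproducibility.
struct NwResult {
  std::string a, b;
  double score;
  int matches, columns, both;
};

static NwResult nw_core(const std::string &sa, const std::string &sb,
                        double match, double mismatch, double gap, int band) {
  bool swapped = sa.size() > sb.size();
  const std::string &a = swapped ? sb : sa;
  const std::string &b = swapped ? sa : sb;
  const int n = a.size(), m = b.size();
  int wl, wr;
  if (band < 0) { wl = n; wr = m; }
  else { wl = std::min(band, n); wr = std::min(m, (m - n) + band); }
  const int W = wl + wr + 1;  // row storage: offset = j - i + wl in [0, W)
  const double NEG = -1e300;
  std::vector<double> prev(W, NEG), cur(W, NEG);
  std::vector<uint8_t> tb((size_t)(n + 1) * W, 255);
  // row 0: j in [0, wr]
  for (int j = 0; j <= std::min(m, wr); ++j) {
    prev[j + wl] = j * gap;
    tb[j + wl] = 2;
  }
  for (int i = 1; i <= n; ++i) {
    std::fill(cur.begin(), cur.end(), NEG);
    const int jlo = std::max(0, i - wl), jhi = std::min(m, i + wr);
    const char ai = a[i - 1];
    uint8_t *tbrow = &tb[(size_t)i * W];
    for (int j = jlo; j <= jhi; ++j) {
      const int off = j - i + wl;
      double best = NEG; uint8_t code = 255;
      if (j > 0) {
        double sdiag = prev[off] + (ai == b[j - 1] ? match : mismatch);
        if (sdiag > best) { best = sdiag; code = 0; }
      } else if (i > 0) {
        // j == 0 column: only gaps in b
      }
      if (off + 1 < W && prev[off + 1] > NEG / 2) {
        double sup = prev[off + 1] + gap;
        if (sup > best) { best = sup; code = 1; }
      }
      if (off - 1 >= 0 && cur[off - 1] > NEG / 2) {
        double sleft = cur[off - 1] + gap;
        if (sleft > best) { best = sleft; code = 2; }
      }
      if (i > 0 && j == 0) { best = i * gap; code = 1; }
      cur[off] = best;
      tbrow[off] = code;
    }
    std::swap(prev, cur);
  }
  NwResult res;
  res.score = prev[m - n + wl];
  std::string ra, rb;
  ra.reserve(n + m); rb.reserve(n + m);
  int i = n, j = m, matches = 0, cols = 0, both = 0;
  while (i > 0 || j > 0) {
    uint8_t code = tb[(size_t)i * W + (j - i + wl)];
    if (code == 0) {
      ra.push_back(a[i - 1]); rb.push_back(b[j - 1]);
      if (a[i - 1] == b[j - 1]) ++matches;
      ++both; --i; --j;
    } else if (code == 1) {
      ra.push_back(a[i - 1]); rb.push_back('-');
      --i;
    } else {
      ra.push_back('-'); rb.push_back(b[j - 1]);
      --j;
    }
    ++cols;
  }
  std::reverse(ra.begin(), ra.end());
  std::reverse(rb.begin(), rb.end());
  res.a = swapped ? rb : ra;
  res.b = swapped ? ra : rb;
  res.matches = matches; res.columns = cols; res.both = both;
  return res;
}

// [[Rcpp::export]]
List nw_align_cpp(std::string a, std::string b,
                  double match, double mismatch, double gap, int band = -1) {
  NwResult r = nw_core(a, b, match, mismatch, gap, band);
  return List::create(
    _["aligned_a"] = r.a, _["aligned_b"] = r.b, _["score"] = r.score,
    _["matches"] = r.matches, _["columns"] = r.columns,
    _["both_aligned"] = r.both);
}

// Single-linkage components under identity/coverage thresholds.
// Pairs are processed in input order; a pair already inside one component
// is skipped without alignment (cannot change the components). Returns the
// 1-based component root of every gene.
// [[Rcpp::export]]
IntegerVector cluster_components_cpp(CharacterVector seqs, IntegerMatrix pairs,
                                     double min_identity, double min_coverage,
                                     double match, double mismatch, double gap,
                                     int band = -1) {
  const int n = seqs.size();
  std::vector<int> parent(n);
  for (int i = 0; i < n; ++i) parent[i] = i;
  std::function<int(int)> find = [&](int x) {
    while (parent[x] != x) { parent[x] = parent[parent[x]]; x = parent[x]; }
    return x;
  };
  std::vector<std::string> sv(n);
  for (int i = 0; i < n; ++i) sv[i] = as<std::string>(seqs[i]);
  for (int r = 0; r < pairs.nrow(); ++r) {
    int i = pairs(r, 0) - 1, j = pairs(r, 1) - 1;
    int ri = find(i), rj = find(j);
    if (ri == rj) continue;
    NwResult al = nw_core(sv[i], sv[j], match, mismatch, gap, band);
    double idn = 100.0 * al.matches / al.columns;
    double cov = 100.0 * al.both /
      std::min(sv[i].size(), sv[j].size());
    if (idn >= min_identity && cov >= min_coverage)
      parent[std::max(ri, rj)] = std::min(ri, rj);
  }
  IntegerVector root(n);
  for (int i = 0; i < n; ++i) root[i] = find(i) + 1;
  return root;
}

static inline int enc(char c) {
  switch (c) {
    case 'A': case 'a': return 0;
    case 'C': case 'c': return 1;
    case 'G': case 'g': return 2;
    case 'T': case 't': return 3;
  }
  return -1;
}

// Candidate gene pairs sharing >= min_shared identical k-mers at identical
// positions (positions sampled every `stride` bases). Exploits the fact that
// homologous family members are positionally aligned (no-indel sequences);
// a heuristic prefilter, not an exact similarity search.
// [[Rcpp::export]]
IntegerMatrix kmer_candidate_pairs_cpp(CharacterVector seqs, int k,
                                       int stride, int min_shared) {
  const int n = seqs.size();
  std::unordered_map<uint64_t, std::vector<int> > buckets;
  buckets.reserve((size_t)n * 64);
  for (int g = 0; g < n; ++g) {
    const char *s = CHAR(STRING_ELT(seqs, g));
    int L = LENGTH(STRING_ELT(seqs, g));
    for (int pos = 0; pos + k <= L; pos += stride) {
      uint64_t key = 0; bool ok = true;
      for (int t = 0; t < k; ++t) {
        int e = enc(s[pos + t]);
        if (e < 0) { ok = false; break; }
        key = (key << 2) | (uint64_t)e;
      }
      if (!ok) continue;
      key |= ((uint64_t)(pos / stride)) << (2 * k);
      buckets[key].push_back(g);
    }
  }
  std::unordered_map<uint64_t, int> counts;
  counts.reserve((size_t)n * 16);
  for (auto &kv : buckets) {
    std::vector<int> &v = kv.second;
    if (v.size() < 2 || v.size() > 4096) continue;
    for (size_t x = 0; x + 1 < v.size(); ++x)
      for (size_t y = x + 1; y < v.size(); ++y) {
        int i = v[x], j = v[y];
        if (i == j) continue;
        uint64_t pk = ((uint64_t)std::min(i, j) << 32) | (uint64_t)std::max(i, j);
        ++counts[pk];
      }
  }
  std::vector<std::pair<uint64_t, int> > keep;
  for (auto &kv : counts)
    if (kv.second >= min_shared) keep.push_back(kv);
  std::sort(keep.begin(), keep.end());
  IntegerMatrix out(keep.size(), 3);
  for (size_t r = 0; r < keep.size(); ++r) {
    out(r, 0) = (int)(keep[r].first >> 32) + 1;
    out(r, 1) = (int)(keep[r].first & 0xffffffffULL) + 1;
    out(r, 2) = keep[r].second;
  }
  colnames(out) = CharacterVector::create("i", "j", "shared");
  return out;
}
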