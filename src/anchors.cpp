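#include <Rcpp.h>
#include <cstdint>
#include <vector>
#include <algorithm>
#include <unordered_map>
using namespace Rcpp;

// 2-bit base codes; -1 marks anything outside ACGT (incl. the chromosome
// separator), which terminates both k-mer windows and anchor extension.
static inline int base_code(char c) {
  switch (c) {
  case 'A': case 'a': return 0;
  case 'C': case 'c': return 1;
  case 'G': case 'g': return 2;
  case 'T': case 't': return 3;
  default: return -1;
  }
}
static inline int comp_code(int c) { return c < 0 ? -1 : 3 - c; }

struct Seedmer { uint64_t kmer; int64_t pos; bool fwd_is_canonical; };

// canonical k-mers occurring exactly once in the sequence
static std::vector<Seedmer> unique_kmers(const std::vector<int>& s, int k) {
  const uint64_t mask = (k == 32) ? ~0ULL : ((1ULL << (2 * k)) - 1);
  std::vector<Seedmer> all;
  all.reserve(s.size());
  uint64_t fwd = 0, rc = 0;
  int run = 0;
  for (size_t i = 0; i < s.size(); ++i) {
    int c = s[i];
    if (c < 0) { run = 0; fwd = 0; rc = 0; continue; }
    fwd = ((fwd << 2) | (uint64_t)c) & mask;
    rc = (rc >> 2) | ((uint64_t)(3 - c) << (2 * (k - 1)));
    if (++run >= k) {
      bool fc = fwd <= rc;
      all.push_back({fc ? fwd : rc, (int64_t)(i + 1 - k), fc});
    }
  }
  std::sort(all.begin(), all.end(),
            [](const Seedmer& a, const Seedmer& b) { return a.kmer < b.kmer; });
  std::vector<Seedmer> uniq;
  size_t i = 0;
  while (i < all.size()) {
    size_t j = i;
    while (j + 1 < all.size() && all[j + 1].kmer == all[i].kmer) ++j;
    if (j == i) uniq.push_back(all[i]);
    i = j + 1;
  }
  return uniq;  // sorted by kmer
}

struct Anchor { int64_t rs, re, qs, qe; bool plus; };

// Maximal exact matches seeded at k-mers unique in both sequences.
// Sequences arrive as single strings with chromosomes joined by 'N'.
// [[Rcpp::export(name = ".anchors_cpp")]]
DataFrame anchors_cpp(std::string ref, std::string query, int k) {
  if (k < 15 || k > 31) stop("k must be in [15, 31]");
  std::vector<int> r(ref.size()), q(query.size());
  for (size_t i = 0; i < ref.size(); ++i) r[i] = base_code(ref[i]);
  for (size_t i = 0; i < query.size(); ++i) q[i] = base_code(query[i]);

  std::vector<Seedmer> ur = unique_kmers(r, k), uq = unique_kmers(q, k);

  // merge-join on canonical kmer value
  struct Seed { int64_t rp, qp; bool plus; };
  std::vector<Seed> seeds;
  size_t i = 0, j = 0;
  while (i < ur.size() && j < uq.size()) {
    if (ur[i].kmer < uq[j].kmer) ++i;
    else if (uq[j].kmer < ur[i].kmer) ++j;
    else {
      seeds.push_back({ur[i].pos, uq[j].pos,
                       ur[i].fwd_is_canonical == uq[j].fwd_is_canonical});
      ++i; ++j;
    }
  }

  // Process seeds in diagonal order so seeds inside an already-extended
  // maximal match are skipped in O(1): per-diagonal furthest ref end.
  std::sort(seeds.begin(), seeds.end(), [](const Seed& a, const Seed& b) {
    if (a.plus != b.plus) return a.plus > b.plus;
    int64_t da = a.plus ? a.rp - a.qp : a.rp + a.qp;
    int64_t db = b.plus ? b.rp - b.qp : b.rp + b.qp;
    if (da != db) return da < db;
    return a.rp < b.rp;
  });

  std::unordered_map<int64_t, int64_t> done_plus, done_minus;
  std::vector<Anchor> out;
  const int64_t R = (int64_t)r.size(), Q = (int64_t)q.size();
  for (const Seed& sd : seeds) {
    if (sd.plus) {
      int64_t diag = sd.rp - sd.qp;
      auto it = done_plus.find(diag);
      if (it != done_plus.end() && sd.rp + k <= it->second) continue;
      int64_t a = sd.rp, b = sd.rp + k, c = sd.qp, d = sd.qp + k;
      while (a > 0 && c > 0 && r[a - 1] >= 0 && r[a - 1] == q[c - 1]) { --a; --c; }
      while (b < R && d < Q && r[b] >= 0 && r[b] == q[d]) { ++b; ++d; }
      done_plus[diag] = b;
      out.push_back({a, b, c, d, true});
    } else {
      // query [c,d) == revcomp(ref [a,b)); a+d and b+c stay constant
      int64_t diag = sd.rp + sd.qp + k;
      auto it = done_minus.find(diag);
      if (it != done_minus.end() && sd.rp + k <= it->second) continue;
      int64_t a = sd.rp, b = sd.rp + k, c = sd.qp, d = sd.qp + k;
      while (a > 0 && d < Q && r[a - 1] >= 0 && comp_code(r[a - 1]) == q[d]) { --a; ++d; }
      while (b < R && c > 0 && r[b] >= 0 && comp_code(r[b]) == q[c - 1]) { ++b; --c; }
      done_minus[diag] = b;
      out.push_back({a, b, c, d, false});
    }
  }

  std::sort(out.begin(), out.end(), [](const Anchor& x, const Anchor& y) {
    if (x.rs != y.rs) return x.rs < y.rs;
    if (x.re != y.re) return x.re < y.re;
    return x.qs < y.qs;
  });
  out.erase(std::unique(out.begin(), out.end(),
                        [](const Anchor& x, const Anchor& y) {
                          return x.rs == y.rs && x.re == y.re && x.qs == y.qs &&
                                 x.qe == y.qe && x.plus == y.plus;
                        }),
            out.end());

  size_t n = out.size();
  NumericVector rs(n), re(n), qs(n), qe(n);
  CharacterVector strand(n);
  for (size_t t = 0; t < n; ++t) {
    rs[t] = (double)out[t].rs; re[t] = (double)out[t].re;
    qs[t] = (double)out[t].qs; qe[t] = (double)out[t].qe;
    strand[t] = out[t].plus ? "+" : "-";
  }
  return DataFrame::create(_["ref_start"] = rs, _["ref_end"] = re,
                           _["query_start"] = qs, _["query_end"] = qe,
                           _["strand"] = strand,
                           _["stringsAsFactors"] = false);
}
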