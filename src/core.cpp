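#include <Rcpp.h>
#include <cstdint>
#include <vector>
#include <algorithm>
#include <string>

using namespace Rcpp;

// 2-bit DNA codes; -1 for anything outside ACGT (separators, N, IUPAC).
static inline int base_code(char c) {
  switch (c) {
    case 'A': case 'a': return 0;
    case 'C': case 'c': return 1;
    case 'G': case 'g': return 2;
    case 'T': case 't': return 3;
    default: return -1;
  }
}

// ---------------------------------------------------------------------------
// Generalized suffix automaton over the ACGT runs of a subject string.
// Non-ACGT characters act as separators: no substring spanning one is
// recognized. Supports matching statistics against a query.
// ---------------------------------------------------------------------------
struct SuffixAutomaton {
  std::vector<int32_t> len, link;
  std::vector<int32_t> nxt; // 4 transitions per state, flattened
  int last;

  explicit SuffixAutomaton(size_t reserve_chars) {
    size_t cap = 2 * reserve_chars + 8;
    len.reserve(cap); link.reserve(cap); nxt.reserve(4 * cap);
    new_state(0, -1);
    last = 0;
  }
  int new_state(int32_t l, int32_t lk) {
    len.push_back(l); link.push_back(lk);
    nxt.insert(nxt.end(), 4, -1);
    return (int)len.size() - 1;
  }
  inline int32_t go(int s, int c) const { return nxt[4 * (size_t)s + c]; }
  inline void set_go(int s, int c, int32_t t) { nxt[4 * (size_t)s + c] = t; }

  void reset_run() { last = 0; }

  void extend(int c) {
    int q0 = go(last, c);
    if (q0 != -1) {
      // generalized-automaton case: transition already present
      if (len[q0] == len[last] + 1) { last = q0; return; }
      int clone = new_state(len[last] + 1, link[q0]);
      for (int b = 0; b < 4; ++b) set_go(clone, b, go(q0, b));
      int p = last;
      while (p != -1 && go(p, c) == q0) { set_go(p, c, clone); p = link[p]; }
      link[q0] = clone;
      last = clone;
      return;
    }
    int cur = new_state(len[last] + 1, -1);
    int p = last;
    while (p != -1 && go(p, c) == -1) { set_go(p, c, cur); p = link[p]; }
    if (p == -1) {
      link[cur] = 0;
    } else {
      int q = go(p, c);
      if (len[q] == len[p] + 1) {
        link[cur] = q;
      } else {
        int clone = new_state(len[p] + 1, link[q]);
        for (int b = 0; b < 4; ++b) set_go(clone, b, go(q, b));
        while (p != -1 && go(p, c) == q) { set_go(p, c, clone); p = link[p]; }
        link[q] = clone; link[cur] = clone;
      }
    }
    last = cur;
  }
};

// Matching statistics of `query` against `subject`: for each 0-based start i,
// the length of the longest prefix of query[i..] that occurs as a substring
// of an ACGT run of `subject`. Non-ACGT query positions match nothing.
// Computed by walking reverse(query) through the automaton of
// reverse(subject): suffix matches of the reversals are prefix matches of
// the originals.
// [[Rcpp::export]]
IntegerVector cpp_matching_stats(const std::string& query,
                                 const std::string& subject) {
  std::string rs(subject.rbegin(), subject.rend());
  SuffixAutomaton sa(rs.size());
  for (char ch : rs) {
    int c = base_code(ch);
    if (c < 0) sa.reset_run(); else sa.extend(c);
  }
  size_t n = query.size();
  IntegerVector out(n);
  int state = 0, l = 0;
  // walk reverse(query)
  for (size_t j = 0; j < n; ++j) {
    int c = base_code(query[n - 1 - j]);
    if (c < 0) { state = 0; l = 0; out[n - 1 - j] = 0; continue; }
    while (state != 0 && sa.go(state, c) == -1) {
      state = sa.link[state];
      l = sa.len[state];
    }
    int t = sa.go(state, c);
    if (t == -1) { state = 0; l = 0; }
    else { state = t; ++l; }
    out[n - 1 - j] = l;
  }
  return out;
}

// ---------------------------------------------------------------------------
// Unique shared k-mer anchors between two (possibly separator-joined)
// sequences: k-mers over ACGT only, occurring exactly once in each.
// Returns a 2-column matrix of 0-based positions (ref, query).
// ---------------------------------------------------------------------------
static void collect_kmers(const std::string& s, int k,
                          std::vector<std::pair<uint64_t, int32_t> >& out) {
  uint64_t mask = (k == 32) ? ~0ULL : ((1ULL << (2 * k)) - 1ULL);
  uint64_t cur = 0;
  int run = 0;
  size_t n = s.size();
  out.reserve(n);
  for (size_t i = 0; i < n; ++i) {
    int c = base_code(s[i]);
    if (c < 0) { run = 0; cur = 0; continue; }
    cur = ((cur << 2) | (uint64_t)c) & mask;
    if (++run >= k) out.push_back(std::make_pair(cur, (int32_t)(i - k + 1)));
  }
}

// position of each k-mer occurring exactly once; sorted by k-mer value
static void unique_kmers(std::vector<std::pair<uint64_t, int32_t> >& v) {
  std::sort(v.begin(), v.end());
  size_t w = 0, i = 0, n = v.size();
  while (i < n) {
    size_t j = i;
    while (j < n && v[j].first == v[i].first) ++j;
    if (j - i == 1) v[w++] = v[i];
    i = j;
  }
  v.resize(w);
}

// [[Rcpp::export]]
IntegerMatrix cpp_kmer_anchors(const std::string& ref,
                               const std::string& query, int k) {
  if (k < 4 || k > 32) stop("k must be in [4, 32]");
  std::vector<std::pair<uint64_t, int32_t> > kr, kq;
  collect_kmers(ref, k, kr);
  collect_kmers(query, k, kq);
  unique_kmers(kr);
  unique_kmers(kq);
  std::vector<int32_t> rp, qp;
  size_t i = 0, j = 0;
  while (i < kr.size() && j < kq.size()) {
    if (kr[i].first < kq[j].first) ++i;
    else if (kq[j].first < kr[i].first) ++j;
    else { rp.push_back(kr[i].second); qp.push_back(kq[j].second); ++i; ++j; }
  }
  IntegerMatrix out((int)rp.size(), 2);
  for (size_t t = 0; t < rp.size(); ++t) { out(t, 0) = rp[t]; out(t, 1) = qp[t]; }
  return out;
}

// All k-mers of a sequence over ACGT runs (2-bit encoded, k <= 15 so the
// code fits an R integer) with their 0-based start positions.
// [[Rcpp::export]]
List cpp_kmer_positions(const std::string& s, int k) {
  if (k < 4 || k > 15) stop("k must be in [4, 15]");
  std::vector<std::pair<uint64_t, int32_t> > v;
  collect_kmers(s, k, v);
  IntegerVector kmer(v.size()), pos(v.size());
  for (size_t i = 0; i < v.size(); ++i) {
    kmer[i] = (int)v[i].first;
    pos[i] = v[i].second;
  }
  return List::create(_["kmer"] = kmer, _["pos"] = pos);
}

// Longest strictly increasing subsequence of v; returns 1-based indices of
// one optimal subsequence, in order.
// [[Rcpp::export]]
IntegerVector cpp_lis(IntegerVector v) {
  int n = v.size();
  if (n == 0) return IntegerVector(0);
  std::vector<int> tail_idx;            // index of smallest tail per length
  std::vector<int> prev(n, -1);
  std::vector<int> tail_val;
  tail_idx.reserve(n); tail_val.reserve(n);
  for (int i = 0; i < n; ++i) {
    int x = v[i];
    // first position with tail value >= x (strict increase)
    int lo = (int)(std::lower_bound(tail_val.begin(), tail_val.end(), x) -
                   tail_val.begin());
    if (lo > 0) prev[i] = tail_idx[lo - 1];
    if (lo == (int)tail_val.size()) { tail_val.push_back(x); tail_idx.push_back(i); }
    else { tail_val[lo] = x; tail_idx[lo] = i; }
  }
  int L = (int)tail_val.size();
  IntegerVector out(L);
  int cur = tail_idx[L - 1];
  for (int pos = L - 1; pos >= 0; --pos) { out[pos] = cur + 1; cur = prev[cur]; }
  return out;
}

// Booth's algorithm: 0-based start of the lexicographically minimal rotation.
// [[Rcpp::export]]
int cpp_min_rotation(const std::string& s) {
  int n = (int)s.size();
  if (n == 0) return 0;
  std::string t = s + s;
  std::vector<int> f(2 * n, -1);
  int kmin = 0;
  for (int j = 1; j < 2 * n; ++j) {
    char sj = t[j];
    int i = f[j - kmin - 1];
    while (i != -1 && sj != t[kmin + i + 1]) {
      if (sj < t[kmin + i + 1]) kmin = j - i - 1;
      i = f[i];
    }
    if (sj != t[kmin + i + 1]) {
      if (sj < t[kmin + i + 1]) kmin = j;
      f[j - kmin] = -1;
    } else {
      f[j - kmin] = i + 1;
    }
  }
  return kmin;
}
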