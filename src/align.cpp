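// Smith-Waterman local alignment and k-mer candidate prefilters.
//
// The similarity graph and the read-to-cluster mapper are defined by
// exhaustive pairwise local alignment; the k-mer machinery here only
// proposes candidate pairs so that desk-scale inputs stay fast.  Scores
// use a simple match/mismatch/linear-gap scheme (defaults +1/-2/-3).

#include <Rcpp.h>
#include <unordered_map>
#include <vector>
#include <string>
#include <algorithm>
#include <cstdint>

using namespace Rcpp;

static inline int base_code(char c) {
  switch (c) {
    case 'A': case 'a': return 0;
    case 'C': case 'c': return 1;
    case 'G': case 'g': return 2;
    case 'T': case 't': return 3;
    default: return -1;
  }
}

static std::string revcomp_str(const std::string& s) {
  std::string r(s.rbegin(), s.rend());
  for (auto& c : r) {
    switch (c) {
      case 'A': c = 'T'; break; case 'C': c = 'G'; break;
      case 'G': c = 'C'; break; case 'T': c = 'A'; break;
      case 'a': c = 't'; break; case 'c': c = 'g'; break;
      case 'g': c = 'c'; break; case 't': c = 'a'; break;
      default: c = 'N';
    }
  }
  return r;
}

// All forward/reverse-complement k-mer codes of s; windows containing
// non-ACGT characters are skipped.
static void kmer_codes(const std::string& s, int k,
                       std::vector<uint64_t>& fwd, std::vector<uint64_t>& rev) {
  fwd.clear(); rev.clear();
  int n = (int)s.size();
  if (n < k || k < 1 || k > 31) return;
  uint64_t mask = (1ULL << (2 * k)) - 1;
  uint64_t f = 0, r = 0;
  int valid = 0;
  for (int i = 0; i < n; ++i) {
    int c = base_code(s[i]);
    if (c < 0) { valid = 0; f = 0; r = 0; continue; }
    f = ((f << 2) | (uint64_t)c) & mask;
    r = (r >> 2) | ((uint64_t)(3 - c) << (2 * (k - 1)));
    if (++valid >= k) { fwd.push_back(f); rev.push_back(r); }
  }
}

// Unique (canonical code, canonical-is-forward) pairs of a sequence.
static std::vector<std::pair<uint64_t, int>> canonical_kmers(
    const std::string& s, int k,
    std::vector<uint64_t>& fwd, std::vector<uint64_t>& rev) {
  kmer_codes(s, k, fwd, rev);
  std::vector<std::pair<uint64_t, int>> out;
  out.reserve(fwd.size());
  for (size_t j = 0; j < fwd.size(); ++j) {
    int isfwd = fwd[j] <= rev[j] ? 1 : 0;
    out.emplace_back(std::min(fwd[j], rev[j]), isfwd);
  }
  std::sort(out.begin(), out.end());
  out.erase(std::unique(out.begin(), out.end()), out.end());
  return out;
}

// Candidate read pairs sharing at least min_shared canonical k-mers.
// Returns a two-column matrix of 1-based indices (i < j).
// [[Rcpp::export]]
IntegerMatrix kmer_pairs_cpp(CharacterVector seqs, int k, int min_shared) {
  int n = seqs.size();
  std::unordered_map<uint64_t, std::vector<int>> index;
  std::vector<uint64_t> fwd, rev;
  for (int i = 0; i < n; ++i) {
    std::string s = as<std::string>(seqs[i]);
    std::vector<uint64_t> canon;
    kmer_codes(s, k, fwd, rev);
    canon.reserve(fwd.size());
    for (size_t j = 0; j < fwd.size(); ++j)
      canon.push_back(std::min(fwd[j], rev[j]));
    std::sort(canon.begin(), canon.end());
    canon.erase(std::unique(canon.begin(), canon.end()), canon.end());
    for (uint64_t c : canon) index[c].push_back(i);
    if (i % 1024 == 0) Rcpp::checkUserInterrupt();
  }
  std::unordered_map<uint64_t, int> pair_count;
  for (auto& kv : index) {
    auto& ids = kv.second;
    size_t m = ids.size();
    if (m < 2) continue;
    for (size_t a = 0; a + 1 < m; ++a)
      for (size_t b = a + 1; b < m; ++b)
        ++pair_count[((uint64_t)ids[a] << 32) | (uint64_t)ids[b]];
  }
  std::vector<int> ia, ja;
  ia.reserve(pair_count.size());
  ja.reserve(pair_count.size());
  for (auto& kv : pair_count) {
    if (kv.second >= min_shared) {
      ia.push_back((int)(kv.first >> 32) + 1);
      ja.push_back((int)(kv.first & 0xffffffffULL) + 1);
    }
  }
  IntegerMatrix out((int)ia.size(), 2);
  for (size_t t = 0; t < ia.size(); ++t) {
    out(t, 0) = ia[t];
    out(t, 1) = ja[t];
  }
  return out;
}

struct SwStats {
  int score, matches, columns;
};

// Full DP with traceback, reporting score, matched positions and
// alignment columns of the best local alignment.
static SwStats sw_traceback(const std::string& a, const std::string& b,
                            int match, int mismatch, int gap) {
  int n = (int)a.size(), m = (int)b.size();
  SwStats st{0, 0, 0};
  if (n == 0 || m == 0) return st;
  std::vector<int> H((size_t)(n + 1) * (m + 1), 0);
  std::vector<uint8_t> D((size_t)(n + 1) * (m + 1), 0);  // 0 stop, 1 diag, 2 up, 3 left
  int best = 0, bi = 0, bj = 0;
  for (int i = 1; i <= n; ++i) {
    size_t row = (size_t)i * (m + 1), prow = (size_t)(i - 1) * (m + 1);
    for (int j = 1; j <= m; ++j) {
      int s = (a[i - 1] == b[j - 1]) ? match : mismatch;
      int v = 0; uint8_t d = 0;
      int diag = H[prow + j - 1] + s;
      if (diag > v) { v = diag; d = 1; }
      int up = H[prow + j] + gap;
      if (up > v) { v = up; d = 2; }
      int left = H[row + j - 1] + gap;
      if (left > v) { v = left; d = 3; }
      H[row + j] = v; D[row + j] = d;
      if (v > best) { best = v; bi = i; bj = j; }
    }
  }
  st.score = best;
  int i = bi, j = bj;
  while (i > 0 && j > 0) {
    uint8_t d = D[(size_t)i * (m + 1) + j];
    if (d == 0) break;
    ++st.columns;
    if (d == 1) {
      if (a[i - 1] == b[j - 1]) ++st.matches;
      --i; --j;
    } else if (d == 2) {
      --i;
    } else {
      --j;
    }
  }
  return st;
}

static int sw_score_only(const std::string& a, const std::string& b,
                         int match, int mismatch, int gap) {
  int n = (int)a.size(), m = (int)b.size();
  if (n == 0 || m == 0) return 0;
  std::vector<int> prev(m + 1, 0), cur(m + 1, 0);
  int best = 0;
  for (int i = 1; i <= n; ++i) {
    cur[0] = 0;
    for (int j = 1; j <= m; ++j) {
      int s = (a[i - 1] == b[j - 1]) ? match : mismatch;
      int v = prev[j - 1] + s;
      int up = prev[j] + gap;
      if (up > v) v = up;
      int left = cur[j - 1] + gap;
      if (left > v) v = left;
      if (v < 0) v = 0;
      cur[j] = v;
      if (v > best) best = v;
    }
    std::swap(prev, cur);
  }
  return best;
}

// Best-orientation alignment stats for explicit index pairs into seqs.
// [[Rcpp::export]]
DataFrame sw_pairs_cpp(CharacterVector seqs, IntegerMatrix pairs,
                       int match, int mismatch, int gap) {
  int np = pairs.nrow();
  int ns = seqs.size();
  std::vector<std::string> ss(ns);
  for (int i = 0; i < ns; ++i) ss[i] = as<std::string>(seqs[i]);
  IntegerVector score(np), matches(np), columns(np);
  CharacterVector orientation(np);
  for (int t = 0; t < np; ++t) {
    const std::string& a = ss[pairs(t, 0) - 1];
    const std::string& b = ss[pairs(t, 1) - 1];
    SwStats f = sw_traceback(a, b, match, mismatch, gap);
    SwStats r = sw_traceback(a, revcomp_str(b), match, mismatch, gap);
    bool rev = r.score > f.score;
    const SwStats& st = rev ? r : f;
    score[t] = st.score;
    matches[t] = st.matches;
    columns[t] = st.columns;
    orientation[t] = rev ? "reverse" : "forward";
    if (t % 2048 == 0) Rcpp::checkUserInterrupt();
  }
  return DataFrame::create(_["score"] = score, _["matches"] = matches,
                           _["columns"] = columns,
                           _["orientation"] = orientation,
                           _["stringsAsFactors"] = false);
}

// For each query, candidate reference sequences sharing >= min_shared
// canonical k-mers, ranked by shared-k-mer count and capped at
// max_candidates (0 = keep all).  strand is +1 when the k-mer votes say
// the query matches the reference forward strand, -1 otherwise.
// [[Rcpp::export]]
List kmer_candidates_cpp(CharacterVector queries, CharacterVector refs,
                         int k, int min_shared, int max_candidates) {
  int nr = refs.size();
  std::unordered_map<uint64_t, std::vector<int>> index;
  std::vector<uint64_t> fwd, rev;
  for (int r = 0; r < nr; ++r) {
    std::string s = as<std::string>(refs[r]);
    auto cf = canonical_kmers(s, k, fwd, rev);
    for (auto& p : cf) index[p.first].push_back((r << 1) | p.second);
    if (r % 1024 == 0) Rcpp::checkUserInterrupt();
  }
  int nq = queries.size();
  std::vector<int> q_out, r_out, s_out;
  std::vector<int> cnt_f(nr, 0), cnt_r(nr, 0);
  std::vector<int> touched;
  for (int q = 0; q < nq; ++q) {
    std::string s = as<std::string>(queries[q]);
    auto cf = canonical_kmers(s, k, fwd, rev);
    for (auto& p : cf) {
      auto it = index.find(p.first);
      if (it == index.end()) continue;
      for (int packed : it->second) {
        int r = packed >> 1;
        if (cnt_f[r] == 0 && cnt_r[r] == 0) touched.push_back(r);
        if ((packed & 1) == p.second) ++cnt_f[r]; else ++cnt_r[r];
      }
    }
    std::vector<std::pair<int, int>> cand;  // (-count, ref)
    for (int r : touched) {
      int c = std::max(cnt_f[r], cnt_r[r]);
      if (c >= min_shared) cand.emplace_back(-c, r);
    }
    std::sort(cand.begin(), cand.end());
    int keep = (max_candidates > 0 && (int)cand.size() > max_candidates)
                   ? max_candidates : (int)cand.size();
    for (int t = 0; t < keep; ++t) {
      int r = cand[t].second;
      q_out.push_back(q + 1);
      r_out.push_back(r + 1);
      s_out.push_back(cnt_f[r] >= cnt_r[r] ? 1 : -1);
    }
    for (int r : touched) { cnt_f[r] = 0; cnt_r[r] = 0; }
    touched.clear();
    if (q % 256 == 0) Rcpp::checkUserInterrupt();
  }
  return List::create(_["query"] = wrap(q_out), _["ref"] = wrap(r_out),
                      _["strand"] = wrap(s_out));
}

// Score-only alignment of query/reference index pairs on a given strand.
// [[Rcpp::export]]
IntegerVector sw_scores_cpp(CharacterVector queries, CharacterVector refs,
                            IntegerVector qidx, IntegerVector ridx,
                            IntegerVector strand,
                            int match, int mismatch, int gap) {
  int nq = queries.size(), nr = refs.size(), np = qidx.size();
  std::vector<std::string> qs(nq), rs(nr), qrc(nq);
  for (int i = 0; i < nq; ++i) qs[i] = as<std::string>(queries[i]);
  for (int i = 0; i < nr; ++i) rs[i] = as<std::string>(refs[i]);
  IntegerVector out(np);
  for (int t = 0; t < np; ++t) {
    int qi = qidx[t] - 1, ri = ridx[t] - 1;
    const std::string* a = &qs[qi];
    if (strand[t] < 0) {
      if (qrc[qi].empty() && !qs[qi].empty()) qrc[qi] = revcomp_str(qs[qi]);
      a = &qrc[qi];
    }
    out[t] = sw_score_only(*a, rs[ri], match, mismatch, gap);
    if (t % 2048 == 0) Rcpp::checkUserInterrupt();
  }
  return out;
}
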