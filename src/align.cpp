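#include <Rcpp.h>
#include <cstdint>
#include <queue>
#include <unordered_set>
#include <algorithm>
using namespace Rcpp;

// Affine-gap global alignment (Gotoh). A gap of length L costs open + extend*L,
// i.e. opening move costs open + extend and each extension costs extend.
// Scores come from a substitution matrix passed in with dimnames (e.g. BLOSUM62).

namespace {

const double NEG_INF = -1e18;

struct SubMat {
  int lut[256];
  std::vector<double> m; // nl x nl
  int nl;
  SubMat(const NumericMatrix& sm) {
    std::fill(lut, lut + 256, -1);
    CharacterVector rn = rownames(sm);
    nl = rn.size();
    for (int i = 0; i < nl; ++i) {
      const char* s = CHAR(STRING_ELT(rn, i));
      lut[(unsigned char)s[0]] = i;
    }
    m.resize(nl * nl);
    for (int i = 0; i < nl; ++i)
      for (int j = 0; j < nl; ++j) m[i * nl + j] = sm(i, j);
  }
  double score(unsigned char a, unsigned char b) const {
    int ia = lut[a], ib = lut[b];
    if (ia < 0 || ib < 0) stop("residue not present in substitution matrix");
    return m[ia * nl + ib];
  }
};

// score-only Gotoh, two rolling rows
double gotoh_score(const std::string& a, const std::string& b, const SubMat& sm,
                   double go, double ge) {
  const int n = a.size(), mlen = b.size();
  std::vector<double> M(mlen + 1), X(mlen + 1), Mp(mlen + 1), Xp(mlen + 1);
  // X: gap in a (consuming b); Y handled as scalar per row (gap in b)
  Mp[0] = 0.0; Xp[0] = NEG_INF;
  for (int j = 1; j <= mlen; ++j) { Mp[j] = -(go + ge * j); Xp[j] = Mp[j]; }
  for (int i = 1; i <= n; ++i) {
    double Y = NEG_INF;
    M[0] = -(go + ge * i); X[0] = NEG_INF;
    double Ycur = M[0];
    for (int j = 1; j <= mlen; ++j) {
      X[j] = std::max(Xp[j] - ge, Mp[j] - go - ge);
      Y = std::max(Ycur - go - ge, Y - ge);
      double diag = Mp[j - 1] + sm.score(a[i - 1], b[j - 1]);
      M[j] = std::max({diag, X[j], Y});
      Ycur = M[j];
    }
    std::swap(M, Mp); std::swap(X, Xp);
  }
  return Mp[mlen];
}

// value the predecessor must have had if the gap was extended
inline double ge_ext(double cur, double ge) { return cur + ge; }

} // namespace

// [[Rcpp::export(name = ".cpp_nw_align")]]
List cpp_nw_align(std::string a, std::string b, NumericMatrix submat,
                  double gap_open, double gap_extend) {
  SubMat sm(submat);
  const int n = a.size(), m = b.size();
  if (n == 0 || m == 0) stop("empty sequence");
  // full DP with traceback; three layers
  std::vector<double> M((n + 1) * (m + 1), NEG_INF);
  std::vector<double> X((n + 1) * (m + 1), NEG_INF); // gap in a
  std::vector<double> Y((n + 1) * (m + 1), NEG_INF); // gap in b
  auto idx = [m](int i, int j) { return i * (m + 1) + j; };
  M[idx(0, 0)] = 0.0;
  for (int j = 1; j <= m; ++j) { X[idx(0, j)] = -(gap_open + gap_extend * j); }
  for (int i = 1; i <= n; ++i) { Y[idx(i, 0)] = -(gap_open + gap_extend * i); }
  for (int i = 1; i <= n; ++i) {
    for (int j = 1; j <= m; ++j) {
      double x = std::max(X[idx(i, j - 1)] - gap_extend,
                          std::max(M[idx(i, j - 1)], Y[idx(i, j - 1)]) - gap_open - gap_extend);
      double y = std::max(Y[idx(i - 1, j)] - gap_extend,
                          std::max(M[idx(i - 1, j)], X[idx(i - 1, j)]) - gap_open - gap_extend);
      X[idx(i, j)] = x;
      Y[idx(i, j)] = y;
      double best = std::max(M[idx(i - 1, j - 1)],
                             std::max(X[idx(i - 1, j - 1)], Y[idx(i - 1, j - 1)]));
      if (best > NEG_INF / 2)
        M[idx(i, j)] = best + sm.score(a[i - 1], b[j - 1]);
    }
  }
  // traceback from best layer at (n, m)
  std::string ra, rb;
  int i = n, j = m;
  char layer;
  double fm = M[idx(n, m)], fx = X[idx(n, m)], fy = Y[idx(n, m)];
  double score = std::max({fm, fx, fy});
  layer = (score == fm) ? 'M' : (score == fx ? 'X' : 'Y');
  while (i > 0 || j > 0) {
    if (layer == 'M' && i > 0 && j > 0) {
      double prev = M[idx(i, j)] - sm.score(a[i - 1], b[j - 1]);
      ra.push_back(a[i - 1]); rb.push_back(b[j - 1]);
      --i; --j;
      double pm = M[idx(i, j)], px = X[idx(i, j)], py = Y[idx(i, j)];
      layer = (std::abs(pm - prev) < 1e-9) ? 'M'
            : (std::abs(px - prev) < 1e-9) ? 'X' : 'Y';
    } else if (layer == 'X' || i == 0) {
      // gap in a: consume b[j-1]
      double cur = X[idx(i, j)];
      ra.push_back('-'); rb.push_back(b[j - 1]);
      --j;
      if (i == 0) { layer = 'X'; continue; }
      if (std::abs(X[idx(i, j)] - ge_ext(cur, gap_extend)) < 1e-9)
        layer = 'X';
      else {
        double opened = cur + gap_open + gap_extend;
        layer = (std::abs(M[idx(i, j)] - opened) < 1e-9) ? 'M' : 'Y';
      }
    } else { // 'Y' or j == 0
      double cur = Y[idx(i, j)];
      ra.push_back(a[i - 1]); rb.push_back('-');
      --i;
      if (j == 0) { layer = 'Y'; continue; }
      if (std::abs(Y[idx(i, j)] - ge_ext(cur, gap_extend)) < 1e-9)
        layer = 'Y';
      else {
        double opened = cur + gap_open + gap_extend;
        layer = (std::abs(M[idx(i, j)] - opened) < 1e-9) ? 'M' : 'X';
      }
    }
  }
  std::reverse(ra.begin(), ra.end());
  std::reverse(rb.begin(), rb.end());
  int matches = 0, cols = 0;
  for (size_t c = 0; c < ra.size(); ++c) {
    if (ra[c] == '-' && rb[c] == '-') continue;
    ++cols;
    if (ra[c] == rb[c]) ++matches;
  }
  return List::create(_["score"] = score,
                      _["identity"] = cols ? (double)matches / cols : NA_REAL,
                      _["aligned_a"] = ra, _["aligned_b"] = rb);
}

// [[Rcpp::export(name = ".cpp_nw_score")]]
double cpp_nw_score(std::string a, std::string b, NumericMatrix submat,
                    double gap_open, double gap_extend) {
  SubMat sm(submat);
  if (a.empty() || b.empty()) stop("empty sequence");
  return gotoh_score(a, b, sm, gap_open, gap_extend);
}

namespace {
// amino-acid 3-mer count profiles for candidate prefiltering
const int AB = 26, NK = AB * AB * AB;
std::vector<std::pair<std::vector<int>, std::vector<int>>> kmer3_profiles(
    const std::vector<std::string>& seqs) {
  // per sequence: (sorted distinct kmer ids, counts)
  std::vector<std::pair<std::vector<int>, std::vector<int>>> out(seqs.size());
  for (size_t s = 0; s < seqs.size(); ++s) {
    std::vector<int> ids;
    const std::string& q = seqs[s];
    for (size_t p = 0; p + 3 <= q.size(); ++p) {
      int id = 0;
      bool ok = true;
      for (int t = 0; t < 3; ++t) {
        char c = q[p + t];
        if (c < 'A' || c > 'Z') { ok = false; break; }
        id = id * AB + (c - 'A');
      }
      if (ok) ids.push_back(id);
    }
    std::sort(ids.begin(), ids.end());
    std::vector<int> d, cnt;
    for (size_t p = 0; p < ids.size();) {
      size_t q2 = p;
      while (q2 < ids.size() && ids[q2] == ids[p]) ++q2;
      d.push_back(ids[p]); cnt.push_back((int)(q2 - p));
      p = q2;
    }
    out[s] = {d, cnt};
  }
  return out;
}
} // namespace

// For each query, NW-score the top_k targets ranked by shared amino-acid
// 3-mer counts, and return candidate indices (1-based), scores and identities.
// [[Rcpp::export(name = ".cpp_best_hit_search")]]
List cpp_best_hit_search(CharacterVector queries, CharacterVector targets,
                         NumericMatrix submat, double gap_open,
                         double gap_extend, int top_k, double min_frac) {
  SubMat sm(submat);
  std::vector<std::string> qs(queries.size()), ts(targets.size());
  for (int i = 0; i < queries.size(); ++i) qs[i] = as<std::string>(queries[i]);
  for (int i = 0; i < targets.size(); ++i) ts[i] = as<std::string>(targets[i]);
  auto qp = kmer3_profiles(qs);
  auto tp = kmer3_profiles(ts);
  int nt = ts.size();
  top_k = std::min(top_k, nt);
  List out(qs.size());
  std::vector<double> shared(nt);
  for (size_t qi = 0; qi < qs.size(); ++qi) {
    const auto& Q = qp[qi];
    for (int t = 0; t < nt; ++t) {
      const auto& T = tp[t];
      double s = 0; size_t a = 0, b = 0;
      while (a < Q.first.size() && b < T.first.size()) {
        if (Q.first[a] == T.first[b]) { s += std::min(Q.second[a], T.second[b]); ++a; ++b; }
        else if (Q.first[a] < T.first[b]) ++a;
        else ++b;
      }
      shared[t] = s;
    }
    std::vector<int> ord(nt);
    for (int t = 0; t < nt; ++t) ord[t] = t;
    std::partial_sort(ord.begin(), ord.begin() + top_k, ord.end(),
                      [&](int x, int y) { return shared[x] > shared[y]; });
    IntegerVector cand(top_k);
    NumericVector score(top_k), ident(top_k);
    // candidates far below the leader in shared 3-mers cannot be the best
    // hit at panel identity levels; skip their (costly) full alignment
    double lead = shared[ord[0]];
    for (int c = 0; c < top_k; ++c) {
      int t = ord[c];
      cand[c] = t + 1;
      bool plausible = (c == 0) || (lead <= 0) || (shared[t] >= min_frac * lead);
      score[c] = plausible ? gotoh_score(qs[qi], ts[t], sm, gap_open, gap_extend)
                           : -1e15;
      ident[c] = shared[t];
    }
    out[qi] = List::create(_["candidates"] = cand, _["scores"] = score,
                           _["kmer_shared"] = ident);
    if (qi % 64 == 0) Rcpp::checkUserInterrupt();
  }
  return out;
}

// ---- MinHash sketching ----------------------------------------------------

namespace {
inline uint64_t splitmix64(uint64_t x) {
  x += 0x9E3779B97F4A7C15ULL;
  x = (x ^ (x >> 30)) * 0xBF58476D1CE4E5B9ULL;
  x = (x ^ (x >> 27)) * 0x94D049BB133111EBULL;
  return x ^ (x >> 31);
}
inline int base2bit(char c) {
  switch (c) {
    case 'A': case 'a': return 0;
    case 'C': case 'c': return 1;
    case 'G': case 'g': return 2;
    case 'T': case 't': return 3;
    default: return -1;
  }
}
} // namespace

// Bottom-s sketch of canonical k-mer hashes, masked to 53 bits so the values
// survive the round trip through R doubles exactly.
// [[Rcpp::export(name = ".cpp_minhash_sketch")]]
NumericVector cpp_minhash_sketch(std::string seq, int k, int s, double seed) {
  if (k < 1 || k > 31) stop("k must be in [1, 31]");
  if ((int)seq.size() < k) stop("sequence shorter than k");
  const uint64_t mask53 = (1ULL << 53) - 1;
  const uint64_t seed64 = (uint64_t)seed;
  const uint64_t kmask = (k == 32) ? ~0ULL : ((1ULL << (2 * k)) - 1);
  uint64_t fwd = 0, rev = 0;
  int run = 0;
  std::priority_queue<uint64_t> heap; // max-heap of kept hashes
  std::unordered_set<uint64_t> seen;
  for (size_t i = 0; i < seq.size(); ++i) {
    int b = base2bit(seq[i]);
    if (b < 0) { run = 0; fwd = rev = 0; continue; } // N or other: restart
    fwd = ((fwd << 2) | (uint64_t)b) & kmask;
    rev = (rev >> 2) | ((uint64_t)(3 - b) << (2 * (k - 1)));
    if (++run < k) continue;
    uint64_t canon = std::min(fwd, rev);
    uint64_t h = splitmix64(canon ^ splitmix64(seed64)) & mask53;
    if (seen.count(h)) continue;
    if ((int)heap.size() < s) { heap.push(h); seen.insert(h); }
    else if (h < heap.top()) {
      seen.erase(heap.top()); heap.pop();
      heap.push(h); seen.insert(h);
    }
  }
  NumericVector out(heap.size());
  for (int i = (int)heap.size() - 1; i >= 0; --i) { out[i] = (double)heap.top(); heap.pop(); }
  return out;
}
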