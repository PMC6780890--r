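#include <Rcpp.h>
#include <cstring>
#include <vector>
using namespace Rcpp;

// Global (Needleman-Wunsch) alignment identity with match +1, mismatch -1,
// gap -2 per column (linear gap cost).  Identity = matches / alignment
// columns.  When several alignments reach the optimal score the one with the
// most matches is used; because score = 2M + 3P - 2(la+lb) with M matches and
// P aligned pairs, fixing (score, M) also fixes P and hence the column count
// C = la + lb - P, so the lexicographic (score, matches) optimum defines
// identity uniquely.

// The (score, matches) pair is packed into one 64-bit value
// V = score * ENC + matches.  matches < min(la, lb) + 1 << ENC, so taking
// the maximum of V is exactly the lexicographic maximisation, and both
// components are additive along an alignment path, so the packed DP is
// additive too: a diagonal step adds ENC + 1 on a match and -ENC on a
// mismatch, and each gap column adds -2 * ENC.
static const int64_t ENC = 1LL << 20;

static double nw_identity_core(const char *a, int la, const char *b, int lb) {
  // Equal lengths with at most 2 mismatches: the ungapped alignment is
  // provably optimal (any gapped alignment of equal-length strings has
  // g >= 2 gap columns and score <= L - 5g/2 <= L - 5 < L - 2m), so the
  // identity is (L - m) / L without running the DP.
  if (la == lb) {
    int m = 0;
    for (int i = 0; i < la && m <= 2; ++i) m += (a[i] != b[i]);
    if (m <= 2) return (double)(la - m) / (double)la;
  }
  std::vector<int64_t> row(lb + 1);
  for (int j = 0; j <= lb; ++j) row[j] = -2 * ENC * j;
  for (int i = 1; i <= la; ++i) {
    int64_t diag = row[0];
    row[0] = -2 * ENC * i;
    int64_t left = row[0];
    const char ai = a[i - 1];
    for (int j = 1; j <= lb; ++j) {
      const int64_t up = row[j];
      int64_t v = diag + ((ai == b[j - 1]) ? (ENC + 1) : -ENC);
      const int64_t gu = up - 2 * ENC;
      if (gu > v) v = gu;
      const int64_t gl = left - 2 * ENC;
      if (gl > v) v = gl;
      row[j] = v;
      diag = up;
      left = v;
    }
  }
  int64_t v = row[lb];
  int64_t matches = ((v % ENC) + ENC) % ENC;
  int64_t score = (v - matches) / ENC;
  // aligned pairs from score = 2M + 3P - 2(la+lb)
  const int64_t pairs = (score - 2 * matches + 2 * (la + lb)) / 3;
  const int64_t columns = la + lb - pairs;
  return columns > 0 ? (double)matches / (double)columns : 1.0;
}

// [[Rcpp::export(name = ".nw_identity")]]
double nw_identity_cpp(std::string a, std::string b) {
  if (a.empty() || b.empty())
    stop("sequence identity is undefined for empty sequences");
  return nw_identity_core(a.c_str(), (int)a.size(), b.c_str(), (int)b.size());
}

// [[Rcpp::export(name = ".nw_identity_matrix")]]
NumericMatrix nw_identity_matrix_cpp(CharacterVector queries, CharacterVector refs) {
  const int nq = queries.size(), nr = refs.size();
  NumericMatrix out(nq, nr);
  for (int i = 0; i < nq; ++i) {
    std::string q = as<std::string>(queries[i]);
    if (q.empty()) stop("sequence identity is undefined for empty sequences");
    for (int j = 0; j < nr; ++j) {
      std::string r = as<std::string>(refs[j]);
      if (r.empty()) stop("sequence identity is undefined for empty sequences");
      out(i, j) = nw_identity_core(q.c_str(), (int)q.size(), r.c_str(), (int)r.size());
    }
  }
  return out;
}

static inline int base_code(char c) {
  switch (c) {
    case 'A': return 0; case 'C': return 1; case 'G': return 2; case 'T': return 3;
    default: return -1;
  }
}

// 8-mers packed into 16 bits (2 bits/base); k-mers spanning a non-ACGT
// character are skipped on both sides, which only weakens (never breaks)
// the screening bound below.
static void kmer_counts(const std::string &s, std::vector<unsigned short> &tab,
                        std::vector<int> &keys) {
  const int k = 8;
  const int n = (int)s.size();
  int code = 0, valid = 0;
  for (int i = 0; i < n; ++i) {
    const int b = base_code(s[i]);
    if (b < 0) { valid = 0; code = 0; continue; }
    code = ((code << 2) | b) & 0xFFFF;
    if (++valid >= k) {
      if (tab[code] == 0) keys.push_back(code);
      ++tab[code];
    }
  }
}

// Identity of every query against every target, with a q-gram screen: a pair
// that provably cannot reach `threshold` is reported as NA without running
// the alignment.  If identity >= t then the edit distance e satisfies
// e <= (la+lb)(1-t)/(1+t), and two sequences at edit distance e share at
// least (Lmin - k + 1) - k*e k-mers; pairs sharing fewer are skipped.
// Results for evaluated pairs are exact, so the screened matrix equals the
// unscreened one everywhere at or above the threshold.
// [[Rcpp::export(name = ".screened_identity_matrix")]]
NumericMatrix screened_identity_matrix_cpp(CharacterVector queries,
                                           CharacterVector targets,
                                           double threshold) {
  const int k = 8;
  const int nq = queries.size(), nt = targets.size();
  NumericMatrix out(nq, nt);

  std::vector<std::string> tseq(nt);
  std::vector<std::vector<unsigned short> > ttab(nt);
  std::vector<std::vector<int> > tkeys(nt);
  for (int j = 0; j < nt; ++j) {
    tseq[j] = as<std::string>(targets[j]);
    if (tseq[j].empty()) stop("sequence identity is undefined for empty sequences");
    ttab[j].assign(1 << 16, 0);
    kmer_counts(tseq[j], ttab[j], tkeys[j]);
  }

  std::vector<unsigned short> qtab(1 << 16, 0);
  for (int i = 0; i < nq; ++i) {
    std::string q = as<std::string>(queries[i]);
    if (q.empty()) stop("sequence identity is undefined for empty sequences");
    std::vector<int> qkeys;
    kmer_counts(q, qtab, qkeys);
    const int la = (int)q.size();
    for (int j = 0; j < nt; ++j) {
      const int lb = (int)tseq[j].size();
      const int lmin = la < lb ? la : lb;
      bool skip = false;
      if (threshold > 0) {
        const int emax = (int)std::floor((la + lb) * (1.0 - threshold) / (1.0 + threshold));
        const int need = (lmin - k + 1) - k * emax;
        if (need > 0) {
          long shared = 0;
          const std::vector<int> &keys = qkeys.size() < tkeys[j].size() ? qkeys : tkeys[j];
          const std::vector<unsigned short> &ta = qtab;
          const std::vector<unsigned short> &tb = ttab[j];
          for (size_t u = 0; u < keys.size(); ++u) {
            const int key = keys[u];
            shared += std::min(ta[key], tb[key]);
          }
          if (shared < need) skip = true;
        }
      }
      out(i, j) = skip ? NA_REAL
                       : nw_identity_core(q.c_str(), la, tseq[j].c_str(), lb);
    }
    for (size_t u = 0; u < qkeys.size(); ++u) qtab[qkeys[u]] = 0;
  }
  return out;
}
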