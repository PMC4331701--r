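#include <Rcpp.h>
#include <cstring>
using namespace Rcpp;

// Complement table over {A,C,G,T,N}; N is self-complementary.
static inline char comp(char c) {
  switch (c) {
    case 'A': return 'T';
    case 'C': return 'G';
    case 'G': return 'C';
    case 'T': return 'A';
    default:  return 'N';
  }
}

// Mismatch budget floor(len * e). The small epsilon guards against IEEE
// products like 10 * 0.3 = 2.999...96 rounding the budget down by one.
static inline int budget(int len, double e) {
  return (int)std::floor((double)len * e + 1e-9);
}

// Hamming distance with N-as-mismatch: a position mismatches when the
// characters differ or either is N.
static inline int hamming_n(const char* a, const char* b, int len) {
  int m = 0;
  for (int i = 0; i < len; ++i)
    if (a[i] != b[i] || a[i] == 'N') ++m;
  return m;
}

// [[Rcpp::export(name = ".hamming_n_cpp")]]
IntegerVector hamming_n_cpp(CharacterVector a, CharacterVector b) {
  R_xlen_t n = a.size();
  if (b.size() != n) stop("`a` and `b` must have equal length");
  IntegerVector out(n);
  for (R_xlen_t i = 0; i < n; ++i) {
    const char* sa = CHAR(STRING_ELT(a, i));
    const char* sb = CHAR(STRING_ELT(b, i));
    int la = (int)std::strlen(sa), lb = (int)std::strlen(sb);
    if (la != lb)
      stop("strings at position %d have unequal lengths (%d vs %d)",
           (int)i + 1, la, lb);
    out[i] = hamming_n(sa, sb, la);
  }
  return out;
}

// Stage-1 scan of one direction: the reverse complement of the first L bases
// of `tmpl` is slid along `target`; every start p (0-based) whose window
// mismatch count is within budget contributes candidate insert length p + L.
// `comparisons` accumulates character comparisons actually performed (the
// inner loop aborts once the budget is exceeded, so the count is bounded by
// (N - L + 1) * L <= L * N).
static void scan_one(const char* tmpl, const char* target, int n_target,
                     int L, double e1,
                     std::vector<int>& out, long long& comparisons) {
  std::vector<char> q(L);
  for (int i = 0; i < L; ++i) q[L - 1 - i] = comp(tmpl[i]);
  int bud = budget(L, e1);
  for (int p = 0; p + L <= n_target; ++p) {
    int m = 0;
    for (int i = 0; i < L; ++i) {
      ++comparisons;
      char a = q[i], b = target[p + i];
      if (a != b || a == 'N' || b == 'N') {
        if (++m > bud) break;
      }
    }
    if (m <= bud) out.push_back(p + L);
  }
}

// [[Rcpp::export(name = ".scan_candidates_cpp")]]
List scan_candidates_cpp(std::string tmpl, std::string target,
                         int L, double e1) {
  std::vector<int> cand;
  long long comparisons = 0;
  if ((int)tmpl.size() >= L && (int)target.size() >= L)
    scan_one(tmpl.c_str(), target.c_str(), (int)target.size(), L, e1,
             cand, comparisons);
  return List::create(_["candidates"] = wrap(cand),
                      _["comparisons"] = (double)comparisons);
}

// Stage-2 validation at candidate insert length n (equal mate lengths N):
// DNA check  — revcomp(r1[0..n)) vs r2[0..n) within floor(n * e2);
// adapter check — r1[n..N) vs r2[n..N) within floor((N - n) * e3),
// vacuous when n == N. A tolerance of 1 disables its check (the budget
// equals the length, which no mismatch count can exceed).
static bool validate_at(const char* s1, const char* s2, int N, int n,
                        double e2, double e3) {
  int m_dna = 0;
  for (int i = 0; i < n; ++i) {
    char a = comp(s1[n - 1 - i]), b = s2[i];
    if (a != b || a == 'N' || b == 'N') ++m_dna;
  }
  if (m_dna > budget(n, e2)) return false;
  if (n < N) {
    int m_ad = hamming_n(s1 + n, s2 + n, N - n);
    if (m_ad > budget(N - n, e3)) return false;
  }
  return true;
}

// [[Rcpp::export(name = ".validate_candidate_cpp")]]
LogicalVector validate_candidate_cpp(std::string s1, std::string s2,
                                     IntegerVector n, double e2, double e3) {
  int N = (int)s1.size();
  if ((int)s2.size() != N) stop("mates must have equal length");
  LogicalVector out(n.size());
  for (R_xlen_t i = 0; i < n.size(); ++i) {
    if (n[i] < 0 || n[i] > N) stop("candidate %d out of range [0, %d]", n[i], N);
    out[i] = validate_at(s1.c_str(), s2.c_str(), N, n[i], e2, e3);
  }
  return out;
}

// Full two-stage decision for a vector of pairs. Returns parallel vectors:
// trimmed flag, accepted insert length (NA when untrimmed and no candidate
// accepted), stage-1 intersection as a list, number of stage-2 validations
// performed, the validated candidate (NA if none accepted), per-pair
// comparison counts, and a skipped flag for pairs the algorithm cannot
// process (unequal mate lengths or mates shorter than L).
// [[Rcpp::export(name = ".trim_pairs_cpp")]]
List trim_pairs_cpp(CharacterVector seq1, CharacterVector seq2,
                    int L, double e1, double e2, double e3,
                    bool strict_singleton) {
  R_xlen_t n_pairs = seq1.size();
  if (seq2.size() != n_pairs) stop("seq1 and seq2 must have equal length");
  LogicalVector trimmed(n_pairs), skipped(n_pairs);
  IntegerVector insert_len(n_pairs, NA_INTEGER);
  IntegerVector validated(n_pairs, NA_INTEGER);
  IntegerVector n_validated(n_pairs, 0);
  NumericVector comparisons(n_pairs, 0.0);
  List candidates(n_pairs);

  for (R_xlen_t i = 0; i < n_pairs; ++i) {
    const char* s1 = CHAR(STRING_ELT(seq1, i));
    const char* s2 = CHAR(STRING_ELT(seq2, i));
    int N1 = (int)std::strlen(s1), N2 = (int)std::strlen(s2);
    if (N1 != N2 || N1 < L) {
      skipped[i] = true;
      candidates[i] = IntegerVector(0);
      continue;
    }
    int N = N1;
    std::vector<int> g1, g2;
    long long comp_count = 0;
    scan_one(s1, s2, N, L, e1, g1, comp_count);
    scan_one(s2, s1, N, L, e1, g2, comp_count);
    comparisons[i] = (double)comp_count;

    // Both scans emit candidates in ascending order; intersect by merge.
    std::vector<int> I;
    size_t a = 0, b = 0;
    while (a < g1.size() && b < g2.size()) {
      if (g1[a] < g2[b]) ++a;
      else if (g2[b] < g1[a]) ++b;
      else { I.push_back(g1[a]); ++a; ++b; }
    }
    candidates[i] = wrap(I);

    int accepted = NA_INTEGER;
    if (I.size() == 1 && !strict_singleton) {
      // A unique doubly-supported site is accepted without validation.
      accepted = I[0];
    } else if (I.size() >= 1) {
      int tried = 0;
      for (size_t k = I.size(); k-- > 0;) {
        ++tried;
        if (validate_at(s1, s2, N, I[k], e2, e3)) { accepted = I[k]; break; }
      }
      n_validated[i] = tried;
    }
    if (accepted != NA_INTEGER) {
      validated[i] = accepted;
      if (accepted < N) {            // accepted == N leaves nothing to remove
        trimmed[i] = true;
        insert_len[i] = accepted;
      }
    }
  }

  return List::create(
    _["trimmed"] = trimmed, _["insert_length"] = insert_len,
    _["candidates"] = candidates, _["validated_candidate"] = validated,
    _["n_validated"] = n_validated, _["comparisons"] = comparisons,
    _["skipped"] = skipped);
}
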