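#include <Rcpp.h>
using namespace Rcpp;

// Edge enumeration for the clonal network: all pairs of equal-length strings
// at Hamming distance exactly 1. Caller buckets by length; early exit at the
// second mismatch keeps random pairs cheap.
// [[Rcpp::export]]
IntegerMatrix hamming1_edges_cpp(CharacterVector seqs) {
  const int n = seqs.size();
  std::vector<const char*> ptr(n);
  std::vector<int> len(n);
  for (int i = 0; i < n; ++i) {
    ptr[i] = CHAR(STRING_ELT(seqs, i));
    len[i] = LENGTH(STRING_ELT(seqs, i));
  }
  std::vector<int> from, to;
  for (int i = 0; i < n; ++i) {
    for (int j = i + 1; j < n; ++j) {
      if (len[i] != len[j]) continue;
      int d = 0;
      const char *a = ptr[i], *b = ptr[j];
      for (int k = 0; k < len[i]; ++k) {
        if (a[k] != b[k] && ++d > 1) break;
      }
      if (d == 1) { from.push_back(i + 1); to.push_back(j + 1); }
    }
  }
  IntegerMatrix out(from.size(), 2);
  for (size_t e = 0; e < from.size(); ++e) {
    out(e, 0) = from[e];
    out(e, 1) = to[e];
  }
  return out;
}

// Majority-vote consensus over equal-length reads. Ties broken towards the
// lexicographically smallest base (A<C<G<T). Certainty is the mean over
// positions of the fraction of reads matching the consensus base.
// [[Rcpp::export]]
List consensus_cpp(CharacterVector seqs) {
  const int n = seqs.size();
  if (n == 0) stop("empty read group");
  const int L = LENGTH(STRING_ELT(seqs, 0));
  std::vector<const char*> ptr(n);
  for (int i = 0; i < n; ++i) {
    if (LENGTH(STRING_ELT(seqs, i)) != L)
      stop("consensus_cpp requires equal-length reads");
    ptr[i] = CHAR(STRING_ELT(seqs, i));
  }
  static const char bases[4] = {'A', 'C', 'G', 'T'};
  std::string cons(L, 'N');
  double support = 0.0;
  for (int k = 0; k < L; ++k) {
    int cnt[4] = {0, 0, 0, 0};
    for (int i = 0; i < n; ++i) {
      switch (ptr[i][k]) {
        case 'A': ++cnt[0]; break;
        case 'C': ++cnt[1]; break;
        case 'G': ++cnt[2]; break;
        case 'T': ++cnt[3]; break;
        default: break;
      }
    }
    int best = 0;
    for (int b = 1; b < 4; ++b) if (cnt[b] > cnt[best]) best = b;
    if (cnt[best] > 0) cons[k] = bases[best];
    double match = 0;
    for (int i = 0; i < n; ++i) if (ptr[i][k] == cons[k]) ++match;
    support += match / n;
  }
  return List::create(_["consensus"] = cons,
                      _["certainty"] = (L > 0) ? support / L : 1.0);
}

// Mismatches between each string and a single reference over the first
// n_compare characters (n_compare <= min length enforced by caller).
// [[Rcpp::export]]
IntegerVector mismatch_to_ref_cpp(CharacterVector seqs, std::string ref,
                                  int n_compare) {
  const int n = seqs.size();
  IntegerVector out(n);
  for (int i = 0; i < n; ++i) {
    const char *a = CHAR(STRING_ELT(seqs, i));
    int L = LENGTH(STRING_ELT(seqs, i));
    int m = std::min(n_compare, std::min(L, (int) ref.size()));
    int d = 0;
    for (int k = 0; k < m; ++k) if (a[k] != ref[k]) ++d;
    out[i] = d;
  }
  return out;
}

// Mismatches between the last n_compare characters of each string and the
// last n_compare characters of the reference (suffix alignment for J genes
// and constant regions).
// [[Rcpp::export]]
IntegerVector suffix_mismatch_cpp(CharacterVector seqs, std::string ref,
                                  int n_compare) {
  const int n = seqs.size();
  const int rlen = ref.size();
  IntegerVector out(n);
  for (int i = 0; i < n; ++i) {
    const char *a = CHAR(STRING_ELT(seqs, i));
    int L = LENGTH(STRING_ELT(seqs, i));
    int m = std::min(n_compare, std::min(L, rlen));
    int d = 0;
    for (int k = 1; k <= m; ++k) if (a[L - k] != ref[rlen - k]) ++d;
    out[i] = d;
  }
  return out;
}
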