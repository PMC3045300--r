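#include <Rcpp.h>
#include <vector>
#include <string>
using namespace Rcpp;

// Global alignment machinery shared by the PCR-error distance, the chimera
// search and the OTU distances. Two scoring schemes are used:
//   * the error-model scheme: substitution cost -log P(m|n) plus gap
//     penalties, with a reduced penalty for homopolymer gaps;
//   * the unit scheme (match 0 / mismatch 1 / gap 1) for plain percent
//     sequence difference.
// A gap column is a homopolymer gap when the inserted/deleted base equals
// either base of the *other* sequence flanking that column (run
// extension/contraction). The test is cell-local so the DP optimum is well
// defined. Ties are broken diagonal > up > left, giving a deterministic
// traceback and a deterministic alignment length.

static inline int enc(char c) {
  switch (c) {
    case 'A': case 'a': return 0;
    case 'C': case 'c': return 1;
    case 'G': case 'g': return 2;
    case 'T': case 't': return 3;
  }
  return -1;
}

struct AlnResult {
  double cost;
  int ncols;
  std::string a_aln, b_aln;
};

// scheme: 0 = error model (sub(s_true, r_obs) = subnll(s, r)), 1 = unit costs.
// a is the noisy read, b the hypothesised true sequence.
static AlnResult nw_core(const std::string &a, const std::string &b,
                         const NumericMatrix &subnll, double gap, double hgap,
                         bool unit, bool traceback) {
  const int n = a.size(), m = b.size();
  std::vector<int> ea(n), eb(m);
  for (int i = 0; i < n; ++i) {
    ea[i] = enc(a[i]);
    if (ea[i] < 0) stop("sequence contains a non-A/C/G/T character");
  }
  for (int j = 0; j < m; ++j) {
    eb[j] = enc(b[j]);
    if (eb[j] < 0) stop("sequence contains a non-A/C/G/T character");
  }
  std::vector<double> C((n + 1) * (m + 1));
  std::vector<int> L((n + 1) * (m + 1));
  std::vector<unsigned char> PT;
  if (traceback) PT.resize((n + 1) * (m + 1));
  const int W = m + 1;

  // gap cost for deleting a[i-1] (1-based i) with j chars of b consumed:
  // flanks are b[j-1] and b[j] (0-based).
  auto gap_a = [&](int i, int j) -> double {
    if (unit) return 1.0;
    char base = a[i - 1];
    bool h = (j > 0 && b[j - 1] == base) || (j < m && b[j] == base);
    return h ? hgap : gap;
  };
  auto gap_b = [&](int j, int i) -> double {
    if (unit) return 1.0;
    char base = b[j - 1];
    bool h = (i > 0 && a[i - 1] == base) || (i < n && a[i] == base);
    return h ? hgap : gap;
  };

  C[0] = 0.0; L[0] = 0;
  for (int i = 1; i <= n; ++i) {
    C[i * W] = C[(i - 1) * W] + gap_a(i, 0);
    L[i * W] = i;
    if (traceback) PT[i * W] = 1;
  }
  for (int j = 1; j <= m; ++j) {
    C[j] = C[j - 1] + gap_b(j, 0);
    L[j] = j;
    if (traceback) PT[j] = 2;
  }
  for (int i = 1; i <= n; ++i) {
    for (int j = 1; j <= m; ++j) {
      double sd = unit ? (ea[i - 1] == eb[j - 1] ? 0.0 : 1.0)
                       : subnll(eb[j - 1], ea[i - 1]);
      double cd = C[(i - 1) * W + (j - 1)] + sd;
      double cu = C[(i - 1) * W + j] + gap_a(i, j);
      double cl = C[i * W + (j - 1)] + gap_b(j, i);
      double best = cd;
      unsigned char pt = 0;
      int len = L[(i - 1) * W + (j - 1)];
      if (cu < best) { best = cu; pt = 1; len = L[(i - 1) * W + j]; }
      if (cl < best) { best = cl; pt = 2; len = L[i * W + (j - 1)]; }
      C[i * W + j] = best;
      L[i * W + j] = len + 1;
      if (traceback) PT[i * W + j] = pt;
    }
  }

  AlnResult res;
  res.cost = C[n * W + m];
  res.ncols = L[n * W + m];
  if (traceback) {
    std::string ra, rb;
    int i = n, j = m;
    while (i > 0 || j > 0) {
      unsigned char pt = PT[i * W + j];
      if (i > 0 && j > 0 && pt == 0) {
        ra.push_back(a[i - 1]); rb.push_back(b[j - 1]); --i; --j;
      } else if (i > 0 && (pt == 1 || j == 0)) {
        ra.push_back(a[i - 1]); rb.push_back('-'); --i;
      } else {
        ra.push_back('-'); rb.push_back(b[j - 1]); --j;
      }
    }
    res.a_aln.assign(ra.rbegin(), ra.rend());
    res.b_aln.assign(rb.rbegin(), rb.rend());
  }
  return res;
}

// [[Rcpp::export]]
List nw_align_pair(const std::string a, const std::string b,
                   const NumericMatrix subnll, const double gap,
                   const double hgap) {
  AlnResult r = nw_core(a, b, subnll, gap, hgap, false, true);
  return List::create(_["a"] = r.a_aln, _["b"] = r.b_aln, _["cost"] = r.cost,
                      _["ncols"] = r.ncols);
}

// e(r, S) = alignment cost / alignment columns for every read x hypothesis
// pair; reads index rows.
// [[Rcpp::export]]
NumericMatrix seq_edist_mat(const CharacterVector reads,
                            const CharacterVector hyps,
                            const NumericMatrix subnll, const double gap,
                            const double hgap) {
  const int N = reads.size(), P = hyps.size();
  NumericMatrix out(N, P);
  std::vector<std::string> rs(N), hs(P);
  for (int i = 0; i < N; ++i) rs[i] = as<std::string>(reads[i]);
  for (int k = 0; k < P; ++k) hs[k] = as<std::string>(hyps[k]);
  for (int k = 0; k < P; ++k) {
    for (int i = 0; i < N; ++i) {
      AlnResult r = nw_core(rs[i], hs[k], subnll, gap, hgap, false, false);
      out(i, k) = r.ncols > 0 ? r.cost / r.ncols : 0.0;
    }
  }
  return out;
}

// Unit-cost global alignment for every pair: differences (mismatches + gap
// columns) and alignment column counts.
// [[Rcpp::export]]
List nw_unit_mat(const CharacterVector seqs_a, const CharacterVector seqs_b) {
  const int N = seqs_a.size(), P = seqs_b.size();
  NumericMatrix diffs(N, P);
  IntegerMatrix cols(N, P);
  NumericMatrix dummy(4, 4);
  std::vector<std::string> as_(N), bs(P);
  for (int i = 0; i < N; ++i) as_[i] = as<std::string>(seqs_a[i]);
  for (int k = 0; k < P; ++k) bs[k] = as<std::string>(seqs_b[k]);
  for (int k = 0; k < P; ++k) {
    for (int i = 0; i < N; ++i) {
      AlnResult r = nw_core(as_[i], bs[k], dummy, 1.0, 1.0, true, false);
      diffs(i, k) = r.cost;
      cols(i, k) = r.ncols;
    }
  }
  return List::create(_["diffs"] = diffs, _["cols"] = cols);
}
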