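#include <Rcpp.h>
using namespace Rcpp;

// Global alignment with linear gap penalty. Tie-breaking is fixed so that the
// reported traceback (and hence the identity of co-optimal alignments) is
// deterministic: diagonal (match/mismatch) is preferred over up (gap in the
// second sequence) over left (gap in the first).

static inline double pair_score(char x, char y, double match, double mismatch) {
  return (x == y) ? match : mismatch;
}

// [[Rcpp::export]]
List nw_align_cpp(std::string a, std::string b,
                  double match, double mismatch, double gap,
                  bool denom_shorter) {
  const int n = a.size(), m = b.size();
  if (n == 0 || m == 0) stop("sequences must be non-empty");

  NumericMatrix S(n + 1, m + 1);
  for (int i = 1; i <= n; ++i) S(i, 0) = i * gap;
  for (int j = 1; j <= m; ++j) S(0, j) = j * gap;
  for (int i = 1; i <= n; ++i) {
    for (int j = 1; j <= m; ++j) {
      double diag = S(i - 1, j - 1) + pair_score(a[i - 1], b[j - 1], match, mismatch);
      double up   = S(i - 1, j) + gap;
      double left = S(i, j - 1) + gap;
      S(i, j) = std::max(diag, std::max(up, left));
    }
  }

  // traceback (diag > up > left)
  std::string ra, rb;
  int i = n, j = m;
  while (i > 0 || j > 0) {
    if (i > 0 && j > 0 &&
        S(i, j) == S(i - 1, j - 1) + pair_score(a[i - 1], b[j - 1], match, mismatch)) {
      ra.push_back(a[i - 1]); rb.push_back(b[j - 1]); --i; --j;
    } else if (i > 0 && S(i, j) == S(i - 1, j) + gap) {
      ra.push_back(a[i - 1]); rb.push_back('-'); --i;
    } else {
      ra.push_back('-'); rb.push_back(b[j - 1]); --j;
    }
  }
  std::reverse(ra.begin(), ra.end());
  std::reverse(rb.begin(), rb.end());

  int matches = 0;
  for (size_t k = 0; k < ra.size(); ++k)
    if (ra[k] != '-' && ra[k] == rb[k]) ++matches;

  double denom = denom_shorter ? (double)std::min(n, m) : (double)ra.size();
  double identity = 100.0 * matches / denom;

  return List::create(_["aligned_a"] = ra, _["aligned_b"] = rb,
                      _["score"] = S(n, m), _["identity_pct"] = identity,
                      _["n_matches"] = matches,
                      _["alignment_length"] = (int)ra.size());
}

// Identity of the deterministically tie-broken optimal alignment, computed
// without materialising the traceback: match count and alignment length are
// carried forward under the same diag > up > left preference.
static double nw_identity_pair(const std::string &a, const std::string &b,
                               double match, double mismatch, double gap,
                               bool denom_shorter) {
  const int n = a.size(), m = b.size();
  std::vector<double> Sprev(m + 1), Scur(m + 1);
  std::vector<int> Mprev(m + 1), Mcur(m + 1), Lprev(m + 1), Lcur(m + 1);
  for (int j = 0; j <= m; ++j) { Sprev[j] = j * gap; Mprev[j] = 0; Lprev[j] = j; }
  for (int i = 1; i <= n; ++i) {
    Scur[0] = i * gap; Mcur[0] = 0; Lcur[0] = i;
    for (int j = 1; j <= m; ++j) {
      double ps = pair_score(a[i - 1], b[j - 1], match, mismatch);
      double diag = Sprev[j - 1] + ps;
      double up   = Sprev[j] + gap;
      double left = Scur[j - 1] + gap;
      double best = std::max(diag, std::max(up, left));
      Scur[j] = best;
      if (best == diag) {
        Mcur[j] = Mprev[j - 1] + (a[i - 1] == b[j - 1] ? 1 : 0);
        Lcur[j] = Lprev[j - 1] + 1;
      } else if (best == up) {
        Mcur[j] = Mprev[j]; Lcur[j] = Lprev[j] + 1;
      } else {
        Mcur[j] = Mcur[j - 1]; Lcur[j] = Lcur[j - 1] + 1;
      }
    }
    std::swap(Sprev, Scur); std::swap(Mprev, Mcur); std::swap(Lprev, Lcur);
  }
  double denom = denom_shorter ? (double)std::min(n, m) : (double)Lprev[m];
  return 100.0 * Mprev[m] / denom;
}

// [[Rcpp::export]]
NumericMatrix nw_identity_matrix_cpp(CharacterVector seqs,
                                     double match, double mismatch, double gap,
                                     bool denom_shorter) {
  const int n = seqs.size();
  std::vector<std::string> s(n);
  for (int i = 0; i < n; ++i) s[i] = as<std::string>(seqs[i]);
  NumericMatrix out(n, n);
  for (int i = 0; i < n; ++i) {
    out(i, i) = 100.0;
    for (int j = i + 1; j < n; ++j) {
      // canonical (lexicographic) orientation makes identity exactly symmetric
      double id = (s[i] <= s[j])
        ? nw_identity_pair(s[i], s[j], match, mismatch, gap, denom_shorter)
        : nw_identity_pair(s[j], s[i], match, mismatch, gap, denom_shorter);
      out(i, j) = id;
      out(j, i) = id;
    }
  }
  return out;
}
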