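#include <Rcpp.h>
#include <string>
#include <vector>
#include <algorithm>

using namespace Rcpp;

// All kernels assume the R wrappers have already lower-cased their inputs.
// Strings are treated as byte sequences; generated data is restricted to
// ASCII so bytes and characters coincide.

static int lev_dp(const std::string& a, const std::string& b) {
  const int n1 = a.size(), n2 = b.size();
  if (n1 == 0) return n2;
  if (n2 == 0) return n1;
  std::vector<int> prev(n2 + 1), cur(n2 + 1);
  for (int j = 0; j <= n2; ++j) prev[j] = j;
  for (int i = 1; i <= n1; ++i) {
    cur[0] = i;
    for (int j = 1; j <= n2; ++j) {
      int sub = prev[j - 1] + (a[i - 1] == b[j - 1] ? 0 : 1);
      cur[j] = std::min(sub, std::min(prev[j] + 1, cur[j - 1] + 1));
    }
    std::swap(prev, cur);
  }
  return prev[n2];
}

// [[Rcpp::export]]
IntegerVector edit_distance_cpp(CharacterVector s1, CharacterVector s2) {
  const R_xlen_t n = s1.size();
  IntegerVector out(n);
  for (R_xlen_t i = 0; i < n; ++i)
    out[i] = lev_dp(as<std::string>(s1[i]), as<std::string>(s2[i]));
  return out;
}

// cost of inserting or deleting character c: w[c - 'a'] for 'a'..'z', else 1
static inline double indel_cost(char c, const NumericVector& w) {
  unsigned char u = static_cast<unsigned char>(c);
  if (u >= 'a' && u <= 'z') return w[u - 'a'];
  return 1.0;
}

static double weighted_lev_dp(const std::string& a, const std::string& b,
                              const NumericVector& w) {
  const int n1 = a.size(), n2 = b.size();
  std::vector<double> prev(n2 + 1), cur(n2 + 1);
  prev[0] = 0.0;
  for (int j = 1; j <= n2; ++j) prev[j] = prev[j - 1] + indel_cost(b[j - 1], w);
  for (int i = 1; i <= n1; ++i) {
    cur[0] = prev[0] + indel_cost(a[i - 1], w);
    for (int j = 1; j <= n2; ++j) {
      double sub = prev[j - 1] + (a[i - 1] == b[j - 1] ? 0.0 : 1.0);
      double del = prev[j] + indel_cost(a[i - 1], w);
      double ins = cur[j - 1] + indel_cost(b[j - 1], w);
      cur[j] = std::min(sub, std::min(del, ins));
    }
    std::swap(prev, cur);
  }
  return prev[n2];
}

// length-normalized weighted edit distance; 0 for two empty strings
// [[Rcpp::export]]
NumericVector weighted_edit_cpp(CharacterVector s1, CharacterVector s2,
                                NumericVector w) {
  const R_xlen_t n = s1.size();
  NumericVector out(n);
  for (R_xlen_t i = 0; i < n; ++i) {
    std::string a = as<std::string>(s1[i]), b = as<std::string>(s2[i]);
    int m = std::max(a.size(), b.size());
    out[i] = (m == 0) ? 0.0 : weighted_lev_dp(a, b, w) / m;
  }
  return out;
}

// Smith-Waterman-Gotoh local alignment with affine gap penalty g(k)=alpha+beta*k.
// class_of maps byte -> equivalence-class id (0 = no class).
static double sw_gotoh(const std::string& a, const std::string& b,
                       double match, double cls, double mism,
                       double alpha, double beta,
                       const IntegerVector& class_of) {
  const int n1 = a.size(), n2 = b.size();
  const double NEG = -1e100;
  std::vector<double> Mprev(n2 + 1, 0.0), Mcur(n2 + 1, 0.0);
  std::vector<double> Xprev(n2 + 1, NEG), Xcur(n2 + 1, NEG);  // gap in b (consume a)
  std::vector<double> Yprev(n2 + 1, NEG), Ycur(n2 + 1, NEG);  // gap in a (consume b)
  double best = 0.0;
  for (int i = 1; i <= n1; ++i) {
    Mcur[0] = 0.0; Xcur[0] = NEG; Ycur[0] = NEG;
    for (int j = 1; j <= n2; ++j) {
      unsigned char ca = a[i - 1], cb = b[j - 1];
      double s;
      if (ca == cb) {
        s = match;
      } else {
        int k1 = class_of[ca], k2 = class_of[cb];
        s = (k1 != 0 && k1 == k2) ? cls : mism;
      }
      double diag = std::max(Mprev[j - 1], std::max(Xprev[j - 1], Yprev[j - 1]));
      Mcur[j] = std::max(0.0, diag + s);
      // open (alpha+beta) from M or the other gap state, extend (beta) within
      Xcur[j] = std::max(Mprev[j] - alpha - beta,
                         std::max(Xprev[j] - beta, Yprev[j] - alpha - beta));
      Ycur[j] = std::max(Mcur[j - 1] - alpha - beta,
                         std::max(Ycur[j - 1] - beta, Xcur[j - 1] - alpha - beta));
      if (Mcur[j] > best) best = Mcur[j];
    }
    std::swap(Mprev, Mcur); std::swap(Xprev, Xcur); std::swap(Yprev, Ycur);
  }
  return best;
}

// local alignment score scaled to [0,1] by match * min(n1, n2)
// [[Rcpp::export]]
NumericVector monge_elkan_cpp(CharacterVector s1, CharacterVector s2,
                              double match, double cls, double mism,
                              double alpha, double beta,
                              IntegerVector class_of) {
  const R_xlen_t n = s1.size();
  NumericVector out(n);
  for (R_xlen_t i = 0; i < n; ++i) {
    std::string a = as<std::string>(s1[i]), b = as<std::string>(s2[i]);
    if (a.empty() || b.empty())
      stop("monge_elkan() is undefined for empty strings");
    double raw = sw_gotoh(a, b, match, cls, mism, alpha, beta, class_of);
    double denom = match * std::min(a.size(), b.size());
    double v = raw / denom;
    out[i] = std::max(0.0, std::min(1.0, v));
  }
  return out;
}

// Jaro similarity with the matching window |i - j| <= floor(min(n1, n2) / 2)
// and T = half the number of matched characters appearing in different order.
static double jaro_one(const std::string& a, const std::string& b) {
  const int n1 = a.size(), n2 = b.size();
  if (n1 == 0 || n2 == 0) return 0.0;
  const int win = std::min(n1, n2) / 2;
  std::vector<bool> used(n2, false);
  std::string ma, mb;
  for (int i = 0; i < n1; ++i) {
    int lo = std::max(0, i - win), hi = std::min(n2 - 1, i + win);
    for (int j = lo; j <= hi; ++j) {
      if (!used[j] && a[i] == b[j]) { used[j] = true; ma.push_back(a[i]); break; }
    }
  }
  int m = ma.size();
  if (m == 0) return 0.0;
  for (int j = 0; j < n2; ++j) if (used[j]) mb.push_back(b[j]);
  int disorder = 0;
  for (int k = 0; k < m; ++k) if (ma[k] != mb[k]) ++disorder;
  double t = disorder / 2.0;
  double md = m;
  return (md / n1 + md / n2 + (md - t) / md) / 3.0;
}

// [[Rcpp::export]]
NumericVector jaro_cpp(CharacterVector s1, CharacterVector s2) {
  const R_xlen_t n = s1.size();
  NumericVector out(n);
  for (R_xlen_t i = 0; i < n; ++i)
    out[i] = jaro_one(as<std::string>(s1[i]), as<std::string>(s2[i]));
  return out;
}

// [[Rcpp::export]]
NumericVector jaro_winkler_cpp(CharacterVector s1, CharacterVector s2) {
  const R_xlen_t n = s1.size();
  NumericVector out(n);
  for (R_xlen_t i = 0; i < n; ++i) {
    std::string a = as<std::string>(s1[i]), b = as<std::string>(s2[i]);
    double jr = jaro_one(a, b);
    int p = 0;
    int lim = std::min(a.size(), b.size());
    while (p < lim && a[p] == b[p]) ++p;
    out[i] = jr + (std::min(p, 4) / 10.0) * (1.0 - jr);
  }
  return out;
}

// multiset intersection count of length-n substrings; each occurrence in a
// matches at most one unmatched occurrence in b
// [[Rcpp::export]]
NumericVector ngram_dice_cpp(CharacterVector s1, CharacterVector s2,
                             int n, bool length_denominator) {
  const R_xlen_t np = s1.size();
  NumericVector out(np);
  for (R_xlen_t i = 0; i < np; ++i) {
    std::string a = as<std::string>(s1[i]), b = as<std::string>(s2[i]);
    const int n1 = a.size(), n2 = b.size();
    const int m1 = n1 - n + 1, m2 = n2 - n + 1;
    if (m1 <= 0 || m2 <= 0) { out[i] = 0.0; continue; }
    std::vector<bool> used(m2, false);
    int c = 0;
    for (int p = 0; p < m1; ++p) {
      for (int q = 0; q < m2; ++q) {
        if (!used[q] && a.compare(p, n, b, q, n) == 0) { used[q] = true; ++c; break; }
      }
    }
    double denom = length_denominator ? (double)(n1 + n2) : (double)(m1 + m2);
    out[i] = denom > 0 ? 2.0 * c / denom : 0.0;
  }
  return out;
}
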