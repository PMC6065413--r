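#include <Rcpp.h>
#include <R_ext/Random.h>
#include <algorithm>
#include <vector>

using namespace Rcpp;

// median of x[0..n-1]; scrambles the buffer
static double med(std::vector<double> &x, int n) {
  int h = n / 2;
  std::nth_element(x.begin(), x.begin() + h, x.begin() + n);
  double hi = x[h];
  if (n % 2 == 1) return hi;
  double lo = *std::max_element(x.begin(), x.begin() + h);
  return 0.5 * (lo + hi);
}

// Null distribution of median(group2) - median(group1) when a random
// m-subset of tissues is assigned to group2. Uses R's RNG stream.
// [[Rcpp::export]]
NumericVector cpp_perm_median_null(NumericVector values, int m, int nperm) {
  int T = values.size();
  if (m < 1 || m >= T) stop("group2 size must be in [1, T-1]");
  std::vector<int> idx(T);
  std::vector<double> g2(T), g1(T);
  NumericVector out(nperm);
  GetRNGstate();
  for (int p = 0; p < nperm; ++p) {
    for (int i = 0; i < T; ++i) idx[i] = i;
    for (int i = 0; i < m; ++i) {
      int j = i + (int)R_unif_index((double)(T - i));
      std::swap(idx[i], idx[j]);
    }
    for (int i = 0; i < m; ++i) g2[i] = values[idx[i]];
    for (int i = m; i < T; ++i) g1[i - m] = values[idx[i]];
    out[p] = med(g2, m) - med(g1, T - m);
  }
  PutRNGstate();
  return out;
}

// One-sided / two-sided KS distance between the ECDFs of the ON and OFF
// groups, right-continuous convention (evaluated at the end of tie blocks).
// side: 1 = ON stochastically greater (D = max F_off - F_on),
//       2 = ON stochastically less   (D = max F_on - F_off),
//       3 = two-sided                (D = max |F_on - F_off|).
static double ks_dist(const std::vector<int> &ord, const NumericVector &values,
                      const LogicalVector &on, int side) {
  int n = ord.size();
  int nOn = 0;
  for (int i = 0; i < n; ++i) if (on[i]) ++nOn;
  int nOff = n - nOn;
  if (nOn == 0 || nOff == 0) return NA_REAL;
  double cOn = 0, cOff = 0, D = 0;
  for (int i = 0; i < n; ++i) {
    int g = ord[i];
    if (on[g]) cOn += 1.0; else cOff += 1.0;
    bool blockEnd = (i == n - 1) || (values[ord[i + 1]] != values[g]);
    if (blockEnd) {
      double d = cOff / nOff - cOn / nOn; // > 0 when ON values run larger
      double cand = (side == 1) ? d : (side == 2) ? -d : std::fabs(d);
      if (cand > D) D = cand;
    }
  }
  return D;
}

// [[Rcpp::export]]
double cpp_ks_distance(NumericVector values, LogicalVector on, int side) {
  int n = values.size();
  std::vector<int> ord(n);
  for (int i = 0; i < n; ++i) ord[i] = i;
  std::sort(ord.begin(), ord.end(),
            [&](int a, int b) { return values[a] < values[b]; });
  return ks_dist(ord, values, on, side);
}

// Null KS distances from label permutations (group sizes fixed).
// [[Rcpp::export]]
NumericVector cpp_ks_perm_null(NumericVector values, LogicalVector on,
                               int nperm, int side) {
  int n = values.size();
  std::vector<int> ord(n);
  for (int i = 0; i < n; ++i) ord[i] = i;
  std::sort(ord.begin(), ord.end(),
            [&](int a, int b) { return values[a] < values[b]; });
  LogicalVector lab = clone(on);
  NumericVector out(nperm);
  GetRNGstate();
  for (int p = 0; p < nperm; ++p) {
    for (int i = n - 1; i > 0; --i) {
      int j = (int)R_unif_index((double)(i + 1));
      int tmp = lab[i]; lab[i] = lab[j]; lab[j] = tmp;
    }
    out[p] = ks_dist(ord, values, lab, side);
  }
  PutRNGstate();
  return out;
}

// nNull means of uniformly drawn (without replacement) size-k gene sets.
// [[Rcpp::export]]
NumericVector cpp_null_means(NumericVector x, int k, int nNull) {
  int n = x.size();
  if (k < 1 || k > n) stop("set size out of range");
  std::vector<int> idx(n);
  for (int i = 0; i < n; ++i) idx[i] = i;
  NumericVector out(nNull);
  std::vector<int> swapped(k);
  GetRNGstate();
  for (int p = 0; p < nNull; ++p) {
    double s = 0;
    for (int i = 0; i < k; ++i) {
      int j = i + (int)R_unif_index((double)(n - i));
      std::swap(idx[i], idx[j]);
      swapped[i] = j;
      s += x[idx[i]];
    }
    out[p] = s / k;
    for (int i = k - 1; i >= 0; --i) std::swap(idx[i], idx[swapped[i]]);
  }
  PutRNGstate();
  return out;
}
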