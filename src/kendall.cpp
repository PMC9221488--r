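#include <Rcpp.h>
#include <algorithm>
#include <vector>

using namespace Rcpp;

// Merge sort on y that counts "discordant" swaps (inversions).
static double merge_count(std::vector<double>& y, std::vector<double>& buf,
                          std::size_t lo, std::size_t hi) {
  if (hi - lo < 2) return 0.0;
  std::size_t mid = lo + (hi - lo) / 2;
  double inv = merge_count(y, buf, lo, mid) + merge_count(y, buf, mid, hi);
  std::size_t i = lo, j = mid, k = lo;
  while (i < mid && j < hi) {
    if (y[j] < y[i]) {
      inv += static_cast<double>(mid - i);
      buf[k++] = y[j++];
    } else {
      buf[k++] = y[i++];
    }
  }
  while (i < mid) buf[k++] = y[i++];
  while (j < hi) buf[k++] = y[j++];
  std::copy(buf.begin() + lo, buf.begin() + hi, y.begin() + lo);
  return inv;
}

// Sum of m*(m-1)/2 over runs of equal values in a sorted vector.
static double tie_pairs(const std::vector<double>& v) {
  double s = 0.0;
  std::size_t i = 0, n = v.size();
  while (i < n) {
    std::size_t j = i + 1;
    while (j < n && v[j] == v[i]) ++j;
    double m = static_cast<double>(j - i);
    s += m * (m - 1.0) / 2.0;
    i = j;
  }
  return s;
}

// Kendall tau-b by Knight's O(n log n) algorithm.
// [[Rcpp::export(name = ".kendall_tau_cpp")]]
double kendall_tau_cpp(NumericVector x, NumericVector y) {
  std::size_t n = x.size();
  if (y.size() != static_cast<R_xlen_t>(n))
    stop("x and y must have equal length");
  if (n < 2) stop("need at least 2 observations");

  std::vector<std::size_t> idx(n);
  for (std::size_t i = 0; i < n; ++i) idx[i] = i;
  std::sort(idx.begin(), idx.end(), [&](std::size_t a, std::size_t b) {
    if (x[a] != x[b]) return x[a] < x[b];
    return y[a] < y[b];
  });

  std::vector<double> xs(n), ys(n);
  for (std::size_t i = 0; i < n; ++i) { xs[i] = x[idx[i]]; ys[i] = y[idx[i]]; }

  double n0 = static_cast<double>(n) * (n - 1.0) / 2.0;
  double n1 = tie_pairs(xs);            // pairs tied in x
  // pairs tied in both x and y (runs of equal (x,y))
  double n3 = 0.0;
  {
    std::size_t i = 0;
    while (i < n) {
      std::size_t j = i + 1;
      while (j < n && xs[j] == xs[i] && ys[j] == ys[i]) ++j;
      double m = static_cast<double>(j - i);
      n3 += m * (m - 1.0) / 2.0;
      i = j;
    }
  }
  std::vector<double> ys2(ys), buf(n);
  double swaps = merge_count(ys2, buf, 0, n);
  std::vector<double> ysorted(ys2);     // now sorted by y
  double n2 = tie_pairs(ysorted);       // pairs tied in y

  // Knight: concordant - discordant = n0 - n1 - n2 + n3 - 2*swaps
  double num = n0 - n1 - n2 + n3 - 2.0 * swaps;
  double den = std::sqrt((n0 - n1) * (n0 - n2));
  if (den <= 0) stop("degenerate input: a variable is constant");
  return num / den;
}

// All-pairs tau matrix for the columns of U.
// [[Rcpp::export(name = ".kendall_tau_matrix_cpp")]]
NumericMatrix kendall_tau_matrix_cpp(NumericMatrix U) {
  int p = U.ncol();
  NumericMatrix out(p, p);
  for (int i = 0; i < p; ++i) {
    out(i, i) = 1.0;
    for (int j = i + 1; j < p; ++j) {
      double t = kendall_tau_cpp(U(_, i), U(_, j));
      out(i, j) = t;
      out(j, i) = t;
    }
  }
  return out;
}
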