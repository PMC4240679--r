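#include <Rcpp.h>
#include <vector>
#include <cmath>

using namespace Rcpp;

// Least-squares linear segmentation of (x, y) into `nseg` contiguous segments.
//
// Each segment is fitted by its own unconstrained least-squares line; the
// objective is the total squared residual. Returns the 1-based end index of
// every segment. Among segmentations whose cost ties with the optimum (within
// a relative tolerance), the lexicographically smallest breakpoint vector is
// returned, reconstructed front-to-back from a suffix DP table.

static inline long double seg_cost(const std::vector<long double>& Sx,
                                   const std::vector<long double>& Sy,
                                   const std::vector<long double>& Sxx,
                                   const std::vector<long double>& Sxy,
                                   const std::vector<long double>& Syy,
                                   const std::vector<long double>& invm,
                                   int i, int j) {
  // cost of fitting points i..j (1-based, inclusive)
  long double im  = invm[j - i + 1];
  long double sx  = Sx[j]  - Sx[i - 1];
  long double sy  = Sy[j]  - Sy[i - 1];
  long double sxx = Sxx[j] - Sxx[i - 1];
  long double sxy = Sxy[j] - Sxy[i - 1];
  long double syy = Syy[j] - Syy[i - 1];
  long double vxx = sxx - sx * sx * im;
  long double vxy = sxy - sx * sy * im;
  long double vyy = syy - sy * sy * im;
  long double c = vyy;
  if (vxx > 1e-24L) c -= vxy * vxy / vxx;
  if (c < 0) c = 0;
  return c;
}

// [[Rcpp::export]]
List cpp_segment_dp(NumericVector x, NumericVector y, int nseg,
                    double tol_rel = 1e-9) {
  int n = y.size();
  if (x.size() != n) stop("x and y must have equal length");
  if (nseg < 1) stop("nseg must be >= 1");
  if (n < nseg) stop("need at least one point per segment");

  std::vector<long double> Sx(n + 1, 0), Sy(n + 1, 0), Sxx(n + 1, 0),
      Sxy(n + 1, 0), Syy(n + 1, 0), invm(n + 1, 0);
  for (int m = 1; m <= n; ++m) invm[m] = 1.0L / (long double)m;
  for (int i = 1; i <= n; ++i) {
    long double xi = x[i - 1], yi = y[i - 1];
    Sx[i]  = Sx[i - 1]  + xi;
    Sy[i]  = Sy[i - 1]  + yi;
    Sxx[i] = Sxx[i - 1] + xi * xi;
    Sxy[i] = Sxy[i - 1] + xi * yi;
    Syy[i] = Syy[i - 1] + yi * yi;
  }

  // B[s][i]: minimal cost of covering i..n with s segments
  std::vector<std::vector<long double>> B(
      nseg + 1, std::vector<long double>(n + 2, 0));
  for (int i = 1; i <= n; ++i)
    B[1][i] = seg_cost(Sx, Sy, Sxx, Sxy, Syy, invm, i, n);
  for (int s = 2; s <= nseg; ++s) {
    // first segment may end at j, j+1..n must still fit s-1 segments
    for (int i = 1; i <= n - s + 1; ++i) {
      long double best = -1;
      for (int j = i; j <= n - s + 1; ++j) {
        long double c = seg_cost(Sx, Sy, Sxx, Sxy, Syy, invm, i, j) + B[s - 1][j + 1];
        if (best < 0 || c < best) best = c;
      }
      B[s][i] = best;
    }
  }

  long double total = B[nseg][1];

  // front-to-back reconstruction: smallest feasible end for every segment
  IntegerVector ends(nseg);
  int pos = 1;
  for (int s = nseg; s >= 2; --s) {
    long double target = B[s][pos];
    long double tol = (long double)tol_rel * (1.0L + std::fabs((double)target));
    int chosen = -1;
    for (int j = pos; j <= n - s + 1; ++j) {
      long double c =
          seg_cost(Sx, Sy, Sxx, Sxy, Syy, invm, pos, j) + B[s - 1][j + 1];
      if (c <= target + tol) { chosen = j; break; }
    }
    if (chosen < 0) chosen = n - s + 1;  // numerical safety net
    ends[nseg - s] = chosen;
    pos = chosen + 1;
  }
  ends[nseg - 1] = n;

  return List::create(_["ends"] = ends, _["cost"] = (double)total);
}

// Longest strictly increasing subsequence by patience sorting with a
// deterministic backtrace: each element records the element currently on top
// of the previous pile; the reported LIS is traced back from the top of the
// last pile. Returns 1-based indices.

// [[Rcpp::export]]
IntegerVector cpp_lis(NumericVector v) {
  int n = v.size();
  if (n == 0) return IntegerVector(0);
  std::vector<double> tails;          // smallest tail value per pile
  std::vector<int> tail_idx;          // index of element on top of each pile
  std::vector<int> pred(n, -1);
  std::vector<int> pile_of(n, -1);
  tails.reserve(n); tail_idx.reserve(n);
  for (int i = 0; i < n; ++i) {
    // first pile whose top >= v[i]  (strict LIS)
    int lo = 0, hi = (int)tails.size();
    while (lo < hi) {
      int mid = (lo + hi) / 2;
      if (tails[mid] < v[i]) lo = mid + 1; else hi = mid;
    }
    if (lo == (int)tails.size()) { tails.push_back(v[i]); tail_idx.push_back(i); }
    else { tails[lo] = v[i]; tail_idx[lo] = i; }
    pile_of[i] = lo;
    pred[i] = (lo > 0) ? tail_idx[lo - 1] : -1;
  }
  int len = (int)tails.size();
  IntegerVector out(len);
  int cur = tail_idx[len - 1];
  for (int k = len - 1; k >= 0; --k) { out[k] = cur + 1; cur = pred[cur]; }
  return out;
}

// Membership in *any* LIS: element i lies on some maximum-length strictly
// increasing subsequence iff lenEnd(i) + lenStart(i) - 1 == max length.
// O(n^2); intended for moderate n.

// [[Rcpp::export]]
LogicalVector cpp_lis_members(NumericVector v) {
  int n = v.size();
  LogicalVector out(n);
  if (n == 0) return out;
  std::vector<int> fwd(n, 1), bwd(n, 1);
  for (int i = 0; i < n; ++i)
    for (int j = 0; j < i; ++j)
      if (v[j] < v[i] && fwd[j] + 1 > fwd[i]) fwd[i] = fwd[j] + 1;
  for (int i = n - 1; i >= 0; --i)
    for (int j = n - 1; j > i; --j)
      if (v[j] > v[i] && bwd[j] + 1 > bwd[i]) bwd[i] = bwd[j] + 1;
  int best = 0;
  for (int i = 0; i < n; ++i) best = std::max(best, fwd[i]);
  for (int i = 0; i < n; ++i) out[i] = (fwd[i] + bwd[i] - 1 == best);
  return out;
}
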