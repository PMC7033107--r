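#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Euclidean distance between rows i and j, accumulated in long double to
// match R's sum() on the same terms.
static inline double row_dist(const double *x, int n, int m, int i, int j) {
  long double acc = 0.0L;
  for (int c = 0; c < m; ++c) {
    double d = x[i + (size_t)c * n] - x[j + (size_t)c * n];
    acc += (long double)(d * d);
  }
  return std::sqrt((double)acc);
}

// Full symmetric Euclidean distance matrix with the same accumulation
// order as rqa_count, so both routes threshold identical values.
// [[Rcpp::export]]
NumericMatrix dist_matrix_cpp(NumericMatrix pts) {
  const int n = pts.nrow(), m = pts.ncol();
  const double *x = REAL(pts);
  NumericMatrix out(n, n);
  for (int j = 0; j < n; ++j)
    for (int i = 0; i < j; ++i) {
      double d = row_dist(x, n, m, i, j);
      out(i, j) = d;
      out(j, i) = d;
    }
  return out;
}

// Recurrence counting over the upper triangle of the (implicit)
// recurrence matrix, diagonal by diagonal, without materializing it.
// Returns raw counts; the R wrapper assembles %REC/%DET/%MAXLINE.
// [[Rcpp::export]]
List rqa_count(NumericMatrix pts, double radius_fraction, int theiler,
               int min_line) {
  const int n = pts.nrow(), m = pts.ncol();
  const double *x = REAL(pts);
  if (n < 2) stop("need at least 2 embedded points");

  // pass 1: maximum pairwise distance (all pairs, band included);
  // maximizing the squared distance and taking one sqrt gives the same
  // value as maximizing the rounded sqrt (sqrt is monotone)
  long double d2max = 0.0L;
  for (int k = 1; k < n; ++k)
    for (int i = 0; i + k < n; ++i) {
      long double acc = 0.0L;
      for (int c = 0; c < m; ++c) {
        double d = x[i + (size_t)c * n] - x[i + k + (size_t)c * n];
        acc += (long double)(d * d);
      }
      if (acc > d2max) d2max = acc;
    }
  double dmax = std::sqrt((double)d2max);
  if (dmax <= 0.0) return List::create(_["degenerate"] = true);
  const double eps = radius_fraction * dmax;

  // pass 2: recurrent cells and diagonal runs on off-band diagonals
  long long valid = 0, recur = 0, det_pts = 0;
  int lmax_any = 0, lmax_q = 0;
  std::vector<long long> hist; // hist[L-1] = number of maximal runs of length L
  for (int k = std::max(theiler, 1); k < n; ++k) {
    int run = 0;
    valid += n - k;
    for (int i = 0; i + k < n; ++i) {
      bool rec = row_dist(x, n, m, i, i + k) <= eps;
      if (rec) {
        ++recur;
        ++run;
      }
      if ((!rec || i + k == n - 1) && run > 0) {
        if ((size_t)run > hist.size()) hist.resize(run, 0);
        ++hist[run - 1];
        if (run > lmax_any) lmax_any = run;
        if (run >= min_line) {
          det_pts += run;
          if (run > lmax_q) lmax_q = run;
        }
        run = 0;
      }
    }
  }
  IntegerVector lens(hist.size());
  NumericVector cnts(hist.size());
  for (size_t i = 0; i < hist.size(); ++i) {
    lens[i] = (int)(i + 1);
    cnts[i] = (double)hist[i];
  }
  return List::create(
    _["degenerate"] = false,
    _["dmax"] = dmax, _["radius"] = eps,
    _["valid_upper"] = (double)valid, _["recurrent_upper"] = (double)recur,
    _["det_points_upper"] = (double)det_pts,
    _["lmax_any"] = lmax_any, _["lmax_qualifying"] = lmax_q,
    _["run_length"] = lens, _["run_count"] = cnts);
}
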