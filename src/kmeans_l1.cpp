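#include <Rcpp.h>
#include <random>
#include <algorithm>
using namespace Rcpp;

// L1 (k-medians) Lloyd iteration: manhattan-distance assignment,
// coordinate-wise median centroid update. Restarts use uniformly sampled
// distinct data points as initial centroids; each restart's RNG stream is
// derived deterministically from the master seed. Empty clusters are
// re-seeded at the point farthest (L1) from its current centroid.

static double l1_dist(const double *a, const double *b, int d) {
  double s = 0.0;
  for (int c = 0; c < d; ++c) s += std::fabs(a[c] - b[c]);
  return s;
}

static double median_inplace(std::vector<double> &v) {
  size_t n = v.size();
  size_t mid = n / 2;
  std::nth_element(v.begin(), v.begin() + mid, v.end());
  double hi = v[mid];
  if (n % 2 == 1) return hi;
  std::nth_element(v.begin(), v.begin() + mid - 1, v.begin() + mid);
  return 0.5 * (hi + v[mid - 1]);
}

// [[Rcpp::export]]
List kmeans_l1_cpp(NumericMatrix x, int k, int restarts, int max_iter,
                   int seed) {
  const int n = x.nrow(), d = x.ncol();
  if (k > n) stop("K exceeds the number of data points");
  // row-major copy for cache-friendly distance loops
  std::vector<double> X((size_t)n * d);
  for (int i = 0; i < n; ++i)
    for (int c = 0; c < d; ++c) X[(size_t)i * d + c] = x(i, c);

  std::vector<int> best_labels(n);
  std::vector<double> best_cent((size_t)k * d);
  double best_obj = R_PosInf;
  int best_restart = -1, best_iters = 0;

  std::vector<int> labels(n), counts(k);
  std::vector<double> cent((size_t)k * d), dist(n);
  std::vector<double> buf, hist, best_hist;

  for (int r = 0; r < restarts; ++r) {
    std::mt19937 rng((uint32_t)seed + 0x9E3779B1u * (uint32_t)(r + 1));
    // sample k distinct initial rows (partial Fisher-Yates)
    std::vector<int> idx(n);
    for (int i = 0; i < n; ++i) idx[i] = i;
    for (int c = 0; c < k; ++c) {
      std::uniform_int_distribution<int> u(c, n - 1);
      std::swap(idx[c], idx[u(rng)]);
      std::copy(&X[(size_t)idx[c] * d], &X[(size_t)idx[c] * d] + d,
                &cent[(size_t)c * d]);
    }
    std::fill(labels.begin(), labels.end(), -1);
    double obj = R_PosInf;
    int it = 0;
    hist.clear();
    for (it = 0; it < max_iter; ++it) {
      // assignment
      bool changed = false;
      for (int i = 0; i < n; ++i) {
        double dbest = R_PosInf;
        int lbest = 0;
        for (int c = 0; c < k; ++c) {
          double dd = l1_dist(&X[(size_t)i * d], &cent[(size_t)c * d], d);
          if (dd < dbest) { dbest = dd; lbest = c; }
        }
        if (lbest != labels[i]) { labels[i] = lbest; changed = true; }
        dist[i] = dbest;
      }
      // empty-cluster repair: move the centroid to the point farthest from
      // its assigned centroid, then reassign
      std::fill(counts.begin(), counts.end(), 0);
      for (int i = 0; i < n; ++i) counts[labels[i]]++;
      bool repaired = false;
      for (int c = 0; c < k; ++c) {
        if (counts[c] == 0) {
          int far = 0;
          double dmax = -1.0;
          for (int i = 0; i < n; ++i)
            if (counts[labels[i]] > 1 && dist[i] > dmax) {
              dmax = dist[i]; far = i;
            }
          std::copy(&X[(size_t)far * d], &X[(size_t)far * d] + d,
                    &cent[(size_t)c * d]);
          counts[labels[far]]--;
          labels[far] = c;
          counts[c] = 1;
          dist[far] = 0.0;
          repaired = true;
        }
      }
      if (repaired) {
        changed = true;
        for (int i = 0; i < n; ++i) {
          double dbest = R_PosInf;
          int lbest = 0;
          for (int c = 0; c < k; ++c) {
            double dd = l1_dist(&X[(size_t)i * d], &cent[(size_t)c * d], d);
            if (dd < dbest) { dbest = dd; lbest = c; }
          }
          labels[i] = lbest;
          dist[i] = dbest;
        }
      }
      obj = 0.0;
      for (int i = 0; i < n; ++i) obj += dist[i];
      hist.push_back(obj);
      if (!changed) break;
      // coordinate-wise median update
      for (int c = 0; c < k; ++c) {
        for (int col = 0; col < d; ++col) {
          buf.clear();
          for (int i = 0; i < n; ++i)
            if (labels[i] == c) buf.push_back(X[(size_t)i * d + col]);
          if (!buf.empty())
            cent[(size_t)c * d + col] = median_inplace(buf);
        }
      }
    }
    // final objective under the final centroids
    obj = 0.0;
    for (int i = 0; i < n; ++i) {
      double dbest = R_PosInf;
      int lbest = 0;
      for (int c = 0; c < k; ++c) {
        double dd = l1_dist(&X[(size_t)i * d], &cent[(size_t)c * d], d);
        if (dd < dbest) { dbest = dd; lbest = c; }
      }
      labels[i] = lbest;
      obj += dbest;
    }
    if (obj < best_obj) {
      best_obj = obj;
      best_labels = labels;
      best_cent = cent;
      best_restart = r + 1;
      best_iters = it + 1;
      best_hist = hist;
    }
  }

  NumericMatrix cent_out(k, d);
  IntegerVector lab_out(n);
  for (int c = 0; c < k; ++c)
    for (int col = 0; col < d; ++col) cent_out(c, col) = best_cent[(size_t)c * d + col];
  for (int i = 0; i < n; ++i) lab_out[i] = best_labels[i] + 1;
  return List::create(_["centroids"] = cent_out, _["labels"] = lab_out,
                      _["objective"] = best_obj,
                      _["best_restart"] = best_restart,
                      _["iterations"] = best_iters,
                      _["objective_trace"] = NumericVector(best_hist.begin(),
                                                           best_hist.end()));
}

// Per-frame mean L1 distance to all other frames, via per-coordinate
// sorted prefix sums: O(d * n log n) instead of the O(n^2) pairwise matrix.
// [[Rcpp::export]]
NumericVector mean_l1_distances_cpp(NumericMatrix x) {
  const int n = x.nrow(), d = x.ncol();
  std::vector<double> tot(n, 0.0);
  std::vector<int> ord(n);
  std::vector<double> xs(n), cs(n);
  for (int col = 0; col < d; ++col) {
    for (int i = 0; i < n; ++i) ord[i] = i;
    std::sort(ord.begin(), ord.end(), [&](int a, int b) {
      return x(a, col) < x(b, col);
    });
    double run = 0.0;
    for (int r = 0; r < n; ++r) {
      xs[r] = x(ord[r], col);
      run += xs[r];
      cs[r] = run;
    }
    const double S = run;
    for (int r = 0; r < n; ++r) {
      // sum_u |x - x_u| with x at sorted rank r (0-based)
      tot[ord[r]] += xs[r] * (2.0 * (r + 1) - n) + S - 2.0 * cs[r];
    }
  }
  NumericVector out(n);
  for (int i = 0; i < n; ++i) out[i] = tot[i] / std::max(n - 1, 1);
  return out;
}
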