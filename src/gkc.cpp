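#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Gaussian kernel convolution of insertion positions: f(x) = sum_i exp(-(x - p_i)^2 / (2 h^2)).
// Direct evaluation at arbitrary (sorted) eval points, with optional truncation of
// contributions beyond truncate_sd * h (absolute error <= n * exp(-truncate_sd^2 / 2)).
// [[Rcpp::export]]
NumericVector cpp_kernel_density(NumericVector positions, double h,
                                 NumericVector eval_points, double truncate_sd) {
  const R_xlen_t n = positions.size(), m = eval_points.size();
  NumericVector out(m);
  const double inv2h2 = 1.0 / (2.0 * h * h);
  const bool trunc = R_finite(truncate_sd);
  const double radius = trunc ? truncate_sd * h : 0.0;
  R_xlen_t lo = 0, hi = 0; // window [lo, hi) of positions within radius of x
  for (R_xlen_t j = 0; j < m; ++j) {
    const double x = eval_points[j];
    double s = 0.0;
    if (trunc) {
      while (lo < n && positions[lo] < x - radius) ++lo;
      if (hi < lo) hi = lo;
      while (hi < n && positions[hi] <= x + radius) ++hi;
      for (R_xlen_t i = lo; i < hi; ++i) {
        const double d = x - positions[i];
        s += std::exp(-d * d * inv2h2);
      }
    } else {
      for (R_xlen_t i = 0; i < n; ++i) {
        const double d = x - positions[i];
        s += std::exp(-d * d * inv2h2);
      }
    }
    out[j] = s;
  }
  return out;
}

// Same convolution evaluated on a regular grid g_j = grid_start + j * grid_step,
// j = 0 .. n_grid-1, truncated at truncate_sd * h. Uses the recurrence
//   K(d + s) = K(d) * C * q(d),  C = exp(-s^2/(2h^2)),  q(d) = exp(-d s / h^2),
//   q(d + s) = q(d) * D,         D = exp(-s^2/h^2),
// started at the grid point nearest each insertion, so each grid cell costs two
// multiplications instead of one exp. Positions need not be sorted.
// [[Rcpp::export]]
NumericVector cpp_kd_grid(NumericVector positions, double h, double grid_start,
                          double grid_step, int n_grid, double truncate_sd) {
  NumericVector out(n_grid);
  const double inv2h2 = 1.0 / (2.0 * h * h);
  const double s = grid_step;
  const double C = std::exp(-s * s * inv2h2);
  const double D = C * C;
  const double radius = truncate_sd * h;
  const R_xlen_t n = positions.size();
  for (R_xlen_t i = 0; i < n; ++i) {
    const double p = positions[i];
    long jc = lround((p - grid_start) / s);
    if (jc < 0) jc = 0;
    if (jc > n_grid - 1) jc = n_grid - 1;
    long jlo = (long)std::ceil((p - radius - grid_start) / s);
    long jhi = (long)std::floor((p + radius - grid_start) / s);
    if (jlo < 0) jlo = 0;
    if (jhi > n_grid - 1) jhi = n_grid - 1;
    if (jlo > jhi) continue;
    if (jc < jlo) jc = jlo;
    if (jc > jhi) jc = jhi;
    const double dc = grid_start + jc * s - p;
    const double Kc = std::exp(-dc * dc * inv2h2);
    const double rc = std::exp(-dc * s * 2.0 * inv2h2); // exp(-dc * s / h^2)
    out[jc] += Kc;
    double K = Kc, r = rc;
    for (long j = jc + 1; j <= jhi; ++j) { // upward sweep
      K *= C * r;
      r *= D;
      out[j] += K;
    }
    K = Kc; r = rc;
    for (long j = jc - 1; j >= jlo; --j) { // downward sweep
      K *= C / r;
      r /= D;
      out[j] += K;
    }
  }
  return out;
}

// Indices (1-based) of local maxima of a height profile: strictly greater than
// the nearest differing value on each side; plateaus report their leftmost
// point; profile ends count as maxima when they exceed their inner neighbor.
// [[Rcpp::export]]
IntegerVector cpp_local_maxima(NumericVector v) {
  const R_xlen_t n = v.size();
  std::vector<int> idx;
  if (n == 0) return IntegerVector(0);
  if (n == 1) {
    if (v[0] > 0) idx.push_back(1);
    return wrap(idx);
  }
  R_xlen_t i = 0;
  while (i < n) {
    R_xlen_t j = i;
    while (j + 1 < n && v[j + 1] == v[i]) ++j; // run [i, j] of equal values
    const bool left_ok = (i == 0) || (v[i - 1] < v[i]);
    const bool right_ok = (j == n - 1) || (v[j + 1] < v[i]);
    if (left_ok && right_ok) idx.push_back((int)(i + 1));
    i = j + 1;
  }
  return wrap(idx);
}

// Monte-Carlo null for CIS calling: n_perm replicates place the observed number
// of insertions uniformly at random (with replacement) over TTAA positions --
// per chromosome (chrom_matched = true) or genome-wide proportional to TTAA
// counts -- then record, at every kernel width, the heights of all local maxima
// supported by >= min_insertions insertions within +/- h, the genome-wide
// maximum height, and the number of peaks. Uses R's RNG (seed-reproducible).
// Hot path: the convolution uses the same recurrence as cpp_kd_grid, writing
// into preallocated buffers.
static void kd_grid_buf(const std::vector<double> &pos, double h, double s,
                        int ng, double truncate_sd, std::vector<double> &out) {
  std::fill(out.begin(), out.begin() + ng, 0.0);
  const double inv2h2 = 1.0 / (2.0 * h * h);
  const double C = std::exp(-s * s * inv2h2);
  const double D = C * C;
  const double radius = truncate_sd * h;
  double *o = out.data();
  for (size_t i = 0; i < pos.size(); ++i) {
    const double p = pos[i];
    long jc = lround((p - 1.0) / s);
    if (jc < 0) jc = 0;
    if (jc > ng - 1) jc = ng - 1;
    long jlo = (long)std::ceil((p - radius - 1.0) / s);
    long jhi = (long)std::floor((p + radius - 1.0) / s);
    if (jlo < 0) jlo = 0;
    if (jhi > ng - 1) jhi = ng - 1;
    if (jlo > jhi) continue;
    if (jc < jlo) jc = jlo;
    if (jc > jhi) jc = jhi;
    const double dc = 1.0 + jc * s - p;
    const double Kc = std::exp(-dc * dc * inv2h2);
    const double rc = std::exp(-dc * s * 2.0 * inv2h2);
    o[jc] += Kc;
    double K = Kc, r = rc;
    for (long j = jc + 1; j <= jhi; ++j) {
      K *= C * r;
      r *= D;
      o[j] += K;
    }
    K = Kc; r = rc;
    for (long j = jc - 1; j >= jlo; --j) {
      K *= C / r;
      r /= D;
      o[j] += K;
    }
  }
}

// [[Rcpp::export]]
List cpp_null_peaks(List ttaa_positions, IntegerVector n_by_chrom,
                    NumericVector chrom_lengths, NumericVector scales,
                    double grid_step_fraction, double truncate_sd,
                    int n_perm, int min_insertions, bool chrom_matched) {
  RNGScope scope;
  const int n_chrom = ttaa_positions.size();
  const int n_scales = scales.size();
  std::vector<std::vector<double> > ttaa(n_chrom);
  std::vector<double> cum_ttaa(n_chrom + 1, 0.0);
  for (int c = 0; c < n_chrom; ++c) {
    ttaa[c] = as<std::vector<double> >(ttaa_positions[c]);
    cum_ttaa[c + 1] = cum_ttaa[c] + (double)ttaa[c].size();
  }
  int n_total = 0, max_ng = 0;
  for (int c = 0; c < n_chrom; ++c) n_total += n_by_chrom[c];
  for (int c = 0; c < n_chrom; ++c) {
    const int ng = (int)std::floor((chrom_lengths[c] - 1.0) /
                                   (grid_step_fraction * scales[0])) + 1;
    if (ng > max_ng) max_ng = ng;
  }
  std::vector<double> prof(max_ng);
  std::vector<std::vector<double> > pooled(n_scales);
  NumericMatrix max_per_rep(n_perm, n_scales);
  IntegerMatrix peaks_per_rep(n_perm, n_scales);
  std::vector<std::vector<double> > pos(n_chrom);
  for (int rep = 0; rep < n_perm; ++rep) {
    for (int c = 0; c < n_chrom; ++c) pos[c].clear();
    if (chrom_matched) {
      for (int c = 0; c < n_chrom; ++c) {
        const int nc = n_by_chrom[c], nt = (int)ttaa[c].size();
        pos[c].reserve(nc);
        for (int k = 0; k < nc; ++k) {
          int idx = (int)(unif_rand() * nt);
          if (idx >= nt) idx = nt - 1;
          pos[c].push_back(ttaa[c][idx]);
        }
      }
    } else {
      for (int k = 0; k < n_total; ++k) {
        double u = unif_rand() * cum_ttaa[n_chrom];
        int c = (int)(std::upper_bound(cum_ttaa.begin(), cum_ttaa.end(), u) -
                      cum_ttaa.begin()) - 1;
        if (c >= n_chrom) c = n_chrom - 1;
        pos[c].push_back(ttaa[c][(size_t)(u - cum_ttaa[c])]);
      }
    }
    for (int c = 0; c < n_chrom; ++c) std::sort(pos[c].begin(), pos[c].end());
    for (int si = 0; si < n_scales; ++si) {
      const double h = scales[si], s = grid_step_fraction * h;
      double repmax = 0.0;
      int npk = 0;
      for (int c = 0; c < n_chrom; ++c) {
        if (pos[c].empty()) continue;
        const int ng = (int)std::floor((chrom_lengths[c] - 1.0) / s) + 1;
        kd_grid_buf(pos[c], h, s, ng, truncate_sd, prof);
        // local maxima (plateaus -> leftmost), fused with member counting
        int i = 0;
        while (i < ng) {
          int j = i;
          while (j + 1 < ng && prof[j + 1] == prof[i]) ++j;
          const bool left_ok = (i == 0) || (prof[i - 1] < prof[i]);
          const bool right_ok = (j == ng - 1) || (prof[j + 1] < prof[i]);
          if (left_ok && right_ok) {
            const double apex = 1.0 + (double)i * s;
            const long n_in =
              std::upper_bound(pos[c].begin(), pos[c].end(), apex + h) -
              std::lower_bound(pos[c].begin(), pos[c].end(), apex - h);
            if (n_in >= min_insertions) {
              pooled[si].push_back(prof[i]);
              ++npk;
              if (prof[i] > repmax) repmax = prof[i];
            }
          }
          i = j + 1;
        }
      }
      max_per_rep(rep, si) = repmax;
      peaks_per_rep(rep, si) = npk;
    }
  }
  List heights(n_scales);
  for (int si = 0; si < n_scales; ++si) heights[si] = wrap(pooled[si]);
  return List::create(_["heights"] = heights, _["max_per_rep"] = max_per_rep,
                      _["peaks_per_rep"] = peaks_per_rep);
}

// Read-count-weighted variant of cpp_kernel_density: each insertion
// contributes weight_i instead of 1.
// [[Rcpp::export]]
NumericVector cpp_kd_weighted(NumericVector positions, NumericVector weights,
                              double h, NumericVector eval_points,
                              double truncate_sd) {
  const R_xlen_t n = positions.size(), m = eval_points.size();
  NumericVector out(m);
  const double inv2h2 = 1.0 / (2.0 * h * h);
  const bool trunc = R_finite(truncate_sd);
  const double radius = trunc ? truncate_sd * h : 0.0;
  R_xlen_t lo = 0, hi = 0;
  for (R_xlen_t j = 0; j < m; ++j) {
    const double x = eval_points[j];
    double s = 0.0;
    R_xlen_t i0 = 0, i1 = n;
    if (trunc) {
      while (lo < n && positions[lo] < x - radius) ++lo;
      if (hi < lo) hi = lo;
      while (hi < n && positions[hi] <= x + radius) ++hi;
      i0 = lo; i1 = hi;
    }
    for (R_xlen_t i = i0; i < i1; ++i) {
      const double d = x - positions[i];
      s += weights[i] * std::exp(-d * d * inv2h2);
    }
    out[j] = s;
  }
  return out;
}
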