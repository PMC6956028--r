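#include <Rcpp.h>
#include <algorithm>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Statistic codes shared with R (see stat_code() in R/signatures.R):
// 1 mean, 2 stdev (population), 3 median, 4 mad (median absolute
// deviation, unscaled), 5 skewness (m3/m2^1.5), 6 excess kurtosis
// (m4/m2^2 - 3). Degenerate neighborhoods (constant or single voxel)
// yield 0 for codes 2, 4, 5 and 6.

// median by partial selection; reorders b
static double buf_median(std::vector<double>& b) {
  const size_t n = b.size();
  std::nth_element(b.begin(), b.begin() + n / 2, b.end());
  const double hi = b[n / 2];
  if (n % 2 == 1) return hi;
  const double lo = *std::max_element(b.begin(), b.begin() + n / 2);
  return 0.5 * (lo + hi);
}

// Local statistics over spherical neighborhoods, truncated at the image
// boundary. `vol` is a 3D array in column-major order with dimensions
// `dim`; `offsets` holds integer voxel offsets (one row per neighbor,
// including the center); `voxels` holds 0-based linear indices of the
// voxels to evaluate; `stats` holds statistic codes. Returns a
// length(voxels) x length(stats) matrix.
// [[Rcpp::export]]
NumericMatrix local_stats_cpp(NumericVector vol, IntegerVector dim,
                              IntegerMatrix offsets, IntegerVector stats,
                              IntegerVector voxels) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const int noff = offsets.nrow(), nstat = stats.size();
  const R_xlen_t nvox = voxels.size();
  NumericMatrix out(nvox, nstat);

  bool need_sort = false, need_moments = false;
  for (int s = 0; s < nstat; ++s) {
    if (stats[s] == 3 || stats[s] == 4) need_sort = true;
    if (stats[s] == 2 || stats[s] == 5 || stats[s] == 6) need_moments = true;
  }

  std::vector<int> dx(noff), dy(noff), dz(noff);
  for (int o = 0; o < noff; ++o) {
    dx[o] = offsets(o, 0);
    dy[o] = offsets(o, 1);
    dz[o] = offsets(o, 2);
  }

  std::vector<double> buf;
  buf.reserve(noff);
  std::vector<double> sorted;

  for (R_xlen_t v = 0; v < nvox; ++v) {
    const int idx = voxels[v];
    const int i = idx % nx;
    const int j = (idx / nx) % ny;
    const int k = idx / (nx * ny);

    buf.clear();
    double sum = 0.0;
    for (int o = 0; o < noff; ++o) {
      const int ii = i + dx[o], jj = j + dy[o], kk = k + dz[o];
      if (ii < 0 || ii >= nx || jj < 0 || jj >= ny || kk < 0 || kk >= nz)
        continue;
      const double val = vol[ii + (R_xlen_t)nx * (jj + (R_xlen_t)ny * kk)];
      buf.push_back(val);
      sum += val;
    }
    const int n = (int)buf.size();
    const double mean = sum / n;

    double m2 = 0.0, m3 = 0.0, m4 = 0.0;
    if (need_moments) {
      for (int o = 0; o < n; ++o) {
        const double d = buf[o] - mean;
        const double d2 = d * d;
        m2 += d2;
        m3 += d2 * d;
        m4 += d2 * d2;
      }
      m2 /= n; m3 /= n; m4 /= n;
    }

    double med = 0.0, mad = 0.0;
    if (need_sort) {
      sorted = buf;
      med = buf_median(sorted);
      for (int o = 0; o < n; ++o) sorted[o] = std::fabs(buf[o] - med);
      mad = buf_median(sorted);
    }

    for (int s = 0; s < nstat; ++s) {
      double val;
      switch (stats[s]) {
      case 1: val = mean; break;
      case 2: val = std::sqrt(m2); break;
      case 3: val = med; break;
      case 4: val = mad; break;
      case 5: val = (m2 > 0.0) ? m3 / std::pow(m2, 1.5) : 0.0; break;
      case 6: val = (m2 > 0.0) ? m4 / (m2 * m2) - 3.0 : 0.0; break;
      default: stop("unknown statistic code");
      }
      out(v, s) = val;
    }
  }
  return out;
}

// Connected-component labelling of a binary 3D array under 6-, 18- or
// 26-connectivity. Returns an integer array of labels, 0 for background.
// [[Rcpp::export]]
IntegerVector label_components_cpp(IntegerVector mask, IntegerVector dim,
                                   int connectivity) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;

  std::vector<int> ox, oy, oz;
  for (int a = -1; a <= 1; ++a)
    for (int b = -1; b <= 1; ++b)
      for (int c = -1; c <= 1; ++c) {
        const int m = std::abs(a) + std::abs(b) + std::abs(c);
        if (m == 0) continue;
        if (connectivity == 6 && m > 1) continue;
        if (connectivity == 18 && m > 2) continue;
        ox.push_back(a); oy.push_back(b); oz.push_back(c);
      }
  const int noff = (int)ox.size();

  IntegerVector labels(n, 0);
  std::vector<R_xlen_t> queue;
  int next_label = 0;

  for (R_xlen_t start = 0; start < n; ++start) {
    if (!mask[start] || labels[start]) continue;
    ++next_label;
    labels[start] = next_label;
    queue.clear();
    queue.push_back(start);
    while (!queue.empty()) {
      const R_xlen_t cur = queue.back();
      queue.pop_back();
      const int i = cur % nx;
      const int j = (cur / nx) % ny;
      const int k = cur / ((R_xlen_t)nx * ny);
      for (int o = 0; o < noff; ++o) {
        const int ii = i + ox[o], jj = j + oy[o], kk = k + oz[o];
        if (ii < 0 || ii >= nx || jj < 0 || jj >= ny || kk < 0 || kk >= nz)
          continue;
        const R_xlen_t nb = ii + (R_xlen_t)nx * (jj + (R_xlen_t)ny * kk);
        if (mask[nb] && !labels[nb]) {
          labels[nb] = next_label;
          queue.push_back(nb);
        }
      }
    }
  }
  labels.attr("dim") = dim;
  return labels;
}
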