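#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// 6-connected neighbourhood offsets are generated on the fly from x/y/z
// coordinates with bounds checks; volumes are column-major 3-D arrays.

static inline void push_neighbours(int c, int nx, int ny, int nz,
                                   std::vector<int> &out) {
  out.clear();
  int x = c % nx, y = (c / nx) % ny, z = c / (nx * ny);
  if (x > 0) out.push_back(c - 1);
  if (x < nx - 1) out.push_back(c + 1);
  if (y > 0) out.push_back(c - nx);
  if (y < ny - 1) out.push_back(c + nx);
  if (z > 0) out.push_back(c - nx * ny);
  if (z < nz - 1) out.push_back(c + nx * ny);
}

// Label 6-connected components of supra-threshold voxels.
// Returns labels (0 = background, 1..k) and component sizes.
// [[Rcpp::export]]
List label_clusters_cpp(LogicalVector supra, IntegerVector dims) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  int n = nx * ny * nz;
  IntegerVector labels(n, 0);
  std::vector<double> sizes;
  std::vector<int> stack, nb;
  int ncomp = 0;
  for (int i = 0; i < n; ++i) {
    if (supra[i] == TRUE && labels[i] == 0) {
      ++ncomp;
      int sz = 0;
      stack.clear();
      stack.push_back(i);
      labels[i] = ncomp;
      while (!stack.empty()) {
        int c = stack.back();
        stack.pop_back();
        ++sz;
        push_neighbours(c, nx, ny, nz, nb);
        for (size_t j = 0; j < nb.size(); ++j) {
          int m = nb[j];
          if (supra[m] == TRUE && labels[m] == 0) {
            labels[m] = ncomp;
            stack.push_back(m);
          }
        }
      }
      sizes.push_back((double)sz);
    }
  }
  labels.attr("dim") = dims;
  return List::create(_["labels"] = labels, _["sizes"] = wrap(sizes));
}

// Threshold-free cluster enhancement of the positive tail of `vol`:
// per voxel, sum over thresholds h = dh, 2*dh, ..., max of
// extent(h)^E * h^H * dh, where extent(h) is the size of the voxel's
// 6-connected supra-threshold (>= h) component. Negative values are
// ignored; callers handle the negative tail by passing -vol.
// [[Rcpp::export]]
NumericVector tfce_cpp(NumericVector vol, IntegerVector dims,
                       double H, double E, int n_steps) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  int n = nx * ny * nz;
  NumericVector out(n);
  double mx = 0.0;
  for (int i = 0; i < n; ++i) {
    double v = vol[i];
    if (!NumericVector::is_na(v) && v > mx) mx = v;
  }
  if (mx <= 0.0 || n_steps < 1) {
    out.attr("dim") = dims;
    return out;
  }
  double dh = mx / n_steps;
  std::vector<int> labels(n), stack, nb, members;
  for (int step = 1; step <= n_steps; ++step) {
    double h = step * dh;
    std::fill(labels.begin(), labels.end(), 0);
    for (int i = 0; i < n; ++i) {
      double vi = vol[i];
      if (NumericVector::is_na(vi) || vi < h || labels[i] != 0) continue;
      members.clear();
      stack.clear();
      stack.push_back(i);
      labels[i] = 1;
      while (!stack.empty()) {
        int c = stack.back();
        stack.pop_back();
        members.push_back(c);
        push_neighbours(c, nx, ny, nz, nb);
        for (size_t j = 0; j < nb.size(); ++j) {
          int m = nb[j];
          double vm = vol[m];
          if (!NumericVector::is_na(vm) && vm >= h && labels[m] == 0) {
            labels[m] = 1;
            stack.push_back(m);
          }
        }
      }
      double add = std::pow((double)members.size(), E) * std::pow(h, H) * dh;
      for (size_t j = 0; j < members.size(); ++j) out[members[j]] += add;
    }
  }
  out.attr("dim") = dims;
  return out;
}
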