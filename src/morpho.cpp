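#include <Rcpp.h>
#include <vector>
#include <cmath>

using namespace Rcpp;

// 26-connected labelling of a 3-D logical mask; returns the largest
// connected component as a logical vector of the same length.
// [[Rcpp::export]]
LogicalVector cc_largest_cpp(LogicalVector mask, IntegerVector dim) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  const int *msk = LOGICAL(mask);
  std::vector<int> label(n, 0);
  int ncomp = 0;
  R_xlen_t best_size = 0;
  int best_label = 0;
  std::vector<R_xlen_t> stack;
  const R_xlen_t sz = (R_xlen_t)nx * ny;

  for (R_xlen_t s = 0; s < n; ++s) {
    if (!msk[s] || label[s] != 0) continue;
    ++ncomp;
    R_xlen_t size = 0;
    stack.clear();
    stack.push_back(s);
    label[s] = ncomp;
    while (!stack.empty()) {
      R_xlen_t v = stack.back();
      stack.pop_back();
      ++size;
      int x = (int)(v % nx);
      int y = (int)((v / nx) % ny);
      int z = (int)(v / sz);
      for (int dz = -1; dz <= 1; ++dz) {
        int zz = z + dz;
        if (zz < 0 || zz >= nz) continue;
        for (int dy = -1; dy <= 1; ++dy) {
          int yy = y + dy;
          if (yy < 0 || yy >= ny) continue;
          const R_xlen_t base = (R_xlen_t)nx * (yy + (R_xlen_t)ny * zz);
          for (int dx = -1; dx <= 1; ++dx) {
            if (dx == 0 && dy == 0 && dz == 0) continue;
            int xx = x + dx;
            if (xx < 0 || xx >= nx) continue;
            R_xlen_t w = base + xx;
            if (msk[w] && label[w] == 0) {
              label[w] = ncomp;
              stack.push_back(w);
            }
          }
        }
      }
    }
    if (size > best_size) { best_size = size; best_label = ncomp; }
  }

  LogicalVector out(n);
  int *o = LOGICAL(out);
  for (R_xlen_t i = 0; i < n; ++i)
    o[i] = (label[i] == best_label && best_label > 0);
  return out;
}

// Fill fully enclosed cavities: background is flood-filled from the volume
// border under 6-connectivity; unreached background voxels are enclosed and
// get added to the mask.
// [[Rcpp::export]]
LogicalVector fill_cavities_cpp(LogicalVector mask, IntegerVector dim) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  const R_xlen_t sz = (R_xlen_t)nx * ny;
  const int *msk = LOGICAL(mask);
  std::vector<char> outside(n, 0);
  std::vector<R_xlen_t> stack;

  for (int z = 0; z < nz; ++z)
    for (int y = 0; y < ny; ++y) {
      const R_xlen_t base = (R_xlen_t)nx * (y + (R_xlen_t)ny * z);
      const bool face = (z == 0 || z == nz - 1 || y == 0 || y == ny - 1);
      for (int x = 0; x < nx; ++x) {
        if (!face && x != 0 && x != nx - 1) continue;
        R_xlen_t v = base + x;
        if (!msk[v] && !outside[v]) { outside[v] = 1; stack.push_back(v); }
      }
    }

  while (!stack.empty()) {
    R_xlen_t v = stack.back();
    stack.pop_back();
    int x = (int)(v % nx);
    int y = (int)((v / nx) % ny);
    int z = (int)(v / sz);
    R_xlen_t w;
    if (x > 0 && !msk[w = v - 1] && !outside[w]) { outside[w] = 1; stack.push_back(w); }
    if (x < nx - 1 && !msk[w = v + 1] && !outside[w]) { outside[w] = 1; stack.push_back(w); }
    if (y > 0 && !msk[w = v - nx] && !outside[w]) { outside[w] = 1; stack.push_back(w); }
    if (y < ny - 1 && !msk[w = v + nx] && !outside[w]) { outside[w] = 1; stack.push_back(w); }
    if (z > 0 && !msk[w = v - sz] && !outside[w]) { outside[w] = 1; stack.push_back(w); }
    if (z < nz - 1 && !msk[w = v + sz] && !outside[w]) { outside[w] = 1; stack.push_back(w); }
  }

  LogicalVector out(n);
  int *o = LOGICAL(out);
  for (R_xlen_t i = 0; i < n; ++i) o[i] = msk[i] || !outside[i];
  return out;
}

// convolve every line along one axis with a symmetric kernel, reflected
// boundaries; src/dst are distinct buffers
static void smooth_axis(const double *src, double *dst,
                        int nx, int ny, int nz, int axis,
                        const std::vector<double> &kern) {
  const int r = (int)(kern.size() / 2);
  const double *k = kern.data() + r;  // k[-r..r]
  const int dims[3] = {nx, ny, nz};
  const R_xlen_t strides[3] = {1, nx, (R_xlen_t)nx * ny};
  const int na = dims[axis];
  const R_xlen_t sa = strides[axis];
  // iterate over all lines: the two non-axis dimensions
  const int b1 = (axis == 0) ? 1 : 0;
  const int b2 = (axis == 2) ? 1 : 2;
  std::vector<double> line(na);
  for (int j2 = 0; j2 < dims[b2]; ++j2)
    for (int j1 = 0; j1 < dims[b1]; ++j1) {
      const R_xlen_t base = strides[b1] * j1 + strides[b2] * j2;
      for (int p = 0; p < na; ++p) line[p] = src[base + sa * p];
      for (int p = 0; p < na; ++p) {
        double acc = 0.0;
        if (p >= r && p < na - r) {
          for (int t = -r; t <= r; ++t) acc += k[t] * line[p + t];
        } else {
          for (int t = -r; t <= r; ++t) {
            int q = p + t;
            if (q < 0) q = -q - 1;
            else if (q >= na) q = 2 * na - q - 1;
            acc += k[t] * line[q];
          }
        }
        dst[base + sa * p] = acc;
      }
    }
}

// Separable Gaussian smoothing (sigma in voxels, reflected boundaries).
// [[Rcpp::export]]
NumericVector gaussian_smooth3_cpp(NumericVector vol, IntegerVector dim, double sigma) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  int r = (int)std::ceil(3.0 * sigma);
  if (r < 1) r = 1;
  std::vector<double> kern(2 * r + 1);
  double s = 0.0;
  for (int t = -r; t <= r; ++t) {
    kern[t + r] = std::exp(-0.5 * (t * t) / (sigma * sigma));
    s += kern[t + r];
  }
  for (size_t i = 0; i < kern.size(); ++i) kern[i] /= s;

  std::vector<double> a(REAL(vol), REAL(vol) + n), b(n);
  smooth_axis(a.data(), b.data(), nx, ny, nz, 0, kern);
  smooth_axis(b.data(), a.data(), nx, ny, nz, 1, kern);
  smooth_axis(a.data(), b.data(), nx, ny, nz, 2, kern);
  return NumericVector(b.begin(), b.end());
}

// Integral of |grad f| over the volume by central differences; with f a
// smoothed indicator this estimates the interface area (co-area formula).
// pitch: voxel pitch per axis (physical units).
// [[Rcpp::export]]
double gradient_area_cpp(NumericVector vol, IntegerVector dim, NumericVector pitch) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const double *v0 = REAL(vol);
  const double ivx = 1.0 / (2 * pitch[0]), ivy = 1.0 / (2 * pitch[1]),
               ivz = 1.0 / (2 * pitch[2]);
  const double voxvol = pitch[0] * pitch[1] * pitch[2];
  const R_xlen_t sz = (R_xlen_t)nx * ny;
  double area = 0.0;
  for (int z = 0; z < nz; ++z)
    for (int y = 0; y < ny; ++y) {
      const R_xlen_t base = (R_xlen_t)nx * (y + (R_xlen_t)ny * z);
      for (int x = 0; x < nx; ++x) {
        const R_xlen_t v = base + x;
        double gx = 0, gy = 0, gz = 0;
        if (x > 0 && x < nx - 1) gx = (v0[v + 1] - v0[v - 1]) * ivx;
        if (y > 0 && y < ny - 1) gy = (v0[v + nx] - v0[v - nx]) * ivy;
        if (z > 0 && z < nz - 1) gz = (v0[v + sz] - v0[v - sz]) * ivz;
        double g2 = gx * gx + gy * gy + gz * gz;
        if (g2 > 0) area += std::sqrt(g2) * voxvol;
      }
    }
  return area;
}

// ---------------------------------------------------------------------------
// k-NN with a fully deterministic tie rule:
//   1) majority vote among the k nearest (distance ties broken by row index);
//   2) vote ties: smallest summed neighbour distance among tied classes;
//   3) then: closest single neighbour among tied classes;
//   4) then: smallest class index (labels are 1..C in sorted label order).
static int knn_one(const double *train, int ntrain, int p,
                   const int *labels, int nclass,
                   const double *q, int k,
                   std::vector<std::pair<double, int> > &d) {
  for (int i = 0; i < ntrain; ++i) {
    double acc = 0.0;
    for (int j = 0; j < p; ++j) {
      double t = train[i + (R_xlen_t)j * ntrain] - q[j];
      acc += t * t;
    }
    d[i] = std::make_pair(acc, i);
  }
  if (k > ntrain) k = ntrain;
  std::partial_sort(d.begin(), d.begin() + k, d.begin() + ntrain);
  std::vector<int> votes(nclass, 0);
  std::vector<double> dsum(nclass, 0.0);
  std::vector<double> dmin(nclass, R_PosInf);
  for (int i = 0; i < k; ++i) {
    int c = labels[d[i].second] - 1;
    votes[c] += 1;
    double dist = std::sqrt(d[i].first);
    dsum[c] += dist;
    if (dist < dmin[c]) dmin[c] = dist;
  }
  int best = -1;
  for (int c = 0; c < nclass; ++c) {
    if (votes[c] == 0) continue;
    if (best < 0) { best = c; continue; }
    if (votes[c] > votes[best]) best = c;
    else if (votes[c] == votes[best]) {
      if (dsum[c] < dsum[best]) best = c;
      else if (dsum[c] == dsum[best] && dmin[c] < dmin[best]) best = c;
      // equal on all: keep the smaller class index (best is already smaller)
    }
  }
  return best + 1;
}

// [[Rcpp::export]]
IntegerVector knn_predict_cpp(NumericMatrix train, IntegerVector labels,
                              NumericMatrix query, int k, int nclass) {
  const int ntrain = train.nrow(), p = train.ncol(), nq = query.nrow();
  IntegerVector out(nq);
  std::vector<double> q(p);
  std::vector<std::pair<double, int> > scratch(ntrain);
  for (int i = 0; i < nq; ++i) {
    for (int j = 0; j < p; ++j) q[j] = query(i, j);
    out[i] = knn_one(REAL(train), ntrain, p, INTEGER(labels), nclass,
                     q.data(), k, scratch);
  }
  return out;
}

// Accuracy of k-NN prediction for many column subsets at once.
// subsets: list of 1-based column index vectors into train/query.
// [[Rcpp::export]]
NumericVector knn_subset_accuracy_cpp(NumericMatrix train, IntegerVector labels,
                                      NumericMatrix query, IntegerVector qlabels,
                                      List subsets, int k, int nclass) {
  const int ntrain = train.nrow(), nq = query.nrow();
  const int ns = subsets.size();
  NumericVector out(ns);
  std::vector<std::pair<double, int> > scratch(ntrain);
  for (int s = 0; s < ns; ++s) {
    IntegerVector cols = subsets[s];
    const int p = cols.size();
    std::vector<double> tr((R_xlen_t)ntrain * p), q(p);
    for (int j = 0; j < p; ++j) {
      int cj = cols[j] - 1;
      const double *col = &train(0, cj);
      std::copy(col, col + ntrain, tr.data() + (R_xlen_t)j * ntrain);
    }
    int correct = 0;
    for (int i = 0; i < nq; ++i) {
      for (int j = 0; j < p; ++j) q[j] = query(i, cols[j] - 1);
      int pred = knn_one(tr.data(), ntrain, p, INTEGER(labels), nclass,
                         q.data(), k, scratch);
      if (pred == qlabels[i]) ++correct;
    }
    out[s] = nq > 0 ? (double)correct / nq : NA_REAL;
  }
  return out;
}
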